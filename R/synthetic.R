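#' Specification for a synthetic forum corpus
#'
#' Describes the structure of a generated peer-support forum corpus with
#' planted ground truth: `K_true` topics over a shared synthetic
#' vocabulary, near-single-topic posts (small `doc_topic_concentration`),
#' a large stratum of very short salutation posts, a sprinkling of posts
#' salted with genuinely valence-bearing terms plus social-media emphasis
#' (ALL-CAPS, punctuation runs), and flagged staff/test posts. Post lengths
#' follow a discretized log-normal with a short-spike salutation stratum,
#' emulating forum corpora in which roughly half the content is brief
#' greetings and check-ins.
#'
#' @param K_true Number of planted topics (>= 1).
#' @param vocab_size Synthetic topical vocabulary size (>= 5 * `K_true`).
#' @param doc_topic_concentration Symmetric Dirichlet parameter for per-post
#'   topic mixtures; small values (default 0.05) give near-single-topic
#'   posts.
#' @param topic_vocab_overlap Fraction of the vocabulary shared by all
#'   topics (default 0.1); the rest is split into topic-exclusive blocks.
#' @param n_posts Total posts to generate.
#' @param salutation_fraction Share of very short greeting posts
#'   (default 0.45).
#' @param pos_inject_fraction,neg_inject_fraction Shares of posts salted
#'   with strong positive / negative valence terms (default 0.10 each).
#' @param staff_fraction Share of flagged staff/test posts (default 0.02).
#' @param length_meanlog,length_sdlog Log-normal parameters for topical
#'   post lengths in tokens (defaults `log(18)`, 0.6: short posts with a
#'   long tail, median ~18 tokens).
#' @param seed Integer seed; the same spec and seed give a byte-identical
#'   corpus.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(K_true = 3, vocab_size = 500,
                           doc_topic_concentration = 0.05,
                           topic_vocab_overlap = 0.1,
                           n_posts = 2000,
                           salutation_fraction = 0.45,
                           pos_inject_fraction = 0.10,
                           neg_inject_fraction = 0.10,
                           staff_fraction = 0.02,
                           length_meanlog = log(18), length_sdlog = 0.6,
                           seed = 1L) {
  stopifnot(K_true >= 1, n_posts >= 0, doc_topic_concentration > 0,
            topic_vocab_overlap >= 0, topic_vocab_overlap <= 1)
  fracs <- c(salutation_fraction, pos_inject_fraction, neg_inject_fraction,
             staff_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (salutation_fraction + staff_fraction > 1) {
    stop("salutation_fraction + staff_fraction exceed 1")
  }
  if (pos_inject_fraction + neg_inject_fraction > 1) {
    stop("pos_inject_fraction + neg_inject_fraction exceed 1")
  }
  if (vocab_size < K_true * 5) {
    stop("infeasible spec: vocab_size must be at least 5 * K_true")
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

.greeting_phrases <- c(
  "good morning everyone", "hey guys", "hello all", "happy friday",
  "morning all hope everyone is well", "hey all checking in",
  "good morning have a nice day", "hello everyone happy monday",
  "hope you all have a good weekend", "hi there", "welcome aboard",
  "good evening folks", "morning thrivers", "hey hope all is well")

.pos_snippets <- c(
  "So happy and grateful, thanks everyone!!!",
  "I LOVE this, thank you so much!!!",
  "Feeling blessed and wonderful today :)",
  "This is awesome, great job!!!",
  "What a beautiful day, feeling great!!!",
  "Amazing news, so proud of you!!!",
  "Thanks for the support, you guys are the best :)",
  "WONDERFUL update, congratulations!!!")

.neg_snippets <- c(
  "I hate this, so awful!!!",
  "Feeling terrible and depressed today.",
  "This is horrible, worst day ever!!!",
  "So sad and angry right now.",
  "AWFUL news, I am devastated!!!",
  "Really stressed and anxious, everything hurts.",
  "I am so frustrated and miserable :(",
  "Terrible anxiety again, feeling hopeless.")

.rdirichlet1 <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc, rate = 1)
  if (sum(g) <= 0) {            # underflow guard at very small conc
    g <- numeric(k)
    g[sample.int(k, 1)] <- 1
  }
  g / sum(g)
}

#' Generate a synthetic forum corpus with planted truth
#'
#' Draws posts as Dirichlet-multinomial topic mixtures over synthetic
#' word-like vocabularies, adds salutation, valence-injected and staff
#' posts per the spec, and records the full planted truth (per-post
#' dominant topic, injection label, staff flag; per-topic term
#' distribution). Valence injection appends real sentiment-bearing phrases
#' so the lexicon scorer has something to react to; everything else in the
#' vocabulary is abstract and sentiment-neutral.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `posts` (a raw-post tibble as [read_forum_table()]
#'   returns) and `truth` (list: `posts` tibble with `post_id`,
#'   `true_topic` and `true_topic_weight` (NA for salutation/staff posts),
#'   `valence` (`"pos"`/`"neg"`/`"none"`), `is_staff`; `topic_term` K x V
#'   matrix; `spec`).
#' @export
generate_forum_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, .generate_impl(spec))
}

.generate_impl <- function(spec) {
  n <- spec$n_posts
  K <- spec$K_true
  V <- spec$vocab_size
  terms <- sprintf("w%04d", seq_len(V))

  # Topic-term structure: a shared slice plus topic-exclusive blocks.
  n_shared <- round(spec$topic_vocab_overlap * V)
  shared_idx <- seq_len(n_shared)
  rest <- setdiff(seq_len(V), shared_idx)
  block <- split(rest, cut(seq_along(rest), K, labels = FALSE))
  # Geometric rank decay gives each planted topic an unambiguous Zipf-like
  # signature (clearly separated top-token masses), so recovery metrics
  # measure recovery rather than near-tie rank noise. The shared slice
  # carries one weight profile common to all topics, scaled to a fraction
  # `topic_vocab_overlap` of each topic's mass: the overlap parameter
  # thereby controls how similar -- and so how confusable -- the planted
  # topics are.
  geom_profile <- function(idx) {
    w <- 0.85^seq_along(idx)
    setNames(w / sum(w), idx)
  }
  phi <- matrix(0, K, V, dimnames = list(NULL, terms))
  shared_w <- if (n_shared > 0) geom_profile(sample(shared_idx)) else NULL
  ov <- spec$topic_vocab_overlap
  for (k in seq_len(K)) {
    excl_w <- geom_profile(sample(block[[k]]))
    phi[k, as.integer(names(excl_w))] <- (1 - ov) * excl_w
    if (n_shared > 0) {
      phi[k, as.integer(names(shared_w))] <- ov * shared_w
    }
  }

  if (n == 0) {
    empty_posts <- tibble::tibble(
      post_id = character(), parent_id = character(),
      author_id = character(), timestamp = as.POSIXct(character()),
      text = character(), is_staff = logical())
    return(list(posts = empty_posts,
                truth = list(posts = tibble::tibble(
                  post_id = character(), true_topic = integer(),
                  true_topic_weight = double(),
                  valence = character(), is_staff = logical()),
                  topic_term = phi, spec = spec)))
  }

  n_staff <- round(spec$staff_fraction * n)
  n_sal <- min(round(spec$salutation_fraction * n), n - n_staff)
  role <- rep("topical", n)
  shuffled <- sample.int(n)
  role[shuffled[seq_len(n_staff)]] <- "staff"
  if (n_sal > 0) role[shuffled[n_staff + seq_len(n_sal)]] <- "salutation"

  true_topic <- rep(NA_integer_, n)
  true_topic_weight <- rep(NA_real_, n)
  text <- character(n)
  for (i in seq_len(n)) {
    if (role[i] == "staff") {
      text[i] <- paste("test post please ignore", sample.int(1000, 1))
    } else if (role[i] == "salutation") {
      text[i] <- sample(.greeting_phrases, 1)
    } else {
      theta <- .rdirichlet1(K, spec$doc_topic_concentration)
      true_topic[i] <- which.max(theta)
      true_topic_weight[i] <- max(theta)
      len <- max(3L, round(stats::rlnorm(1, spec$length_meanlog,
                                         spec$length_sdlog)))
      z <- sample.int(K, len, replace = TRUE, prob = theta)
      toks <- vapply(z, function(k) {
        terms[sample.int(V, 1, prob = phi[k, ])]
      }, character(1))
      text[i] <- paste(toks, collapse = " ")
    }
  }

  # Valence injection among non-staff posts, pos and neg sets disjoint.
  eligible <- which(role != "staff")
  n_pos <- min(round(spec$pos_inject_fraction * n), length(eligible))
  pos_ids <- if (n_pos > 0) sample(eligible, n_pos) else integer()
  remaining <- setdiff(eligible, pos_ids)
  n_neg <- min(round(spec$neg_inject_fraction * n), length(remaining))
  neg_ids <- if (n_neg > 0) sample(remaining, n_neg) else integer()
  valence <- rep("none", n)
  valence[pos_ids] <- "pos"
  valence[neg_ids] <- "neg"
  for (i in pos_ids) text[i] <- paste(text[i], sample(.pos_snippets, 1))
  for (i in neg_ids) text[i] <- paste(text[i], sample(.neg_snippets, 1))

  post_id <- sprintf("p%05d", seq_len(n))
  author <- ifelse(role == "staff",
                   "staff_tester",
                   sample(sprintf("user%02d", 1:40), n, replace = TRUE))
  t0 <- as.POSIXct("2016-10-01 08:00:00", tz = "UTC")
  timestamp <- t0 + cumsum(sample.int(180, n, replace = TRUE)) * 60
  parent <- character(n)
  for (i in seq_len(n)) {
    if (i > 1 && stats::runif(1) < 0.3) {
      parent[i] <- post_id[sample.int(i - 1, 1)]
    }
  }

  posts <- tibble::tibble(
    post_id = post_id, parent_id = parent, author_id = author,
    timestamp = timestamp, text = text, is_staff = role == "staff")
  truth_posts <- tibble::tibble(
    post_id = post_id, true_topic = true_topic,
    true_topic_weight = true_topic_weight, valence = valence,
    is_staff = role == "staff")
  list(posts = posts,
       truth = list(posts = truth_posts, topic_term = phi, spec = spec))
}

.permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- .permutations(k - 1)
  out <- vector("list", k * length(sub))
  idx <- 1
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[idx]] <- append(p, k, after = pos - 1)
      idx <- idx + 1
    }
  }
  out
}

#' Match fitted topics to planted topics
#'
#' Finds the permutation of fitted topics minimizing the total base-2
#' Jensen-Shannon divergence to the planted topic-term rows, comparing
#' distributions over the union of the two term supports. Exhaustive over
#' permutations, supported for K <= 6.
#'
#' @param fitted A [fit_lda()] model with `K` equal to the planted
#'   `K_true`.
#' @param truth The `truth` element of [generate_forum_corpus()].
#' @return A list with `permutation` (index `j` gives the fitted topic
#'   matched to planted topic `j`), `mean_jsd` (mean matched divergence)
#'   and `jsd_matrix` (fitted x planted).
#' @export
match_topics <- function(fitted, truth) {
  K <- fitted$K
  if (K != nrow(truth$topic_term)) {
    stop("fitted K (", K, ") differs from planted K_true (",
         nrow(truth$topic_term), ")")
  }
  if (K > 6) stop("exhaustive matching supported for K <= 6")
  vocab <- union(colnames(fitted$topic_term), colnames(truth$topic_term))
  expand <- function(m) {
    out <- matrix(0, nrow(m), length(vocab),
                  dimnames = list(NULL, vocab))
    out[, colnames(m)] <- m
    out
  }
  fm <- expand(fitted$topic_term)
  tm <- expand(truth$topic_term)
  jsd <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      jsd[i, j] <- js_divergence(fm[i, ], tm[j, ])
    }
  }
  perms <- .permutations(K)
  costs <- vapply(perms, function(p) {
    sum(jsd[cbind(p, seq_len(K))])
  }, numeric(1))
  best <- perms[[which.min(costs)]]
  list(permutation = as.integer(best), mean_jsd = min(costs) / K,
       jsd_matrix = jsd)
}

#' Recovery metrics against the planted truth
#'
#' Quantifies how well a fitted model recovered the plant: mean matched
#' topic-term Jensen-Shannon divergence (0 = perfect), mean Jaccard overlap
#' of the matched top-10 token lists, dominant-topic assignment accuracy
#' over posts with a planted topic, and -- when condensed sentiment strata
#' are supplied -- the recall and precision of the valence-injected posts
#' within the retained (+)Pos / (-)Neg strata.
#'
#' @param fitted A [fit_lda()] model.
#' @param truth The `truth` element of [generate_forum_corpus()].
#' @param assignment Named vector from [assign_dominant_topic()].
#' @param sentiment_strata Optional list from
#'   [condense_sentiment_strata()].
#' @param match Optional precomputed [match_topics()] result.
#' @return A list of metrics, each in \[0, 1\].
#' @export
recovery_metrics <- function(fitted, truth, assignment,
                             sentiment_strata = NULL, match = NULL) {
  if (is.null(match)) match <- match_topics(fitted, truth)
  K <- fitted$K
  perm <- match$permutation
  inv <- order(perm)  # fitted topic f -> planted topic inv[f]

  fit_top <- top_tokens(fitted, n = min(10, length(fitted$terms)))
  true_top <- lapply(seq_len(K), function(k) {
    p <- truth$topic_term[k, ]
    ord <- order(-p, names(p), method = "radix")
    names(p)[ord][seq_len(min(10, sum(p > 0)))]
  })
  jaccard <- vapply(seq_len(K), function(j) {
    a <- fit_top[[perm[j]]]
    b <- true_top[[j]]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))

  tp <- setNames(truth$posts$true_topic, truth$posts$post_id)
  ids <- intersect(names(assignment), names(tp)[!is.na(tp)])
  accuracy <- if (length(ids) == 0) NA_real_ else {
    mean(inv[assignment[ids]] == tp[ids])
  }

  out <- list(mean_matched_jsd = match$mean_jsd,
              mean_top10_jaccard = mean(jaccard),
              dominant_topic_accuracy = accuracy)
  if (!is.null(sentiment_strata)) {
    lab <- setNames(truth$posts$valence, truth$posts$post_id)
    for (side in c("pos", "neg")) {
      retained <- sentiment_strata[[side]]$retained_ids
      injected <- names(lab)[lab == side]
      out[[paste0(side, "_stratum_recall")]] <-
        if (length(injected)) length(intersect(retained, injected)) /
          length(injected) else NA_real_
      out[[paste0(side, "_stratum_precision")]] <-
        if (length(retained)) length(intersect(retained, injected)) /
          length(retained) else NA_real_
    }
  }
  out
}
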
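#' Fit a latent Dirichlet allocation topic model
#'
#' Fits LDA by collapsed Gibbs sampling. Documents that are empty after
#' pruning are excluded from the fit (and listed in the returned object) but
#' remain part of the corpus with a null topic: very short salutation posts
#' routinely normalize to nothing. The posterior point estimates of the
#' topic-term matrix and the document-topic mixtures are averages over the
#' post-burn-in sweeps. The sampler uses its own counter-based generator, so
#' a fixed `seed` gives bit-identical output regardless of R's RNG state.
#'
#' @param docs Named list of pruned token vectors (see [build_vocabulary()]).
#' @param K Number of topics (integer >= 1), a model *input*: the pipeline
#'   emits diagnostics over a configured K range rather than auto-selecting.
#' @param alpha Document-topic Dirichlet concentration; default `1/K`.
#' @param eta Topic-term Dirichlet concentration; default `1/K`.
#' @param n_iter Number of Gibbs sweeps (default 500).
#' @param burnin Sweeps discarded before averaging (default `n_iter %/% 2`).
#' @param seed Integer seed for the sampler.
#' @param n_restarts Independent chains run from seeds derived
#'   deterministically from `seed`; the chain with the highest in-sample
#'   log-likelihood is kept (default 3). Collapsed Gibbs on corpora of
#'   near-single-topic documents occasionally sticks in a mode where two
#'   topics merge; restarts make the fit robust to that.
#'
#' @return An object of class `topic_model`: a list with `K`, `topic_term`
#'   (K x V matrix, rows sum to 1, columns named by term), `doc_topic`
#'   (D x K matrix, rows named by post id, rows sum to 1), `terms`,
#'   `excluded_docs` (ids empty after pruning), `alpha`, `eta`, `n_iter`,
#'   `burnin`, `seed`, `log_likelihood`.
#' @export
fit_lda <- function(docs, K, alpha = 1 / K, eta = 1 / K,
                    n_iter = 500, burnin = n_iter %/% 2, seed = 1L,
                    n_restarts = 3) {
  if (K < 1) stop("K must be >= 1")
  lens <- lengths(docs)
  excluded <- names(docs)[lens == 0]
  fit_docs <- docs[lens > 0]
  if (length(fit_docs) == 0) stop("no non-empty documents to fit")
  if (K > length(fit_docs)) {
    warning("K (", K, ") exceeds the number of non-empty documents (",
            length(fit_docs), ")")
  }
  terms <- unique(unlist(fit_docs, use.names = FALSE))
  word_index <- setNames(seq_along(terms) - 1L, terms)
  doc_vec <- rep(seq_along(fit_docs) - 1L, lengths(fit_docs))
  word_vec <- unname(word_index[unlist(fit_docs, use.names = FALSE)])

  loglik <- function(phi, theta) {
    ll <- 0
    for (d in seq_along(fit_docs)) {
      w <- word_index[fit_docs[[d]]] + 1L
      ll <- ll + sum(log(as.vector(theta[d, , drop = FALSE] %*%
                                     phi[, w, drop = FALSE])))
    }
    ll
  }

  best <- NULL
  for (r in seq_len(max(1, n_restarts))) {
    chain_seed <- (as.double(seed) + (r - 1) * 1000003) %% 2147483647
    res <- lda_gibbs_cpp(doc_vec, word_vec,
                         n_docs = length(fit_docs),
                         n_vocab = length(terms),
                         K = as.integer(K), alpha = alpha, eta = eta,
                         n_iter = as.integer(n_iter),
                         burnin = as.integer(burnin), seed = chain_seed)
    ll <- loglik(res$phi, res$theta)
    if (is.null(best) || ll > best$ll) best <- list(res = res, ll = ll)
  }
  phi <- best$res$phi
  colnames(phi) <- terms
  theta <- best$res$theta
  rownames(theta) <- names(fit_docs)
  structure(
    list(K = as.integer(K), topic_term = phi, doc_topic = theta,
         terms = terms, excluded_docs = excluded,
         alpha = alpha, eta = eta, n_iter = n_iter, burnin = burnin,
         seed = seed, n_restarts = n_restarts, log_likelihood = best$ll),
    class = "topic_model"
  )
}

#' @export
print.topic_model <- function(x, ...) {
  cat("<topic_model> K =", x$K, "|", nrow(x$doc_topic), "documents |",
      length(x$terms), "terms\n")
  tt <- top_tokens(x, n = 8)
  for (k in seq_len(x$K)) {
    cat("  topic ", k, ": ", paste(tt[[k]], collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Top tokens per topic
#'
#' The `n` highest-probability terms of each topic, descending, with ties
#' broken lexicographically. These ordered lists are the objects a coder
#' inspects when labeling topics, and the top-30 lists define each topic's
#' signature tokens for affinity scoring.
#'
#' @param model A [fit_lda()] model.
#' @param n Number of tokens per topic (default 30).
#' @return A list of character vectors, one per topic.
#' @export
top_tokens <- function(model, n = 30) {
  stopifnot(n >= 1)
  if (n > length(model$terms)) {
    warning("n (", n, ") exceeds vocabulary size (", length(model$terms),
            "); returning the full ordered vocabulary")
    n <- length(model$terms)
  }
  lapply(seq_len(model$K), function(k) {
    p <- model$topic_term[k, ]
    ord <- order(-p, names(p), method = "radix")
    names(p)[ord][seq_len(n)]
  })
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' Base-2 JSD, bounded in \[0, 1\]; 0 for identical distributions, 1 for
#' distributions with disjoint support.
#'
#' @param p,q Non-negative numeric vectors of equal length summing to 1.
#' @return A scalar in \[0, 1\].
#' @export
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Numeric topic-model diagnostics
#'
#' Replaces visual topic-separation inspection with numbers: the K x K
#' matrix of pairwise base-2 Jensen-Shannon divergences between topic-term
#' rows (intertopic distance), a 2-D classical multidimensional scaling of
#' that matrix (the analogue of an intertopic distance map), and per-topic
#' prevalence, i.e. each topic's expected share of corpus token mass
#' (document-topic weights weighted by document lengths). A coherent model
#' shows large pairwise divergences and non-negligible prevalence for every
#' topic.
#'
#' @param model A [fit_lda()] model.
#' @param docs The pruned token lists the model was fitted on.
#' @return A list with `jsd` (K x K symmetric, zero diagonal), `coords_2d`
#'   (K x 2 matrix), `prevalence` (length-K vector summing to 1),
#'   `mean_pairwise_jsd` and `prevalence_dispersion` (coefficient of
#'   variation across topics).
#' @export
topic_diagnostics <- function(model, docs) {
  K <- model$K
  jsd <- matrix(0, K, K)
  if (K >= 2) {
    for (i in seq_len(K - 1)) {
      for (j in seq(i + 1, K)) {
        jsd[i, j] <- jsd[j, i] <-
          js_divergence(model$topic_term[i, ], model$topic_term[j, ])
      }
    }
  }
  coords <- matrix(0, K, 2)
  if (K >= 2) {
    # degenerate eigenvalues (coincident topics) legitimately give fewer
    # than 2 usable dimensions; missing coordinates stay 0
    mds <- suppressWarnings(cmdscale(stats::as.dist(jsd),
                                     k = min(2L, K - 1L)))
    if (length(mds) > 0) coords[, seq_len(ncol(mds))] <- mds
  }
  lens <- lengths(docs[rownames(model$doc_topic)])
  mass <- colSums(model$doc_topic * lens)
  prevalence <- mass / sum(mass)
  off <- jsd[upper.tri(jsd)]
  list(
    jsd = jsd,
    coords_2d = coords,
    prevalence = prevalence,
    mean_pairwise_jsd = if (length(off)) mean(off) else 0,
    prevalence_dispersion = stats::sd(prevalence) / mean(prevalence)
  )
}

#' Dominant-topic assignment
#'
#' Maps every fitted document to the topic of maximal document-topic weight
#' (ties broken toward the lowest topic index), partitioning the modeled
#' posts among topics. Documents excluded from the fit (empty after pruning)
#' are absent from the mapping.
#'
#' @param model A [fit_lda()] model.
#' @return A named integer vector: post id -> topic index (1-based).
#' @export
assign_dominant_topic <- function(model) {
  setNames(max.col(model$doc_topic, ties.method = "first"),
           rownames(model$doc_topic))
}
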
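# Rule-based valence scorer for social-media text: an R port of the VADER
# (Valence Aware Dictionary for sEntiment Reasoner) procedure of Hutto &
# Gilbert (2014), matching the published reference rule set so that printed
# worked examples reproduce at 3-decimal precision. Scoring is applied to
# the *verbatim* SA corpus: capitalization, punctuation runs and emoticons
# are signal, not noise, and must not be normalized away.

B_INCR <- 0.293
B_DECR <- -0.293
C_INCR <- 0.733   # ALL-CAPS emphasis increment
N_SCALAR <- -0.74 # negation flip-and-damp factor

.vader_negate <- c(
  "aint", "arent", "cannot", "cant", "couldnt", "darent", "didnt", "doesnt",
  "ain't", "aren't", "can't", "couldn't", "daren't", "didn't", "doesn't",
  "dont", "hadnt", "hasnt", "havent", "isnt", "mightnt", "mustnt", "neither",
  "don't", "hadn't", "hasn't", "haven't", "isn't", "mightn't", "mustn't",
  "neednt", "needn't", "never", "none", "nope", "nor", "not", "nothing",
  "nowhere", "oughtnt", "shant", "shouldnt", "uhuh", "wasnt", "werent",
  "oughtn't", "shan't", "shouldn't", "uh-uh", "wasn't", "weren't",
  "without", "wont", "wouldnt", "won't", "wouldn't", "rarely", "seldom",
  "despite")

.vader_boosters <- c(
  "absolutely" = B_INCR, "amazingly" = B_INCR, "awfully" = B_INCR,
  "completely" = B_INCR, "considerable" = B_INCR, "considerably" = B_INCR,
  "decidedly" = B_INCR, "deeply" = B_INCR, "effing" = B_INCR,
  "enormous" = B_INCR, "enormously" = B_INCR, "entirely" = B_INCR,
  "especially" = B_INCR, "exceptional" = B_INCR, "exceptionally" = B_INCR,
  "extreme" = B_INCR, "extremely" = B_INCR, "fabulously" = B_INCR,
  "flipping" = B_INCR, "flippin" = B_INCR, "frackin" = B_INCR,
  "fracking" = B_INCR, "fricking" = B_INCR, "frickin" = B_INCR,
  "frigging" = B_INCR, "friggin" = B_INCR, "fully" = B_INCR,
  "fuckin" = B_INCR, "fucking" = B_INCR, "fuggin" = B_INCR,
  "fugging" = B_INCR, "greatly" = B_INCR, "hella" = B_INCR,
  "highly" = B_INCR, "hugely" = B_INCR, "incredible" = B_INCR,
  "incredibly" = B_INCR, "intensely" = B_INCR, "major" = B_INCR,
  "majorly" = B_INCR, "more" = B_INCR, "most" = B_INCR,
  "particularly" = B_INCR, "purely" = B_INCR, "quite" = B_INCR,
  "really" = B_INCR, "remarkably" = B_INCR, "so" = B_INCR,
  "substantially" = B_INCR, "thoroughly" = B_INCR, "total" = B_INCR,
  "totally" = B_INCR, "tremendous" = B_INCR, "tremendously" = B_INCR,
  "uber" = B_INCR, "unbelievably" = B_INCR, "unusually" = B_INCR,
  "utter" = B_INCR, "utterly" = B_INCR, "very" = B_INCR,
  "almost" = B_DECR, "barely" = B_DECR, "hardly" = B_DECR,
  "just enough" = B_DECR, "kind of" = B_DECR, "kinda" = B_DECR,
  "kindof" = B_DECR, "kind-of" = B_DECR, "less" = B_DECR,
  "little" = B_DECR, "marginal" = B_DECR, "marginally" = B_DECR,
  "occasional" = B_DECR, "occasionally" = B_DECR, "partly" = B_DECR,
  "scarce" = B_DECR, "scarcely" = B_DECR, "slight" = B_DECR,
  "slightly" = B_DECR, "somewhat" = B_DECR, "sort of" = B_DECR,
  "sorta" = B_DECR, "sortof" = B_DECR, "sort-of" = B_DECR)

.vader_special_cases <- c(
  "the shit" = 3, "the bomb" = 3, "bad ass" = 1.5, "badass" = 1.5,
  "bus stop" = 0.0, "yeah right" = -2, "kiss of death" = -1.5,
  "to die for" = 3, "beating heart" = 3.5)

# Python string.punctuation, the exact set stripped from token edges.
.vader_punct_chars <- strsplit("!\"#$%&'()*+,-./:;<=>?@[\\]^_`{|}~", "")[[1]]

#' The bundled valence lexicon
#'
#' Returns the published VADER sentiment lexicon (Hutto & Gilbert 2014;
#' MIT license) bundled with the package as plain text: ~7500 terms,
#' emoticons, slang and initialisms, each with a mean human valence rating
#' in \[-4, 4\]. When a term is listed more than once the last entry wins,
#' matching the reference loader.
#'
#' @return A named numeric vector: term -> valence.
#' @export
vader_lexicon <- function() {
  if (is.null(.fc_cache$lexicon)) {
    lines <- c(readLines(fc_extdata("vader_lexicon_1.txt"), encoding = "UTF-8"),
               readLines(fc_extdata("vader_lexicon_2.txt"), encoding = "UTF-8"))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    words <- vapply(parts, `[`, character(1), 1L)
    vals <- as.numeric(vapply(parts, `[`, character(1), 2L))
    keep <- !duplicated(words, fromLast = TRUE)
    lex <- setNames(vals[keep], words[keep])
    .fc_cache$lexicon <- lex
    .fc_cache$lexicon_env <- list2env(as.list(lex), hash = TRUE,
                                      parent = emptyenv())
  }
  .fc_cache$lexicon
}

.lex_env <- function() {
  vader_lexicon()
  .fc_cache$lexicon_env
}

.in_lexicon <- function(w, env) {
  vapply(w, function(x) exists(x, envir = env, inherits = FALSE), logical(1),
         USE.NAMES = FALSE)
}

.lex_val <- function(w, env) {
  get(w, envir = env, inherits = FALSE)
}

# Strip leading/trailing ASCII punctuation; if the remainder has <= 2
# characters the token was likely an emoticon, so keep it whole.
.strip_punc_if_word <- function(token) {
  chars <- strsplit(token, "", fixed = TRUE)[[1]]
  i <- 1L
  j <- length(chars)
  while (i <= j && chars[i] %in% .vader_punct_chars) i <- i + 1L
  while (j >= i && chars[j] %in% .vader_punct_chars) j <- j - 1L
  stripped <- if (i > j) "" else substr(token, i, j)
  if (nchar(stripped) <= 2) token else stripped
}

.words_and_emoticons <- function(text) {
  raw <- strsplit(trimws(text), "[ \t\r\n\f\v]+")[[1]]
  raw <- raw[nzchar(raw)]
  vapply(raw, .strip_punc_if_word, character(1), USE.NAMES = FALSE)
}

# TRUE when the token has at least one letter and all letters are uppercase
# (the analogue of str.isupper()).
.is_upper <- function(w) {
  grepl("[[:alpha:]]", w) & w == toupper(w)
}

.allcap_differential <- function(words) {
  n_upper <- sum(.is_upper(words))
  diff <- length(words) - n_upper
  diff > 0 && diff < length(words)
}

.negated <- function(words) {
  words <- tolower(words)
  any(words %in% .vader_negate) || any(grepl("n't", words, fixed = TRUE))
}

.vader_normalize <- function(score, alpha = 15) {
  norm <- score / sqrt(score * score + alpha)
  max(-1, min(1, norm))
}

.scalar_inc_dec <- function(word, valence, is_cap_diff) {
  scalar <- 0
  wl <- tolower(word)
  if (wl %in% names(.vader_boosters)) {
    scalar <- unname(.vader_boosters[wl])
    if (valence < 0) scalar <- -scalar
    if (.is_upper(word) && is_cap_diff) {
      scalar <- if (valence > 0) scalar + C_INCR else scalar - C_INCR
    }
  }
  scalar
}

.negation_check <- function(valence, wl, start_i, i) {
  # wl: lowercase tokens; i, start_i follow the reference control flow
  # (i is 1-based here).
  if (start_i == 0) {
    if (.negated(wl[i - 1])) valence <- valence * N_SCALAR
  } else if (start_i == 1) {
    if (wl[i - 2] == "never" && wl[i - 1] %in% c("so", "this")) {
      valence <- valence * 1.25
    } else if (wl[i - 2] == "without" && wl[i - 1] == "doubt") {
      # explicit pass-through
    } else if (.negated(wl[i - 2])) {
      valence <- valence * N_SCALAR
    }
  } else if (start_i == 2) {
    # operator precedence preserved from the reference:
    # (never AND so/this at -2) OR (so/this at -1)
    if ((wl[i - 3] == "never" && wl[i - 2] %in% c("so", "this")) ||
        wl[i - 1] %in% c("so", "this")) {
      valence <- valence * 1.25
    } else if (wl[i - 3] == "without" &&
               (wl[i - 2] == "doubt" || wl[i - 1] == "doubt")) {
      # pass-through
    } else if (.negated(wl[i - 3])) {
      valence <- valence * N_SCALAR
    }
  }
  valence
}

.special_idioms_check <- function(valence, wl, i) {
  n <- length(wl)
  onezero <- paste(wl[i - 1], wl[i])
  twoonezero <- paste(wl[i - 2], wl[i - 1], wl[i])
  twoone <- paste(wl[i - 2], wl[i - 1])
  threetwoone <- paste(wl[i - 3], wl[i - 2], wl[i - 1])
  threetwo <- paste(wl[i - 3], wl[i - 2])
  for (seq in c(onezero, twoonezero, twoone, threetwoone, threetwo)) {
    if (seq %in% names(.vader_special_cases)) {
      valence <- unname(.vader_special_cases[seq])
      break
    }
  }
  if (n > i) {
    zeroone <- paste(wl[i], wl[i + 1])
    if (zeroone %in% names(.vader_special_cases)) {
      valence <- unname(.vader_special_cases[zeroone])
    }
  }
  if (n > i + 1) {
    zeroonetwo <- paste(wl[i], wl[i + 1], wl[i + 2])
    if (zeroonetwo %in% names(.vader_special_cases)) {
      valence <- unname(.vader_special_cases[zeroonetwo])
    }
  }
  for (ng in c(threetwoone, threetwo, twoone)) {
    if (ng %in% names(.vader_boosters)) {
      valence <- valence + unname(.vader_boosters[ng])
    }
  }
  valence
}

.least_check <- function(valence, wl, i, env) {
  if (i > 2 && !.in_lexicon(wl[i - 1], env) && wl[i - 1] == "least") {
    if (wl[i - 2] != "at" && wl[i - 2] != "very") {
      valence <- valence * N_SCALAR
    }
  } else if (i > 1 && !.in_lexicon(wl[i - 1], env) && wl[i - 1] == "least") {
    valence <- valence * N_SCALAR
  }
  valence
}

.sentiment_valence <- function(wes, wl, is_cap_diff, i, env) {
  valence <- 0
  item_l <- wl[i]
  n <- length(wes)
  if (.in_lexicon(item_l, env)) {
    valence <- .lex_val(item_l, env)
    # "no" before a lexicon item acts as negation, not as its own item
    if (item_l == "no" && i != n && .in_lexicon(wl[i + 1], env)) {
      valence <- 0
    }
    if ((i > 1 && wl[i - 1] == "no") ||
        (i > 2 && wl[i - 2] == "no") ||
        (i > 3 && wl[i - 3] == "no" && wl[i - 1] %in% c("or", "nor"))) {
      valence <- .lex_val(item_l, env) * N_SCALAR
    }
    if (.is_upper(wes[i]) && is_cap_diff) {
      valence <- if (valence > 0) valence + C_INCR else valence - C_INCR
    }
    for (start_i in 0:2) {
      if (i - 1 > start_i && !.in_lexicon(wl[i - start_i - 1], env)) {
        s <- .scalar_inc_dec(wes[i - start_i - 1], valence, is_cap_diff)
        if (start_i == 1 && s != 0) s <- s * 0.95
        if (start_i == 2 && s != 0) s <- s * 0.9
        valence <- valence + s
        valence <- .negation_check(valence, wl, start_i, i)
        if (start_i == 2) {
          valence <- .special_idioms_check(valence, wl, i)
        }
      }
    }
    valence <- .least_check(valence, wl, i, env)
  }
  valence
}

# Contrastive-conjunction reweighting: sentiment before "but" is halved,
# after it amplified 1.5x. The reference updates the *first* position whose
# value equals the current one; that quirk is preserved for exactness.
.but_check <- function(wl, sentiments) {
  bi <- match("but", wl)
  if (!is.na(bi)) {
    for (p in seq_along(sentiments)) {
      v <- sentiments[p]
      si <- match(v, sentiments)
      if (si < bi) {
        sentiments[si] <- v * 0.5
      } else if (si > bi) {
        sentiments[si] <- v * 1.5
      }
    }
  }
  sentiments
}

.punctuation_emphasis <- function(text) {
  ep <- min(lengths(regmatches(text, gregexpr("!", text, fixed = TRUE))), 4)
  qm <- lengths(regmatches(text, gregexpr("?", text, fixed = TRUE)))
  qm_amp <- if (qm > 1) {
    if (qm <= 3) qm * 0.18 else 0.96
  } else 0
  ep * 0.292 + qm_amp
}

#' Score one post for sentiment polarity
#'
#' Applies the full published rule set to the unmodified text: lexicon
#' valences, ALL-CAPS emphasis, exclamation/question-mark amplification,
#' degree-modifier boosting and damping with distance decay, negation
#' flipping (including "no", "least" and n't-contractions), special-case
#' idioms, and contrastive-conjunction ("but") reweighting. `pos`, `neu`
#' and `neg` are the proportions of the text's tokens falling in each
#' class (summing to 1); `compound` is the normalized sum of term valences
#' in \[-1, 1\]. Empty or whitespace-only input scores all zeros.
#'
#' Emoji-codepoint translation is not implemented; classic character
#' emoticons (":)", "(:", ":D" ...) are scored via the lexicon.
#'
#' @param text A single character string, scored verbatim.
#' @return A named list with elements `pos`, `neu`, `neg` (3 decimals) and
#'   `compound` (4 decimals).
#' @examples
#' vader_scores("I love you positiveness.............")
#' @export
vader_scores <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  env <- .lex_env()
  if (is.na(text)) text <- ""
  text <- trimws(text)
  wes <- .words_and_emoticons(text)
  wl <- tolower(wes)
  is_cap_diff <- .allcap_differential(wes)
  n <- length(wes)
  sentiments <- numeric(n)
  for (i in seq_len(n)) {
    if (wl[i] %in% names(.vader_boosters)) {
      sentiments[i] <- 0
    } else if (i < n && wl[i] == "kind" && wl[i + 1] == "of") {
      sentiments[i] <- 0
    } else {
      sentiments[i] <- .sentiment_valence(wes, wl, is_cap_diff, i, env)
    }
  }
  sentiments <- .but_check(wl, sentiments)

  if (n > 0) {
    sum_s <- sum(sentiments)
    punct_amp <- .punctuation_emphasis(text)
    if (sum_s > 0) {
      sum_s <- sum_s + punct_amp
    } else if (sum_s < 0) {
      sum_s <- sum_s - punct_amp
    }
    compound <- .vader_normalize(sum_s)
    pos_sum <- sum(sentiments[sentiments > 0] + 1)
    neg_sum <- sum(sentiments[sentiments < 0] - 1)
    neu_count <- sum(sentiments == 0)
    if (pos_sum > abs(neg_sum)) {
      pos_sum <- pos_sum + punct_amp
    } else if (pos_sum < abs(neg_sum)) {
      neg_sum <- neg_sum - punct_amp
    }
    total <- pos_sum + abs(neg_sum) + neu_count
    pos <- abs(pos_sum / total)
    neg <- abs(neg_sum / total)
    neu <- abs(neu_count / total)
  } else {
    compound <- 0
    pos <- 0
    neg <- 0
    neu <- 0
  }
  list(pos = round(pos, 3), neu = round(neu, 3), neg = round(neg, 3),
       compound = round(compound, 4))
}

#' Score every post of the SA corpus
#'
#' Applies [vader_scores()] post by post. Scoring is stateless: identical
#' texts receive identical scores regardless of position.
#'
#' @param sa_texts Tibble with columns `post_id`, `text` (the `sa` element
#'   of a [build_dual_corpus()] object).
#' @return A tibble `post_id`, `pos`, `neu`, `neg`, `compound`, one row per
#'   post, input order preserved.
#' @export
score_corpus <- function(sa_texts) {
  scores <- lapply(sa_texts$text, vader_scores)
  tibble::tibble(
    post_id = sa_texts$post_id,
    pos = vapply(scores, `[[`, numeric(1), "pos"),
    neu = vapply(scores, `[[`, numeric(1), "neu"),
    neg = vapply(scores, `[[`, numeric(1), "neg"),
    compound = vapply(scores, `[[`, numeric(1), "compound")
  )
}
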
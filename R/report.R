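#' Export condensed strata as coder-ready files
#'
#' Writes one CSV per meta-theme (each topic stratum and the (+)Pos /
#' (-)Neg strata) with columns `post_id`, `score`, `text`, ordered by
#' descending score, for human thematic coding. Text is taken verbatim
#' from the SA corpus, so retained posts round-trip byte-identically.
#'
#' @param strata A list of `condensed_stratum` objects (topic and/or
#'   sentiment strata; a combined `c(topic_strata, sentiment_strata)` list
#'   is fine).
#' @param sa_texts Tibble `post_id`, `text` with the verbatim corpus.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named character vector of file paths.
#' @export
export_strata <- function(strata, sa_texts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  text_of <- setNames(sa_texts$text, sa_texts$post_id)
  paths <- vapply(strata, function(s) {
    if (s$n_retained == 0) {
      warning("stratum \"", s$label, "\" is empty; writing header only")
    }
    # scores serialized at full precision so the round trip is exact
    out <- tibble::tibble(post_id = s$retained$post_id,
                          score = formatC(s$retained$score, digits = 17,
                                          format = "g"),
                          text = unname(text_of[s$retained$post_id]))
    fname <- paste0(gsub("[^A-Za-z0-9]+", "_", s$label), ".csv")
    path <- file.path(dir, fname)
    readr::write_csv(out, path, progress = FALSE)
    path
  }, character(1))
  invisible(paths)
}

#' Condensation summary table
#'
#' One row per stratum -- stratum size, share of the corpus, percentile
#' threshold, retained count and share, retained-score mean and SD -- plus
#' a total row summing the retained counts over all strata (the size of
#' the condensed data set advanced to thematic analysis).
#'
#' @param stats Corpus statistics from [corpus_stats()].
#' @param strata List of `condensed_stratum` objects.
#' @return A tibble with columns `stratum`, `n_posts`, `pct_of_corpus`,
#'   `threshold`, `n_retained`, `pct_retained`, `mean`, `sd`.
#' @export
summary_table <- function(stats, strata) {
  n_corpus <- stats$n_posts
  rows <- lapply(strata, function(s) {
    tibble::tibble(
      stratum = s$label,
      n_posts = s$n_total,
      pct_of_corpus = 100 * s$n_total / n_corpus,
      threshold = s$threshold,
      n_retained = s$n_retained,
      pct_retained = 100 * s$n_retained / s$n_total,
      mean = s$mean,
      sd = s$sd
    )
  })
  total <- tibble::tibble(
    stratum = "condensed_total",
    n_posts = n_corpus,
    pct_of_corpus = 100,
    threshold = NA_real_,
    n_retained = sum(vapply(strata, `[[`, integer(1), "n_retained")),
    pct_retained = 100 *
      sum(vapply(strata, `[[`, integer(1), "n_retained")) / n_corpus,
    mean = NA_real_,
    sd = NA_real_
  )
  dplyr::bind_rows(c(rows, list(total)))
}

#' Pooled two-coder Cohen's kappa
#'
#' Chance-corrected agreement for a multi-code qualitative schema: every
#' (post, code) pair becomes one binary applied/not-applied decision per
#' coder, the decisions are pooled across all pairs into a single 2x2
#' table, and Cohen's kappa \eqn{(p_o - p_e)/(1 - p_e)} is computed on it.
#' This is the standard pooled construction when coders may apply several
#' codes per excerpt. Invariant to code relabeling and post order.
#'
#' @param labels Long-format data frame with columns `post_id`,
#'   `coder_id`, `code`: one row per applied code. Exactly two coders,
#'   both assumed to have seen every post in `posts`.
#' @param code_universe Character vector of all possible codes.
#' @param posts Character vector of all posts shown to both coders.
#'   Defaults to the posts appearing in `labels`; supply the full set when
#'   some shown posts received no code from either coder, since those
#'   posts contribute neither-applied decisions.
#' @return The pooled kappa, a value in \[-1, 1\].
#' @examples
#' labs <- data.frame(post_id = c("p1", "p1"), coder_id = c("c1", "c2"),
#'                    code = c("A", "A"))
#' pooled_kappa(labs, code_universe = c("A", "B"))
#' @export
pooled_kappa <- function(labels, code_universe,
                         posts = unique(labels$post_id)) {
  stopifnot(all(c("post_id", "coder_id", "code") %in% names(labels)))
  coders <- sort(unique(labels$coder_id))
  if (length(coders) != 2) {
    stop("pooled kappa requires exactly 2 coders; found ", length(coders))
  }
  if (!all(labels$code %in% code_universe)) {
    stop("labels contain codes outside code_universe")
  }
  if (!all(labels$post_id %in% posts)) {
    stop("labels contain posts outside the stated post set")
  }
  if (anyDuplicated(labels[c("post_id", "coder_id", "code")])) {
    stop("duplicate (post_id, coder_id, code) rows")
  }
  key <- function(coder) {
    sub <- labels[labels$coder_id == coder, ]
    paste(sub$post_id, sub$code, sep = "\r")
  }
  grid <- as.vector(outer(posts, code_universe, paste, sep = "\r"))
  a1 <- grid %in% key(coders[1])
  a2 <- grid %in% key(coders[2])
  n <- length(grid)
  both <- sum(a1 & a2)
  neither <- sum(!a1 & !a2)
  p_o <- (both + neither) / n
  p_yes1 <- mean(a1)
  p_yes2 <- mean(a2)
  p_e <- p_yes1 * p_yes2 + (1 - p_yes1) * (1 - p_yes2)
  if (isTRUE(all.equal(p_e, 1))) {
    stop("degenerate agreement table: expected agreement is 1, ",
         "kappa undefined")
  }
  (p_o - p_e) / (1 - p_e)
}
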
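#' Inclusive linear-interpolation percentile
#'
#' The spreadsheet-style inclusive percentile: with sorted values
#' \eqn{v_1 \le \dots \le v_n} and rank position \eqn{h = 1 + p(n - 1)},
#' returns \eqn{v_{\lfloor h \rfloor} + (h - \lfloor h \rfloor)
#' (v_{\lfloor h \rfloor + 1} - v_{\lfloor h \rfloor})}. This is the
#' convention condensation thresholds are defined by; it may return a
#' fractional value even for integer scores (e.g. 9.1 for the 90th
#' percentile of 1..10), and the strict retention cut applies to that raw
#' fractional threshold.
#'
#' @param values Non-empty numeric vector.
#' @param p Fraction in \[0, 1\].
#' @return The interpolated percentile value.
#' @examples
#' percentile_inc(1:4, 0.9)   # 3.7
#' percentile_inc(1:10, 0.9)  # 9.1
#' @export
percentile_inc <- function(values, p) {
  if (length(values) == 0) stop("percentile of an empty value set is undefined")
  stopifnot(is.numeric(values), p >= 0, p <= 1)
  v <- sort(values)
  n <- length(v)
  h <- 1 + p * (n - 1)
  lo <- floor(h)
  frac <- h - lo
  if (lo >= n) v[n] else v[lo] + frac * (v[lo + 1] - v[lo])
}

# Shared stratum-condensation core: rank a stratum's scores, compute the
# percentile threshold, retain scores above it (strictly by default), and
# summarize the retained scores (sample sd, n-1 denominator).
condense_stratum <- function(ids, scores, label, p = 0.90, strict = TRUE) {
  stopifnot(length(ids) == length(scores), length(ids) > 0)
  threshold <- percentile_inc(scores, p)
  keep <- if (strict) scores > threshold else scores >= threshold
  if (!any(keep)) {
    warning("stratum \"", label, "\": no posts retained ",
            "(degenerate score distribution; threshold ", threshold, ")")
  }
  ord <- order(-scores[keep])
  retained <- tibble::tibble(post_id = ids[keep][ord],
                             score = scores[keep][ord])
  structure(
    list(label = label, percentile = p, threshold = threshold,
         strict = strict,
         retained = retained,
         retained_ids = retained$post_id,
         n_total = length(ids),
         n_retained = nrow(retained),
         mean = if (nrow(retained)) mean(retained$score) else NA_real_,
         sd = if (nrow(retained) > 1) stats::sd(retained$score) else NA_real_),
    class = "condensed_stratum"
  )
}

#' @export
print.condensed_stratum <- function(x, ...) {
  cat(sprintf(
    "<condensed_stratum> %s: %d/%d retained %s %.4g (mean %.3g, sd %.3g)\n",
    x$label, x$n_retained, x$n_total, if (x$strict) ">" else ">=",
    x$threshold, x$mean, x$sd))
  invisible(x)
}

#' Per-post topic-token affinity scores
#'
#' For every modeled post, counts (with multiplicity) how many of its
#' normalized tokens belong to its dominant topic's signature token list.
#' Affinity measures how representative a post is of the topic it was
#' assigned to: a post using many of the topic's signature tokens is a rich
#' exemplar. Posts with a null topic (empty after pruning) are excluded.
#' Matching is on whole normalized tokens by default; `substring = TRUE`
#' counts posts' tokens that contain a signature token as a substring, for
#' sensitivity analysis.
#'
#' @param docs Named list of pruned token vectors.
#' @param assignment Named integer vector from [assign_dominant_topic()].
#' @param topic_tokens List of per-topic signature token vectors, normally
#'   the refined model's [top_tokens()] (top 30).
#' @param substring Count substring matches instead of whole tokens.
#' @return Tibble `post_id`, `topic`, `affinity` (non-negative integer).
#' @export
affinity_scores <- function(docs, assignment, topic_tokens,
                            substring = FALSE) {
  ids <- names(assignment)
  missing_ids <- setdiff(names(docs), ids)
  if (length(missing_ids) > 0) {
    message(length(missing_ids),
            " post(s) without a topic (empty after pruning) excluded ",
            "from affinity scoring")
  }
  affinity <- vapply(ids, function(id) {
    toks <- docs[[id]]
    sig <- topic_tokens[[assignment[[id]]]]
    if (substring) {
      sum(vapply(toks, function(tk) any(vapply(
        sig, grepl, logical(1), x = tk, fixed = TRUE)), logical(1)))
    } else {
      sum(toks %in% sig)
    }
  }, integer(1))
  tibble::tibble(post_id = ids, topic = unname(assignment[ids]),
                 affinity = unname(affinity))
}

#' Condense the topic strata
#'
#' Within each dominant-topic stratum independently, computes the
#' percentile threshold of the affinity scores and retains the posts
#' strictly above it (the ">n topic-specific tokens per post" standard).
#' Strict retention means a degenerate stratum whose affinities are all
#' equal retains nothing, which is reported as a warning, not an error.
#'
#' @param records Tibble from [affinity_scores()].
#' @param p Percentile cut, default 0.90.
#' @param strict Retain strictly above the threshold (default). `FALSE`
#'   retains scores >= threshold.
#' @return A named list of `condensed_stratum` objects, one per topic
#'   (labels `"topic_A"`, `"topic_B"`, ...).
#' @export
condense_topic_strata <- function(records, p = 0.90, strict = TRUE) {
  topics <- sort(unique(records$topic))
  strata <- lapply(topics, function(k) {
    sub <- records[records$topic == k, ]
    condense_stratum(sub$post_id, sub$affinity,
                     label = paste0("topic_", LETTERS[k]),
                     p = p, strict = strict)
  })
  setNames(strata, paste0("topic_", LETTERS[topics]))
}

#' Condense the sentiment strata
#'
#' Ranks all posts on the positive polarity proportion for the (+)Pos
#' stratum and, independently, on the negative proportion for the (-)Neg
#' stratum, retaining posts strictly above each stratum's percentile
#' threshold. The two rankings are not a partition: a post may in principle
#' be retained in both, which [overlap_report()] surfaces.
#'
#' @param scores Tibble from [score_corpus()].
#' @param p Percentile cut, default 0.90.
#' @param strict Strict (>) retention, as in [condense_topic_strata()].
#' @return A named list of two `condensed_stratum` objects, `pos` (label
#'   `"(+)Pos"`) and `neg` (label `"(-)Neg"`).
#' @export
condense_sentiment_strata <- function(scores, p = 0.90, strict = TRUE) {
  stopifnot(nrow(scores) > 0)
  list(
    pos = condense_stratum(scores$post_id, scores$pos, label = "(+)Pos",
                           p = p, strict = strict),
    neg = condense_stratum(scores$post_id, scores$neg, label = "(-)Neg",
                           p = p, strict = strict)
  )
}

#' Posts retained in both a topic and a sentiment stratum
#'
#' Reports the exact intersection of the retained ids, without
#' deduplicating the strata themselves: whether doubly retained posts are
#' coded once or twice is a downstream coder decision.
#'
#' @param topic_strata List from [condense_topic_strata()].
#' @param sentiment_strata List from [condense_sentiment_strata()].
#' @return Character vector of post ids (each reported once).
#' @export
overlap_report <- function(topic_strata, sentiment_strata) {
  tm_ids <- unique(unlist(lapply(topic_strata, `[[`, "retained_ids")))
  sa_ids <- unique(unlist(lapply(sentiment_strata, `[[`, "retained_ids")))
  intersect(tm_ids, sa_ids)
}
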
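#' Run the full forum-condensation pipeline
#'
#' Drives the whole workflow on a table of raw posts: staff filtering, dual
#' corpus construction, TM-corpus normalization, vocabulary building with
#' the SMART stoplist and a minimum-frequency filter, first-pass LDA,
#' optional token-removal refinement and refit (the second-pass model),
#' numeric topic diagnostics, dominant-topic assignment, affinity scoring
#' and topic-stratum condensation, verbatim-corpus sentiment scoring and
#' valence-stratum condensation, and the cross-corpus overlap report. Every
#' stochastic step derives from `seed`, so identical inputs and
#' configuration reproduce the result bit for bit.
#'
#' @param posts Raw-post tibble ([read_forum_table()] or
#'   [generate_forum_corpus()]).
#' @param staff_ids Author ids removed as staff (in addition to the
#'   `is_staff` flag).
#' @param K Number of topics.
#' @param min_count Minimum unigram frequency (default 3).
#' @param stoplist Stoplist terms; defaults to the SMART 571.
#' @param removal_list Terms excised before the refined second-pass fit;
#'   empty to keep a single-pass model.
#' @param p Condensation percentile (default 0.90).
#' @param strict Strict (>) retention cut (default TRUE).
#' @param n_top Signature-token list length per topic (default 30).
#' @param n_iter,burnin Gibbs sweeps and burn-in (see [fit_lda()]).
#' @param seed Integer seed for the sampler.
#' @return An object of class `forum_pipeline`: list with `corpus`,
#'   `vocabulary`, `model` (refined model if a removal list was given),
#'   `model1` (first-pass model), `diagnostics`, `assignment`,
#'   `affinity`, `scores`, `topic_strata`, `sentiment_strata`, `overlap`,
#'   `summary`, and `config`.
#' @export
run_forum_pipeline <- function(posts, staff_ids = character(),
                               K = 3, min_count = 3,
                               stoplist = smart_stopwords(),
                               removal_list = character(),
                               p = 0.90, strict = TRUE, n_top = 30,
                               n_iter = 500, burnin = n_iter %/% 2,
                               seed = 1L) {
  kept <- filter_staff(posts, staff_ids)
  corpus <- build_dual_corpus(kept)
  stats <- corpus_stats(kept)

  docs <- normalize_and_tokenize(corpus$tm)
  vb <- build_vocabulary(docs, stoplist = stoplist, min_count = min_count)
  model1 <- fit_lda(vb$docs, K = K, n_iter = n_iter, burnin = burnin,
                    seed = seed)
  if (length(removal_list) > 0) {
    rf <- refine_tokens(vb$docs, vb$vocabulary, removal_list)
    model <- fit_lda(rf$docs, K = K, n_iter = n_iter, burnin = burnin,
                     seed = seed)
    vocab <- rf$vocabulary
    fit_docs <- rf$docs
  } else {
    model <- model1
    vocab <- vb$vocabulary
    fit_docs <- vb$docs
  }

  diagnostics <- topic_diagnostics(model, fit_docs)
  assignment <- assign_dominant_topic(model)
  signature <- top_tokens(model, n = min(n_top, length(model$terms)))
  affinity <- affinity_scores(fit_docs, assignment, signature)
  topic_strata <- condense_topic_strata(affinity, p = p, strict = strict)

  scores <- score_corpus(corpus$sa)
  sentiment_strata <- condense_sentiment_strata(scores, p = p,
                                                strict = strict)

  all_strata <- c(topic_strata, sentiment_strata)
  structure(
    list(corpus = corpus, stats = stats, vocabulary = vocab,
         docs = fit_docs,
         model = model, model1 = model1,
         diagnostics = diagnostics, assignment = assignment,
         signature_tokens = signature,
         affinity = affinity, scores = scores,
         topic_strata = topic_strata, sentiment_strata = sentiment_strata,
         overlap = overlap_report(topic_strata, sentiment_strata),
         summary = summary_table(stats, all_strata),
         config = list(K = K, min_count = min_count, p = p,
                       strict = strict, n_top = n_top, n_iter = n_iter,
                       burnin = burnin, seed = seed,
                       removal_list = removal_list)),
    class = "forum_pipeline"
  )
}

#' @export
print.forum_pipeline <- function(x, ...) {
  cat("<forum_pipeline> ", x$stats$n_posts, " posts, ", x$stats$n_words,
      " words | K = ", x$model$K, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write the strata manifest of a pipeline run
#'
#' Serializes the condensation result -- per-stratum label, percentile,
#' threshold, retained ids and summary statistics, plus the configuration
#' -- as canonical JSON. Two runs with identical inputs, configuration and
#' seed produce byte-identical manifests, which is the pipeline's
#' determinism contract.
#'
#' @param result A [run_forum_pipeline()] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_manifest <- function(result, path) {
  strata <- c(result$topic_strata, result$sentiment_strata)
  manifest <- list(
    config = result$config,
    corpus = result$stats,
    strata = lapply(unname(strata), function(s) {
      list(label = s$label, percentile = s$percentile,
           threshold = s$threshold, n_total = s$n_total,
           n_retained = s$n_retained, mean = s$mean, sd = s$sd,
           retained_ids = s$retained_ids)
    }),
    overlap = result$overlap
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
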
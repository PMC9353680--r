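# Shared fixture builders: everything is generated in code at test time.

write_forum_csv <- function(rows, path = tempfile(fileext = ".csv"),
                            header = "id,parent,user,when,body,staff") {
  writeLines(c(header, rows), path)
  path
}

full_column_map <- c(post_id = "id", parent_id = "parent",
                     author_id = "user", timestamp = "when",
                     text = "body", is_staff = "staff")

make_posts <- function(ids, texts, authors = paste0("u", seq_along(ids)),
                       staff = rep(FALSE, length(ids))) {
  tibble::tibble(post_id = ids, parent_id = "", author_id = authors,
                 timestamp = as.POSIXct(NA), text = texts,
                 is_staff = staff)
}

# A minimal hand-built topic model object for unit tests that do not need
# a Gibbs fit.
make_toy_model <- function(topic_term, doc_topic) {
  structure(list(K = nrow(topic_term), topic_term = topic_term,
                 doc_topic = doc_topic, terms = colnames(topic_term),
                 excluded_docs = character(), alpha = 0.1, eta = 0.1,
                 n_iter = 0, burnin = 0, seed = 0L),
            class = "topic_model")
}

make_fake_stratum <- function(label, ids, scores, p = 0.9,
                              threshold = NULL) {
  if (is.null(threshold)) threshold <- percentile_inc(scores, p)
  keep <- scores > threshold
  ord <- order(-scores[keep])
  retained <- tibble::tibble(post_id = ids[keep][ord],
                             score = scores[keep][ord])
  structure(list(label = label, percentile = p, threshold = threshold,
                 strict = TRUE, retained = retained,
                 retained_ids = retained$post_id,
                 n_total = length(ids), n_retained = nrow(retained),
                 mean = if (nrow(retained)) mean(retained$score) else NA_real_,
                 sd = if (nrow(retained) > 1) sd(retained$score) else NA_real_),
            class = "condensed_stratum")
}
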
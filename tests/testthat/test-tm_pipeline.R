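test_that("normalize_and_tokenize lowercases, strips punctuation to spaces, splits", {
  expect_equal(normalize_and_tokenize(c(p = "Hello, WORLD!"))$p,
               c("hello", "world"))
  # punctuation becomes a space, so URLs fragment into separate unigrams
  expect_equal(normalize_and_tokenize(c(p = "https://x.org"))$p,
               c("https", "x", "org"))
  expect_equal(normalize_and_tokenize(c(p = ""))$p, character(0))
  expect_equal(normalize_and_tokenize(c(p = "...!?"))$p, character(0))
})

test_that("build_vocabulary applies stoplist and frequency floor on normalized forms", {
  docs <- normalize_and_tokenize(c(
    a = paste(rep("the", 50), collapse = " "),
    b = "HIV hiv HIV.",
    c = "rare rare meds meds meds"))
  vb <- build_vocabulary(docs, min_count = 3)
  expect_false("the" %in% vb$vocabulary$term)      # SMART stoplist
  expect_false("rare" %in% vb$vocabulary$term)     # frequency 2 < 3
  expect_equal(vb$vocabulary$frequency[vb$vocabulary$term == "hiv"], 3L)
  expect_equal(vb$docs$b, c("hiv", "hiv", "hiv"))

  expect_error(build_vocabulary(normalize_and_tokenize(c(a = "the of and"))),
               "empty model input")
})

test_that("vocabulary is monotone in min_count", {
  set.seed(3)
  docs <- lapply(1:30, function(i)
    sample(c("alpha", "beta", "gamma", "delta", "epsilon"),
           sample(2:8, 1), replace = TRUE))
  names(docs) <- paste0("d", 1:30)
  terms_at <- function(mc)
    build_vocabulary(docs, stoplist = character(), min_count = mc)$vocabulary$term
  v1 <- terms_at(1)
  for (mc in 2:8) {
    expect_true(all(terms_at(mc) %in% v1))
    expect_true(length(terms_at(mc)) <= length(terms_at(mc - 1)))
  }
})

test_that("refine_tokens excises terms and commutes with stoplist pruning", {
  docs <- normalize_and_tokenize(c(
    a = "just meds don meds doctor", b = "just don just meds"))
  vb <- build_vocabulary(docs, stoplist = character(), min_count = 1)

  same <- refine_tokens(vb$docs, vb$vocabulary, character())
  expect_identical(same$vocabulary, vb$vocabulary)
  expect_identical(same$docs, vb$docs)

  rf <- refine_tokens(vb$docs, vb$vocabulary, c("just", "don"))
  expect_false(any(c("just", "don") %in% unlist(rf$docs)))
  expect_false(any(c("just", "don") %in% rf$vocabulary$term))

  noop <- refine_tokens(vb$docs, vb$vocabulary, "absent_term")
  expect_identical(noop$docs, vb$docs)

  # pruning with a removal list == building with stoplist + removal list
  via_stop <- build_vocabulary(docs, stoplist = c("just", "don"),
                               min_count = 1)
  expect_identical(rf$vocabulary$term, via_stop$vocabulary$term)
  expect_identical(rf$docs, via_stop$docs)
})

test_that("K = 1 LDA degenerates to the smoothed corpus distribution", {
  set.seed(5)
  docs <- lapply(1:120, function(i)
    sample(sprintf("t%02d", 1:40), sample(10:25, 1), replace = TRUE))
  names(docs) <- paste0("d", 1:120)
  fit <- fit_lda(docs, K = 1, n_iter = 30, seed = 9L)
  expect_true(all(fit$doc_topic == 1))
  # brute-force smoothed unigram oracle
  toks <- unlist(docs)
  freq <- table(toks)[fit$terms]
  oracle <- (as.numeric(freq) + fit$eta) /
    (length(toks) + fit$eta * length(fit$terms))
  tv <- sum(abs(fit$topic_term[1, ] - oracle)) / 2
  expect_lt(tv, 0.05)
})

test_that("fit_lda is deterministic for a fixed seed and validates inputs", {
  set.seed(6)
  docs <- lapply(1:40, function(i)
    sample(letters[1:12], sample(5:15, 1), replace = TRUE))
  names(docs) <- paste0("d", 1:40)
  f1 <- fit_lda(docs, K = 3, n_iter = 60, seed = 123L)
  f2 <- fit_lda(docs, K = 3, n_iter = 60, seed = 123L)
  expect_identical(f1$topic_term, f2$topic_term)
  expect_identical(f1$doc_topic, f2$doc_topic)
  f3 <- fit_lda(docs, K = 3, n_iter = 60, seed = 124L)
  expect_false(identical(f1$topic_term, f3$topic_term))

  expect_error(fit_lda(docs, K = 0), "K must be >= 1")
  expect_warning(fit_lda(docs[1:3], K = 5, n_iter = 10, seed = 1L),
                 "exceeds the number")

  # rows are proper distributions
  expect_true(all(abs(rowSums(f1$topic_term) - 1) < 1e-8))
  expect_true(all(abs(rowSums(f1$doc_topic) - 1) < 1e-8))
  expect_true(all(f1$topic_term >= 0 & f1$topic_term <= 1))

  # empty documents are excluded but reported
  docs$empty1 <- character(0)
  f4 <- fit_lda(docs, K = 2, n_iter = 10, seed = 1L)
  expect_equal(f4$excluded_docs, "empty1")
  expect_false("empty1" %in% rownames(f4$doc_topic))
})

test_that("fit_lda recovers planted disjoint-vocabulary topics", {
  spec <- synthetic_spec(K_true = 2, vocab_size = 100,
                         topic_vocab_overlap = 0, n_posts = 400,
                         salutation_fraction = 0, pos_inject_fraction = 0,
                         neg_inject_fraction = 0, staff_fraction = 0,
                         seed = 31L)
  gen <- generate_forum_corpus(spec)
  docs <- normalize_and_tokenize(gen$posts[, c("post_id", "text")])
  vb <- build_vocabulary(docs, stoplist = character(), min_count = 3)
  fit <- fit_lda(vb$docs, K = 2, n_iter = 200, seed = 31L)
  m <- recovery_metrics(fit, gen$truth, assign_dominant_topic(fit))
  expect_gte(m$mean_top10_jaccard, 0.8)
  expect_gte(m$dominant_topic_accuracy, 0.9)
})

test_that("top_tokens orders by probability with lexicographic tie-break", {
  tt <- matrix(c(0.5, 0.3, 0.2), 1, dimnames = list(NULL, c("a", "b", "c")))
  m <- make_toy_model(tt, matrix(1, 1, 1))
  expect_equal(top_tokens(m, 2)[[1]], c("a", "b"))

  tie <- matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("b", "a")))
  m2 <- make_toy_model(tie, matrix(1, 1, 1))
  expect_equal(top_tokens(m2, 2)[[1]], c("a", "b"))

  expect_warning(full <- top_tokens(m, 30), "vocabulary size")
  expect_equal(full[[1]], c("a", "b", "c"))
  expect_error(top_tokens(m, 0))
})

test_that("topic diagnostics: divergences, coordinates and prevalence", {
  p <- c(0.6, 0.4, 0, 0)
  q <- c(0, 0, 0.3, 0.7)
  expect_equal(js_divergence(p, p), 0)
  expect_equal(js_divergence(p, q), 1)          # disjoint support, base 2

  tt <- rbind(c(0.6, 0.4, 0, 0), c(0, 0, 0.3, 0.7), c(0.25, 0.25, 0.25, 0.25))
  colnames(tt) <- c("a", "b", "c", "d")
  dt <- rbind(c(0.8, 0.1, 0.1), c(0.2, 0.5, 0.3), c(0.1, 0.2, 0.7))
  rownames(dt) <- c("d1", "d2", "d3")
  docs <- list(d1 = rep("a", 4), d2 = rep("b", 6), d3 = rep("c", 2))
  m <- make_toy_model(tt, dt)
  dg <- topic_diagnostics(m, docs)

  expect_true(all(diag(dg$jsd) == 0))
  expect_identical(dg$jsd, t(dg$jsd))
  expect_true(all(dg$jsd >= 0 & dg$jsd <= 1))
  expect_equal(sum(dg$prevalence), 1, tolerance = 1e-8)
  expect_equal(dim(dg$coords_2d), c(3L, 2L))

  # brute-force prevalence oracle: expected token mass per topic
  lens <- c(4, 6, 2)
  oracle <- colSums(dt * lens) / sum(lens)
  expect_equal(dg$prevalence, oracle, tolerance = 1e-6)

  # K = 1 degenerate case: a single point at the origin
  dg1 <- topic_diagnostics(make_toy_model(tt[1, , drop = FALSE],
                                          matrix(1, 2, 1,
                                                 dimnames = list(c("d1", "d2")))),
                           list(d1 = "a", d2 = "b"))
  expect_equal(dg1$coords_2d, matrix(0, 1, 2))
})

test_that("dominant-topic assignment takes the argmax with lowest-index ties", {
  dt <- rbind(c(0.7, 0.2, 0.1), c(0.5, 0.5, 0.0), c(0.1, 0.2, 0.7))
  rownames(dt) <- c("d1", "d2", "d3")
  tt <- matrix(1 / 4, 3, 4, dimnames = list(NULL, letters[1:4]))
  asg <- assign_dominant_topic(make_toy_model(tt, dt))
  expect_equal(unname(asg), c(1L, 1L, 3L))

  # partition property on a fitted model
  set.seed(8)
  docs <- lapply(1:60, function(i)
    sample(letters[1:10], sample(4:12, 1), replace = TRUE))
  names(docs) <- paste0("d", 1:60)
  fit <- fit_lda(docs, K = 3, n_iter = 40, seed = 2L)
  asg2 <- assign_dominant_topic(fit)
  expect_equal(sum(table(asg2)), nrow(fit$doc_topic))
})
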
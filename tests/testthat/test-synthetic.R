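test_that("generator handles the zero case and validates its spec", {
  gen <- generate_forum_corpus(synthetic_spec(n_posts = 0, seed = 1L))
  expect_equal(nrow(gen$posts), 0)
  expect_equal(nrow(gen$truth$posts), 0)
  expect_equal(nrow(gen$truth$topic_term), 3)

  expect_error(synthetic_spec(salutation_fraction = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_spec(salutation_fraction = 0.7,
                              staff_fraction = 0.5), "exceed 1")
  expect_error(synthetic_spec(pos_inject_fraction = 0.6,
                              neg_inject_fraction = 0.6), "exceed 1")
  expect_error(synthetic_spec(K_true = 10, vocab_size = 20), "infeasible")
})

test_that("same spec and seed give a byte-identical corpus", {
  spec <- synthetic_spec(n_posts = 200, seed = 99L)
  g1 <- generate_forum_corpus(spec)
  g2 <- generate_forum_corpus(spec)
  expect_identical(g1$posts, g2$posts)
  expect_identical(g1$truth$posts, g2$truth$posts)
  expect_identical(g1$truth$topic_term, g2$truth$topic_term)

  g3 <- generate_forum_corpus(synthetic_spec(n_posts = 200, seed = 100L))
  expect_false(identical(g1$posts$text, g3$posts$text))
})

test_that("planted truth covers every post once with consistent strata shares", {
  spec <- synthetic_spec(n_posts = 1000, seed = 5L)
  gen <- generate_forum_corpus(spec)
  expect_identical(gen$truth$posts$post_id, gen$posts$post_id)
  expect_equal(sum(gen$posts$is_staff), round(0.02 * 1000))
  expect_equal(sum(is.na(gen$truth$posts$true_topic) & !gen$posts$is_staff),
               round(0.45 * 1000))
  expect_equal(sum(gen$truth$posts$valence == "pos"), 100)
  expect_equal(sum(gen$truth$posts$valence == "neg"), 100)
  expect_true(all(abs(rowSums(gen$truth$topic_term) - 1) < 1e-12))
})

test_that("small doc-topic concentration gives near-single-topic posts", {
  spec <- synthetic_spec(n_posts = 2000, doc_topic_concentration = 0.05,
                         seed = 13L)
  gen <- generate_forum_corpus(spec)
  w <- gen$truth$posts$true_topic_weight
  w <- w[!is.na(w)]
  # independent large-n simulation of symmetric Dirichlet(0.05), K = 3,
  # gives P(max weight > 0.9) = 0.808
  expect_lt(abs(mean(w > 0.9) - 0.808), 0.04)
  expect_gt(mean(w > 0.8), 0.8)
})

test_that("a generated corpus passes ingest and preprocessing cleanly", {
  for (s in c(3L, 8L)) {
    spec <- synthetic_spec(n_posts = 150, seed = s)
    gen <- generate_forum_corpus(spec)
    expect_no_error({
      kept <- filter_staff(gen$posts)
      dc <- build_dual_corpus(kept)
      docs <- normalize_and_tokenize(dc$tm)
      vb <- build_vocabulary(docs)
    })
    expect_false(any(kept$is_staff))
  }
})

test_that("match_topics recovers identity and planted permutations", {
  spec <- synthetic_spec(n_posts = 0, seed = 7L)
  gen <- generate_forum_corpus(spec)
  phi <- gen$truth$topic_term
  fake <- make_toy_model(phi, matrix(1 / 3, 2, 3,
                                     dimnames = list(c("d1", "d2"))))
  m <- match_topics(fake, gen$truth)
  expect_equal(m$permutation, 1:3)
  expect_equal(m$mean_jsd, 0, tolerance = 1e-12)

  perm <- c(3L, 1L, 2L)
  fake2 <- make_toy_model(phi[perm, ], fake$doc_topic)
  m2 <- match_topics(fake2, gen$truth)
  # fitted row i holds planted topic perm[i]; the match must invert that
  expect_equal(m2$permutation[perm], 1:3)
  expect_equal(m2$mean_jsd, 0, tolerance = 1e-12)

  fake_k2 <- make_toy_model(phi[1:2, ], fake$doc_topic)
  expect_error(match_topics(fake_k2, gen$truth), "differs")
})

test_that("match_topics equals the exhaustive brute-force oracle", {
  set.seed(17)
  mk <- function() {
    m <- matrix(rgamma(3 * 8, 1), 3, 8,
                dimnames = list(NULL, paste0("t", 1:8)))
    m / rowSums(m)
  }
  fitted_phi <- mk()
  planted_phi <- mk()
  fake <- make_toy_model(fitted_phi, matrix(1 / 3, 1, 3,
                                            dimnames = list("d1")))
  truth <- list(topic_term = planted_phi,
                posts = tibble::tibble(post_id = character(),
                                       true_topic = integer(),
                                       valence = character()))
  m <- match_topics(fake, truth)

  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  costs <- vapply(perms, function(p) {
    sum(vapply(1:3, function(j)
      js_divergence(fitted_phi[p[j], ], planted_phi[j, ]), numeric(1)))
  }, numeric(1))
  expect_equal(m$mean_jsd, min(costs) / 3, tolerance = 1e-12)
  expect_equal(m$permutation, as.integer(perms[[which.min(costs)]]))
})

test_that("recovery metrics are exact for perfect and null assignments", {
  spec <- synthetic_spec(n_posts = 2000, salutation_fraction = 0,
                         pos_inject_fraction = 0, neg_inject_fraction = 0,
                         staff_fraction = 0, seed = 23L)
  gen <- generate_forum_corpus(spec)
  tp <- gen$truth$posts
  fake <- make_toy_model(gen$truth$topic_term,
                         matrix(1 / 3, 1, 3, dimnames = list("d1")))
  perfect <- setNames(tp$true_topic, tp$post_id)
  m <- recovery_metrics(fake, gen$truth, perfect)
  expect_equal(m$mean_matched_jsd, 0, tolerance = 1e-12)
  expect_equal(m$mean_top10_jaccard, 1)
  expect_equal(m$dominant_topic_accuracy, 1)

  # random-guess assignment on a balanced 3-topic plant: accuracy ~ 1/3
  set.seed(24)
  null_asg <- setNames(sample(1:3, nrow(tp), replace = TRUE), tp$post_id)
  m0 <- recovery_metrics(fake, gen$truth, null_asg)
  expect_lt(abs(m0$dominant_topic_accuracy - 1 / 3), 0.05)
})

test_that("more vocabulary overlap makes plants harder and recovery worse", {
  grid <- c(0.1, 0.5, 0.9)
  out <- vapply(grid, function(ov) {
    spec <- synthetic_spec(K_true = 2, vocab_size = 120,
                           topic_vocab_overlap = ov, n_posts = 300,
                           salutation_fraction = 0, pos_inject_fraction = 0,
                           neg_inject_fraction = 0, staff_fraction = 0,
                           seed = 41L)
    gen <- generate_forum_corpus(spec)
    docs <- normalize_and_tokenize(gen$posts[, c("post_id", "text")])
    vb <- build_vocabulary(docs, stoplist = character())
    fit <- fit_lda(vb$docs, K = 2, n_iter = 150, seed = 41L)
    m <- recovery_metrics(fit, gen$truth, assign_dominant_topic(fit))
    c(plant_jsd = js_divergence(gen$truth$topic_term[1, ],
                                gen$truth$topic_term[2, ]),
      acc = m$dominant_topic_accuracy)
  }, numeric(2))
  # plant hardness: the planted topics converge as overlap grows (their
  # inter-topic divergence is 1 - overlap by construction)
  expect_true(all(diff(out["plant_jsd", ]) < 0))
  expect_equal(out["plant_jsd", ], 1 - grid, tolerance = 1e-8,
               ignore_attr = TRUE)
  # worse recovery: assignment accuracy never improves on harder plants
  expect_true(all(diff(out["acc", ]) <= 0))
})
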
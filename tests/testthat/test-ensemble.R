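test_that("rank-based AUROC matches exhaustive pairwise counting", {
  # frozen case: 3 pos {0.9, 0.8, 0.4}, 3 neg {0.7, 0.3, 0.2} -> 8/9
  s <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  lb <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(auroc(s, lb), 8 / 9)
  expect_equal(auroc(s, lb), bf_auroc(s, lb))

  # perfect separation and the all-ties constant scorer
  expect_equal(auroc(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)

  # property: random small cases, including ties
  set.seed(41)
  for (i in 1:20) {
    sc <- sample(seq(0, 1, 0.1), 16, replace = TRUE)
    lb <- sample(c(TRUE, FALSE), 16, replace = TRUE)
    if (!any(lb) || all(lb)) next
    expect_equal(auroc(sc, lb), bf_auroc(sc, lb))
  }
})

test_that("rank AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  sc <- runif(40)
  lb <- rbinom(40, 1, 0.5)
  if (any(lb == 1) && any(lb == 0)) {
    ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(sc, lb == 1), ref, tolerance = 1e-12)
  }
})

test_that("fourth-power AUROC weighting normalizes and is symmetric", {
  expect_equal(unname(combine_weights(c(0.7, 0.7, 0.7))), rep(1 / 3, 3))
  w <- combine_weights(c(0.9, 0.8, 0.7))
  expect_equal(unname(w), c(0.5025, 0.3137, 0.1839), tolerance = 1e-4)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  set.seed(43)
  for (i in 1:10) {
    r <- runif(3, 0.01, 1)
    expect_equal(sum(combine_weights(r)), 1, tolerance = 1e-12)
  }
  expect_error(combine_weights(c(0, 0, 0)), "zero")
})

test_that("weighted score is the inner product, bounded and monotone", {
  w <- combine_weights(c(0.9, 0.8, 0.7))
  expect_equal(weighted_score(c(1, 1, 1), w), 1, tolerance = 1e-12)
  expect_equal(weighted_score(c(0, 0, 0), w), 0)
  expect_equal(weighted_score(c(1, 0, 0), w), 0.5025, tolerance = 1e-4)
  set.seed(44)
  for (i in 1:10) {
    s <- runif(3)
    ws <- weighted_score(s, w)
    expect_gte(ws, min(s)); expect_lte(ws, max(s))
    bump <- s; bump[2] <- min(1, s[2] + 0.1)
    expect_gte(weighted_score(bump, w), ws)
  }
})

test_that("cutoff sweep maximizes F1 with the largest-cutoff tie-break", {
  # pos {0.9, 0.8}, neg {0.2, 0.1}: F1 = 1 on grid 0.20..0.79 -> 0.79
  cut <- select_positive_cutoff(c(0.9, 0.8, 0.2, 0.1),
                                c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(as.numeric(cut), 0.79)
  expect_equal(attr(cut, "f1"), 1)
  # invariant to score order permutation
  set.seed(45)
  sc <- runif(30); lb <- rep(c(TRUE, FALSE), 15)
  p <- sample(30)
  expect_equal(
    suppressWarnings(as.numeric(select_positive_cutoff(sc, lb))),
    suppressWarnings(as.numeric(select_positive_cutoff(sc[p], lb[p]))))
  # inverted scores are pathological: flagged as degenerate and clamped
  w <- capture_warnings(select_positive_cutoff(c(0.1, 0.2, 0.8, 0.9),
                                               c(TRUE, TRUE, FALSE, FALSE)))
  expect_true(any(grepl("barely separate", w)))
  expect_true(any(grepl("clamping", w)))
  # clamped strictly above the negative cutoff
  expect_warning(low <- select_positive_cutoff(c(0.25, 0.28, 0.05, 0.1),
                                               c(TRUE, TRUE, FALSE, FALSE)),
                 "clamping")
  expect_gt(as.numeric(low), 0.3)
  expect_error(select_positive_cutoff(c(0.5, 0.6), c(TRUE, TRUE)),
               "both classes")
})

test_that("calibrated SVM separates a separable toy set deterministically", {
  set.seed(46)
  x <- rbind(matrix(rnorm(40, 2), ncol = 2), matrix(rnorm(40, -2), ncol = 2))
  y <- rep(c(TRUE, FALSE), each = 20)
  sc <- train_binary_classifier(x, y, seed = 1)
  s <- score_features(sc, x)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(s[y] > 0.5))
  expect_true(all(s[!y] < 0.5))
  # determinism
  sc2 <- train_binary_classifier(x, y, seed = 1)
  expect_equal(score_features(sc2, x), s, tolerance = 1e-12)
  # label inversion approximately flips the calibrated scores
  sc3 <- train_binary_classifier(x, !y, seed = 1)
  expect_equal(score_features(sc3, x), 1 - s, tolerance = 0.1)
  expect_error(train_binary_classifier(x, rep(TRUE, 40)), "both classes")
})

test_that("cross-validated AUROC is high for motif classes and errors on tiny data", {
  rec <- tiny_benchmark(seed = 13, n_members = 16, mutation_rate = 0,
                        n_nonenzymes = 16)
  seqs <- setNames(rec$sequence, rec$id)
  pos <- rec$id[rec$ec == "1.-.-.-"]
  neg <- c(rec$id[rec$ec == "2.-.-.-"][1:8], rec$id[rec$ec == ""][1:8])
  ds <- class_dataset("1.-.-.-", pos[1:14], neg, pos[15:16],
                      rec$id[rec$ec == ""][9:10])
  cfg <- tiny_config(seed = 13)
  r <- cross_validate_auroc(ds, seqs, "spmap", cfg)
  expect_gte(r$auroc, 0.9)  # exact motifs are near-perfectly separable
  expect_length(r$scores, 30L)
  r2 <- cross_validate_auroc(ds, seqs, "knn", cfg)
  expect_gte(r2$auroc, 0.9)
  # too few proteins for the fold count
  ds_small <- class_dataset("1.-.-.-", pos[1:2], neg[1:2], pos[3], neg[3])
  expect_error(cross_validate_auroc(ds_small, seqs, "pepstats", cfg),
               "too few")
})

test_that("a trained class model carries normalized weights and ordered cutoffs", {
  rec <- tiny_benchmark(seed = 14, n_members = 20, mutation_rate = 0,
                        n_nonenzymes = 20)
  seqs <- setNames(rec$sequence, rec$id)
  pos <- rec$id[rec$ec == "1.-.-.-"]
  other <- rec$id[rec$ec == "2.-.-.-"]
  ne <- rec$id[rec$ec == ""]
  ds <- class_dataset("1.-.-.-", pos[1:16], c(other[1:8], ne[1:8]),
                      pos[17:20], c(other[9:10], ne[9:10]))
  m <- train_class_model(ds, seqs, tiny_config(seed = 14))
  expect_s3_class(m, "ec_class_model")
  expect_equal(sum(m$weights), 1, tolerance = 1e-12)
  expect_gt(m$positive_cutoff, m$negative_cutoff)
  expect_true(all(m$auroc >= 0 & m$auroc <= 1))
  # the model scores its own positives above its negatives on average
  sc <- model_base_scores(m, seqs[c(pos[1:4], ne[1:4])])
  expect_gt(mean(sc$weighted[1:4]), mean(sc$weighted[5:8]))
})
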
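test_that("annotation propagation lists proteins under all ancestors and drops multi-EC", {
  rec <- make_records(c("p1", "p2", "p3"),
                      strrep("ACDEFGHIKL", 5),
                      ec = c("1.1.2.4", "2.-.-.-", "1.1.2.4;3.1.3.16"))
  cm <- propagate_annotations(rec)
  expect_setequal(names(cm), c("1.-.-.-", "1.1.-.-", "1.1.2.-", "1.1.2.4",
                               "2.-.-.-"))
  for (k in c("1.-.-.-", "1.1.-.-", "1.1.2.-", "1.1.2.4")) {
    expect_equal(cm[[k]], "p1")
  }
  expect_equal(cm[["2.-.-.-"]], "p2")  # level-1 annotation stays put
  expect_false("p3" %in% unlist(cm))   # multi-EC protein discarded

  # propagation is monotone: parents at least as populated as children
  rec2 <- toy_class_records()
  cm2 <- propagate_annotations(rec2)
  for (k in names(cm2)) {
    p <- ec_parent(k)
    if (!is.null(p) && ec_level(p) >= 1L) {
      expect_gte(length(cm2[[ec_format(p)]]), length(cm2[[k]]))
    }
  }
})

test_that("class eligibility respects the member-count boundary", {
  cm <- list("1.-.-.-" = sprintf("p%02d", 1:50),
             "2.-.-.-" = sprintf("q%02d", 1:49))
  expect_equal(select_trainable_classes(cm, 50), "1.-.-.-")
  expect_equal(select_trainable_classes(list(), 50), character(0))
  # ordering: level first, then components
  cm2 <- list("1.1.2.4" = letters[1:5], "2.-.-.-" = letters[1:5],
              "1.1.-.-" = letters[1:5], "1.-.-.-" = letters[1:5])
  expect_equal(select_trainable_classes(cm2, 1),
               c("1.-.-.-", "2.-.-.-", "1.1.-.-", "1.1.2.4"))
})

test_that("non-enzyme selection requires no EC and a reliable annotation score", {
  rec <- toy_class_records()
  ne <- select_nonenzymes(rec)
  expect_setequal(ne, sprintf("n%02d", 1:6))  # 5-star non-enzymes
  expect_false(any(sprintf("m%02d", 1:3) %in% ne))  # 2-star excluded
  expect_false(any(grepl("^a", ne)))               # enzymes excluded
  expect_length(select_nonenzymes(rec, min_annotation_score = 1L), 9L)
})

test_that("negative pool reproduces the hierarchy coloring", {
  rec <- toy_class_records()
  cm <- propagate_annotations(rec)
  ne <- select_nonenzymes(rec)
  pool <- build_negative_pool("1.1.-.-", cm, ne)
  positives <- attr(pool, "positive")

  # positives: 1.1.-.- and its descendants
  expect_setequal(positives, c(sprintf("a%02d", 1:6), sprintf("b%02d", 1:5)))
  # sibling branch: 1.2.-.- and 1.3.-.- subtrees
  expect_setequal(pool$sibling_branch,
                  c(sprintf("c%02d", 1:4), sprintf("d%02d", 1:3)))
  # other main classes: everything under 2 and 3
  expect_setequal(pool$other_main,
                  c(sprintf("e%02d", 1:8), sprintf("f%02d", 1:7)))
  expect_setequal(pool$nonenzyme, sprintf("n%02d", 1:6))
  # the four sets are mutually disjoint
  all_ids <- c(positives, pool$sibling_branch, pool$other_main, pool$nonenzyme)
  expect_equal(anyDuplicated(all_ids), 0L)

  # for a main class the sibling branch covers all other mains
  pool1 <- build_negative_pool("1.-.-.-", cm, ne)
  expect_length(pool1$other_main, 0L)
  expect_setequal(pool1$sibling_branch,
                  c(sprintf("e%02d", 1:8), sprintf("f%02d", 1:7)))
})

test_that("balanced negative sampling honors the mix, determinism and pool limits", {
  pool <- list(sibling_branch = sprintf("s%03d", 1:100),
               other_main = sprintf("o%03d", 1:100),
               nonenzyme = sprintf("n%03d", 1:100))
  x <- sample_balanced_negatives(pool, 40, c(sibling = 0.5, other = 0.25,
                                             nonenzyme = 0.25), seed = 3)
  expect_length(x, 40L)
  expect_equal(attr(x, "composition"),
               c(sibling = 20L, other = 10L, nonenzyme = 10L))
  expect_identical(
    as.character(x),
    as.character(sample_balanced_negatives(pool, 40,
                                           c(sibling = 0.5, other = 0.25,
                                             nonenzyme = 0.25), seed = 3)))

  # enzymes-only mix
  y <- sample_balanced_negatives(pool, 10, c(sibling = 1, other = 0,
                                             nonenzyme = 0), seed = 1)
  expect_true(all(grepl("^s", y)))

  # odd split mirrors the half-and-half balance within one id
  z <- sample_balanced_negatives(pool, 41, c(sibling = 0.5, other = 0,
                                             nonenzyme = 0.5), seed = 1)
  comp <- attr(z, "composition")
  expect_equal(sum(comp), 41L)
  expect_lte(abs(comp[["sibling"]] - comp[["nonenzyme"]]), 1L)

  # exhausted partition refills with a warning; undersized pool errors
  small <- list(sibling_branch = "s1", other_main = character(0),
                nonenzyme = sprintf("n%03d", 1:20))
  expect_warning(w <- sample_balanced_negatives(small, 10,
                                                c(sibling = 0.5, other = 0,
                                                  nonenzyme = 0.5), seed = 1),
                 "exhausted")
  expect_length(w, 10L)
  expect_error(sample_balanced_negatives(small, 50,
                                         c(sibling = 0.5, other = 0,
                                           nonenzyme = 0.5), seed = 1),
               "smaller")
})

test_that("greedy clustering matches the all-pairs identity oracle on a 3-sequence case", {
  set.seed(42)
  a <- random_aa_seq(100)
  b <- a
  pos <- sample(100, 38)
  for (p in pos) {
    substr(b, p, p) <- sample(setdiff(echier:::AA20,
                                      substr(a, p, p)), 1)
  }
  cc <- random_aa_seq(100)
  # oracle: independent identity computation confirms the design of the case
  expect_gte(bs_identity(a, b), 0.5)
  expect_lt(bs_identity(a, cc), 0.5)
  expect_lt(bs_identity(b, cc), 0.5)

  rec <- make_records(c("A", "B", "C"), c(a, b, cc))
  cl <- reduce_redundancy(rec, 0.5)
  memb <- lapply(cl$clusters, `[[`, "members")
  expect_length(memb, 2L)
  expect_setequal(memb[[which(vapply(memb, length, 1L) == 2L)]], c("A", "B"))
  expect_setequal(memb[[which(vapply(memb, length, 1L) == 1L)]], "C")

  # identical sequences share a cluster; sub-threshold pairs do not
  rec2 <- make_records(c("X", "Y"), c(a, a))
  expect_length(reduce_redundancy(rec2, 0.5)$clusters, 1L)
  rec3 <- make_records(c("X", "Y"), c(a, cc))
  expect_length(reduce_redundancy(rec3, 0.5)$clusters, 2L)

  # every input in exactly one cluster
  ids <- unlist(lapply(cl$clusters, `[[`, "members"))
  expect_setequal(ids, rec$id)
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("train/validation split is cluster-atomic and deterministic", {
  set.seed(7)
  rec <- make_records(sprintf("p%02d", 1:10),
                      vapply(1:10, function(i) random_aa_seq(80), ""))
  cl <- reduce_redundancy(rec, 0.5)
  expect_length(cl$clusters, 10L)  # random sequences are all dissimilar
  sp <- split_train_validation(cl, 0.1, seed = 5)
  expect_length(sp$validation, 1L)
  expect_length(sp$train, 9L)
  expect_length(intersect(sp$train, sp$validation), 0L)
  sp2 <- split_train_validation(cl, 0.1, seed = 5)
  expect_identical(sp, sp2)

  one <- make_records("p1", random_aa_seq(60))
  expect_warning(sp3 <- split_train_validation(reduce_redundancy(one), 0.1),
                 "fewer than two")
  expect_equal(sp3$train, "p1")
})
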
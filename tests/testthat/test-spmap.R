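test_that("sliding-window extraction keeps order and skips masked windows", {
  expect_equal(extract_subsequences("ACDEF", 5), "ACDEF")
  expect_equal(extract_subsequences("ACDEFG", 5), c("ACDEF", "CDEFG"))
  expect_equal(extract_subsequences("ACD", 5), character(0))
  # windows containing X are dropped
  expect_equal(extract_subsequences("ACXDEFGH", 3), c("DEF", "EFG", "FGH"))
})

test_that("subsequence similarity is the positionwise BLOSUM62 sum", {
  expect_equal(subsequence_similarity("AAAAA", "AAAAA"), 20)
  expect_equal(subsequence_similarity("AAAAA", "WWWWW"), -15)
  expect_error(subsequence_similarity("AAA", "AAAA"), "length")
  set.seed(3)
  for (i in 1:20) {
    x <- random_aa_seq(5); y <- random_aa_seq(5)
    expect_equal(subsequence_similarity(x, y), subsequence_similarity(y, x))
  }
})

test_that("online clustering follows the threshold rule on frozen cases", {
  c1 <- cluster_subsequences("AAAAA", t = 8)
  expect_length(c1, 1L)
  expect_equal(c1[[1]]$size, 1L)

  c2 <- cluster_subsequences(c("AAAAA", "AAAAA"), t = 8)  # s = 20 >= 8
  expect_length(c2, 1L)
  expect_equal(c2[[1]]$size, 2L)

  c3 <- cluster_subsequences(c("AAAAA", "WWWWW"), t = 8)  # s = -15 < 8
  expect_length(c3, 2L)
  expect_equal(vapply(c3, `[[`, "", "representative"), c("AAAAA", "WWWWW"))
})

test_that("online clustering matches the brute-force rescan oracle", {
  set.seed(11)
  for (rep in 1:5) {
    ss <- vapply(1:20, function(i) random_aa_seq(5), "")
    got <- cluster_subsequences(ss, t = 8)
    expect_equal(attr(got, "assignment"), bf_cluster_assign(ss, 8))
    # determinism: identical input gives identical clusters
    again <- cluster_subsequences(ss, t = 8)
    expect_identical(got[], again[])
  }
})

test_that("cluster counts are conserved per position", {
  set.seed(12)
  ss <- vapply(1:60, function(i) random_aa_seq(5), "")
  cl <- cluster_subsequences(ss, t = 8)
  for (c_id in seq_along(cl)) {
    expect_equal(unname(rowSums(cl[[c_id]]$counts)),
                 rep(cl[[c_id]]$size, 5))
  }
  expect_equal(sum(vapply(cl, `[[`, 1L, "size")), length(ss))
})

test_that("profiles implement the pseudo-count log formula and the discard rule", {
  # S_c = 5 out of 100 positives at 10% threshold -> discarded
  ss_small <- rep("AAAAA", 5)
  cl <- cluster_subsequences(ss_small, t = 8)
  expect_error(build_profiles(cl, n_positive = 100, discard_fraction = 0.10),
               "no profiles retained")

  # zero count with S_c = 100: ln(0.01/100) = ln(1e-4)
  cl2 <- cluster_subsequences(rep("AAAAA", 100), t = 8)
  pm2 <- build_profiles(cl2, n_positive = 100, discard_fraction = 0.10)
  pp <- pm2$profiles[[1]]$profile
  expect_equal(unname(pp[1, "W"]), log(1e-4), tolerance = 1e-9)
  expect_equal(unname(pp[1, "W"]), -9.21034, tolerance = 1e-4)
  expect_equal(unname(pp[1, "A"]), log(100.01 / 100), tolerance = 1e-9)

  # single-member cluster: ln(1.01)
  cl3 <- cluster_subsequences("AAAAA", t = 8)
  pm3 <- build_profiles(cl3, n_positive = 1, discard_fraction = 0.10)
  expect_equal(unname(pm3$profiles[[1]]$profile[1, "A"]), log(1.01), tolerance = 1e-9)
  expect_equal(unname(pm3$profiles[[1]]$profile[1, "A"]), 0.00995, tolerance = 1e-4)
})

test_that("subsequence log-probability sums the per-position profile terms", {
  pm <- build_profiles(cluster_subsequences("AAAAA", t = 8),
                       n_positive = 1, discard_fraction = 0.10)
  pp <- pm$profiles[[1]]$profile
  expect_equal(subsequence_log_prob("AAAAA", pp), 5 * log(1.01),
               tolerance = 1e-9)
  expect_equal(subsequence_log_prob("WWWWW", pp), 5 * log(0.01),
               tolerance = 1e-9)
  # monotone: swapping a residue to a zero-count symbol cannot increase it
  expect_lt(subsequence_log_prob("AAAAW", pp),
            subsequence_log_prob("AAAAA", pp))
})

test_that("feature vectors exponentiate the best window, clipped into (0, 1]", {
  pm <- build_profiles(cluster_subsequences("AAAAA", t = 8),
                       n_positive = 1, discard_fraction = 0.10)
  v <- spmap_featurize("AAAAA", pm)
  expect_equal(dim(v), c(1L, 1L))
  expect_equal(v[1, 1], 1)  # exp(5 ln 1.01) = 1.051 clipped to 1
  w <- spmap_featurize("WWWWW", pm)
  expect_equal(w[1, 1], exp(5 * log(0.01)), tolerance = 1e-12)
  expect_equal(w[1, 1], 1e-10, tolerance = 1e-12)
  # dimension equals the number of retained profiles
  set.seed(5)
  ss <- c(rep("AAAAA", 4), rep("WWWWW", 4), rep("CCCCC", 4))
  pm2 <- build_profiles(cluster_subsequences(ss, t = 8), n_positive = 10,
                        discard_fraction = 0.10)
  x <- spmap_featurize(c("AAAAAWWWWW", "CCCCC"), pm2)
  expect_equal(ncol(x), length(pm2$profiles))
  expect_true(all(x > 0))
  # too-short sequence: zero vector with a warning
  expect_warning(z <- spmap_featurize("ACD", pm2), "shorter")
  expect_true(all(z == 0))
})

test_that("profile maps survive a JSON round trip", {
  set.seed(6)
  ss <- unlist(lapply(1:8, function(i) {
    s <- random_aa_seq(5)
    rep(s, 3)
  }))
  pm <- build_profiles(cluster_subsequences(ss, t = 8), n_positive = 8,
                       discard_fraction = 0.10)
  f <- withr::local_tempfile(fileext = ".json")
  write_profile_map(pm, f)
  back <- read_profile_map(f)
  expect_equal(back$l, pm$l)
  expect_equal(length(back$profiles), length(pm$profiles))
  for (i in seq_along(pm$profiles)) {
    expect_equal(back$profiles[[i]]$profile, pm$profiles[[i]]$profile,
                 tolerance = 1e-12)
  }
  q <- random_aa_seq(30)
  expect_equal(spmap_featurize(q, back), spmap_featurize(q, pm))
})
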
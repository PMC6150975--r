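# A scripted model tree covering main classes 1 and 2, subclasses of 1,
# sub-subclasses of 1.1 and substrates of 1.1.2, with hand-set scores
# per query id, exercising every decision rule in isolation.
scripted_tree <- function() {
  sc <- function(...) c(...)
  model_tree(list(
    scripted_model("1.-.-.-", sc(q_full = 0.95, q_stop1 = 0.91,
                                 q_nonez = 0.05, q_nopred = 0.45,
                                 q_tie = 0.80),
                   positive_cutoff = 0.70),
    scripted_model("2.-.-.-", sc(q_full = 0.20, q_nonez = 0.10,
                                 q_nopred = 0.20, q_tie = 0.80),
                   positive_cutoff = 0.75),
    scripted_model("1.1.-.-", sc(q_full = 0.90, q_stop1 = 0.30),
                   positive_cutoff = 0.65),
    scripted_model("1.2.-.-", sc(q_full = 0.40, q_stop1 = 0.20),
                   positive_cutoff = 0.65),
    scripted_model("1.1.2.-", sc(q_full = 0.88), positive_cutoff = 0.60),
    scripted_model("1.1.2.4", sc(q_full = 0.85), positive_cutoff = 0.55)))
}

test_that("single-level decision applies cutoffs, maxima and tie-breaks", {
  tree <- scripted_tree()
  top <- unname(tree$models[c("1.-.-.-", "2.-.-.-")])

  # accept: one class above its cutoff
  d <- predict_level(c(q_full = "SEQ"), top, check_negative = TRUE)
  expect_equal(d$decision, "accept")
  expect_equal(d$ec, "1.-.-.-")
  expect_equal(d$score, 0.95)

  # all below the negative cutoff at the gate -> non-enzyme evidence
  d2 <- predict_level(c(q_nonez = "SEQ"), top, check_negative = TRUE)
  expect_equal(d2$decision, "below_negative")

  # in between: neither accepted nor rejected
  d3 <- predict_level(c(q_nopred = "SEQ"), top, check_negative = TRUE)
  expect_equal(d3$decision, "none_above_cutoff")

  # two classes above cutoff and tied -> lexicographically smallest EC
  d4 <- predict_level(c(q_tie = "SEQ"), top, check_negative = TRUE)
  expect_equal(d4$decision, "accept")
  expect_equal(d4$ec, "1.-.-.-")

  # below deeper levels the negative rule does not apply
  subs <- unname(tree$models[c("1.1.-.-", "1.2.-.-")])
  d5 <- predict_level(c(q_nonez = "SEQ"), subs, check_negative = FALSE)
  expect_equal(d5$decision, "none_above_cutoff")

  expect_error(predict_level(c(q = "SEQ"), list()), "no candidate")
})

test_that("traversal reproduces the accept-chain to a four-component EC", {
  tree <- scripted_tree()
  r <- predict_protein(tree, "SEQ", "q_full")
  expect_equal(r$label, "1.1.2.4")
  expect_equal(r$confidence, 0.85)  # weighted score of the deepest accept
  # the audit trail covers all four levels walked
  expect_setequal(names(r$per_level), c("1", "2", "3", "4"))
  # path consistency: each accepted level is a descendant of the previous
  path <- c("1.-.-.-", "1.1.-.-", "1.1.2.-", "1.1.2.4")
  for (i in 2:4) {
    expect_equal(ec_relation(path[i - 1], path[i]), "ancestor")
  }
})

test_that("traversal labels sub-negative queries non-enzyme and ambiguous ones no prediction", {
  tree <- scripted_tree()
  expect_equal(predict_protein(tree, "SEQ", "q_nonez")$label, "non-enzyme")
  expect_equal(predict_protein(tree, "SEQ", "q_nopred")$label, "no prediction")
})

test_that("traversal finalizes at the previous level when children miss their cutoffs", {
  tree <- scripted_tree()
  r <- predict_protein(tree, "SEQ", "q_stop1")
  expect_equal(r$label, "1.-.-.-")
  expect_equal(r$confidence, 0.91)
  # a class without trained children finalizes at that class
  r2 <- predict_protein(tree, "SEQ", "q_tie")  # accepts 1.-.-.- then 1.1/1.2 score 0
  expect_equal(r2$label, "1.-.-.-")
})

test_that("a query never gets an EC label without passing the level-1 gate", {
  tree <- scripted_tree()
  ids <- c("q_full", "q_stop1", "q_nonez", "q_nopred", "q_tie", "q_unknown")
  for (id in ids) {
    r <- predict_protein(tree, "SEQ", id)
    if (!r$label %in% c("non-enzyme", "no prediction")) {
      l1 <- r$per_level[["1"]]
      acc <- ec_format(ec_truncate(r$label, 1))
      expect_gt(l1[[acc]],
                tree$models[[acc]]$positive_cutoff)
    }
  }
})

test_that("model tree construction validates parents and duplicates", {
  expect_error(model_tree(list(
    scripted_model("1.1.-.-", c(q = 1), 0.5))), "no parent")
  expect_error(model_tree(list(
    scripted_model("1.-.-.-", c(q = 1), 0.5),
    scripted_model("1.-.-.-", c(q = 1), 0.5))), "duplicate")
})

test_that("batch prediction returns one row per query with audit details", {
  tree <- scripted_tree()
  rec <- data.frame(id = c("q_full", "q_nonez"), sequence = c("SEQ", "SEQ"),
                    stringsAsFactors = FALSE)
  out <- predict_sequences(tree, rec)
  expect_equal(nrow(out), 2L)
  expect_equal(out$label, c("1.1.2.4", "non-enzyme"))
  expect_length(attr(out, "details"), 2L)
})
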
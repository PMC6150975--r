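#' Area under the ROC curve (rank formulation)
#'
#' Mann-Whitney form: mean rank of the positive scores among all
#' scores, with 0.5 credit for ties.  Equals the probability that a
#' random positive outscores a random negative.
#'
#' @param scores numeric vector.
#' @param labels logical vector, `TRUE` = positive.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both classes required for AUROC")
  r <- rank(scores)  # ties get average rank = 0.5 credit per tied pair
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Stratified fold assignment: within each class, ids are shuffled under
# the seed and dealt to folds round-robin.
stratified_folds <- function(labels, folds, seed = 42L) {
  labels <- as.logical(labels)
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' AUROC-derived ensemble weights
#'
#' Each base predictor's weight is its cross-validated AUROC raised to
#' the fourth power, normalized over the three predictors -- a sharp
#' weighting that concentrates mass on the better-ranked predictor
#' while keeping all three in play.
#'
#' @param r numeric vector of 3 AUROC values in \[0, 1\] (named by
#'   predictor; names are preserved).
#' @return weights summing to 1.
#' @export
combine_weights <- function(r) {
  stopifnot(length(r) == 3L, all(r >= 0), all(r <= 1))
  if (all(r == 0)) stop("all AUROC values are zero; weights undefined")
  r^4 / sum(r^4)
}

#' Weighted ensemble score
#'
#' @param scores numeric vector of base-predictor scores in \[0, 1\]
#'   (same order as `weights`).
#' @param weights weights from [combine_weights()].
#' @return weighted mean in \[0, 1\].
#' @export
weighted_score <- function(scores, weights) {
  stopifnot(length(scores) == length(weights))
  sum(scores * weights)
}

#' F1-optimal positive score cutoff
#'
#' Sweeps candidate cutoffs over a regular grid on \[0, 1\].  At each
#' cutoff a positive validation protein scoring strictly above it is a
#' TP (otherwise FN) and a negative one strictly above is an FP
#' (otherwise TN); the cutoff maximizing F1 is returned, ties broken
#' toward the largest cutoff (the most conservative of the equally
#' good choices).  The result is clamped strictly above
#' `negative_cutoff` so that the positive and negative decision bands
#' cannot overlap.
#'
#' @param scores numeric validation scores in \[0, 1\].
#' @param labels logical vector, `TRUE` = positive; both classes
#'   required.
#' @param negative_cutoff lower bound (exclusive) for the result.
#' @param grid_step cutoff grid resolution (default 0.01).
#' @return the selected cutoff, with attribute `"f1"` (the F1 achieved
#'   at it on the validation scores).
#' @export
select_positive_cutoff <- function(scores, labels, negative_cutoff = 0.3,
                                   grid_step = 0.01) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("both classes required to select a cutoff")
  }
  grid <- seq(0, 1, by = grid_step)
  pos <- scores[labels]
  neg <- scores[!labels]
  f1 <- vapply(grid, function(cut) {
    tp <- sum(pos > cut)
    fn <- length(pos) - tp
    fp <- sum(neg > cut)
    precision_recall_f1(tp, fp, fn)[["f1"]]
  }, numeric(1))
  best <- max(f1)
  cut <- grid[max(which(f1 == best))]
  if (best < 0.5 || cut < min(scores)) {
    warning("cutoff sweep is degenerate (best F1 = ", signif(best, 3),
            ", cutoff ", cut, "); validation scores barely separate ",
            "the classes")
  }
  if (cut <= negative_cutoff) {
    warning("F1-optimal cutoff ", cut, " at or below the negative cutoff ",
            negative_cutoff, "; clamping above it")
    cand <- grid[grid > negative_cutoff]
    cut <- if (length(cand) > 0L) cand[1] else negative_cutoff + grid_step
  }
  structure(cut, f1 = best)
}

# ---- per-predictor scoring helpers ----------------------------------------

spmap_fit <- function(pos_seqs, config) {
  ss <- unlist(lapply(pos_seqs, extract_subsequences, l = config$l),
               use.names = FALSE)
  clusters <- cluster_subsequences(ss, t = config$t,
                                   comparison = config$cluster_comparison)
  build_profiles(clusters, n_positive = length(pos_seqs),
                 discard_fraction = config$discard_fraction)
}

knn_scores_from_matrix <- function(sim, query_ids, train_ids, positive_ids, k) {
  vapply(query_ids, function(q) {
    db <- setdiff(train_ids, q)
    knn_unit_score(knn_score(sim[q, db], positive_ids, k = k))
  }, numeric(1))
}

#' Cross-validated AUROC of one base predictor on a class dataset
#'
#' Stratified fold assignment under the configuration seed; for each
#' fold the predictor is refitted on the in-fold training data (the
#' profile map is rebuilt on in-fold positives for `"spmap"`, the
#' scaler refitted for `"pepstats"`, the neighbour database restricted
#' for `"knn"`), out-of-fold proteins are scored, and a single AUROC
#' is computed over the pooled out-of-fold scores.
#'
#' @param dataset a [class_dataset()].
#' @param sequences named character vector: id to sanitized sequence.
#' @param predictor `"spmap"`, `"knn"` or `"pepstats"`.
#' @param config an [ec_config()].
#' @param sim optional precomputed [similarity_matrix()] over the
#'   training ids (computed on demand for `"knn"`).
#' @return list with `auroc` and the pooled out-of-fold `scores`
#'   (named by protein id).
#' @export
cross_validate_auroc <- function(dataset, sequences,
                                 predictor = c("spmap", "knn", "pepstats"),
                                 config = ec_config(), sim = NULL) {
  predictor <- match.arg(predictor)
  ids <- c(dataset$positive_train, dataset$negative_train)
  labels <- c(rep(TRUE, length(dataset$positive_train)),
              rep(FALSE, length(dataset$negative_train)))
  if (sum(labels) < config$folds || sum(!labels) < config$folds) {
    stop("class ", dataset$ec, ": too few training proteins for ",
         config$folds, "-fold cross-validation")
  }
  seqs <- sequences[ids]
  folds <- stratified_folds(labels, config$folds,
                            derive_seed(config$seed, paste0("cv-", dataset$ec)))
  oof <- setNames(numeric(length(ids)), ids)

  if (predictor == "pepstats") feats <- pepstats_matrix(seqs)
  if (predictor == "knn" && is.null(sim)) {
    sim <- similarity_matrix(seqs, config$gap_open_local, config$gap_ext_local)
  }
  for (f in seq_len(config$folds)) {
    in_f <- folds != f
    out_f <- !in_f
    if (predictor == "spmap") {
      pmap <- spmap_fit(seqs[in_f & labels], config)
      x_in <- spmap_featurize(seqs[in_f], pmap)
      scorer <- train_binary_classifier(x_in, labels[in_f],
                                        cost = config$svm_cost,
                                        gamma = config$svm_gamma,
                                        seed = config$seed)
      oof[out_f] <- score_features(scorer, spmap_featurize(seqs[out_f], pmap))
    } else if (predictor == "pepstats") {
      scaler <- fit_scaler(feats[in_f, , drop = FALSE], config$scaling)
      scorer <- train_binary_classifier(
        apply_scaler(scaler, feats[in_f, , drop = FALSE]), labels[in_f],
        cost = config$svm_cost, gamma = config$svm_gamma, seed = config$seed)
      oof[out_f] <- score_features(
        scorer, apply_scaler(scaler, feats[out_f, , drop = FALSE]))
    } else {
      train_ids <- ids[in_f]
      pos_ids <- ids[in_f & labels]
      oof[out_f] <- knn_scores_from_matrix(sim, ids[out_f], train_ids,
                                           pos_ids, config$k)
    }
  }
  list(auroc = auroc(oof, labels), scores = oof)
}

# ---- the per-class ensemble model -----------------------------------------

#' Train the full ensemble model of one EC class
#'
#' Orchestrates, for a single EC class: profile-map construction on the
#' positive training proteins and SVM training on its features; the
#' physicochemical-descriptor scaler and SVM; the local-alignment
#' neighbour database; per-predictor cross-validated AUROC
#' ([cross_validate_auroc()]); fourth-power AUROC weights
#' ([combine_weights()]); and the F1-optimal positive cutoff selected
#' on the held-out validation scores of the weighted ensemble
#' ([select_positive_cutoff()]).  The negative cutoff is the global
#' configuration value.
#'
#' @param dataset a [class_dataset()] with non-empty validation sets.
#' @param sequences named character vector: id to sanitized sequence.
#' @param config an [ec_config()].
#' @return object of class `ec_class_model`.
#' @export
train_class_model <- function(dataset, sequences, config = ec_config()) {
  train_ids <- c(dataset$positive_train, dataset$negative_train)
  labels <- c(rep(TRUE, length(dataset$positive_train)),
              rep(FALSE, length(dataset$negative_train)))
  seqs <- sequences[train_ids]
  sim <- similarity_matrix(seqs, config$gap_open_local, config$gap_ext_local)

  cv <- list(
    spmap = cross_validate_auroc(dataset, sequences, "spmap", config),
    knn = cross_validate_auroc(dataset, sequences, "knn", config, sim = sim),
    pepstats = cross_validate_auroc(dataset, sequences, "pepstats", config))
  r <- vapply(cv, `[[`, numeric(1), "auroc")
  weights <- combine_weights(r)

  # final scorers on the full training data
  pmap <- spmap_fit(seqs[labels], config)
  spmap_scorer <- train_binary_classifier(
    spmap_featurize(seqs, pmap), labels,
    cost = config$svm_cost, gamma = config$svm_gamma, seed = config$seed)
  pep_feats <- pepstats_matrix(seqs)
  pep_scaler <- fit_scaler(pep_feats, config$scaling)
  pep_scorer <- train_binary_classifier(
    apply_scaler(pep_scaler, pep_feats), labels,
    cost = config$svm_cost, gamma = config$svm_gamma, seed = config$seed)

  model <- structure(list(
    ec = dataset$ec,
    pmap = pmap,
    spmap_scorer = spmap_scorer,
    pepstats_scaler = pep_scaler,
    pepstats_scorer = pep_scorer,
    knn = list(train_seqs = seqs, positive_ids = dataset$positive_train,
               k = config$k, gap_open = config$gap_open_local,
               gap_ext = config$gap_ext_local),
    auroc = r,
    weights = weights,
    positive_cutoff = NA_real_,
    negative_cutoff = config$negative_cutoff,
    composition = list(train = dataset$composition_train,
                       val = dataset$composition_val)),
    class = "ec_class_model")

  val_ids <- c(dataset$positive_val, dataset$negative_val)
  if (length(dataset$positive_val) == 0L || length(dataset$negative_val) == 0L) {
    stop("class ", dataset$ec, ": validation set must contain both classes")
  }
  val_scores <- model_weighted_scores(model, sequences[val_ids])
  val_labels <- c(rep(TRUE, length(dataset$positive_val)),
                  rep(FALSE, length(dataset$negative_val)))
  cut <- select_positive_cutoff(val_scores, val_labels,
                                negative_cutoff = config$negative_cutoff,
                                grid_step = config$cutoff_grid_step)
  model$positive_cutoff <- as.numeric(cut)
  model$validation_f1 <- attr(cut, "f1")
  model
}

#' Base-predictor and ensemble scores of query sequences
#'
#' @param model an `ec_class_model`.
#' @param sequences character vector of sanitized query sequences.
#' @return data frame with columns `spmap`, `knn`, `pepstats`,
#'   `weighted`.
#' @export
model_base_scores <- function(model, sequences) {
  sp <- score_features(model$spmap_scorer,
                       spmap_featurize(sequences, model$pmap))
  pp <- score_features(model$pepstats_scorer,
                       apply_scaler(model$pepstats_scaler,
                                    pepstats_matrix(sequences)))
  kn <- vapply(sequences, function(s) {
    sc <- similarity_scores(s, model$knn$train_seqs,
                            model$knn$gap_open, model$knn$gap_ext)
    knn_unit_score(knn_score(sc, model$knn$positive_ids, k = model$knn$k))
  }, numeric(1), USE.NAMES = FALSE)
  w <- model$weights
  data.frame(spmap = sp, knn = kn, pepstats = pp,
             weighted = w[["spmap"]] * sp + w[["knn"]] * kn +
               w[["pepstats"]] * pp)
}

#' Weighted ensemble score of query sequences under a class model
#'
#' Generic so that scripted stand-in models (fixed scores per query id,
#' see [scripted_model()]) can be used to exercise the hierarchical
#' traversal rules.
#'
#' @param model an `ec_class_model` or `scripted_model`.
#' @param sequences named (by query id, for scripted models) character
#'   vector of sequences.
#' @return numeric vector of weighted scores, one per query.
#' @export
model_weighted_scores <- function(model, sequences) {
  UseMethod("model_weighted_scores")
}

#' @export
model_weighted_scores.ec_class_model <- function(model, sequences) {
  model_base_scores(model, sequences)$weighted
}

#' @export
print.ec_class_model <- function(x, ...) {
  cat("<ec_class_model ", x$ec, ">\n", sep = "")
  cat("  AUROC:  ", paste(sprintf("%s=%.3f", names(x$auroc), x$auroc),
                          collapse = "  "), "\n")
  cat("  weights:", paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                          collapse = "  "), "\n")
  cat(sprintf("  cutoffs: positive=%.2f negative=%.2f\n",
              x$positive_cutoff, x$negative_cutoff))
  invisible(x)
}

#' Scripted class model with fixed scores
#'
#' A stand-in class model whose "ensemble score" for a query is looked
#' up by query id instead of computed from sequence.  Useful to test
#' and demonstrate the hierarchical decision rules in isolation from
#' any trained scorer.
#'
#' @param ec EC class of the model.
#' @param score_by_id named numeric vector: query id to score; ids
#'   absent from it score 0.
#' @param positive_cutoff class-specific acceptance threshold.
#' @param negative_cutoff rejection threshold (used at the top level).
#' @return object of classes `scripted_model` and `ec_class_model`.
#' @export
scripted_model <- function(ec, score_by_id, positive_cutoff,
                           negative_cutoff = 0.3) {
  structure(list(ec = ec_format(ec), score_by_id = score_by_id,
                 positive_cutoff = positive_cutoff,
                 negative_cutoff = negative_cutoff),
            class = c("scripted_model", "ec_class_model"))
}

#' @export
model_weighted_scores.scripted_model <- function(model, sequences) {
  ids <- names(sequences)
  if (is.null(ids)) stop("scripted models need queries named by id")
  out <- unname(model$score_by_id[ids])
  out[is.na(out)] <- 0
  out
}
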
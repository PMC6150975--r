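#' Precision, recall and F1 from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`.  Zero
#' denominators follow the documented conventions: a quantity with an
#' empty denominator is 1 when there was nothing to get wrong
#' (`TP+FP = 0` and `FN = 0` gives P = 1; `TP+FN = 0` and `FP = 0`
#' gives R = 1) and 0 otherwise; F1 is 0 whenever `TP = 0` while
#' `FP > 0` or `FN > 0`.
#'
#' @param tp,fp,fn non-negative integer counts.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else if (fn == 0) 1 else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else if (fp == 0) 1 else 0
  f1 <- if (tp == 0 && (fp > 0 || fn > 0)) 0
        else if (precision + recall > 0) 2 * precision * recall / (precision + recall)
        else 0
  if (tp == 0 && fp == 0 && fn == 0) f1 <- 1  # degenerate: nothing to score
  c(precision = precision, recall = recall, f1 = f1)
}

#' Level-wise evaluation of hierarchical predictions
#'
#' Level 0 scores the enzyme / non-enzyme gate (positive class:
#' enzyme).  At levels 1-4 a prediction is correct for a protein iff
#' the predicted EC number truncated to that level equals the true EC
#' number truncated to the same level; only proteins whose true
#' annotation reaches the level are scored there.  A query answered
#' "no prediction" counts as a miss for its true class (it hurts
#' recall) but never as a false positive (it does not hurt precision).
#' Micro metrics pool the confusion counts; macro metrics are the
#' unweighted mean of the per-class precision / recall / F1 over the
#' classes present in the truth at that level.
#'
#' @param predictions data frame with columns `protein_id` and `label`
#'   (EC string, `"non-enzyme"` or `"no prediction"`).
#' @param truth named character vector: protein id to true EC string or
#'   `"non-enzyme"`.  Every predicted id must be present.
#' @return data frame with one row per level (0 up to the deepest true
#'   annotation): confusion counts, micro precision/recall/F1 and macro
#'   variants (macro columns are NA at level 0, where there is a single
#'   positive class).
#' @export
evaluate_levelwise <- function(predictions, truth) {
  missing_ids <- setdiff(predictions$protein_id, names(truth))
  if (length(missing_ids) > 0L) {
    stop("prediction id(s) absent from truth: ",
         paste(head(missing_ids, 5), collapse = ", "))
  }
  tr <- truth[predictions$protein_id]
  pred <- predictions$label

  truth_is_enzyme <- tr != "non-enzyme"
  pred_is_enzyme <- !(pred %in% c("non-enzyme", "no prediction"))
  pred_says_non <- pred == "non-enzyme"

  rows <- list()
  tp <- sum(truth_is_enzyme & pred_is_enzyme)
  fn <- sum(truth_is_enzyme & !pred_is_enzyme)
  fp <- sum(!truth_is_enzyme & pred_is_enzyme)
  tn <- sum(!truth_is_enzyme & !pred_is_enzyme)
  prf <- precision_recall_f1(tp, fp, fn)
  rows[[1]] <- data.frame(level = 0L, tp = tp, fp = fp, fn = fn, tn = tn,
                          precision = prf[["precision"]],
                          recall = prf[["recall"]], f1 = prf[["f1"]],
                          macro_precision = NA_real_, macro_recall = NA_real_,
                          macro_f1 = NA_real_)

  truth_level <- ifelse(truth_is_enzyme,
                        vapply(tr, function(x)
                          if (x == "non-enzyme") 0L else ec_level(x), 0L), 0L)
  pred_level <- ifelse(pred_is_enzyme,
                       vapply(pred, function(x)
                         if (x %in% c("non-enzyme", "no prediction")) 0L
                         else ec_level(x), 0L), 0L)
  max_level <- max(c(0L, truth_level))

  trunc_str <- function(x, d) ec_format(ec_truncate(x, d))
  for (d in seq_len(max_level)) {
    scored <- truth_level >= d
    t_d <- ifelse(scored, vapply(tr, function(x)
      if (x == "non-enzyme" || ec_level(x) < d) NA_character_
      else trunc_str(x, d), ""), NA_character_)
    p_d <- ifelse(pred_level >= d,
                  vapply(pred, function(x)
                    if (x %in% c("non-enzyme", "no prediction") ||
                        ec_level(x) < d) NA_character_
                    else trunc_str(x, d), ""), NA_character_)
    classes <- sort(unique(t_d[!is.na(t_d)]))
    per_class <- lapply(classes, function(cl) {
      tp_c <- sum(!is.na(t_d) & t_d == cl & !is.na(p_d) & p_d == cl)
      fn_c <- sum(!is.na(t_d) & t_d == cl & (is.na(p_d) | p_d != cl))
      fp_c <- sum((is.na(t_d) | t_d != cl) & !is.na(p_d) & p_d == cl)
      c(tp = tp_c, fp = fp_c, fn = fn_c,
        precision_recall_f1(tp_c, fp_c, fn_c))
    })
    counts <- do.call(rbind, per_class)
    tp <- sum(counts[, "tp"]); fp <- sum(counts[, "fp"]); fn <- sum(counts[, "fn"])
    prf <- precision_recall_f1(tp, fp, fn)
    rows[[d + 1L]] <- data.frame(
      level = d, tp = tp, fp = fp, fn = fn,
      tn = sum(scored) * length(classes) - tp - fp - fn,
      precision = prf[["precision"]], recall = prf[["recall"]],
      f1 = prf[["f1"]],
      macro_precision = mean(counts[, "precision"]),
      macro_recall = mean(counts[, "recall"]),
      macro_f1 = mean(counts[, "f1"]))
  }
  do.call(rbind, rows)
}

#' Write a level-wise evaluation report
#'
#' @param report data frame from [evaluate_levelwise()].
#' @param path output TSV path.
#' @export
write_level_report <- function(report, path) {
  write.table(format(report, digits = 4), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
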
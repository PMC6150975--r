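#' Train a calibrated binary SVM scorer
#'
#' Radial-kernel support-vector machine (via \pkg{e1071}/libsvm) whose
#' decision values are mapped to \[0, 1\] by a Platt-style logistic
#' calibration fitted on the training decision values.  The default
#' kernel width is `1 / (n_features * var(features))` (falling back to
#' `1 / n_features` for degenerate variance).  Training is
#' deterministic for fixed inputs; `seed` is kept for interface
#' stability and future stochastic kernels.
#'
#' @param features numeric training matrix.
#' @param labels logical (or 0/1) vector, `TRUE` = positive class; both
#'   classes must be present.
#' @param cost soft-margin cost C (default 1).
#' @param gamma RBF kernel width; `NULL` for the default above.
#' @param seed integer seed.
#' @return object of class `binary_scorer`.
#' @export
train_binary_classifier <- function(features, labels, cost = 1,
                                    gamma = NULL, seed = 42L) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to train a binary classifier")
  }
  if (is.null(gamma)) {
    v <- var(as.vector(features))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(features) * v)
             else 1 / ncol(features)
  }
  y <- factor(ifelse(labels, "pos", "neg"), levels = c("neg", "pos"))
  fit <- with_seed(seed, e1071::svm(x = features, y = y, kernel = "radial",
                                    cost = cost, gamma = gamma,
                                    scale = FALSE, probability = FALSE))
  dv <- attr(predict(fit, features, decision.values = TRUE),
             "decision.values")[, 1]
  # Platt calibration; the glm learns the sign of the decision values,
  # so the libsvm label orientation is irrelevant.  Perfect separation
  # only drives the fitted probabilities to 0/1, which is acceptable.
  cal <- suppressWarnings(glm(labels ~ dv, family = binomial()))
  coefs <- stats::coef(cal)
  if (anyNA(coefs)) coefs[is.na(coefs)] <- 0
  structure(list(svm = fit, platt = unname(coefs), gamma = gamma,
                 cost = cost, n_train = nrow(features)),
            class = "binary_scorer")
}

#' Score proteins with a trained binary scorer
#'
#' @param scorer a [train_binary_classifier()] result.
#' @param features numeric matrix (same columns as at training).
#' @return numeric vector of scores in \[0, 1\].
#' @export
score_features <- function(scorer, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  dv <- attr(predict(scorer$svm, features, decision.values = TRUE),
             "decision.values")[, 1]
  unname(plogis(scorer$platt[1] + scorer$platt[2] * dv))
}

#' @export
print.binary_scorer <- function(x, ...) {
  cat("<binary_scorer> RBF SVM (cost=", x$cost, ", gamma=",
      signif(x$gamma, 4), ") trained on ", x$n_train,
      " samples, Platt-calibrated\n", sep = "")
  invisible(x)
}
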
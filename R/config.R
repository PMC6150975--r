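#' Pipeline configuration
#'
#' Collects every tunable of the training and prediction pipeline with
#' its default.  Unknown keys are rejected.
#'
#' Key parameters (defaults in parentheses):
#' \describe{
#'   \item{l (5)}{subsequence window length of the profile-map featurizer.}
#'   \item{t (8)}{BLOSUM62 similarity threshold for joining a subsequence
#'     cluster.}
#'   \item{k (5)}{neighbours used by the similarity vote.}
#'   \item{folds (5)}{cross-validation folds for AUROC weighting.}
#'   \item{discard_fraction (0.10)}{minimum cluster size as a fraction of
#'     the positive training-set size; smaller clusters are dropped.}
#'   \item{min_class_size (50)}{minimum proteins per EC class for a model
#'     to be trained.}
#'   \item{min_annotation_score (4)}{minimum star rating for a protein
#'     without enzymatic annotation to count as a reliable non-enzyme.}
#'   \item{identity_threshold (0.5)}{global-alignment identity at or above
#'     which two sequences share a redundancy cluster.}
#'   \item{val_fraction (0.1)}{fraction of redundancy clusters held out
#'     for validation.}
#'   \item{negative_cutoff (0.3)}{global rejection threshold applied at
#'     the enzyme/non-enzyme gate.}
#'   \item{mix_main / mix_sub}{negative-set composition (fractions over
#'     sibling-branch enzymes, other-main-class enzymes, non-enzymes).}
#'   \item{wne (FALSE)}{ablation: drop non-enzymes from negative sets,
#'     redistributing their share to the enzyme partitions.}
#' }
#'
#' @param ... named overrides of the defaults.
#' @return A list of class `ec_config`.
#' @export
ec_config <- function(...) {
  cfg <- list(
    l = 5L,
    t = 8L,
    k = 5L,
    folds = 5L,
    discard_fraction = 0.10,
    min_class_size = 50L,
    min_annotation_score = 4L,
    identity_threshold = 0.5,
    val_fraction = 0.1,
    negative_cutoff = 0.3,
    mix_main = c(sibling = 0.5, other = 0.0, nonenzyme = 0.5),
    mix_sub = c(sibling = 0.5, other = 0.25, nonenzyme = 0.25),
    wne = FALSE,
    use_representatives = TRUE,
    residue_policy = "mask",
    cluster_comparison = "representative",
    scaling = "minmax",
    svm_cost = 1,
    svm_gamma = NULL,
    gap_open_local = 11,
    gap_ext_local = 1,
    gap_open_global = 10,
    gap_ext_global = 1,
    cutoff_grid_step = 0.01,
    seed = 42L
  )
  over <- list(...)
  if (length(over) > 0L) {
    if (is.null(names(over)) || any(!nzchar(names(over)))) {
      stop("all configuration overrides must be named")
    }
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0L) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  structure(cfg, class = "ec_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$l >= 1, cfg$k >= 1, cfg$folds >= 2,
            cfg$discard_fraction >= 0, cfg$discard_fraction <= 1,
            cfg$identity_threshold > 0, cfg$identity_threshold <= 1,
            cfg$val_fraction > 0, cfg$val_fraction < 1,
            cfg$negative_cutoff >= 0, cfg$negative_cutoff < 1)
  for (nm in c("mix_main", "mix_sub")) {
    mx <- cfg[[nm]]
    if (!setequal(names(mx), c("sibling", "other", "nonenzyme")) ||
        abs(sum(mx) - 1) > 1e-9 || any(mx < 0)) {
      stop(nm, " must be non-negative fractions over ",
           "{sibling, other, nonenzyme} summing to 1")
    }
  }
  if (!cfg$residue_policy %in% c("mask", "strict")) {
    stop("residue_policy must be 'mask' or 'strict'")
  }
  if (!cfg$cluster_comparison %in% c("representative", "members")) {
    stop("cluster_comparison must be 'representative' or 'members'")
  }
  if (!cfg$scaling %in% c("minmax", "zscore")) {
    stop("scaling must be 'minmax' or 'zscore'")
  }
  invisible(cfg)
}

# wne ablation: zero the non-enzyme share of a mix and scale the enzyme
# shares back up to 1.
apply_wne <- function(mix) {
  mix["nonenzyme"] <- 0
  s <- sum(mix)
  if (s <= 0) stop("negative mix degenerate after removing non-enzymes")
  mix / s
}

#' @export
print.ec_config <- function(x, ...) {
  cat("<ec_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}

#' Read / write a configuration file
#'
#' Plain-text YAML serialization of an [ec_config()].  Unknown keys in
#' the file are rejected.
#'
#' @param path file path.
#' @param config an `ec_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  for (nm in c("mix_main", "mix_sub")) {
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  }
  do.call(ec_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$mix_main <- as.list(x$mix_main)
  x$mix_sub <- as.list(x$mix_sub)
  yaml::write_yaml(x, path)
  invisible(path)
}
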
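# Physicochemical constants (EMBOSS-style defaults, shipped as code so
# they are versioned with the package): average residue masses (Da),
# ionizable-group pK values, molar extinction coefficients at 280 nm.
AA_RESIDUE_MASS <- c(
  A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
  S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)
WATER_MASS <- 18.01524

PK_VALUES <- c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
               D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

EXT_TRP <- 5500
EXT_TYR <- 1490
EXT_CYSTINE <- 125

# Physicochemical residue classes (EMBOSS groupings, canonical residues).
AA_CLASSES <- list(
  tiny      = c("A", "C", "G", "S", "T"),
  small     = c("A", "C", "D", "G", "N", "P", "S", "T", "V"),
  aliphatic = c("A", "I", "L", "V"),
  aromatic  = c("F", "H", "W", "Y"),
  non_polar = c("A", "C", "F", "G", "I", "L", "M", "P", "V", "W", "Y"),
  polar     = c("D", "E", "H", "K", "N", "Q", "R", "S", "T"),
  charged   = c("D", "E", "H", "K", "R"),
  basic     = c("H", "K", "R"),
  acidic    = c("D", "E"))

# Net charge of a composition at a given pH (Henderson-Hasselbalch over
# the ionizable side chains plus one N- and one C-terminus).
protein_net_charge <- function(counts, pH, pk = PK_VALUES) {
  pos_groups <- c(Nterm = 1, counts[c("K", "R", "H")])
  names(pos_groups) <- c("Nterm", "K", "R", "H")
  neg_groups <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  names(neg_groups) <- c("Cterm", "D", "E", "C", "Y")
  positive <- sum(pos_groups / (1 + 10^(pH - pk[names(pos_groups)])))
  negative <- sum(neg_groups / (1 + 10^(pk[names(neg_groups)] - pH)))
  positive - negative
}

# Isoelectric point by bisection on the monotone charge-vs-pH curve.
isoelectric_point <- function(counts, tol = 1e-4, pk = PK_VALUES) {
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- protein_net_charge(counts, mid, pk)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical descriptor vector of a protein
#'
#' A 37-dimensional, composition-based summary in the spirit of the
#' EMBOSS peptide-statistics report: the 20 amino-acid mole
#' percentages, 9 physicochemical-class mole percentages (tiny, small,
#' aliphatic, aromatic, non-polar, polar, charged, basic, acidic),
#' molecular weight (Da), residue count, average residue weight (Da),
#' net charge at pH 7, isoelectric point, the molar extinction
#' coefficients at 280 nm with free cysteines and with cystine
#' bridges (M^-1 cm^-1), and the extinction of a 1 mg/ml solution
#' (reduced).  The unknown residue X counts toward the residue total
#' but contributes nothing to masses, charges or class memberships.
#' All descriptors are order-free: permuting the sequence leaves the
#' vector unchanged.
#'
#' @param sequence sanitized amino-acid string (non-empty).
#' @return named numeric vector of length 37.
#' @export
pepstats_features <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("pepstats_features() needs one non-empty sequence")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (any(!chars %in% c(AA20, "X"))) {
    stop("sequence must be sanitized first (20 canonical residues or X)")
  }
  n <- length(chars)
  counts <- vapply(AA20, function(a) sum(chars == a), numeric(1))

  mole <- 100 * counts / n
  names(mole) <- paste0("mole_pct_", AA20)

  cls <- vapply(AA_CLASSES, function(members) {
    100 * sum(counts[members]) / n
  }, numeric(1))
  names(cls) <- paste0("class_pct_", names(AA_CLASSES))

  mw <- sum(counts * AA_RESIDUE_MASS[AA20]) + WATER_MASS
  charge <- protein_net_charge(counts, 7)
  pI <- isoelectric_point(counts)
  ext_red <- EXT_TRP * counts["W"] + EXT_TYR * counts["Y"]
  ext_cys <- ext_red + EXT_CYSTINE * floor(counts["C"] / 2)

  c(mole, cls,
    molecular_weight = mw,
    residues = n,
    avg_residue_weight = (mw - WATER_MASS) / n,
    charge_ph7 = charge,
    isoelectric_point = pI,
    ext_coef_reduced = unname(ext_red),
    ext_coef_cystines = unname(ext_cys),
    ext_1mgml_reduced = unname(ext_red) / mw)
}

#' Feature matrix of physicochemical descriptors
#'
#' @param sequences character vector of sanitized sequences.
#' @return numeric matrix, one row per sequence, 37 columns.
#' @export
pepstats_matrix <- function(sequences) {
  t(vapply(sequences, pepstats_features, numeric(37), USE.NAMES = FALSE))
}

#' Fit / apply a per-dimension feature scaler
#'
#' `fit_scaler()` learns per-column scaling parameters on training
#' features only; `apply_scaler()` maps new features through them.
#' With `method = "minmax"` (the default, standard for margin
#' classifiers) the training minimum maps to 0, the maximum to 1, and
#' out-of-range values are clipped into \[0, 1\]; a constant training
#' column maps everything to 0.  With `method = "zscore"` columns are
#' centred and divided by the training standard deviation (no \[0, 1\]
#' guarantee; constant columns map to 0).
#'
#' @param features numeric training matrix.
#' @param method `"minmax"` or `"zscore"`.
#' @return `fit_scaler()`: an object of class `feature_scaler`;
#'   `apply_scaler()`: the scaled matrix.
#' @export
fit_scaler <- function(features, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  stopifnot(nrow(features) >= 1L)
  if (method == "minmax") {
    structure(list(method = method,
                   min = apply(features, 2, min),
                   max = apply(features, 2, max)),
              class = "feature_scaler")
  } else {
    structure(list(method = method,
                   center = colMeans(features),
                   sd = apply(features, 2, stats::sd)),
              class = "feature_scaler")
  }
}

#' @rdname fit_scaler
#' @param scaler a `feature_scaler`.
#' @export
apply_scaler <- function(scaler, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (scaler$method == "minmax") {
    rng <- scaler$max - scaler$min
    out <- sweep(features, 2, scaler$min)
    out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
    out[, rng <= 0] <- 0
    pmin(pmax(out, 0), 1)
  } else {
    s <- scaler$sd
    out <- sweep(features, 2, scaler$center)
    out <- sweep(out, 2, ifelse(!is.na(s) & s > 0, s, 1), "/")
    out[, is.na(s) | s <= 0] <- 0
    out
  }
}
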
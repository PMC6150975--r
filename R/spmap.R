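#' Extract fixed-length subsequence windows
#'
#' All overlapping windows of length `l` of a sequence, in order
#' (sliding window, step 1).  Windows containing the unknown residue X
#' are skipped, so masked non-canonical residues never enter a profile.
#' Sequences shorter than `l` yield an empty vector.
#'
#' @param sequence amino-acid string (already sanitized).
#' @param l window length (default 5).
#' @return character vector of length-`l` windows.
#' @export
extract_subsequences <- function(sequence, l = 5L) {
  stopifnot(l >= 1L)
  n <- nchar(sequence)
  if (n < l) return(character(0))
  starts <- seq_len(n - l + 1L)
  ss <- substring(sequence, starts, starts + l - 1L)
  ss[!grepl("X", ss, fixed = TRUE)]
}

#' Ungapped BLOSUM62 similarity of two equal-length subsequences
#'
#' Position-wise sum of BLOSUM62 scores.
#'
#' @param x,y equal-length amino-acid strings.
#' @return integer score.
#' @export
subsequence_similarity <- function(x, y) {
  if (nchar(x) != nchar(y)) stop("subsequences differ in length")
  sub <- blosum62()
  sum(sub[cbind(aa_indices(x), aa_indices(y))])
}

#' Online clustering of subsequences by BLOSUM62 similarity
#'
#' Single pass in input order.  Each subsequence is scored against every
#' existing cluster -- against the cluster's founding representative by
#' default, or against all members with `comparison = "members"` -- and
#' joins the highest-scoring cluster if that score reaches `t`, ties
#' going to the earliest-created cluster; otherwise it founds a new
#' cluster with itself as representative.  Each cluster accumulates a
#' position x residue count matrix over all its members.
#'
#' @param subsequences character vector of equal-length windows.
#' @param t similarity threshold (default 8).
#' @param comparison `"representative"` or `"members"`.
#' @return object of class `spmap_clusters`: list of clusters, each with
#'   `representative`, `size` and an `l x 20` `counts` matrix; window
#'   length and threshold are attached as attributes.
#' @export
cluster_subsequences <- function(subsequences, t = 8L,
                                 comparison = c("representative", "members")) {
  comparison <- match.arg(comparison)
  if (length(subsequences) == 0L) {
    return(structure(list(), class = "spmap_clusters", l = NA_integer_, t = t))
  }
  l <- unique(nchar(subsequences))
  if (length(l) != 1L) stop("subsequences must share one length")
  mat <- t(vapply(subsequences, aa_indices, integer(l), USE.NAMES = FALSE))
  if (l == 1L) mat <- matrix(mat, ncol = 1L)
  if (any(mat > 20L)) stop("subsequence windows must not contain X")
  res <- cpp_spmap_cluster(mat, blosum62()[1:20, 1:20], as.integer(t),
                           comparison == "members")
  nc <- length(res$sizes)
  counts <- res$counts  # dim (l, 20, nc)
  clusters <- lapply(seq_len(nc), function(c_id) {
    cm <- matrix(counts[, , c_id], nrow = l, ncol = 20L,
                 dimnames = list(NULL, AA20))
    list(representative = subsequences[res$representative_row[c_id]],
         size = res$sizes[c_id],
         counts = cm)
  })
  structure(clusters, class = "spmap_clusters", l = l, t = t,
            assignment = res$assignment)
}

#' @export
print.spmap_clusters <- function(x, ...) {
  cat("<spmap_clusters> ", length(x), " clusters, window l=",
      attr(x, "l"), ", threshold t=", attr(x, "t"), "\n", sep = "")
  invisible(x)
}

#' Build a profile map from subsequence clusters
#'
#' Clusters smaller than `discard_fraction` of the positive training-set
#' size (number of proteins, not subsequences) are discarded; each
#' retained cluster's count matrix is converted to a probabilistic
#' profile `PP(i, j) = ln((count(i, j) + 0.01) / S_c)`, where `S_c` is
#' the cluster size and 0.01 a pseudo-count guarding against zero
#' probabilities.  The feature dimension of the resulting map equals
#' the number of retained profiles.
#'
#' @param clusters an [cluster_subsequences()] result.
#' @param n_positive number of proteins in the positive training set.
#' @param discard_fraction minimum relative cluster size (default 0.10).
#' @return object of class `profile_map`.
#' @export
build_profiles <- function(clusters, n_positive, discard_fraction = 0.10) {
  min_size <- discard_fraction * n_positive
  keep <- vapply(clusters, function(cl) cl$size >= min_size, logical(1))
  if (!any(keep)) {
    stop("no profiles retained (all ", length(clusters), " clusters below ",
         min_size, " members); consider lowering discard_fraction")
  }
  profiles <- lapply(clusters[keep], function(cl) {
    cl$profile <- log((cl$counts + 0.01) / cl$size)
    cl
  })
  structure(list(l = attr(clusters, "l"), t = attr(clusters, "t"),
                 discard_fraction = discard_fraction,
                 n_positive = n_positive,
                 profiles = profiles),
            class = "profile_map")
}

#' @export
print.profile_map <- function(x, ...) {
  cat("<profile_map> ", length(x$profiles), " profiles (l=", x$l,
      ", t=", x$t, ", built on ", x$n_positive, " positives)\n", sep = "")
  invisible(x)
}

#' Log-probability of a subsequence under one profile
#'
#' Sum over positions of the profile's log-probability for the
#' subsequence's residue at that position.
#'
#' @param ss length-`l` amino-acid string.
#' @param profile an `l x 20` log-probability matrix (columns in the
#'   fixed alphabet order).
#' @return numeric log-probability.
#' @export
subsequence_log_prob <- function(ss, profile) {
  idx <- aa_indices(ss)
  if (length(idx) != nrow(profile)) stop("subsequence length mismatch")
  if (any(idx > 20L)) stop("subsequence must not contain X")
  sum(profile[cbind(seq_along(idx), idx)])
}

#' Profile-map feature vectors
#'
#' For each retained profile, the feature is the exponential of the
#' best (maximum) log-probability over all subsequence windows of the
#' protein; features therefore lie in (0, 1] (the pseudo-count can push
#' the raw value marginally above 1, which is clipped).  A protein with
#' no valid window gets an all-zero vector.
#'
#' @param sequences character vector of sanitized sequences.
#' @param pmap a [build_profiles()] result.
#' @return numeric matrix, one row per sequence, one column per profile.
#' @export
spmap_featurize <- function(sequences, pmap) {
  d <- length(pmap$profiles)
  l <- pmap$l
  # profiles restacked per window position: l matrices of 20 x d, so one
  # subscript per position scores every profile at once
  pp_by_pos <- lapply(seq_len(l), function(i) {
    vapply(pmap$profiles, function(p) p$profile[i, ], numeric(20))
  })
  out <- matrix(0, nrow = length(sequences), ncol = d)
  short <- 0L
  for (r in seq_along(sequences)) {
    ss <- extract_subsequences(sequences[r], l)
    if (length(ss) == 0L) { short <- short + 1L; next }
    m <- t(vapply(ss, aa_indices, integer(l), USE.NAMES = FALSE))
    if (l == 1L) m <- matrix(m, ncol = 1L)
    acc <- pp_by_pos[[1]][m[, 1], , drop = FALSE]
    for (i in seq_len(l)[-1]) {
      acc <- acc + pp_by_pos[[i]][m[, i], , drop = FALSE]
    }
    out[r, ] <- pmin(exp(apply(acc, 2, max)), 1)
  }
  if (short > 0L) {
    warning(short, " sequence(s) shorter than l=", l,
            " (or fully masked): zero feature vectors")
  }
  out
}

#' Serialize / restore a profile map as JSON
#'
#' The layout is plain JSON: scalars `l`, `t`, `discard_fraction`,
#' `n_positive` and an array `profiles`, each with `representative`,
#' `size` and the integer `counts` matrix (row = window position,
#' column = residue in the fixed alphabet order).  Profiles are
#' recomputed from counts on load.
#'
#' @param pmap a `profile_map`.
#' @param path JSON file path.
#' @export
write_profile_map <- function(pmap, path) {
  obj <- list(l = pmap$l, t = pmap$t,
              discard_fraction = pmap$discard_fraction,
              n_positive = pmap$n_positive,
              profiles = lapply(pmap$profiles, function(p) {
                list(representative = p$representative, size = p$size,
                     counts = unname(p$counts))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_map
#' @export
read_profile_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  profiles <- lapply(seq_len(nrow_or_len(obj$profiles)), function(i) {
    p <- if (is.data.frame(obj$profiles)) {
      list(representative = obj$profiles$representative[i],
           size = obj$profiles$size[i],
           counts = obj$profiles$counts[[i]])
    } else obj$profiles[[i]]
    cm <- matrix(as.numeric(p$counts), nrow = obj$l, ncol = 20L,
                 dimnames = list(NULL, AA20))
    list(representative = p$representative, size = p$size, counts = cm,
         profile = log((cm + 0.01) / p$size))
  })
  structure(list(l = obj$l, t = obj$t,
                 discard_fraction = obj$discard_fraction,
                 n_positive = obj$n_positive,
                 profiles = profiles),
            class = "profile_map")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
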
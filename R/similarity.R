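#' Local-alignment similarity between two protein sequences
#'
#' The internal similarity backend of the k-nearest-neighbour vote:
#' Smith-Waterman local alignment score with BLOSUM62 and affine gaps
#' (open 11, extend 1), floored at 0.  An external search tool can
#' stand behind the same contract (any non-negative score monotone in
#' alignment quality); this scorer keeps the package self-contained.
#'
#' @param query,target amino-acid strings.
#' @param gap_open,gap_ext affine gap parameters.
#' @return non-negative numeric score.
#' @export
pairwise_similarity <- function(query, target, gap_open = 11, gap_ext = 1) {
  if (!nzchar(query) || !nzchar(target)) stop("empty sequence")
  similarity_scores(query, target, gap_open, gap_ext)[1]
}

#' Similarity of one query against many targets
#'
#' @param query amino-acid string.
#' @param targets character vector of target sequences (names, if any,
#'   are kept on the result).
#' @inheritParams pairwise_similarity
#' @return named non-negative numeric vector.
#' @export
similarity_scores <- function(query, targets, gap_open = 11, gap_ext = 1) {
  if (!nzchar(query)) stop("empty sequence")
  if (length(targets) == 0L) return(numeric(0))
  if (any(!nzchar(targets))) stop("empty sequence")
  s <- cpp_align_batch(aa_indices(query), lapply(targets, aa_indices),
                       blosum62(), gap_open, gap_ext, TRUE)
  setNames(pmax(s, 0), names(targets))
}

#' Symmetric similarity matrix of a sequence set
#'
#' All pairwise local-alignment scores of a set (used once per class to
#' drive cross-validated neighbour voting).
#'
#' @param sequences named character vector of sequences.
#' @inheritParams pairwise_similarity
#' @return symmetric numeric matrix with the sequence names as
#'   dimnames; the diagonal holds self-alignment scores.
#' @export
similarity_matrix <- function(sequences, gap_open = 11, gap_ext = 1) {
  n <- length(sequences)
  enc <- lapply(sequences, aa_indices)
  m <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  sub <- blosum62()
  for (i in seq_len(n)) {
    s <- cpp_align_batch(enc[[i]], enc[i:n], sub, gap_open, gap_ext, TRUE)
    m[i, i:n] <- pmax(s, 0)
    m[i:n, i] <- m[i, i:n]
  }
  m
}

#' Signed k-nearest-neighbour vote
#'
#' Takes the `k` highest-scoring training proteins across the positive
#' and negative sets combined and returns
#' `O_B = (S_p - S_n) / (S_p + S_n)`, where `S_p` (`S_n`) is the summed
#' similarity of the selected neighbours that are positive (negative).
#' `O_B` is +1 when every neighbour is positive, -1 when every
#' neighbour is negative, and 0 (flagged `no_homology`) when no
#' neighbour has a positive score.  Ties in the neighbour ranking are
#' broken by target id for determinism.
#'
#' @param scores named numeric vector: similarity of the query to each
#'   training protein (positives and negatives together).
#' @param positive_ids ids of the positive training proteins.
#' @param k neighbours to use (default 5).
#' @return numeric in \[-1, 1\] with logical attribute `"no_homology"`.
#' @export
knn_score <- function(scores, positive_ids, k = 5L) {
  stopifnot(k >= 1L, length(scores) >= 1L)
  ids <- names(scores)
  if (is.null(ids)) stop("scores must be named by training protein id")
  ord <- order(-scores, ids)
  top <- ord[seq_len(min(k, length(scores)))]
  pos <- ids[top] %in% positive_ids
  sp <- sum(scores[top][pos])
  sn <- sum(scores[top][!pos])
  if (sp + sn <= 0) {
    return(structure(0, no_homology = TRUE))
  }
  structure((sp - sn) / (sp + sn), no_homology = FALSE)
}

# Rescale the signed vote to [0, 1] so all base predictors share one range.
knn_unit_score <- function(ob) (ob + 1) / 2
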
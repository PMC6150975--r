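# Independent brute-force oracles used to cross-check the optimized
# implementations.  These deliberately re-derive each quantity from its
# definition, not from the package's code paths.

# Online clustering re-implemented naively in R: rescan every cluster's
# representative at each step, join the best-scoring one if >= t.
bf_cluster_assign <- function(subseqs, t) {
  reps <- character(0)
  assign <- integer(length(subseqs))
  for (i in seq_along(subseqs)) {
    best <- -Inf; best_c <- NA_integer_
    for (c_id in seq_along(reps)) {
      sc <- subsequence_similarity(subseqs[i], reps[c_id])
      if (sc > best) { best <- sc; best_c <- c_id }
    }
    if (!is.na(best_c) && best >= t) {
      assign[i] <- best_c
    } else {
      reps <- c(reps, subseqs[i])
      assign[i] <- length(reps)
    }
  }
  assign
}

# AUROC by exhaustive pairwise comparison: P(pos > neg) + 0.5 P(tie).
bf_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Affine-gap Smith-Waterman in plain R (full matrices, no tricks);
# gap of length L costs open + L * ext.
bf_smith_waterman <- function(q, t, open = 11, ext = 1) {
  sub <- blosum62()
  qi <- strsplit(q, "")[[1]]; ti <- strsplit(t, "")[[1]]
  m <- length(qi); n <- length(ti)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)  # gap consuming target
  F <- matrix(-Inf, m + 1, n + 1)  # gap consuming query
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(E[i, j - 1], H[i, j - 1] - open) - ext
      F[i, j] <- max(F[i - 1, j], H[i - 1, j] - open) - ext
      H[i, j] <- max(0, H[i - 1, j - 1] + sub[qi[i - 1], ti[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Exhaustive k-nearest-neighbour vote from the definition.
bf_knn_vote <- function(scores, positive_ids, k) {
  ord <- order(-scores, names(scores))
  sel <- ord[seq_len(min(k, length(scores)))]
  sp <- sum(scores[sel][names(scores)[sel] %in% positive_ids])
  sn <- sum(scores[sel][!names(scores)[sel] %in% positive_ids])
  if (sp + sn == 0) 0 else (sp - sn) / (sp + sn)
}

# Global-alignment identity via Biostrings (independent implementation).
bs_identity <- function(a, b) {
  env <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = env)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = env$BLOSUM62, gapOpening = 10, gapExtension = 1,
    type = "global")
  Biostrings::pid(aln, type = "PID1") / 100
}

random_aa_seq <- function(n) paste(sample(echier:::AA20, n, TRUE), collapse = "")
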
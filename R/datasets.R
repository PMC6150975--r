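#' Propagate EC annotations up the hierarchy
#'
#' Builds the class membership map used for training: a protein
#' annotated with an EC number is listed under that number and under
#' every ancestor of it, following the inheritance structure of the EC
#' system.  Proteins carrying more than one distinct EC number are
#' discarded entirely (multi-functional enzymes confuse the binary
#' classifiers).
#'
#' @param records protein record data frame (columns `id`, `ec`; `ec`
#'   empty or `;`-separated EC strings).
#' @return named list mapping canonical EC string to a character vector
#'   of protein ids, ordered by level then components.
#' @export
propagate_annotations <- function(records) {
  out <- list()
  for (r in seq_len(nrow(records))) {
    ecs <- records$ec[r]
    if (is.na(ecs) || !nzchar(ecs)) next
    parts <- unique(strsplit(ecs, ";", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    if (length(parts) != 1L) next  # multi-EC proteins are discarded
    ec <- ec_parse(parts)
    keys <- vapply(ec_ancestors(ec, include_self = TRUE), ec_format, "")
    for (k in keys) out[[k]] <- c(out[[k]], records$id[r])
  }
  if (length(out) == 0L) return(out)
  out <- lapply(out, unique)
  out[ec_sort_strings(names(out))]
}

#' Select EC classes with enough members to train
#'
#' @param class_map output of [propagate_annotations()].
#' @param min_count minimum number of member proteins (default 50).
#' @return character vector of EC strings sorted by level then
#'   components.
#' @export
select_trainable_classes <- function(class_map, min_count = 50L) {
  if (length(class_map) == 0L) return(character(0))
  keep <- names(class_map)[vapply(class_map, length, integer(1)) >= min_count]
  ec_sort_strings(keep)
}

#' Select reliable non-enzymes
#'
#' Non-enzymes admitted to negative training sets must have no
#' enzymatic annotation and an annotation-reliability score of at least
#' `min_annotation_score` stars (default 4), so that poorly annotated
#' proteins -- potential unrecorded enzymes -- are kept out.
#'
#' @param records protein record data frame.
#' @param min_annotation_score minimum star rating (1-5).
#' @return character vector of protein ids.
#' @export
select_nonenzymes <- function(records, min_annotation_score = 4L) {
  no_ec <- is.na(records$ec) | !nzchar(records$ec)
  flagged_enzyme <- !is.na(records$is_enzyme) & records$is_enzyme
  score_ok <- !is.na(records$annotation_score) &
    records$annotation_score >= min_annotation_score
  records$id[no_ec & !flagged_enzyme & score_ok]
}

#' Build the partitioned negative pool for an EC class
#'
#' The negative candidates for class `ec` come from three disjoint
#' partitions: (i) `sibling_branch` -- proteins under siblings of `ec`
#' and their descendants; (ii) `other_main` -- proteins under EC main
#' classes other than `ec`'s, excluding the sibling branch; and (iii)
#' `nonenzyme` -- the reliable non-enzymes.  Proteins positive for `ec`
#' (that is, under `ec` or any of its descendants) never appear in any
#' partition.  For a main (level-1) class the sibling branch already
#' covers all other main classes, so `other_main` is empty.
#'
#' @param ec the target EC class (string or `ec_number`).
#' @param class_map output of [propagate_annotations()].
#' @param nonenzyme_ids ids from [select_nonenzymes()].
#' @return list with character vectors `sibling_branch`, `other_main`,
#'   `nonenzyme`; the positive ids are attached as attribute
#'   `"positive"`.
#' @export
build_negative_pool <- function(ec, class_map, nonenzyme_ids) {
  ec <- ec_parse(ec)
  key <- ec_format(ec)
  if (is.null(class_map[[key]])) {
    stop("class ", key, " is not present in the class map")
  }
  positives <- class_map[[key]]
  lev <- ec$level
  parent_key <- if (lev >= 2L) ec_format(ec_parent(ec)) else NULL

  sib_keys <- names(class_map)[vapply(names(class_map), function(k) {
    e <- ec_parse(k)
    if (e$level != lev) return(FALSE)
    if (identical(k, key)) return(FALSE)
    if (lev == 1L) return(TRUE)  # all other top-level classes
    identical(ec_format(ec_parent(e)), parent_key)
  }, logical(1))]
  sibling_branch <- setdiff(unique(unlist(class_map[sib_keys],
                                          use.names = FALSE)), positives)

  main_keys <- names(class_map)[vapply(names(class_map), function(k) {
    e <- ec_parse(k)
    e$level == 1L && e$components[1] != ec$components[1]
  }, logical(1))]
  other_main <- setdiff(
    setdiff(unique(unlist(class_map[main_keys], use.names = FALSE)), positives),
    sibling_branch)

  nonenzyme <- setdiff(nonenzyme_ids, c(positives, sibling_branch, other_main))
  structure(list(sibling_branch = sibling_branch,
                 other_main = other_main,
                 nonenzyme = nonenzyme),
            positive = positives)
}

#' Sample a balanced negative set
#'
#' Draws exactly `n_negative` ids without replacement from the
#' partitioned pool, split according to `mix` (fractions over
#' `sibling`, `other`, `nonenzyme` summing to 1).  When a partition is
#' smaller than its allocation the deficit is refilled from the other
#' partitions, with a warning.  Deterministic under `seed`.
#'
#' @param pool output of [build_negative_pool()].
#' @param n_negative number of ids to draw (normally the positive-set
#'   size, for balanced training).
#' @param mix named fractions `c(sibling=, other=, nonenzyme=)`.
#' @param seed integer seed.
#' @return character vector of `n_negative` ids with attribute
#'   `"composition"` (named counts per partition).
#' @export
sample_balanced_negatives <- function(pool, n_negative,
                                      mix = c(sibling = 0.5, other = 0,
                                              nonenzyme = 0.5),
                                      seed = 42L) {
  stopifnot(abs(sum(mix) - 1) < 1e-9, all(mix >= 0))
  parts <- list(sibling = pool$sibling_branch,
                other = pool$other_main,
                nonenzyme = pool$nonenzyme)
  sizes <- vapply(parts, length, integer(1))
  if (sum(sizes) < n_negative) {
    stop("negative pool (", sum(sizes), ") smaller than requested sample (",
         n_negative, ")")
  }
  mix <- mix[c("sibling", "other", "nonenzyme")]

  # integer allocation: floors, remainder to the largest fractional parts
  target <- mix * n_negative
  alloc <- floor(target)
  rem <- n_negative - sum(alloc)
  if (rem > 0) {
    frac <- target - alloc
    ord <- order(-frac, seq_along(frac))  # deterministic tie-break
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }
  # refill deficits from partitions with spare capacity (pool exhaustion)
  alloc <- pmin(alloc, sizes)
  deficit <- n_negative - sum(alloc)
  if (deficit > 0) {
    warning("negative partition(s) exhausted; refilling ", deficit,
            " draw(s) from the remaining partitions")
    while (deficit > 0) {
      spare <- sizes - alloc
      i <- which(spare > 0)[1]
      take <- min(deficit, spare[i])
      alloc[i] <- alloc[i] + take
      deficit <- deficit - take
    }
  }
  drawn <- with_seed(seed, {
    unlist(lapply(seq_along(parts), function(i) {
      ids <- sort(parts[[i]])
      if (alloc[i] == 0L) character(0)
      else ids[sample.int(length(ids), alloc[i])]
    }), use.names = FALSE)
  })
  structure(drawn, composition = setNames(as.integer(alloc), names(parts)))
}

#' Greedy redundancy clustering of protein sequences
#'
#' Emulates identity-based redundancy reduction (UniRef50-style):
#' sequences are processed longest-first; each sequence joins the first
#' existing cluster whose representative (the cluster's founding,
#' longest sequence) shares at least `identity_threshold` global
#' identity with it, and otherwise founds a new cluster.  Identity is
#' matches / alignment-length of a global BLOSUM62 alignment with
#' affine gaps (open 10, extend 1).  Pairs whose length ratio already
#' bounds identity below the threshold are skipped without alignment
#' (identity can never exceed `min(n1,n2)/max(n1,n2)`).
#'
#' @param records protein record data frame (columns `id`, `sequence`).
#' @param identity_threshold fraction in (0, 1]; default 0.5.
#' @param gap_open,gap_ext affine gap parameters of the global aligner.
#' @return object of class `redundancy_clustering`: list with
#'   `clusters` (each a list of `representative` and `members` ids) and
#'   `identity_threshold`.
#' @export
reduce_redundancy <- function(records, identity_threshold = 0.5,
                              gap_open = 10, gap_ext = 1) {
  stopifnot(nrow(records) >= 1L)
  lens <- nchar(records$sequence)
  ord <- order(-lens, seq_len(nrow(records)))  # longest first, stable
  sub <- blosum62()
  enc <- lapply(records$sequence[ord], aa_indices)
  ids <- records$id[ord]
  n <- length(ids)

  rep_idx <- integer(0)          # indices into the ordered records
  members <- list()
  for (i in seq_len(n)) {
    joined <- FALSE
    if (length(rep_idx) > 0L) {
      li <- length(enc[[i]])
      rl <- vapply(rep_idx, function(r) length(enc[[r]]), integer(1))
      bound <- pmin(li, rl) / pmax(li, rl)
      cand <- which(bound >= identity_threshold)
      if (length(cand) > 0L) {
        stats <- cpp_global_align_stats(enc[[i]], enc[rep_idx[cand]],
                                        sub, gap_open, gap_ext)
        identity <- stats[, "matches"] / stats[, "alnlen"]
        hit <- which(identity >= identity_threshold)
        if (length(hit) > 0L) {
          c_id <- cand[hit[1]]   # first cluster in creation order
          members[[c_id]] <- c(members[[c_id]], i)
          joined <- TRUE
        }
      }
    }
    if (!joined) {
      rep_idx <- c(rep_idx, i)
      members[[length(rep_idx)]] <- i
    }
  }
  clusters <- lapply(seq_along(rep_idx), function(c_id) {
    list(representative = ids[rep_idx[c_id]],
         members = ids[members[[c_id]]])
  })
  structure(list(clusters = clusters,
                 identity_threshold = identity_threshold),
            class = "redundancy_clustering")
}

#' @export
print.redundancy_clustering <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), integer(1))
  cat("<redundancy_clustering> ", length(x$clusters), " clusters over ",
      sum(sizes), " sequences (identity >= ", x$identity_threshold,
      ")\n", sep = "")
  invisible(x)
}

#' Cluster-atomic train/validation split
#'
#' Whole redundancy clusters are assigned to one side, so no
#' train/validation pair can exceed the identity threshold.  Validation
#' receives `ceiling(val_fraction * n_clusters)` clusters, drawn
#' deterministically under `seed`.  By default only cluster
#' representatives are returned (redundancy-reduced datasets); set
#' `use_representatives = FALSE` to keep all members.
#'
#' @param clustering a [reduce_redundancy()] result.
#' @param val_fraction fraction of clusters held out (default 0.1).
#' @param seed integer seed.
#' @param use_representatives representatives only, or all members.
#' @return list with character vectors `train` and `validation`.
#' @export
split_train_validation <- function(clustering, val_fraction = 0.1,
                                   seed = 42L, use_representatives = TRUE) {
  k <- length(clustering$clusters)
  pick <- function(cl) if (use_representatives) cl$representative else cl$members
  if (k < 2L) {
    warning("fewer than two clusters; everything assigned to training")
    return(list(train = unlist(lapply(clustering$clusters, pick)),
                validation = character(0)))
  }
  n_val <- ceiling(val_fraction * k)
  val_idx <- with_seed(seed, sample.int(k, n_val))
  val <- unlist(lapply(clustering$clusters[val_idx], pick))
  train <- unlist(lapply(clustering$clusters[-val_idx], pick))
  list(train = train, validation = val)
}

#' Per-class training/validation dataset
#'
#' Plain container for the four id sets of one EC class plus the
#' composition metadata of its negative draws.
#'
#' @param ec EC class (string or `ec_number`).
#' @param positive_train,negative_train,positive_val,negative_val id
#'   vectors; positives and negatives must be disjoint.
#' @param composition_train,composition_val named counts per negative
#'   partition (attributes of [sample_balanced_negatives()] draws).
#' @return object of class `class_dataset`.
#' @export
class_dataset <- function(ec, positive_train, negative_train,
                          positive_val, negative_val,
                          composition_train = NULL, composition_val = NULL) {
  if (length(intersect(c(positive_train, positive_val),
                       c(negative_train, negative_val))) > 0L) {
    stop("positive and negative sets overlap for class ", ec_format(ec))
  }
  structure(list(ec = ec_format(ec),
                 positive_train = positive_train,
                 negative_train = negative_train,
                 positive_val = positive_val,
                 negative_val = negative_val,
                 composition_train = composition_train,
                 composition_val = composition_val),
            class = "class_dataset")
}

#' @export
print.class_dataset <- function(x, ...) {
  cat("<class_dataset ", x$ec, "> +train ", length(x$positive_train),
      " -train ", length(x$negative_train),
      " +val ", length(x$positive_val),
      " -val ", length(x$negative_val), "\n", sep = "")
  invisible(x)
}
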
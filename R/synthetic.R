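#' Specification of a synthetic enzyme family
#'
#' A family is a set of proteins sharing one EC class and one or more
#' conserved sequence motifs implanted into random background
#' sequence -- the kind of signal (conserved active-site and binding
#' regions) that subsequence profiles, alignment similarity and, more
#' weakly, residue composition can all pick up.  Child families are
#' built by inheriting the parent's motifs and adding their own, so
#' each hierarchy level stays separable.
#'
#' @param ec EC class of the family.
#' @param motifs character vector of amino-acid motifs to implant.
#' @param n_members family size.
#' @param seq_length length-2 integer range; member lengths are drawn
#'   uniformly from it (default 120-400, long enough for stable
#'   composition statistics and profile windows).
#' @param mutation_rate per-residue probability that an implanted motif
#'   position is replaced by a random other residue, in \[0, 1).
#' @param background residue sampling probabilities (length 20, the
#'   fixed alphabet order); default uniform.
#' @return object of class `family_spec`.
#' @export
family_spec <- function(ec, motifs, n_members,
                        seq_length = c(120L, 400L),
                        mutation_rate = 0.05,
                        background = NULL) {
  stopifnot(length(motifs) >= 1L, n_members >= 1L,
            mutation_rate >= 0, mutation_rate < 1,
            length(seq_length) == 2L, seq_length[1] <= seq_length[2])
  if (is.null(background)) background <- rep(1 / 20, 20)
  stopifnot(length(background) == 20L, all(background >= 0),
            abs(sum(background) - 1) < 1e-9)
  motifs <- toupper(motifs)
  bad <- motifs[!grepl(paste0("^[", paste(AA20, collapse = ""), "]+$"), motifs)]
  if (length(bad) > 0L) stop("motif(s) with non-canonical residues: ",
                             paste(bad, collapse = ", "))
  if (sum(nchar(motifs) + 1L) - 1L > seq_length[1]) {
    stop("motifs do not fit into the minimum sequence length")
  }
  structure(list(ec = ec_format(ec), motifs = motifs,
                 n_members = as.integer(n_members),
                 seq_length = as.integer(seq_length),
                 mutation_rate = mutation_rate,
                 background = background),
            class = "family_spec")
}

random_background <- function(n, background) {
  paste(sample(AA20, n, replace = TRUE, prob = background), collapse = "")
}

# Non-overlapping motif start positions in a sequence of length n:
# draw the spare residues between/around motifs from a uniform
# composition of the slack.
motif_positions <- function(motif_lens, n) {
  slack <- n - sum(motif_lens)
  cuts <- sort(sample.int(slack + 1L, length(motif_lens), replace = TRUE)) - 1L
  starts <- integer(length(motif_lens))
  off <- 0L
  for (i in seq_along(motif_lens)) {
    starts[i] <- cuts[i] + off + 1L
    off <- off + motif_lens[i]
  }
  starts
}

mutate_motif <- function(motif, rate) {
  if (rate <= 0) return(motif)
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a)
      sample(setdiff(AA20, a), 1L), "")
  }
  paste(chars, collapse = "")
}

#' Generate one synthetic enzyme family
#'
#' Each member is a random background sequence with every motif of the
#' spec implanted at a random non-overlapping position, each motif
#' residue independently mutated at the spec's rate.  Deterministic
#' under `seed`.
#'
#' @param spec a [family_spec()].
#' @param seed integer seed.
#' @param id_prefix prefix for member ids.
#' @return protein record data frame (`id`, `sequence`, `ec`,
#'   `annotation_score`, `is_enzyme`).
#' @export
generate_family <- function(spec, seed = 42L, id_prefix = NULL) {
  if (is.null(id_prefix)) {
    id_prefix <- paste0("ec", gsub(".", "_", sub("(\\.-)+$", "", spec$ec),
                                   fixed = TRUE))
  }
  lens <- seq(spec$seq_length[1], spec$seq_length[2])
  with_seed(seed, {
    seqs <- vapply(seq_len(spec$n_members), function(i) {
      n <- lens[sample.int(length(lens), 1L)]
      s <- random_background(n, spec$background)
      starts <- motif_positions(nchar(spec$motifs), n)
      ord <- order(starts)
      for (j in ord) {
        m <- mutate_motif(spec$motifs[j], spec$mutation_rate)
        substr(s, starts[j], starts[j] + nchar(m) - 1L) <- m
      }
      s
    }, "")
    data.frame(id = sprintf("%s_%03d", id_prefix, seq_len(spec$n_members)),
               sequence = seqs, ec = spec$ec,
               annotation_score = 5L, is_enzyme = TRUE,
               stringsAsFactors = FALSE)
  })
}

#' Default toy benchmark: six motif-defined main classes
#'
#' Builds the family specs for the standard synthetic benchmark: one
#' family per EC main class, each defined by its own conserved motifs
#' implanted in uniform random background.  Motifs are drawn
#' deterministically from `motif_seed`, so the benchmark's signal is
#' stable across runs while the family members themselves vary with
#' the generation seed.
#'
#' @param n_classes number of main classes (default 6).
#' @param n_members family size (default 80).
#' @param mutation_rate per-residue motif mutation rate (default 0.05).
#' @param motifs_per_class,motif_length motif layout per family
#'   (default two motifs of length 12, a realistic footprint for an
#'   active site plus a binding region).
#' @param seq_length member length range (default 120-400).
#' @param motif_seed seed for motif generation.
#' @return list of [family_spec()]s.
#' @export
default_benchmark_specs <- function(n_classes = 6L, n_members = 80L,
                                    mutation_rate = 0.05,
                                    motifs_per_class = 2L, motif_length = 12L,
                                    seq_length = c(120L, 400L),
                                    motif_seed = 7L) {
  motifs <- with_seed(motif_seed, {
    lapply(seq_len(n_classes), function(i)
      vapply(seq_len(motifs_per_class), function(j)
        paste(sample(AA20, motif_length, replace = TRUE), collapse = ""), ""))
  })
  lapply(seq_len(n_classes), function(i) {
    family_spec(ec = paste0(i, ".-.-.-"), motifs = motifs[[i]],
                n_members = n_members, seq_length = seq_length,
                mutation_rate = mutation_rate)
  })
}

#' Derive a child family spec
#'
#' The child inherits every parent motif and adds its own, so members
#' of the child carry both signals and the levels of the hierarchy
#' remain separable.
#'
#' @param parent a [family_spec()].
#' @param ec EC class of the child (must be a descendant of the
#'   parent's class).
#' @param extra_motifs motifs added on top of the inherited ones.
#' @param n_members,mutation_rate overrides (default: the parent's).
#' @return a [family_spec()].
#' @export
child_family_spec <- function(parent, ec, extra_motifs,
                              n_members = parent$n_members,
                              mutation_rate = parent$mutation_rate) {
  if (!ec_relation(parent$ec, ec) %in% c("ancestor")) {
    stop(ec_format(ec), " is not a descendant of ", parent$ec)
  }
  family_spec(ec = ec, motifs = c(parent$motifs, extra_motifs),
              n_members = n_members, seq_length = parent$seq_length,
              mutation_rate = mutation_rate, background = parent$background)
}

#' Generate the full synthetic benchmark
#'
#' Labeled enzyme families per the specs plus motif-free non-enzymes
#' (random background, annotation score 5, verified not to contain any
#' family motif verbatim), optionally written out as FASTA plus
#' annotation TSV.  Byte-identical under a fixed seed.
#'
#' @param specs list of [family_spec()]s (default:
#'   [default_benchmark_specs()]).
#' @param n_nonenzymes number of non-enzyme records (default 480).
#' @param seed integer seed.
#' @param fasta,annotations optional output paths.
#' @param seq_length length range of non-enzymes.
#' @return protein record data frame covering all families plus
#'   non-enzymes.
#' @export
generate_benchmark <- function(specs = default_benchmark_specs(),
                               n_nonenzymes = 480L, seed = 42L,
                               fasta = NULL, annotations = NULL,
                               seq_length = c(120L, 400L)) {
  fams <- lapply(seq_along(specs), function(i) {
    generate_family(specs[[i]], seed = derive_seed(seed, paste0("fam-", i)))
  })
  all_motifs <- unique(unlist(lapply(specs, `[[`, "motifs")))
  lens <- seq(seq_length[1], seq_length[2])
  ne <- with_seed(derive_seed(seed, "nonenzymes"), {
    seqs <- character(n_nonenzymes)
    for (i in seq_len(n_nonenzymes)) {
      repeat {
        n <- lens[sample.int(length(lens), 1L)]
        s <- random_background(n, rep(1 / 20, 20))
        if (!any(vapply(all_motifs, grepl, logical(1), x = s, fixed = TRUE)))
          break
      }
      seqs[i] <- s
    }
    data.frame(id = sprintf("ne_%04d", seq_len(n_nonenzymes)),
               sequence = seqs, ec = "", annotation_score = 5L,
               is_enzyme = FALSE, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, c(fams, list(ne)))
  if (anyDuplicated(records$id)) stop("duplicate ids in benchmark specs")
  if (!is.null(fasta)) write_fasta(records, fasta)
  if (!is.null(annotations)) {
    ann <- records[c("id", "ec", "annotation_score", "is_enzyme")]
    names(ann)[1] <- "protein_id"
    write_annotation_table(ann, annotations)
  }
  records
}
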
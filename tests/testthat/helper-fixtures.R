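# Small programmatic fixtures shared across tests.

make_records <- function(ids, sequences, ec = "", score = NA_integer_,
                         is_enzyme = NA) {
  data.frame(id = ids, sequence = sequences,
             ec = rep_len(ec, length(ids)),
             annotation_score = rep_len(score, length(ids)),
             is_enzyme = rep_len(is_enzyme, length(ids)),
             stringsAsFactors = FALSE)
}

# A toy annotated proteome covering a 3-level hierarchy under main
# class 1 plus two other main classes and non-enzymes, with controlled
# counts per class (sequences are irrelevant placeholders).
toy_class_records <- function() {
  mk <- function(prefix, n, ec, score = 5L, enz = TRUE) {
    make_records(sprintf("%s%02d", prefix, seq_len(n)),
                 strrep("ACDEFGHIKLMNPQRSTVWY", 3), ec, score, enz)
  }
  rbind(
    mk("a", 6, "1.1.1.1"),
    mk("b", 5, "1.1.2.4"),
    mk("c", 4, "1.2.1.-"),
    mk("d", 3, "1.3.-.-"),
    mk("e", 8, "2.3.1.-"),
    mk("f", 7, "3.1.3.16"),
    mk("n", 6, "", score = 5L, enz = FALSE),
    mk("m", 3, "", score = 2L, enz = FALSE))
}

# Two strongly motif-marked families plus non-enzymes, small enough for
# fast end-to-end tests.
tiny_benchmark <- function(seed = 11L, n_members = 24L, mutation_rate = 0,
                           n_nonenzymes = 24L) {
  specs <- default_benchmark_specs(n_classes = 2, n_members = n_members,
                                   mutation_rate = mutation_rate)
  generate_benchmark(specs, n_nonenzymes = n_nonenzymes, seed = seed)
}

tiny_config <- function(seed = 11L) {
  ec_config(min_class_size = 20, folds = 3, seed = seed)
}
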
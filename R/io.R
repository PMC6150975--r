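#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that returns a
#' plain data frame of protein records.  The record id is the first
#' whitespace-delimited token of the FASTA header; file order is
#' preserved.  Sequences are sanitized according to the non-canonical
#' residue policy (see [sanitize_sequence()]).
#'
#' @param path path to a FASTA file.
#' @param residue_policy `"mask"` (default: B/Z/J/U/O/`*` become X) or
#'   `"strict"` (error on any residue outside the 20-letter alphabet).
#' @return data frame with columns `id` and `sequence`; zero rows for an
#'   empty file.
#' @export
read_fasta <- function(path, residue_policy = c("mask", "strict")) {
  residue_policy <- match.arg(residue_policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  first <- nonempty[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA in '", path, "': line ", first,
         " does not start a record ('>' expected)")
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  if (anyDuplicated(ids)) {
    warning("duplicated ids in '", path, "': ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- as.character(set)
  seqs <- mapply(sanitize_sequence, seqs, id = ids,
                 MoreArgs = list(policy = residue_policy), USE.NAMES = FALSE)
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param records data frame with columns `id` and `sequence`.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read an annotation table
#'
#' The annotation table is a TSV with header columns `protein_id`, `ec`,
#' `annotation_score` and `is_enzyme`.  `ec` is empty for proteins
#' without enzymatic annotation and may list several EC numbers
#' separated by `;` (such multi-EC proteins are later discarded by
#' [propagate_annotations()]).  `annotation_score` is the 1-5 star
#' annotation-reliability rating (empty allowed); `is_enzyme` is
#' `TRUE`/`FALSE` or empty for unknown.
#'
#' @param path path to the TSV file.
#' @return data frame with columns `protein_id`, `ec` (canonicalized,
#'   `;`-separated), `annotation_score` (integer, NA allowed) and
#'   `is_enzyme` (logical, NA allowed).
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("protein_id", "ec", "annotation_score", "is_enzyme")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("annotation table '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$ec[is.na(df$ec)] <- ""
  df$ec <- vapply(df$ec, function(x) {
    if (!nzchar(x)) return("")
    parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    paste(vapply(parts, function(p) ec_format(ec_parse(p)), ""), collapse = ";")
  }, "", USE.NAMES = FALSE)
  score <- suppressWarnings(as.integer(df$annotation_score))
  bad <- !is.na(score) & !(score %in% 1:5)
  if (any(bad)) {
    stop("annotation score out of range 1-5 for: ",
         paste(df$protein_id[bad], collapse = ", "))
  }
  df$annotation_score <- score
  df$is_enzyme <- as.logical(df$is_enzyme)
  df[c("protein_id", "ec", "annotation_score", "is_enzyme")]
}

#' Write an annotation table
#'
#' @param annotations data frame as returned by [read_annotation_table()].
#' @param path output path.
#' @export
write_annotation_table <- function(annotations, path) {
  out <- annotations
  out$annotation_score[is.na(out$annotation_score)] <- ""
  out$is_enzyme <- ifelse(is.na(out$is_enzyme), "",
                          ifelse(out$is_enzyme, "TRUE", "FALSE"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Join sequences with their annotations into protein records
#'
#' @param fasta data frame from [read_fasta()].
#' @param annotations data frame from [read_annotation_table()]; ids
#'   absent from it get empty annotations.
#' @return data frame with columns `id`, `sequence`, `ec`,
#'   `annotation_score`, `is_enzyme`.
#' @export
merge_records <- function(fasta, annotations = NULL) {
  rec <- fasta
  if (is.null(annotations)) {
    rec$ec <- ""
    rec$annotation_score <- NA_integer_
    rec$is_enzyme <- NA
    return(rec)
  }
  m <- match(rec$id, annotations$protein_id)
  rec$ec <- ifelse(is.na(m), "", annotations$ec[m])
  rec$annotation_score <- annotations$annotation_score[m]
  rec$is_enzyme <- annotations$is_enzyme[m]
  rec
}

#' Write hierarchical predictions as TSV
#'
#' One row per query with the four EC components split into columns
#' (`-` where unpredicted), the final label (an EC path, `"non-enzyme"`
#' or `"no prediction"`) and the ensemble confidence of the deepest
#' accepted class.
#'
#' @param results data frame with columns `protein_id`, `label`,
#'   `confidence` (as produced by [predict_sequences()]).
#' @param path output path.
#' @return the path, invisibly.  The file has a header row plus exactly
#'   `nrow(results)` data rows.
#' @export
write_predictions_tsv <- function(results, path) {
  comp <- function(label, i) {
    vapply(label, function(lb) {
      if (lb %in% c("non-enzyme", "no prediction")) return("-")
      x <- ec_parse(lb)$components[i]
      if (is.na(x)) "-" else as.character(x)
    }, "", USE.NAMES = FALSE)
  }
  out <- data.frame(
    protein_id = results$protein_id,
    main_class = comp(results$label, 1),
    subclass = comp(results$label, 2),
    sub_subclass = comp(results$label, 3),
    substrate_class = comp(results$label, 4),
    label = results$label,
    confidence = sprintf("%.4f", results$confidence),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a predictions TSV back into a data frame
#'
#' @param path path written by [write_predictions_tsv()].
#' @export
read_predictions_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(confidence = "numeric"))
  df
}
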
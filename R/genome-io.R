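#' Construct a genome object from named sequences
#'
#' @param scaffolds named character vector of DNA sequences.  Sequences are
#'   uppercased; characters outside `A/C/G/T/N` (including IUPAC ambiguity
#'   codes) are replaced by `N`.
#' @param quiet suppress the message reporting replaced characters.
#' @return an object of class `genome`: a list with `scaffolds` (named
#'   character vector over `A/C/G/T/N`) and `total_length`.
#' @export
genome <- function(scaffolds, quiet = FALSE) {
  if (length(scaffolds) == 0L) stop("genome must contain at least one scaffold")
  ids <- names(scaffolds)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids)) {
    stop("all scaffolds must have non-empty ids")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate scaffold id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(scaffolds))) stop("empty scaffold sequence(s) rejected")
  seqs <- toupper(scaffolds)
  cleaned <- gsub("[^ACGTN]", "N", seqs)
  n_sub <- sum(nchar(gsub("[ACGTN]", "", seqs)))
  if (n_sub > 0L && !quiet) {
    message(n_sub, " non-ACGTN character(s) replaced by N")
  }
  structure(
    list(scaffolds = cleaned, total_length = sum(nchar(cleaned))),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d scaffold(s), %s bp total\n",
              length(x$scaffolds), format(x$total_length, big.mark = ",")))
  n <- min(5L, length(x$scaffolds))
  for (i in seq_len(n)) {
    cat(sprintf("  %s  %s bp\n", names(x$scaffolds)[i],
                format(nchar(x$scaffolds[i]), big.mark = ",")))
  }
  if (length(x$scaffolds) > n) cat("  ...\n")
  invisible(x)
}

#' Read a multi-scaffold genome from FASTA
#'
#' Sequences are uppercased and any character outside `A/C/G/T/N` is mapped
#' to `N` (count reported via a message).  Empty records and duplicate ids
#' are rejected.
#'
#' @param path path to a FASTA file.
#' @return a [genome] object.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse FASTA ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  names(seqs) <- ids
  genome(seqs)
}

#' Write a genome to FASTA
#'
#' @param x a [genome] object.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_genome_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "genome"))
  set <- Biostrings::DNAStringSet(x$scaffolds)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Write interval records as BED6
#'
#' Coordinates are 0-based half-open throughout the package and on disk.
#'
#' @param records a data.frame with columns `scaffold`, `start`, `end`,
#'   `name`, `score`, `strand`.
#' @param path output path.
#' @export
write_intervals <- function(records, path) {
  need <- c("scaffold", "start", "end", "name", "score", "strand")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("records must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  if (nrow(records) > 0L) {
    if (any(records$start < 0L) || any(records$start >= records$end)) {
      stop("invalid interval(s): require 0 <= start < end")
    }
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   records$scaffold, as.integer(records$start),
                   as.integer(records$end), records$name,
                   as.character(records$score), records$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read BED6 interval records
#'
#' @param path path to a BED6 file written by [write_intervals()].
#' @return a data.frame with columns `scaffold`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("scaffold", "start", "end",
                                        "name", "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "character", "character"),
                          comment.char = "#", quote = "")
  df
}
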
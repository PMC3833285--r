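#' Construct a restriction enzyme object
#'
#' @param name enzyme name.
#' @param recognition recognition sequence, 4-8 IUPAC characters.
#' @param cut_offset 0-based position of the top-strand cut measured from the
#'   5' end of the recognition site; must lie in `[0, nchar(recognition)]`.
#' @return an object of class `enzyme` with fields `name`, `recognition`,
#'   `cut_offset` and the derived `is_palindromic`.
#' @export
enzyme <- function(name, recognition, cut_offset) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("enzyme name must be a non-empty string")
  }
  if (!is.character(recognition) || length(recognition) != 1L) {
    stop("recognition must be a single string")
  }
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4L || nchar(recognition) > 8L) {
    stop("recognition sequence must be 4-8 bp, got '", recognition, "'")
  }
  pattern_bits(recognition)  # validates the alphabet
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition)) {
    stop("cut_offset must be an integer in [0, ", nchar(recognition),
         "] for site ", recognition)
  }
  structure(
    list(name = name, recognition = recognition, cut_offset = cut_offset,
         is_palindromic = is_palindromic_pattern(recognition)),
    class = "enzyme"
  )
}

#' @export
print.enzyme <- function(x, ...) {
  site <- paste0(substr(x$recognition, 1, x$cut_offset), "^",
                 substr(x$recognition, x$cut_offset + 1, nchar(x$recognition)))
  cat(sprintf("<enzyme> %s  %s%s\n", x$name, site,
              if (x$is_palindromic) "" else "  (non-palindromic)"))
  invisible(x)
}

#' Load a restriction enzyme table
#'
#' Reads a tab-separated enzyme table (`name <TAB> recognition <TAB>
#' cut_offset`, `#` comments allowed).  With no argument, returns the
#' built-in panel shipped with the package: the isoschizomer pairs
#' MspI/HpaII (C^CGG) and AluI/AluBI (AG^CT), RsaI (GT^AC), FatI (^CATG),
#' Kzo9I (^GATC), AspS9I (G^GNCC) and Bme18I (G^GWCC).
#'
#' @param source optional path to a TSV file; `NULL` loads the shipped panel.
#' @return a named list of [enzyme] objects.
#' @examples
#' panel <- load_enzyme_table()
#' panel[["Kzo9I"]]$recognition  # "GATC"
#' @export
load_enzyme_table <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "enzymes.tsv", package = "midsat",
                          mustWork = TRUE)
  }
  if (!file.exists(source)) stop("enzyme table not found: ", source)
  lines <- readLines(source, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(line))) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) != 3L || !all(nzchar(fields))) {
      stop("malformed enzyme table row at line ", i, ": expected ",
           "'name<TAB>recognition<TAB>cut_offset'")
    }
    off <- suppressWarnings(as.integer(fields[3]))
    if (is.na(off)) stop("malformed cut_offset at line ", i, ": '", fields[3], "'")
    enz <- tryCatch(enzyme(fields[1], fields[2], off),
                    error = function(e) stop("line ", i, ": ",
                                             conditionMessage(e), call. = FALSE))
    if (enz$name %in% names(out)) stop("duplicate enzyme name at line ", i,
                                       ": ", enz$name)
    out[[enz$name]] <- enz
  }
  if (length(out) == 0L) stop("enzyme table contains no entries: ", source)
  out
}
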
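# Column profiles: each input letter contributes its IUPAC expansion set,
# weight split evenly over the set; gaps contribute nothing.  Returns a
# 4 x L matrix (rows A,C,G,T) of relative frequencies plus gap fractions.
.column_profiles <- function(units) {
  L <- nchar(units[1])
  mat <- matrix(0, nrow = 4L, ncol = L, dimnames = list(BASES, NULL))
  gaps <- numeric(L)
  for (u in units) {
    ch <- utf8ToInt(u)
    is_gap <- ch == utf8ToInt("-")
    gaps <- gaps + is_gap
    bits <- ifelse(is_gap, 0L, .pattern_lookup[ch])
    if (anyNA(bits)) stop("unit contains non-IUPAC character")
    w <- 1 / pmax(1, (bitwAnd(bits, 1L) > 0) + (bitwAnd(bits, 2L) > 0) +
                     (bitwAnd(bits, 4L) > 0) + (bitwAnd(bits, 8L) > 0))
    for (b in 1:4) {
      hit <- bitwAnd(bits, c(1L, 2L, 4L, 8L)[b]) > 0
      mat[b, ] <- mat[b, ] + hit * w
    }
  }
  depth <- length(units) - gaps
  list(freq = sweep(mat, 2L, pmax(depth, 1), "/"),
       gap_fraction = gaps / length(units))
}

# IUPAC consensus call per column from a 4 x L frequency matrix
.profile_to_consensus <- function(freq, inclusion = 0.25, majority = 0.75) {
  vapply(seq_len(ncol(freq)), function(j) {
    f <- freq[, j]
    if (max(f) > majority) return(BASES[which.max(f)])
    set <- which(f >= inclusion)
    if (length(set) == 0L) set <- which.max(f)
    mask_to_code(sum(c(1L, 2L, 4L, 8L)[set]))
  }, character(1))
}

#' Build an IUPAC consensus monomer from aligned repeat units
#'
#' Per alignment column, the consensus character is the IUPAC code for the
#' set of bases whose frequency reaches the inclusion threshold; a single
#' base above the majority threshold is written as that base.  Columns where
#' more than half of the units carry a gap are dropped.  A 50/50 polymorphic
#' G/C column thus becomes `S`, A/T becomes `W`, A/C becomes `M` -- the codes
#' that appear in satellite monomer consensi.
#'
#' @param units character vector (>= 2) of equal-length, equal-orientation,
#'   pre-aligned unit sequences; `-` marks gapped positions.
#' @param inclusion minimal per-column base frequency for inclusion in the
#'   ambiguity set (default 0.25).
#' @param majority frequency above which a column is written as a single
#'   base (default 0.75).
#' @return an object of class `consensus_unit`: list with `sequence` (IUPAC
#'   string), `length`, and `profile` (4 x length base-frequency matrix).
#' @examples
#' build_consensus(c("ACGT", "ACGA"))  # "ACGW"
#' @export
build_consensus <- function(units, inclusion = 0.25, majority = 0.75) {
  if (!is.character(units) || length(units) < 2L) {
    stop("build_consensus requires >= 2 unit sequences")
  }
  units <- toupper(units)
  if (length(unique(nchar(units))) != 1L) {
    stop("units must be pre-aligned to equal length (use '-' for gaps)")
  }
  prof <- .column_profiles(units)
  keep <- prof$gap_fraction <= 0.5
  if (!any(keep)) stop("all columns are gap-dominated")
  freq <- prof$freq[, keep, drop = FALSE]
  consensus_unit(paste(.profile_to_consensus(freq, inclusion, majority),
                       collapse = ""),
                 profile = freq)
}

#' Construct a consensus monomer object
#'
#' @param sequence IUPAC DNA string.
#' @param profile optional 4 x length base-frequency matrix (rows
#'   `A,C,G,T`); derived from the sequence when omitted (each code's
#'   expansion set at equal frequencies).
#' @return a `consensus_unit` object.
#' @export
consensus_unit <- function(sequence, profile = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- toupper(sequence)
  pattern_bits(sequence)  # validate alphabet
  if (is.null(profile)) {
    profile <- .column_profiles(sequence)$freq
  }
  stopifnot(nrow(profile) == 4L, ncol(profile) == nchar(sequence))
  structure(list(sequence = sequence, length = nchar(sequence),
                 profile = profile),
            class = "consensus_unit")
}

#' @export
print.consensus_unit <- function(x, ...) {
  cat(sprintf("<consensus_unit> %d bp\n", x$length))
  seq <- x$sequence
  for (i in seq(1L, nchar(seq), by = 60L)) {
    cat(sprintf("  %4d  %s\n", i, substr(seq, i, min(i + 59L, nchar(seq)))))
  }
  amb <- gsub("[ACGT]", "", seq)
  if (nzchar(amb)) {
    cat("  ambiguity codes: ",
        paste(sort(unique(strsplit(amb, "")[[1]])), collapse = " "), "\n")
  }
  invisible(x)
}

#' Map restriction sites onto a circularised consensus monomer
#'
#' An interior unit of a head-to-tail tandem array is effectively circular:
#' digestion fragments are the circular gaps between consecutive cut
#' positions, and their lengths sum to the monomer length.  A monomer with a
#' unique site yields monomer-length fragments; two sites split the monomer
#' into two sub-fragments (e.g. 36 + 118 = 154).  Sites are matched with
#' IUPAC-vs-IUPAC intersection semantics, since the consensus is itself
#' degenerate.
#'
#' @param consensus a `consensus_unit` (or plain IUPAC string).
#' @param enzymes a named list of [enzyme] objects (e.g. from
#'   [load_enzyme_table()]), or a single enzyme.
#' @return an object of class `site_map`: per enzyme, `sites` (0-based start
#'   positions on the monomer), `cuts` (0-based circular cut positions),
#'   `fragments` (predicted circular fragment lengths, summing to the
#'   monomer length), and `uncut` flag.
#' @export
map_sites <- function(consensus, enzymes) {
  if (is.character(consensus)) consensus <- consensus_unit(consensus)
  stopifnot(inherits(consensus, "consensus_unit"))
  if (inherits(enzymes, "enzyme")) enzymes <- stats::setNames(list(enzymes), enzymes$name)
  L <- consensus$length
  seqbits <- pattern_bits(consensus$sequence)  # degenerate letters kept
  per_enzyme <- lapply(enzymes, function(enz) {
    p <- pattern_bits(enz$recognition)
    k <- length(p)
    ext <- c(seqbits, seqbits[seq_len(min(k - 1L, L))])
    starts <- .scan_starts_iupac(ext, p)
    starts <- starts[starts <= L - 1L]                  # one copy per circular site
    cuts <- sort(unique((starts + enz$cut_offset) %% L))
    if (!enz$is_palindromic) {
      rc <- rev(.comp_mask[p + 1L])
      starts_rc <- .scan_starts_iupac(ext, rc)
      starts_rc <- starts_rc[starts_rc <= L - 1L]
      cuts <- sort(unique(c(cuts, (starts_rc + (k - enz$cut_offset)) %% L)))
    }
    frags <- if (length(cuts) == 0L) integer(0)
             else if (length(cuts) == 1L) L
             else as.integer(c(diff(cuts), L - cuts[length(cuts)] + cuts[1]))
    list(sites = as.integer(sort(starts)), cuts = as.integer(cuts),
         fragments = sort(as.integer(frags)), uncut = length(cuts) == 0L)
  })
  structure(list(consensus = consensus, enzymes = per_enzyme),
            class = "site_map")
}

# 0-based start positions where the IUPAC pattern is compatible with the
# (IUPAC-encoded) sequence at every position: intersection semantics
.scan_starts_iupac <- function(seqbits, p) {
  k <- length(p)
  n <- length(seqbits)
  if (n < k) return(integer(0))
  m <- n - k + 1L
  ok <- bitwAnd(seqbits[seq_len(m)], p[1L]) > 0L
  for (j in seq_len(k - 1L)) {
    ok <- ok & bitwAnd(seqbits[seq_len(m) + j], p[j + 1L]) > 0L
  }
  which(ok) - 1L
}

#' @export
print.site_map <- function(x, ...) {
  cat(sprintf("<site_map> on %d bp consensus monomer (circular)\n",
              x$consensus$length))
  for (e in names(x$enzymes)) {
    m <- x$enzymes[[e]]
    if (m$uncut) {
      cat(sprintf("  %-8s no sites (uncut)\n", e))
    } else {
      cat(sprintf("  %-8s sites at %s -> fragments %s bp\n", e,
                  paste(m$sites, collapse = ","),
                  paste(m$fragments, collapse = " + ")))
    }
  }
  invisible(x)
}

#' Tabulate a site map as a data.frame
#'
#' @param object a `site_map`.
#' @param ... unused.
#' @return data.frame with columns `enzyme`, `n_sites`, `sites`,
#'   `fragments`, `uncut`.
#' @export
summary.site_map <- function(object, ...) {
  data.frame(
    enzyme = names(object$enzymes),
    n_sites = vapply(object$enzymes, function(m) length(m$sites), integer(1)),
    sites = vapply(object$enzymes, function(m) paste(m$sites, collapse = ","),
                   character(1)),
    fragments = vapply(object$enzymes,
                       function(m) paste(m$fragments, collapse = ","),
                       character(1)),
    uncut = vapply(object$enzymes, function(m) m$uncut, logical(1)),
    row.names = NULL
  )
}
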
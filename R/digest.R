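#' Locate restriction sites and cut positions on a sequence
#'
#' Scans a sequence for all occurrences of an enzyme's recognition site
#' (IUPAC-degenerate positions expanded; genome `N` matches nothing) and
#' returns the top-strand cut positions, `site_start + cut_offset`, in
#' 0-based between-base coordinates.  Overlapping site occurrences each
#' produce a cut; coincident cut positions are collapsed.  Non-palindromic
#' recognition sequences are additionally scanned as their reverse
#' complement, with bottom-strand cuts mapped to top-strand coordinates.
#'
#' @param sequence DNA string over `A/C/G/T/N`.
#' @param enz an [enzyme] object.
#' @return a list of class `cutset` with `cuts` (strictly increasing integer
#'   vector, each in `[0, nchar(sequence)]`) and `scaffold_length`.
#' @examples
#' hpaii <- enzyme("HpaII", "CCGG", 1)
#' find_sites("ACCGGT", hpaii)$cuts  # 2
#' @export
find_sites <- function(sequence, enz) {
  stopifnot(inherits(enz, "enzyme"))
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("sequence must be a single string")
  }
  n <- nchar(sequence)
  s <- genome_bits(sequence)
  cuts <- .scan_cuts(s, pattern_bits(enz$recognition), enz$cut_offset)
  if (!enz$is_palindromic) {
    p <- pattern_bits(enz$recognition)
    rc <- rev(.comp_mask[p + 1L])
    # a bottom-strand site at top-strand start s0 cuts the top strand at
    # s0 + (len - cut_offset)
    cuts <- c(cuts, .scan_cuts(s, rc, length(p) - enz$cut_offset))
  }
  structure(list(cuts = sort(unique(cuts)), scaffold_length = n),
            class = "cutset")
}

# vectorised bitmask scan: start positions (0-based) where every pattern
# position intersects the sequence mask, shifted by the cut offset
.scan_cuts <- function(s, p, offset) {
  k <- length(p)
  n <- length(s)
  if (n < k) return(integer(0))
  m <- n - k + 1L
  ok <- bitwAnd(s[seq_len(m)], p[1L]) > 0L
  for (j in seq_len(k - 1L)) {
    ok <- ok & bitwAnd(s[seq_len(m) + j], p[j + 1L]) > 0L
  }
  (which(ok) - 1L) + offset
}

#' Fragment lengths of a linearly cut molecule
#'
#' Successive differences of the cut positions, including the terminal
#' fragments from the scaffold start to the first cut and from the last cut
#' to the scaffold end.  Zero-length fragments (cuts at position 0 or at the
#' scaffold end, coincident cuts) are dropped.
#'
#' @param cutset a `cutset` from [find_sites()], or an integer vector of cut
#'   positions.
#' @param scaffold_length scaffold length in bp (taken from the cutset when
#'   omitted).
#' @return integer vector of fragment lengths.
#' @export
fragment_lengths <- function(cutset, scaffold_length = NULL) {
  if (inherits(cutset, "cutset")) {
    cuts <- cutset$cuts
    if (is.null(scaffold_length)) scaffold_length <- cutset$scaffold_length
  } else {
    cuts <- as.integer(cutset)
  }
  if (is.null(scaffold_length)) stop("scaffold_length required")
  if (length(cuts) > 0L &&
      (any(cuts < 0L) || any(cuts > scaffold_length) || is.unsorted(cuts))) {
    stop("cuts must be sorted and within [0, scaffold_length]")
  }
  d <- diff(c(0L, cuts, scaffold_length))
  as.integer(d[d > 0L])
}

#' Digest a genome and build its fragment-length distribution
#'
#' The core in silico digestion: every scaffold is cut at all theoretical
#' recognition sites of the enzyme and the multiset of fragment lengths is
#' aggregated into a distribution diagram.  Terminal (scaffold-end) fragments
#' are included, so combined fragment mass is conserved:
#' `sum(length * count) == total genome length`.
#'
#' @param gen a [genome] object.
#' @param enz an [enzyme] object.
#' @return an object of class `fragdist`: list with `enzyme`, `counts` (a
#'   data.frame with columns `length`, `count`, `mass = length * count`,
#'   sorted by length), `total_bp`, and `n_fragments`.
#' @export
digest_genome <- function(gen, enz) {
  stopifnot(inherits(gen, "genome"), inherits(enz, "enzyme"))
  lens <- unlist(lapply(gen$scaffolds, function(s) fragment_lengths(find_sites(s, enz))),
                 use.names = FALSE)
  tab <- table(lens)
  counts <- data.frame(length = as.integer(names(tab)),
                       count = as.integer(tab))
  counts <- counts[order(counts$length), , drop = FALSE]
  counts$mass <- counts$length * counts$count
  rownames(counts) <- NULL
  structure(
    list(enzyme = enz$name, counts = counts,
         total_bp = gen$total_length, n_fragments = length(lens)),
    class = "fragdist"
  )
}

#' @export
print.fragdist <- function(x, ...) {
  cat(sprintf("<fragdist> %s digestion: %s fragments, %s bp total\n",
              x$enzyme, format(x$n_fragments, big.mark = ","),
              format(x$total_bp, big.mark = ",")))
  top <- x$counts[order(-x$counts$count), , drop = FALSE]
  top <- utils::head(top, 5L)
  cat("  most frequent lengths:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %6d bp  x%d\n", top$length[i], top$count[i]))
  }
  invisible(x)
}

#' Plot a fragment-length distribution diagram
#'
#' @param x a `fragdist`.
#' @param xlim length range to display (default 1-2000 bp, the range in which
#'   satellite monomer peaks live).
#' @param mass plot combined mass (`length * count`) instead of counts.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fragdist <- function(x, xlim = c(1, 2000), mass = FALSE, ...) {
  sel <- x$counts$length >= xlim[1] & x$counts$length <= xlim[2]
  df <- x$counts[sel, , drop = FALSE]
  y <- if (mass) df$mass else df$count
  graphics::plot(df$length, y, type = "h",
                 xlab = "fragment length (bp)",
                 ylab = if (mass) "combined mass (bp)" else "fragment count",
                 main = paste0(x$enzyme, " in silico digestion"), ...)
  invisible(x)
}

#' Write a fragment-length distribution as TSV
#'
#' @param dist a `fragdist`.
#' @param path output path; columns `length`, `count`, `mass`.
#' @export
write_fragdist <- function(dist, path) {
  stopifnot(inherits(dist, "fragdist"))
  utils::write.table(dist$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a fragment-length distribution TSV
#'
#' @param path a TSV written by [write_fragdist()].
#' @param enzyme enzyme name to record (defaults to the file name).
#' @return a `fragdist` object.
#' @export
read_fragdist <- function(path, enzyme = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  stopifnot(all(c("length", "count") %in% names(df)))
  df$mass <- df$length * df$count
  structure(
    list(enzyme = enzyme %||% tools::file_path_sans_ext(basename(path)),
         counts = df[order(df$length), c("length", "count", "mass")],
         total_bp = sum(df$length * df$count),
         n_fragments = sum(df$count)),
    class = "fragdist"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
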
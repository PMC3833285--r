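# Pairwise alignment helpers.  All alignments in the package use a simple
# unit-cost scheme (match +1, mismatch -1, linear gap -2) with IUPAC
# intersection semantics: two letters "match" iff their expansion sets
# intersect.  Alignment itself is delegated to Biostrings::pairwiseAlignment
# with a custom substitution matrix over the full IUPAC alphabet.

.align_cache <- new.env(parent = emptyenv())

# default +1/-1 IUPAC intersection matrix, built on first use
.iupac_submat <- function() {
  if (is.null(.align_cache$default)) {
    m <- outer(IUPAC_BITS, IUPAC_BITS,
               function(a, b) ifelse(bitwAnd(a, b) > 0L, 1, -1))
    dimnames(m) <- list(names(IUPAC_BITS), names(IUPAC_BITS))
    .align_cache$default <- m
  }
  .align_cache$default
}

# TRUE per column where two aligned IUPAC letters are compatible (neither a
# gap, expansion sets intersect).
iupac_compatible <- function(a_chars, b_chars) {
  ia <- .pattern_lookup[utf8ToInt(paste0(a_chars, collapse = ""))]
  ib <- .pattern_lookup[utf8ToInt(paste0(b_chars, collapse = ""))]
  ok <- !is.na(ia) & !is.na(ib)
  out <- logical(length(ia))
  out[ok] <- bitwAnd(ia[ok], ib[ok]) > 0L
  out
}

# Internal alignment runner.  type is one of "global", "local",
# "global-local" (whole pattern against the best-matching stretch of the
# subject).  Returns score, aligned strings, identity (% compatible columns)
# and 1-based matched ranges on pattern and subject.
align_pair <- function(a, b, type = "global", match = 1, mismatch = -1, gap = 2) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align empty sequences")
  submat <- if (match == 1 && mismatch == -1) .iupac_submat() else {
    m <- outer(IUPAC_BITS, IUPAC_BITS,
               function(x, y) ifelse(bitwAnd(x, y) > 0L, match, mismatch))
    dimnames(m) <- list(names(IUPAC_BITS), names(IUPAC_BITS))
    m
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = type,
    substitutionMatrix = submat, gapOpening = 0, gapExtension = gap
  )
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  pa <- as.character(pat)   # aligned region with '-' for gaps
  sa <- as.character(sub)
  if (type == "global") {
    # the aligned view trims terminal-gap overhangs; restore them so that
    # end gaps count as alignment columns
    ps <- Biostrings::start(pat); pe <- Biostrings::end(pat)
    ss <- Biostrings::start(sub); se <- Biostrings::end(sub)
    pre_p <- substr(a, 1L, ps - 1L); pre_s <- substr(b, 1L, ss - 1L)
    suf_p <- substr(a, pe + 1L, nchar(a)); suf_s <- substr(b, se + 1L, nchar(b))
    pa <- paste0(pre_p, strrep("-", nchar(pre_s)), pa,
                 suf_p, strrep("-", nchar(suf_s)))
    sa <- paste0(strrep("-", nchar(pre_p)), pre_s, sa,
                 strrep("-", nchar(suf_p)), suf_s)
  }
  ia <- .pattern_lookup[utf8ToInt(pa)]
  ib <- .pattern_lookup[utf8ToInt(sa)]
  matches <- sum(!is.na(ia) & !is.na(ib) & bitwAnd(ifelse(is.na(ia), 0L, ia),
                                                   ifelse(is.na(ib), 0L, ib)) > 0L)
  list(
    score = Biostrings::score(aln),
    pattern_aln = pa,
    subject_aln = sa,
    identity = 100 * matches / nchar(pa),
    n_columns = nchar(pa),
    pattern_start = Biostrings::start(pat),
    pattern_end = Biostrings::end(pat),
    subject_start = Biostrings::start(sub),
    subject_end = Biostrings::end(sub)
  )
}

# ungapped identity of two equal-length strings, IUPAC-aware; equals the
# global-alignment identity whenever the optimal alignment opens no gaps
hamming_identity <- function(a, b) {
  ia <- .pattern_lookup[utf8ToInt(a)]
  ib <- .pattern_lookup[utf8ToInt(b)]
  if (length(ia) != length(ib)) stop("hamming_identity needs equal lengths")
  100 * sum(bitwAnd(ifelse(is.na(ia), 0L, ia),
                    ifelse(is.na(ib), 0L, ib)) > 0L) / length(ia)
}

#' Percent identity between two sequences under global alignment
#'
#' Aligns the two sequences globally (Needleman-Wunsch; match +1, mismatch -1,
#' gap -2 by default) and reports `matches / alignment columns * 100`.
#' IUPAC-compatible letter pairs (intersecting expansion sets, e.g. `W` vs
#' `A`) count as matches, so degenerate consensus sequences can be compared
#' against concrete repeat units.
#'
#' @param a,b non-empty DNA strings (IUPAC alphabet allowed).
#' @param match,mismatch,gap alignment scores; `gap` is the (positive) cost
#'   per gapped base.
#' @return identity as a percentage in `[0, 100]`.
#' @examples
#' percent_identity("AGCT", "AGCT")  # 100
#' percent_identity("AGCT", "AGAT")  # 75
#' @export
percent_identity <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L ||
      length(b) != 1L || !nzchar(a) || !nzchar(b)) {
    stop("percent_identity requires two non-empty sequences")
  }
  align_pair(a, b, type = "global", match = match,
             mismatch = mismatch, gap = gap)$identity
}
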
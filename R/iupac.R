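# IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8).
IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

BASES <- c("A", "C", "G", "T")

# genome alphabet: A,C,G,T carry their bit; N (and anything else) carries 0,
# so an assembly-gap N can never satisfy a recognition-site position.
.genome_lookup <- local({
  x <- integer(256L)
  x[utf8ToInt("A")] <- 1L
  x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 4L
  x[utf8ToInt("T")] <- 8L
  x
})

.pattern_lookup <- local({
  x <- rep(NA_integer_, 256L)
  x[vapply(names(IUPAC_BITS), utf8ToInt, integer(1))] <- IUPAC_BITS
  x
})

# complement of a 4-bit mask: swap A<->T and C<->G bits
.comp_mask <- local({
  m <- 0:15
  as.integer(
    ifelse(bitwAnd(m, 1L) > 0L, 8L, 0L) +
    ifelse(bitwAnd(m, 2L) > 0L, 4L, 0L) +
    ifelse(bitwAnd(m, 4L) > 0L, 2L, 0L) +
    ifelse(bitwAnd(m, 8L) > 0L, 1L, 0L)
  )
})

# Encode a genome sequence (A/C/G/T/N) as a bitmask vector; N -> 0.
genome_bits <- function(sequence) {
  .genome_lookup[utf8ToInt(sequence)]
}

# Encode an IUPAC pattern as a bitmask vector; errors on non-IUPAC letters.
pattern_bits <- function(pattern) {
  b <- .pattern_lookup[utf8ToInt(pattern)]
  if (anyNA(b)) {
    bad <- unique(strsplit(pattern, "")[[1]][is.na(b)[seq_len(nchar(pattern))]])
    stop("non-IUPAC character(s) in pattern: ", paste(bad, collapse = ", "))
  }
  b
}

mask_to_code <- function(mask) {
  code <- names(IUPAC_BITS)[match(mask, IUPAC_BITS)]
  if (anyNA(code)) stop("invalid IUPAC mask: ", paste(mask[is.na(code)], collapse = ","))
  code
}

#' Test whether a base satisfies an IUPAC pattern character
#'
#' Degenerate-site semantics used throughout the package: a pattern character
#' matches a genome base iff the base belongs to the character's expansion
#' set.  A genome `N` (assembly gap / unknown base) matches nothing, including
#' pattern `N`, so N-runs in draft assemblies cannot fabricate recognition
#' sites.
#'
#' @param pattern_char single IUPAC character (one of `A C G T R Y S W K M B D
#'   H V N`).
#' @param base single genome character, one of `A C G T N`.
#' @return `TRUE` iff `base` is in the expansion set of `pattern_char`.
#' @examples
#' iupac_match("W", "A")  # TRUE: W = A or T
#' iupac_match("S", "A")  # FALSE: S = G or C
#' iupac_match("N", "N")  # FALSE: genome N is unmatchable
#' @export
iupac_match <- function(pattern_char, base) {
  if (!is.character(pattern_char) || length(pattern_char) != 1L ||
      nchar(pattern_char) != 1L || is.na(.pattern_lookup[utf8ToInt(pattern_char)])) {
    stop("pattern_char must be a single IUPAC character")
  }
  if (!is.character(base) || length(base) != 1L || nchar(base) != 1L ||
      !(base %in% c(BASES, "N"))) {
    stop("base must be one of A, C, G, T, N")
  }
  bitwAnd(.pattern_lookup[utf8ToInt(pattern_char)], .genome_lookup[utf8ToInt(base)]) > 0L
}

#' Reverse complement of an IUPAC string
#'
#' @param x a single DNA string over the IUPAC alphabet.
#' @return the reverse complement, preserving ambiguity codes (S and W are
#'   self-complementary, R pairs with Y, etc.).
#' @export
revcomp_iupac <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  flipped <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  intToUtf8(rev(utf8ToInt(flipped)))
}

# TRUE iff the IUPAC pattern equals its own reverse complement at the level
# of expansion sets (e.g. GGNCC, CCGG, GTAC are palindromic).
is_palindromic_pattern <- function(pattern) {
  b <- pattern_bits(pattern)
  identical(b, rev(.comp_mask[b + 1L]))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
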
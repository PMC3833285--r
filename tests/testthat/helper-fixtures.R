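# shared fixtures and independent oracles

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a scaffold with an exact head-to-tail array between random flanks
exact_array_scaffold <- function(unit, copies, flank = 1000) {
  paste0(rand_seq(flank), strrep(unit, copies), rand_seq(flank))
}

# --- independent restriction-site oracle (PCRE lookahead regex) ----------

iupac_regex <- function(pattern) {
  classes <- c(A = "A", C = "C", G = "G", T = "T",
               R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
               K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
               H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(classes[strsplit(pattern, "")[[1]]], collapse = "")
}

# overlapping occurrences via lookahead; genome N never matches because the
# character classes contain only A/C/G/T
oracle_cuts <- function(sequence, enz) {
  find_starts <- function(pat) {
    hits <- gregexpr(paste0("(?=", iupac_regex(pat), ")"), sequence,
                     perl = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
  }
  cuts <- find_starts(enz$recognition) + enz$cut_offset
  if (!enz$is_palindromic) {
    k <- nchar(enz$recognition)
    cuts <- c(cuts,
              find_starts(revcomp_iupac(enz$recognition)) + (k - enz$cut_offset))
  }
  sort(unique(cuts))
}

# --- brute-force global alignment oracle (tiny inputs only) ---------------
# enumerates all global alignments; returns the best score and, among
# optimal alignments, the maximal identity (% of columns with equal letters)
enum_align_best <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf
  best$identity <- NA_real_
  recurse <- function(i, j, score, matches, cols) {
    if (i > length(av) && j > length(bv)) {
      id <- 100 * matches / cols
      if (score > best$score ||
          (score == best$score && id > best$identity)) {
        best$score <- score
        best$identity <- id
      }
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      recurse(i + 1, j + 1, score + s, matches + (av[i] == bv[j]), cols + 1)
    }
    if (i <= length(av)) recurse(i + 1, j, score + gap, matches, cols + 1)
    if (j <= length(bv)) recurse(i, j + 1, score + gap, matches, cols + 1)
  }
  recurse(1L, 1L, 0, 0L, 0L)
  list(score = best$score, identity = best$identity)
}

# expansion sets for the exhaustive iupac_match truth table
iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
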
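#' Call peaks in a fragment-length distribution
#'
#' A length `L` is reported as a peak when (i) `count[L] >= min_count`,
#' (ii) `count[L]` exceeds the count at every other length in the window
#' `[L - window, L + window]` (ties broken toward the smaller length), and
#' (iii) `count[L] >= min_prominence * median(counts over the window)`
#' (absent lengths in the window count as zero).  Sharp peaks at the monomer
#' length or its sub-fragments are the digestion signature of tandem
#' arrays.
#'
#' @param dist a `fragdist` from [digest_genome()].
#' @param min_count minimal fragment count for a peak; the default (100) is
#'   tuned to megabase-scale genomes and should be scaled down for small
#'   test sequences.
#' @param window half-width (bp) of the local-maximum / background window.
#' @param min_prominence required ratio of the peak count to the median count
#'   over the window.
#' @return a data.frame of class `peaks` with columns `length`, `count`,
#'   `mass`, `prominence` (ratio of count to local background, `Inf` when the
#'   background median is zero), sorted by descending count.
#' @export
detect_peaks <- function(dist, min_count = 100L, window = 5L,
                         min_prominence = 5) {
  stopifnot(inherits(dist, "fragdist"))
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be >= 1")
  if (nrow(dist$counts) == 0L) stop("empty fragment distribution")
  df <- dist$counts
  max_len <- max(df$length)
  cnt <- integer(max_len)
  cnt[df$length] <- df$count

  cand <- df$length[df$count >= min_count]
  keep <- logical(length(cand))
  prom <- numeric(length(cand))
  for (i in seq_along(cand)) {
    L <- cand[i]
    lo <- max(1L, L - window)
    hi <- min(max_len, L + window)
    win <- cnt[lo:hi]
    # pad the window with zeros when it is clipped at the ends of the
    # length axis, so the background median is over 2*window+1 values
    win <- c(win, integer(2L * window + 1L - length(win)))
    others_lo <- if (L - window >= 1L) cnt[max(1L, L - window):(L - 1L)] else
      cnt[seq_len(L - 1L)]
    others_hi <- if (L + 1L <= hi) cnt[(L + 1L):hi] else integer(0)
    c0 <- cnt[L]
    is_max <- (length(others_lo) == 0L || all(c0 > others_lo)) &&
              (length(others_hi) == 0L || all(c0 >= others_hi))
    med <- stats::median(win)
    keep[i] <- is_max && c0 >= min_prominence * med
    prom[i] <- c0 / max(med, 1)
  }
  out <- data.frame(length = cand[keep], count = cnt[cand[keep]])
  out$mass <- out$length * out$count
  out$prominence <- prom[keep]
  out <- out[order(-out$count, out$length), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peaks", "data.frame")
  attr(out, "enzyme") <- dist$enzyme
  out
}

#' Predict which fragment lengths are visible as gel bands
#'
#' On an electrophoresis gel a fragment length is detectable only when the
#' combined molecular mass of all fragments of that length is a large enough
#' fraction of the loaded DNA; abundant but very short fragments can stay
#' below the detection level.  This returns the lengths whose combined mass
#' `length * count` reaches `mass_fraction_threshold * total_bp`.
#'
#' @param dist a `fragdist`.
#' @param mass_fraction_threshold fraction of total genome mass per 1-bp
#'   length bin required for visibility (default 0.0005, i.e. 0.05%).
#' @return integer vector of visible lengths, sorted by descending mass.
#' @export
predict_visible_bands <- function(dist, mass_fraction_threshold = 5e-4) {
  stopifnot(inherits(dist, "fragdist"))
  if (!(mass_fraction_threshold > 0 && mass_fraction_threshold < 1)) {
    stop("mass_fraction_threshold must be in (0, 1)")
  }
  df <- dist$counts
  sel <- df$mass >= mass_fraction_threshold * dist$total_bp
  df <- df[sel, , drop = FALSE]
  df$length[order(-df$mass)]
}

#' Intersect peak lengths across enzymes to nominate tandem repeat units
#'
#' Fragments of the same size produced by different enzymes are the
#' hallmark of a tandemly repeated unit carrying one recognition site per
#' enzyme.  Peak lengths from all enzymes are clustered by single linkage
#' with a length tolerance, and clusters supported by at least two distinct
#' enzymes are reported as candidate unit lengths.
#'
#' @param peaksets named list (one element per enzyme) of `peaks` data.frames
#'   from [detect_peaks()], or of numeric peak-length vectors.
#' @param tolerance_bp maximal length difference joining two peaks into one
#'   cluster.
#' @return a data.frame with columns `length` (median of member peak
#'   lengths), `n_enzymes`, `enzymes` (comma-separated supporter names),
#'   sorted by descending support then length.
#' @export
cross_enzyme_candidates <- function(peaksets, tolerance_bp = 5) {
  if (!is.list(peaksets) || length(peaksets) < 2L || is.null(names(peaksets))) {
    stop("peaksets must be a named list covering >= 2 enzymes")
  }
  recs <- do.call(rbind, lapply(names(peaksets), function(e) {
    p <- peaksets[[e]]
    lens <- if (is.data.frame(p)) p$length else as.numeric(p)
    if (length(lens) == 0L) return(NULL)
    data.frame(enzyme = e, length = lens)
  }))
  if (is.null(recs) || nrow(recs) == 0L) {
    return(data.frame(length = numeric(0), n_enzymes = integer(0),
                      enzymes = character(0)))
  }
  recs <- recs[order(recs$length), , drop = FALSE]
  cluster_id <- cumsum(c(1, diff(recs$length) > tolerance_bp))
  out <- do.call(rbind, lapply(split(recs, cluster_id), function(g) {
    supporters <- sort(unique(g$enzyme))
    if (length(supporters) < 2L) return(NULL)
    data.frame(length = stats::median(g$length),
               n_enzymes = length(supporters),
               enzymes = paste(supporters, collapse = ","))
  }))
  if (is.null(out)) {
    return(data.frame(length = numeric(0), n_enzymes = integer(0),
                      enzymes = character(0)))
  }
  out <- out[order(-out$n_enzymes, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}
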
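# k-mer integer codes for every start position of a scaffold (2 bits/base);
# NA where the window contains an N.  k <= 15 so codes stay exact doubles.
.kmer_codes <- function(sequence, k) {
  b2 <- c(A = 0, C = 1, G = 2, T = 3)
  lookup <- rep(NA_real_, 256L)
  lookup[vapply(names(b2), utf8ToInt, integer(1))] <- b2
  v <- lookup[utf8ToInt(sequence)]
  n <- length(v)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  code <- numeric(m)
  for (j in 0:(k - 1L)) {
    code <- code + v[seq_len(m) + j] * 4^j   # NA propagates from N positions
  }
  code
}

#' Scan a genome for medium-sized tandem arrays
#'
#' A purpose-built detector for head-to-tail repeated units of roughly
#' 40-500 bp.  Exact `k`-mer matches at a distance `d` within the period
#' range seed candidate arrays; votes with consistent distance and position
#' are merged into candidate regions; each region is segmented into repeat
#' units by re-anchoring the first unit along the array with glocal
#' alignment; and candidates are verified by globally aligning adjacent
#' units.  Maximal non-overlapping arrays passing the copy-number and
#' identity thresholds are reported; overlaps are resolved in favour of the
#' higher `copy_number * identity`, ties to the leftmost.
#'
#' @param gen a [genome] object.
#' @param min_period,max_period unit-length range searched, bp.
#' @param min_copies minimal copy number of a reported array.
#' @param min_identity minimal mean adjacent-unit identity (percent).
#' @param k seed k-mer length (exact match); must not exceed `min_period`.
#' @return a data.frame of class `tandem_arrays`, one row per array:
#'   `scaffold`, `start`, `end` (0-based half-open), `period` (median unit
#'   length, bp), `copy_number`, `mean_identity` (percent), `n_units`,
#'   `consensus` (per-array IUPAC consensus string).
#' @export
scan_tandem_arrays <- function(gen, min_period = 40L, max_period = 500L,
                               min_copies = 3, min_identity = 75, k = 12L) {
  stopifnot(inherits(gen, "genome"))
  if (min_period < k) stop("min_period must be >= k")
  if (min_period > max_period || min_period < 1L) stop("invalid period range")
  rows <- list()
  for (sid in names(gen$scaffolds)) {
    seq <- gen$scaffolds[[sid]]
    cands <- .candidate_runs(seq, min_period, max_period, min_copies, k)
    for (cand in cands) {
      arr <- .verify_array(seq, cand$start, cand$end, cand$period,
                           min_copies, min_identity, k)
      if (is.null(arr)) next
      if (arr$period < min_period || arr$period > max_period) next
      rows[[length(rows) + 1L]] <- c(list(scaffold = sid), arr)
    }
  }
  out <- .resolve_overlaps(rows)
  class(out) <- c("tandem_arrays", "data.frame")
  out
}

# Seed stage: positions whose k-mer recurs at distance d within the period
# range vote for (position, d).  Votes are grouped by position adjacency,
# then by single-linkage clustering of d, then split at large position gaps.
.candidate_runs <- function(seq, min_period, max_period, min_copies, k) {
  code <- .kmer_codes(seq, k)
  idx <- which(!is.na(code))
  if (length(idx) < 2L) return(list())
  o <- idx[order(code[idx], idx)]
  same <- code[o[-1]] == code[o[-length(o)]]
  d <- o[-1] - o[-length(o)]
  sel <- which(same & d >= min_period & d <= max_period)
  if (length(sel) == 0L) return(list())
  p <- o[sel]
  dd <- d[sel]
  ord <- order(p)
  p <- p[ord]; dd <- dd[ord]

  runs <- list()
  block_id <- cumsum(c(1, diff(p) > max_period))
  for (blk in split(seq_along(p), block_id)) {
    bp <- p[blk]; bd <- dd[blk]
    # cluster the distances (single linkage)
    du <- sort(unique(bd))
    dcl <- cumsum(c(1, diff(du) > pmax(3, 0.05 * du[-length(du)])))
    dmap <- stats::setNames(dcl, du)
    for (g in split(seq_along(bp), dmap[as.character(bd)])) {
      gp <- bp[g]; gd <- bd[g]
      per <- stats::median(gd)
      # split where consecutive votes are further apart than one unit
      sub_id <- cumsum(c(1, diff(gp) > per + 50))
      for (s in split(seq_along(gp), sub_id)) {
        sp <- gp[s]; sd0 <- gd[s]
        per2 <- stats::median(sd0)
        span_end <- max(sp) + round(per2) + k - 1
        span <- span_end - min(sp) + 1
        if (span < 0.8 * min_copies * per2) next
        if (length(sp) < 2L) next
        runs[[length(runs) + 1L]] <- list(start = min(sp),
                                          end = min(span_end, nchar(seq)),
                                          period = per2)
      }
    }
  }
  runs
}

# Segment a candidate region into units by re-anchoring the first unit along
# the array (offset with fewest mismatches near each expected unit start),
# then verify with adjacent-unit global alignments.
.verify_array <- function(seq, start, end, period, min_copies, min_identity, k) {
  P0 <- as.integer(round(period))
  if (end - start + 1 < 1.5 * P0) return(NULL)
  slack <- max(6L, round(0.15 * P0))
  reg <- utf8ToInt(substr(seq, start, end))   # local 1-based coords
  m <- length(reg)
  ref <- reg[seq_len(P0)]
  bounds <- 1L
  cur <- 1L
  repeat {
    exp_next <- cur + P0
    if (m - exp_next + 1L < 0.6 * P0 - slack) break
    best_off <- NA_integer_; best_mm <- Inf
    for (off in order(abs(-slack:slack))) {   # prefer offsets near 0 on ties
      o <- (-slack:slack)[off]
      s0 <- exp_next + o
      if (s0 <= cur + 0.5 * P0 || s0 > m) next
      L0 <- min(P0, m - s0 + 1L)
      if (L0 < 0.6 * P0) next
      mm <- mean(reg[s0:(s0 + L0 - 1L)] != ref[seq_len(L0)])
      if (mm < best_mm - 1e-12) { best_mm <- mm; best_off <- o }
    }
    if (is.na(best_off)) break
    cur <- exp_next + best_off
    bounds <- c(bounds, cur)
  }
  tail_len <- m - cur + 1L
  ends <- c(bounds[-1] - 1L, if (tail_len >= 0.6 * P0) m else NA_integer_)
  if (is.na(ends[length(ends)])) {
    bounds <- bounds[-length(bounds)]
    ends <- ends[-length(ends)]
    if (length(bounds) == 0L) return(NULL)
    m <- ends[length(ends)]
  }
  end <- start + m - 1L
  units <- substring(substr(seq, start, end), bounds, ends)
  if (length(units) < max(2L, ceiling(min_copies))) return(NULL)
  per <- as.integer(round(stats::median(nchar(units))))
  # adjacent-unit identity on up to 10 evenly spaced pairs; the ungapped
  # identity is a lower bound on the global-alignment identity, so it only
  # stands in when it is already clearly above the threshold
  pair_idx <- unique(round(seq(1L, length(units) - 1L,
                               length.out = min(length(units) - 1L, 10L))))
  ids <- vapply(pair_idx, function(i) {
    if (nchar(units[i]) == nchar(units[i + 1L])) {
      h <- hamming_identity(units[i], units[i + 1L])
      if (h >= min_identity + 5) return(h)
    }
    align_pair(units[i], units[i + 1L], type = "global")$identity
  }, numeric(1))
  mean_id <- mean(ids)
  span <- end - start + 1L
  copy_number <- span / per
  if (mean_id < min_identity || copy_number < min_copies ||
      span < min_copies * per * 0.8) {
    return(NULL)
  }
  cons <- .stack_consensus(units, per)
  list(start = start - 1L, end = end,   # convert to 0-based half-open
       period = per, copy_number = copy_number,
       mean_identity = mean_id, n_units = length(units),
       consensus = cons, score = copy_number * mean_id)
}

# Column-wise IUPAC consensus of units projected onto a reference unit.
.stack_consensus <- function(units, period) {
  ref <- units[[which.min(abs(nchar(units) - period))]]
  projected <- vapply(units, function(u) {
    if (nchar(u) == nchar(ref)) return(u)
    .project_onto(ref, u)
  }, character(1))
  if (length(projected) < 2L) return(ref)
  build_consensus(unname(projected))$sequence
}

# align u globally to ref and return u's letters per ref column ('-' where
# deleted; insertions relative to ref dropped)
.project_onto <- function(ref, u) {
  aln <- align_pair(ref, u, type = "global")
  pc <- strsplit(aln$pattern_aln, "")[[1]]
  sc <- strsplit(aln$subject_aln, "")[[1]]
  paste(sc[pc != "-"], collapse = "")
}

.resolve_overlaps <- function(rows) {
  empty <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), period = integer(0),
                      copy_number = numeric(0), mean_identity = numeric(0),
                      n_units = integer(0), consensus = character(0))
  if (length(rows) == 0L) return(empty)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(scaffold = r$scaffold, start = r$start, end = r$end,
               period = r$period, copy_number = r$copy_number,
               mean_identity = r$mean_identity, n_units = r$n_units,
               consensus = r$consensus, score = r$score)
  }))
  keep <- logical(nrow(df))
  for (sid in unique(df$scaffold)) {
    sel <- which(df$scaffold == sid)
    ord <- sel[order(-df$score[sel], df$start[sel])]
    taken_s <- integer(0); taken_e <- integer(0)
    for (i in ord) {
      if (!any(df$start[i] < taken_e & df$end[i] > taken_s)) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, df$start[i])
        taken_e <- c(taken_e, df$end[i])
      }
    }
  }
  df <- df[keep, setdiff(names(df), "score"), drop = FALSE]
  df <- df[order(df$scaffold, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-period census of tandem repeat units and clusters
#'
#' @param arrays a `tandem_arrays` data.frame from [scan_tandem_arrays()].
#' @param ranges optional list of `c(lo, hi)` period ranges to pool; when
#'   `NULL`, one bin per distinct period.
#' @return a data.frame with columns `period` (or `period_lo`/`period_hi`
#'   when `ranges` is given), `unit_count` (sum of rounded copy numbers) and
#'   `cluster_count` (number of arrays).
#' @export
census <- function(arrays, ranges = NULL) {
  stopifnot(is.data.frame(arrays))
  units <- round(arrays$copy_number)
  if (is.null(ranges)) {
    if (nrow(arrays) == 0L) {
      return(data.frame(period = integer(0), unit_count = numeric(0),
                        cluster_count = integer(0)))
    }
    agg <- stats::aggregate(cbind(unit_count = units,
                                  cluster_count = rep(1L, nrow(arrays))),
                            by = list(period = arrays$period), FUN = sum)
    agg$cluster_count <- as.integer(agg$cluster_count)
    agg <- agg[order(agg$period), , drop = FALSE]
    rownames(agg) <- NULL
    return(agg)
  }
  do.call(rbind, lapply(ranges, function(r) {
    sel <- arrays$period >= r[1] & arrays$period <= r[2]
    data.frame(period_lo = r[1], period_hi = r[2],
               unit_count = sum(units[sel]), cluster_count = sum(sel))
  }))
}

#' Pool per-array consensi into one family consensus monomer
#'
#' Collects the arrays whose period falls in a range, rotationally aligns
#' each array's consensus to the first array's consensus (best circular
#' offset by maximal IUPAC-aware identity), stacks them, and calls the
#' column-wise IUPAC consensus.
#'
#' @param arrays a `tandem_arrays` data.frame.
#' @param period_range `c(lo, hi)` period range selecting the family.
#' @param inclusion,majority consensus thresholds, see [build_consensus()].
#' @return a `consensus_unit`.
#' @export
pool_consensus <- function(arrays, period_range, inclusion = 0.25,
                           majority = 0.75) {
  stopifnot(is.data.frame(arrays), length(period_range) == 2L)
  sel <- arrays$period >= period_range[1] & arrays$period <= period_range[2]
  cons <- arrays$consensus[sel]
  if (length(cons) == 0L) stop("no arrays with period in [",
                               period_range[1], ", ", period_range[2], "]")
  if (length(cons) == 1L) return(consensus_unit(cons))
  # reference: the consensus of median length (robust against per-array
  # indel noise inflating or shrinking the pooled monomer)
  ref <- cons[which.min(abs(nchar(cons) - stats::median(nchar(cons))))]
  rotated <- vapply(cons, function(cc) {
    r <- best_rotation(cc, ref)
    rotate_seq(cc, r)
  }, character(1))
  projected <- vapply(rotated, function(cc) {
    if (nchar(cc) == nchar(ref)) cc else .project_onto(ref, cc)
  }, character(1))
  build_consensus(unname(projected), inclusion = inclusion, majority = majority)
}

#' Rotate a circular sequence
#'
#' @param x DNA string; @param r left-rotation offset in `[0, nchar(x) - 1]`.
#' @return `x` rotated so that position `r + 1` comes first.
#' @export
rotate_seq <- function(x, r) {
  n <- nchar(x)
  r <- r %% n
  if (r == 0L) return(x)
  paste0(substr(x, r + 1L, n), substr(x, 1L, r))
}

# best left-rotation of x maximising ungapped IUPAC identity to ref
best_rotation <- function(x, ref) {
  xb <- pattern_bits(x)
  rb <- pattern_bits(ref)
  n <- length(xb)
  m <- min(n, length(rb))
  scores <- vapply(0:(n - 1L), function(r) {
    xr <- xb[((seq_len(m) - 1L + r) %% n) + 1L]
    sum(bitwAnd(xr, rb[seq_len(m)]) > 0L)
  }, numeric(1))
  which.max(scores) - 1L
}

#' Circular percent identity between two monomer sequences
#'
#' Maximal [percent_identity()] over all rotations of `a` (and of its
#' reverse complement when `both_strands`), for comparing consensus monomers
#' whose phase is arbitrary.
#'
#' @param a,b IUPAC DNA strings.
#' @param both_strands also try the reverse complement of `a`.
#' @return list with `identity` (percent), `rotation`, `strand`.
#' @export
circular_identity <- function(a, b, both_strands = TRUE) {
  best <- list(identity = -1, rotation = 0L, strand = "+")
  for (strand in if (both_strands) c("+", "-") else "+") {
    aa <- if (strand == "+") a else revcomp_iupac(a)
    r <- best_rotation(aa, b)
    id <- percent_identity(rotate_seq(aa, r), b)
    if (id > best$identity) best <- list(identity = id, rotation = r,
                                         strand = strand)
  }
  best
}

#' Write tandem arrays as BED6 plus a sidecar TSV
#'
#' @param arrays a `tandem_arrays` data.frame.
#' @param bed_path BED6 output (name = `period<P>_unit`, score = rounded
#'   copy number).
#' @param tsv_path optional sidecar with period, copy number and identity.
#' @export
write_arrays <- function(arrays, bed_path, tsv_path = NULL) {
  bed <- data.frame(scaffold = arrays$scaffold, start = arrays$start,
                    end = arrays$end,
                    name = sprintf("period%d_unit", arrays$period),
                    score = round(arrays$copy_number),
                    strand = rep("+", nrow(arrays)))
  write_intervals(bed, bed_path)
  if (!is.null(tsv_path)) {
    utils::write.table(
      arrays[, c("scaffold", "start", "end", "period", "copy_number",
                 "mean_identity", "n_units")],
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(bed_path)
}
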
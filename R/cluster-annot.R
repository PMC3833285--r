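#' Decompose a repeat-cluster locus by tiling a consensus along it
#'
#' Greedy score-descending tiling: the best local alignment of the consensus
#' monomer against the not-yet-annotated region sequence is accepted,
#' masked, and the search repeated until the best match falls below the
#' identity or length thresholds; unmatched stretches become spacers.  Each
#' accepted match is classified as a full unit, a length variant
#' (`full_variant`, within `length_tolerance` bp of the consensus length), a
#' 5'-truncated copy (`truncated5p`: alignment starts at least `trunc5_min`
#' bases into the consensus and reaches its 3' end) or a short fragment
#' (`short_fragment`, at most `short_max` bp).  Local alignment trims
#' mismatching terminal bases, so matches are re-extended by up to 4 bp per
#' side when that restores the full consensus span; genuinely truncated
#' copies are not bridged.
#'
#' @param region_seq DNA string of the locus.
#' @param consensus a `consensus_unit` or plain IUPAC string.
#' @param min_identity minimal local-alignment identity (percent) for a
#'   match to be annotated.
#' @param min_match minimal matched length in bp.
#' @param length_tolerance full-length variants may differ from the
#'   consensus length by at most this many bp.
#' @param trunc5_min minimal number of missing 5' consensus bases for the
#'   `truncated5p` class.
#' @param short_max maximal length of a `short_fragment`.
#' @return an object of class `cluster_annotation`: list with
#'   `region_length`, `segments` (data.frame: `start`, `end` 0-based
#'   half-open, `class`, `identity`, `cons_start`, `cons_end` 1-based on the
#'   consensus, `flank6` = the 6-mer immediately downstream of each
#'   short_fragment) and `summary` (counts per class).
#' @export
tile_cluster <- function(region_seq, consensus, min_identity = 80,
                         min_match = 20L, length_tolerance = 3L,
                         trunc5_min = 8L, short_max = 35L) {
  if (is.character(consensus)) consensus <- consensus_unit(consensus)
  stopifnot(inherits(consensus, "consensus_unit"))
  if (!is.character(region_seq) || length(region_seq) != 1L || !nzchar(region_seq)) {
    stop("region_seq must be a non-empty string")
  }
  region_seq <- toupper(region_seq)
  n <- nchar(region_seq)
  L <- consensus$length
  cseq <- consensus$sequence
  ext_slack <- 4L

  stretches <- list(c(1L, n))          # 1-based inclusive unannotated spans
  cache <- list()                      # best alignment per stretch key
  segments <- list()

  best_for <- function(s, e) {
    key <- paste0(s, ":", e)
    if (!is.null(cache[[key]])) return(cache[[key]][[1]])
    if (e - s + 1L < min_match) {
      res <- NULL
    } else {
      aln <- align_pair(cseq, substr(region_seq, s, e), type = "local")
      tr <- .trim_terminal_runs(aln)
      res <- list(score = aln$score, identity = tr$identity,
                  rs = s + aln$subject_start - 1L + tr$sub_left,
                  re = s + aln$subject_end - 1L - tr$sub_right,
                  cs = aln$pattern_start + tr$pat_left,
                  ce = aln$pattern_end - tr$pat_right)
    }
    cache[[key]] <<- list(res)
    res
  }

  reject <- function(i, res) {
    # mask a below-threshold (or insignificant) match as spacer and keep
    # searching the remainder of its stretch
    st <- stretches[[i]]
    if (res$re - res$rs + 1L >= min_match && res$rs >= st[1] &&
        res$re <= st[2]) {
      new_str <- list()
      if (res$rs - st[1] >= 1L) new_str[[1L]] <- c(st[1], res$rs - 1L)
      if (st[2] - res$re >= 1L) new_str[[length(new_str) + 1L]] <-
        c(res$re + 1L, st[2])
      dead <- c(res$rs, res$re)
      attr(dead, "dead") <- TRUE
      stretches <<- c(stretches[-i], new_str, list(dead))
    } else {
      attr(stretches[[i]], "dead") <<- TRUE
    }
  }

  repeat {
    best <- NULL; best_i <- NA_integer_
    for (i in seq_along(stretches)) {
      st <- stretches[[i]]
      if (isTRUE(attr(st, "dead"))) next
      res <- best_for(st[1], st[2])
      if (is.null(res)) next
      if (is.null(best) || res$score > best$score ||
          (res$score == best$score && res$rs < best$rs)) {
        best <- res; best_i <- i
      }
    }
    if (is.null(best)) break
    if (best$identity < min_identity ||
        (best$re - best$rs + 1L) < min_match) {
      reject(best_i, best)
      next
    }
    # significance against chance sequence: a matching column is ~4x more
    # likely under copy than junk, a mismatching one ~25x less; a real
    # fragment clears +15 nats easily, a lucky 20-column junk match does not
    nc <- best$re - best$rs + 1L
    nm <- best$identity / 100 * nc
    if (nm * log(0.97 / 0.25) + (nc - nm) * log(0.03 / 0.75) < 15) {
      reject(best_i, best)
      next
    }

    st <- stretches[[best_i]]
    rs <- best$rs; re <- best$re; cs <- best$cs; ce <- best$ce
    strip_max <- trunc5_min + 3L

    # restore a near-complete 3' end (a mutated edge base the aligner
    # trimmed) so the 3' end can anchor the 5'-boundary derivation; when a
    # neighbouring segment leaves less room, restore what fits
    if (ce < L && L - ce <= ext_slack) {
      ext <- min(L - ce, st[2] - re)
      re <- re + ext; ce <- ce + ext
    }

    # 5' boundary, re-derived by an ungapped scan anchored at the (reliable)
    # 3' end of the match.  Local alignment can accrete chance-matched,
    # gap-optimised columns from the adjacent piece at a junction; anchored
    # ungapped columns cannot be faked (random sequence gives ~25%
    # identity), so the first offset whose leading window looks like signal
    # is the true copy start.  This is what separates a full copy with a
    # diverged 5' edge from a genuinely 5'-truncated copy.
    # Changepoint model over a fixed leading window: under "the copy starts
    # at consensus column s+1", columns 1..s are chance sequence (P(match)
    # = 0.25) and columns s+1.. are copy sequence (P(match) = 0.97).
    # Relative to s = 0, skipping a mismatching column gains log(.75/.03),
    # skipping a matching one loses log(.97/.25); the ML changepoint is the
    # argmax of the prefix sums.  This is what separates a full copy with a
    # diverged 5' edge (keep the columns) from a genuinely 5'-truncated
    # copy preceded by junk (skip them).
    r1_est <- re - ce + 1L     # region position of consensus column 1
    smax <- min(strip_max + 4L, ce - 16L, r1_est - st[1] + strip_max)
    found <- FALSE
    if (smax >= 0L && r1_est + smax >= st[1]) {
      w0 <- max(0L, st[1] - r1_est)          # skip columns left of the stretch
      W0 <- min(smax + 24L, ce, re - r1_est + 1L)
      if (W0 - w0 >= 16L) {
        m <- .ungapped_id(region_seq, cseq, r1_est + w0, 1L + w0,
                          W0 - w0, per_column = TRUE)
        gain <- cumsum(3.22 - 4.58 * m)      # gain of skipping cols w0+1..i
        cand_max <- min(smax - w0, length(gain) - 16L)
        if (cand_max >= 0L) {
          cand <- 0:cand_max
          # prior: moving the boundary at all costs 8 (so one or two
          # mutated edge bases are kept with the copy, while a run of junk
          # columns, gaining ~3.2 each, still pays for the move)
          adj <- c(0, gain)[cand + 1L] - 8 * (cand > 0L)
          # among near-tied changepoints, trust the one whose downstream
          # window is cleanest: chance-matched junk runs just before the
          # true start otherwise stall the argmax a few columns early
          short_list <- cand[adj >= max(adj) - 3.3]
          ids <- vapply(short_list, function(sc) {
            .ungapped_id(region_seq, cseq, r1_est + w0 + sc, 1L + w0 + sc, 16L)
          }, numeric(1))
          s <- w0 + short_list[which.max(ids)]
          # sanity: the window after the changepoint must look like copy
          if (.ungapped_id(region_seq, cseq, r1_est + s, 1L + s, 16L) >= 65) {
            rs <- r1_est + s; cs <- 1L + s
            found <- TRUE
          }
        }
      }
    }
    if (!found && cs > 1L) {
      # gappy body or heavily diverged edge: fall back to stripping leading
      # columns while their cumulative identity stays junk-like
      a <- .noisy_run(region_seq, cseq, rs, cs, +1L,
                      max(0L, min(40L, re - rs + 1L - min_match, ce - cs)),
                      max_id = 75)
      rs <- rs + a; cs <- cs + a
    }
    # 3' boundary of matches that do not reach the consensus 3' end (short
    # fragments): strip chance-matched trailing columns
    if (ce < L - 2L) {
      b <- .noisy_run(region_seq, cseq, re, ce, -1L,
                      max(0L, min(40L, re - rs + 1L - min_match, ce - cs)),
                      max_id = 75)
      re <- re - b; ce <- ce - b
    }
    ml <- re - rs + 1L
    cls <- if (ml == L && cs == 1L && ce == L) "full"
      else if (abs(ml - L) <= length_tolerance && cs <= 1L + ext_slack) "full_variant"
      else if (ml <= short_max) "short_fragment"
      else if (cs - 1L >= trunc5_min && ce >= L - 4L) "truncated5p"
      else "full_variant"
    flank6 <- if (cls == "short_fragment" && re + 6L <= n) {
      substr(region_seq, re + 1L, re + 6L)
    } else NA_character_
    segments[[length(segments) + 1L]] <- data.frame(
      start = rs - 1L, end = re, class = cls, identity = best$identity,
      cons_start = cs, cons_end = ce, flank6 = flank6
    )
    # split the stretch, invalidate its cache entry implicitly via new keys
    new_str <- list()
    if (rs - st[1] >= 1L) new_str[[length(new_str) + 1L]] <- c(st[1], rs - 1L)
    if (st[2] - re >= 1L) new_str[[length(new_str) + 1L]] <- c(re + 1L, st[2])
    stretches <- c(stretches[-best_i], new_str)
  }

  seg_df <- if (length(segments) > 0L) do.call(rbind, segments) else
    data.frame(start = integer(0), end = integer(0), class = character(0),
               identity = numeric(0), cons_start = integer(0),
               cons_end = integer(0), flank6 = character(0))
  # unannotated stretches become spacers
  for (st in stretches) {
    seg_df <- rbind(seg_df, data.frame(start = st[1] - 1L, end = st[2],
                                       class = "spacer", identity = NA_real_,
                                       cons_start = NA_integer_,
                                       cons_end = NA_integer_,
                                       flank6 = NA_character_))
  }
  seg_df <- seg_df[order(seg_df$start), , drop = FALSE]
  # merge runs of adjacent spacer pieces into single spacer segments
  if (nrow(seg_df) > 1L) {
    drop <- logical(nrow(seg_df))
    for (i in 2:nrow(seg_df)) {
      if (seg_df$class[i] == "spacer" && seg_df$class[i - 1L] == "spacer" &&
          seg_df$start[i] == seg_df$end[i - 1L]) {
        seg_df$start[i] <- seg_df$start[i - 1L]
        drop[i - 1L] <- TRUE
      }
    }
    seg_df <- seg_df[!drop, , drop = FALSE]
  }
  rownames(seg_df) <- NULL

  # tiling must partition the region
  stopifnot(nrow(seg_df) == 0L ||
            (seg_df$start[1] == 0L && seg_df$end[nrow(seg_df)] == n &&
             all(seg_df$start[-1] == seg_df$end[-nrow(seg_df)])))

  classes <- c("full", "full_variant", "truncated5p", "short_fragment", "spacer")
  counts <- vapply(classes, function(cl) sum(seg_df$class == cl), integer(1))
  structure(list(region_length = n, segments = seg_df,
                 summary = counts, consensus_length = L),
            class = "cluster_annotation")
}

# ungapped IUPAC identity of region[r0 .. r0+n-1] vs consensus
# [c0 .. c0+n-1]: percent, or the per-column 0/1 match vector
.ungapped_id <- function(region_seq, cseq, r0, c0, n, per_column = FALSE) {
  if (n < 1L) return(if (per_column) integer(0) else 100)
  rb <- .pattern_lookup[utf8ToInt(substr(region_seq, r0, r0 + n - 1L))]
  cb <- .pattern_lookup[utf8ToInt(substr(cseq, c0, c0 + n - 1L))]
  m <- as.integer(!is.na(rb) & !is.na(cb) &
                  bitwAnd(ifelse(is.na(rb), 0L, rb),
                          ifelse(is.na(cb), 0L, cb)) > 0L)
  # pad when the window runs past either sequence end
  if (length(m) < n) m <- c(m, integer(n - length(m)))
  if (per_column) m else 100 * sum(m) / n
}

# Longest terminal run (walking inward from region position r0 / consensus
# position c0 in direction dir) whose ungapped identity stays <= max_id %;
# returns the number of columns to strip (0 when the end is real signal).
.noisy_run <- function(region_seq, cseq, r0, c0, dir, amax, max_id = 60) {
  if (amax < 1L) return(0L)
  rr <- utf8ToInt(substr(region_seq, min(r0, r0 + dir * (amax - 1L)),
                         max(r0, r0 + dir * (amax - 1L))))
  cc <- utf8ToInt(substr(cseq, min(c0, c0 + dir * (amax - 1L)),
                         max(c0, c0 + dir * (amax - 1L))))
  if (dir < 0L) { rr <- rev(rr); cc <- rev(cc) }
  rb <- .pattern_lookup[rr]; cb <- .pattern_lookup[cc]
  hits <- cumsum(!is.na(rb) & !is.na(cb) & bitwAnd(ifelse(is.na(rb), 0L, rb),
                                                   ifelse(is.na(cb), 0L, cb)) > 0L)
  ok <- which(hits / seq_along(hits) <= max_id / 100)
  if (length(ok) == 0L) 0L else max(ok)
}

# Local alignments can accrete terminal runs that pay for themselves only
# marginally (e.g. a few chance matches bridging into a neighbouring repeat
# copy).  Drop terminal column runs whose cumulative score is <= 0 from
# either end; the core of the match is untouched.
.trim_terminal_runs <- function(aln) {
  pc <- strsplit(aln$pattern_aln, "")[[1]]
  sc <- strsplit(aln$subject_aln, "")[[1]]
  gap <- pc == "-" | sc == "-"
  colscore <- ifelse(gap, -2, ifelse(iupac_compatible(pc, sc), 1, -1))
  n <- length(colscore)
  cum_l <- cumsum(colscore)
  lefts <- which(cum_l <= 0)
  trim_l <- if (length(lefts)) max(lefts) else 0L
  cum_r <- cumsum(rev(colscore))
  rights <- which(cum_r <= 0)
  trim_r <- if (length(rights)) max(rights) else 0L
  if (trim_l + trim_r >= n) { trim_l <- 0L; trim_r <- 0L }
  keep <- seq.int(trim_l + 1L, n - trim_r)
  list(
    pat_left = sum(pc[seq_len(trim_l)] != "-"),
    pat_right = sum(pc[seq.int(n - trim_r + 1L, length.out = trim_r)] != "-"),
    sub_left = sum(sc[seq_len(trim_l)] != "-"),
    sub_right = sum(sc[seq.int(n - trim_r + 1L, length.out = trim_r)] != "-"),
    identity = 100 * sum(colscore[keep] == 1) / length(keep)
  )
}

#' @export
print.cluster_annotation <- function(x, ...) {
  cat(sprintf("<cluster_annotation> %d bp region, %d segment(s)\n",
              x$region_length, nrow(x$segments)))
  for (cl in names(x$summary)) {
    if (x$summary[[cl]] > 0L) cat(sprintf("  %-14s %d\n", cl, x$summary[[cl]]))
  }
  invisible(x)
}

#' Summarise a cluster annotation
#'
#' Per-class segment counts plus the length histogram of `full_variant`
#' segments (the odd-length near-full units of a cluster).
#'
#' @param annotation a `cluster_annotation` from [tile_cluster()].
#' @return list with `counts` (data.frame class/count) and
#'   `variant_lengths` (table of full_variant segment lengths).
#' @export
summarize_cluster <- function(annotation) {
  stopifnot(inherits(annotation, "cluster_annotation"))
  seg <- annotation$segments
  counts <- data.frame(class = names(annotation$summary),
                       count = as.integer(annotation$summary),
                       row.names = NULL)
  vl <- seg$end[seg$class == "full_variant"] - seg$start[seg$class == "full_variant"]
  list(counts = counts, variant_lengths = table(vl))
}
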
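#' Run the combined repeat-discovery pipeline
#'
#' Ties the stages into the end-to-end workflow: per-enzyme in silico
#' digestion and peak calling, cross-enzyme peak intersection, tandem-array
#' scanning and census, family consensus assembly for each census family,
#' and restriction-site mapping on each family consensus (predicted circular
#' monomer fragments vs observed digestion peaks).
#'
#' Families are defined by single-linkage clustering of detected array
#' periods (tolerance 2 bp) and ranked by total unit count; clusters with at
#' least `min_family_units` units are reported.
#'
#' @param gen a [genome] object, or a path to a FASTA file.
#' @param enzymes named list of [enzyme] objects (default: the shipped
#'   panel).
#' @param out_dir optional directory; when given, writes `dist_<enzyme>.tsv`,
#'   `peaks.tsv`, `candidates.tsv`, `arrays.bed`/`arrays.tsv`, `census.tsv`,
#'   `families.tsv`, `consensus_<period>.fa` and a human-readable
#'   `report.md`.
#' @param min_period,max_period,min_copies,min_identity,k tandem-scan
#'   parameters, see [scan_tandem_arrays()].
#' @param peak_min_count,peak_window,peak_min_prominence peak-calling
#'   parameters, see [detect_peaks()].
#' @param candidate_tolerance_bp tolerance for [cross_enzyme_candidates()].
#' @param min_family_units minimal total unit count for a reported family.
#' @return an object of class `midsat_report`: list with `peaks` (per
#'   enzyme), `candidates`, `arrays`, `census`, `families` (data.frame:
#'   `period`, `unit_count`, `cluster_count`, `consensus`), `site_maps`
#'   (per family), and the parameters used.
#' @export
run_pipeline <- function(gen, enzymes = load_enzyme_table(), out_dir = NULL,
                         min_period = 40L, max_period = 500L,
                         min_copies = 3, min_identity = 75, k = 12L,
                         peak_min_count = 100L, peak_window = 5L,
                         peak_min_prominence = 5,
                         candidate_tolerance_bp = 5,
                         min_family_units = 50L) {
  if (is.character(gen)) gen <- read_genome_fasta(gen)
  stopifnot(inherits(gen, "genome"))

  dists <- lapply(enzymes, function(e) digest_genome(gen, e))
  peaks <- lapply(dists, function(d) {
    detect_peaks(d, min_count = peak_min_count, window = peak_window,
                 min_prominence = peak_min_prominence)
  })
  candidates <- if (length(peaks) >= 2L) {
    cross_enzyme_candidates(peaks, tolerance_bp = candidate_tolerance_bp)
  } else {
    data.frame(length = numeric(0), n_enzymes = integer(0),
               enzymes = character(0))
  }

  arrays <- scan_tandem_arrays(gen, min_period = min_period,
                               max_period = max_period,
                               min_copies = min_copies,
                               min_identity = min_identity, k = k)
  cens <- census(arrays)

  families <- .family_clusters(arrays, min_family_units)
  site_maps <- list()
  if (nrow(families) > 0L) {
    cons_seqs <- character(nrow(families))
    for (i in seq_len(nrow(families))) {
      cu <- pool_consensus(arrays, c(families$period_lo[i],
                                     families$period_hi[i]))
      cons_seqs[i] <- cu$sequence
      site_maps[[as.character(families$period[i])]] <- map_sites(cu, enzymes)
    }
    families$consensus <- cons_seqs
  } else {
    families$consensus <- character(0)
  }

  report <- structure(
    list(peaks = peaks, candidates = candidates, arrays = arrays,
         census = cens, families = families, site_maps = site_maps,
         total_bp = gen$total_length,
         params = list(min_period = min_period, max_period = max_period,
                       min_copies = min_copies, min_identity = min_identity,
                       k = k, peak_min_count = peak_min_count,
                       peak_window = peak_window,
                       peak_min_prominence = peak_min_prominence,
                       candidate_tolerance_bp = candidate_tolerance_bp,
                       min_family_units = min_family_units)),
    class = "midsat_report"
  )
  if (!is.null(out_dir)) .write_report(report, dists, out_dir)
  report
}

# single-linkage clustering of array periods (tol 2 bp) ranked by units
.family_clusters <- function(arrays, min_family_units) {
  empty <- data.frame(period = integer(0), period_lo = integer(0),
                      period_hi = integer(0), unit_count = numeric(0),
                      cluster_count = integer(0))
  if (nrow(arrays) == 0L) return(empty)
  per <- sort(unique(arrays$period))
  grp <- cumsum(c(1, diff(per) > 2))
  out <- do.call(rbind, lapply(split(per, grp), function(ps) {
    sel <- arrays$period %in% ps
    units <- sum(round(arrays$copy_number[sel]))
    data.frame(period = stats::median(rep(arrays$period[sel],
                                          round(arrays$copy_number[sel]))),
               period_lo = min(ps), period_hi = max(ps),
               unit_count = units, cluster_count = sum(sel))
  }))
  out <- out[out$unit_count >= min_family_units, , drop = FALSE]
  out <- out[order(-out$unit_count), , drop = FALSE]
  rownames(out) <- NULL
  out$period <- as.integer(round(out$period))
  out
}

.write_report <- function(report, dists, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (e in names(dists)) {
    write_fragdist(dists[[e]], file.path(out_dir, paste0("dist_", e, ".tsv")))
  }
  peak_df <- do.call(rbind, lapply(names(report$peaks), function(e) {
    p <- report$peaks[[e]]
    if (nrow(p) == 0L) return(NULL)
    cbind(enzyme = e, as.data.frame(p))
  }))
  if (is.null(peak_df)) {
    peak_df <- data.frame(enzyme = character(0), length = integer(0),
                          count = integer(0), mass = integer(0),
                          prominence = numeric(0))
  }
  utils::write.table(peak_df, file.path(out_dir, "peaks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$candidates, file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_arrays(report$arrays, file.path(out_dir, "arrays.bed"),
               file.path(out_dir, "arrays.tsv"))
  utils::write.table(report$census, file.path(out_dir, "census.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fam <- report$families
  utils::write.table(fam, file.path(out_dir, "families.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(fam))) {
    writeLines(c(sprintf(">family_%dbp_consensus", fam$period[i]),
                 fam$consensus[i]),
               file.path(out_dir, sprintf("consensus_%d.fa", fam$period[i])))
  }

  md <- c("# Repeat-family discovery report", "",
          sprintf("Genome: %s bp; enzymes: %s", report$total_bp,
                  paste(names(report$peaks), collapse = ", ")), "",
          "## Candidate families", "")
  if (nrow(fam) == 0L) {
    md <- c(md, "No candidate repeat families detected.")
  }
  for (i in seq_len(nrow(fam))) {
    sm <- report$site_maps[[as.character(fam$period[i])]]
    smdf <- summary.site_map(sm)
    cut_rows <- smdf[!smdf$uncut, , drop = FALSE]
    md <- c(md,
            sprintf("### %d bp family", fam$period[i]),
            "",
            sprintf("- units: %d, clusters: %d", fam$unit_count[i],
                    fam$cluster_count[i]),
            sprintf("- consensus (%d bp): `%s`", nchar(fam$consensus[i]),
                    fam$consensus[i]),
            "- predicted circular monomer fragments vs observed peaks:",
            vapply(seq_len(nrow(cut_rows)), function(j) {
              pred <- as.integer(strsplit(cut_rows$fragments[j], ",")[[1]])
              obs <- report$peaks[[cut_rows$enzyme[j]]]$length
              hit <- pred[pred %in% unlist(lapply(obs, function(o) (o - 1):(o + 1)))]
              sprintf("    - %s: predicted %s bp; observed peak support: %s",
                      cut_rows$enzyme[j], paste(pred, collapse = " + "),
                      if (length(hit)) paste(hit, collapse = ", ") else "none")
            }, character(1)),
            "")
  }
  md <- c(md, "## Cross-enzyme same-size peak candidates", "")
  if (nrow(report$candidates) == 0L) {
    md <- c(md, "none")
  } else {
    md <- c(md, sprintf("- %.0f bp (%d enzymes: %s)",
                        report$candidates$length, report$candidates$n_enzymes,
                        report$candidates$enzymes))
  }
  md <- c(md, "", "## Parameters", "",
          sprintf("- %s: %s", names(report$params),
                  vapply(report$params, format, character(1))))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' @export
print.midsat_report <- function(x, ...) {
  cat(sprintf("<midsat_report> %s bp genome, %d enzyme(s)\n",
              format(x$total_bp, big.mark = ","), length(x$peaks)))
  cat(sprintf("  arrays: %d; census bins: %d; candidate families: %d\n",
              nrow(x$arrays), nrow(x$census), nrow(x$families)))
  for (i in seq_len(nrow(x$families))) {
    cat(sprintf("  family %d bp: %d units in %d clusters\n",
                x$families$period[i], x$families$unit_count[i],
                x$families$cluster_count[i]))
  }
  invisible(x)
}
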
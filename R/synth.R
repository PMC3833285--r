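#' The 172 bp satellite family consensus monomer
#'
#' IUPAC consensus of the 172 bp medium-sized tandem repeat family; the
#' ambiguity codes S, W and M mark its polymorphic columns, and the monomer
#' carries two CATG (FatI) sites.  Used by [make_multifamily_genome()] to
#' instantiate the high-divergence family and available as a reference
#' monomer.
#'
#' @format a single 172-character IUPAC string.
#' @export
SAT172_CONSENSUS <- paste0(
  "TACCATSAAATATCCTACATAGACATAGGTCGAAAATTCCCAACCCCATAACTCGGCCAAAACTCAACC",
  "GATTTTCATAAGGTWTAMMTTTTTGTTCATGGTTTGACCTCWATATCAATCTGGCATATAAATCTGACA",
  "ACTTTATTTTTGGTCAAAATTCATGTGAAAATGG"
)

#' Specify a synthetic genome with planted repeat structures
#'
#' @param seed integer RNG seed; identical specs generate byte-identical
#'   output.
#' @param background_length background (non-planted) sequence length, bp.
#' @param gc_content background GC fraction.
#' @param arrays list of array specs, each a list with fields `unit` (DNA
#'   string, IUPAC codes allowed -- degenerate positions are resolved
#'   independently per copy) or `period` (random unit of that length),
#'   `copies` (>= 1, fractional part becomes a partial 3' copy),
#'   `substitution` and `indel` per-base rates (each <= 0.25), optional
#'   `name`.
#' @param remnants list of truncated-copy specs (transposon-remnant style),
#'   each a list with `unit`, `keep_frac` (5' fraction kept), `copies`
#'   (number of independent insertions), `substitution`.
#' @param scaffold scaffold id for the output genome.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(seed, background_length, gc_content = 0.5,
                       arrays = list(), remnants = list(),
                       scaffold = "synth_1") {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            background_length >= 1, gc_content > 0, gc_content < 1)
  arrays <- lapply(arrays, function(a) {
    a$substitution <- a$substitution %||% 0
    a$indel <- a$indel %||% 0
    if (a$substitution < 0 || a$substitution > 0.25 ||
        a$indel < 0 || a$indel > 0.25) {
      stop("mutation rates must lie in [0, 0.25]")
    }
    if (is.null(a$unit) && is.null(a$period)) stop("array needs unit or period")
    if (!is.null(a$period) && (a$period < 1 || a$period > background_length)) {
      stop("array period out of range")
    }
    if (is.null(a$copies) || a$copies < 1) stop("array copies must be >= 1")
    a
  })
  remnants <- lapply(remnants, function(r) {
    r$substitution <- r$substitution %||% 0
    if (is.null(r$unit)) stop("remnant needs a source unit")
    if (is.null(r$keep_frac) || r$keep_frac <= 0 || r$keep_frac > 1) {
      stop("remnant keep_frac must be in (0, 1]")
    }
    r$copies <- r$copies %||% 1
    r
  })
  structure(list(seed = as.integer(seed),
                 background_length = as.integer(background_length),
                 gc_content = gc_content, arrays = arrays,
                 remnants = remnants, scaffold = scaffold),
            class = "synth_spec")
}

# run expr with a private RNG stream seeded by `seed`
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# resolve IUPAC codes (uniform over the expansion set), then mutate:
# substitutions uniform over the three alternative bases, then single-base
# indels (equal insert/delete probability) at the indel rate
.instantiate_copy <- function(unit_chars, substitution, indel) {
  x <- unit_chars
  amb <- which(!(x %in% BASES))
  for (i in amb) {
    set <- BASES[bitwAnd(IUPAC_BITS[[x[i]]], c(1L, 2L, 4L, 8L)) > 0L]
    x[i] <- set[sample.int(length(set), 1L)]
  }
  n <- length(x)
  if (substitution > 0) {
    m <- which(stats::runif(n) < substitution)
    for (i in m) x[i] <- sample(setdiff(BASES, x[i]), 1L)
  }
  if (indel > 0) {
    ev <- which(stats::runif(n) < indel)
    if (length(ev) > 0L) {
      dele <- stats::runif(length(ev)) < 0.5
      keep <- rep(TRUE, n)
      keep[ev[dele]] <- FALSE
      ins <- character(n)
      for (i in ev[!dele]) ins[i] <- sample(BASES, 1L)
      x <- unlist(lapply(seq_len(n), function(i) {
        c(if (nzchar(ins[i])) ins[i], if (keep[i]) x[i])
      }))
    }
  }
  x
}

.build_array_seq <- function(unit, copies, substitution, indel) {
  uc <- strsplit(unit, "")[[1]]
  full <- floor(copies)
  frac <- copies - full
  parts <- character(full + (frac > 0))
  for (i in seq_len(full)) {
    parts[i] <- paste(.instantiate_copy(uc, substitution, indel), collapse = "")
  }
  if (frac > 0) {
    partial <- uc[seq_len(max(1L, round(frac * length(uc))))]
    parts[full + 1L] <- paste(.instantiate_copy(partial, substitution, indel),
                              collapse = "")
  }
  paste(parts, collapse = "")
}

#' Generate a synthetic genome with planted ground truth
#'
#' Background sequence is drawn i.i.d. at the requested GC content; each
#' array is built as head-to-tail copies of its unit (each copy
#' independently resolving IUPAC positions and mutating at the stated
#' rates) and inserted at a random position; remnants are inserted as
#' mutated 5' prefixes of their source unit.  Insertion (rather than
#' overwriting) keeps the bookkeeping exact: output length =
#' background_length + sum of planted feature lengths.  Every planted
#' feature is recorded in a truth table with its class and parameters.
#'
#' @param spec a [synth_spec()].
#' @return list with `genome` (a [genome]) and `truth` (data.frame:
#'   `scaffold`, `start`, `end` 0-based half-open, `name`, `class`
#'   (`array`/`remnant`), `period`, `copies`, `substitution`, `indel`).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  .with_seed(spec$seed, {
    background <- random_dna(spec$background_length, spec$gc_content)
    feats <- list()
    for (i in seq_along(spec$arrays)) {
      a <- spec$arrays[[i]]
      unit <- a$unit %||% random_dna(a$period, spec$gc_content)
      seq <- .build_array_seq(unit, a$copies, a$substitution, a$indel)
      feats[[length(feats) + 1L]] <- list(
        seq = seq, class = "array",
        name = a$name %||% sprintf("array_%d", i),
        period = nchar(unit), copies = a$copies,
        substitution = a$substitution, indel = a$indel)
    }
    for (i in seq_along(spec$remnants)) {
      r <- spec$remnants[[i]]
      kept <- substr(r$unit, 1L, max(1L, round(r$keep_frac * nchar(r$unit))))
      kc <- strsplit(kept, "")[[1]]
      for (j in seq_len(r$copies)) {
        feats[[length(feats) + 1L]] <- list(
          seq = paste(.instantiate_copy(kc, r$substitution, 0), collapse = ""),
          class = "remnant", name = sprintf("remnant_%d_%d", i, j),
          period = nchar(kept), copies = 1,
          substitution = r$substitution, indel = 0)
      }
    }
    nf <- length(feats)
    if (nf > spec$background_length + 1L) {
      stop("cannot place ", nf, " features without overlap; ",
           "increase background_length")
    }
    points <- if (nf > 0L) sort(sample.int(spec$background_length + 1L, nf) - 1L)
              else integer(0)
    feats <- if (nf > 0L) feats[sample.int(nf)] else feats

    pieces <- character(2L * nf + 1L)
    truth <- vector("list", nf)
    prev <- 0L
    offset <- 0L
    for (i in seq_len(nf)) {
      pieces[2L * i - 1L] <- substr(background, prev + 1L, points[i])
      pieces[2L * i] <- feats[[i]]$seq
      flen <- nchar(feats[[i]]$seq)
      truth[[i]] <- data.frame(
        scaffold = spec$scaffold, start = points[i] + offset,
        end = points[i] + offset + flen, name = feats[[i]]$name,
        class = feats[[i]]$class, period = feats[[i]]$period,
        copies = feats[[i]]$copies, substitution = feats[[i]]$substitution,
        indel = feats[[i]]$indel)
      offset <- offset + flen
      prev <- points[i]
    }
    pieces[2L * nf + 1L] <- substr(background, prev + 1L,
                                   spec$background_length)
    seqs <- stats::setNames(paste(pieces, collapse = ""), spec$scaffold)
    truth_df <- if (nf > 0L) do.call(rbind, truth) else
      data.frame(scaffold = character(0), start = integer(0), end = integer(0),
                 name = character(0), class = character(0), period = integer(0),
                 copies = numeric(0), substitution = numeric(0),
                 indel = numeric(0))
    truth_df <- truth_df[order(truth_df$start), , drop = FALSE]
    rownames(truth_df) <- NULL
    list(genome = genome(seqs, quiet = TRUE), truth = truth_df)
  })
}

#' Write a planted-truth table as BED6 (plus sidecar columns)
#'
#' @param truth the truth data.frame from [synth_generate()].
#' @param path BED6 output path (name = feature name, score = rounded copy
#'   number).
#' @export
write_truth_bed <- function(truth, path) {
  write_intervals(data.frame(scaffold = truth$scaffold, start = truth$start,
                             end = truth$end, name = truth$name,
                             score = round(truth$copies),
                             strand = rep("+", nrow(truth))),
                  path)
}

# A random unit with a prescribed restriction-site layout: `plant` is a
# named list site -> 0-based positions; `avoid` sites may not occur at all.
# Edits the sequence until the layout is exact.
.unit_with_sites <- function(length, plant, avoid, gc = 0.45,
                             max_iter = 200L) {
  for (attempt in seq_len(max_iter)) {
    u <- random_dna(length, gc)
    # stamp the wanted sites
    for (site in names(plant)) {
      for (p0 in plant[[site]]) {
        substr(u, p0 + 1L, p0 + nchar(site)) <- site
      }
    }
    # knock out unwanted occurrences (wanted positions excluded)
    ok <- TRUE
    for (rep_i in 1:50) {
      bad <- list()
      for (site in unique(c(names(plant), avoid))) {
        hits <- gregexpr(paste0("(?=", site, ")"), u, perl = TRUE)[[1]]
        hits <- if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
        extra <- setdiff(hits, plant[[site]] %||% integer(0))
        if (length(extra) > 0L) bad[[site]] <- extra
      }
      if (length(bad) == 0L) break
      for (site in names(bad)) {
        for (p0 in bad[[site]]) {
          j <- p0 + sample.int(nchar(site), 1L)
          cur <- substr(u, j, j)
          substr(u, j, j) <- sample(setdiff(BASES, cur), 1L)
        }
      }
      if (rep_i == 50L) ok <- FALSE
    }
    if (!ok) next
    # verify the layout survived the knockouts -- on the circular unit, so
    # that head-to-tail copy junctions cannot carry stray sites
    good <- TRUE
    for (site in unique(c(names(plant), avoid))) {
      ext <- paste0(u, substr(u, 1L, nchar(site) - 1L))
      hits <- gregexpr(paste0("(?=", site, ")"), ext, perl = TRUE)[[1]]
      hits <- if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
      if (!setequal(hits, plant[[site]] %||% integer(0))) good <- FALSE
    }
    if (good) return(u)
  }
  stop("failed to construct unit with requested site layout")
}

#' Build the bundled multi-family test genome
#'
#' A ~2 Mb, three-scaffold synthetic genome emulating the repeat landscape
#' that motivates the pipeline: (i) arrays of a 225 bp unit carrying one
#' CCGG (HpaII/MspI), one GTAC (RsaI) and two CATG (FatI) sites, at 1%
#' per-copy substitution; (ii) arrays of a 154 bp unit carrying two GATC
#' (Kzo9I) sites that split the circular monomer 36 + 118 and one AGCT
#' (AluI) site, at 1% substitution; (iii) arrays instantiated from the
#' degenerate 172 bp satellite consensus (`SAT172_CONSENSUS`, IUPAC
#' positions resolved independently per copy) at 9% substitution and 1%
#' indel -- a high-divergence family whose digestion peak dissolves while
#' its tandem census peak persists; plus interspersed 5'-truncated remnants
#' of the 154 bp unit.
#'
#' @param seed integer seed; the whole fixture is a deterministic function
#'   of it.
#' @return list with `genome`, `truth` (as in [synth_generate()]), and
#'   `units` (the three planted unit sequences).
#' @export
make_multifamily_genome <- function(seed = 1L) {
  .with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, 4L)
    unit225 <- .unit_with_sites(
      225L,
      plant = list(CCGG = 40L, GTAC = 120L, CATG = c(10L, 180L)),
      avoid = c("AGCT", "GATC", "GGACC", "GGTCC", "GGCCC", "GGGCC",
                "GGCC")  # GGCC blocks GGNCC-with-flank ambiguity cheaply
    )
    # two GATC sites 36 bp apart on the circle (at 10 and 46 -> 36 + 118)
    unit154 <- .unit_with_sites(
      154L,
      plant = list(GATC = c(10L, 46L), AGCT = 100L),
      avoid = c("CCGG", "GTAC", "CATG")
    )
    unit172 <- SAT172_CONSENSUS

    scafs <- list()
    truths <- list()
    plans <- list(
      list(n_arr = 4, unit = unit225, copies = c(18, 35), sub = 0.01, ind = 0,
           name = "fam225"),
      list(n_arr = 5, unit = unit154, copies = c(18, 40), sub = 0.01, ind = 0,
           name = "fam154"),
      list(n_arr = 4, unit = unit172, copies = c(20, 40), sub = 0.09,
           ind = 0.01, name = "fam172")
    )
    for (sc in 1:3) {
      arrays <- list()
      for (pl in plans) {
        for (i in seq_len(pl$n_arr)) {
          arrays[[length(arrays) + 1L]] <- list(
            unit = pl$unit,
            copies = sample(seq(pl$copies[1], pl$copies[2]), 1L),
            substitution = pl$sub, indel = pl$ind,
            name = sprintf("%s_s%d_%d", pl$name, sc, i))
        }
      }
      remnants <- list(list(unit = unit154, keep_frac = 0.6, copies = 8L,
                            substitution = 0.05))
      spec <- synth_spec(seed = sub_seeds[sc], background_length = 540000L,
                         gc_content = 0.4, arrays = arrays,
                         remnants = remnants,
                         scaffold = sprintf("scaffold_%d", sc))
      g <- synth_generate(spec)
      scafs[[sc]] <- g$genome$scaffolds
      truths[[sc]] <- g$truth
    }
    list(genome = genome(unlist(scafs), quiet = TRUE),
         truth = do.call(rbind, truths),
         units = list(unit225 = unit225, unit154 = unit154,
                      unit172 = unit172))
  })
}
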
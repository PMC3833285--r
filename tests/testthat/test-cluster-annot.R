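# deterministic 172 bp unit for cluster compositions
cluster_unit <- function() {
  set.seed(555)
  rand_seq(172)
}

test_that("a planted cluster composition is decomposed into its classes", {
  unit <- cluster_unit()
  region <- paste0(strrep(unit, 3),                 # 3 full units
                   substr(unit, 12, 172),           # one copy missing 11 5' bp
                   substr(unit, 1, 29))             # one 29 bp fragment
  ann <- tile_cluster(region, unit)
  expect_identical(unname(ann$summary["full"]), 3L)
  expect_identical(unname(ann$summary["truncated5p"]), 1L)
  expect_identical(unname(ann$summary["short_fragment"]), 1L)
  expect_identical(unname(ann$summary["spacer"]), 0L)
  s <- summarize_cluster(ann)
  expect_identical(s$counts$count[s$counts$class == "full"], 3L)
})

test_that("an unrelated region is a single spacer and an exact unit is full at 100%", {
  unit <- cluster_unit()
  set.seed(556)
  noise <- rand_seq(800)
  ann <- tile_cluster(noise, unit)
  expect_identical(nrow(ann$segments), 1L)
  expect_identical(ann$segments$class, "spacer")

  ann2 <- tile_cluster(unit, unit)
  expect_identical(ann2$segments$class, "full")
  expect_equal(ann2$segments$identity, 100)
})

test_that("segments tile the region exactly (partition invariant)", {
  unit <- cluster_unit()
  set.seed(557)
  region <- paste0(rand_seq(300), strrep(unit, 2), rand_seq(150),
                   substr(unit, 12, 172), rand_seq(90), substr(unit, 1, 28),
                   rand_seq(200))
  ann <- tile_cluster(region, unit)
  seg <- ann$segments
  expect_identical(seg$start[1], 0L)
  expect_identical(seg$end[nrow(seg)], nchar(region))
  expect_identical(seg$start[-1], seg$end[-nrow(seg)])
  expect_identical(unname(ann$summary["full"]), 2L)
  expect_identical(unname(ann$summary["truncated5p"]), 1L)
  expect_identical(unname(ann$summary["short_fragment"]), 1L)
  # the downstream flank 6-mer of short fragments is reported
  sf <- seg[seg$class == "short_fragment", ]
  expect_identical(nchar(sf$flank6), 6L)
})

test_that("near-full-length variants are classified and histogrammed", {
  unit <- cluster_unit()
  v170 <- paste0(substr(unit, 1, 100), substr(unit, 103, 172))  # internal 2 bp deletion
  v175 <- paste0(substr(unit, 1, 100), "TAG", substr(unit, 101, 172))
  region <- paste0(unit, v170, unit, v175)
  ann <- tile_cluster(region, unit)
  expect_identical(unname(ann$summary["full"]), 2L)
  expect_identical(unname(ann$summary["full_variant"]), 2L)
  h <- summarize_cluster(ann)$variant_lengths
  expect_identical(as.integer(names(h)), c(170L, 175L))
  expect_identical(unname(as.integer(h)), c(1L, 1L))
})

test_that("lowering min_identity never decreases the number of annotated segments", {
  unit <- cluster_unit()
  set.seed(558)
  mutate <- function(s, rate) {
    v <- strsplit(s, "")[[1]]
    m <- which(runif(length(v)) < rate)
    for (i in m) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    paste(v, collapse = "")
  }
  region <- paste0(rand_seq(200), mutate(unit, 0.05), rand_seq(100),
                   mutate(unit, 0.15), rand_seq(100), mutate(unit, 0.3),
                   rand_seq(200))
  n_prev <- -1L
  for (mi in c(95, 85, 75, 65)) {
    ann <- tile_cluster(region, unit, min_identity = mi)
    n_nonspacer <- sum(ann$segments$class != "spacer")
    if (n_prev >= 0L) expect_gte(n_nonspacer, n_prev)
    n_prev <- n_nonspacer
  }
})
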
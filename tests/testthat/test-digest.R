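panel <- load_enzyme_table()

test_that("find_sites places cuts at site start plus cut offset", {
  expect_identical(find_sites("ACCGGT", panel$HpaII)$cuts, 2L)
  expect_identical(find_sites("AAGATCAAGATCAA", panel$Kzo9I)$cuts, c(2L, 8L))
  # degenerate site GGNCC matches GGACC and GGTCC (confirmed by the
  # independent window-scan oracle)
  s <- "GGACCGGTCC"
  expect_identical(find_sites(s, panel$AspS9I)$cuts, c(1L, 6L))
  expect_identical(find_sites(s, panel$AspS9I)$cuts,
                   oracle_cuts(s, panel$AspS9I))
  # overlapping occurrences each cut once; coincident cuts collapse
  expect_identical(find_sites("GATCGATC", panel$Kzo9I)$cuts, c(0L, 4L))
  # N blocks recognition
  expect_identical(find_sites("ACNGGT", panel$HpaII)$cuts, integer(0))
})

test_that("find_sites agrees with the independent regex oracle on random sequences", {
  set.seed(42)
  for (rep_i in 1:25) {
    s <- rand_seq(5000)
    # sprinkle some Ns to exercise the unmatchable-N policy
    if (rep_i %% 5 == 0) {
      pos <- sample(nchar(s), 50)
      for (p in pos) substr(s, p, p) <- "N"
    }
    for (e in panel) {
      expect_identical(find_sites(s, e)$cuts, oracle_cuts(s, e),
                       info = paste(e$name, rep_i))
    }
  }
})

test_that("fragment_lengths implements the linear-molecule model", {
  expect_identical(fragment_lengths(c(2L, 8L), 14L), c(2L, 6L, 6L))
  expect_identical(fragment_lengths(integer(0), 100L), 100L)
  # boundary cuts yield no zero-length terminal fragments
  expect_identical(fragment_lengths(c(0L, 50L), 50L), 50L)
  expect_error(fragment_lengths(c(5L, 3L), 10L), "sorted")
})

test_that("digesting an exact tandem array yields monomer-length interior fragments", {
  # 154 bp unit with exactly one GATC, safe across copy junctions
  unit <- paste0(strrep("AC", 30), "GATC", strrep("GT", 45))
  expect_identical(nchar(unit), 154L)
  g <- genome(c(s1 = strrep(unit, 10)))
  d <- digest_genome(g, panel$Kzo9I)
  expect_identical(d$counts$count[d$counts$length == 154], 9L)
  terminals <- d$counts$length[d$counts$length != 154]
  expect_identical(sum(terminals), 154L)
  # independent oracle: strsplit on the recognition text
  n_sites <- length(gregexpr("GATC", g$scaffolds[[1]], fixed = TRUE)[[1]])
  expect_identical(d$n_fragments, n_sites + 1L)
})

test_that("fragment mass and count are conserved in every digestion", {
  set.seed(99)
  for (rep_i in 1:5) {
    g <- genome(c(a = rand_seq(4000), b = rand_seq(2500)))
    for (e in panel[c("HpaII", "Kzo9I", "AspS9I")]) {
      d <- digest_genome(g, e)
      expect_identical(sum(d$counts$mass), g$total_length)
      n_cuts <- sum(vapply(g$scaffolds,
                           function(s) length(find_sites(s, e)$cuts),
                           integer(1)))
      # terminal fragments included; boundary cuts are absent in random
      # ACGT sequence so counts = cuts + one per scaffold
      expect_identical(sum(d$counts$count), n_cuts + 2L)
    }
  }
  # a site-free enzyme leaves one fragment per scaffold
  g2 <- genome(c(x = strrep("A", 500), y = strrep("AC", 300)))
  d2 <- digest_genome(g2, panel$HpaII)
  expect_identical(d2$counts$length, c(500L, 600L))
  expect_identical(d2$counts$count, c(1L, 1L))
})
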
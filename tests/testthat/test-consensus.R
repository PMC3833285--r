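panel <- load_enzyme_table()

test_that("column-wise IUPAC consensus follows the inclusion/majority thresholds", {
  expect_identical(build_consensus(c("ACGT", "ACGT"))$sequence, "ACGT")
  # 50/50 polymorphic columns get the two-base codes
  expect_identical(build_consensus(c("AAGA", "TACC"))$sequence, "WASM")
  # a 90% majority base wins outright
  units <- c(rep("A", 9), "G")
  expect_identical(build_consensus(units)$sequence, "A")
  # 75% is not "above" the majority threshold: code kept
  expect_identical(build_consensus(c("A", "A", "A", "G"))$sequence, "R")
  # gap-dominated columns are dropped
  expect_identical(build_consensus(c("A-CG", "A-CG", "ATCG"))$sequence, "ACG")
  expect_error(build_consensus("ACGT"), ">= 2")
})

test_that("site maps on the circular monomer predict fragments summing to the length", {
  # one HpaII site in a 225 bp monomer -> monomer-length fragments
  u225 <- paste0(strrep("AT", 50), "CCGG", strrep("AG", 60), "T")
  expect_identical(nchar(u225), 225L)
  sm <- map_sites(u225, panel["HpaII"])
  expect_identical(sm$enzymes$HpaII$fragments, 225L)

  # two GATC sites 36 bp apart on the circle -> 36 + 118
  u154 <- paste0(strrep("A", 10), "GATC", strrep("C", 32), "GATC",
                 strrep("T", 104))
  sm2 <- map_sites(u154, panel["Kzo9I"])
  expect_identical(sm2$enzymes$Kzo9I$sites, c(10L, 46L))
  expect_identical(sm2$enzymes$Kzo9I$fragments, c(36L, 118L))
  expect_identical(sum(sm2$enzymes$Kzo9I$fragments), 154L)

  # no sites -> flagged uncut with no fragments
  sm3 <- map_sites(strrep("A", 100), panel["HpaII"])
  expect_true(sm3$enzymes$HpaII$uncut)
  expect_length(sm3$enzymes$HpaII$fragments, 0)

  # a site spanning the origin of the circularised monomer is found
  u <- paste0("ATC", strrep("A", 96), "G")  # GATC across the junction
  sm4 <- map_sites(u, panel["Kzo9I"])
  expect_identical(sm4$enzymes$Kzo9I$sites, 99L)
  expect_identical(sm4$enzymes$Kzo9I$fragments, 100L)

  # degenerate consensus letters match by intersection (S vs CCGG's C)
  u5 <- paste0("CSGG", strrep("T", 96))
  expect_false(map_sites(u5, panel["HpaII"])$enzymes$HpaII$uncut)
})

test_that("circular fragment conservation holds for every panel enzyme on random monomers", {
  set.seed(31)
  for (rep_i in 1:10) {
    u <- rand_seq(sample(80:400, 1))
    sm <- map_sites(u, panel)
    for (e in names(sm$enzymes)) {
      m <- sm$enzymes[[e]]
      if (!m$uncut) {
        expect_identical(sum(m$fragments), nchar(u),
                         info = paste(e, rep_i))
      }
    }
  }
})

test_that("map_sites predictions equal interior fragments of a digested exact array", {
  set.seed(57)
  for (rep_i in 1:5) {
    u <- rand_seq(180)
    g <- genome(c(s = exact_array_scaffold(u, 50, flank = 500)), quiet = TRUE)
    sm <- map_sites(u, panel)
    for (e in c("HpaII", "Kzo9I", "AluI")) {
      pred <- sm$enzymes[[e]]$fragments
      if (length(pred) == 0) next
      d <- digest_genome(g, panel[[e]])
      n_per_unit <- length(sm$enzymes[[e]]$cuts)
      interior <- d$counts[d$counts$count >= 45, ]  # array-borne lengths
      expect_setequal(interior$length, unique(pred))
      # each circular fragment appears once per interior unit (edge effects
      # of +/- 1 at the array ends)
      for (L in unique(pred)) {
        expected_n <- 50 * sum(pred == L)
        obs <- interior$count[interior$length == L]
        expect_lte(abs(obs - expected_n), n_per_unit + 1)
      }
    }
  }
})

test_that("a mutated site in one unit fuses the two flanking fragments", {
  u154 <- paste0(strrep("A", 10), "GATC", strrep("C", 32), "GATC",
                 strrep("T", 104))
  arr <- strrep(u154, 30)
  # knock out the second GATC of copy 16 (0-based unit offset 46)
  pos <- 15 * 154 + 46 + 1
  substr(arr, pos, pos + 3) <- "GTTC"
  g <- genome(c(s = arr), quiet = TRUE)
  d <- digest_genome(g, panel$Kzo9I)
  # the 118 + 36 neighbours fuse into a 154 fragment
  expect_identical(d$counts$count[d$counts$length == 154L], 1L)
  expect_identical(sum(d$counts$mass), g$total_length)
})

test_that("percent identity is computed over global alignment columns", {
  ident <- paste0(strrep("ACGT", 56), "A")
  expect_equal(percent_identity(ident, ident), 100)
  # one substitution in a 225-mer pair: 224/225
  a <- strrep("ACGTG", 45)
  b <- a; substr(b, 100, 100) <- "A"
  expect_equal(percent_identity(a, b), 100 * 224 / 225, tolerance = 1e-10)
  # brute-force enumeration confirms the best alignment of AGCT vs AGAT
  oracle <- enum_align_best("AGCT", "AGAT")
  expect_equal(percent_identity("AGCT", "AGAT"), oracle$identity)
  expect_equal(oracle$identity, 75)
  # IUPAC-compatible pairs count as matches
  expect_equal(percent_identity("AWGT", "ATGT"), 100)
  expect_error(percent_identity("", "ACGT"), "non-empty")
})
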
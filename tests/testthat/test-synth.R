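test_that("identical specs generate byte-identical output", {
  spec <- synth_spec(seed = 1, background_length = 5000, arrays = list(
    list(period = 154, copies = 10, substitution = 0.02, indel = 0.01)))
  g1 <- synth_generate(spec)
  g2 <- synth_generate(spec)
  expect_identical(g1$genome$scaffolds, g2$genome$scaffolds)
  expect_identical(g1$truth, g2$truth)
  tf1 <- withr::local_tempfile(fileext = ".fa")
  tf2 <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g1$genome, tf1)
  write_genome_fasta(g2$genome, tf2)
  expect_identical(readLines(tf1), readLines(tf2))
  # a different seed changes the output
  g3 <- synth_generate(synth_spec(seed = 2, background_length = 5000,
                                  arrays = spec$arrays))
  expect_false(identical(g1$genome$scaffolds, g3$genome$scaffolds))
})

test_that("planted-feature bookkeeping is exact", {
  spec <- synth_spec(seed = 9, background_length = 3000, arrays = list(
    list(period = 154, copies = 10)))
  g <- synth_generate(spec)
  expect_identical(g$truth$end - g$truth$start, 1540L)
  expect_identical(g$genome$total_length, 3000L + 1540L)
  # the planted interval re-extracts as exact head-to-tail copies
  arrseq <- substr(g$genome$scaffolds[[1]], g$truth$start + 1L, g$truth$end)
  unit <- substr(arrseq, 1, 154)
  expect_identical(arrseq, strrep(unit, 10))

  # multiple features: genome length = background + sum of feature lengths
  spec2 <- synth_spec(seed = 10, background_length = 8000,
                      arrays = list(list(period = 60, copies = 5),
                                    list(period = 100, copies = 4.5)),
                      remnants = list(list(unit = strrep("ACGGT", 31),
                                           keep_frac = 0.4, copies = 3)))
  g2 <- synth_generate(spec2)
  expect_identical(g2$genome$total_length,
                   8000L + sum(g2$truth$end - g2$truth$start))
  expect_identical(sum(g2$truth$class == "remnant"), 3L)
  # remnants are 5' prefixes of their source unit
  rem <- g2$truth[g2$truth$class == "remnant", ][1, ]
  expect_identical(substr(g2$genome$scaffolds[[1]], rem$start + 1L, rem$end),
                   substr(strrep("ACGGT", 31), 1, 62))
})

test_that("background composition matches the requested GC content", {
  g <- synth_generate(synth_spec(seed = 3, background_length = 100000,
                                 gc_content = 0.5))
  s <- strsplit(g$genome$scaffolds[[1]], "")[[1]]
  gc <- mean(s %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.01)  # ~6 sd of Binomial(1e5, .5)
  g2 <- synth_generate(synth_spec(seed = 3, background_length = 100000,
                                  gc_content = 0.35))
  s2 <- strsplit(g2$genome$scaffolds[[1]], "")[[1]]
  expect_lt(abs(mean(s2 %in% c("G", "C")) - 0.35), 0.01)
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(synth_spec(1, 1000, arrays = list(
    list(period = 100, copies = 10, substitution = 0.5))), "rates")
  expect_error(synth_spec(1, 1000, arrays = list(
    list(period = 2000, copies = 3))), "period")
  expect_error(synth_spec(1, 1000, arrays = list(
    list(period = 100, copies = 0.5))), "copies")
  expect_error(synth_spec(1, 1000, remnants = list(
    list(unit = "ACGT", keep_frac = 1.5))), "keep_frac")
})

test_that("IUPAC positions in a planted unit are resolved per copy", {
  unit <- paste0(strrep("A", 50), "S", strrep("T", 49))
  g <- synth_generate(synth_spec(seed = 8, background_length = 500,
                                 arrays = list(list(unit = unit,
                                                    copies = 40))))
  arrseq <- substr(g$genome$scaffolds[[1]], g$truth$start + 1L, g$truth$end)
  at51 <- vapply(0:39, function(i) substr(arrseq, i * 100 + 51, i * 100 + 51),
                 character(1))
  expect_true(all(at51 %in% c("C", "G")))
  expect_true(all(c("C", "G") %in% at51))  # both alleles appear across copies
})

test_that("the bundled multi-family fixture has the advertised structure", {
  fx <- make_multifamily_genome(1)
  expect_identical(length(fx$genome$scaffolds), 3L)
  expect_gt(fx$genome$total_length, 1.5e6)
  expect_identical(nchar(fx$units$unit225), 225L)
  expect_identical(nchar(fx$units$unit154), 154L)
  expect_identical(fx$units$unit172, SAT172_CONSENSUS)
  # unit site layouts: one CCGG + one GTAC + two CATG in the 225 bp unit;
  # two GATC (36/118 circular split) + one AGCT in the 154 bp unit
  panel <- load_enzyme_table()
  sm225 <- map_sites(fx$units$unit225, panel[c("HpaII", "RsaI", "FatI")])
  expect_identical(sm225$enzymes$HpaII$fragments, 225L)
  expect_identical(sm225$enzymes$RsaI$fragments, 225L)
  expect_length(sm225$enzymes$FatI$sites, 2L)
  sm154 <- map_sites(fx$units$unit154, panel[c("Kzo9I", "AluI")])
  expect_identical(sm154$enzymes$Kzo9I$fragments, c(36L, 118L))
  expect_identical(sm154$enzymes$AluI$fragments, 154L)
  # determinism
  fx2 <- make_multifamily_genome(1)
  expect_identical(fx$genome$scaffolds, fx2$genome$scaffolds)
})
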
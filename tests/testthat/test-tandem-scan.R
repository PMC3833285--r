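test_that("a planted noisy array is recovered with its period and copy number", {
  spec <- synth_spec(seed = 11, background_length = 4000, arrays = list(
    list(period = 100, copies = 20, substitution = 0.01)))
  g <- synth_generate(spec)
  arr <- scan_tandem_arrays(g$genome)
  expect_identical(nrow(arr), 1L)
  expect_lte(abs(arr$period - 100), 1)
  expect_lte(abs(arr$copy_number - 20), 1)
  expect_gte(arr$mean_identity, 95)
  # detected interval agrees with the planted truth to within a few bp
  expect_lte(abs(arr$start - g$truth$start), 5)
  expect_lte(abs(arr$end - g$truth$end), 5)
})

test_that("random sequence yields no arrays at default thresholds", {
  for (seed in 1:10) {
    g <- synth_generate(synth_spec(seed = seed, background_length = 50000))
    arr <- scan_tandem_arrays(g$genome)
    expect_identical(nrow(arr), 0L, info = paste("seed", seed))
  }
})

test_that("two planted arrays of different periods are reported separately", {
  spec <- synth_spec(seed = 23, background_length = 12000, arrays = list(
    list(period = 154, copies = 12, substitution = 0.02),
    list(period = 225, copies = 8, substitution = 0.02)))
  g <- synth_generate(spec)
  arr <- scan_tandem_arrays(g$genome)
  expect_identical(nrow(arr), 2L)
  expect_lte(abs(sort(arr$period)[1] - 154), 1)
  expect_lte(abs(sort(arr$period)[2] - 225), 1)
})

test_that("no reported period falls outside the configured range", {
  spec <- synth_spec(seed = 5, background_length = 20000, arrays = list(
    list(period = 60, copies = 15, substitution = 0.01),
    list(period = 450, copies = 6, substitution = 0.01)))
  g <- synth_generate(spec)
  arr <- scan_tandem_arrays(g$genome, min_period = 100, max_period = 400)
  expect_true(all(arr$period >= 100 & arr$period <= 400))
})

test_that("the census pools units and clusters per period bin", {
  arr <- data.frame(scaffold = "s", start = c(0L, 2000L, 5000L),
                    end = c(924L, 2926L, 5940L),
                    period = c(154L, 154L, 172L),
                    copy_number = c(6.0, 6.01, 5.5),
                    mean_identity = c(99, 98, 97),
                    n_units = c(6L, 6L, 6L),
                    consensus = c("A", "A", "A"))
  cen <- census(arr)
  expect_identical(cen$unit_count[cen$period == 154], 12)
  expect_identical(cen$cluster_count[cen$period == 154], 2L)
  pooled <- census(arr, ranges = list(c(153, 154), c(170, 174)))
  expect_identical(pooled$unit_count, c(12, 6))
  expect_identical(pooled$cluster_count, c(2L, 1L))
  # unit totals conserve the rounded copy numbers
  expect_identical(sum(cen$unit_count), sum(round(arr$copy_number)))
})

test_that("pooled consensus recovers the unit up to rotation, with IUPAC polymorphisms", {
  set.seed(303)
  unit <- random_unit <- paste(sample(c("A", "C", "G", "T"), 120,
                                      replace = TRUE), collapse = "")
  spec <- synth_spec(seed = 61, background_length = 15000, arrays = list(
    list(unit = unit, copies = 12, substitution = 0.01),
    list(unit = unit, copies = 10, substitution = 0.01),
    list(unit = unit, copies = 8, substitution = 0.01)))
  g <- synth_generate(spec)
  arr <- scan_tandem_arrays(g$genome)
  expect_gte(nrow(arr), 3L)
  cu <- pool_consensus(arr, c(119, 121))
  ci <- circular_identity(cu$sequence, unit, both_strands = FALSE)
  expect_gte(ci$identity, 98)

  # a 50/50 polymorphic column in the planted unit surfaces as its code
  amb <- unit
  substr(amb, 60, 60) <- "S"
  spec2 <- synth_spec(seed = 62, background_length = 9000, arrays = list(
    list(unit = amb, copies = 30, substitution = 0)))
  g2 <- synth_generate(spec2)
  arr2 <- scan_tandem_arrays(g2$genome)
  expect_identical(nrow(arr2), 1L)
  cu2 <- pool_consensus(arr2, c(119, 121))
  ci2 <- circular_identity(cu2$sequence, amb, both_strands = FALSE)
  expect_gte(ci2$identity, 99)
  expect_true(grepl("S", cu2$sequence))

  # a single array pools to its own consensus
  cu3 <- pool_consensus(arr2, c(119, 121))
  expect_identical(cu3$length, 120L)
  expect_error(pool_consensus(arr2, c(300, 310)), "no arrays")
})
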
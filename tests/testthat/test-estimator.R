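test_that("T events count maximal runs, doublets collapse to one", {
  r <- countTEvents("TATT")
  expect_equal(r$t_events, 2L)
  expect_equal(r$multi_run_positions, 2L)       # 0-based start of "TT"
  expect_equal(countTEvents("")$t_events, 0L)
  expect_equal(countTEvents("ACGACG")$t_events, 0L)
  expect_equal(countTEvents("TTTT")$t_events, 1L)   # one maximal run
  expect_error(countTEvents("TAXT"), "DNA")
})

test_that("364 T letters as 360 singletons + 2 doublets give 362 events", {
  set.seed(50)
  pieces <- c(rep("TACG", 360), rep("TTACG", 2))
  dna <- paste(sample(pieces), collapse = "")
  r <- countTEvents(dna)
  expect_equal(r$t_events, 362L)
  expect_equal(length(r$multi_run_positions), 2L)
  expect_equal(sum(strsplit(dna, "")[[1]] == "T"), 364L)
})

test_that("calibration rates match the worked examples", {
  cal <- calibrateRate(362L, 101L)
  expect_equal(round(perRepeatRate(cal), 2), 3.58)
  expect_equal(tEvents(cal), 362L)
  expect_equal(perRepeatRate(calibrateRate(0L, 10L)), 0)
  expect_equal(round(perRepeatRate(calibrateRate(715L, 220L)), 2), 3.25)
  expect_error(calibrateRate(10L, 0L), "n_repeats")
})

test_that("repeat-delta estimation divides and rounds half away from zero", {
  cal <- calibrateRate(362L, 101L)
  expect_equal(estimateRepeatDelta(13, cal), 4L)
  expect_equal(estimateRepeatDelta(0, cal), 0L)
  expect_equal(estimateRepeatDelta(-36, cal), -10L)  # -10.04 -> -10
  expect_error(estimateRepeatDelta(5, calibrateRate(0L, 5L)), "rate")
})

test_that("delta estimation is an odd function", {
  cal <- calibrateRate(362L, 101L)
  for (x in 0:50)
    expect_equal(estimateRepeatDelta(-x, cal), -estimateRepeatDelta(x, cal))
})

test_that("repeat counts estimate from the calibration baseline", {
  cal <- calibrateRate(362L, 101L)
  expect_equal(estimateRepeatCount(362L, cal), 101L)
  expect_equal(estimateRepeatCount(375L, cal), 105L)  # the worked example
  expect_warning(
    estimateRepeatCount(375L, cal, query_unit = "PSTTPITTTT",
                        calibration_unit = "GGGGAAAAVV"),
    "identity")
})

test_that("a +6-unit variant is estimated exactly from T counts", {
  loc <- makeLocus(30, cysd_positions = integer(0), seed = 51)
  var <- deriveVariant(loc, n_unit_snps = 0, delta_repeats = 6, seed = 52)
  cal <- calibrateRate(as.character(trRegionSeq(loc)), 30L)
  expect_equal(length(cal@multiRunPositions), 0L)   # no TT in template DNA
  est <- estimateRepeatCount(as.character(trRegionSeq(var)), cal)
  expect_equal(est, 36L)
})

test_that("repeat recovery tolerates unit-length variants within +-1", {
  base <- makeLocus(40, cysd_positions = integer(0), seed = 53)
  cal <- calibrateRate(as.character(trRegionSeq(base)), 40L)
  ok <- 0L
  set.seed(54)
  trials <- 100L
  for (i in seq_len(trials)) {
    delta <- sample(-15:15, 1)
    n2 <- 40L + delta
    vl <- setNames(sample(c(21L, 22L, 24L), 3, replace = TRUE),
                   sample(seq_len(n2), 3))
    var <- makeLocus(n2, variant_lengths = vl,
                     cysd_positions = integer(0), intron_lengths = c(50L, 50L),
                     seed = 1000L + i)
    est <- estimateRepeatCount(as.character(trRegionSeq(var)), cal)
    ok <- ok + (abs(est - n2) <= 1L)
  }
  expect_gte(ok / trials, 0.9)
})

test_that("T-event counts are invariant under non-T homopolymer edits", {
  set.seed(55)
  dna <- "ACCCGTACAAAGTATCGGGA"
  edited <- sub("CCC", "CC", dna)      # deletion in a C run
  edited <- sub("AAA", "AAAA", edited) # insertion in an A run
  v <- verifyTInvariance(dna, edited)
  expect_true(v$invariant)
  broken <- sub("GTA", "GA", dna)      # deletes a singleton T
  v2 <- verifyTInvariance(dna, broken)
  expect_false(v2$invariant)
  expect_equal(v2$t_raw - v2$t_adjusted, 1L)
  expect_true(verifyTInvariance("TATA", "TATA")$invariant)
})
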
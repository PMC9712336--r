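test_that("the 101-repeat locus has a 6969 nt repeat region", {
  loc <- makeLocus(101, cysd_positions = c(0, 51), seed = 3)
  expect_equal(nRepeats(loc), 101L)
  expect_equal(length(trRegionSeq(loc)), 101L * 69L)   # 101 x 23 aa x 3
  b <- blockTable(loc)
  expect_equal(sum(b$kind == "CYSD"), 2L)
})

test_that("zero repeats give a HEAD+TAIL exon", {
  loc <- makeLocus(0, cysd_positions = integer(0), seed = 1)
  expect_equal(blockTable(loc)$kind, c("HEAD", "TAIL"))
})

test_that("the same seed reproduces identical DNA", {
  a <- makeLocus(7, seed = 99)
  b <- makeLocus(7, seed = 99)
  expect_identical(as.character(locusSeq(a)), as.character(locusSeq(b)))
  expect_false(identical(as.character(locusSeq(a)),
                         as.character(locusSeq(makeLocus(7, seed = 100)))))
})

test_that("exon DNA never contains a TT doublet and translates cleanly", {
  for (seed in 1:3) {
    loc <- makeLocus(12, seed = seed)
    exon <- as.character(exonSeq(loc))
    expect_false(grepl("TT", exon, fixed = TRUE))
    prot <- translateExon(exon)
    expect_equal(attr(prot, "stops"), 0L)
  }
  expect_error(makeLocus(3, unit_template = "PSFTPSTT"), "residue")
})

test_that("deriveVariant changes exactly what it promises", {
  loc <- makeLocus(10, seed = 4)
  same <- deriveVariant(loc, 0, 0, seed = 1)
  expect_identical(blockTable(same)$dna, blockTable(loc)$dna)

  plus4 <- deriveVariant(loc, 0, 4, seed = 1)
  expect_equal(nRepeats(plus4), 14L)
  expect_identical(plus4@intronUp, loc@intronUp)
  expect_identical(plus4@intronDown, loc@intronDown)

  minus <- deriveVariant(loc, 0, -3, seed = 1)
  expect_equal(nRepeats(minus), 7L)
  expect_error(deriveVariant(loc, 0, -11), "more units")

  snped <- deriveVariant(loc, 5, 0, seed = 2)
  expect_equal(nrow(snped@provenance$snps), 5L)
  # SNPs never touch the start motif
  expect_true(all(snped@provenance$snps$offset >= 2))
  diffs <- sum(blockTable(snped)$protein != blockTable(loc)$protein)
  expect_gt(diffs, 0)
})

test_that("error-free reads are exact substrings on their truth strand", {
  loc <- makeLocus(8, seed = 2)
  lstr <- as.character(locusSeq(loc))
  rds <- suppressWarnings(
    simulateReads(loc, n_reads = 12, length_range = c(800, 2000),
                  profile = errorProfile(pTotal = 0), seed = 6))
  mc <- S4Vectors::mcols(rds)
  for (i in seq_along(rds)) {
    frag <- substr(lstr, mc$truth_start[i] + 1L, mc$truth_end[i])
    obs <- as.character(rds[[i]])
    if (mc$truth_strand[i] == "-") obs <- revcomp(obs)
    expect_identical(obs, frag)
  }
  # strands sampled evenly
  expect_lte(abs(sum(mc$truth_strand == "+") - sum(mc$truth_strand == "-")),
             1L)
})

test_that("mean per-base coverage hits the requested depth on a 15 kb locus", {
  loc <- makeLocus(160, intron_lengths = c(1300L, 1300L), seed = 8)
  L <- length(locusSeq(loc))
  expect_gt(L, 13000)
  rds <- suppressWarnings(
    simulateReads(loc, mean_depth = 20, length_range = c(4000, 9000),
                  profile = errorProfile(pTotal = 0), seed = 3))
  mc <- S4Vectors::mcols(rds)
  mean_cov <- sum(mc$truth_end - mc$truth_start) / L
  expect_gt(mean_cov, 17)
  expect_lt(mean_cov, 23)
})

test_that("the injected error rate converges to pTotal", {
  loc <- makeLocus(30, seed = 5)
  prof <- errorProfile(pTotal = 0.2)
  rds <- suppressWarnings(
    simulateReads(loc, n_reads = 30, length_range = c(2500, 3500),
                  profile = prof, seed = 9))
  mc <- S4Vectors::mcols(rds)
  n_bases <- sum(mc$truth_end - mc$truth_start)
  rate <- sum(mc$n_errors) / n_bases
  se <- sqrt(0.2 * 0.8 / n_bases)
  expect_lt(abs(rate - 0.2), 2 * se + 1e-6)
})

test_that("per-read alignment identity sits in the expected band at p = 0.2", {
  loc <- makeLocus(30, seed = 5)
  lstr <- as.character(locusSeq(loc))
  rds <- suppressWarnings(
    simulateReads(loc, n_reads = 24, length_range = c(2000, 3000),
                  profile = errorProfile(pTotal = 0.2), seed = 11))
  mc <- S4Vectors::mcols(rds)
  ids <- vapply(seq_along(rds), function(i) {
    frag <- substr(lstr, mc$truth_start[i] + 1L, mc$truth_end[i])
    obs <- as.character(rds[[i]])
    if (mc$truth_strand[i] == "-") obs <- revcomp(obs)
    al <- globalAlign(frag, obs, 1, -1, -1, band = 400)
    ca <- strsplit(al$a, "")[[1]]; cb <- strsplit(al$b, "")[[1]]
    sum(ca == cb & ca != "-") / length(ca)
  }, numeric(1))
  expect_gte(mean(ids >= 0.75 & ids <= 0.85), 0.95)
})

test_that("anchorsFromLocus picks a mid-domain island and cysdReferences lists all", {
  loc <- makeLocus(20, seed = 1)
  anch <- anchorsFromLocus(loc)
  expect_s4_class(anch, "AnchorSet")
  refs <- cysdReferences(loc)
  expect_equal(length(refs), 2L)
  expect_true(all(grepl("C", refs)))
})
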
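test_that("translation follows the standard code and frames", {
  expect_equal(as.character(translateExon("ATGCCA")), "MP")
  expect_equal(as.character(translateExon("ATGCCA", 1)), "C")
  p <- translateExon("ATGTAAGGG")
  expect_equal(as.character(p), "M*G")
  expect_equal(attr(p, "stops"), 1L)
})

test_that("a random 999-nt ORF matches an independent translation", {
  set.seed(30)
  dna <- random_dna(999)
  mine <- as.character(translateExon(dna))
  oracle <- paste(seqinr::translate(strsplit(tolower(dna), "")[[1]]),
                  collapse = "")
  expect_identical(mine, oracle)
})

test_that("planted CysD references are found with exact spans", {
  set.seed(31)
  pts <- function(n) paste(sample(c("P", "T", "S", "A", "G"), n,
                                  replace = TRUE), collapse = "")
  ref <- paste0("AC", pts(20), "C", pts(10), "CDC")   # last C at the end
  prot <- paste0(pts(40), ref, pts(50), ref, pts(30))
  hits <- findCysD(prot, ref)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$start, c(40L, 40L + nchar(ref) + 50L))
  expect_equal(hits$identity, c(1, 1))
  # delimiter = last cysteine inside each span (the final C of "CDC")
  expect_equal(hits$delimiter_pos - hits$start, rep(nchar(ref) - 1L, 2))
})

test_that("a few substitutions away from cysteines still match", {
  set.seed(32)
  pts <- function(n) paste(sample(c("P", "T", "S"), n, replace = TRUE),
                           collapse = "")
  ref <- paste0("GG", strrep("AC", 15), "CQC")
  mut <- ref
  substr(mut, 4, 4) <- "V"; substr(mut, 10, 10) <- "H"
  substr(mut, 20, 20) <- "N"
  prot <- paste0(pts(25), mut, pts(25))
  hits <- findCysD(prot, ref, max_mismatch_fraction = 0.1)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 25L)
  expect_equal(hits$delimiter_pos, 25L + nchar(ref) - 1L)
})

test_that("a PTS-only segment has no CysD hit; a Cys-free reference errors", {
  expect_equal(nrow(findCysD(strrep("PTSTP", 40), paste0(strrep("PC", 10)))),
               0L)
  expect_error(findCysD("PPPP", "PTSPTS"), "cysteine")
})

test_that("start-motif decomposition mirrors the 28-repeat architecture", {
  set.seed(33)
  lens <- sample(7:26, 28, replace = TRUE)
  units <- vapply(lens, function(l)
    paste0("PS", paste(sample(c("T", "A", "G", "V", "Q"), l - 2,
                              replace = TRUE), collapse = "")),
    character(1))
  head <- "GAVQT"                                  # motif-free head
  seg <- paste0(head, paste(units, collapse = ""))
  dec <- decomposeByStartMotif(seg, "PS", 4, 40)
  expect_equal(sum(blockTable(dec)$kind == "TR"), 28L)
  expect_equal(unitLengths(dec), as.integer(lens))
  expect_equal(blockTable(dec)$kind[1], "HEAD")
  # spans partition the segment
  expect_identical(paste(blockTable(dec)$seq, collapse = ""), seg)
})

test_that("motif edge cases: none, and a single leading motif", {
  dec0 <- decomposeByStartMotif("TTTAAAGGG", "PS")
  expect_equal(sum(blockTable(dec0)$kind == "TR"), 0L)
  expect_equal(blockTable(dec0)$kind, "HEAD")
  dec1 <- decomposeByStartMotif("PSTTTTTTT", "PS")
  expect_equal(sum(blockTable(dec1)$kind == "TR"), 1L)
  expect_equal(blockTable(dec1)$seq[1], "PSTTTTTTT")
  expect_equal(nrow(blockTable(decomposeByStartMotif("", "PS"))), 0L)
})

test_that("periodic decomposition returns exactly n units on exact copies", {
  unit23 <- "PSTTPITTTTMVTPTPTPTGTQT"
  for (n in c(0L, 1L, 5L, 17L, 101L)) {
    seg <- strrep(unit23, n)
    dec <- decomposePeriodic(seg, unit23)
    expect_equal(sum(blockTable(dec)$kind == "TR"), n)
    if (n > 0) expect_true(all(unitLengths(dec) == 23L))
  }
  unit8 <- "PSTTVAGQ"
  dec8 <- decomposePeriodic(strrep(unit8, 12), unit8)
  expect_equal(sum(blockTable(dec8)$kind == "TR"), 12L)
})

test_that("length-variant units are recovered exactly", {
  unit <- "PSTTPITTTTMVTPTPTPTGTQT"
  u22 <- substr(unit, 1, 22)
  u24 <- paste0(unit, substr(unit, 3, 3))
  seg <- paste0(strrep(unit, 3), u22, strrep(unit, 2), u24,
                strrep(unit, 3))
  dec <- decomposePeriodic(seg, unit)
  expect_equal(unitLengths(dec),
               c(23L, 23L, 23L, 22L, 23L, 23L, 24L, 23L, 23L, 23L))
  expect_identical(paste(blockTable(dec)$seq, collapse = ""), seg)
})

test_that("a truncated terminal unit is accepted; junk becomes TAIL", {
  unit <- strrep("PSTTPITTTTMVTPTPTPTGTQT", 1)
  seg <- paste0(strrep(unit, 5), substr(unit, 1, 12))
  dec <- decomposePeriodic(seg, unit)
  expect_equal(unitLengths(dec), c(rep(23L, 5), 12L))
  set.seed(34)
  junk <- paste(sample(c("D", "E", "K", "R", "N", "H"), 30, replace = TRUE),
                collapse = "")
  dec2 <- decomposePeriodic(paste0(strrep(unit, 4), junk), unit)
  expect_equal(sum(blockTable(dec2)$kind == "TR"), 4L)
  expect_equal(blockTable(dec2)$kind[nrow(blockTable(dec2))], "TAIL")
  dec3 <- decomposePeriodic(junk, unit)
  expect_equal(sum(blockTable(dec3)$kind == "TR"), 0L)
})

test_that("identical decompositions compare clean", {
  unit <- "PSTTPITTTTMVTPTPTPTGTQT"
  dec <- decomposePeriodic(strrep(unit, 10), unit)
  cmp <- compareDecompositions(dec, dec)
  expect_equal(nrow(snpTable(cmp)), 0L)
  expect_equal(nrow(cnvTable(cmp)), 0L)
})

test_that("a mid-array deletion is located when units are distinguishable", {
  unit <- "PSTTPITTTTMVTPTPTPTGTQT"
  lens <- c(23L, 21L, 25L, 23L, 19L, 27L, 23L, 20L, 24L)
  units <- vapply(lens, function(l) {
    if (l <= 23L) substr(unit, 1, l) else paste0(unit, substr(unit, 3, l - 21))
  }, character(1))
  mk <- function(us) {
    ends <- cumsum(nchar(us))
    blocks <- data.frame(kind = "TR", start = c(0L, head(ends, -1)),
                         end = ends, seq = us, stringsAsFactors = FALSE)
    new("RepeatDecomposition", blocks = blocks,
        unitLengths = as.integer(nchar(us)))
  }
  a <- mk(units)
  b <- mk(units[-5])
  cmp <- compareDecompositions(a, b)
  expect_equal(nrow(cnvTable(cmp)), 1L)
  expect_equal(cnvTable(cmp)$delta, -1L)
  expect_equal(cnvTable(cmp)$after_unit, 4L)
  # antisymmetry
  cmp2 <- compareDecompositions(b, a)
  expect_equal(cnvTable(cmp2)$delta, 1L)
  expect_equal(nrow(snpTable(cmp2)), nrow(snpTable(cmp)))
})

test_that("derived variants round-trip through comparison", {
  loc <- makeLocus(30, cysd_positions = integer(0), seed = 40)
  var <- deriveVariant(loc, n_unit_snps = 5, delta_repeats = 2, seed = 41)
  unit <- unitTemplate(loc)
  dec_a <- decomposePeriodic(as.character(translateExon(trRegionSeq(loc))),
                             unit)
  dec_b <- decomposePeriodic(as.character(translateExon(trRegionSeq(var))),
                             unit)
  expect_equal(sum(blockTable(dec_a)$kind == "TR"), 30L)
  expect_equal(sum(blockTable(dec_b)$kind == "TR"), 32L)
  cmp <- compareDecompositions(dec_a, dec_b)
  expect_equal(nrow(cnvTable(cmp)), 1L)
  expect_equal(cnvTable(cmp)$delta, 2L)
  expect_equal(nrow(snpTable(cmp)), 5L)
  # antisymmetric on the same data
  cmp_rev <- compareDecompositions(dec_b, dec_a)
  expect_equal(cnvTable(cmp_rev)$delta, -2L)
  snps <- snpTable(cmp); snps_rev <- snpTable(cmp_rev)
  expect_setequal(paste(snps$a, snps$b), paste(snps_rev$b, snps_rev$a))
})
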
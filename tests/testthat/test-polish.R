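test_that("accuracy bounds reproduce the printed per-nucleotide values", {
  b <- accuracyBounds(c(7L, 6L, 5L, 1L))
  pct <- accuracyPercent(b)
  expect_equal(pct$low_pct, c("99.98", "99.93", "99.76", "70.00"))
  expect_equal(b$low, 1 - 0.3^c(7, 6, 5, 1))
  expect_equal(b$high, 1 - 0.15^c(7, 6, 5, 1))
  expect_error(accuracyBounds(c(3L, 0L)), "depth")
})

test_that("rounded display can also truncate (99.9998% prints as 99.99)", {
  b <- accuracyBounds(7L)
  expect_equal(accuracyPercent(b)$high_pct, "100.00")       # round half-up
  expect_equal(accuracyPercent(b, truncate = TRUE)$high_pct, "99.99")
})

test_that("accuracy bounds are monotone in depth", {
  set.seed(2)
  for (i in 1:5) {
    d <- sample(1:40, 30, replace = TRUE)
    b <- accuracyBounds(d, p_low = 0.1, p_high = 0.25)
    o <- order(d)
    expect_true(all(diff(b$low[o]) >= 0))
    expect_true(all(diff(b$high[o]) >= 0))
    expect_true(all(b$low <= b$high))
  }
})

test_that("error-free data produce no suspect loci", {
  x <- random_dna(400)
  expect_equal(nrow(realignAndFlag(x, rep(x, 8))), 0L)
})

test_that("a lost or gained homopolymer base is flagged with its kind", {
  set.seed(4)
  truth <- paste0(random_dna(60), "AAAA", random_dna(60), "TT",
                  random_dna(60))
  # consensus lost one A of the AAAA run
  consA <- sub("AAAA", "AAA", truth)
  sus <- realignAndFlag(consA, rep(truth, 10))
  expect_true(any(sus$kind == "MISSING_BASE" & sus$run_base == "A" &
                    sus$alt_length - sus$run_length == 1L))
  # consensus gained a T: TT became TTT
  consT <- sub("TT", "TTT", truth)
  sus2 <- realignAndFlag(consT, rep(truth, 10))
  expect_true(any(sus2$kind == "EXTRA_BASE" & sus2$run_base == "T"))
})

test_that("a clean ORF is left untouched", {
  loc <- makeLocus(4, intron_lengths = c(100L, 100L), seed = 12)
  lstr <- as.character(locusSeq(loc))
  exon_span <- c(100L, 100L + length(exonSeq(loc)))
  pol <- correctFrameshifts(lstr, exon_span, mucintr:::.emptySuspects())
  expect_identical(pol$sequence, lstr)
  expect_equal(nrow(pol$edits), 0L)
  expect_true(pol$resolved)
})

test_that("translation-guided repair restores engineered homopolymer indels", {
  loc <- makeLocus(6, intron_lengths = c(100L, 100L), seed = 13)
  lstr <- as.character(locusSeq(loc))
  truth_prot <- as.character(translateExon(exonSeq(loc)))
  exon_chars <- strsplit(as.character(exonSeq(loc)), "")[[1]]
  runs <- rle(exon_chars)
  long <- which(runs$lengths >= 3)
  pos_in_exon <- cumsum(runs$lengths)[long[2]]          # run end, 1-based

  # delete one base inside that run
  mut <- paste0(substr(lstr, 1, 100 + pos_in_exon - 1),
                substr(lstr, 100 + pos_in_exon + 1, nchar(lstr)))
  segs <- rep(lstr, 10)
  sus <- realignAndFlag(mut, segs)
  pol <- correctFrameshifts(mut, c(100L, 100L + length(exonSeq(loc)) - 1L),
                            sus)
  exon_fixed <- substr(pol$sequence, pol$exon_span[1] + 1, pol$exon_span[2])
  expect_identical(exon_fixed, as.character(exonSeq(loc)))
  expect_identical(as.character(translateExon(exon_fixed)), truth_prot)
  expect_gte(nrow(pol$edits), 1L)

  # insert one extra base into the run
  mut2 <- paste0(substr(lstr, 1, 100 + pos_in_exon),
                 runs$values[long[2]],
                 substr(lstr, 100 + pos_in_exon + 1, nchar(lstr)))
  sus2 <- realignAndFlag(mut2, segs)
  pol2 <- correctFrameshifts(mut2, c(100L, 100L + length(exonSeq(loc)) + 1L),
                             sus2)
  exon_fixed2 <- substr(pol2$sequence, pol2$exon_span[1] + 1,
                        pol2$exon_span[2])
  expect_identical(exon_fixed2, as.character(exonSeq(loc)))
})

test_that("edits stay within flagged loci and below the suspect capacity", {
  loc <- makeLocus(6, intron_lengths = c(100L, 100L), seed = 14)
  lstr <- as.character(locusSeq(loc))
  set.seed(6)
  prof <- errorProfile(pTotal = 0.08)
  segs <- vapply(1:10, function(i) mucintr:::.injectErrors(lstr, prof)$seq,
                 character(1))
  cons <- refineConsensus(segs, with_msa = FALSE)$consensus@sequence
  sus <- realignAndFlag(cons, segs)
  pol <- correctFrameshifts(cons, c(100L, nchar(cons) - 100L), sus)
  cap <- sum(pmax(nchar(sus$ins_seq), 1)) + sum(sus$kind != "MISSING_BASE")
  expect_lte(nrow(pol$edits), max(cap, 0) )
  if (nrow(pol$edits) && nrow(sus))
    expect_true(all(vapply(pol$edits$position, function(p)
      min(abs(p - sus$position)) <= max(sus$run_length) + 2, logical(1))))
})

test_that("engineered frameshifts are repaired in at least 95% of trials", {
  loc <- makeLocus(8, intron_lengths = c(50L, 50L), seed = 15)
  lstr <- as.character(locusSeq(loc))
  exon_len <- length(exonSeq(loc))
  truth_exon <- as.character(exonSeq(loc))
  exon_chars <- strsplit(truth_exon, "")[[1]]
  runs <- rle(exon_chars)
  ends <- cumsum(runs$lengths)
  long <- which(runs$lengths >= 3)
  prof <- errorProfile(pTotal = 0.1)
  ok <- 0L
  n_trials <- 100L
  set.seed(20)
  for (trial in seq_len(n_trials)) {
    k <- sample(1:5, 1)
    at <- sample(long, k)
    mut_chars <- exon_chars
    drop <- ends[at]                       # delete one base per chosen run
    mut <- paste(mut_chars[-drop], collapse = "")
    cons <- paste0(substr(lstr, 1, 50), mut,
                   substr(lstr, nchar(lstr) - 49, nchar(lstr)))
    segs <- vapply(1:10, function(i) mucintr:::.injectErrors(lstr, prof)$seq,
                   character(1))
    sus <- realignAndFlag(cons, segs)
    pol <- correctFrameshifts(cons, c(50L, 50L + nchar(mut)), sus)
    got <- substr(pol$sequence, pol$exon_span[1] + 1, pol$exon_span[2])
    ok <- ok + identical(as.character(translateExon(got)),
                         as.character(translateExon(truth_exon)))
  }
  expect_gte(ok / n_trials, 0.95)
})
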
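test_that("self-alignment has no gaps and full match score", {
  x <- random_dna(40)
  al <- globalAlign(x, x)
  expect_identical(al$a, x)
  expect_identical(al$b, x)
  expect_equal(al$score, nchar(x))
})

test_that("alignment scores equal exhaustive enumeration on short pairs", {
  pairs <- expand.grid(a = unlist(lapply(1:4, all_strings,
                                         alphabet = c("A", "C"))),
                       b = unlist(lapply(1:4, all_strings,
                                         alphabet = c("A", "C"))),
                       stringsAsFactors = FALSE)
  for (scores in list(c(1, 0, 0), c(2, -1, -1))) {
    got <- mapply(function(a, b)
      globalAlign(a, b, scores[1], scores[2], scores[3])$score,
      pairs$a, pairs$b)
    want <- mapply(function(a, b)
      enumerate_align_score(a, b, scores[1], scores[2], scores[3]),
      pairs$a, pairs$b)
    expect_equal(unname(got), unname(want))
  }
})

test_that("zero-penalty score equals the LCS length (independent oracle)", {
  strs <- unlist(lapply(5:6, all_strings, alphabet = c("A", "C")))
  pairs <- expand.grid(a = strs, b = strs, stringsAsFactors = FALSE)
  got <- mapply(function(a, b) globalAlign(a, b, 1, 0, 0)$score,
                pairs$a, pairs$b)
  want <- mapply(lcs_via_adist, pairs$a, pairs$b)
  expect_equal(unname(got), unname(want))
})

test_that("an extra repeat unit aligns as one contiguous free gap block", {
  loc <- makeLocus(6, seed = 44)
  unit <- blockTable(loc)$dna[blockTable(loc)$kind == "TR_UNIT"][1]
  expect_equal(nchar(unit), 69L)
  a <- strrep(unit, 5)
  b <- strrep(unit, 6)
  al <- globalAlign(a, b, 1, 0, 0)
  gaps <- gregexpr("-+", al$a)[[1]]
  expect_equal(length(gaps), 1L)                         # one block
  expect_equal(attr(gaps, "match.length"), 69L)          # one whole unit
  expect_false(grepl("-", al$b, fixed = TRUE))
})

test_that("MSA rows reproduce their inputs after gap removal", {
  x <- random_dna(1000)
  msa1 <- buildMsa(x)
  expect_equal(length(msa1@rows), 1L)
  expect_false(grepl("-", msa1@rows, fixed = TRUE))

  copies <- rep(x, 10)
  msa2 <- buildMsa(copies)
  expect_true(all(msa2@rows == x))                       # gap-free

  set.seed(3)
  prof <- errorProfile(pTotal = 0.1)
  noisy <- vapply(1:10, function(i) mucintr:::.injectErrors(x, prof)$seq,
                  character(1))
  msa3 <- buildMsa(noisy)
  expect_identical(gsub("-", "", msa3@rows), noisy)
})

test_that("majority voting keeps bases, drops gap-won columns", {
  # (A,A,A,T) column: A with support 0.75
  m <- new("Msa", rowIds = as.character(1:4),
           rows = c("CAG", "CAG", "CAG", "CTG"),
           columnDepth = rep(4L, 3))
  cons <- consensusByMajority(m)
  expect_equal(cons@sequence, "CAG")
  expect_equal(cons@support[2], 0.75)
  # the missing-base hazard: one base against three gaps is dropped
  m2 <- new("Msa", rowIds = as.character(1:4),
            rows = c("CAG", "C-G", "C-G", "C-G"),
            columnDepth = rep(4L, 3))
  cons2 <- consensusByMajority(m2)
  expect_equal(cons2@sequence, "CG")
  expect_equal(cons2@depth, c(4L, 4L))
})

test_that("consensus matches a brute-force per-column vote", {
  set.seed(12)
  for (rep_i in 1:20) {
    rows <- vapply(1:6, function(i) {
      mid <- paste(sample(c("A", "C", "G", "T", "-"), 48, replace = TRUE,
                          prob = c(.22, .22, .22, .22, .12)),
                   collapse = "")
      paste0(sample(c("A", "C", "G", "T"), 1), mid,
             sample(c("A", "C", "G", "T"), 1))
    }, character(1))
    m <- new("Msa", rowIds = as.character(1:6), rows = rows,
             columnDepth = rep(6L, 50))
    got <- consensusByMajority(m)
    want <- brute_force_consensus(rows)
    expect_equal(got@sequence, want$sequence)
    expect_equal(got@depth, as.integer(want$depth))
    expect_equal(got@support, want$support)
    # row order never matters
    perm <- sample(6)
    m2 <- new("Msa", rowIds = as.character(perm), rows = rows[perm],
              columnDepth = rep(6L, 50))
    expect_equal(consensusByMajority(m2)@sequence, got@sequence)
  }
})

test_that("the consensus of identical rows is the common row", {
  x <- random_dna(300)
  m <- buildMsa(rep(x, 8))
  cons <- consensusByMajority(m)
  expect_equal(cons@sequence, x)
  expect_true(all(cons@depth == 8L))
  expect_true(all(cons@support == 1))
})

test_that("refined consensus error is consistent with the 1-p^n model", {
  x <- random_dna(2000)
  set.seed(5)
  prof <- errorProfile(pTotal = 0.05)
  noisy <- vapply(1:12, function(i) mucintr:::.injectErrors(x, prof)$seq,
                  character(1))
  cons <- refineConsensus(noisy, with_msa = FALSE)$consensus
  al <- globalAlign(x, cons@sequence, 1, -1, -1, band = 200)
  mism <- sum(strsplit(al$a, "")[[1]] != strsplit(al$b, "")[[1]])
  # bound: mismatch rate <= 10 x (1 - lower accuracy bound) at depth 12
  bound <- 10 * (1 - min(accuracyBounds(cons@depth)$low))
  expect_lte(mism / nchar(x), max(bound, 0.5 / nchar(x)))
})
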
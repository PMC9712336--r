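test_that("length filtering is strict and matches a direct recount", {
  set.seed(42)
  lens <- sample(3000:8000, 100, replace = TRUE)
  reads <- vapply(lens, random_dna, character(1))
  kept <- filterReadsByLength(reads, 5000)
  expect_equal(length(kept), sum(lens > 5000))
  expect_true(all(nchar(kept) > 5000))
  expect_length(filterReadsByLength(character(0), 5000), 0)
  expect_length(filterReadsByLength(c(strrep("A", 5000)), 5000), 0)
})

test_that("a verbatim planted anchor is found exactly", {
  set.seed(7)
  anchor <- random_dna(300)
  read <- paste0(random_dna(2000), anchor, random_dna(1500))
  hit <- locateAnchor(read, anchor)
  expect_equal(hit$strand, "+")
  expect_equal(hit$identity, 1)
  expect_equal(hit$start, 2000L)
  expect_equal(hit$end, 2300L)
})

test_that("a reverse-complemented anchor is found on the minus strand", {
  set.seed(8)
  anchor <- random_dna(300)
  read_fwd <- paste0(random_dna(1000), anchor, random_dna(500))
  hit_fwd <- locateAnchor(read_fwd, anchor)
  hit_rev <- locateAnchor(revcomp(read_fwd), anchor)
  expect_equal(hit_rev$strand, "-")
  # coordinates are on the oriented (reverse-complemented) read, i.e.
  # identical to the forward twin's
  expect_equal(hit_rev$start, hit_fwd$start)
  expect_equal(hit_rev$end, hit_fwd$end)
})

test_that("unrelated random reads never produce a spurious hit", {
  set.seed(9)
  for (i in 1:100) {
    read <- random_dna(10000)
    anchor <- random_dna(1000)
    expect_null(locateAnchor(read, anchor, min_identity = 0.8))
  }
})

test_that("read classes follow the intron/delimiter hit pattern", {
  h <- function(strand = "+") list(start = 0L, end = 10L, strand = strand)
  expect_equal(classifyRead(list(intronUp = h(), delimiter = NULL,
                                 intronDown = h())), "FULL")
  expect_equal(classifyRead(list(intronUp = h(), delimiter = h(),
                                 intronDown = NULL)), "TYPE_I")
  expect_equal(classifyRead(list(intronUp = NULL, delimiter = h(),
                                 intronDown = h())), "TYPE_II")
  expect_equal(classifyRead(list(intronUp = NULL, delimiter = NULL,
                                 intronDown = NULL)), "NONE")
  expect_warning(
    cls <- classifyRead(list(intronUp = h("+"), delimiter = NULL,
                             intronDown = h("-"))),
    "conflicting")
  expect_equal(cls, "NONE")
})

test_that("builder counts reproduce the published bookkeeping", {
  classes <- rep(c("FULL", "TYPE_I", "TYPE_II"), c(4, 18, 9))
  expect_equal(unname(countUsableReads(classes)), c(22L, 13L))
  expect_equal(unname(countUsableReads(rep("NONE", 5))), c(0L, 0L))
  expect_equal(unname(countUsableReads(rep("FULL", 10))), c(10L, 10L))
  # order independence
  expect_equal(countUsableReads(sample(classes)),
               countUsableReads(classes))
})

test_that("error-free segments match truth coordinates", {
  loc <- makeLocus(12, intron_lengths = c(600L, 600L), seed = 21)
  lstr <- as.character(locusSeq(loc))
  L <- nchar(lstr)
  anch <- anchorsFromLocus(loc)
  b <- blockTable(loc)
  starts <- 600L + cumsum(c(0L, nchar(b$dna)))[seq_len(nrow(b))]
  delim_start <- starts[which(b$kind == "CYSD")[2]]

  cfg <- pipelineConfig(minReadLength = 500L)
  # a FULL read spanning the whole locus, plus its reverse twin, plus a
  # TYPE_II read from just before the delimiter island to the locus end
  reads <- Biostrings::DNAStringSet(c(
    full = lstr,
    twin = revcomp(lstr),
    typeII = substr(lstr, delim_start - 49L, L)))
  rec <- recruitReads(reads, anch, cfg)
  expect_equal(unname(rec$classes), c("FULL", "FULL", "TYPE_II"))
  segs <- as.character(rec$segments)
  expect_identical(segs[["full"]], lstr)
  expect_identical(segs[["twin"]], lstr)       # strand symmetry
  expect_identical(segs[["typeII"]], substr(lstr, delim_start + 1L, L))
})

test_that("classification is strand-invariant on noisy reads", {
  loc <- makeLocus(10, seed = 31)
  anch <- anchorsFromLocus(loc)
  rds <- simulateReads(loc, n_reads = 6, length_range = c(3500, 4500),
                       profile = errorProfile(pTotal = 0.1), seed = 13)
  for (i in seq_along(rds)) {
    rd <- as.character(rds[[i]])
    cls1 <- classifyRead(list(
      intronUp = locateAnchor(rd, anch@intronUp),
      delimiter = locateAnchor(rd, anch@delimiter),
      intronDown = locateAnchor(rd, anch@intronDown)))
    rc <- revcomp(rd)
    cls2 <- classifyRead(list(
      intronUp = locateAnchor(rc, anch@intronUp),
      delimiter = locateAnchor(rc, anch@delimiter),
      intronDown = locateAnchor(rc, anch@intronDown)))
    expect_equal(cls1, cls2)
  }
})

test_that("nearly all covering reads classify FULL at p = 0.15", {
  loc <- makeLocus(10, seed = 31)
  anch <- anchorsFromLocus(loc)
  rds <- simulateReads(loc, n_reads = 40, length_range = c(4200, 6000),
                       profile = errorProfile(pTotal = 0.15), seed = 17)
  cfg <- pipelineConfig(minReadLength = 1000L)
  rec <- recruitReads(rds, anch, cfg)
  covers <- S4Vectors::mcols(rds)$truth_start == 0 &
    S4Vectors::mcols(rds)$truth_end == length(locusSeq(loc))
  expect_gte(mean(rec$classes[covers] == "FULL"), 0.95)
})
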
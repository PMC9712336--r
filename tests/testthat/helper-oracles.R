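# Independent oracles and small generators used across the suite.

# Exhaustive alignment-score oracle: plain recursion over every possible
# alignment (no DP sharing), feasible for short strings only.
enumerate_align_score <- function(a, b, match, mismatch, gap) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1L, j - 1L) + s)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# LCS length through base R's generalized edit distance: with
# substitution cost 2 and indel cost 1, d = n + m - 2 * LCS.
lcs_via_adist <- function(a, b) {
  d <- utils::adist(a, b, costs = list(ins = 1, del = 1, sub = 2))
  (nchar(a) + nchar(b) - as.integer(d)) / 2
}

# brute-force per-column majority vote (A<C<G<T order, base beats gap),
# counting only rows whose non-gap extent covers the column
brute_force_consensus <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  nc <- ncol(mat)
  keep_chars <- character(0)
  depth <- integer(0)
  support <- numeric(0)
  ext <- t(vapply(seq_len(nrow(mat)), function(i) {
    nz <- which(mat[i, ] != "-")
    c(nz[1], nz[length(nz)])
  }, numeric(2)))
  for (j in seq_len(nc)) {
    cov <- which(ext[, 1] <= j & ext[, 2] >= j)
    if (!length(cov)) next
    votes <- mat[cov, j]
    counts <- vapply(c("A", "C", "G", "T", "-"),
                     function(s) sum(votes == s), integer(1))
    win <- names(counts)[which.max(counts)]   # first max: A<C<G<T<-
    if (win == "-" || counts[[win]] == 0L) next
    keep_chars <- c(keep_chars, win)
    depth <- c(depth, length(cov))
    support <- c(support, counts[[win]] / length(cov))
  }
  list(sequence = paste(keep_chars, collapse = ""), depth = depth,
       support = support)
}

all_strings <- function(alphabet, len) {
  if (len == 0L) return("")
  apply(do.call(expand.grid, rep(list(alphabet), len)), 1,
        paste, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# forward-oriented read sequences of a simulated read set
oriented_reads <- function(reads) {
  s <- as.character(reads)
  neg <- S4Vectors::mcols(reads)$truth_strand == "-"
  s[neg] <- vapply(s[neg], revcomp, character(1))
  s
}
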
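# Zero-gap-penalty multiple alignment and majority-vote consensus.
#
# With default TR-friendly scores (match +1, mismatch 0, gap 0) a whole
# extra repeat unit aligns as one contiguous free gap block instead of
# interrupting a unit - the property the alignment parameters exist for.
# A negative mismatch would always be dominated by a gap pair under gap 0;
# mismatch 0 with diagonal-first traceback keeps substitutions in aligned
# columns, which SNP calling needs.

#' Global pairwise alignment with configurable scores
#'
#' Needleman-Wunsch with linear gap scores and deterministic traceback
#' (ties resolved diagonal > up > left). The default scores (match +1,
#' mismatch 0, gap 0) are the TR-friendly setting in which whole repeat
#' units align as free contiguous gap blocks.
#'
#' @param a,b non-empty sequences (character or XString).
#' @param match,mismatch,gap alignment scores.
#' @param band if > 0, restrict the DP to a diagonal band of this half
#'   width (plus the length difference); 0 computes the full matrix.
#' @return list with elements `a`, `b` (gapped strings of equal length)
#'   and `score` (the DP optimum).
#' @examples
#' globalAlign("ACGTACGT", "ACGACGT")
#' @export
globalAlign <- function(a, b, match = 1, mismatch = 0, gap = 0, band = 0) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(nzchar(a), nzchar(b))
  .nw_align_cpp(a, b, match, mismatch, gap, band)
}

.autoBand <- function(na, nb) {
  # reads of one locus drift by their net indel excess, a few hundred
  # bases at 10 kb under a 30% indel-dominant error rate
  max(180L, as.integer(round(0.03 * max(na, nb))) + 50L)
}

# Locate-then-align a segment against a (possibly much longer)
# consensus: the densest shared-k-mer diagonal picks the consensus
# window the segment belongs to, and the segment is aligned globally to
# that window only. Returns gapped strings plus the window's 0-based
# offset on the consensus, or NULL when the segment shares no seeds.
.alignSegToCons <- function(cons, seg, band = NULL, k = 13L) {
  n <- nchar(cons)
  m <- nchar(seg)
  if (m >= 0.9 * n) {
    b <- if (is.null(band)) .autoBand(n, m) else band
    al <- .nw_align_cpp(cons, seg, 1, -1, -1, b)
    return(list(a = al$a, b = al$b, offset = 0L))
  }
  cl <- .seedCluster(cons, seg, k)
  if (is.null(cl)) return(NULL)
  pad <- 100L
  wstart <- max(1L, min(cl) + 1L - pad)
  wend <- min(n, max(cl) + m + pad)
  win <- substr(cons, wstart, wend)
  b <- if (is.null(band)) .autoBand(nchar(win), m) else band
  al <- .nw_align_cpp(win, seg, 1, -1, -1, b,
                      free_a_start = TRUE, free_a_end = TRUE)
  list(a = al$a, b = al$b, offset = wstart - 1L)
}

# Median-string tile polish: carve the consensus into tiles anchored at
# aligned flank positions; within each tile, every read contributes its
# own version of the tile, and the string minimizing the summed edit
# distance to all read versions (restricted to observed candidates)
# replaces the consensus tile when it strictly improves the sum. This is
# the maximum-likelihood local consensus under a symmetric error model
# and is robust to the vote scattering that per-column majorities suffer
# in quasi-repeat context.
.medianTilePolish <- function(cons, segs, width = 9L, offset = 0L,
                              margin = 1, band = NULL) {
  n <- nchar(cons)
  bnd <- sort(unique(c(0L, seq.int(offset, n, by = width), n)))
  bnd <- bnd[bnd >= 0L & bnd <= n]
  if (length(bnd) < 2L) return(cons)
  # never split a homopolymer run across tiles: snap each interior
  # boundary to the end of the run it falls in
  cch0 <- .chars(cons)
  rr0 <- rle(cch0)
  rend0 <- cumsum(rr0$lengths)
  rid0 <- rep(seq_along(rr0$lengths), rr0$lengths)
  mid <- bnd > 0L & bnd < n
  bnd[mid] <- rend0[rid0[bnd[mid]]]
  bnd <- sort(unique(bnd))
  if (length(bnd) < 2L) return(cons)
  wins <- cbind(bnd[-length(bnd)], bnd[-1])
  tiles <- vector("list", nrow(wins))
  for (si in seq_along(segs)) {
    al <- .alignSegToCons(cons, segs[[si]], band)
    if (is.null(al)) next
    norm <- .pushGapsRight(.chars(al$a), .chars(al$b))
    ca <- norm$a; cb <- norm$b
    cpos <- cumsum(ca != "-") + al$offset
    bpos <- cumsum(cb != "-")
    readpos <- rep(NA_integer_, n)
    ok <- ca != "-" & cb != "-"
    readpos[cpos[ok]] <- bpos[ok]
    sch <- .chars(segs[[si]])
    for (k in seq_len(nrow(wins))) {
      p1 <- wins[k, 1]; p2 <- wins[k, 2]
      a1 <- if (p1 == 0L) 0L else readpos[p1]
      a2 <- if (p2 == n) nchar(segs[[si]]) + 1L else readpos[p2 + 1L]
      if ((p1 > 0L && is.na(a1)) || (p2 < n && is.na(a2))) next
      if (is.na(a1)) a1 <- 0L
      w <- if (a2 - 1L >= a1 + 1L) .collapse(sch[(a1 + 1L):(a2 - 1L)])
           else ""
      tiles[[k]] <- c(tiles[[k]], w)
    }
  }
  out <- character(nrow(wins))
  for (k in seq_len(nrow(wins))) {
    p1 <- wins[k, 1]; p2 <- wins[k, 2]
    cw <- substr(cons, p1 + 1L, p2)
    v <- tiles[[k]]
    out[k] <- cw
    if (length(v) < 3L) next
    cands <- unique(c(cw, v))
    if (length(cands) == 1L) next
    tabv <- table(v)
    D <- utils::adist(cands, names(tabv))
    tot <- as.numeric(D %*% as.integer(tabv))
    best <- which.min(tot)
    if (cands[best] != cw && tot[best] <= tot[1] - margin)
      out[k] <- cands[best]
  }
  .collapse(out)
}

#' Build a center-star multiple alignment
#'
#' The center is the segment with the highest summed shared-k-mer count
#' against all others; every other segment is pairwise aligned to the
#' center and the pairwise alignments are merged under "once a gap, always
#' a gap". Insertions relative to the center at the same center position
#' are stacked left-aligned into shared columns, so bases the center lost
#' still accumulate votes. Deleting "-" from any row reproduces the input
#' segment exactly.
#'
#' @param segments character vector or [Biostrings::DNAStringSet] (>= 1).
#' @param match,mismatch,gap alignment scores (see [globalAlign()]).
#' @param band diagonal band half-width for the pairwise alignments;
#'   `NULL` chooses one from the segment lengths.
#' @param k k-mer size for center selection.
#' @param center optional explicit center sequence used as an alignment
#'   scaffold only (it contributes no row and no votes); used when
#'   re-aligning reads to a previous consensus.
#' @return An [Msa-class].
#' @export
buildMsa <- function(segments, match = 1, mismatch = 0, gap = 0,
                     band = NULL, k = 11L, center = NULL) {
  if (methods::is(segments, "XStringSet")) {
    ids <- names(segments)
    segments <- as.character(segments)
  } else {
    ids <- names(segments)
  }
  if (is.null(ids)) ids <- paste0("seg", seq_along(segments))
  ns <- length(segments)
  stopifnot(ns >= 1L, all(nzchar(segments)))
  if (!is.null(center)) {
    cseq <- as.character(center)
    center_row <- 0L
    others <- seq_len(ns)
  } else {
    if (ns == 1L) {
      return(new("Msa", rowIds = ids, rows = unname(segments),
                 columnDepth = rep(1L, nchar(segments))))
    }
    sim <- .shared_kmer_matrix_cpp(segments, as.integer(k))
    center_row <- which.max(rowSums(sim))
    cseq <- segments[[center_row]]
    others <- setdiff(seq_len(ns), center_row)
  }
  n <- nchar(cseq)

  slot_ins <- integer(n + 1L)            # max insertion length per slot
  row_data <- vector("list", ns)
  for (s in others) {
    b <- if (is.null(band)) .autoBand(n, nchar(segments[[s]])) else band
    al <- .nw_align_cpp(cseq, segments[[s]], match, mismatch, gap, b)
    norm <- .pushGapsRight(.chars(al$a), .chars(al$b))
    cg <- norm$a; sg <- norm$b
    isgap <- cg == "-"
    cpos <- cumsum(!isgap)               # center base index per column
    bases <- character(n)
    bases[cpos[!isgap]] <- sg[!isgap]
    slots <- list()
    if (any(isgap)) {
      slots <- lapply(split(sg[isgap], cpos[isgap] + 1L), .collapse)
      sl <- as.integer(names(slots))
      slot_ins[sl] <- pmax(slot_ins[sl], nchar(unlist(slots)))
    }
    row_data[[s]] <- list(bases = bases, slots = slots)
  }

  pad <- function(x, width) paste0(x, strrep("-", width - nchar(x)))
  build_row <- function(bases, slots) {
    pieces <- character(2L * n + 1L)
    pieces[seq(1L, 2L * n + 1L, by = 2L)] <- strrep("-", slot_ins)
    pieces[seq(2L, 2L * n, by = 2L)] <- bases
    if (length(slots)) {
      sl <- as.integer(names(slots))
      pieces[2L * sl - 1L] <- pad(unlist(slots), slot_ins[sl])
    }
    .collapse(pieces)
  }
  rows <- character(ns)
  if (center_row > 0L) rows[center_row] <- build_row(.chars(cseq), list())
  for (s in others)
    rows[s] <- build_row(row_data[[s]]$bases, row_data[[s]]$slots)

  ncol <- nchar(rows[1])
  cover <- integer(ncol)
  for (s in seq_len(ns)) {
    nz <- which(.chars(rows[s]) != "-")
    cover[nz[1]:nz[length(nz)]] <- cover[nz[1]:nz[length(nz)]] + 1L
  }
  new("Msa", rowIds = ids, rows = rows, columnDepth = cover)
}

#' Iteratively refined majority consensus
#'
#' One center-star alignment round uses a (noisy) read as coordinate
#' scaffold; its own errors scatter the other reads' votes. Re-aligning
#' every read against the first-round consensus and re-voting (the
#' "align the consensus back to all reads" step) removes the scaffold
#' noise; the loop stops at a fixed point or after `rounds` refinements.
#'
#' The first round aligns reads with the TR-friendly scores
#' (`match`/`mismatch`/`gap`, zero penalties by default) that tolerate
#' differing read extents; the refinement rounds realign each read to the
#' consensus with strict unit-cost edit scores
#' (`refine_mismatch`/`refine_gap`), because reads of one individual share
#' the repeat count and positional precision is what majority voting
#' needs.
#'
#' @param segments read segments (character vector or DNAStringSet).
#' @param match,mismatch,gap alignment scores (see [globalAlign()]).
#' @param rounds maximum refinement rounds.
#' @param band pairwise alignment band (`NULL`: auto).
#' @param refine_mismatch,refine_gap scores for the refinement rounds.
#' @return list: `msa` (final [Msa-class], reads only) and `consensus`
#'   (final [ConsensusTrack-class]).
#' @export
refineConsensus <- function(segments, match = 1, mismatch = 0, gap = 0,
                            rounds = 2L, band = NULL,
                            refine_mismatch = -1, refine_gap = -1,
                            median_passes = 4L, tile_width = 9L,
                            with_msa = TRUE) {
  if (methods::is(segments, "XStringSet")) segments <- as.character(segments)
  msa <- buildMsa(segments, match, mismatch, gap, band)
  cons <- consensusByMajority(msa)
  seqc <- cons@sequence
  for (r in seq_len(rounds)) {
    msa2 <- buildMsa(segments, match, refine_mismatch, refine_gap, band,
                     center = seqc)
    cons2 <- consensusByMajority(msa2)
    done <- identical(cons2@sequence, seqc)
    seqc <- cons2@sequence
    if (done) break
  }
  offs <- (seq_len(max(median_passes, 1L)) - 1L) %% 4L *
    max(tile_width %/% 4L, 1L)
  for (pass in seq_len(median_passes)) {
    seq2 <- .medianTilePolish(seqc, segments, tile_width, offs[pass],
                              band = band)
    if (identical(seq2, seqc) && pass >= 2L) break
    seqc <- seq2
  }
  msa <- if (with_msa)
    buildMsa(segments, match, refine_mismatch, refine_gap, band,
             center = seqc) else NULL
  cons <- .trackForCenter(seqc, segments, band)
  list(msa = msa, consensus = cons)
}

# depth / support track for an externally fixed consensus sequence
.trackForCenter <- function(center, segments, band = NULL) {
  n <- nchar(center)
  cch <- .chars(center)
  depth <- integer(n)
  agree <- integer(n)
  for (si in seq_along(segments)) {
    al <- .alignSegToCons(center, segments[[si]], band)
    if (is.null(al)) next
    ca <- .chars(al$a); cb <- .chars(al$b)
    cpos <- cumsum(ca != "-") + al$offset
    nz <- which(cb != "-")
    lo <- max(cpos[nz[1]], 1L); hi <- cpos[nz[length(nz)]]
    if (hi >= lo) depth[lo:hi] <- depth[lo:hi] + 1L
    ok <- ca != "-" & ca == cb
    agree[cpos[ok]] <- agree[cpos[ok]] + 1L
  }
  new("ConsensusTrack", sequence = center, depth = pmax(depth, 1L),
      support = ifelse(depth > 0L, agree / pmax(depth, 1L), 0))
}

#' Majority-vote consensus of a multiple alignment
#'
#' Per column, the modal symbol over A, C, G, T and "-" among the rows
#' whose aligned extent covers the column; columns won by "-" are dropped
#' (insertions removed). Ties between a base and "-" go to the base;
#' ties among bases go to the alphabetically first. The rule is
#' independent of row order. Depth at a column counts the covering rows
#' (gap or not) - the number of reads aligned at that position.
#'
#' @param msa an [Msa-class].
#' @return A [ConsensusTrack-class]: the consensus sequence with
#'   per-position depth and agreement support.
#' @export
consensusByMajority <- function(msa) {
  rows <- msa@rows
  nr <- length(rows)
  nc <- nchar(rows[1])
  code <- integer(128L)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[utf8ToInt("-")] <- 5L  # N and anything else -> 0 (no vote)
  M <- matrix(0L, nr, nc)
  cover <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    v <- code[utf8ToInt(rows[i])]
    M[i, ] <- v
    nz <- which(v != 5L)  # non-gap symbols (N included) define the extent
    if (length(nz)) cover[i, nz[1]:nz[length(nz)]] <- TRUE
  }
  counts <- matrix(0L, 5L, nc)
  for (k in 1:5) counts[k, ] <- colSums((M == k) & cover)
  depth <- colSums(cover)
  w <- max.col(t(counts), ties.method = "first")  # A<C<G<T then gap
  wcount <- counts[cbind(w, seq_len(nc))]
  keep <- w <= 4L & wcount > 0L
  new("ConsensusTrack",
      sequence = .collapse(c("A", "C", "G", "T")[w[keep]]),
      depth = as.integer(depth[keep]),
      support = unname(wcount[keep] / depth[keep]))
}
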
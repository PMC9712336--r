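# Read recruitment: find, orient, classify and trim the reads that can
# build the mucin-domain consensus. Anchor search is seed-and-extend
# (exact k-mer seeds, densest-diagonal clustering, then a fitting
# alignment of the anchor inside the clustered read window). Recruitment
# uses its own edit-like alignment scores (match +1, mismatch -1, gap -1):
# the zero-gap-penalty MSA scores would degenerate a fitting alignment to
# a longest-common-subsequence stretch with meaningless span and identity.

#' Keep reads strictly longer than a cutoff
#'
#' @param reads [Biostrings::DNAStringSet] or character vector.
#' @param min_length length cutoff in bases (default 5000: reads must be
#'   longer than 5 kb); survivors are strictly longer. Order is preserved;
#'   an empty result is allowed.
#' @return The surviving reads, same container as the input.
#' @export
filterReadsByLength <- function(reads, min_length = 5000L) {
  stopifnot(min_length >= 0)
  w <- if (methods::is(reads, "XStringSet")) Biostrings::width(reads)
       else nchar(reads)
  reads[w > min_length]
}

.seedCluster <- function(read, anchor, k) {
  n <- nchar(read); la <- nchar(anchor)
  if (la < k || n < k) return(NULL)
  akm <- substring(anchor, 1:(la - k + 1L), k:la)
  amap <- split(seq_along(akm), akm)
  rkm <- substring(read, 1:(n - k + 1L), k:n)
  ix <- which(rkm %in% names(amap))
  if (!length(ix)) return(NULL)
  hits <- amap[rkm[ix]]
  d <- rep(ix, lengths(hits)) - unlist(hits, use.names = FALSE)
  ds <- sort(d)
  W <- max(50L, as.integer(round(0.3 * la)))
  upper <- findInterval(ds + W, ds)
  b <- which.max(upper - seq_along(ds))
  ds[b:upper[b]]
}

.anchorHitOneStrand <- function(read, anchor, k, min_identity, min_coverage) {
  n <- nchar(read); la <- nchar(anchor)
  cl <- .seedCluster(read, anchor, k)
  if (is.null(cl)) return(NULL)
  pad <- 50L + as.integer(round(0.1 * la))
  wstart <- max(1L, min(cl) + 1L - pad)
  wend <- min(n, max(cl) + la + pad)
  window <- substr(read, wstart, wend)
  al <- .nw_align_cpp(anchor, window, 1, -1, -1, band = 0,
                      free_a_start = (wstart == 1L),
                      free_a_end = (wend == n),
                      free_b_start = TRUE, free_b_end = TRUE)
  ca <- .chars(al$a); cb <- .chars(al$b)
  apos <- cumsum(ca != "-"); bpos <- cumsum(cb != "-")
  both <- which(ca != "-" & cb != "-")
  if (!length(both)) return(NULL)
  core <- both[1]:both[length(both)]
  matches <- sum(ca[core] == cb[core] & ca[core] != "-")
  identity <- matches / length(core)
  coverage <- (apos[both[length(both)]] - apos[both[1]] + 1L) / la
  if (identity < min_identity || coverage < min_coverage) return(NULL)
  list(start = wstart - 1L + bpos[both[1]] - 1L,   # 0-based half-open
       end = wstart - 1L + bpos[both[length(both)]],
       identity = identity, coverage = coverage,
       aln = list(a = al$a, b = al$b, wstart = wstart))
}

#' Locate an anchor sequence in a read
#'
#' Seed-and-extend search (exact `k`-mer seeds, densest diagonal cluster,
#' fitting alignment of the anchor inside the clustered window) on both
#' strands. A hit is accepted at identity >= `min_identity` over at least
#' `min_coverage` of the anchor length; absence is a valid outcome. Among
#' multiple candidate placements the densest seed diagonal, then highest
#' identity, then "+" strand wins (deterministic).
#'
#' @param read,anchor sequences (character or XString).
#' @param min_identity,min_coverage acceptance thresholds.
#' @param k exact seed length.
#' @return `NULL`, or a list with `start`, `end` (0-based half-open on the
#'   oriented read: the read itself for strand "+", its reverse complement
#'   for "-"), `identity`, `coverage`, `strand`, and the fitting alignment.
#' @examples
#' read <- paste0(strrep("A", 50), "ACGTACGTGGCCAATT", strrep("C", 50))
#' locateAnchor(read, "ACGTACGTGGCCAATT", k = 8)
#' @export
locateAnchor <- function(read, anchor, min_identity = 0.70,
                         min_coverage = 0.60, k = 13L) {
  read <- as.character(read); anchor <- as.character(anchor)
  if (nchar(anchor) < k)
    stop("anchor shorter than the seed size k = ", k)
  fwd <- .anchorHitOneStrand(read, anchor, k, min_identity, min_coverage)
  rev <- .anchorHitOneStrand(.revcomp(read), anchor, k, min_identity,
                             min_coverage)
  if (is.null(fwd) && is.null(rev)) return(NULL)
  if (!is.null(fwd) && (is.null(rev) || fwd$identity >= rev$identity)) {
    fwd$strand <- "+"
    return(fwd)
  }
  rev$strand <- "-"
  rev
}

#' Classify a read from its anchor hits
#'
#' FULL reads hit both introns; TYPE_I reads hit the upstream intron and
#' the CysD delimiter (but not the downstream intron); TYPE_II reads hit
#' the delimiter and the downstream intron (but not the upstream intron).
#' Hits on conflicting strands give NONE with a warning.
#'
#' @param hits named list with elements `intronUp`, `delimiter`,
#'   `intronDown`; each a [locateAnchor()] hit or `NULL`.
#' @return "FULL", "TYPE_I", "TYPE_II" or "NONE".
#' @export
classifyRead <- function(hits) {
  got <- !vapply(hits[c("intronUp", "delimiter", "intronDown")], is.null,
                 logical(1))
  strands <- unique(vapply(hits[got], `[[`, character(1), "strand"))
  if (length(strands) > 1L) {
    warning("anchor hits on conflicting strands; read classified NONE")
    return("NONE")
  }
  up <- got[["intronUp"]]; de <- got[["delimiter"]]; dn <- got[["intronDown"]]
  if (up && dn) return("FULL")
  if (up && de) return("TYPE_I")
  if (de && dn) return("TYPE_II")
  "NONE"
}

#' Builder-read bookkeeping
#'
#' FULL reads serve both consensus parts; TYPE_I reads only the upstream
#' part, TYPE_II only the downstream part.
#'
#' @param classes character vector (multiset) of read classes.
#' @return Named integer vector `c(upstream=, downstream=)`:
#'   `|FULL| + |TYPE_I|` and `|FULL| + |TYPE_II|`.
#' @examples
#' countUsableReads(rep(c("FULL", "TYPE_I", "TYPE_II"), c(4, 18, 9)))
#' @export
countUsableReads <- function(classes) {
  c(upstream = sum(classes == "FULL") + sum(classes == "TYPE_I"),
    downstream = sum(classes == "FULL") + sum(classes == "TYPE_II"))
}

# 0-based exclusive oriented-read coordinate of an anchor offset
# (aoff bases of the anchor consumed). Falls in a read gap -> snapped
# right to the next aligned read base.
.mapAnchorEnd <- function(hit, aoff) {
  ca <- .chars(hit$aln$a); cb <- .chars(hit$aln$b)
  apos <- cumsum(ca != "-"); bpos <- cumsum(cb != "-")
  col <- which(apos == aoff & ca != "-")[1]
  if (is.na(col)) col <- length(ca)
  hit$aln$wstart - 1L + bpos[col]
}

.delimLastCysEnd <- function(delimiter_dna) {
  prot <- .translateDNA(delimiter_dna)
  w <- which(.chars(prot) == "C")
  if (!length(w)) stop("delimiter has no cysteine codon")
  max(w) * 3L  # 0-based exclusive nt offset of the last cysteine codon end
}

.segmentSpan <- function(cls, hits, delim_end_off) {
  if (cls == "FULL") {
    span <- c(hits$intronUp$start, hits$intronDown$end)
  } else if (cls == "TYPE_I") {
    span <- c(hits$intronUp$start, .mapAnchorEnd(hits$delimiter,
                                                 delim_end_off))
  } else if (cls == "TYPE_II") {
    span <- c(hits$delimiter$start, hits$intronDown$end)
  } else {
    return(NULL)
  }
  if (span[1] >= span[2]) return(NULL)   # inconsistent hit order
  as.integer(span)
}

#' Extract the usable segment of a recruited read
#'
#' The segment runs from the start of the first relevant anchor hit to the
#' end of the last, in locus-forward orientation (reverse-strand reads are
#' reverse-complemented first). For TYPE_I reads the segment ends at the
#' position aligned to the delimiter's last cysteine codon; for TYPE_II
#' reads it starts at the delimiter hit start (the whole island is kept,
#' so the two parts overlap across the island and can be stitched at the
#' last cysteine).
#'
#' @param x a [RecruitedRead-class] with class other than NONE.
#' @param anchors the [AnchorSet-class] used for recruitment.
#' @return A [Biostrings::DNAString] segment.
#' @export
extractSegment <- function(x, anchors) {
  if (readClass(x) == "NONE") stop("read was not recruited (class NONE)")
  segmentSeq(x)
}

#' Recruit reads for consensus building
#'
#' Filters reads by length, locates the three anchors on both strands,
#' classifies every read, and extracts the usable segments in
#' locus-forward orientation.
#'
#' @param reads [Biostrings::DNAStringSet] or character vector.
#' @param anchors an [AnchorSet-class].
#' @param config a [PipelineConfig-class].
#' @param k exact seed length for anchor search.
#' @return A list: `reads` ([RecruitedRead-class] list, all surviving
#'   reads), `classes`, `counts` (from [countUsableReads()] plus per-class
#'   tallies) and `segments` (named [Biostrings::DNAStringSet] of the
#'   usable segments, with read class in `mcols`).
#' @export
recruitReads <- function(reads, anchors, config = pipelineConfig(),
                         k = 13L) {
  reads <- filterReadsByLength(reads, config@minReadLength)
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  n <- length(reads)
  have_delim <- !is.na(anchors@delimiter)
  delim_end_off <- if (have_delim) .delimLastCysEnd(anchors@delimiter) else NA
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rd <- as.character(reads[[i]])
    hits <- list(
      intronUp = locateAnchor(rd, anchors@intronUp, anchors@minIdentity,
                              anchors@minAnchorCoverage, k),
      delimiter = if (have_delim)
        locateAnchor(rd, anchors@delimiter, anchors@minIdentity,
                     anchors@minAnchorCoverage, k) else NULL,
      intronDown = locateAnchor(rd, anchors@intronDown, anchors@minIdentity,
                                anchors@minAnchorCoverage, k))
    cls <- classifyRead(hits)
    got <- !vapply(hits, is.null, logical(1))
    ori <- if (any(got)) hits[got][[1]]$strand else "+"
    span <- if (cls != "NONE") .segmentSpan(cls, hits, delim_end_off)
            else NULL
    if (cls != "NONE" && is.null(span)) cls <- "NONE"  # inconsistent order
    out[[i]] <- new("RecruitedRead", readId = ids[i], bases = rd,
                    readClass = cls, orientation = ori,
                    segStart = if (is.null(span)) NA_integer_ else span[1],
                    segEnd = if (is.null(span)) NA_integer_ else span[2],
                    hits = hits)
  }
  classes <- vapply(out, readClass, character(1))
  usable <- which(classes != "NONE")
  segments <- Biostrings::DNAStringSet(
    vapply(out[usable], function(r) as.character(segmentSeq(r)),
           character(1)))
  names(segments) <- ids[usable]
  S4Vectors::mcols(segments) <- S4Vectors::DataFrame(
    class = classes[usable])
  tallies <- c(FULL = sum(classes == "FULL"),
               TYPE_I = sum(classes == "TYPE_I"),
               TYPE_II = sum(classes == "TYPE_II"),
               NONE = sum(classes == "NONE"))
  list(reads = out, classes = classes,
       counts = c(countUsableReads(classes), tallies),
       segments = segments)
}
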
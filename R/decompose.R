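# Translation, CysD delimiter finding, repeat-unit decomposition and
# SNP/CNV comparison of two individuals' domains.

#' Translate an exon with the standard genetic code
#'
#' @param dna DNA (character or XString).
#' @param frame 0, 1 or 2: bases skipped before the first codon; a
#'   trailing incomplete codon is dropped.
#' @return Protein as a character scalar; internal stop codons are
#'   rendered `*` and their count is attached as `attr(, "stops")`.
#' @examples
#' translateExon("ATGCCA")       # "MP"
#' translateExon("ATGCCA", 1)    # "C"
#' @export
translateExon <- function(dna, frame = 0L) {
  dna <- toupper(as.character(dna))
  if (nchar(dna) - frame < 3L) stop("fewer than one codon after the frame")
  prot <- .translateDNA(dna, frame)
  structure(prot, stops = .countStops(prot))
}

#' Find CysD islands in a domain protein
#'
#' Slides the CysD reference over the protein allowing up to
#' `max_mismatch_fraction` substitutions; overlapping hits are reduced
#' greedily left to right. Each hit reports the position of the last
#' cysteine inside the matched span - the delimiter residue between
#' upstream and downstream repeat regions.
#'
#' @param protein domain protein (character or AAString).
#' @param cysd_reference CysD reference protein; must contain a cysteine.
#' @param max_mismatch_fraction maximum substitution fraction.
#' @return data.frame sorted by position: `start`, `end` (0-based
#'   half-open), `identity`, `delimiter_pos` (0-based position of the last
#'   cysteine in the span).
#' @export
findCysD <- function(protein, cysd_reference, max_mismatch_fraction = 0.1) {
  protein <- as.character(protein)
  ref <- as.character(cysd_reference)
  if (!grepl("C", ref, fixed = TRUE))
    stop("CysD reference contains no cysteine")
  maxmm <- floor(max_mismatch_fraction * nchar(ref))
  m <- Biostrings::matchPattern(Biostrings::AAString(ref),
                                Biostrings::AAString(protein),
                                max.mismatch = maxmm, with.indels = FALSE)
  if (!length(m))
    return(data.frame(start = integer(0), end = integer(0),
                      identity = numeric(0), delimiter_pos = integer(0)))
  st <- BiocGenerics::start(m); en <- BiocGenerics::end(m)
  o <- order(st)
  st <- st[o]; en <- en[o]
  keep <- logical(length(st))
  last_end <- 0L
  for (i in seq_along(st)) {
    if (st[i] > last_end) { keep[i] <- TRUE; last_end <- en[i] }
  }
  st <- st[keep]; en <- en[keep]
  hit_seq <- substring(protein, st, en)
  refc <- .chars(ref)
  ident <- vapply(hit_seq,
                  function(h) mean(.chars(h) == refc), numeric(1))
  delim <- vapply(hit_seq, function(h) {
    w <- which(.chars(h) == "C")
    if (length(w)) max(w) else NA_integer_
  }, numeric(1))
  data.frame(start = st - 1L, end = en,
             identity = unname(ident),
             delimiter_pos = as.integer(st - 1L + delim - 1L))
}

.emptyBlocks <- function() {
  data.frame(kind = character(0), start = integer(0), end = integer(0),
             seq = character(0), stringsAsFactors = FALSE)
}

.mkDecomposition <- function(blocks) {
  rownames(blocks) <- NULL
  new("RepeatDecomposition", blocks = blocks,
      unitLengths = as.integer(nchar(blocks$seq[blocks$kind == "TR"])))
}

#' Decompose a repeat region by a start motif
#'
#' Repeat units begin at successive occurrences of the motif (the "PS"
#' rule of MUC2's upstream repeat array); residues before the first
#' occurrence form the HEAD. An occurrence that would create a unit
#' shorter than `min_unit` or longer than `max_unit` is skipped and its
#' span absorbed into the previous unit. The last unit runs to the end of
#' the segment.
#'
#' @param segment protein segment (character or AAString).
#' @param motif start motif (>= 2 residues).
#' @param min_unit,max_unit accepted unit length range in amino acids.
#' @return A [RepeatDecomposition-class].
#' @export
decomposeByStartMotif <- function(segment, motif = "PS", min_unit = 4L,
                                  max_unit = 40L) {
  segment <- as.character(segment)
  stopifnot(nchar(motif) >= 2L)
  n <- nchar(segment)
  if (n == 0L) return(.mkDecomposition(.emptyBlocks()))
  occ <- gregexpr(motif, segment, fixed = TRUE)[[1]]
  if (occ[1] == -1L) {
    blocks <- data.frame(kind = "HEAD", start = 0L, end = n, seq = segment,
                         stringsAsFactors = FALSE)
    return(.mkDecomposition(blocks))
  }
  occ <- as.integer(occ)           # 1-based motif starts
  kept <- occ[1]
  for (o in occ[-1]) {
    span <- o - kept[length(kept)]
    if (span >= min_unit && span <= max_unit) kept <- c(kept, o)
  }
  starts0 <- kept - 1L             # 0-based
  blocks <- list()
  if (starts0[1] > 0L)
    blocks[[1]] <- data.frame(kind = "HEAD", start = 0L, end = starts0[1],
                              seq = substr(segment, 1L, starts0[1]),
                              stringsAsFactors = FALSE)
  ends0 <- c(starts0[-1], n)
  for (i in seq_along(starts0)) {
    blocks[[length(blocks) + 1L]] <- data.frame(
      kind = "TR", start = starts0[i], end = ends0[i],
      seq = substr(segment, starts0[i] + 1L, ends0[i]),
      stringsAsFactors = FALSE)
  }
  .mkDecomposition(do.call(rbind, blocks))
}

#' Decompose a repeat region by periodic alignment to a unit consensus
#'
#' Greedy left-to-right cutting: at each cursor every cut length within
#' `length_tolerance` of the unit length (and the full remainder, for a
#' truncated terminal unit) is scored by aligning the window against the
#' unit consensus (match +1, mismatch -1, gap -1, the unit's tail free)
#' plus a register bonus for cuts after which the next unit starts like
#' the unit consensus; the best-scoring cut wins, ties to the shortest.
#' Cutting stops when the best score falls below `floor_frac` of the
#' aligned length; the remainder becomes TAIL. Handles length-variant
#' units (22/24 aa among 23-aa copies) and truncated terminal units
#' (including suffix-only partial copies at the segment end).
#'
#' @param segment protein segment (character or AAString).
#' @param unit_consensus canonical unit protein (>= 4 residues).
#' @param length_tolerance allowed deviation from the unit length (aa).
#' @param floor_frac acceptance floor as a fraction of the aligned length.
#' @return A [RepeatDecomposition-class].
#' @export
decomposePeriodic <- function(segment, unit_consensus, length_tolerance = 3L,
                              floor_frac = 0.5) {
  segment <- as.character(segment)
  unit <- as.character(unit_consensus)
  L <- nchar(unit)
  stopifnot(L >= 4L)
  n <- nchar(segment)
  blocks <- list()
  cursor <- 0L
  ustart <- substr(unit, 1L, 2L)
  while (cursor < n) {
    remaining <- n - cursor
    cand <- seq.int(max(1L, L - length_tolerance),
                    min(L + length_tolerance, remaining))
    if (remaining < L - length_tolerance) cand <- remaining
    best <- NULL
    for (len in cand) {
      win <- substr(segment, cursor + 1L, cursor + len)
      terminal <- len == remaining
      al <- .nw_align_cpp(unit, win, 1, -1, -1, band = 0,
                          free_a_end = TRUE, free_a_start = terminal)
      # register bonus: the residues after the cut should look like a
      # unit start, which disambiguates where a length variant ends
      sc <- al$score
      if (!terminal) {
        nxt <- substr(segment, cursor + len + 1L, cursor + len + 2L)
        sc <- sc + sum(.chars(nxt) == .chars(substr(ustart, 1L,
                                                    nchar(nxt))))
      }
      if (is.null(best) || sc > best$sc) best <- list(len = len, sc = sc,
                                                      raw = al$score)
    }
    if (best$raw < floor_frac * min(L, best$len)) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        kind = "TAIL", start = cursor, end = n,
        seq = substr(segment, cursor + 1L, n), stringsAsFactors = FALSE)
      break
    }
    blocks[[length(blocks) + 1L]] <- data.frame(
      kind = "TR", start = cursor, end = cursor + best$len,
      seq = substr(segment, cursor + 1L, cursor + best$len),
      stringsAsFactors = FALSE)
    cursor <- cursor + best$len
  }
  if (!length(blocks)) return(.mkDecomposition(.emptyBlocks()))
  .mkDecomposition(do.call(rbind, blocks))
}

# unit identity = LCS matches / longer length, memoized
.unitIdentity <- function(u, v, memo) {
  if (u == v) return(1)
  key <- paste0(u, "\r", v)
  got <- memo[[key]]
  if (!is.null(got)) return(got)
  al <- .nw_align_cpp(u, v, 1, 0, 0, band = 0)
  id <- sum(.chars(al$a) == .chars(al$b) &
              .chars(al$a) != "-") / max(nchar(u), nchar(v))
  memo[[key]] <- id
  id
}

.snpsBetweenUnits <- function(ua, ub, unit_index) {
  if (nchar(ua) == nchar(ub)) {
    ca <- .chars(ua); cb <- .chars(ub)
    d <- which(ca != cb)
    if (!length(d)) return(NULL)
    return(data.frame(unit = unit_index, offset = d - 1L,
                      a = ca[d], b = cb[d], stringsAsFactors = FALSE))
  }
  al <- .nw_align_cpp(ua, ub, 1, -1, -1, band = 0)
  ca <- .chars(al$a); cb <- .chars(al$b)
  apos <- cumsum(ca != "-")
  d <- which(ca != cb & ca != "-" & cb != "-")
  if (!length(d)) return(NULL)
  data.frame(unit = unit_index, offset = apos[d] - 1L,
             a = ca[d], b = cb[d], stringsAsFactors = FALSE)
}

#' Compare two repeat decompositions (SNPs and copy-number events)
#'
#' The two unit lists are aligned as token sequences (substitution cost 0
#' for units at identity >= 0.9, else 1 - identity; gap 0.45 per unit, so
#' a whole-unit indel is preferred over matching two dissimilar units).
#' Matched units are compared residue-wise into SNP records; unmatched
#' runs become CNV events with signed copy delta (positive: the second
#' decomposition has more copies).
#'
#' @param a,b [RepeatDecomposition-class] objects of homologous segments.
#' @param sim_zero identity at or above which two units are treated as
#'   the same unit (substitution cost 0).
#' @param gap_cost cost of leaving one unit unmatched.
#' @return A [DomainComparison-class].
#' @export
compareDecompositions <- function(a, b, sim_zero = 0.9, gap_cost = 0.45) {
  ua <- trUnits(a); ub <- trUnits(b)
  n <- length(ua); m <- length(ub)
  memo <- new.env(parent = emptyenv())
  subcost <- function(i, j) {
    id <- .unitIdentity(ua[i], ub[j], memo)
    if (id >= sim_zero) 0 else 1 - id
  }
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1L] <- (0:n) * gap_cost
  D[1L, ] <- (0:m) * gap_cost
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- min(D[i, j] + subcost(i, j),
                               D[i, j + 1L] + gap_cost,
                               D[i + 1L, j] + gap_cost)
    }
  }
  # backward traceback, diagonal preferred on ties
  ops <- character(0)
  i <- n; j <- m
  eps <- 1e-9
  while (i > 0L || j > 0L) {
    cur <- D[i + 1L, j + 1L]
    if (i > 0L && j > 0L &&
        abs(D[i, j] + subcost(i, j) - cur) < eps) {
      ops <- c("M", ops); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && abs(D[i, j + 1L] + gap_cost - cur) < eps) {
      ops <- c("A", ops); i <- i - 1L          # unit only in a
    } else {
      ops <- c("B", ops); j <- j - 1L          # unit only in b
    }
  }
  snps <- list(); cnv <- list()
  i <- 0L; j <- 0L
  runop <- ""; runlen <- 0L; runafter <- 0L; runseq <- ""
  flush <- function() {
    if (runlen > 0L) {
      cnv[[length(cnv) + 1L]] <<- data.frame(
        after_unit = runafter,
        delta = if (runop == "B") runlen else -runlen,
        unit_seq = runseq, stringsAsFactors = FALSE)
    }
    runop <<- ""; runlen <<- 0L
  }
  for (op in ops) {
    if (op == "M") {
      flush()
      i <- i + 1L; j <- j + 1L
      s <- .snpsBetweenUnits(ua[i], ub[j], i)
      if (!is.null(s)) snps[[length(snps) + 1L]] <- s
    } else {
      if (op != runop) { flush(); runop <- op; runafter <- i
                         runseq <- if (op == "B") ub[j + 1L] else ua[i + 1L] }
      runlen <- runlen + 1L
      if (op == "A") i <- i + 1L else j <- j + 1L
    }
  }
  flush()
  snps <- if (length(snps)) do.call(rbind, snps)
          else data.frame(unit = integer(0), offset = integer(0),
                          a = character(0), b = character(0),
                          stringsAsFactors = FALSE)
  cnv <- if (length(cnv)) do.call(rbind, cnv)
         else data.frame(after_unit = integer(0), delta = integer(0),
                         unit_seq = character(0), stringsAsFactors = FALSE)
  new("DomainComparison", snps = snps, cnv = cnv)
}
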
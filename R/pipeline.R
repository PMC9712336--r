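# The full consensus pipeline: recruit -> align -> majority consensus ->
# translation-guided frameshift polish -> decomposition -> estimator
# inputs. When TYPE_I / TYPE_II reads are present the upstream and
# downstream parts are built separately and stitched at the CysD
# delimiter's last cysteine; when every usable read is FULL a single
# joint alignment is built.

.noCoveringReads <- function(msg) {
  stop(errorCondition(msg, class = c("mucintr_no_covering_reads",
                                     "error", "condition")))
}

.mapSpanThroughAlignment <- function(al, span) {
  # map a 0-based half-open span on sequence a to sequence b coordinates
  ca <- .chars(al$a); cb <- .chars(al$b)
  apos <- cumsum(ca != "-"); bpos <- cumsum(cb != "-")
  cols <- which(ca != "-" & apos > span[1] & apos <= span[2])
  if (!length(cols)) return(c(0L, 0L))
  c(bpos[cols[1]] - (cb[cols[1]] != "-"), bpos[cols[length(cols)]])
}

.consPart <- function(track, from, to) {
  # subset of a ConsensusTrack, 0-based half-open
  new("ConsensusTrack",
      sequence = substr(track@sequence, from + 1L, to),
      depth = track@depth[seq.int(from + 1L, to)],
      support = track@support[seq.int(from + 1L, to)])
}

.concatTracks <- function(a, b) {
  new("ConsensusTrack", sequence = paste0(a@sequence, b@sequence),
      depth = c(a@depth, b@depth), support = c(a@support, b@support))
}

# Upstream / downstream sub-segment of a FULL recruited read. Rows are
# padded 30 bases past the island boundaries so the later stitch cut at
# the last cysteine falls in the interior of each part consensus, never
# on its ragged edge.
.fullPartSpans <- function(r, delim_end_off) {
  h <- r@hits
  if (is.null(h$delimiter))
    return(list(up = c(r@segStart, r@segEnd), down = c(r@segStart, r@segEnd)))
  list(up = c(h$intronUp$start, min(r@segEnd, h$delimiter$end + 30L)),
       down = c(max(r@segStart, h$delimiter$start - 30L),
                h$intronDown$end))
}

.orientedRead <- function(r) {
  if (r@orientation == "-") .revcomp(r@bases) else r@bases
}

#' Run the full consensus pipeline
#'
#' Chains read recruitment, zero-gap-penalty multiple alignment,
#' majority-vote consensus, translation-guided frameshift polishing,
#' repeat decomposition of the translated exon, per-position accuracy
#' bounds, and the single-T estimator inputs. Deterministic for fixed
#' inputs and configuration.
#'
#' @param reads [Biostrings::DNAStringSet] or character vector of reads.
#' @param anchors an [AnchorSet-class] (introns + optional delimiter).
#' @param config a [PipelineConfig-class].
#' @param unit_consensus optional canonical repeat-unit protein; when
#'   given, repeat regions are decomposed periodically against it,
#'   otherwise by the start-motif rule.
#' @param cysd_references protein sequences of the locus's CysD islands
#'   (config inputs, as for real loci they come from reference
#'   annotation); default: the translated delimiter anchor only.
#' @param motif,min_unit,max_unit start-motif decomposition parameters.
#' @param verbose log per-stage counters to stderr.
#' @return A [PipelineReport-class].
#' @export
runPipeline <- function(reads, anchors, config = pipelineConfig(),
                        unit_consensus = NULL, cysd_references = NULL,
                        motif = "PS", min_unit = 4L, max_unit = 40L,
                        verbose = TRUE) {
  say <- function(...) if (verbose) message("[mucintr] ", ...)
  rec <- recruitReads(reads, anchors, config)
  cnt <- rec$counts
  say("recruited: FULL=", cnt[["FULL"]], " TYPE_I=", cnt[["TYPE_I"]],
      " TYPE_II=", cnt[["TYPE_II"]], " NONE=", cnt[["NONE"]],
      " -> builders ", cnt[["upstream"]], "/", cnt[["downstream"]])
  if (length(rec$segments) == 0L)
    .noCoveringReads("no covering reads: no read carries the anchor pair")
  if (cnt[["upstream"]] == 0L || cnt[["downstream"]] == 0L)
    .noCoveringReads("no covering reads for one side of the delimiter")

  split_build <- cnt[["TYPE_I"]] > 0L || cnt[["TYPE_II"]] > 0L
  have_delim <- !is.na(anchors@delimiter)
  delim_end_off <- if (have_delim) .delimLastCysEnd(anchors@delimiter) else NA

  if (!split_build) {
    rcs <- refineConsensus(as.character(rec$segments), config@match,
                           config@mismatch, config@gap, with_msa = FALSE)
    cons <- rcs$consensus
    say("single joint alignment: ", length(rec$segments), " rows, ",
        nchar(cons@sequence), " bp consensus")
  } else {
    if (!have_delim)
      .noCoveringReads("partial reads present but no delimiter anchor")
    up_rows <- character(0); down_rows <- character(0)
    for (r in rec$reads) {
      cls <- readClass(r)
      if (cls == "NONE") next
      seq <- .orientedRead(r)
      if (cls == "FULL") {
        sp <- .fullPartSpans(r, delim_end_off)
        up_rows <- c(up_rows, substr(seq, sp$up[1] + 1L, sp$up[2]))
        down_rows <- c(down_rows, substr(seq, sp$down[1] + 1L, sp$down[2]))
      } else if (cls == "TYPE_I") {
        endp <- min(nchar(seq), r@hits$delimiter$end + 30L)
        up_rows <- c(up_rows, substr(seq, r@segStart + 1L, endp))
      } else {
        startp <- max(0L, r@hits$delimiter$start - 30L)
        down_rows <- c(down_rows, substr(seq, startp + 1L, r@segEnd))
      }
    }
    up_cons <- refineConsensus(up_rows, config@match, config@mismatch,
                               config@gap, with_msa = FALSE)$consensus
    down_cons <- refineConsensus(down_rows, config@match, config@mismatch,
                                 config@gap, with_msa = FALSE)$consensus
    hit_up <- locateAnchor(up_cons@sequence, anchors@delimiter,
                           anchors@minIdentity, anchors@minAnchorCoverage)
    hit_down <- locateAnchor(down_cons@sequence, anchors@delimiter,
                             anchors@minIdentity, anchors@minAnchorCoverage)
    if (is.null(hit_up) || is.null(hit_down))
      .noCoveringReads("delimiter not recovered in a part consensus")
    up_cut <- .mapAnchorEnd(hit_up, delim_end_off)
    down_cut <- .mapAnchorEnd(hit_down, delim_end_off)
    cons <- .concatTracks(.consPart(up_cons, 0L, up_cut),
                          .consPart(down_cons, down_cut,
                                    nchar(down_cons@sequence)))
    say("stitched parts at delimiter: ", up_cut, " | ", down_cut)
  }

  segments <- as.character(rec$segments)

  hu <- locateAnchor(cons@sequence, anchors@intronUp, anchors@minIdentity,
                     anchors@minAnchorCoverage)
  hd <- locateAnchor(cons@sequence, anchors@intronDown, anchors@minIdentity,
                     anchors@minAnchorCoverage)
  if (is.null(hu) || is.null(hd) || hu$end >= hd$start)
    .noCoveringReads("intron anchors not recovered on the consensus")
  exon_span <- c(hu$end, hd$start)

  # realign / repair rounds: each round re-flags against the edited
  # sequence; stop at a fixed point
  cur <- cons@sequence
  span <- exon_span
  suspects <- .emptySuspects()
  all_edits <- list()
  resolved <- TRUE
  locked <- integer(0)
  for (round in 1:8) {
    sus <- realignAndFlag(cur, segments)
    if (round == 1L) suspects <- sus
    pol <- correctFrameshifts(cur, span, sus, blocked = locked)
    cur <- pol$sequence
    span <- pol$exon_span
    resolved <- pol$resolved
    if (nrow(pol$edits) == 0L) break
    all_edits[[round]] <- pol$edits
    # a decided site stays decided: record edit positions (shifting the
    # earlier ones as later edits move coordinates)
    for (i in seq_len(nrow(pol$edits))) {
      p <- pol$edits$position[i]
      shift <- switch(pol$edits$op[i], insert = 1L, delete = -1L, 0L)
      locked[locked > p] <- locked[locked > p] + shift
      locked <- c(locked, p)
    }
  }
  edits_df <- if (length(all_edits)) do.call(rbind, all_edits)
              else data.frame(position = integer(0), op = character(0),
                              base = character(0), stringsAsFactors = FALSE)
  rownames(edits_df) <- NULL
  pol <- list(sequence = cur, exon_span = span, edits = edits_df,
              resolved = resolved)
  say("frameshift edits: ", nrow(pol$edits),
      if (pol$resolved) " (resolved)" else " (UNRESOLVED)")
  exon <- substr(pol$sequence, pol$exon_span[1] + 1L, pol$exon_span[2])
  prot <- translateExon(exon)

  # decomposition: islands first, then each inter-island repeat segment
  if (is.null(cysd_references) && have_delim)
    cysd_references <- .translateDNA(anchors@delimiter)
  hits <- NULL
  if (!is.null(cysd_references)) {
    hits <- do.call(rbind, lapply(cysd_references, function(ref)
      findCysD(prot, ref, 0.1)))
    if (!is.null(hits) && nrow(hits)) {
      hits <- hits[order(hits$start), , drop = FALSE]
      keep <- logical(nrow(hits)); last_end <- 0L
      for (i in seq_len(nrow(hits)))
        if (hits$start[i] >= last_end) { keep[i] <- TRUE
                                         last_end <- hits$end[i] }
      hits <- hits[keep, , drop = FALSE]
    }
  }
  bounds <- if (is.null(hits) || !nrow(hits)) cbind(integer(0), integer(0))
            else cbind(hits$start, hits$end)
  np <- nchar(prot)
  blocks <- list()
  segs <- rbind(if (nrow(bounds)) cbind(c(0L, bounds[, 2]),
                                        c(bounds[, 1], np))
                else cbind(0L, np))
  decompose_one <- function(piece) {
    if (!is.null(unit_consensus))
      decomposePeriodic(piece, unit_consensus)
    else decomposeByStartMotif(piece, motif, min_unit, max_unit)
  }
  for (k in seq_len(nrow(segs))) {
    from <- segs[k, 1]; to <- segs[k, 2]
    if (from < to) {
      piece <- substr(prot, from + 1L, to)
      d <- decompose_one(piece)
      pb <- blockTable(d)
      if (nrow(pb)) {
        pb$start <- pb$start + from; pb$end <- pb$end + from
        if (k == 1L) pb$kind[pb$kind == "TAIL"] <- "HEAD"
        blocks[[length(blocks) + 1L]] <- pb
      }
    }
    if (k <= nrow(bounds)) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        kind = "CYSD", start = bounds[k, 1], end = bounds[k, 2],
        seq = substr(prot, bounds[k, 1] + 1L, bounds[k, 2]),
        stringsAsFactors = FALSE)
    }
  }
  blocks <- do.call(rbind, blocks)
  if (is.null(blocks) || !nrow(blocks)) {
    blocks <- if (np > 0L)
      data.frame(kind = "HEAD", start = 0L, end = np, seq = prot,
                 stringsAsFactors = FALSE)
    else .emptyBlocks()
  }
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  dec <- .mkDecomposition(blocks)
  say("decomposition: ", sum(blocks$kind == "TR"), " TR units, ",
      sum(blocks$kind == "CYSD"), " CysD islands")

  acc <- accuracyBounds(cons@depth, config@pLow, config@pHigh)

  # estimator inputs: single-T events of the TR region, and the same
  # region on the raw consensus for the invariance check
  trb <- blocks[blocks$kind == "TR", , drop = FALSE]
  tr_dna <- if (nrow(trb))
    .collapse(substring(exon, trb$start * 3L + 1L, trb$end * 3L)) else ""
  est <- list(t_events = NA_integer_, rate = NA_real_,
              n_units = nrow(trb), anomalies = integer(0),
              t_raw = NA_integer_, t_invariant = NA)
  if (nrow(trb)) {
    cnt_t <- countTEvents(tr_dna)
    est$t_events <- cnt_t$t_events
    est$anomalies <- cnt_t$multi_run_positions
    est$rate <- cnt_t$t_events / nrow(trb)
    raw_exon <- substr(cons@sequence, exon_span[1] + 1L, exon_span[2])
    al <- .nw_align_cpp(exon, raw_exon, 1, -1, -1,
                        band = .autoBand(nchar(exon), nchar(raw_exon)))
    raw_tr <- .collapse(apply(trb, 1, function(row) {
      sp <- .mapSpanThroughAlignment(
        al, c(as.integer(row[["start"]]) * 3L,
              as.integer(row[["end"]]) * 3L))
      substr(raw_exon, sp[1] + 1L, sp[2])
    }))
    est$t_raw <- countTEvents(raw_tr)$t_events
    est$t_invariant <- est$t_raw == est$t_events
    say("estimator: ", est$t_events, " single-T events over ",
        est$n_units, " units (raw consensus: ", est$t_raw, ")")
  }

  new("PipelineReport", consensus = cons, polished = pol$sequence,
      exonSpan = as.integer(pol$exon_span), editLog = pol$edits,
      resolved = pol$resolved, suspects = suspects, accuracy = acc,
      decomposition = dec,
      counts = c(cnt, edits = nrow(pol$edits)),
      estimator = est, config = config, version = "1.0")
}
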
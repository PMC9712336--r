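# Consensus polishing: realign the consensus to every read segment, flag
# homopolymer runs whose read-supported length disagrees, and repair
# frameshifts inside the exon by translation. The per-position accuracy
# of a majority consensus is bounded by 1 - p^depth for per-read error
# rate p: all aligned reads must fail together for the column to be wrong.

.emptySuspects <- function() {
  data.frame(position = integer(0), kind = character(0),
             run_base = character(0), run_length = integer(0),
             alt_length = integer(0), evidence = numeric(0),
             gain = numeric(0), ins_seq = character(0),
             stringsAsFactors = FALSE)
}

#' Realign consensus to reads and flag suspect indel loci
#'
#' Every read segment is realigned against the consensus with indel
#' placement normalized to the end of homopolymer runs. For every run of
#' the consensus, each covering read then supports a run length (the
#' consensus run length minus its aligned gaps in the run, plus its
#' inserted copies of the run base at the run end); where the modal
#' read-supported length differs from the consensus run length the run
#' is flagged as a MISSING_BASE / EXTRA_BASE site - the slippage
#' ambiguity of majority voting in which some reads give "- - - A" and
#' others "A - - -" and the base is erased (or a redundant base kept).
#' Read insertions not adjacent to a run of the same base are flagged as
#' standalone MISSING_BASE sites with the modal inserted string.
#'
#' @param consensus consensus DNA (character, XString or
#'   [ConsensusTrack-class]).
#' @param segments read segments (character vector or DNAStringSet).
#' @param band alignment band half-width (`NULL`: auto).
#' @param min_evidence minimum fraction of covering reads that must
#'   support the alternative for a flag to be raised.
#' @return data.frame sorted by position: `position` (0-based; for
#'   EXTRA_BASE the consensus base to drop, for MISSING_BASE the
#'   insertion point), `kind`, `run_base`, `run_length` (consensus run
#'   length at the site), `alt_length` (modal read-supported length),
#'   `evidence` (fraction of covering reads supporting the modal
#'   alternative), `ins_seq` (bases to insert, MISSING_BASE only).
#'   Error-free data give zero rows.
#' @export
realignAndFlag <- function(consensus, segments, band = NULL,
                           min_evidence = 0.25) {
  if (methods::is(consensus, "ConsensusTrack")) consensus <- consensus@sequence
  consensus <- as.character(consensus)
  if (methods::is(segments, "XStringSet")) segments <- as.character(segments)
  stopifnot(nzchar(consensus), length(segments) >= 1L)
  n <- nchar(consensus)
  cch <- .chars(consensus)
  cr <- rle(cch)
  nrun <- length(cr$lengths)
  run_id <- rep(seq_len(nrun), cr$lengths)
  run_end <- cumsum(cr$lengths)
  run_start <- run_end - cr$lengths + 1L
  run_str <- strrep(cr$values, cr$lengths)
  nseg <- length(segments)
  n_agree <- integer(nrun)              # reads matching the run exactly
  votes <- vector("list", nrun)         # divergent window strings
  for (si in seq_len(nseg)) {
    seg <- segments[[si]]
    schars <- .chars(seg)
    al <- .alignSegToCons(consensus, seg, band)
    if (is.null(al)) next
    norm <- .pushGapsRight(.chars(al$a), .chars(al$b))
    ca <- norm$a; cb <- norm$b
    cpos <- cumsum(ca != "-") + al$offset
    bpos <- cumsum(cb != "-")
    readpos <- rep(NA_integer_, n)
    ok <- ca != "-" & cb != "-"
    readpos[cpos[ok]] <- bpos[ok]
    # anchored window per run: the read bases strictly between the read
    # positions aligned to the consensus bases flanking the run
    pA <- c(NA_integer_, readpos)[run_start]       # readpos[s-1]
    pB <- c(readpos, NA_integer_)[run_end + 1L]    # readpos[e+1]
    usable <- !is.na(pA) & !is.na(pB)
    # runs untouched by any alignment difference match the consensus
    badp <- cpos[(ca != "-" & cb == "-") | (ok & ca != cb)]
    insp <- cpos[ca == "-"]
    dirty <- logical(nrun)
    badp <- badp[badp >= 1L & badp <= n]
    dirty[run_id[badp]] <- TRUE
    dirty[run_id[pmax(insp, 1L)]] <- TRUE
    dirty[run_id[pmin(insp + 1L, n)]] <- TRUE
    clean <- usable & !dirty
    n_agree[clean] <- n_agree[clean] + 1L
    for (r in which(usable & dirty)) {
      w <- if (pB[r] - 1L >= pA[r] + 1L)
        .collapse(schars[(pA[r] + 1L):(pB[r] - 1L)]) else ""
      if (w == run_str[r]) n_agree[r] <- n_agree[r] + 1L
      else votes[[r]] <- c(votes[[r]], w)
    }
  }
  recs <- list()
  for (r in seq_len(nrun)) {
    v <- votes[[r]]
    if (is.null(v)) next
    tab <- sort(table(v), decreasing = TRUE)
    modal <- names(tab)[1]
    nm <- as.integer(tab[1])
    if (nm < 2L) next
    # head-to-head support: the modal alternative against the reads that
    # agree with the consensus; scattered one-off read errors dilute
    # neither side
    ev <- nm / (nm + n_agree[r])
    if (ev < min_evidence) next
    # median criterion: does the modal string explain ALL read windows
    # (scattered ones included) better than the consensus string does?
    uq <- names(tab)
    cnt <- as.integer(tab)
    U0 <- run_str[r]
    d_cons <- as.integer(utils::adist(uq, U0))
    d_modal <- as.integer(utils::adist(uq, modal))
    gain <- sum(cnt * d_cons) - sum(cnt * d_modal) -
      n_agree[r] * as.integer(utils::adist(U0, modal))
    U <- run_str[r]; M <- modal
    # minimal prefix/suffix trim between consensus run and modal string
    lu <- nchar(U); lm <- nchar(M)
    p <- 0L
    while (p < min(lu, lm) &&
           substr(U, p + 1L, p + 1L) == substr(M, p + 1L, p + 1L)) p <- p + 1L
    s2 <- 0L
    while (s2 < min(lu, lm) - p &&
           substr(U, lu - s2, lu - s2) == substr(M, lm - s2, lm - s2))
      s2 <- s2 + 1L
    consRem <- substr(U, p + 1L, lu - s2)
    modalRem <- substr(M, p + 1L, lm - s2)
    s0 <- run_start[r] - 1L                  # 0-based run start
    if (!nzchar(consRem) && nzchar(modalRem)) {
      recs[[length(recs) + 1L]] <- data.frame(
        position = s0 + p, kind = "MISSING_BASE", run_base = cr$values[r],
        run_length = lu, alt_length = lm, evidence = ev,
        gain = gain, ins_seq = modalRem, stringsAsFactors = FALSE)
    } else if (nzchar(consRem) && !nzchar(modalRem)) {
      k <- nchar(consRem)
      recs[[length(recs) + 1L]] <- data.frame(
        position = s0 + p + k - 1L, kind = "EXTRA_BASE",
        run_base = cr$values[r], run_length = lu, alt_length = lm,
        evidence = ev, gain = gain, ins_seq = "",
        stringsAsFactors = FALSE)
    } else if (nchar(consRem) == nchar(modalRem) && nzchar(consRem)) {
      for (j in seq_len(nchar(consRem))) {
        cj <- substr(consRem, j, j); mj <- substr(modalRem, j, j)
        if (cj == mj) next
        recs[[length(recs) + 1L]] <- data.frame(
          position = s0 + p + j - 1L, kind = "SUBSTITUTION",
          run_base = cj, run_length = lu, alt_length = lm,
          evidence = ev, gain = gain, ins_seq = mj,
          stringsAsFactors = FALSE)
      }
    }
    # mixed-length replacements (rare) are left unflagged
  }
  if (!length(recs)) return(.emptySuspects())
  out <- do.call(rbind, recs)
  out <- out[order(out$position, -out$evidence), , drop = FALSE]
  # overlapping run windows key the same event twice (e.g. an inserted
  # base sits between two runs); keep the better-supported record
  if (nrow(out) > 1L) {
    drop <- logical(nrow(out))
    for (i in 2:nrow(out)) {
      j <- i - 1L
      if (!drop[j] && out$kind[i] == out$kind[j] &&
          out$ins_seq[i] == out$ins_seq[j] &&
          out$position[i] - out$position[j] <= 1L)
        drop[i] <- TRUE
    }
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

.countStops <- function(prot) sum(.chars(prot) == "*")

#' Correct homopolymer frameshifts by translation
#'
#' Two phases, both confined to flagged suspect loci. Majority phase:
#' every suspect supported by more than half of the covering reads is
#' applied outright - the realigned read majority at a run is a stronger
#' estimator than the column votes that produced the consensus.
#' Translation phase: the exon is translated in frame 0 from
#' `exon_span[1]`; at the first premature stop (or, failing that, a
#' 3-divisibility break at the exon end) every not-yet-exhausted suspect
#' at or before the disruption proposes its single-base insertion or
#' deletion, candidates are scored by the number of stop codons in a
#' look-ahead window downstream of the edit (fewest wins, ties to the
#' best-supported then smallest position), the winner is applied, and the
#' loop repeats.
#'
#' @param consensus consensus DNA (character or XString).
#' @param exon_span length-2 integer, 0-based half-open exon span on the
#'   consensus; the exon frame starts at `exon_span[1]`.
#' @param suspects data.frame from [realignAndFlag()].
#' @param look_ahead scoring window, in codons, downstream of an edit.
#' @param blocked positions (0-based) already decided by an earlier
#'   repair round; suspects within 6 bases are ignored so a site is
#'   decided at most once and repair rounds cannot oscillate.
#' @return list: `sequence` (edited consensus), `exon_span` (updated),
#'   `edits` (data.frame position/op/base, positions at application time),
#'   `resolved` (FALSE when a disruption could not be repaired).
#' @export
correctFrameshifts <- function(consensus, exon_span, suspects,
                               look_ahead = 200L, blocked = integer(0)) {
  seqstr <- as.character(consensus)
  s <- as.integer(exon_span[1]); e <- as.integer(exon_span[2])
  stopifnot(s >= 0L, e <= nchar(seqstr), s < e)
  sus <- suspects
  if (length(blocked) && nrow(sus)) {
    near <- vapply(sus$position, function(p) any(abs(p - blocked) <= 6L),
                   logical(1))
    sus <- sus[!near, , drop = FALSE]
  }
  if (is.null(sus$ins_seq))
    sus$ins_seq <- ifelse(sus$kind == "MISSING_BASE",
                          strrep(sus$run_base,
                                 pmax(sus$alt_length - sus$run_length, 1L)),
                          "")
  if (is.null(sus$evidence)) sus$evidence <- rep(1, nrow(sus))
  if (is.null(sus$gain))
    sus$gain <- ifelse(sus$evidence > 0.5, 2, 0)
  sus$capacity <- as.integer(ifelse(sus$kind == "MISSING_BASE",
                         pmax(nchar(sus$ins_seq), 1L),
                         ifelse(sus$kind == "SUBSTITUTION", 1L,
                                pmax(sus$run_length - sus$alt_length, 1L))))
  sus$applied <- rep(0L, nrow(sus))
  edits <- list()
  phase <- "translation"

  apply_edit <- function(ci) {
    if (sus$kind[ci] == "MISSING_BASE") {
      pos <- sus$position[ci] + sus$applied[ci]
      base <- substr(sus$ins_seq[ci], sus$applied[ci] + 1L,
                     sus$applied[ci] + 1L)
      seqstr <<- paste0(substr(seqstr, 1L, pos), base,
                        substr(seqstr, pos + 1L, nchar(seqstr)))
      shift <- 1L
      op <- "insert"
    } else if (sus$kind[ci] == "SUBSTITUTION") {
      pos <- sus$position[ci]
      base <- sus$ins_seq[ci]
      substr(seqstr, pos + 1L, pos + 1L) <<- base
      shift <- 0L
      op <- "substitute"
    } else {
      pos <- sus$position[ci] - sus$applied[ci]
      base <- substr(seqstr, pos + 1L, pos + 1L)
      seqstr <<- paste0(substr(seqstr, 1L, pos),
                        substr(seqstr, pos + 2L, nchar(seqstr)))
      shift <- -1L
      op <- "delete"
    }
    edits[[length(edits) + 1L]] <<- data.frame(
      position = pos, op = op, base = base, stringsAsFactors = FALSE)
    if (phase == "majority") {
      inv_kind <- switch(op, insert = "EXTRA_BASE",
                         delete = "MISSING_BASE", "SUBSTITUTION")
      inv_seq <- switch(op, insert = "", delete = base,
                        sus$run_base[ci])
      sus <<- rbind(sus, data.frame(
        position = pos, kind = inv_kind, run_base = base,
        run_length = 1L, alt_length = if (op == "insert") 0L else 2L,
        evidence = 0.5, gain = 0, ins_seq = inv_seq,
        capacity = 1L, applied = 0L,
        cluster = max(sus$cluster, 0L) + nrow(sus) + 1L,
        stringsAsFactors = FALSE))
    }
    sus$applied[ci] <<- sus$applied[ci] + 1L
    sus$position[sus$position > pos] <<-
      sus$position[sus$position > pos] + shift
    if (pos < s) s <<- s + shift
    if (pos < e) e <<- e + shift
    invisible(NULL)
  }

  # Nearby suspects are usually alternative placements of one underlying
  # indel (score-equivalent alignments in quasi-repeat context split the
  # read votes); cluster them so one event gets one repair.
  ord <- order(sus$position)
  cluster <- integer(nrow(sus))
  if (nrow(sus)) {
    cid <- 1L
    cluster[ord[1]] <- cid
    if (nrow(sus) > 1L) for (k in 2:length(ord)) {
      if (sus$position[ord[k]] - sus$position[ord[k - 1L]] > 4L) cid <- cid + 1L
      cluster[ord[k]] <- cid
    }
  }
  sus$cluster <- cluster
  exhaust_siblings <- function(ci) {
    sib <- which(sus$cluster == sus$cluster[ci] & seq_len(nrow(sus)) != ci &
                   sus$evidence <= 0.5)
    sus$capacity[sib] <<- sus$applied[sib]
  }

  # Majority phase: per cluster, the best-supported alternative wins when
  # a read majority backs it (individually, or combined over the
  # score-equivalent placements of one side). One repair per cluster per
  # call; callers iterate realign-and-flag until no edits remain, so
  # clusters holding several genuine events resolve over rounds with
  # fresh evidence.
  # Majority phase: per cluster the best-supported alternative (median
  # gain >= 2 over all read windows) wins outright. Each applied edit
  # registers its inverse as a candidate, so the later translation phase
  # can undo a majority call that turns out to break the reading frame.
  # Majority phase: per cluster the best-supported alternative (median
  # gain >= 2 over all read windows) wins outright. Each applied edit
  # registers its inverse as a candidate, so the later translation phase
  # can undo a majority call that turns out to break the reading frame.
  phase <- "majority"
  for (cl in unique(sus$cluster)) {
    idx <- which(sus$cluster == cl)
    strong <- idx[sus$gain[idx] >= 2]
    if (!length(strong)) next
    ci <- strong[which.max(sus$gain[strong])]
    while (sus$applied[ci] < sus$capacity[ci]) apply_edit(ci)
    sus$capacity[setdiff(idx, ci)] <- sus$applied[setdiff(idx, ci)]
  }
  phase <- "translation"

  apply_edit <- function(ci) {
    if (sus$kind[ci] == "MISSING_BASE") {
      pos <- sus$position[ci] + sus$applied[ci]
      base <- substr(sus$ins_seq[ci], sus$applied[ci] + 1L,
                     sus$applied[ci] + 1L)
      seqstr <<- paste0(substr(seqstr, 1L, pos), base,
                        substr(seqstr, pos + 1L, nchar(seqstr)))
      shift <- 1L
      op <- "insert"
    } else if (sus$kind[ci] == "SUBSTITUTION") {
      pos <- sus$position[ci]
      base <- sus$ins_seq[ci]
      substr(seqstr, pos + 1L, pos + 1L) <<- base
      shift <- 0L
      op <- "substitute"
    } else {
      pos <- sus$position[ci] - sus$applied[ci]
      base <- substr(seqstr, pos + 1L, pos + 1L)
      seqstr <<- paste0(substr(seqstr, 1L, pos),
                        substr(seqstr, pos + 2L, nchar(seqstr)))
      shift <- -1L
      op <- "delete"
    }
    edits[[length(edits) + 1L]] <<- data.frame(
      position = pos, op = op, base = base, stringsAsFactors = FALSE)
    if (phase == "majority") {
      inv_kind <- switch(op, insert = "EXTRA_BASE",
                         delete = "MISSING_BASE", "SUBSTITUTION")
      inv_seq <- switch(op, insert = "", delete = base,
                        sus$run_base[ci])
      sus <<- rbind(sus, data.frame(
        position = pos, kind = inv_kind, run_base = base,
        run_length = 1L, alt_length = if (op == "insert") 0L else 2L,
        evidence = 0.5, gain = 0, ins_seq = inv_seq,
        capacity = 1L, applied = 0L,
        cluster = max(sus$cluster, 0L) + nrow(sus) + 1L,
        stringsAsFactors = FALSE))
    }
    sus$applied[ci] <<- sus$applied[ci] + 1L
    sus$position[sus$position > pos] <<-
      sus$position[sus$position > pos] + shift
    if (pos < s) s <<- s + shift
    if (pos < e) e <<- e + shift
    invisible(NULL)
  }

  # Nearby suspects are usually alternative placements of one underlying
  # indel (score-equivalent alignments in quasi-repeat context split the
  # read votes); cluster them so one event gets one repair.
  ord <- order(sus$position)
  cluster <- integer(nrow(sus))
  if (nrow(sus)) {
    cid <- 1L
    cluster[ord[1]] <- cid
    if (nrow(sus) > 1L) for (k in 2:length(ord)) {
      if (sus$position[ord[k]] - sus$position[ord[k - 1L]] > 4L) cid <- cid + 1L
      cluster[ord[k]] <- cid
    }
  }
  sus$cluster <- cluster
  exhaust_siblings <- function(ci) {
    sib <- which(sus$cluster == sus$cluster[ci] & seq_len(nrow(sus)) != ci &
                   sus$evidence <= 0.5)
    sus$capacity[sib] <<- sus$applied[sib]
  }

  # Majority phase: per cluster, the best-supported alternative wins when
  # a read majority backs it (individually, or combined over the
  # score-equivalent placements of one side). One repair per cluster per
  # call; callers iterate realign-and-flag until no edits remain, so
  # clusters holding several genuine events resolve over rounds with
  # fresh evidence.
  # Majority phase: per cluster the best-supported alternative (median
  # gain >= 2 over all read windows) wins outright. Each applied edit
  # registers its inverse as a candidate, so the later translation phase
  # can undo a majority call that turns out to break the reading frame.
  # The application thresholds are asymmetric because the error model is:
  # deletions dominate and are boosted inside runs, so a read showing a
  # LONGER run than the consensus is strong evidence (spurious same-base
  # insertions are rare), while a shorter majority must be decisive
  # before a base is dropped.
  phase <- "majority"
  strong_call <- function(i) {
    (sus$kind[i] == "MISSING_BASE" & sus$evidence[i] >= 0.35 &
       sus$gain[i] >= 0) |
    (sus$kind[i] == "EXTRA_BASE" & sus$evidence[i] >= 0.65 &
       sus$gain[i] >= 2) |
    (sus$kind[i] == "SUBSTITUTION" & sus$evidence[i] > 0.5 &
       sus$gain[i] >= 2)
  }
  for (cl in unique(sus$cluster)) {
    idx <- which(sus$cluster == cl)
    strong <- idx[strong_call(idx)]
    if (!length(strong)) next
    ci <- strong[which.max(sus$gain[strong] + sus$evidence[strong])]
    while (sus$applied[ci] < sus$capacity[ci]) apply_edit(ci)
    sus$capacity[setdiff(idx, ci)] <- sus$applied[setdiff(idx, ci)]
  }
  phase <- "translation"

  budget <- sum(sus$capacity) + 5L
  seen <- character(0)
  resolved <- TRUE
  repeat {
    exon <- substr(seqstr, s + 1L, e)
    prot <- .translateDNA(exon)
    stars <- which(.chars(prot) == "*")
    frame_ok <- (e - s) %% 3L == 0L
    if (!length(stars) && frame_ok) break
    disruption <- if (length(stars)) s + (stars[1] - 1L) * 3L else e
    state <- paste(disruption, length(stars), (e - s) %% 3L,
                   paste(sus$applied, collapse = ","))
    cand <- which(sus$applied < sus$capacity & sus$position >= s &
                    sus$position <= disruption &
                    sus$position >= disruption - 3L * look_ahead &
                    sus$kind != "SUBSTITUTION")
    if (!length(cand) || budget <= 0L || state %in% seen) {
      resolved <- FALSE
      break
    }
    seen <- c(seen, state)
    need <- (3L - (e - s) %% 3L) %% 3L     # 0: frame fine, else insert need
    best <- NULL
    for (ci in cand) {
      if (sus$kind[ci] == "MISSING_BASE") {
        pos <- sus$position[ci] + sus$applied[ci]
        base <- substr(sus$ins_seq[ci], sus$applied[ci] + 1L,
                       sus$applied[ci] + 1L)
        seq2 <- paste0(substr(seqstr, 1L, pos), base,
                       substr(seqstr, pos + 1L, nchar(seqstr)))
        e2 <- e + 1L
        delta <- 1L
      } else {
        pos <- sus$position[ci] - sus$applied[ci]
        seq2 <- paste0(substr(seqstr, 1L, pos),
                       substr(seqstr, pos + 2L, nchar(seqstr)))
        e2 <- e - 1L
        delta <- -1L
      }
      # score: stops within the look-ahead window downstream of the edit,
      # with and without the edit; an edit must strictly improve
      from <- s + ((pos - s) %/% 3L) * 3L
      to <- min(e2, from + 3L * look_ahead)
      nstop <- .countStops(.translateDNA(substr(seq2, from + 1L, to)))
      nstop0 <- .countStops(.translateDNA(substr(seqstr, from + 1L,
                                                 min(e, to))))
      improves <- if (length(stars)) nstop < nstop0
                  else (need == 1L && delta == 1L) ||
                       (need == 2L && delta == -1L)
      if (!improves) next
      # rank: fewest remaining stops, then read support (median gain,
      # then head-to-head evidence), then smallest position
      key <- c(nstop, -sus$gain[ci], -sus$evidence[ci], pos)
      better <- is.null(best)
      if (!better) {
        nz <- which(key != best$key)
        better <- length(nz) > 0 && key[nz[1]] < best$key[nz[1]]
      }
      if (better) best <- list(ci = ci, pos = pos, key = key)
    }
    if (is.null(best)) {
      resolved <- FALSE
      break
    }
    apply_edit(best$ci)
    exhaust_siblings(best$ci)
    budget <- budget - 1L
  }
  edits <- if (length(edits)) do.call(rbind, edits)
           else data.frame(position = integer(0), op = character(0),
                           base = character(0), stringsAsFactors = FALSE)
  list(sequence = seqstr, exon_span = c(s, e), edits = edits,
       resolved = resolved)
}

#' Per-position accuracy bounds of a majority consensus
#'
#' With per-read error rate between `p_low` and `p_high`, a position
#' where `n` reads align is wrong only if all `n` fail, so its accuracy
#' lies in `[1 - p_high^n, 1 - p_low^n]`. At depth 7 and the default band
#' this gives the familiar 99.98-99.99% range.
#'
#' @param depth integer vector of per-position aligned-read counts
#'   (all >= 1).
#' @param p_low,p_high assumed per-base error band.
#' @return data.frame: `pos` (0-based), `depth`, `low`, `high` (exact
#'   fractional accuracies).
#' @examples
#' accuracyBounds(c(7, 6, 5))
#' @export
accuracyBounds <- function(depth, p_low = 0.15, p_high = 0.30) {
  if (any(depth < 1L)) stop("depth must be >= 1 everywhere (no aligned read)")
  stopifnot(p_low >= 0, p_low <= p_high, p_high < 1)
  data.frame(pos = seq_along(depth) - 1L, depth = as.integer(depth),
             low = 1 - p_high^depth, high = 1 - p_low^depth)
}

#' Display accuracy bounds as percentages
#'
#' @param bounds data.frame from [accuracyBounds()].
#' @param truncate FALSE (default) rounds half-up to 2 decimals; TRUE
#'   truncates instead (so 99.9998 prints as 99.99, not 100.00).
#' @return data.frame with `low_pct`, `high_pct` character columns.
#' @export
accuracyPercent <- function(bounds, truncate = FALSE) {
  f <- if (truncate) function(x) floor(x * 1e4) / 100 else .pct2
  data.frame(pos = bounds$pos,
             low_pct = sprintf("%.2f", f(bounds$low)),
             high_pct = sprintf("%.2f", f(bounds$high)))
}
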
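# Synthetic mucin-like loci and SMRT-like noisy reads.
#
# Protein blocks are encoded with a deterministic codon table keyed by
# (residue, position-in-block mod 3), so identical repeat units get
# identical DNA and the repeat structure is exact at DNA level. The table
# is chosen so the DNA never contains a "TT" doublet - the property real
# mucin TR DNA shows and the single-T repeat estimator relies on - while
# still carrying T-bearing codons (ACT, CCT, AGT ...), so that, as in real
# PTS-coding DNA, a frameshifted reading frame soon hits a stop codon and
# translation-guided repair has signal. Codons may end in T but only the
# starts-with-T codons of cysteine (TGC), tryptophan (TGG) and tyrosine
# (TAC) begin with T; before those the preceding codon is swapped to a
# non-T-ending variant so no TT doublet can form across a junction.
# Phenylalanine (TTT/TTC only) cannot be encoded and is rejected.

.CODONS <- list(
  A = c("GCT", "GCA", "GCC"),
  C = c("TGC", "TGC", "TGC"),
  D = c("GAT", "GAC", "GAC"),
  E = c("GAA", "GAG", "GAA"),
  G = c("GGT", "GGA", "GGC"),
  H = c("CAT", "CAC", "CAC"),
  I = c("ATA", "ATC", "ATC"),
  K = c("AAA", "AAG", "AAA"),
  L = c("CTA", "CTC", "CTG"),
  M = c("ATG", "ATG", "ATG"),
  N = c("AAT", "AAC", "AAC"),
  P = c("CCT", "CCA", "CCC"),
  Q = c("CAA", "CAG", "CAA"),
  R = c("CGT", "AGA", "CGC"),
  S = c("AGT", "AGC", "AGC"),
  T = c("ACT", "ACA", "ACC"),
  V = c("GTA", "GTC", "GTG"),
  W = c("TGG", "TGG", "TGG"),
  Y = c("TAC", "TAC", "TAC")
)

# non-T-ending fallback used before a starts-with-T codon
.SAFE_CODON <- c(A = "GCA", C = "TGC", D = "GAC", E = "GAA", G = "GGA",
                 H = "CAC", I = "ATA", K = "AAA", L = "CTA", M = "ATG",
                 N = "AAC", P = "CCA", Q = "CAA", R = "AGA", S = "AGC",
                 T = "ACA", V = "GTA", W = "TGG", Y = "TAC")

.DEFAULT_UNIT <- "PSTTPITTTTMVTPTPTPTGTQT"  # 23 aa, starts with "PS"

.PTS_FILL <- c(P = 5, T = 6, S = 5, A = 2, G = 2, V = 1, Q = 1, E = 1,
               N = 1, H = 1)

.encodeProtein <- function(protein) {
  res <- .chars(protein)
  bad <- setdiff(unique(res), names(.CODONS))
  if (length(bad))
    stop("cannot encode residue(s) ", paste(bad, collapse = ", "),
         " without introducing stop codons or TT doublets", call. = FALSE)
  k <- (seq_along(res) - 1L) %% 3L + 1L
  codons <- vapply(seq_along(res),
                   function(i) .CODONS[[res[i]]][k[i]], character(1))
  # guard junctions: a starts-with-T codon must not follow an ends-with-T
  # codon, so the preceding codon drops to its non-T-ending variant
  if (length(codons) > 1L) {
    startsT <- substr(codons, 1L, 1L) == "T"
    endsT <- substr(codons, 3L, 3L) == "T"
    fix <- which(endsT[-length(codons)] & startsT[-1L])
    codons[fix] <- .SAFE_CODON[res[fix]]
  }
  .collapse(codons)
}

.randomProtein <- function(n) {
  .collapse(sample(names(.PTS_FILL), n, replace = TRUE,
                   prob = .PTS_FILL / sum(.PTS_FILL)))
}

.randomDNA <- function(n) {
  .collapse(sample(c("A", "C", "G", "T"), n, replace = TRUE))
}

# cysteine-rich island protein: fixed cysteine scaffold, random PTS-like
# fill elsewhere; the last cysteine sits near the island end
.randomCysD <- function(len) {
  pos <- unique(pmax(1L, pmin(len, round(len * c(0.05, 0.12, 0.25, 0.33,
                                                 0.47, 0.58, 0.66, 0.79,
                                                 0.88, 0.97)))))
  res <- .chars(.randomProtein(len))
  res[pos] <- "C"
  .collapse(res)
}

.unitProtein <- function(template, len) {
  tl <- nchar(template)
  if (len == tl) return(template)
  if (len < tl) return(substr(template, 1L, len))
  extra <- len - tl
  if (extra > tl - 2L)
    stop("variant unit length ", len, " too long for a ", tl, "-aa template")
  # extend with residues after the start motif so no second motif appears
  paste0(template, substr(template, 3L, 2L + extra))
}

#' Generate a ground-truth mucin-like locus
#'
#' The locus is intron - (HEAD | repeat array with CysD islands | TAIL) -
#' intron. Repeat units are copies of `unit_template` (with optional length
#' variants); CysD islands are independently generated cysteine-scaffold
#' proteins, so each island is distinct and can act as a unique anchor.
#'
#' @param n_repeats number of TR units (>= 0).
#' @param unit_template canonical repeat-unit protein; must be encodable
#'   (see package details; phenylalanine is rejected).
#' @param variant_lengths optional named integer vector mapping unit index
#'   (1-based) to an amino-acid length differing from the template.
#' @param cysd_positions integer vector: a CysD island is inserted after
#'   each listed unit index (0 = before the first unit). `NULL` places two
#'   islands (before unit 1 and after unit `ceiling(n_repeats/2)`) when
#'   `n_repeats >= 2`, none otherwise.
#' @param intron_lengths length-2 integer: upstream/downstream intron sizes.
#' @param head_length,tail_length,cysd_length block sizes in amino acids.
#' @param strand "+" or "-".
#' @param seed integer seed; the same seed reproduces the same locus.
#' @return A [LocusModel-class] object.
#' @examples
#' loc <- makeLocus(5, seed = 1)
#' loc
#' @export
makeLocus <- function(n_repeats, unit_template = .DEFAULT_UNIT,
                      variant_lengths = NULL, cysd_positions = NULL,
                      intron_lengths = c(1000L, 1000L), head_length = 20L,
                      tail_length = 20L, cysd_length = 100L, strand = "+",
                      seed = NULL) {
  stopifnot(n_repeats >= 0, nchar(unit_template) >= 4)
  if (is.null(cysd_positions))
    cysd_positions <- if (n_repeats >= 2L)
      c(0L, as.integer(ceiling(n_repeats / 2))) else integer(0)
  stopifnot(all(cysd_positions >= 0L), all(cysd_positions <= n_repeats))
  .withSeed(seed, {
    lens <- rep(nchar(unit_template), n_repeats)
    if (!is.null(variant_lengths)) {
      ix <- as.integer(names(variant_lengths))
      stopifnot(all(ix >= 1L), all(ix <= n_repeats))
      lens[ix] <- as.integer(variant_lengths)
    }
    kind <- "HEAD"
    prot <- .randomProtein(head_length)
    for (u in seq_len(n_repeats + 1L) - 1L) {   # u = 0 .. n_repeats
      if (u > 0L) {
        kind <- c(kind, "TR_UNIT")
        prot <- c(prot, .unitProtein(unit_template, lens[u]))
      }
      if (u %in% cysd_positions) {
        for (rep_i in seq_len(sum(cysd_positions == u))) {
          kind <- c(kind, "CYSD")
          prot <- c(prot, .randomCysD(cysd_length))
        }
      }
    }
    kind <- c(kind, "TAIL")
    prot <- c(prot, .randomProtein(tail_length))
    blocks <- data.frame(kind = kind, protein = prot,
                         dna = vapply(prot, .encodeProtein, character(1)),
                         row.names = NULL, stringsAsFactors = FALSE)
    new("LocusModel",
        intronUp = .randomDNA(intron_lengths[1]),
        blocks = blocks,
        intronDown = .randomDNA(intron_lengths[2]),
        strand = strand, unitTemplate = unit_template,
        provenance = list())
  })
}

#' Derive an individual variant of a locus
#'
#' Applies whole-unit copy-number change and single-codon substitutions to
#' the repeat array; introns and all other blocks are untouched. Inserted
#' copies are pristine template units placed contiguously after
#' `after_unit`; substitutions are placed at unit offsets >= 2 (never
#' inside the start motif), at globally distinct offsets, and only in
#' original (non-inserted) units, so the planted SNP/CNV truth is
#' unambiguous for later comparison. The planted truth is recorded in the
#' returned locus's provenance.
#'
#' @param locus a [LocusModel-class].
#' @param n_unit_snps number of single-codon substitutions inside units.
#' @param delta_repeats signed whole-unit copy-number change.
#' @param after_unit unit index after which copies are inserted / from
#'   which deletions start (0 = before the first unit); default: sampled.
#' @param seed integer seed.
#' @return A new [LocusModel-class]; `x@provenance$snps` and
#'   `x@provenance$cnv` hold the planted truth.
#' @export
deriveVariant <- function(locus, n_unit_snps = 0L, delta_repeats = 0L,
                          after_unit = NULL, seed = NULL) {
  blocks <- locus@blocks
  unit_rows <- which(blocks$kind == "TR_UNIT")
  n <- length(unit_rows)
  if (n + delta_repeats < 0L)
    stop("delta_repeats removes more units than the locus has")
  .withSeed(seed, {
    cnv <- NULL
    inserted_rows <- integer(0)
    if (delta_repeats > 0L) {
      if (is.null(after_unit))
        after_unit <- if (n > 0L) sample(0:n, 1L) else 0L
      tmpl_prot <- locus@unitTemplate
      ins <- data.frame(kind = "TR_UNIT", protein = tmpl_prot,
                        dna = .encodeProtein(tmpl_prot),
                        stringsAsFactors = FALSE)
      ins <- ins[rep(1L, delta_repeats), , drop = FALSE]
      at <- if (after_unit == 0L) {
        # before the first unit (or before TAIL if the locus has no units)
        if (n > 0L) unit_rows[1] - 1L else which(blocks$kind == "TAIL")[1] - 1L
      } else unit_rows[after_unit]
      tail_blocks <- if (at < nrow(blocks))
        blocks[seq.int(at + 1L, nrow(blocks)), , drop = FALSE]
      else blocks[0, , drop = FALSE]
      blocks <- rbind(blocks[seq_len(at), , drop = FALSE], ins, tail_blocks)
      rownames(blocks) <- NULL
      inserted_rows <- at + seq_len(delta_repeats)
      cnv <- list(after_unit = after_unit, delta = as.integer(delta_repeats))
    } else if (delta_repeats < 0L) {
      k <- -delta_repeats
      if (is.null(after_unit)) after_unit <- sample(0:(n - k), 1L)
      stopifnot(after_unit >= 0L, after_unit + k <= n)
      drop_rows <- unit_rows[after_unit + seq_len(k)]
      blocks <- blocks[-drop_rows, , drop = FALSE]
      rownames(blocks) <- NULL
      cnv <- list(after_unit = as.integer(after_unit),
                  delta = as.integer(delta_repeats))
    }
    snps <- NULL
    if (n_unit_snps > 0L) {
      unit_rows2 <- setdiff(which(blocks$kind == "TR_UNIT"), inserted_rows)
      if (!length(unit_rows2)) stop("no units available for SNPs")
      min_len <- min(nchar(blocks$protein[unit_rows2]))
      offs <- 2:(min_len - 1L)
      if (n_unit_snps > length(offs))
        stop("too many SNPs for globally distinct offsets")
      offsets <- sample(offs, n_unit_snps)
      rows <- sample(unit_rows2, n_unit_snps, replace = TRUE)
      alphabet <- c("P", "T", "S", "A", "G", "V", "Q", "N", "H")
      recs <- vector("list", n_unit_snps)
      for (i in seq_len(n_unit_snps)) {
        r <- rows[i]; off <- offsets[i]
        old <- substr(blocks$protein[r], off + 1L, off + 1L)
        new_res <- sample(setdiff(alphabet, old), 1L)
        substr(blocks$protein[r], off + 1L, off + 1L) <- new_res
        codon <- .CODONS[[new_res]][off %% 3L + 1L]
        nxt <- substr(blocks$dna[r], off * 3L + 4L, off * 3L + 4L)
        if (substr(codon, 3L, 3L) == "T" && nxt == "T")
          codon <- .SAFE_CODON[[new_res]]
        substr(blocks$dna[r], off * 3L + 1L, off * 3L + 3L) <- codon
        unit_index <- match(r, which(blocks$kind == "TR_UNIT"))
        recs[[i]] <- data.frame(unit = unit_index, offset = off,
                                from = old, to = new_res,
                                stringsAsFactors = FALSE)
      }
      snps <- do.call(rbind, recs)
      snps <- snps[order(snps$unit, snps$offset), , drop = FALSE]
      rownames(snps) <- NULL
    }
    new("LocusModel", intronUp = locus@intronUp, blocks = blocks,
        intronDown = locus@intronDown, strand = locus@strand,
        unitTemplate = locus@unitTemplate,
        provenance = list(snps = snps, cnv = cnv))
  })
}

.injectErrors <- function(seq, profile) {
  ch <- .chars(seq)
  n <- length(ch)
  p <- profile@pTotal
  if (p == 0 || n == 0L) return(list(seq = seq, n_errors = 0L))
  r <- rle(ch)
  in_run <- rep(r$lengths >= 2L, r$lengths)
  idx <- which(runif(n) < p)
  out <- ch
  ins <- character(n)
  del <- logical(n)
  bases <- c("A", "C", "G", "T")
  mix0 <- profile@mix
  mix_run <- mix0
  shift <- min(mix0[["deletion"]] * (profile@hpBoost - 1), mix0[["mismatch"]])
  mix_run[["deletion"]] <- mix0[["deletion"]] + shift
  mix_run[["mismatch"]] <- mix0[["mismatch"]] - shift
  for (i in idx) {
    m <- if (in_run[i]) mix_run else mix0
    type <- sample(c("mismatch", "insertion", "deletion"), 1L, prob = m)
    if (type == "mismatch") {
      out[i] <- sample(bases[bases != ch[i]], 1L)
    } else if (type == "insertion") {
      ins[i] <- sample(bases, 1L)
    } else {
      del[i] <- TRUE
    }
  }
  out[del] <- ""
  list(seq = .collapse(paste0(out, ins)), n_errors = length(idx))
}

#' Simulate long reads from a locus
#'
#' Read lengths are drawn uniformly from `length_range`; a read longer than
#' the locus is the whole locus. Strands are sampled evenly. Errors are
#' injected position-wise independently at total rate `profile@pTotal`
#' with the profile's mismatch/insertion/deletion mix; inside homopolymer
#' runs the mix shifts toward deletion (the profile's `hpBoost`) while the
#' total rate is unchanged. With `pTotal = 0` every read is an exact
#' substring of the locus (reverse-complemented for "-" reads).
#'
#' @param locus a [LocusModel-class].
#' @param mean_depth target mean per-base fold coverage (ignored when
#'   `n_reads` is given).
#' @param n_reads exact number of reads to draw.
#' @param length_range length-2 integer range of target read lengths.
#' @param profile an [ErrorProfile-class].
#' @param seed integer seed (default: the profile's).
#' @return A [Biostrings::DNAStringSet]; `mcols()` carries `truth_start`,
#'   `truth_end` (0-based half-open on the forward locus), `truth_strand`,
#'   `n_errors` (generator bookkeeping) and `quality` (flat Phred string
#'   matching `pTotal`).
#' @examples
#' loc <- makeLocus(5, seed = 1)
#' rds <- simulateReads(loc, n_reads = 4, length_range = c(1000, 2000),
#'                      profile = errorProfile(pTotal = 0), seed = 2)
#' @export
simulateReads <- function(locus, mean_depth = NULL, n_reads = NULL,
                          length_range = c(5000L, 20000L),
                          profile = errorProfile(), seed = profile@seed) {
  stopifnot(length_range[1] >= 1L, length_range[2] >= length_range[1])
  locus_str <- as.character(locusSeq(locus))
  L <- nchar(locus_str)
  if (length_range[2] < L)
    warning("maximum read length (", length_range[2],
            ") is below the locus length (", L,
            "); no read can span the whole locus")
  if (is.null(n_reads)) {
    if (is.null(mean_depth) || mean_depth <= 0)
      stop("give either mean_depth > 0 or n_reads")
    grid <- seq(length_range[1], length_range[2], length.out = 201L)
    el <- mean(pmin(grid, L))
    n_reads <- max(1L, as.integer(round(mean_depth * L / el)))
  }
  .withSeed(seed, {
    strands <- sample(rep(c("+", "-"), length.out = n_reads))
    seqs <- character(n_reads)
    ts <- integer(n_reads); te <- integer(n_reads); ne <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      len <- sample(seq.int(length_range[1], length_range[2]), 1L)
      start <- if (L > len) sample(0:(L - len), 1L) else 0L
      end <- min(start + len, L)
      frag <- substr(locus_str, start + 1L, end)
      if (strands[i] == "-") frag <- .revcomp(frag)
      inj <- .injectErrors(frag, profile)
      seqs[i] <- inj$seq
      ts[i] <- start; te[i] <- end; ne[i] <- inj$n_errors
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("read%04d", seq_len(n_reads))
    q <- max(2L, min(40L, as.integer(round(-10 * log10(max(profile@pTotal,
                                                           1e-4))))))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      truth_start = ts, truth_end = te, truth_strand = strands,
      n_errors = ne,
      quality = vapply(nchar(seqs),
                       function(n) strrep(rawToChar(as.raw(33L + q)), n),
                       character(1)))
    out
  })
}

#' CysD island reference proteins of a locus
#'
#' The translated CysD blocks of a locus model, in order - the island
#' references a user of real data would take from reference annotation.
#'
#' @param locus a [LocusModel-class].
#' @return Character vector of island proteins (possibly empty).
#' @export
cysdReferences <- function(locus) {
  locus@blocks$protein[locus@blocks$kind == "CYSD"]
}

#' Anchors matching a simulated locus
#'
#' Convenience helper: builds the [AnchorSet-class] a user would supply for
#' real data (the two flanking introns plus one mid-domain CysD island as
#' delimiter) from a locus model's ground truth.
#'
#' @param locus a [LocusModel-class].
#' @param delimiter_index which CysD island to use as delimiter (default:
#'   the island nearest the exon midpoint); NA for no delimiter.
#' @param minIdentity,minAnchorCoverage thresholds for [anchorSet()].
#' @return An [AnchorSet-class].
#' @export
anchorsFromLocus <- function(locus, delimiter_index = NULL,
                             minIdentity = 0.70, minAnchorCoverage = 0.60) {
  b <- locus@blocks
  cys <- which(b$kind == "CYSD")
  delim <- NA_character_
  if (length(cys) && (is.null(delimiter_index) || !is.na(delimiter_index))) {
    if (is.null(delimiter_index)) {
      starts <- cumsum(c(0L, nchar(b$dna)))[seq_len(nrow(b))]
      mid <- sum(nchar(b$dna)) / 2
      delimiter_index <- which.min(abs(starts[cys] +
                                         nchar(b$dna)[cys] / 2 - mid))
    }
    delim <- b$dna[cys[delimiter_index]]
  }
  anchorSet(locus@intronUp, locus@intronDown, delim,
            minIdentity = minIdentity,
            minAnchorCoverage = minAnchorCoverage)
}
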
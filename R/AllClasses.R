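#' Pipeline configuration
#'
#' Holds every tunable of the consensus pipeline: the read-length cutoff,
#' anchor acceptance thresholds, the (zero-gap-penalty) alignment scores
#' used for the multiple alignment, the assumed per-base error band of the
#' sequencing technology, and the estimator rounding mode.
#'
#' @slot minReadLength integer, reads must be strictly longer (bases).
#' @slot minIdentity minimum anchor-hit identity fraction.
#' @slot minAnchorCoverage minimum fraction of the anchor that must align.
#' @slot match,mismatch,gap alignment scores for the multiple alignment.
#' @slot pLow,pHigh assumed per-base error band (0 <= pLow <= pHigh < 1).
#' @slot roundingMode estimator rounding; only "half-away" is defined.
#' @slot seed integer random seed recorded in reports.
#' @export
setClass("PipelineConfig",
  representation(
    minReadLength = "integer",
    minIdentity = "numeric",
    minAnchorCoverage = "numeric",
    match = "numeric",
    mismatch = "numeric",
    gap = "numeric",
    pLow = "numeric",
    pHigh = "numeric",
    roundingMode = "character",
    seed = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@minReadLength <= 0L) msg <- c(msg, "minReadLength must be > 0")
  if (!(object@pLow >= 0 && object@pLow <= object@pHigh && object@pHigh < 1))
    msg <- c(msg, "need 0 <= pLow <= pHigh < 1")
  if (!(object@minIdentity > 0 && object@minIdentity <= 1))
    msg <- c(msg, "minIdentity must be in (0, 1]")
  if (!identical(object@roundingMode, "half-away"))
    msg <- c(msg, "roundingMode must be 'half-away'")
  if (length(msg)) msg else TRUE
})

#' Create a pipeline configuration
#'
#' Defaults mirror the method's published conditions: a 5 kb read-length
#' cutoff, an assumed per-base error band of 0.15-0.30, zero-penalty
#' alignment scores (match +1, mismatch 0, gap 0) so that whole repeat
#' units align as free gap blocks, and permissive anchor thresholds
#' (identity >= 0.70 over >= 60% of the anchor) so recruitment still works
#' at 30% read error.
#'
#' @param minReadLength reads must be strictly longer than this (bases).
#' @param minIdentity,minAnchorCoverage anchor acceptance thresholds.
#' @param match,mismatch,gap multiple-alignment scores.
#' @param pLow,pHigh assumed per-base error band.
#' @param roundingMode estimator rounding mode ("half-away").
#' @param seed integer seed recorded in reports.
#' @return A [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig()
#' cfg
#' @export
pipelineConfig <- function(minReadLength = 5000L, minIdentity = 0.70,
                           minAnchorCoverage = 0.60, match = 1, mismatch = 0,
                           gap = 0, pLow = 0.15, pHigh = 0.30,
                           roundingMode = "half-away", seed = 1L) {
  new("PipelineConfig",
      minReadLength = as.integer(minReadLength),
      minIdentity = minIdentity, minAnchorCoverage = minAnchorCoverage,
      match = match, mismatch = mismatch, gap = gap,
      pLow = pLow, pHigh = pHigh, roundingMode = roundingMode,
      seed = as.integer(seed))
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirror the [pipelineConfig()] arguments (snake_case also
#' accepted, e.g. `min_read_length`).
#'
#' @param path YAML file path.
#' @return A [PipelineConfig-class] object.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  canon <- function(x) gsub("_", "", tolower(x))
  args <- formals(pipelineConfig)
  nm <- names(args)
  got <- list()
  for (k in seq_along(raw)) {
    hit <- nm[canon(nm) == canon(names(raw)[k])]
    if (length(hit) == 1L) got[[hit]] <- raw[[k]]
  }
  do.call(pipelineConfig, got)
}

#' Sequencing error profile for the read simulator
#'
#' @slot pTotal per-base total error probability (0 <= p < 0.5).
#' @slot mix named fractions (mismatch, insertion, deletion) summing to 1.
#' @slot hpBoost deletion-rate multiplier inside homopolymer runs >= 2;
#'   redistributive (mismatch mass shifts to deletion) so the total
#'   per-base error rate stays exactly pTotal.
#' @slot seed integer default seed for [simulateReads()].
#' @export
setClass("ErrorProfile",
  representation(pTotal = "numeric", mix = "numeric", hpBoost = "numeric",
                 seed = "integer"))

setValidity("ErrorProfile", function(object) {
  msg <- character()
  if (!(object@pTotal >= 0 && object@pTotal < 0.5))
    msg <- c(msg, "need 0 <= pTotal < 0.5")
  m <- object@mix
  if (length(m) != 3L ||
      !setequal(names(m), c("mismatch", "insertion", "deletion")))
    msg <- c(msg, "mix must be named (mismatch, insertion, deletion)")
  else {
    if (any(m < 0)) msg <- c(msg, "mix components must be non-negative")
    if (abs(sum(m) - 1) > 1e-8) msg <- c(msg, "mix must sum to 1")
  }
  if (object@hpBoost < 1) msg <- c(msg, "hpBoost must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create an error profile
#'
#' The default is indel-dominant (mismatch 0.25, insertion 0.42, deletion
#' 0.33), the regime in which gap-placement ambiguity inside homopolymer
#' runs actually produces the frameshift problem this pipeline corrects.
#' The default total rate 0.20 sits inside the assumed 0.15-0.30 band.
#'
#' @param pTotal per-base total error probability.
#' @param mix named fractions (mismatch, insertion, deletion).
#' @param hpBoost deletion boost inside homopolymer runs (>= 2 long).
#' @param seed default seed for [simulateReads()].
#' @return An [ErrorProfile-class] object.
#' @export
errorProfile <- function(pTotal = 0.20,
                         mix = c(mismatch = 0.25, insertion = 0.42,
                                 deletion = 0.33),
                         hpBoost = 1.5, seed = 1L) {
  new("ErrorProfile", pTotal = pTotal, mix = mix[c("mismatch", "insertion",
                                                   "deletion")],
      hpBoost = hpBoost, seed = as.integer(seed))
}

#' Ground-truth synthetic mucin-like locus
#'
#' A locus of structure intron - (HEAD | TR array | CysD islands | TAIL) -
#' intron. The exon blocks are held at both protein and DNA level; the DNA
#' encoding is deterministic so identical repeat units have identical DNA.
#'
#' @slot intronUp,intronDown flanking intron DNA.
#' @slot blocks data.frame with columns kind (HEAD/TR_UNIT/CYSD/TAIL),
#'   protein, dna; ordered as on the exon.
#' @slot strand "+" or "-".
#' @slot unitTemplate canonical repeat-unit protein.
#' @slot provenance list; for derived variants, the planted SNP/CNV truth.
#' @export
setClass("LocusModel",
  representation(intronUp = "character", blocks = "data.frame",
                 intronDown = "character", strand = "character",
                 unitTemplate = "character", provenance = "list"))

setValidity("LocusModel", function(object) {
  msg <- character()
  b <- object@blocks
  if (!all(c("kind", "protein", "dna") %in% names(b)))
    msg <- c(msg, "blocks needs columns kind, protein, dna")
  else {
    if (!all(b$kind %in% c("HEAD", "TR_UNIT", "CYSD", "TAIL")))
      msg <- c(msg, "unknown block kind")
    if (!all(nchar(b$dna) == 3L * nchar(b$protein)))
      msg <- c(msg, "block dna must be 3x protein length")
    exon <- .collapse(b$dna)
    if (nchar(exon) %% 3L != 0L)
      msg <- c(msg, "exon length must be divisible by 3")
    else if (nchar(exon) >= 3L) {
      prot <- .translateDNA(exon)
      if (grepl("\\*", substr(prot, 1L, nchar(prot) - 1L)))
        msg <- c(msg, "exon translation has an internal stop codon")
    }
  }
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  if (length(msg)) msg else TRUE
})

#' Anchor set for read recruitment
#'
#' The two flanking introns plus (optionally) the DNA of a mid-domain CysD
#' island whose last cysteine codon serves as the split point between the
#' upstream and downstream consensus builds.
#'
#' @slot intronUp,intronDown flanking intron DNA anchors.
#' @slot delimiter CysD island DNA, or NA when the exon is not split.
#' @slot minIdentity,minAnchorCoverage acceptance thresholds.
#' @export
setClass("AnchorSet",
  representation(intronUp = "character", intronDown = "character",
                 delimiter = "character", minIdentity = "numeric",
                 minAnchorCoverage = "numeric"))

setValidity("AnchorSet", function(object) {
  msg <- character()
  if (!nzchar(object@intronUp) || !nzchar(object@intronDown))
    msg <- c(msg, "intron anchors must be non-empty")
  if (!(object@minIdentity > 0 && object@minIdentity <= 1))
    msg <- c(msg, "minIdentity must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Create an anchor set
#'
#' @param intronUp,intronDown flanking intron DNA (characters or
#'   [Biostrings::DNAString]).
#' @param delimiter optional CysD island DNA used as mid-domain delimiter.
#' @param minIdentity,minAnchorCoverage acceptance thresholds for hits.
#' @return An [AnchorSet-class] object.
#' @export
anchorSet <- function(intronUp, intronDown, delimiter = NA_character_,
                      minIdentity = 0.70, minAnchorCoverage = 0.60) {
  new("AnchorSet",
      intronUp = .assertDNA(as.character(intronUp), "intronUp"),
      intronDown = .assertDNA(as.character(intronDown), "intronDown"),
      delimiter = if (is.na(delimiter)) NA_character_
                  else .assertDNA(as.character(delimiter), "delimiter"),
      minIdentity = minIdentity, minAnchorCoverage = minAnchorCoverage)
}

#' A read recruited for consensus building
#'
#' @slot readId read identifier.
#' @slot bases read sequence as sequenced (never reverse-complemented).
#' @slot readClass "FULL", "TYPE_I", "TYPE_II" or "NONE".
#' @slot orientation "+" or "-": strand on which the anchors were found.
#' @slot segStart,segEnd extracted segment, 0-based half-open coordinates
#'   on the oriented read (NA when readClass is "NONE").
#' @slot hits named list of anchor hits (intronUp / delimiter / intronDown).
#' @export
setClass("RecruitedRead",
  representation(readId = "character", bases = "character",
                 readClass = "character", orientation = "character",
                 segStart = "integer", segEnd = "integer", hits = "list"))

setValidity("RecruitedRead", function(object) {
  msg <- character()
  if (!object@readClass %in% c("FULL", "TYPE_I", "TYPE_II", "NONE"))
    msg <- c(msg, "invalid readClass")
  if (object@readClass == "NONE") {
    if (!is.na(object@segStart) || !is.na(object@segEnd))
      msg <- c(msg, "NONE reads must not carry a segment")
  } else {
    if (is.na(object@segStart) || is.na(object@segEnd) ||
        object@segStart < 0L || object@segEnd > nchar(object@bases) ||
        object@segStart >= object@segEnd)
      msg <- c(msg, "segment must lie within the read")
  }
  if (length(msg)) msg else TRUE
})

#' Gapped multiple alignment
#'
#' Rows are equal-length strings over A,C,G,T,N,-. `columnDepth` counts, per
#' column, the rows whose aligned extent (first to last non-gap symbol)
#' covers that column; rows absent at a flank are external there, not
#' gapped.
#'
#' @slot rowIds row identifiers.
#' @slot rows gapped row strings.
#' @slot columnDepth per-column covering-row counts.
#' @export
setClass("Msa",
  representation(rowIds = "character", rows = "character",
                 columnDepth = "integer"))

setValidity("Msa", function(object) {
  msg <- character()
  if (length(object@rows) < 1L) msg <- c(msg, "Msa needs >= 1 row")
  w <- unique(nchar(object@rows))
  if (length(w) > 1L) msg <- c(msg, "all rows must have equal length")
  else if (length(object@columnDepth) != w)
    msg <- c(msg, "columnDepth must have one entry per column")
  if (length(object@rowIds) != length(object@rows))
    msg <- c(msg, "rowIds must match rows")
  if (length(msg)) msg else TRUE
})

#' Consensus sequence with per-position depth and support
#'
#' @slot sequence consensus DNA (gap columns removed).
#' @slot depth per-position number of reads aligned there.
#' @slot support per-position fraction of aligned reads agreeing with the
#'   consensus symbol.
#' @export
setClass("ConsensusTrack",
  representation(sequence = "character", depth = "integer",
                 support = "numeric"))

setValidity("ConsensusTrack", function(object) {
  n <- nchar(object@sequence)
  msg <- character()
  if (length(object@depth) != n || length(object@support) != n)
    msg <- c(msg, "depth and support must match sequence length")
  if (n > 0 && any(object@depth < 1L))
    msg <- c(msg, "every emitted consensus base needs depth >= 1")
  if (length(msg)) msg else TRUE
})

#' Ordered decomposition of a domain protein into blocks
#'
#' @slot blocks data.frame with columns kind (HEAD/CYSD/TR/TAIL), start,
#'   end (0-based half-open protein coordinates), seq.
#' @slot unitLengths amino-acid lengths of the TR blocks, in order.
#' @export
setClass("RepeatDecomposition",
  representation(blocks = "data.frame", unitLengths = "integer"))

setValidity("RepeatDecomposition", function(object) {
  b <- object@blocks
  msg <- character()
  if (!all(c("kind", "start", "end", "seq") %in% names(b)))
    msg <- c(msg, "blocks needs columns kind, start, end, seq")
  else if (nrow(b)) {
    if (!all(b$kind %in% c("HEAD", "CYSD", "TR", "TAIL")))
      msg <- c(msg, "unknown block kind")
    if (b$start[1] != 0L) msg <- c(msg, "blocks must start at 0")
    if (nrow(b) > 1L && any(b$start[-1] != b$end[-nrow(b)]))
      msg <- c(msg, "blocks must be contiguous")
    if (any(nchar(b$seq) != b$end - b$start))
      msg <- c(msg, "block seq must match its span")
    if (!identical(object@unitLengths,
                   as.integer(nchar(b$seq[b$kind == "TR"]))))
      msg <- c(msg, "unitLengths must mirror the TR blocks")
  }
  if (length(msg)) msg else TRUE
})

#' SNP / copy-number comparison of two repeat decompositions
#'
#' @slot snps data.frame (unit, offset, a, b): residue differences between
#'   1:1 matched units; `unit` indexes units of the first decomposition
#'   (1-based), `offset` is 0-based within the unit.
#' @slot cnv data.frame (after_unit, delta, unit_seq): whole-unit gains
#'   (delta > 0: the second decomposition has more copies) or losses,
#'   positioned after the given unit index of the first decomposition.
#' @export
setClass("DomainComparison",
  representation(snps = "data.frame", cnv = "data.frame"))

setValidity("DomainComparison", function(object) {
  msg <- character()
  if (nrow(object@cnv) && any(object@cnv$delta == 0))
    msg <- c(msg, "cnv delta must be non-zero")
  if (length(msg)) msg else TRUE
})

#' Calibration of the single-T repeat-number estimator
#'
#' @slot tEvents maximal T-run count of the calibration TR region
#'   (a run of any length counts once).
#' @slot nRepeats repeat count of the calibration TR region.
#' @slot rate per-repeat single-T rate, tEvents / nRepeats (full precision).
#' @slot multiRunPositions 0-based start positions of T-runs of length >= 2
#'   (anomalies; interpreted as SNPs and collapsed to one event).
#' @export
setClass("EstimatorCalibration",
  representation(tEvents = "integer", nRepeats = "integer", rate = "numeric",
                 multiRunPositions = "integer"))

setValidity("EstimatorCalibration", function(object) {
  msg <- character()
  if (object@nRepeats < 1L) msg <- c(msg, "nRepeats must be >= 1")
  if (object@tEvents > 0L && !(object@rate > 0))
    msg <- c(msg, "rate must be > 0 when tEvents > 0")
  if (length(msg)) msg else TRUE
})

#' Full pipeline report
#'
#' Every stage's artifact from one [runPipeline()] call. Coordinates are
#' 0-based half-open on the final consensus.
#'
#' @slot consensus raw majority-vote [ConsensusTrack-class].
#' @slot polished polished consensus DNA (frameshift-corrected exon).
#' @slot exonSpan integer length-2: exon span on the polished consensus.
#' @slot editLog data.frame of applied frameshift edits (position, op, base).
#' @slot resolved logical: FALSE when some frame disruption could not be
#'   repaired (too few reads).
#' @slot suspects data.frame of flagged homopolymer loci.
#' @slot accuracy data.frame (pos, depth, low, high): per-position accuracy
#'   bounds 1 - pHigh^depth .. 1 - pLow^depth.
#' @slot decomposition [RepeatDecomposition-class] of the translated exon.
#' @slot counts named integer vector: read-class and builder counts.
#' @slot estimator list of single-T estimator inputs for the TR region.
#' @slot config the [PipelineConfig-class] used.
#' @slot version report schema version string.
#' @export
setClass("PipelineReport",
  representation(consensus = "ConsensusTrack", polished = "character",
                 exonSpan = "integer", editLog = "data.frame",
                 resolved = "logical", suspects = "data.frame",
                 accuracy = "data.frame",
                 decomposition = "RepeatDecomposition",
                 counts = "integer", estimator = "list",
                 config = "PipelineConfig", version = "character"))
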
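# Accessor and show methods.

#' @rawNamespace exportMethods(show)
NULL

#' @rdname mucintr-accessors
#' @aliases exonSeq,LocusModel-method
setMethod("exonSeq", "LocusModel", function(x) {
  Biostrings::DNAString(.collapse(x@blocks$dna))
})

#' @rdname mucintr-accessors
setMethod("locusSeq", "LocusModel", function(x) {
  fwd <- paste0(x@intronUp, .collapse(x@blocks$dna), x@intronDown)
  if (x@strand == "-") fwd <- .revcomp(fwd)
  Biostrings::DNAString(fwd)
})

#' @rdname mucintr-accessors
setMethod("blockTable", "LocusModel", function(x) x@blocks)

#' @rdname mucintr-accessors
setMethod("nRepeats", "LocusModel", function(x) {
  sum(x@blocks$kind == "TR_UNIT")
})

#' @rdname mucintr-accessors
setMethod("unitTemplate", "LocusModel", function(x) x@unitTemplate)

#' @rdname mucintr-accessors
setMethod("trRegionSeq", "LocusModel", function(x) {
  Biostrings::DNAString(.collapse(x@blocks$dna[x@blocks$kind == "TR_UNIT"]))
})

setMethod("show", "LocusModel", function(object) {
  b <- object@blocks
  cat("LocusModel:", nchar(object@intronUp), "bp intron |",
      sum(nchar(b$dna)), "bp exon |", nchar(object@intronDown),
      "bp intron, strand", object@strand, "\n")
  cat("  blocks:", paste(sprintf("%s=%d", names(table(b$kind)),
                                 table(b$kind)), collapse = ", "), "\n")
  cat("  unit template:", object@unitTemplate, "\n")
})

#' @rdname mucintr-accessors
setMethod("msaRows", "Msa", function(x) setNames(x@rows, x@rowIds))

#' @rdname mucintr-accessors
setMethod("msaDepth", "Msa", function(x) x@columnDepth)

setMethod("show", "Msa", function(object) {
  cat("Msa:", length(object@rows), "rows x", nchar(object@rows[1]),
      "columns; depth", min(object@columnDepth), "-",
      max(object@columnDepth), "\n")
})

#' @rdname mucintr-accessors
setMethod("consensusSeq", "ConsensusTrack", function(x) {
  Biostrings::DNAString(x@sequence)
})

#' @rdname mucintr-accessors
setMethod("consensusDepth", "ConsensusTrack", function(x) x@depth)

#' @rdname mucintr-accessors
setMethod("consensusSupport", "ConsensusTrack", function(x) x@support)

setMethod("show", "ConsensusTrack", function(object) {
  cat("ConsensusTrack:", nchar(object@sequence), "bp; depth",
      min(object@depth), "-", max(object@depth),
      sprintf("; mean support %.3f", mean(object@support)), "\n")
})

#' @rdname mucintr-accessors
setMethod("readClass", "RecruitedRead", function(x) x@readClass)

#' @rdname mucintr-accessors
setMethod("orientation", "RecruitedRead", function(x) x@orientation)

#' @rdname mucintr-accessors
setMethod("segmentSeq", "RecruitedRead", function(x) {
  if (x@readClass == "NONE") return(NULL)
  oriented <- if (x@orientation == "-") .revcomp(x@bases) else x@bases
  Biostrings::DNAString(substr(oriented, x@segStart + 1L, x@segEnd))
})

#' @rdname mucintr-accessors
setMethod("anchorHits", "RecruitedRead", function(x) x@hits)

setMethod("show", "RecruitedRead", function(object) {
  cat("RecruitedRead", object@readId, ":", object@readClass,
      "strand", object@orientation)
  if (object@readClass != "NONE")
    cat(sprintf(", segment [%d, %d)", object@segStart, object@segEnd))
  cat("\n")
})

#' @rdname mucintr-accessors
setMethod("blockTable", "RepeatDecomposition", function(x) x@blocks)

#' @rdname mucintr-accessors
setMethod("unitLengths", "RepeatDecomposition", function(x) x@unitLengths)

#' @rdname mucintr-accessors
setMethod("trUnits", "RepeatDecomposition", function(x) {
  x@blocks$seq[x@blocks$kind == "TR"]
})

#' @rdname mucintr-accessors
setMethod("nRepeats", "RepeatDecomposition", function(x) {
  sum(x@blocks$kind == "TR")
})

setMethod("show", "RepeatDecomposition", function(object) {
  k <- table(object@blocks$kind)
  cat("RepeatDecomposition:", sum(object@blocks$end - object@blocks$start),
      "aa;", paste(sprintf("%s=%d", names(k), k), collapse = ", "), "\n")
  if (length(object@unitLengths))
    cat("  unit lengths:", min(object@unitLengths), "-",
        max(object@unitLengths), "aa\n")
})

#' @rdname mucintr-accessors
setMethod("snpTable", "DomainComparison", function(x) x@snps)

#' @rdname mucintr-accessors
setMethod("cnvTable", "DomainComparison", function(x) x@cnv)

setMethod("show", "DomainComparison", function(object) {
  cat("DomainComparison:", nrow(object@snps), "SNPs,",
      nrow(object@cnv), "CNV events\n")
  if (nrow(object@cnv))
    cat("  deltas:", paste(sprintf("%+d", object@cnv$delta),
                           collapse = ", "), "\n")
})

#' @rdname mucintr-accessors
setMethod("tEvents", "EstimatorCalibration", function(x) x@tEvents)

#' @rdname mucintr-accessors
setMethod("perRepeatRate", "EstimatorCalibration", function(x) x@rate)

#' @rdname mucintr-accessors
setMethod("nRepeats", "EstimatorCalibration", function(x) x@nRepeats)

setMethod("show", "EstimatorCalibration", function(object) {
  cat(sprintf(
    "EstimatorCalibration: %d single-T events over %d repeats (%.2f per repeat)\n",
    object@tEvents, object@nRepeats, object@rate))
  if (length(object@multiRunPositions))
    cat("  multi-T anomalies at:",
        paste(object@multiRunPositions, collapse = ", "), "\n")
})

#' @rdname mucintr-accessors
setMethod("consensusSeq", "PipelineReport", function(x) {
  consensusSeq(x@consensus)
})

#' @rdname mucintr-accessors
setMethod("polishedExon", "PipelineReport", function(x) {
  Biostrings::DNAString(substr(x@polished, x@exonSpan[1] + 1L, x@exonSpan[2]))
})

#' @rdname mucintr-accessors
setMethod("editLog", "PipelineReport", function(x) x@editLog)

#' @rdname mucintr-accessors
setMethod("decomposition", "PipelineReport", function(x) x@decomposition)

#' @rdname mucintr-accessors
setMethod("accuracyTrack", "PipelineReport", function(x) x@accuracy)

#' @rdname mucintr-accessors
setMethod("builderCounts", "PipelineReport", function(x) x@counts)

setMethod("show", "PipelineReport", function(object) {
  cat("PipelineReport (schema", object@version, ")\n")
  cat("  reads:", paste(sprintf("%s=%d", names(object@counts),
                                object@counts), collapse = ", "), "\n")
  cat("  consensus:", nchar(object@consensus@sequence), "bp; exon",
      sprintf("[%d, %d)", object@exonSpan[1], object@exonSpan[2]), "\n")
  cat("  frameshift edits:", nrow(object@editLog),
      if (object@resolved) "(resolved)" else "(UNRESOLVED)", "\n")
  cat("  decomposition:", sum(object@decomposition@blocks$kind == "TR"),
      "TR units\n")
  cat(sprintf("  accuracy lower bound (min depth %d): %.2f%%\n",
              min(object@accuracy$depth),
              .pct2(min(object@accuracy$low))))
})
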
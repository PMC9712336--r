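#' @name mucintr-accessors
#' @title Accessors for mucintr classes
#' @description Accessor generics for the package's S4 classes; use these
#'   instead of reaching into slots.
#' @param x an object of the documented class.
#' @return The accessed component; see each method.
NULL

#' @rdname mucintr-accessors
#' @export
setGeneric("exonSeq", function(x) standardGeneric("exonSeq"))

#' @rdname mucintr-accessors
#' @export
setGeneric("locusSeq", function(x) standardGeneric("locusSeq"))

#' @rdname mucintr-accessors
#' @export
setGeneric("blockTable", function(x) standardGeneric("blockTable"))

#' @rdname mucintr-accessors
#' @export
setGeneric("nRepeats", function(x) standardGeneric("nRepeats"))

#' @rdname mucintr-accessors
#' @export
setGeneric("unitTemplate", function(x) standardGeneric("unitTemplate"))

#' @rdname mucintr-accessors
#' @export
setGeneric("trRegionSeq", function(x) standardGeneric("trRegionSeq"))

#' @rdname mucintr-accessors
#' @export
setGeneric("msaRows", function(x) standardGeneric("msaRows"))

#' @rdname mucintr-accessors
#' @export
setGeneric("msaDepth", function(x) standardGeneric("msaDepth"))

#' @rdname mucintr-accessors
#' @export
setGeneric("consensusSeq", function(x) standardGeneric("consensusSeq"))

#' @rdname mucintr-accessors
#' @export
setGeneric("consensusDepth", function(x) standardGeneric("consensusDepth"))

#' @rdname mucintr-accessors
#' @export
setGeneric("consensusSupport", function(x) standardGeneric("consensusSupport"))

#' @rdname mucintr-accessors
#' @export
setGeneric("readClass", function(x) standardGeneric("readClass"))

#' @rdname mucintr-accessors
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))

#' @rdname mucintr-accessors
#' @export
setGeneric("segmentSeq", function(x) standardGeneric("segmentSeq"))

#' @rdname mucintr-accessors
#' @export
setGeneric("anchorHits", function(x) standardGeneric("anchorHits"))

#' @rdname mucintr-accessors
#' @export
setGeneric("unitLengths", function(x) standardGeneric("unitLengths"))

#' @rdname mucintr-accessors
#' @export
setGeneric("trUnits", function(x) standardGeneric("trUnits"))

#' @rdname mucintr-accessors
#' @export
setGeneric("snpTable", function(x) standardGeneric("snpTable"))

#' @rdname mucintr-accessors
#' @export
setGeneric("cnvTable", function(x) standardGeneric("cnvTable"))

#' @rdname mucintr-accessors
#' @export
setGeneric("tEvents", function(x) standardGeneric("tEvents"))

#' @rdname mucintr-accessors
#' @export
setGeneric("perRepeatRate", function(x) standardGeneric("perRepeatRate"))

#' @rdname mucintr-accessors
#' @export
setGeneric("polishedExon", function(x) standardGeneric("polishedExon"))

#' @rdname mucintr-accessors
#' @export
setGeneric("editLog", function(x) standardGeneric("editLog"))

#' @rdname mucintr-accessors
#' @export
setGeneric("decomposition", function(x) standardGeneric("decomposition"))

#' @rdname mucintr-accessors
#' @export
setGeneric("accuracyTrack", function(x) standardGeneric("accuracyTrack"))

#' @rdname mucintr-accessors
#' @export
setGeneric("builderCounts", function(x) standardGeneric("builderCounts"))

#' @rdname mucintr-accessors
#' @export
setGeneric("reportJSON", function(x) standardGeneric("reportJSON"))
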
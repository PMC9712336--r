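#' Read sequences from FASTA or FASTQ
#'
#' Returns a [Biostrings::DNAStringSet]; lowercase input is uppercased and
#' U is mapped to T. For FASTQ, per-base Phred qualities are kept in
#' `mcols(x)$quality` as character strings of the same length as each read.
#' Record order is preserved. Malformed records raise a parse error naming
#' the 1-based record index.
#'
#' @param path input file.
#' @param format "fasta" or "fastq".
#' @return A [Biostrings::DNAStringSet] of reads.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ACGT", ">r2", "ttgg"), tf)
#' readSequences(tf, "fasta")
#' @export
readSequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  clean <- function(s) chartr("acgtun", "ACGTTN", chartr("U", "T", s))
  if (format == "fasta") {
    hdr <- grep("^>", lines)
    if (!length(hdr)) stop("no FASTA records in ", path)
    if (hdr[1] != 1L) stop("FASTA parse error at record 1: leading junk")
    starts <- hdr
    ends <- c(hdr[-1] - 1L, length(lines))
    ids <- sub("^>\\s*", "", lines[starts])
    ids <- sub("\\s.*$", "", ids)
    seqs <- character(length(starts))
    for (i in seq_along(starts)) {
      body <- lines[seq.int(starts[i] + 1L, length.out = ends[i] - starts[i])]
      s <- clean(.collapse(body))
      if (!nzchar(s))
        stop("FASTA parse error at record ", i, ": empty sequence")
      if (!grepl("^[ACGTN]+$", s))
        stop("FASTA parse error at record ", i, ": non-DNA characters")
      seqs[i] <- s
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    return(out)
  }
  # fastq
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  nrec <- length(lines) %/% 4
  if (length(lines) %% 4 != 0L)
    stop("FASTQ parse error at record ", floor(length(lines) / 4) + 1,
         ": truncated record")
  ids <- character(nrec); seqs <- character(nrec); quals <- character(nrec)
  for (i in seq_len(nrec)) {
    blk <- lines[(i - 1L) * 4L + 1:4]
    if (!startsWith(blk[1], "@"))
      stop("FASTQ parse error at record ", i, ": header must start with @")
    if (!startsWith(blk[3], "+"))
      stop("FASTQ parse error at record ", i, ": separator must start with +")
    s <- clean(blk[2])
    if (!grepl("^[ACGTN]+$", s))
      stop("FASTQ parse error at record ", i, ": non-DNA characters")
    if (nchar(blk[4]) != nchar(s))
      stop("FASTQ parse error at record ", i,
           ": quality length differs from sequence length")
    ids[i] <- sub("\\s.*$", "", sub("^@", "", blk[1]))
    seqs[i] <- s
    quals[i] <- blk[4]
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$quality <- quals
  out
}

#' Write sequences to FASTA (or FASTQ)
#'
#' Accepts a [Biostrings::DNAStringSet], a named character vector, or a
#' single consensus string. FASTA output wraps at 80 columns;
#' [readSequences()] of the result reproduces ids and bases exactly.
#' FASTQ output requires qualities in `mcols(x)$quality` (as produced by
#' [simulateReads()] / [readSequences()]).
#'
#' @param x sequences to write; must be non-empty.
#' @param path output file.
#' @param format "fasta" or "fastq".
#' @return Invisibly, `path`.
#' @export
writeSequences <- function(x, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x <- Biostrings::DNAStringSet(x)
  }
  if (length(x) == 0L) stop("no records to write")
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- paste0("seq", seq_along(x))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    for (i in seq_along(x)) {
      s <- as.character(x[[i]])
      writeLines(paste0(">", names(x)[i]), con)
      starts <- seq(1L, nchar(s), by = 80L)
      writeLines(substring(s, starts, pmin(starts + 79L, nchar(s))), con)
    }
  } else {
    q <- S4Vectors::mcols(x)$quality
    if (is.null(q)) stop("FASTQ output needs mcols(x)$quality")
    for (i in seq_along(x)) {
      s <- as.character(x[[i]])
      writeLines(c(paste0("@", names(x)[i]), s, "+", q[i]), con)
    }
  }
  invisible(path)
}

#' @rdname mucintr-accessors
setMethod("reportJSON", "PipelineReport", function(x) {
  dec <- x@decomposition
  obj <- list(
    schema = x@version,
    seed = x@config@seed,
    counts = as.list(x@counts),
    consensus_length = nchar(x@consensus@sequence),
    exon_span = x@exonSpan,
    exon_length = x@exonSpan[2] - x@exonSpan[1],
    frameshift_edits = nrow(x@editLog),
    resolved = x@resolved,
    n_tr_units = sum(dec@blocks$kind == "TR"),
    unit_lengths = dec@unitLengths,
    accuracy_low_min = min(x@accuracy$low),
    accuracy_high_max = max(x@accuracy$high),
    estimator = x@estimator
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
})
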
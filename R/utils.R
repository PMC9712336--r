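# Small shared helpers. All intervals are 0-based, half-open.

.collapse <- function(v) paste(v, collapse = "")

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Evaluate expr under a temporary RNG state seeded with `seed`
# (NULL = use the current stream), restoring the caller's stream after.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Standard-code translation; internal stops rendered '*'; trailing
# incomplete codon dropped.
.translateDNA <- function(dna, frame = 0L) {
  stopifnot(frame %in% 0:2)
  s <- substr(dna, frame + 1L, nchar(dna))
  usable <- nchar(s) - nchar(s) %% 3L
  if (usable < 3L) return("")
  s <- substr(s, 1L, usable)
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X"))
}

# round half away from zero
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# percentage with 2 decimals, round half-up (display convention)
.pct2 <- function(x) floor(x * 100 * 100 + 0.5) / 100

.isDNAString <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[ACGTN]*$", x)
}

.assertDNA <- function(x, what = "sequence") {
  if (!.isDNAString(toupper(x)))
    stop(what, " must be a DNA string over {A,C,G,T,N}", call. = FALSE)
  toupper(x)
}

# gapped-string coordinate map: for each position of the ungapped `a`
# (1-based), the aligned column index
.baseColumns <- function(gapped) which(.chars(gapped) != "-")

# Canonicalize indel placement in a pairwise alignment: slide every gap
# column rightwards through (B,B) match columns of the same base, so
# equivalent placements of an indel inside a homopolymer run land on the
# run's last column and votes from different reads stack up.
.pushGapsRight <- function(ca, cb) {
  out <- .push_gaps_right_cpp(.collapse(ca), .collapse(cb))
  list(a = .chars(out$a), b = .chars(out$b))
}

# identity of a pairwise alignment: matches / aligned columns
.alnIdentity <- function(ga, gb) {
  ca <- .chars(ga); cb <- .chars(gb)
  sum(ca == cb & ca != "-") / length(ca)
}
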
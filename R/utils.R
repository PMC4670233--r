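# Small shared helpers: alphabet handling, quality decoding, strand arithmetic.

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a character vector of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that
#' accepts and returns plain character vectors.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complementBase <- function(b) unname(COMPLEMENT[b])

## Phred+33 decode of one quality string -> integer vector
qualToInt <- function(q, offset = 33L) {
  as.integer(charToRaw(q)) - offset
}

intToQual <- function(q, offset = 33L) {
  rawToChar(as.raw(q + offset))
}

## Split equal-width sequences into a character matrix (reads x positions)
seqCharMatrix <- function(seqs) {
  w <- unique(nchar(seqs))
  stopifnot(length(w) == 1L)
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = w, byrow = TRUE)
}

## Mismatch class on the transcript strand, e.g. "A>G"; for minus-strand
## sites both alleles are complemented so the class follows the transcript.
mismatchClass <- function(ref, alt, strand) {
  minus <- strand == "-"
  ref[minus] <- complementBase(ref[minus])
  alt[minus] <- complementBase(alt[minus])
  paste0(ref, ">", alt)
}

## The 12 ordered substitution classes, fixed report order
allMismatchClasses <- function() {
  out <- character(0)
  for (r in BASES) for (a in setdiff(BASES, r)) out <- c(out, paste0(r, ">", a))
  out
}

## Deterministic per-component seed derivation from a master seed (keeps
## every derived seed a valid 32-bit integer).
deriveSeed <- function(master, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(master) * 7919 + h) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
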
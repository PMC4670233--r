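# FMRP RNA-recognition-element (RRE) scanning: the ACUK and WGGA motif
# classes (IUPAC K = G/U, W = A/U; U and T treated identically), plus
# exact cross-species conserved-segment matching.

RRE_MOTIFS <- c(ACUK = "ACTK", WGGA = "WGGA")

#' Scan sequences for FMRP RRE motifs (ACUK, WGGA)
#'
#' Finds every occurrence of the two RRE motif classes; overlapping
#' occurrences are all reported. RNA input (U) is handled by unifying the
#' alphabet on T internally; matched 4-mers are reported in the input's
#' DNA form. With a region annotation, each match is labeled by the
#' feature category at its start position (\code{CDS}, \code{3'-UTR}, or
#' \code{other}).
#'
#' @param seqs Named character vector, \code{DNAStringSet} or single
#'   string of nucleotide sequences.
#' @param annotation Optional \linkS4class{AnnotationSet}; sequence names
#'   must then be contig names of the annotation's coordinate system.
#' @return Data frame: \code{seqid}, \code{start} (1-based), \code{motif}
#'   (\code{ACUK}/\code{WGGA}), \code{match} (the 4-mer), \code{region};
#'   rows in ascending (seqid, start, motif) order. Sequences shorter
#'   than 4 yield no rows.
#' @examples
#' scanRre(c(x = "ACTGAGGATGGA"))
#' @export
scanRre <- function(seqs, annotation = NULL) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- if (length(seqs) == 1) "seq1" else
      paste0("seq", seq_along(seqs))
  out <- list()
  for (id in names(seqs)) {
    s <- chartr("Uu", "Tt", seqs[[id]])
    s <- toupper(s)
    if (nchar(s) < 4L) next
    subj <- Biostrings::DNAString(s)
    for (mclass in names(RRE_MOTIFS)) {
      m <- Biostrings::matchPattern(RRE_MOTIFS[[mclass]], subj,
                                    fixed = FALSE)
      if (!length(m)) next
      out[[length(out) + 1L]] <- data.frame(
        seqid = id, start = Biostrings::start(m), motif = mclass,
        match = as.character(m), row.names = NULL)
    }
  }
  if (!length(out))
    return(data.frame(seqid = character(), start = integer(),
                      motif = character(), match = character(),
                      region = character()))
  d <- do.call(rbind, out)
  d <- d[order(d$seqid, d$start, d$motif), , drop = FALSE]
  rownames(d) <- NULL
  d$region <- "other"
  if (!is.null(annotation)) {
    gr <- GRanges(d$seqid, IRanges(d$start, d$start))
    cat_ <- classifyPositions(gr, annotation)
    d$region <- ifelse(cat_ %in% c("CDS", "3'-UTR"), cat_, "other")
  }
  d
}

#' Extract flank-extended RRE segments from a sequence
#'
#' Each RRE 4-mer is extended by \code{flank} bases on each side
#' (truncated at sequence ends); useful as the query set for
#' [conservedRreMatches()].
#'
#' @param seq A single nucleotide sequence.
#' @param flank Bases added on each side of the 4-mer (default 0).
#' @return Character vector of segments (DNA alphabet).
#' @export
extractRreSegments <- function(seq, flank = 0L) {
  hits <- scanRre(c(q = as.character(seq)))
  if (!nrow(hits)) return(character(0))
  s <- toupper(chartr("Uu", "Tt", as.character(seq)))
  from <- pmax(1L, hits$start - flank)
  to <- pmin(nchar(s), hits$start + 3L + flank)
  substring(s, from, to)
}

#' Count query segments with exact occurrences in a target sequence
#'
#' A query counts once if it occurs verbatim in the target (optionally on
#' either strand). Longer segments (larger flank) can only match less,
#' so counts are non-increasing in the flank length used to build the
#' queries.
#'
#' @param querySegments Character vector of segments (e.g. from
#'   [extractRreSegments()]).
#' @param target Target nucleotide sequence (e.g. a CDS).
#' @param bothStrands Also search the reverse complement of the target
#'   (default FALSE: the given strand only).
#' @return List with \code{count} (number of matching queries) and
#'   \code{matched} (logical per query).
#' @export
conservedRreMatches <- function(querySegments, target,
                                bothStrands = FALSE) {
  if (!length(querySegments)) return(list(count = 0L, matched = logical(0)))
  tgt <- Biostrings::DNAString(toupper(chartr("Uu", "Tt",
                                              as.character(target))))
  tgts <- list(tgt)
  if (bothStrands) tgts <- c(tgts, list(Biostrings::reverseComplement(tgt)))
  matched <- vapply(querySegments, function(q) {
    q <- toupper(chartr("Uu", "Tt", q))
    any(vapply(tgts, function(tt)
      Biostrings::countPattern(q, tt) > 0, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  list(count = sum(matched), matched = matched)
}
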
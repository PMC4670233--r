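# Per-position, quality-filtered allele counting (samtools-style pileup
# semantics: deletions reduce depth, insertions are ignored, N bases are
# discarded), with optional read-identity tracking for phasing support.

parseCigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("\\d+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  list(lens = lens, ops = ops)
}

## Expand one read into aligned (refPos, readIdx) pairs for M/=/X blocks.
alignedPairs <- function(pos, cigar) {
  pc <- parseCigar(cigar)
  refPos <- integer(0); readIdx <- integer(0)
  r <- pos; q <- 1L
  for (k in seq_along(pc$ops)) {
    len <- pc$lens[k]
    switch(pc$ops[k],
      M = , `=` = , X = {
        refPos <- c(refPos, seq.int(r, length.out = len))
        readIdx <- c(readIdx, seq.int(q, length.out = len))
        r <- r + len; q <- q + len
      },
      I = , S = { q <- q + len },
      D = { r <- r + len },
      stop("unsupported CIGAR operator in ", cigar)
    )
  }
  list(refPos = refPos, readIdx = readIdx)
}

## Reference span (rightmost aligned position) of reads
refEnd <- function(pos, cigar) {
  vapply(seq_along(pos), function(i) {
    pc <- parseCigar(cigar[i])
    pos[i] + sum(pc$lens[pc$ops %in% c("M", "=", "X", "D")]) - 1L
  }, integer(1))
}

#' Build a quality-filtered pileup from aligned reads
#'
#' Converts aligned reads into one column per covered reference position,
#' counting A/C/G/T bases that pass the base-quality floor. Deleted
#' positions contribute nothing (deletions reduce depth rather than count
#' as a fifth allele), insertions are ignored, N bases are discarded, and
#' a read contributes at most one base per column. Reads from the same
#' fragment are counted independently (single-end chemistry; no overlap
#' de-duplication).
#'
#' @param reads Alignment data frame (see [loadAlignments()]); mapping
#'   quality filtering is assumed done at load time.
#' @param genome Reference \code{DNAStringSet}.
#' @param region Optional \code{GRanges} restricting output columns.
#' @param thresholds A \linkS4class{FilterThresholds}; only
#'   \code{minBaseQual} is used here.
#' @param strand Transcript strand recorded on the columns (\code{"+"},
#'   \code{"-"}); used downstream to orient mismatch classes.
#' @param trackReads If \code{TRUE}, attach a \code{supporters} list column
#'   mapping each base to the supporting read ids.
#' @return A \code{DataFrame} with columns \code{contig}, \code{pos}
#'   (1-based), \code{strand}, \code{ref}, \code{A}, \code{C}, \code{G},
#'   \code{T}, \code{depth} (= A+C+G+T), ordered by contig then position.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC"))
#' rd <- data.frame(qname = "r1", sample = NA, contig = "chr1", pos = 1L,
#'                  mapq = 60L, cigar = "4M", seq = "ACGA",
#'                  qual = "IIII", strand = "+")
#' buildPileup(rd, g)
#' @export
buildPileup <- function(reads, genome, region = NULL,
                        thresholds = filterThresholds(), strand = "+",
                        trackReads = FALSE) {
  if (nrow(reads) == 0L) return(emptyPileup())
  ends <- refEnd(reads$pos, reads$cigar)
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  over <- ends > clen[reads$contig] | reads$pos < 1L
  if (any(is.na(over)))
    stop("read aligned to unknown contig: ",
         reads$qname[which(is.na(over))[1]])
  if (any(over))
    stop("read overhangs contig end: ", reads$qname[which(over)[1]])

  per <- lapply(seq_len(nrow(reads)), function(i) {
    ap <- alignedPairs(reads$pos[i], reads$cigar[i])
    if (!length(ap$refPos)) return(NULL)
    b <- substring(reads$seq[i], ap$readIdx, ap$readIdx)
    q <- qualToInt(reads$qual[i])[ap$readIdx]
    keep <- q >= thresholds@minBaseQual & b %in% BASES
    if (!any(keep)) return(NULL)
    data.table::data.table(contig = reads$contig[i], pos = ap$refPos[keep],
                           base = b[keep], qname = reads$qname[i])
  })
  dt <- data.table::rbindlist(per)
  if (is.null(dt) || nrow(dt) == 0L) return(emptyPileup())

  if (!is.null(region)) {
    keep <- logical(nrow(dt))
    for (i in seq_along(region)) {
      keep <- keep | (dt$contig == as.character(seqnames(region))[i] &
                        dt$pos >= start(region)[i] & dt$pos <= end(region)[i])
    }
    dt <- dt[keep]
    if (nrow(dt) == 0L) return(emptyPileup())
  }

  counts <- data.table::dcast(
    dt[, .N, by = c("contig", "pos", "base")],
    contig + pos ~ base, value.var = "N", fill = 0L)
  for (b in setdiff(BASES, names(counts))) counts[[b]] <- 0L
  data.table::setorder(counts, contig, pos)
  refb <- vapply(seq_len(nrow(counts)), function(i)
    as.character(Biostrings::subseq(genome[[counts$contig[i]]],
                                    counts$pos[i], counts$pos[i])),
    character(1))
  out <- DataFrame(
    contig = counts$contig, pos = counts$pos, strand = strand, ref = refb,
    A = counts$A, C = counts$C, G = counts$G, T = counts$T)
  out$depth <- out$A + out$C + out$G + out$T
  if (trackReads) {
    key <- paste(counts$contig, counts$pos)
    sup <- split(dt, paste(dt$contig, dt$pos))[key]
    out$supporters <- lapply(sup, function(d) split(d$qname, d$base))
  }
  out
}

emptyPileup <- function() {
  DataFrame(contig = character(), pos = integer(), strand = character(),
            ref = character(), A = integer(), C = integer(), G = integer(),
            T = integer(), depth = integer())
}

#' Editing level from allele counts
#'
#' The fraction of edited reads among reference plus edited reads,
#' \code{nAlt / (nRef + nAlt)} — for A-to-I editing, G/(A+G) among
#' quality-passing bases. Vectorised; when both counts are zero the level
#' is undefined and \code{NA} is returned (distinct from 0).
#'
#' @param nRef,nAlt Non-negative counts (recycled).
#' @return Numeric vector of levels in \code{[0, 1]}, \code{NA} where
#'   \code{nRef + nAlt == 0}.
#' @examples
#' editingLevel(98, 2)   # 0.02
#' editingLevel(0, 7)    # 1
#' editingLevel(0, 0)    # NA
#' @export
editingLevel <- function(nRef, nAlt) {
  if (any(nRef < 0 | nAlt < 0, na.rm = TRUE)) stop("counts must be >= 0")
  tot <- nRef + nAlt
  ifelse(tot > 0, nAlt / tot, NA_real_)
}

#' Write a pileup report TSV
#'
#' @param pileup A pileup \code{DataFrame} from [buildPileup()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writePileupReport <- function(pileup, path) {
  df <- as.data.frame(pileup[, c("contig", "pos", "ref", "A", "C", "G",
                                 "T", "depth")])
  df <- df[order(df$contig, df$pos), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
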
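# Readers/writers for external formats (FASTA, FASTQ, SAM subset, BED4)
# and point-query annotation helpers shared by all downstream modules.
#
# Coordinates are 1-based closed internally (the GRanges convention); BED
# input is converted on read, so every report is directly comparable with
# the 1-based "chr5:25066153"-style positions used in site tables.

#' Load a reference genome from FASTA
#'
#' Sequences are upper-cased and any character outside A/C/G/T/N is mapped
#' to N. Duplicate contig names and empty files are hard errors.
#'
#' @param path Path to a FASTA file.
#' @return A \link[Biostrings]{DNAStringSet}, one entry per contig; names
#'   are the first whitespace-delimited token of each header.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT", ">chr2", "TTTT"), fa)
#' loadReference(fa)
#' @export
loadReference <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA: ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate contig name in ", path, ": ",
         names(x)[duplicated(names(x))][1])
  chr <- toupper(as.character(x))
  chr <- gsub("[^ACGTN]", "N", chr)
  if (any(nchar(chr) == 0L)) stop("empty sequence in ", path)
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(x)
  out
}

#' Write a reference genome to FASTA
#'
#' @param genome A named \code{DNAStringSet} (or named character vector).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeReference <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read FASTQ reads with qualities
#'
#' @param path FASTQ file (Phred+33).
#' @return \code{DNAStringSet} with a \code{qualities} metadata column
#'   (\code{BStringSet} of quality strings).
#' @export
loadFastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
}

#' Write FASTQ reads
#'
#' @param reads \code{DNAStringSet} carrying a \code{qualities} metadata
#'   column (as produced by [loadFastq()] or the simulator).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeFastq <- function(reads, path) {
  q <- S4Vectors::mcols(reads)$qualities
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
  invisible(path)
}

SAM_CIGAR_OK <- "MIDS=X"

#' Load aligned reads from a SAM file
#'
#' Parses the plain-text SAM subset used throughout the package: QNAME,
#' FLAG, RNAME, POS, MAPQ, CIGAR (operators M/I/D/S/=/X), SEQ, QUAL.
#' Unmapped records (FLAG bit 0x4 or RNAME \code{*}) and records below
#' \code{minMapq} are excluded. Records whose CIGAR contains an
#' unsupported operator are skipped with a warning; a line with fewer than
#' 11 fields is a hard error naming the line number.
#'
#' @param path SAM file path.
#' @param minMapq Minimum mapping quality (default 20).
#' @param sample Optional sample id attached to every read.
#' @return A data frame of aligned reads with columns \code{qname},
#'   \code{sample}, \code{contig}, \code{pos} (1-based leftmost),
#'   \code{mapq}, \code{strand}, \code{cigar}, \code{seq}, \code{qual}.
#' @export
loadAlignments <- function(path, minMapq = 20, sample = NA_character_) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  if (!length(body)) return(emptyAlignments())
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("malformed SAM line ", body[which(nf < 11L)[1]], " in ", path,
         ": fewer than 11 fields")
  m <- vapply(fields, function(f) f[c(1:6, 10, 11)], character(8))
  df <- data.frame(
    qname = m[1, ], sample = sample,
    flag = as.integer(m[2, ]), contig = m[3, ],
    pos = as.integer(m[4, ]), mapq = as.integer(m[5, ]),
    cigar = m[6, ], seq = toupper(m[7, ]), qual = m[8, ],
    stringsAsFactors = FALSE
  )
  if (any(is.na(df$pos) | is.na(df$flag)))
    stop("malformed SAM line ", body[which(is.na(df$pos) | is.na(df$flag))[1]],
         " in ", path)
  bad <- grepl(sprintf("[^0-9%s]", SAM_CIGAR_OK), df$cigar) & df$cigar != "*"
  if (any(bad)) {
    warning(sum(bad), " record(s) skipped: unsupported CIGAR operator")
    df <- df[!bad, , drop = FALSE]
  }
  mapped <- bitwAnd(df$flag, 4L) == 0L & df$contig != "*" & df$cigar != "*"
  df <- df[mapped & df$mapq >= minMapq, , drop = FALSE]
  df$strand <- ifelse(bitwAnd(df$flag, 16L) != 0L, "-", "+")
  df$flag <- NULL
  rownames(df) <- NULL
  df
}

emptyAlignments <- function() {
  data.frame(qname = character(), sample = character(), contig = character(),
             pos = integer(), mapq = integer(), cigar = character(),
             seq = character(), qual = character(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Write aligned reads as SAM
#'
#' @param reads Alignment data frame as returned by [loadAlignments()].
#' @param path Output path.
#' @param genome Optional reference \code{DNAStringSet} used to emit
#'   \code{@SQ} header lines.
#' @return Invisibly, \code{path}.
#' @export
writeAlignments <- function(reads, path, genome = NULL) {
  hdr <- "@HD\tVN:1.6\tSO:unsorted"
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(genome), width(genome)))
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, flag, reads$contig, reads$pos, reads$mapq,
                  reads$cigar, reads$seq, reads$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

readBed4 <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 4)))
  if (ncol(dt) < 4L) stop("BED4 expected (4 columns) in ", path)
  names(dt)[1:4] <- c("contig", "start", "end", "name")
  if (any(dt$start >= dt$end))
    stop("BED interval with start >= end in ", path)
  # BED is 0-based half-open; convert to 1-based closed GRanges
  GRanges(dt$contig, IRanges(dt$start + 1L, dt$end),
          strand = if (ncol(dt) >= 6) dt[[6]] else "*",
          name = dt$name)
}

#' Load gene-feature and repeat annotations from BED4
#'
#' Column 4 carries the label: feature categories (\code{CDS},
#' \code{5'-UTR}, \code{3'-UTR}, \code{intron}; unknown labels preserved
#' verbatim) in the feature track, repeat-family names in the repeat
#' track. Either path may be \code{NULL} for an empty track.
#'
#' @param featuresBed,repeatsBed BED4 file paths (0-based half-open, an
#'   optional 6th column giving strand).
#' @return An \linkS4class{AnnotationSet}.
#' @export
loadAnnotations <- function(featuresBed = NULL, repeatsBed = NULL) {
  feats <- if (is.null(featuresBed)) GRanges() else readBed4(featuresBed)
  reps <- if (is.null(repeatsBed)) GRanges() else readBed4(repeatsBed)
  if (length(feats)) names(S4Vectors::mcols(feats)) <- "category"
  if (length(reps)) names(S4Vectors::mcols(reps)) <- "family"
  annotationSet(features = feats, repeats = reps)
}

#' Write intervals as BED4
#'
#' @param gr A \code{GRanges} whose first metadata column is the label.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeBed4 <- function(gr, path) {
  name <- if (ncol(S4Vectors::mcols(gr)) >= 1)
    as.character(S4Vectors::mcols(gr)[[1]]) else "."
  lines <- sprintf("%s\t%d\t%d\t%s", as.character(seqnames(gr)),
                   start(gr) - 1L, end(gr), name)
  writeLines(lines, path)
  invisible(path)
}

FEATURE_PRECEDENCE <- c("CDS", "3'-UTR", "5'-UTR", "intron")

#' Classify genomic positions into feature categories
#'
#' Assigns each position exactly one category using the precedence
#' CDS > 3'-UTR > 5'-UTR > intron > intergenic when intervals overlap.
#' Repeat membership is orthogonal and queried with [repeatFamilyAt()].
#'
#' @param positions \code{GRanges} of query positions.
#' @param annotation An \linkS4class{AnnotationSet}.
#' @return Character vector of categories, one per position.
#' @export
classifyPositions <- function(positions, annotation) {
  out <- rep("intergenic", length(positions))
  feats <- featureTrack(annotation)
  if (!length(feats) || !length(positions)) return(out)
  hits <- findOverlaps(positions, feats, ignore.strand = TRUE)
  if (!length(hits)) return(out)
  cat_rank <- match(feats$category[S4Vectors::subjectHits(hits)],
                    FEATURE_PRECEDENCE, nomatch = length(FEATURE_PRECEDENCE) + 1L)
  best <- tapply(seq_along(cat_rank), S4Vectors::queryHits(hits),
                 function(i) i[which.min(cat_rank[i])])
  qi <- as.integer(names(best))
  out[qi] <- feats$category[S4Vectors::subjectHits(hits)[unlist(best)]]
  out
}

#' Repeat family at genomic positions
#'
#' @param positions \code{GRanges} of query positions.
#' @param annotation An \linkS4class{AnnotationSet}.
#' @return Character vector of repeat-family names (\code{NA} outside
#'   repeats); overlapping repeat elements resolve to the first by track
#'   order.
#' @export
repeatFamilyAt <- function(positions, annotation) {
  out <- rep(NA_character_, length(positions))
  reps <- repeatTrack(annotation)
  if (!length(reps) || !length(positions)) return(out)
  hits <- findOverlaps(positions, reps, ignore.strand = TRUE, select = "first")
  ok <- !is.na(hits)
  out[ok] <- reps$family[hits[ok]]
  out
}
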
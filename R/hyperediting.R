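# Candidate editing-site calling, dense same-class cluster detection, and
# the descriptive analytics around them: mismatch spectrum, nucleotide
# neighbor preference, genomic-category assignment, repeat-family and
# hyperedited-gene enrichment.

#' Call candidate editing sites from a pileup
#'
#' Emits a site for every non-reference allele supported by strictly more
#' than \code{heMinEditedReads - 1} quality-passing reads (default: more
#' than five) with an editing level strictly above \code{heMinLevel}
#' (default 0.01). Mismatch classes are expressed on the transcript
#' strand: for minus-strand columns both alleles are complemented, so a
#' genomic T>C appears as A>G.
#'
#' @param pileup Pileup \code{DataFrame} from [buildPileup()].
#' @param thresholds A \linkS4class{FilterThresholds}.
#' @param strand \code{"+"}, \code{"-"} to override the column strand, or
#'   \code{"auto"} (default) to use the strand recorded on each column.
#' @return Width-1 \code{GRanges} with metadata columns \code{class},
#'   \code{nRef}, \code{nAlt}, \code{level}.
#' @export
callCandidateSites <- function(pileup, thresholds = filterThresholds(),
                               strand = "auto") {
  if (nrow(pileup) == 0L) return(emptySites())
  rows <- list()
  colStrand <- if (strand == "auto") pileup$strand else rep(strand, nrow(pileup))
  for (alt in BASES) {
    isAlt <- pileup$ref != alt
    nAlt <- pileup[[alt]]
    nRef <- integer(nrow(pileup))
    for (b in BASES) nRef[pileup$ref == b] <- pileup[[b]][pileup$ref == b]
    lev <- editingLevel(nRef, nAlt)
    hit <- isAlt & nAlt > (thresholds@heMinEditedReads - 1) &
      !is.na(lev) & lev > thresholds@heMinLevel
    if (!any(hit)) next
    rows[[alt]] <- DataFrame(
      contig = pileup$contig[hit], pos = pileup$pos[hit],
      strand = colStrand[hit],
      class = mismatchClass(pileup$ref[hit], rep(alt, sum(hit)),
                            colStrand[hit]),
      nRef = nRef[hit], nAlt = nAlt[hit], level = lev[hit])
  }
  if (!length(rows)) return(emptySites())
  d <- do.call(rbind, unname(rows))
  o <- order(d$contig, d$pos, d$class)
  d <- d[o, ]
  GRanges(d$contig, IRanges(d$pos, d$pos), strand = d$strand,
          class = d$class, nRef = d$nRef, nAlt = d$nAlt, level = d$level)
}

emptySites <- function() {
  GRanges(class = character(), nRef = integer(), nAlt = integer(),
          level = numeric())
}

#' Group candidate sites into dense same-class clusters
#'
#' A cluster is a maximal run of sites sharing contig, strand and mismatch
#' class in which consecutive sites are separated by at most
#' \code{clusterWindowBp} and which contains at least
#' \code{clusterMinSites} sites. Sites in no qualifying run are dropped.
#'
#' @param sites \code{GRanges} from [callCandidateSites()].
#' @param thresholds A \linkS4class{FilterThresholds}.
#' @return \code{GRanges} of cluster spans with metadata \code{class},
#'   \code{size} and \code{members} (an IntegerList of site indices into
#'   the sorted input).
#' @export
clusterCandidates <- function(sites, thresholds = filterThresholds()) {
  if (length(sites) == 0L)
    return(GRanges(class = character(), size = integer()))
  o <- order(as.character(seqnames(sites)), as.character(strand(sites)),
             sites$class, start(sites))
  s <- sites[o]
  key <- paste(as.character(seqnames(s)), as.character(strand(s)), s$class)
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    p <- start(s)[idx]
    newrun <- c(TRUE, diff(p) > thresholds@clusterWindowBp)
    runid <- cumsum(newrun)
    for (r in unique(runid)) {
      m <- idx[runid == r]
      if (length(m) < thresholds@clusterMinSites) next
      out[[length(out) + 1L]] <- data.frame(
        contig = as.character(seqnames(s))[m[1]],
        start = min(start(s)[m]), end = max(start(s)[m]),
        strand = as.character(strand(s))[m[1]],
        class = s$class[m[1]], size = length(m))
    }
  }
  if (!length(out)) return(GRanges(class = character(), size = integer()))
  d <- do.call(rbind, out)
  d <- d[order(d$contig, d$start, d$class), , drop = FALSE]
  GRanges(d$contig, IRanges(d$start, d$end), strand = d$strand,
          class = d$class, size = d$size)
}

#' Detect hyperediting candidates and clusters from aligned reads
#'
#' Convenience wrapper for strand-specific data: builds a pileup per read
#' strand, calls candidate sites with the transcript strand set to the
#' read strand, and clusters the combined candidates.
#'
#' @param alignments Alignment data frame (see [loadAlignments()]).
#' @param genome Reference \code{DNAStringSet}.
#' @param thresholds A \linkS4class{FilterThresholds}.
#' @return List with \code{sites} (candidate \code{GRanges}) and
#'   \code{clusters} (cluster \code{GRanges}).
#' @export
detectHyperediting <- function(alignments, genome,
                               thresholds = filterThresholds()) {
  sites <- list()
  for (st in intersect(c("+", "-"), unique(alignments$strand))) {
    pu <- buildPileup(alignments[alignments$strand == st, , drop = FALSE],
                      genome, thresholds = thresholds, strand = st)
    sites[[st]] <- callCandidateSites(pu, thresholds)
  }
  sites <- do.call(c, unname(sites))
  list(sites = sites, clusters = clusterCandidates(sites, thresholds))
}

#' Mismatch spectrum over the 12 substitution classes
#'
#' @param sites \code{GRanges} with a \code{class} metadata column.
#' @return Named numeric vector of 12 fractions summing to 1, in fixed
#'   class order. Empty input is an error (the spectrum is undefined).
#' @export
mismatchSpectrum <- function(sites) {
  if (length(sites) == 0L) stop("mismatch spectrum undefined for zero sites")
  cls <- factor(sites$class, levels = allMismatchClasses())
  if (anyNA(cls)) stop("unknown mismatch class in input")
  tab <- table(cls)
  as.vector(tab) / length(sites) -> frac
  stats::setNames(frac, names(tab))
}

#' Nucleotide preference of the immediate neighbors of editing sites
#'
#' For each site, the bases 1 bp upstream (offset -1) and downstream
#' (offset +1) are read from the reference and tallied on the transcript
#' strand: for a minus-strand site the -1 neighbor is the reverse
#' complement of the plus-strand base at \code{pos + 1}. Sites at contig
#' ends are skipped (their count is reported in the \code{skipped}
#' attribute).
#'
#' @param sites Width-1 \code{GRanges} with strand.
#' @param genome Reference \code{DNAStringSet}.
#' @return A 2 x 4 matrix of frequencies (rows \code{"-1"}, \code{"+1"};
#'   columns A/C/G/T), each row summing to 1.
#' @export
neighborPreference <- function(sites, genome) {
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  ctg <- as.character(seqnames(sites))
  pos <- start(sites)
  ok <- pos > 1L & pos < clen[ctg]
  skipped <- sum(!ok)
  if (skipped) message(skipped, " site(s) at contig ends skipped")
  sites <- sites[ok]; ctg <- ctg[ok]; pos <- pos[ok]
  if (!length(sites)) stop("no sites with both neighbors inside the contig")
  baseAt <- function(p) {
    vapply(seq_along(p), function(i)
      as.character(Biostrings::subseq(genome[[ctg[i]]], p[i], p[i])),
      character(1))
  }
  up <- baseAt(pos - 1L)   # plus-strand base at -1
  dn <- baseAt(pos + 1L)
  minus <- as.character(strand(sites)) == "-"
  # transcript-strand neighbors: on minus strand, -1 is revcomp of pos+1
  m1 <- ifelse(minus, complementBase(dn), up)
  p1 <- ifelse(minus, complementBase(up), dn)
  prof <- rbind(`-1` = table(factor(m1, levels = BASES)),
                `+1` = table(factor(p1, levels = BASES)))
  prof <- prof / rowSums(prof)
  attr(prof, "skipped") <- skipped
  prof
}

#' Assign sites to genomic feature categories
#'
#' Each site receives exactly one category by the precedence
#' CDS > 3'-UTR > 5'-UTR > intron > intergenic.
#'
#' @param sites \code{GRanges} of sites.
#' @param annotation An \linkS4class{AnnotationSet}.
#' @return A list with \code{assignment} (character per site) and
#'   \code{fractions} (named fractions over observed categories, summing
#'   to 1).
#' @export
annotateSites <- function(sites, annotation) {
  assign <- classifyPositions(sites, annotation)
  frac <- table(assign) / length(assign)
  list(assignment = assign, fractions = c(frac))
}

#' Repeat-family enrichment of edited sites
#'
#' For each repeat family: its share of total repeat bases in the genome
#' (\code{genomicFraction}), its share of repeat-resident edited sites
#' (\code{editedFraction}), and the fold enrichment
#' \code{editedFraction / genomicFraction}. A family holding edited sites
#' but zero annotated bases reports \code{Inf} fold.
#'
#' @param sites \code{GRanges} of edited sites.
#' @param annotation An \linkS4class{AnnotationSet} with a non-empty
#'   repeat track.
#' @return Data frame with columns \code{family}, \code{genomicFraction},
#'   \code{editedFraction}, \code{fold}, sorted by decreasing fold.
#' @export
repeatEnrichment <- function(sites, annotation) {
  reps <- repeatTrack(annotation)
  if (!length(reps)) stop("repeat track is empty")
  baseTot <- tapply(width(reps), reps$family, sum)
  genomicFraction <- baseTot / sum(baseTot)
  fam <- repeatFamilyAt(sites, annotation)
  fam <- fam[!is.na(fam)]
  if (!length(fam)) stop("no edited sites inside repeats")
  edited <- table(factor(fam, levels = union(names(genomicFraction),
                                             unique(fam))))
  editedFraction <- as.vector(edited) / sum(edited)
  gf <- as.vector(genomicFraction)[match(names(edited),
                                         names(genomicFraction))]
  gf[is.na(gf)] <- 0
  out <- data.frame(family = names(edited), genomicFraction = gf,
                    editedFraction = editedFraction,
                    fold = ifelse(gf > 0, editedFraction / gf,
                                  ifelse(editedFraction > 0, Inf, NA)),
                    row.names = NULL)
  out[order(-out$fold), , drop = FALSE]
}

#' Enrichment of hyperedited genes in a target panel
#'
#' Fold enrichment of hyperediting-cluster-containing genes among a gene
#' panel, relative to the genome-wide background fraction:
#' \code{(|panel intersect he| / |panel|) / background}.
#'
#' @param panelGenes Character vector of panel gene names (non-empty).
#' @param heGenes Character vector of genes containing hyperediting
#'   clusters.
#' @param background Genome-wide fraction of genes containing clusters,
#'   in \code{(0, 1]}.
#' @return Fold enrichment (numeric scalar).
#' @examples
#' geneHeEnrichment(paste0("g", 1:12), paste0("g", 1:7), 0.029) # ~20-fold
#' @export
geneHeEnrichment <- function(panelGenes, heGenes, background) {
  if (!length(panelGenes)) stop("panel is empty")
  if (background <= 0 || background > 1)
    stop("background fraction must be in (0, 1]")
  (length(intersect(panelGenes, heGenes)) / length(panelGenes)) / background
}

#' Write a site table TSV
#'
#' @param sites \code{GRanges} with \code{class}, \code{nRef}, \code{nAlt},
#'   \code{level} metadata (optionally \code{category}, \code{family}).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeSiteTable <- function(sites, path) {
  df <- data.frame(contig = as.character(seqnames(sites)),
                   pos = start(sites),
                   strand = as.character(strand(sites)),
                   as.data.frame(S4Vectors::mcols(sites)))
  df <- df[order(df$contig, df$pos), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
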
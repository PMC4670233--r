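# Read-backed phasing of adjacent editing sites into joint allele tuples,
# protein-variant labelling via per-amplicon codon maps, and genotype
# comparison of mRNA-variant abundances.

#' Extract read-backed haplotypes over clustered editing sites
#'
#' Each read spanning \emph{all} clustered sites of one amplicon
#' contributes one allele tuple (transcript-strand bases, one of A/G per
#' site). Reads that do not span every site, carry a base below the
#' quality floor at any site, or show a base other than A/G at any site
#' are excluded (the read is discarded, not the base, so tuples stay
#' complete); per-sample exclusion counts are kept.
#'
#' @param alignments Alignment data frame with a \code{sample} column.
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param ampliconId Amplicon to phase; all \code{sites} must lie on it.
#' @param sites Optional integer vector of 1-based genomic positions
#'   (default: the amplicon's targeted sites); at least two.
#' @param samples Sample ids defining column order (default: those seen
#'   in \code{alignments}).
#' @param thresholds A \linkS4class{FilterThresholds}.
#' @return A \linkS4class{HaplotypeTable}.
#' @export
extractReadHaplotypes <- function(alignments, panel, ampliconId,
                                  sites = NULL, samples = NULL,
                                  thresholds = filterThresholds()) {
  info <- panelInfo(panel)
  a <- match(ampliconId, info$id)
  if (is.na(a)) stop("unknown amplicon: ", ampliconId)
  pos <- sites %||% info$sites[[a]]
  if (length(pos) < 2) stop("phasing requires at least two sites")
  if (any(pos < info$start[a] | pos > info$end[a]))
    stop("sites on different amplicons: positions outside ", ampliconId)
  pos <- sort(pos)
  strandA <- info$strand[a]
  aln <- if ("amplicon" %in% names(alignments))
    alignments[alignments$amplicon == ampliconId, , drop = FALSE]
  else alignments[alignments$contig == info$contig[a], , drop = FALSE]
  samples <- samples %||% unique(aln$sample)

  k <- length(pos)
  baseM <- matrix(NA_character_, nrow(aln), k)
  qualM <- matrix(NA_integer_, nrow(aln), k)
  for (j in seq_len(k)) {
    bq <- baseQualAt(aln, info$contig[a], pos[j])
    baseM[, j] <- bq$base; qualM[, j] <- bq$qual
  }
  spanning <- rowSums(is.na(baseM)) == 0L
  qualOK <- spanning & rowSums(qualM < thresholds@minBaseQual) == 0L
  ts <- baseM
  if (strandA == "-") ts[] <- complementBase(as.vector(ts))
  agOK <- qualOK & rowSums(matrix(!(ts %in% c("A", "G")), nrow(aln))) == 0L

  tuples <- apply(ts, 1, paste0, collapse = "")
  allTuples <- apply(expand.grid(rep(list(c("A", "G")), k))[, k:1,
                                                            drop = FALSE],
                     1, paste0, collapse = "")
  allTuples <- sort(allTuples)
  counts <- matrix(0L, length(allTuples), length(samples),
                   dimnames = list(allTuples, samples))
  sm <- factor(aln$sample, levels = samples)
  if (any(agOK)) {
    tab <- table(factor(tuples[agOK], levels = allTuples), sm[agOK])
    counts[] <- as.integer(tab)
  }
  excl <- rbind(
    notSpanning = as.integer(table(sm[!spanning])),
    lowQual = as.integer(table(sm[spanning & !qualOK])),
    nonAG = as.integer(table(sm[qualOK & !agOK])))
  colnames(excl) <- samples

  gr <- GRanges(info$contig[a], IRanges(pos, pos), strand = strandA)
  labels <- character(0)
  cm <- panel@codonMaps[[ampliconId]]
  if (!is.null(cm)) {
    labels <- vapply(allTuples, labelProteinVariants, character(1),
                     codonMap = cm, sitePositions = pos)
  }
  new("HaplotypeTable", amplicon = ampliconId, sites = gr,
      counts = counts, excluded = excl, labels = labels)
}

#' Protein-variant label for an allele tuple
#'
#' Substitutes each site's transcript-strand allele (A or G) into its
#' reference codon at the mapped codon position and translates with the
#' standard genetic code; per-codon amino acids are concatenated in codon
#' order (sites sharing a codon index are substituted into the same
#' codon). For example, an unedited tuple may translate to \code{"LR"}
#' and a double-edited one to \code{"AV"}.
#'
#' @param tuple Allele tuple string over \{A, G\}, in site order (e.g.
#'   \code{"AG"}).
#' @param codonMap Data frame with columns \code{site}, \code{codon},
#'   \code{refCodon}, \code{codonPos} (see
#'   \linkS4class{AmpliconPanel}).
#' @param sitePositions Genomic positions giving the tuple's site order
#'   (default: \code{codonMap$site} in ascending order).
#' @return Single amino-acid label string.
#' @export
labelProteinVariants <- function(tuple, codonMap, sitePositions = NULL) {
  pos <- sitePositions %||% sort(codonMap$site)
  alleles <- strsplit(tuple, "")[[1]]
  if (length(alleles) != length(pos))
    stop("tuple arity does not match the number of sites")
  if (!all(alleles %in% c("A", "G"))) stop("tuple must be over {A, G}")
  codons <- list()
  for (ci in unique(codonMap$codon)) codons[[as.character(ci)]] <-
    strsplit(codonMap$refCodon[match(ci, codonMap$codon)], "")[[1]]
  for (j in seq_along(pos)) {
    row <- match(pos[j], codonMap$site)
    if (is.na(row)) stop("site ", pos[j], " absent from codon map")
    cp <- codonMap$codonPos[row]
    if (cp < 1 || cp > 3)
      stop("codon position inconsistent with frame at site ", pos[j])
    codons[[as.character(codonMap$codon[row])]][cp] <- alleles[j]
  }
  aa <- vapply(unique(codonMap$codon), function(ci) {
    codon <- paste0(codons[[as.character(ci)]], collapse = "")
    Biostrings::GENETIC_CODE[[codon]]
  }, character(1))
  paste0(aa[order(unique(codonMap$codon))], collapse = "")
}

#' Per-sample relative abundance of variant tuples
#'
#' @param ht A \linkS4class{HaplotypeTable}.
#' @return Matrix of per-sample tuple proportions (columns sum to 1;
#'   samples with zero phased reads give \code{NA}).
#' @export
variantAbundance <- function(ht) {
  cnt <- haplotypeCounts(ht)
  tot <- colSums(cnt)
  sweep(cnt, 2, ifelse(tot > 0, tot, NA_real_), "/")
}

#' Differential variant abundance between genotypes
#'
#' Per tuple, compares per-sample relative abundances between the two
#' genotypes with Welch's t-test. A variant absent from every sample of a
#' group enters with abundance 0, not skipped.
#'
#' @param ht A \linkS4class{HaplotypeTable}.
#' @param sheet Sample sheet with \code{id} and \code{genotype} covering
#'   the table's samples (>= 2 samples per genotype).
#' @return Data frame: \code{tuple}, \code{label}, per-group mean/SEM,
#'   \code{t}, \code{df}, \code{p}.
#' @export
differentialVariantAbundance <- function(ht, sheet) {
  ab <- variantAbundance(ht)
  gt <- sheet$genotype[match(colnames(ab), sheet$id)]
  gl <- unique(gt[!is.na(gt)])
  if (length(gl) != 2) stop("exactly two genotypes required")
  labs <- variantLabels(ht)
  rows <- lapply(rownames(ab), function(tp) {
    x <- ab[tp, gt == gl[1]]; x <- x[!is.na(x)]
    y <- ab[tp, gt == gl[2]]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    w <- welchTTest(x, y)
    data.frame(tuple = tp,
               label = if (length(labs)) labs[[tp]] else NA_character_,
               mean1 = w$meanX, sem1 = stats::sd(x) / sqrt(length(x)),
               mean2 = w$meanY, sem2 = stats::sd(y) / sqrt(length(y)),
               t = w$t, df = w$df, p = w$p.value, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- gl
  out
}

#' Write a haplotype table TSV
#'
#' @param ht A \linkS4class{HaplotypeTable}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeHaplotypeTable <- function(ht, path) {
  cnt <- haplotypeCounts(ht)
  ab <- variantAbundance(ht)
  labs <- variantLabels(ht)
  long <- do.call(rbind, lapply(colnames(cnt), function(s)
    data.frame(amplicon = ht@amplicon, sample = s, tuple = rownames(cnt),
               label = if (length(labs)) labs[rownames(cnt)] else NA,
               count = cnt[, s], abundance = ab[, s], row.names = NULL)))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
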
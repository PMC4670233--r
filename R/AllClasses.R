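#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#' @importFrom IRanges IRanges findOverlaps
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowRanges
NULL

# ---------------------------------------------------------------------------
# FilterThresholds
# ---------------------------------------------------------------------------

#' Filter thresholds for editing-site detection and quantification
#'
#' A single value object holding every numeric cutoff used across the
#' pipeline, so that each report is reproducible from counts plus one
#' threshold set.
#'
#' Slots (with defaults):
#' \describe{
#'   \item{minBaseQual}{Minimum Phred base quality for a base to be counted
#'     (default 20).}
#'   \item{minMapq}{Minimum mapping quality for a read to be used
#'     (default 20).}
#'   \item{minMismatchReads}{Minimum number of quality-passing mismatch
#'     (G) reads required to call a novel off-target site (default 10).}
#'   \item{heMinEditedReads}{Hyperediting candidate calling requires
#'     strictly more than \code{heMinEditedReads - 1} edited reads, i.e. the
#'     default 6 encodes "more than five edited reads".}
#'   \item{heMinLevel}{Editing level must strictly exceed this value for a
#'     hyperediting candidate (default 0.01, exclusive).}
#'   \item{ampMinCoverage}{A sample/site cell counts as captured when its
#'     A+G depth is at least this many reads (default 400).}
#'   \item{ampMinLevel}{Minimum genotype-mean editing level for a site to be
#'     retained in the amplicon cascade (default 0.02).}
#'   \item{ampMinIncidence}{Minimum fraction of a genotype's samples in
#'     which a site must be captured (default 0.75).}
#'   \item{clusterWindowBp}{Maximum gap between consecutive same-class sites
#'     within a hyperediting cluster (default 100 bp).}
#'   \item{clusterMinSites}{Minimum number of same-class sites per cluster
#'     (default 3).}
#'   \item{snpMaxGdnaAlt}{A site is masked as a genomic SNP when the pooled
#'     gDNA alternate fraction exceeds this value (default 0.01).}
#' }
#'
#' @aliases FilterThresholds
#' @export
setClass("FilterThresholds", representation(
  minBaseQual = "numeric",
  minMapq = "numeric",
  minMismatchReads = "numeric",
  heMinEditedReads = "numeric",
  heMinLevel = "numeric",
  ampMinCoverage = "numeric",
  ampMinLevel = "numeric",
  ampMinIncidence = "numeric",
  clusterWindowBp = "numeric",
  clusterMinSites = "numeric",
  snpMaxGdnaAlt = "numeric"
), prototype(
  minBaseQual = 20, minMapq = 20, minMismatchReads = 10,
  heMinEditedReads = 6, heMinLevel = 0.01,
  ampMinCoverage = 400, ampMinLevel = 0.02, ampMinIncidence = 0.75,
  clusterWindowBp = 100, clusterMinSites = 3, snpMaxGdnaAlt = 0.01
))

setValidity("FilterThresholds", function(object) {
  vals <- vapply(slotNames(object), function(s) slot(object, s), numeric(1))
  if (any(vals < 0)) return("all thresholds must be non-negative")
  lv <- c(object@heMinLevel, object@ampMinLevel, object@ampMinIncidence,
          object@snpMaxGdnaAlt)
  if (any(lv < 0 | lv > 1)) return("level thresholds must lie in [0, 1]")
  TRUE
})

#' Construct a FilterThresholds object
#'
#' @param ... Named threshold overrides; see \linkS4class{FilterThresholds}
#'   for slot names and defaults.
#' @return A \linkS4class{FilterThresholds} object.
#' @examples
#' filterThresholds()
#' filterThresholds(ampMinCoverage = 500)
#' @export
filterThresholds <- function(...) new("FilterThresholds", ...)

setMethod("show", "FilterThresholds", function(object) {
  cat("FilterThresholds\n")
  for (s in slotNames(object))
    cat(sprintf("  %-18s %g\n", s, slot(object, s)))
})

# ---------------------------------------------------------------------------
# AnnotationSet
# ---------------------------------------------------------------------------

#' Gene-feature and repeat annotation container
#'
#' Holds two interval tracks as \link[GenomicRanges]{GRanges}: gene features
#' labeled \code{CDS}, \code{5'-UTR}, \code{3'-UTR} or \code{intron} (label in
#' the \code{category} metadata column) and repeat elements labeled with a
#' repeat-family name (in the \code{family} metadata column). Feature
#' categories and repeat membership are orthogonal: a position may be, say,
#' both intronic and inside a repeat.
#'
#' @aliases AnnotationSet
#' @export
setClass("AnnotationSet", representation(
  features = "GRanges",
  repeats = "GRanges"
))

setValidity("AnnotationSet", function(object) {
  if (length(object@features) && is.null(object@features$category))
    return("features must carry a 'category' metadata column")
  if (length(object@repeats) && is.null(object@repeats$family))
    return("repeats must carry a 'family' metadata column")
  TRUE
})

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet:", length(object@features), "feature intervals,",
      length(object@repeats), "repeat intervals\n")
  if (length(object@repeats))
    cat("  repeat families:",
        paste(unique(object@repeats$family), collapse = ", "), "\n")
})

#' @rdname AnnotationSet-class
#' @param features,repeats \code{GRanges} with \code{category} /
#'   \code{family} metadata columns (either may be empty).
#' @return An \linkS4class{AnnotationSet}.
#' @export
annotationSet <- function(features = GRanges(), repeats = GRanges()) {
  new("AnnotationSet", features = features, repeats = repeats)
}

#' @rdname AnnotationSet-class
#' @param x An \code{AnnotationSet}.
#' @export
featureTrack <- function(x) x@features

#' @rdname AnnotationSet-class
#' @export
repeatTrack <- function(x) x@repeats

# ---------------------------------------------------------------------------
# AmpliconPanel
# ---------------------------------------------------------------------------

#' Targeted amplicon panel definition
#'
#' One row per amplicon: genomic interval, transcript strand, reference
#' subsequence, primer lengths and the targeted editing-site positions
#' (1-based genomic coordinates). Optional per-amplicon codon maps allow
#' protein-recoding labels for phased variants.
#'
#' @slot info A \code{DataFrame} with columns \code{id}, \code{gene},
#'   \code{contig}, \code{start}, \code{end}, \code{strand}, \code{refseq}
#'   (amplicon sequence on the genome plus strand), \code{fwdPrimerLen},
#'   \code{revPrimerLen} and a list column \code{sites} of 1-based genomic
#'   positions.
#' @slot codonMaps Named list (amplicon id) of codon-map data frames with
#'   columns \code{site} (genomic position), \code{codon} (codon index in
#'   label order), \code{refCodon} (transcript-strand reference codon) and
#'   \code{codonPos} (1-3, position of the editable base in the codon).
#' @aliases AmpliconPanel
#' @export
setClass("AmpliconPanel", representation(
  info = "DataFrame",
  codonMaps = "list"
))

setValidity("AmpliconPanel", function(object) {
  need <- c("id", "gene", "contig", "start", "end", "strand", "refseq",
            "fwdPrimerLen", "revPrimerLen", "sites")
  miss <- setdiff(need, colnames(object@info))
  if (length(miss))
    return(paste("panel info missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(object@info$id)) return("amplicon ids must be unique")
  for (i in seq_len(nrow(object@info))) {
    st <- object@info$start[i]; en <- object@info$end[i]
    if (nchar(object@info$refseq[i]) != en - st + 1L)
      return(sprintf("amplicon %s: refseq length != interval width",
                     object@info$id[i]))
    ss <- object@info$sites[[i]]
    f <- object@info$fwdPrimerLen[i]; r <- object@info$revPrimerLen[i]
    if (length(ss) && (any(ss < st + f) || any(ss > en - r)))
      return(sprintf("amplicon %s: targeted site inside primer span or outside amplicon",
                     object@info$id[i]))
  }
  TRUE
})

setMethod("show", "AmpliconPanel", function(object) {
  cat("AmpliconPanel:", nrow(object@info), "amplicons,",
      sum(lengths(object@info$sites)), "targeted sites\n")
})

#' @rdname AmpliconPanel-class
#' @param info,codonMaps See the slot descriptions.
#' @export
ampliconPanel <- function(info, codonMaps = list()) {
  if (is.data.frame(info)) info <- DataFrame(info, check.names = FALSE)
  new("AmpliconPanel", info = info, codonMaps = codonMaps)
}

#' @rdname AmpliconPanel-class
#' @param x An \code{AmpliconPanel}.
#' @export
panelInfo <- function(x) x@info

#' @rdname AmpliconPanel-class
#' @param id Amplicon identifier.
#' @export
codonMap <- function(x, id) x@codonMaps[[id]]

#' Targeted sites of a panel as a GRanges
#'
#' @param panel An \linkS4class{AmpliconPanel}.
#' @return \code{GRanges} of all targeted sites (width 1) with metadata
#'   columns \code{amplicon}, \code{gene} and \code{targeted = TRUE}; strand
#'   is the transcript strand of the amplicon.
#' @export
panelSites <- function(panel) {
  info <- panelInfo(panel)
  if (!nrow(info) || !sum(lengths(info$sites))) return(GRanges())
  idx <- rep(seq_len(nrow(info)), lengths(info$sites))
  pos <- unlist(info$sites, use.names = FALSE)
  GRanges(info$contig[idx], IRanges(pos, pos), strand = info$strand[idx],
          amplicon = info$id[idx], gene = info$gene[idx], targeted = TRUE)
}

# ---------------------------------------------------------------------------
# SiteEditingTable
# ---------------------------------------------------------------------------

#' Samples-by-sites editing level table
#'
#' The central object of the amplicon pipeline: a
#' \link[SummarizedExperiment]{RangedSummarizedExperiment} whose rows are
#' editing sites (width-1 \code{GRanges}, strand = transcript strand) and
#' whose columns are samples. Assays:
#' \describe{
#'   \item{nA}{quality-passing A counts on the transcript strand}
#'   \item{nG}{quality-passing G counts on the transcript strand}
#'   \item{depth}{\code{nA + nG}}
#'   \item{level}{editing level \code{nG / (nA + nG)}, \code{NA} at depth 0}
#' }
#' \code{rowData} carries \code{amplicon}, \code{gene} and \code{targeted}
#' (FALSE for discovered off-target sites); \code{colData} carries the
#' sample sheet columns (\code{barcode}, \code{genotype}, \code{material}).
#'
#' @aliases SiteEditingTable
#' @export
setClass("SiteEditingTable", contains = "RangedSummarizedExperiment")

setValidity("SiteEditingTable", function(object) {
  need <- c("nA", "nG", "depth", "level")
  miss <- setdiff(need, SummarizedExperiment::assayNames(object))
  if (length(miss))
    return(paste("missing assays:", paste(miss, collapse = ", ")))
  d <- assay(object, "depth")
  if (length(d) && any(d != assay(object, "nA") + assay(object, "nG")))
    return("depth must equal nA + nG")
  TRUE
})

setMethod("show", "SiteEditingTable", function(object) {
  cat("SiteEditingTable:", nrow(object), "sites x", ncol(object), "samples\n")
  if (nrow(object)) {
    tg <- rowData(object)$targeted
    cat("  targeted:", sum(tg), " off-target:", sum(!tg), "\n")
  }
  callNextMethod()
})

#' Accessors for SiteEditingTable assays
#'
#' @param x A \linkS4class{SiteEditingTable}.
#' @return \code{editingLevels} returns the level matrix (sites x samples);
#'   \code{coverageDepth} the A+G depth matrix.
#' @export
editingLevels <- function(x) assay(x, "level")

#' @rdname editingLevels
#' @export
coverageDepth <- function(x) assay(x, "depth")

# ---------------------------------------------------------------------------
# HaplotypeTable
# ---------------------------------------------------------------------------

#' Read-backed haplotypes over clustered editing sites
#'
#' Joint A/G allele tuples observed on single reads spanning all clustered
#' sites of one amplicon, counted per sample. Tuples are strings over
#' \{A, G\} in site order (e.g. \code{"AG"}), expressed on the transcript
#' strand.
#'
#' @slot amplicon Amplicon id.
#' @slot sites Width-1 \code{GRanges} of the phased sites, in tuple order.
#' @slot counts Integer matrix, tuples x samples; rownames are tuples.
#' @slot excluded Integer matrix of per-sample excluded read counts with
#'   rows \code{notSpanning}, \code{lowQual}, \code{nonAG}.
#' @slot labels Optional named character vector mapping tuple to
#'   protein-variant label (e.g. \code{"LR"}).
#' @aliases HaplotypeTable
#' @export
setClass("HaplotypeTable", representation(
  amplicon = "character",
  sites = "GRanges",
  counts = "matrix",
  excluded = "matrix",
  labels = "character"
))

setValidity("HaplotypeTable", function(object) {
  k <- length(object@sites)
  if (k < 2) return("phasing requires at least two sites")
  if (!all(nchar(rownames(object@counts)) == k))
    return("tuple arity must equal the number of sites")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable:", object@amplicon, "-", length(object@sites),
      "sites,", nrow(object@counts), "tuples x", ncol(object@counts),
      "samples;", sum(object@counts), "phased reads\n")
})

#' @rdname HaplotypeTable-class
#' @param x A \code{HaplotypeTable}.
#' @export
haplotypeCounts <- function(x) x@counts

#' @rdname HaplotypeTable-class
#' @export
phasedSites <- function(x) x@sites

#' @rdname HaplotypeTable-class
#' @export
variantLabels <- function(x) x@labels

# ---------------------------------------------------------------------------
# SimConfig / SyntheticTruth
# ---------------------------------------------------------------------------

#' Synthetic-data generator configuration
#'
#' Defaults describe the desk-scale study conditions the package simulates:
#' 76-bp strand-specific transcriptome reads over a small genome with
#' hyperediting clusters planted inside inverted repeats, and a targeted
#' amplicon panel read at deep coverage in two genotypes of ten samples
#' each with a small genotype-dependent editing shift.
#'
#' @slot nContigs,contigLength Genome layout.
#' @slot readLength Transcriptome read length (bp).
#' @slot readDepth Transcriptome reads per cluster region.
#' @slot clusterCount,clusterSize,clusterSpacing Planted hyperediting
#'   clusters: how many, sites per cluster, spacing between sites (bp).
#' @slot siteLevel Editing level of planted transcriptome sites.
#' @slot propAG Proportion of planted mismatch sites that are A-to-G
#'   (remainder spread over the other 11 classes).
#' @slot nAmplicons,ampliconLength,sitesPerAmplicon,primerLen Amplicon
#'   panel layout.
#' @slot samplesPerGenotype,gdnaPerGenotype Samples per genotype for RNA
#'   and matched gDNA.
#' @slot ampliconDepth Reads per amplicon per sample.
#' @slot baseLevel Mean editing level of targeted amplicon sites in the
#'   reference genotype.
#' @slot effectSize Genotype shift in editing level at affected sites.
#' @slot errorRate Per-base substitution sequencing error rate.
#' @slot barcodeLength Sample barcode length (bp).
#' @slot seed Master seed; every derived random stream is a pure function
#'   of it.
#' @aliases SimConfig
#' @export
setClass("SimConfig", representation(
  nContigs = "integer", contigLength = "integer",
  readLength = "integer", readDepth = "integer",
  clusterCount = "integer", clusterSize = "integer",
  clusterSpacing = "integer", siteLevel = "numeric", propAG = "numeric",
  nAmplicons = "integer", ampliconLength = "integer",
  sitesPerAmplicon = "integer", primerLen = "integer",
  samplesPerGenotype = "integer", gdnaPerGenotype = "integer",
  ampliconDepth = "integer", baseLevel = "numeric", effectSize = "numeric",
  errorRate = "numeric", barcodeLength = "integer", seed = "integer"
), prototype(
  nContigs = 2L, contigLength = 20000L,
  readLength = 76L, readDepth = 60L,
  clusterCount = 8L, clusterSize = 5L, clusterSpacing = 12L,
  siteLevel = 0.3, propAG = 0.93,
  nAmplicons = 8L, ampliconLength = 120L, sitesPerAmplicon = 2L,
  primerLen = 18L,
  samplesPerGenotype = 10L, gdnaPerGenotype = 3L,
  ampliconDepth = 2000L, baseLevel = 0.3, effectSize = 0.04,
  errorRate = 0.001, barcodeLength = 8L, seed = 1L
))

setValidity("SimConfig", function(object) {
  ints <- c(object@nContigs, object@contigLength, object@readLength,
            object@clusterCount, object@clusterSize, object@nAmplicons,
            object@ampliconLength, object@sitesPerAmplicon,
            object@samplesPerGenotype, object@ampliconDepth,
            object@barcodeLength)
  if (any(ints <= 0)) return("all counts must be positive")
  if (object@baseLevel + object@effectSize > 1 ||
      object@baseLevel - object@effectSize < 0)
    return("effect size must keep levels inside [0, 1]")
  if (object@errorRate < 0 || object@errorRate > 0.5)
    return("errorRate must lie in [0, 0.5]")
  TRUE
})

#' @rdname SimConfig-class
#' @param ... Named slot overrides (integers may be given as doubles).
#' @export
simConfig <- function(...) {
  args <- list(...)
  proto <- new("SimConfig")
  for (nm in names(args)) {
    if (is(slot(proto, nm), "integer")) args[[nm]] <- as.integer(args[[nm]])
  }
  do.call(new, c(list("SimConfig"), args))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig (seed", object@seed, ")\n")
  cat("  transcriptome:", object@nContigs, "x", object@contigLength,
      "bp contigs,", object@clusterCount, "clusters of",
      object@clusterSize, "sites at level", object@siteLevel, "\n")
  cat("  amplicons:", object@nAmplicons, "x", object@ampliconLength, "bp,",
      object@samplesPerGenotype, "samples/genotype at depth",
      object@ampliconDepth, "\n")
})

#' Ground truth of a synthetic dataset
#'
#' Everything the generator planted, for use as the oracle in recovery
#' tests: transcriptome sites and clusters, per-genotype amplicon editing
#' levels, joint haplotype distributions, SNP positions and the seed tree.
#'
#' @slot sites \code{GRanges} of planted transcriptome editing sites with
#'   metadata \code{class} (mismatch class, transcript strand),
#'   \code{level} and \code{cluster} (cluster id).
#' @slot siteLevels Data frame of planted amplicon site levels: columns
#'   \code{site} (genomic position), \code{amplicon}, \code{strand}, and
#'   one column per genotype.
#' @slot haplotypes Named list (amplicon id) of per-genotype joint tuple
#'   probability vectors.
#' @slot snps Data frame of planted genomic SNPs: \code{contig},
#'   \code{pos}, \code{amplicon}, \code{zygosity} (\code{het}/\code{hom}),
#'   \code{altBase} (plus-strand).
#' @slot ampliconDepths Data frame of per-amplicon read depths
#'   (\code{amplicon}, \code{depth}): the configured depth scaled by a
#'   shared amplification-efficiency factor, identical across samples.
#' @slot config The \linkS4class{SimConfig} used.
#' @aliases SyntheticTruth
#' @export
setClass("SyntheticTruth", representation(
  sites = "GRanges",
  siteLevels = "data.frame",
  haplotypes = "list",
  snps = "data.frame",
  ampliconDepths = "data.frame",
  config = "SimConfig"
))

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@sites), "transcriptome sites,",
      nrow(object@siteLevels), "amplicon sites,",
      nrow(object@snps), "SNPs\n")
})

#' @rdname SyntheticTruth-class
#' @param x A \code{SyntheticTruth}.
#' @export
trueSites <- function(x) x@sites

#' @rdname SyntheticTruth-class
#' @export
trueSiteLevels <- function(x) x@siteLevels

#' @rdname SyntheticTruth-class
#' @export
trueHaplotypes <- function(x) x@haplotypes

#' @rdname SyntheticTruth-class
#' @export
trueSnps <- function(x) x@snps
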
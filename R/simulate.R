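# Synthetic-data generation with full ground truth: a small genome with
# repeat/feature annotation and hyperediting clusters planted inside
# inverted-repeat elements; strand-specific transcriptome reads with
# binomial per-site editing; and a complete targeted amplicon experiment
# (barcoded RNA and gDNA reads, panel, sample sheet) with per-genotype
# editing levels, linked haplotypes, heterozygous/homozygous SNPs and
# Phred-scored sequencing error. Every random stream derives
# deterministically from the master seed.

Q30CHAR <- "?"  # Phred+33 for Q30

randomSeq <- function(n) paste(sample(BASES, n, replace = TRUE),
                               collapse = "")

## Repeat-family layout: genomic base fractions of the repeat track, and
## the probability that a planted cluster lands in each family (the hAT
## share is inflated to emulate inverted-repeat-driven editing).
SIM_FAMILIES <- c(hAT = 0.08, TC1 = 0.30, LINE = 0.25, SINE = 0.22,
                  LTR = 0.15)
SIM_CLUSTER_HOST <- c(hAT = 0.26,
                      TC1 = 0.30 / 0.92 * 0.74, LINE = 0.25 / 0.92 * 0.74,
                      SINE = 0.22 / 0.92 * 0.74, LTR = 0.15 / 0.92 * 0.74)

#' Simulate a reference genome with annotations and planted clusters
#'
#' Builds random contigs; places non-overlapping repeat elements whose
#' per-family base fractions follow a fixed layout (hAT 8% of repeat
#' bases), including one exact inverted-repeat pair of hAT arms; places
#' gene features (5'-UTR, CDS, intron, 3'-UTR); and plants
#' \code{clusterCount} same-class editing-site clusters, preferentially
#' inside hAT elements, rewriting the reference base at each site to
#' match its mismatch class. Deterministic for a fixed
#' \code{config@seed}.
#'
#' @param config A \linkS4class{SimConfig}.
#' @return List with \code{genome} (\code{DNAStringSet}),
#'   \code{annotation} (\linkS4class{AnnotationSet}) and \code{truth}
#'   (\linkS4class{SyntheticTruth} skeleton: planted sites only).
#' @export
simulateReference <- function(config = simConfig()) {
  set.seed(deriveSeed(config@seed, "reference"))
  contigs <- stats::setNames(
    vapply(seq_len(config@nContigs), function(i)
      randomSeq(config@contigLength), character(1)),
    paste0("chr", seq_len(config@nContigs)))

  elementLen <- 240L
  armLen <- 120L
  if (armLen * 2 + 100 > config@contigLength)
    stop("inverted-repeat arms longer than contig")
  repTargetBases <- round(0.3 * config@contigLength * config@nContigs)
  famBases <- round(SIM_FAMILIES / sum(SIM_FAMILIES) * repTargetBases)
  reps <- list()
  cursor <- stats::setNames(rep(1L, config@nContigs), names(contigs))
  ctgIdx <- 1L
  for (fam in names(famBases)) {
    placed <- 0L
    while (placed < famBases[[fam]]) {
      ctg <- names(contigs)[ctgIdx]
      ctgIdx <- ctgIdx %% config@nContigs + 1L
      st <- cursor[ctg]
      if (st + elementLen > config@contigLength) next
      reps[[length(reps) + 1L]] <- data.frame(
        contig = ctg, start = st, end = st + elementLen - 1L, family = fam)
      cursor[ctg] <- st + elementLen + 60L
      placed <- placed + elementLen
    }
  }
  repDf <- do.call(rbind, reps)

  # inverted-repeat pair: overwrite two hAT elements with exact
  # reverse-complement arms separated by a loop
  hat <- which(repDf$family == "hAT")
  ir <- hat[1:2]
  arm <- randomSeq(armLen)
  s1 <- repDf$start[ir[1]]; s2 <- repDf$start[ir[2]]
  ctg1 <- repDf$contig[ir[1]]
  substr(contigs[[ctg1]], s1, s1 + armLen - 1L) <- arm
  if (repDf$contig[ir[2]] == ctg1)
    substr(contigs[[ctg1]], s2, s2 + armLen - 1L) <- revcomp(arm)
  else
    substr(contigs[[repDf$contig[ir[2]]]], s2, s2 + armLen - 1L) <-
      revcomp(arm)

  # gene features: one gene per contig half, fixed internal layout
  featDf <- do.call(rbind, lapply(names(contigs), function(ctg) {
    gstart <- round(config@contigLength * 0.55)
    w <- round(config@contigLength * 0.4 / 5)
    cats <- c("5'-UTR", "CDS", "intron", "CDS", "3'-UTR")
    data.frame(contig = ctg,
               start = gstart + (seq_along(cats) - 1L) * w,
               end = gstart + seq_along(cats) * w - 1L,
               category = cats)
  }))

  # plant clusters: host family sampled with the configured preference
  nc <- config@clusterCount
  hostFam <- sample(names(SIM_CLUSTER_HOST), nc, replace = TRUE,
                    prob = SIM_CLUSTER_HOST)
  siteRows <- list()
  used <- integer(0)
  for (ci in seq_len(nc)) {
    candidates <- setdiff(which(repDf$family == hostFam[ci]), used)
    if (!length(candidates)) candidates <- setdiff(seq_len(nrow(repDf)), used)
    el <- candidates[sample.int(length(candidates), 1L)]
    used <- c(used, el)
    ctg <- repDf$contig[el]
    strand <- sample(c("+", "-"), 1L)
    cls <- if (stats::runif(1) < config@propAG) "A>G" else
      sample(setdiff(allMismatchClasses(), "A>G"), 1L)
    refTs <- substr(cls, 1, 1)
    altTs <- substr(cls, 3, 3)
    refPlus <- if (strand == "+") refTs else complementBase(refTs)
    pos <- repDf$start[el] +
      seq(0L, by = config@clusterSpacing,
          length.out = config@clusterSize)
    pos <- pos[pos <= repDf$end[el]]
    for (p in pos)
      substr(contigs[[ctg]], p, p) <- refPlus
    siteRows[[ci]] <- data.frame(
      contig = ctg, pos = pos, strand = strand, class = cls,
      altTs = altTs, level = config@siteLevel, cluster = ci)
  }
  sitesDf <- do.call(rbind, siteRows)
  genome <- Biostrings::DNAStringSet(contigs)
  ann <- annotationSet(
    features = GRanges(featDf$contig, IRanges(featDf$start, featDf$end),
                       category = featDf$category),
    repeats = GRanges(repDf$contig, IRanges(repDf$start, repDf$end),
                      family = repDf$family))
  truth <- new("SyntheticTruth",
               sites = GRanges(sitesDf$contig,
                               IRanges(sitesDf$pos, sitesDf$pos),
                               strand = sitesDf$strand,
                               class = sitesDf$class, altTs = sitesDf$altTs,
                               level = sitesDf$level,
                               cluster = sitesDf$cluster),
               siteLevels = data.frame(), haplotypes = list(),
               snps = data.frame(), ampliconDepths = data.frame(),
               config = config)
  list(genome = genome, annotation = ann, truth = truth)
}

#' Simulate strand-specific transcriptome reads over planted clusters
#'
#' For each planted cluster, draws \code{readDepth} gapless reads of
#' \code{readLength} bp from the cluster's transcript strand, uniformly
#' positioned over the cluster span; each read independently carries the
#' edited base at each covered planted site with that site's level, then
#' uniform substitution error at \code{errorRate}. Qualities are
#' constant Q30; alignments are returned directly so the pipeline runs
#' without an external aligner.
#'
#' @param genome,truth Output of [simulateReference()].
#' @param config A \linkS4class{SimConfig}.
#' @return Alignment data frame (see [loadAlignments()]).
#' @export
simulateTranscriptomeReads <- function(genome, truth,
                                       config = simConfig()) {
  set.seed(deriveSeed(config@seed, "transcriptome"))
  sites <- trueSites(truth)
  if (config@readDepth == 0L) return(emptyAlignments())
  L <- config@readLength
  rows <- list()
  for (ci in unique(sites$cluster)) {
    cs <- sites[sites$cluster == ci]
    ctg <- as.character(seqnames(cs))[1]
    strand <- as.character(strand(cs))[1]
    clen <- Biostrings::width(genome)[match(ctg, names(genome))]
    lo <- max(1L, min(start(cs)) - L + 1L)
    hi <- min(clen - L + 1L, max(start(cs)))
    starts <- sample(seq.int(lo, hi), config@readDepth, replace = TRUE)
    seqs <- vapply(starts, function(st)
      as.character(Biostrings::subseq(genome[[ctg]], st, st + L - 1L)),
      character(1))
    # plant edits: per read, per covered site, Bernoulli(level)
    altPlus <- if (strand == "+") cs$altTs else complementBase(cs$altTs)
    for (k in seq_along(cs)) {
      off <- start(cs)[k] - starts + 1L
      cov <- off >= 1L & off <= L
      edit <- cov & stats::runif(length(starts)) < cs$level[k]
      idx <- which(edit)
      for (i in idx) substr(seqs[i], off[i], off[i]) <- altPlus[k]
    }
    if (config@errorRate > 0) seqs <- addSeqErrors(seqs, config@errorRate)
    rows[[length(rows) + 1L]] <- data.frame(
      qname = sprintf("c%d_r%d", ci, seq_along(starts)),
      sample = "txome", contig = ctg, pos = starts, mapq = 60L,
      cigar = paste0(L, "M"), seq = seqs, qual = strrep(Q30CHAR, L),
      strand = strand, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## uniform substitution errors over a character vector of sequences
addSeqErrors <- function(seqs, rate) {
  L <- nchar(seqs)
  stopifnot(length(unique(L)) == 1L)
  L <- L[1]
  total <- length(seqs) * L
  k <- stats::rbinom(1L, total, rate)
  if (k == 0L) return(seqs)
  pick <- sample.int(total, k)
  ri <- (pick - 1L) %/% L + 1L
  pi <- (pick - 1L) %% L + 1L
  for (j in seq_len(k)) {
    cur <- substr(seqs[ri[j]], pi[j], pi[j])
    substr(seqs[ri[j]], pi[j], pi[j]) <-
      sample(setdiff(BASES, cur), 1L)
  }
  seqs
}

#' Plant a mismatch-class site set for spectrum analysis
#'
#' Draws \code{n} sites whose class is A>G with probability \code{propAG}
#' and otherwise uniform over the remaining 11 classes — the site-level
#' generator used to exercise [mismatchSpectrum()] at scale.
#'
#' @param n Number of sites.
#' @param propAG A>G proportion (default 0.93).
#' @param seed Seed.
#' @return \code{GRanges} with a \code{class} metadata column.
#' @export
simulateMismatchSites <- function(n, propAG = 0.93, seed = 1L) {
  set.seed(deriveSeed(seed, "spectrum"))
  isAG <- stats::runif(n) < propAG
  cls <- ifelse(isAG, "A>G",
                sample(setdiff(allMismatchClasses(), "A>G"), n,
                       replace = TRUE))
  GRanges("chrS", IRanges(seq_len(n) * 10L, seq_len(n) * 10L),
          strand = "+", class = cls)
}

## barcode for sample i: deterministic base-4 expansion
sampleBarcode <- function(i, len) {
  digits <- integer(len)
  x <- i * 7L + 3L
  for (k in seq_len(len)) { digits[k] <- x %% 4L; x <- x %/% 4L }
  paste(BASES[digits + 1L], collapse = "")
}

#' Simulate a complete targeted amplicon experiment
#'
#' Builds an amplicon panel over a dedicated contig (one minus-strand
#' amplicon; two amplicons carry adjacent recoding site pairs with codon
#' maps, whose unedited/double-edited translations are \code{"LR"} and
#' \code{"AV"}), a sample sheet (RNA and matched gDNA samples for two
#' genotypes), and barcoded reads: RNA reads sample a joint haplotype
#' tuple per read from the genotype's planted distribution (marginals
#' equal per-site levels by construction), gDNA reads carry planted SNP
#' alleles (het: 50% alternate in expectation; hom: 100%). Sequencing
#' error is uniform substitution at \code{errorRate}; qualities are
#' constant Q30; half the reads are reverse-complemented to exercise
#' orientation handling.
#'
#' Planted structure beyond the targeted sites: one genuine off-target
#' editing site (level 0.10), one heterozygous SNP at a targeted site,
#' one homozygous and one heterozygous SNP at untargeted positions.
#' A configurable subset of targeted sites carries a genotype shift of
#' \code{effectSize} (recorded in the truth table).
#'
#' @param config A \linkS4class{SimConfig}.
#' @return List with \code{panel}, \code{sheet}, \code{rnaReads},
#'   \code{gdnaReads} (barcoded \code{DNAStringSet}s with qualities),
#'   \code{genome} and \code{truth}.
#' @export
simulateAmpliconPanel <- function(config = simConfig()) {
  set.seed(deriveSeed(config@seed, "ampliconPanel"))
  nA <- config@nAmplicons
  L <- config@ampliconLength
  pr <- config@primerLen
  gap <- 80L
  contig <- "chrA"
  glen <- nA * (L + gap) + 200L
  gseq <- randomSeq(glen)

  starts <- 100L + (seq_len(nA) - 1L) * (L + gap)
  strands <- rep("+", nA)
  if (nA >= 3) strands[3] <- "-"
  genes <- paste0("gene", seq_len(nA))
  if (nA >= 1) genes[1] <- "gria2a"
  if (nA >= 2) genes[2] <- "gria3a"

  ampIds <- sprintf("amp%02d", seq_len(nA))
  sitesList <- vector("list", nA)
  codonMaps <- list()
  for (a in seq_len(nA)) {
    st <- starts[a]; en <- st + L - 1L
    insLo <- st + pr; insHi <- en - pr
    if (a == 1) {
      # adjacent pair across a codon boundary: TTA|AGA -> "LR" unedited
      p <- insLo + 20L
      substr(gseq, p - 2L, p + 3L) <- "TTAAGA"
      sitesList[[a]] <- c(p, p + 1L)
      codonMaps[[ampIds[a]]] <- data.frame(
        site = c(p, p + 1L), codon = c(1L, 2L),
        refCodon = c("TTA", "AGA"), codonPos = c(3L, 1L))
    } else if (a == 2) {
      # consecutive codons ACA ATA -> "TI" unedited, "AV" double-edited
      q <- insLo + 20L
      substr(gseq, q, q + 5L) <- "ACAATA"
      sitesList[[a]] <- c(q, q + 3L)
      codonMaps[[ampIds[a]]] <- data.frame(
        site = c(q, q + 3L), codon = c(1L, 2L),
        refCodon = c("ACA", "ATA"), codonPos = c(1L, 1L))
    } else {
      k <- config@sitesPerAmplicon
      pos <- insLo + 15L + (seq_len(k) - 1L) * 20L
      pos <- pos[pos <= insHi]
      refPlus <- if (strands[a] == "+") "A" else "T"
      for (p in pos) substr(gseq, p, p) <- refPlus
      sitesList[[a]] <- pos
    }
  }

  # planted SNPs and the genuine off-target site (untargeted A positions)
  snps <- data.frame(contig = character(), pos = integer(),
                     amplicon = character(), zygosity = character(),
                     altTs = character())
  offTarget <- NULL
  pickFree <- function(a) {
    p <- starts[a] + pr + 5L
    refPlus <- if (strands[a] == "+") "A" else "T"
    substr(gseq, p, p) <<- refPlus
    p
  }
  if (nA >= 4) {
    p <- sitesList[[4]][1]  # het SNP right on a targeted site
    snps <- rbind(snps, data.frame(contig = contig, pos = p,
                                   amplicon = ampIds[4], zygosity = "het",
                                   altTs = "G"))
  }
  if (nA >= 5) {
    p <- pickFree(5L)
    snps <- rbind(snps, data.frame(contig = contig, pos = p,
                                   amplicon = ampIds[5], zygosity = "hom",
                                   altTs = "G"))
  }
  if (nA >= 6) {
    p <- pickFree(6L)
    snps <- rbind(snps, data.frame(contig = contig, pos = p,
                                   amplicon = ampIds[6], zygosity = "het",
                                   altTs = "G"))
  }
  if (nA >= 7) offTarget <- data.frame(contig = contig, pos = pickFree(7L),
                                       amplicon = ampIds[7], level = 0.10)

  genome <- Biostrings::DNAStringSet(stats::setNames(gseq, contig))
  info <- DataFrame(
    id = ampIds, gene = genes, contig = contig,
    start = starts, end = starts + L - 1L, strand = strands,
    refseq = vapply(seq_len(nA), function(a)
      substr(gseq, starts[a], starts[a] + L - 1L), character(1)),
    fwdPrimerLen = pr, revPrimerLen = pr)
  info$sites <- sitesList
  panel <- ampliconPanel(info, codonMaps)

  # per-site, per-genotype editing levels; a subset of sites shifted
  allSites <- panelSites(panel)
  ns <- length(allSites)
  wt <- seq(0.15, 0.45, length.out = ns)
  shifted <- rep(c(TRUE, FALSE), length.out = ns)
  mut <- ifelse(shifted, wt - config@effectSize, wt)
  if (nA >= 4) { # genomic het SNP at a targeted site: allele ratio 0.5
    hetIdx <- which(start(allSites) == sitesList[[4]][1] &
                      allSites$amplicon == ampIds[4])
    wt[hetIdx] <- 0.5; mut[hetIdx] <- 0.5; shifted[hetIdx] <- FALSE
  }
  siteLevels <- data.frame(
    site = start(allSites), amplicon = allSites$amplicon,
    strand = as.character(strand(allSites)),
    WT = wt, MUT = mut, shifted = shifted, offTarget = FALSE)
  if (!is.null(offTarget))
    siteLevels <- rbind(siteLevels, data.frame(
      site = offTarget$pos, amplicon = offTarget$amplicon, strand = "+",
      WT = offTarget$level, MUT = offTarget$level, shifted = FALSE,
      offTarget = TRUE))

  # joint haplotype distributions for 2-site amplicons (linked for the
  # two recoding amplicons, independent elsewhere)
  haplotypes <- list()
  for (a in seq_len(nA)) {
    pos <- sitesList[[a]]
    if (length(pos) != 2L) next
    rows <- match(pos, siteLevels$site)
    for (g in c("WT", "MUT")) {
      p1 <- siteLevels[[g]][rows[1]]; p2 <- siteLevels[[g]][rows[2]]
      d <- if (a <= 2) min(0.05, p1 * (1 - p2), (1 - p1) * p2,
                           p1 * p2, (1 - p1) * (1 - p2)) * 0.8 else 0
      pj <- c(AA = (1 - p1) * (1 - p2) + d, AG = (1 - p1) * p2 - d,
              GA = p1 * (1 - p2) - d, GG = p1 * p2 + d)
      haplotypes[[ampIds[a]]][[g]] <- pj
    }
  }

  nSamp <- config@samplesPerGenotype
  nG <- config@gdnaPerGenotype
  sheet <- data.frame(
    id = c(paste0("WT", seq_len(nSamp)), paste0("MUT", seq_len(nSamp)),
           paste0("gWT", seq_len(nG)), paste0("gMUT", seq_len(nG))),
    genotype = c(rep("WT", nSamp), rep("MUT", nSamp),
                 rep("WT", nG), rep("MUT", nG)),
    material = c(rep("RNA", 2L * nSamp), rep("gDNA", 2L * nG)),
    stringsAsFactors = FALSE)
  sheet$barcode <- vapply(seq_len(nrow(sheet)), sampleBarcode,
                          character(1), len = config@barcodeLength)
  sheet <- sheet[, c("id", "barcode", "genotype", "material")]
  validateSampleSheet(sheet)

  # shared per-amplicon amplification efficiency: identical in every
  # sample, so between-genotype mean depths correlate across amplicons
  eff <- pmin(pmax(exp(stats::rnorm(nA, 0, 0.25)), 0.5), 1.8)
  ampliconDepths <- data.frame(
    amplicon = ampIds,
    depth = as.integer(round(config@ampliconDepth * eff)))
  truth <- new("SyntheticTruth", sites = GRanges(),
               siteLevels = siteLevels, haplotypes = haplotypes,
               snps = snps, ampliconDepths = ampliconDepths,
               config = config)

  rna <- drawPanelReads(panel, sheet[sheet$material == "RNA", ], truth,
                        config, material = "RNA")
  gdna <- drawPanelReads(panel, sheet[sheet$material == "gDNA", ], truth,
                         config, material = "gDNA")
  list(panel = panel, sheet = sheet, rnaReads = rna, gdnaReads = gdna,
       genome = genome, truth = truth)
}

## draw barcoded reads for all samples of one material type
drawPanelReads <- function(panel, sheet, truth, config, material) {
  info <- panelInfo(panel)
  sl <- trueSiteLevels(truth)
  snps <- trueSnps(truth)
  out <- vector("list", nrow(sheet) * nrow(info))
  k <- 0L
  for (si in seq_len(nrow(sheet))) {
    sid <- sheet$id[si]
    g <- sheet$genotype[si]
    set.seed(deriveSeed(config@seed, paste0(material, ":", sid)))
    for (a in seq_len(nrow(info))) {
      k <- k + 1L
      out[[k]] <- drawAmpliconReads(info, a, sid, g, truth, config,
                                    material)
    }
  }
  seqs <- unlist(lapply(out, `[[`, "seq"), use.names = FALSE)
  ids <- unlist(lapply(out, `[[`, "id"), use.names = FALSE)
  bc <- sheet$barcode[match(sub("_.*", "", ids), sheet$id)]
  # orientation: roughly half the reads reverse-complemented
  n <- length(seqs)
  flip <- stats::runif(n) < 0.5
  if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
  seqs <- paste0(bc, seqs)
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- ids
  S4Vectors::mcols(reads)$qualities <-
    Biostrings::BStringSet(strrep(Q30CHAR, nchar(seqs)))
  reads
}

drawAmpliconReads <- function(info, a, sid, genotype, truth, config,
                              material) {
  L <- nchar(info$refseq[a])
  ad <- truth@ampliconDepths
  n <- if (nrow(ad)) ad$depth[match(info$id[a], ad$amplicon)] else
    config@ampliconDepth
  # per-sample library-size jitter around the amplicon's shared depth
  n <- max(1L, stats::rpois(1L, n))
  sl <- trueSiteLevels(truth)
  snps <- trueSnps(truth)
  ampSites <- sl[sl$amplicon == info$id[a] & !sl$offTarget, , drop = FALSE]
  ampOff <- sl[sl$amplicon == info$id[a] & sl$offTarget, , drop = FALSE]
  ampSnps <- snps[snps$amplicon == info$id[a], , drop = FALSE]
  strandA <- info$strand[a]
  tsToPlus <- function(b) if (strandA == "+") b else complementBase(b)

  varPos <- integer(0)
  alleleM <- matrix(character(0), nrow = n, ncol = 0)
  addVar <- function(pos, chars) {
    varPos <<- c(varPos, pos)
    alleleM <<- cbind(alleleM, chars)
  }
  joint <- trueHaplotypes(truth)[[info$id[a]]]
  if (material == "RNA" && !is.null(joint) && nrow(ampSites) == 2L) {
    pj <- joint[[genotype]]
    tu <- sample(names(pj), n, replace = TRUE, prob = pj)
    b1 <- substr(tu, 1, 1); b2 <- substr(tu, 2, 2)
    addVar(ampSites$site[1], tsToPlus(b1))
    addVar(ampSites$site[2], tsToPlus(b2))
  } else if (material == "RNA" && nrow(ampSites)) {
    for (r in seq_len(nrow(ampSites))) {
      lv <- ampSites[[genotype]][r]
      edited <- stats::runif(n) < lv
      addVar(ampSites$site[r], tsToPlus(ifelse(edited, "G", "A")))
    }
  }
  if (material == "RNA" && nrow(ampOff)) {
    for (r in seq_len(nrow(ampOff))) {
      edited <- stats::runif(n) < ampOff[[genotype]][r]
      addVar(ampOff$site[r], tsToPlus(ifelse(edited, "G", "A")))
    }
  }
  if (nrow(ampSnps)) {
    for (r in seq_len(nrow(ampSnps))) {
      if (ampSnps$pos[r] %in% varPos && material == "RNA") next
      pAlt <- if (ampSnps$zygosity[r] == "het") 0.5 else 1
      alt <- stats::runif(n) < pAlt
      addVar(ampSnps$pos[r],
             tsToPlus(ifelse(alt, ampSnps$altTs[r], "A")))
    }
  }

  if (ncol(alleleM)) {
    off <- varPos - info$start[a] + 1L
    key <- do.call(paste0, as.data.frame(alleleM, stringsAsFactors = FALSE))
    seqs <- character(n)
    for (kk in unique(key)) {
      tmpl <- info$refseq[a]
      ch <- strsplit(kk, "")[[1]]
      for (j in seq_along(off)) substr(tmpl, off[j], off[j]) <- ch[j]
      seqs[key == kk] <- tmpl
    }
  } else {
    seqs <- rep(info$refseq[a], n)
  }
  if (config@errorRate > 0) seqs <- addSeqErrors(seqs, config@errorRate)
  list(seq = seqs, id = sprintf("%s_%s_r%d", sid, info$id[a], seq_len(n)))
}
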
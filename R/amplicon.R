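# The targeted amplicon (mmPCR-style) pipeline: demultiplexing, gapless
# alignment to the amplicon panel, per-sample/site editing quantification,
# off-target site discovery, genomic-SNP masking against matched gDNA, the
# three-criterion selection cascade and genotype differential testing.

#' Read a sample sheet TSV
#'
#' Columns: \code{id}, \code{barcode}, \code{genotype}, \code{material}
#' (\code{RNA} or \code{gDNA}). Duplicate barcodes are a hard error.
#'
#' @param path TSV path.
#' @return Data frame sample sheet.
#' @export
readSampleSheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "barcode", "genotype", "material")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  validateSampleSheet(df)
  df
}

validateSampleSheet <- function(sheet) {
  if (anyDuplicated(sheet$barcode))
    stop("duplicate barcode in sample sheet: ",
         sheet$barcode[duplicated(sheet$barcode)][1])
  if (anyDuplicated(sheet$id))
    stop("duplicate sample id in sample sheet")
  invisible(sheet)
}

#' Write a sample sheet TSV
#' @param sheet Sample sheet data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeSampleSheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an amplicon panel TSV
#'
#' Columns: \code{id}, \code{gene}, \code{contig}, \code{start},
#' \code{end} (1-based closed), \code{strand}, \code{fwdPrimerLen},
#' \code{revPrimerLen}, \code{sites} (comma-separated 1-based genomic
#' positions, may be empty) and optionally \code{refseq} (plus-strand
#' amplicon sequence; required unless \code{genome} is given). An
#' optional codon-map TSV (\code{amplicon}, \code{site}, \code{codon},
#' \code{refCodon}, \code{codonPos}) enables protein-variant labels.
#'
#' @param path Panel TSV path.
#' @param codonPath Optional codon-map TSV path.
#' @param genome Optional \code{DNAStringSet} to slice \code{refseq} from.
#' @return An \linkS4class{AmpliconPanel}.
#' @export
readPanel <- function(path, codonPath = NULL, genome = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(sites = "character"))
  if (!"refseq" %in% names(df)) {
    if (is.null(genome)) stop("panel has no refseq column and no genome given")
    df$refseq <- vapply(seq_len(nrow(df)), function(i)
      as.character(Biostrings::subseq(genome[[df$contig[i]]],
                                      df$start[i], df$end[i])),
      character(1))
  }
  sites <- lapply(strsplit(df$sites, ","), function(s)
    as.integer(s[nzchar(s)]))
  info <- DataFrame(id = df$id, gene = df$gene, contig = df$contig,
                    start = as.integer(df$start), end = as.integer(df$end),
                    strand = df$strand, refseq = df$refseq,
                    fwdPrimerLen = as.integer(df$fwdPrimerLen),
                    revPrimerLen = as.integer(df$revPrimerLen))
  info$sites <- sites
  maps <- list()
  if (!is.null(codonPath)) {
    cm <- utils::read.delim(codonPath, stringsAsFactors = FALSE)
    maps <- split(cm[, c("site", "codon", "refCodon", "codonPos")],
                  cm$amplicon)
  }
  ampliconPanel(info, maps)
}

#' Write an amplicon panel TSV (and optional codon-map TSV)
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param path Output TSV path.
#' @param codonPath Optional codon-map output path.
#' @return Invisibly, \code{path}.
#' @export
writePanel <- function(panel, path, codonPath = NULL) {
  info <- panelInfo(panel)
  df <- as.data.frame(info[, setdiff(colnames(info), "sites")])
  df$sites <- vapply(info$sites, paste, character(1), collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(codonPath) && length(panel@codonMaps)) {
    cm <- do.call(rbind, lapply(names(panel@codonMaps), function(id)
      cbind(amplicon = id, panel@codonMaps[[id]])))
    utils::write.table(cm, codonPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Demultiplex barcoded reads by exact 5' barcode match
#'
#' The barcode is the first \code{barcodeLength} bases of each read;
#' assignment requires an exact match to a sheet barcode (one mismatch
#' lands the read in the unassigned bin) and the barcode is trimmed from
#' assigned reads. Every input read lands in exactly one bin.
#'
#' @param reads \code{DNAStringSet} with a \code{qualities} metadata
#'   column.
#' @param sheet Sample sheet data frame (unique barcodes).
#' @param barcodeLength Barcode length; defaults to the sheet's barcode
#'   width.
#' @return Named list of per-sample \code{DNAStringSet}s (barcode
#'   trimmed, qualities carried along) plus an \code{unassigned} element.
#' @export
demultiplex <- function(reads, sheet, barcodeLength = NULL) {
  validateSampleSheet(sheet)
  bl <- barcodeLength %||% unique(nchar(sheet$barcode))
  if (length(bl) != 1L) stop("barcodes have mixed lengths; give barcodeLength")
  pre <- as.character(Biostrings::subseq(reads, 1L, bl))
  hit <- match(pre, sheet$barcode)
  quals <- S4Vectors::mcols(reads)$qualities
  bins <- stats::setNames(vector("list", nrow(sheet)), sheet$id)
  for (i in seq_len(nrow(sheet))) {
    sel <- which(!is.na(hit) & hit == i)
    r <- Biostrings::subseq(reads[sel], bl + 1L)
    S4Vectors::mcols(r)$qualities <- Biostrings::subseq(quals[sel], bl + 1L)
    bins[[i]] <- r
  }
  un <- reads[is.na(hit)]
  S4Vectors::mcols(un)$qualities <- quals[is.na(hit)]
  bins$unassigned <- un
  bins
}

#' Align amplicon reads to the panel by exhaustive gapless comparison
#'
#' Each read is compared, in both orientations and at every feasible
#' offset, against every amplicon reference; it is assigned to the
#' placement minimising the mismatch count. Reads whose best mismatch
#' count exceeds \code{maxMismatchFrac * length} or whose best count is
#' tied across different amplicons are dropped (counts reported via
#' message). Assigned reads get MAPQ 60 and an all-M CIGAR; sequences are
#' stored in genome-forward orientation.
#'
#' @param reads \code{DNAStringSet} (barcode already trimmed) with a
#'   \code{qualities} metadata column.
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param sample Sample id attached to the alignments.
#' @param maxMismatchFrac Mismatch ceiling as a fraction of read length
#'   (default 0.1).
#' @return Alignment data frame (see [loadAlignments()]) with an extra
#'   \code{amplicon} column.
#' @export
alignAmpliconReads <- function(reads, panel, sample = NA_character_,
                               maxMismatchFrac = 0.1) {
  info <- panelInfo(panel)
  if (!nrow(info)) stop("empty amplicon panel")
  n <- length(reads)
  if (!n) return(cbind(emptyAlignments(), amplicon = character(0)))
  quals <- as.character(S4Vectors::mcols(reads)$qualities)
  rc <- Biostrings::reverseComplement(reads)
  widths <- Biostrings::width(reads)

  best <- rep(Inf, n); bestAmp <- rep(NA_integer_, n)
  bestOff <- rep(NA_integer_, n); bestStrand <- rep(NA_character_, n)
  tied <- rep(FALSE, n)
  for (w in unique(widths)) {
    idx <- which(widths == w)
    fw <- reads[idx]; rv <- rc[idx]
    for (a in seq_len(nrow(info))) {
      La <- nchar(info$refseq[a])
      if (w > La) next
      ref <- Biostrings::DNAString(info$refseq[a])
      for (off in seq_len(La - w + 1L)) {
        win <- Biostrings::subseq(ref, off, off + w - 1L)
        for (ori in c("+", "-")) {
          mm <- as.vector(Biostrings::neditStartingAt(
            win, if (ori == "+") fw else rv, starting.at = 1L))
          gi <- idx
          better <- mm < best[gi]
          same <- !is.na(bestAmp[gi]) & mm == best[gi] & bestAmp[gi] != a
          tied[gi[same]] <- TRUE
          upd <- gi[better]
          best[upd] <- mm[better]; bestAmp[upd] <- a
          bestOff[upd] <- off; bestStrand[upd] <- ori
          tied[upd] <- FALSE
        }
      }
    }
  }
  ceilings <- floor(maxMismatchFrac * widths)
  drop <- is.infinite(best) | best > ceilings | tied
  nDropMM <- sum(!tied & (is.infinite(best) | best > ceilings))
  nDropTie <- sum(tied & !(is.infinite(best)))
  if (any(drop))
    message(nDropMM, " read(s) dropped over mismatch ceiling, ",
            nDropTie, " dropped as ambiguous")
  keep <- which(!drop)
  if (!length(keep)) return(cbind(emptyAlignments(), amplicon = character(0)))
  fwdSeq <- character(length(keep)); fwdQual <- character(length(keep))
  plus <- bestStrand[keep] == "+"
  fwdSeq[plus] <- as.character(reads[keep[plus]])
  fwdSeq[!plus] <- as.character(rc[keep[!plus]])
  fwdQual[plus] <- quals[keep[plus]]
  fwdQual[!plus] <- vapply(quals[keep[!plus]], function(q)
    paste(rev(strsplit(q, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
  qn <- names(reads)[keep] %||% paste0("read", keep)
  a <- bestAmp[keep]
  data.frame(
    qname = qn, sample = sample, contig = info$contig[a],
    pos = info$start[a] + bestOff[keep] - 1L, mapq = 60L,
    cigar = paste0(widths[keep], "M"),
    seq = fwdSeq, qual = fwdQual,
    strand = bestStrand[keep], amplicon = info$id[a],
    stringsAsFactors = FALSE)
}

## Base and quality at one genomic position for every read (NA when the
## read does not cover it). Vectorised fast path for pure-M CIGARs.
baseQualAt <- function(aln, contig, pos) {
  n <- nrow(aln)
  base <- rep(NA_character_, n); qual <- rep(NA_integer_, n)
  onCtg <- aln$contig == contig
  allM <- grepl("^\\d+M$", aln$cigar)
  w <- nchar(aln$seq)
  off <- pos - aln$pos + 1L
  fast <- onCtg & allM & off >= 1L & off <= w
  if (any(fast)) {
    base[fast] <- substr(aln$seq[fast], off[fast], off[fast])
    qual[fast] <- as.integer(charToRaw(paste0(
      substr(aln$qual[fast], off[fast], off[fast]), collapse = ""))) - 33L
  }
  slow <- which(onCtg & !allM)
  for (i in slow) {
    ap <- alignedPairs(aln$pos[i], aln$cigar[i])
    j <- match(pos, ap$refPos)
    if (!is.na(j)) {
      k <- ap$readIdx[j]
      base[i] <- substr(aln$seq[i], k, k)
      qual[i] <- qualToInt(aln$qual[i])[k]
    }
  }
  list(base = base, qual = qual)
}

## Transcript-strand A/G counts per sample at one site
countAGAtSite <- function(aln, contig, pos, siteStrand, samples,
                          thresholds) {
  bq <- baseQualAt(aln, contig, pos)
  ok <- !is.na(bq$base) & bq$qual >= thresholds@minBaseQual
  b <- bq$base
  if (siteStrand == "-") b <- complementBase(b)
  nA <- integer(length(samples)); nG <- integer(length(samples))
  if (any(ok)) {
    sm <- factor(aln$sample[ok], levels = samples)
    tA <- table(sm[b[ok] == "A"])
    tG <- table(sm[b[ok] == "G"])
    nA <- as.integer(tA); nG <- as.integer(tG)
  }
  list(nA = nA, nG = nG)
}

#' Quantify editing levels at panel sites
#'
#' Counts quality-passing A and G bases on the transcript strand at each
#' targeted site (plus any \code{extraSites}, e.g. discovered off-target
#' sites) in each sample and assembles a \linkS4class{SiteEditingTable}.
#' Sites not covered by any read get depth 0 and an undefined level.
#'
#' @param alignments Alignment data frame carrying a \code{sample} column
#'   (all samples of one material type pooled).
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param sheet Sample sheet rows for the samples being quantified; its
#'   \code{id} order defines the column order.
#' @param thresholds A \linkS4class{FilterThresholds}.
#' @param extraSites Optional \code{GRanges} of additional sites with
#'   metadata \code{amplicon}, \code{gene}, \code{targeted}.
#' @return A \linkS4class{SiteEditingTable}.
#' @export
quantifySites <- function(alignments, panel, sheet,
                          thresholds = filterThresholds(),
                          extraSites = NULL) {
  sites <- panelSites(panel)
  if (!is.null(extraSites) && length(extraSites))
    sites <- c(sites, extraSites)
  samples <- sheet$id
  ns <- length(sites)
  nA <- matrix(0L, ns, length(samples))
  nG <- matrix(0L, ns, length(samples))
  byAmp <- if ("amplicon" %in% names(alignments))
    split(alignments, alignments$amplicon) else NULL
  for (i in seq_len(ns)) {
    aln <- if (!is.null(byAmp)) byAmp[[sites$amplicon[i]]] else alignments
    if (is.null(aln)) next
    cnt <- countAGAtSite(aln, as.character(seqnames(sites))[i],
                         start(sites)[i], as.character(strand(sites))[i],
                         samples, thresholds)
    nA[i, ] <- cnt$nA; nG[i, ] <- cnt$nG
  }
  depth <- nA + nG
  level <- ifelse(depth > 0, nG / depth, NA_real_)
  rn <- sprintf("%s:%d:%s", as.character(seqnames(sites)), start(sites),
                as.character(strand(sites)))
  dimnames(nA) <- dimnames(nG) <- dimnames(depth) <- dimnames(level) <-
    list(rn, samples)
  se <- SummarizedExperiment(
    assays = list(nA = nA, nG = nG, depth = depth, level = level),
    rowRanges = sites,
    colData = DataFrame(sheet, row.names = sheet$id))
  rownames(se) <- rn
  new("SiteEditingTable", se)
}

#' Discover off-target editing sites within amplicons
#'
#' Scans every position of each amplicon insert (between the primer
#' spans) whose transcript-strand reference base is A and which is not a
#' targeted site; a position is called when, in at least one sample, it
#' is supported by at least \code{minMismatchReads} quality-passing G
#' reads. Counting per sample (rather than pooled over all samples)
#' keeps the read-support threshold meaningful at high aggregate depth,
#' where pooled sequencing errors alone would exceed it.
#'
#' @param alignments Alignment data frame (RNA samples).
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param thresholds A \linkS4class{FilterThresholds}.
#' @return \code{GRanges} of off-target sites with metadata
#'   \code{amplicon}, \code{gene}, \code{targeted = FALSE}, suitable as
#'   \code{extraSites} for [quantifySites()].
#' @export
discoverOfftargetSites <- function(alignments, panel,
                                   thresholds = filterThresholds()) {
  info <- panelInfo(panel)
  found <- list()
  for (a in seq_len(nrow(info))) {
    ins <- seq.int(info$start[a] + info$fwdPrimerLen[a],
                   info$end[a] - info$revPrimerLen[a])
    refChars <- strsplit(info$refseq[a], "")[[1]]
    tsRef <- refChars[ins - info$start[a] + 1L]
    if (info$strand[a] == "-") tsRef <- complementBase(tsRef)
    cand <- ins[tsRef == "A"]
    cand <- setdiff(cand, info$sites[[a]])
    aln <- alignments[alignments$contig == info$contig[a] &
                        alignments$pos >= info$start[a] - 1000L &
                        alignments$pos <= info$end[a], , drop = FALSE]
    for (p in cand) {
      bq <- baseQualAt(aln, info$contig[a], p)
      ok <- !is.na(bq$base) & bq$qual >= thresholds@minBaseQual
      b <- bq$base[ok]
      if (info$strand[a] == "-") b <- complementBase(b)
      gPerSample <- table(aln$sample[ok][b == "G"])
      if (length(gPerSample) &&
          max(gPerSample) >= thresholds@minMismatchReads)
        found[[length(found) + 1L]] <- data.frame(
          contig = info$contig[a], pos = p, strand = info$strand[a],
          amplicon = info$id[a], gene = info$gene[a])
    }
  }
  if (!length(found))
    return(GRanges(amplicon = character(), gene = character(),
                   targeted = logical()))
  d <- do.call(rbind, found)
  GRanges(d$contig, IRanges(d$pos, d$pos), strand = d$strand,
          amplicon = d$amplicon, gene = d$gene, targeted = FALSE)
}

#' Mask genomic variants using matched gDNA sequencing
#'
#' A site is excluded when it appears in \code{knownSnps}, when its
#' pooled gDNA alternate (G) fraction exceeds \code{snpMaxGdnaAlt}, or —
#' conservatively — when it has no gDNA evidence at all (zero pooled gDNA
#' depth or no matching gDNA row).
#'
#' @param rnaTable,gdnaTable \linkS4class{SiteEditingTable}s built over
#'   the same panel from RNA and gDNA samples respectively.
#' @param knownSnps Optional \code{GRanges} of known SNP positions.
#' @param thresholds A \linkS4class{FilterThresholds}.
#' @return List with \code{table} (the filtered RNA table) and
#'   \code{exclusions} (data frame: \code{site}, \code{reason},
#'   \code{gdnaAltFraction}).
#' @export
maskGenomicVariants <- function(rnaTable, gdnaTable, knownSnps = NULL,
                                thresholds = filterThresholds()) {
  rn <- rownames(rnaTable)
  gIdx <- match(rn, rownames(gdnaTable))
  gA <- assay(gdnaTable, "nA"); gG <- assay(gdnaTable, "nG")
  pooledG <- ifelse(is.na(gIdx), NA_real_, rowSums(gG)[gIdx])
  pooledD <- ifelse(is.na(gIdx), 0, rowSums(gA)[gIdx] + rowSums(gG)[gIdx])
  altFrac <- ifelse(pooledD > 0, pooledG / pooledD, NA_real_)
  inKnown <- rep(FALSE, length(rn))
  if (!is.null(knownSnps) && length(knownSnps)) {
    hits <- findOverlaps(rowRanges(rnaTable), knownSnps,
                         ignore.strand = TRUE)
    inKnown[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  reason <- rep(NA_character_, length(rn))
  reason[pooledD == 0] <- "no gDNA evidence"
  reason[!is.na(altFrac) & altFrac > thresholds@snpMaxGdnaAlt] <-
    "gDNA variant"
  reason[inKnown] <- "known SNP"
  drop <- !is.na(reason)
  list(table = rnaTable[!drop, ],
       exclusions = data.frame(site = rn[drop], reason = reason[drop],
                               gdnaAltFraction = altFrac[drop],
                               row.names = NULL))
}

#' Apply the three-criterion site selection cascade
#'
#' Per genotype: a sample/site cell is \emph{captured} when its A+G depth
#' is at least \code{ampMinCoverage} (criterion ii); a site passes for a
#' genotype when it is captured in at least \code{ampMinIncidence} of the
#' genotype's samples (criterion i) and its mean editing level over
#' captured samples is at least \code{ampMinLevel} (criterion iii). A
#' site is retained when it passes in every genotype. The audit reports,
#' per site and genotype, the incidence, mean level and the first
#' criterion that failed (coverage when no sample was captured,
#' incidence otherwise, then level).
#'
#' @param table A \linkS4class{SiteEditingTable} whose \code{colData}
#'   carries \code{genotype}.
#' @param thresholds A \linkS4class{FilterThresholds}.
#' @return List with \code{table} (retained rows), \code{retained}
#'   (site ids) and \code{audit} (data frame).
#' @export
applySelectionCriteria <- function(table, thresholds = filterThresholds()) {
  gt <- colData(table)$genotype
  if (is.null(gt)) stop("colData must carry a genotype column")
  depth <- coverageDepth(table); level <- editingLevels(table)
  audit <- list()
  passAll <- rep(TRUE, nrow(table))
  for (g in unique(gt)) {
    cols <- which(gt == g)
    cap <- depth[, cols, drop = FALSE] >= thresholds@ampMinCoverage
    incidence <- rowMeans(cap)
    meanLevel <- vapply(seq_len(nrow(table)), function(i) {
      v <- level[i, cols][cap[i, ]]
      if (length(v)) mean(v, na.rm = TRUE) else NA_real_
    }, numeric(1))
    passI <- incidence >= thresholds@ampMinIncidence
    passIII <- !is.na(meanLevel) & meanLevel >= thresholds@ampMinLevel
    fail <- rep(NA_character_, nrow(table))
    fail[!passI] <- ifelse(incidence[!passI] == 0, "coverage", "incidence")
    fail[passI & !passIII] <- "level"
    passAll <- passAll & passI & passIII
    audit[[g]] <- data.frame(site = rownames(table), genotype = g,
                             incidence = incidence, meanLevel = meanLevel,
                             fail = fail, row.names = NULL)
  }
  list(table = table[passAll, ], retained = rownames(table)[passAll],
       audit = do.call(rbind, c(audit, list(make.row.names = FALSE))))
}

#' Differential editing between two genotypes
#'
#' Welch's unequal-variance t-test on per-sample editing levels at each
#' site, comparing the two genotype groups; raw two-sided p-values are
#' reported (the paper-style default), with Benjamini-Hochberg adjusted
#' values added behind \code{correct = TRUE}. Sites with fewer than two
#' defined levels in either group are skipped with a message.
#'
#' @param table A \linkS4class{SiteEditingTable} (typically the retained
#'   table from [applySelectionCriteria()]).
#' @param correct Add a BH-adjusted \code{padj} column (default FALSE).
#' @return Data frame: \code{site}, \code{gene}, group means/SEMs/ns,
#'   \code{t}, \code{df}, \code{p} (and \code{padj} when requested).
#'   Group 1 is the first genotype in \code{colData} order.
#' @export
differentialEditing <- function(table, correct = FALSE) {
  gt <- colData(table)$genotype
  gl <- unique(gt)
  if (length(gl) != 2) stop("exactly two genotypes required")
  level <- editingLevels(table)
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(table))) {
    x <- level[i, gt == gl[1]]; x <- x[!is.na(x)]
    y <- level[i, gt == gl[2]]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) { skipped <- skipped + 1L; next }
    w <- welchTTest(x, y)
    rows[[length(rows) + 1L]] <- data.frame(
      site = rownames(table)[i], gene = rowData(table)$gene[i],
      mean1 = w$meanX, sem1 = stats::sd(x) / sqrt(length(x)),
      n1 = length(x),
      mean2 = w$meanY, sem2 = stats::sd(y) / sqrt(length(y)),
      n2 = length(y),
      t = w$t, df = w$df, p = w$p.value, row.names = NULL)
  }
  if (skipped) message(skipped, " site(s) skipped: <2 defined levels in a group")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = character(), gene = character(), mean1 = numeric(),
               sem1 = numeric(), n1 = integer(), mean2 = numeric(),
               sem2 = numeric(), n2 = integer(), t = numeric(),
               df = numeric(), p = numeric())
  attr(out, "groups") <- gl
  if (correct) out$padj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Coverage-depth correlation between genotypes
#'
#' Pearson correlation, across amplicons, of the per-genotype mean A+G
#' read depth — a check that coverage is unaffected by genotype.
#'
#' @param table A \linkS4class{SiteEditingTable} with \code{genotype}
#'   colData and \code{amplicon} rowData.
#' @return List with \code{r}, \code{r.squared} and the per-amplicon
#'   mean-depth matrix (\code{means}).
#' @export
depthCorrelation <- function(table) {
  gt <- colData(table)$genotype
  gl <- unique(gt)
  if (length(gl) != 2) stop("exactly two genotypes required")
  amp <- rowData(table)$amplicon
  if (length(unique(amp)) < 2) stop("need at least 2 amplicons")
  depth <- coverageDepth(table)
  means <- vapply(gl, function(g)
    tapply(rowMeans(depth[, gt == g, drop = FALSE]), amp, mean),
    numeric(length(unique(amp))))
  pr <- pearsonR(means[, 1], means[, 2])
  c(pr, list(means = means))
}

#' Write a SiteEditingTable as a long-format TSV
#'
#' @param table A \linkS4class{SiteEditingTable}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeSiteEditingTable <- function(table, path) {
  rd <- rowData(table)
  long <- do.call(rbind, lapply(seq_len(ncol(table)), function(j)
    data.frame(sample = colnames(table)[j], site = rownames(table),
               gene = rd$gene, amplicon = rd$amplicon,
               targeted = rd$targeted,
               nA = assay(table, "nA")[, j], nG = assay(table, "nG")[, j],
               depth = assay(table, "depth")[, j],
               level = assay(table, "level")[, j], row.names = NULL)))
  long <- long[order(long$sample, long$site), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
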
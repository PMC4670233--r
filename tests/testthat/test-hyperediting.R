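mkCol <- function(ref, counts, pos = 100L, strand = "+") {
  full <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  full[names(counts)] <- as.integer(counts)
  S4Vectors::DataFrame(contig = "chr1", pos = pos, strand = strand,
                       ref = ref, A = full[["A"]], C = full[["C"]],
                       G = full[["G"]], T = full[["T"]],
                       depth = sum(full))
}

test_that("candidate calling honours the edited-read and level cutoffs", {
  thr <- filterThresholds()
  # 6 edited reads at level 0.06: called; 5 edited reads: not
  s <- callCandidateSites(mkCol("A", c(A = 94, G = 6)), thr)
  expect_equal(length(s), 1L)
  expect_equal(s$class, "A>G")
  expect_equal(s$nAlt, 6L)
  expect_equal(length(callCandidateSites(mkCol("A", c(A = 95, G = 5)),
                                         thr)), 0L)
  # 9 edited reads but level 0.00892 (< 0.01): not called
  expect_equal(length(callCandidateSites(mkCol("A", c(A = 1000, G = 9)),
                                         thr)), 0L)
  # exactly level 0.01 is excluded (strict inequality)
  expect_equal(length(callCandidateSites(mkCol("A", c(A = 990, G = 10)),
                                         thr)), 0L)
  expect_equal(length(callCandidateSites(mkCol("A", c(A = 989, G = 10)),
                                         thr)), 1L)
})

test_that("minus-strand columns report transcript-strand classes", {
  s <- callCandidateSites(mkCol("T", c(T = 90, C = 10), strand = "-"))
  expect_equal(s$class, "A>G")  # genomic T>C on minus strand
  s2 <- callCandidateSites(mkCol("T", c(T = 90, C = 10), strand = "+"))
  expect_equal(s2$class, "T>C")
})

test_that("tightening thresholds never adds candidate sites", {
  set.seed(8)
  cols <- do.call(rbind, lapply(1:50, function(i) {
    nG <- sample(0:30, 1); nA <- sample(0:500, 1)
    mkCol("A", c(A = nA, G = nG), pos = i * 7L)
  }))
  base <- length(callCandidateSites(cols, filterThresholds()))
  for (thr in list(filterThresholds(heMinEditedReads = 10),
                   filterThresholds(heMinLevel = 0.05))) {
    expect_lte(length(callCandidateSites(cols, thr)), base)
  }
})

siteGR <- function(df) {
  GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$pos, df$pos),
                         strand = df$strand, class = df$class)
}

test_that("clustering forms maximal windowed runs of same-class sites", {
  d <- data.frame(contig = "chr1", pos = c(10L, 50L, 90L), strand = "+",
                  class = "A>G")
  cl <- clusterCandidates(siteGR(d))
  expect_equal(length(cl), 1L)
  expect_equal(cl$size, 3L)
  expect_equal(GenomicRanges::start(cl), 10L)
  expect_equal(GenomicRanges::end(cl), 90L)

  d2 <- transform(d, pos = c(10L, 200L, 400L))
  expect_equal(length(clusterCandidates(siteGR(d2))), 0L)
})

test_that("clustering matches a brute-force maximal-run scan and is
           order independent", {
  set.seed(9)
  for (trial in 1:30) {
    d <- data.frame(
      contig = sample(c("chr1", "chr2"), 50, TRUE),
      pos = sample(1:2000, 50),
      strand = sample(c("+", "-"), 50, TRUE),
      class = sample(c("A>G", "C>T"), 50, TRUE, prob = c(.8, .2)))
    d <- d[!duplicated(d[c("contig", "pos")]), ]
    got <- clusterCandidates(siteGR(d))
    want <- oracleClusters(d, 100, 3)
    expect_equal(length(got), length(want))
    if (length(want)) {
      wantSpans <- sort(vapply(want, function(w)
        paste(min(w$pos), max(w$pos)), character(1)))
      gotSpans <- sort(paste(GenomicRanges::start(got),
                             GenomicRanges::end(got)))
      expect_equal(gotSpans, wantSpans)
    }
    # shuffled input gives identical clusters
    got2 <- clusterCandidates(siteGR(d[sample(nrow(d)), ]))
    expect_equal(sort(paste(GenomicRanges::start(got2),
                            GenomicRanges::end(got2))),
                 sort(paste(GenomicRanges::start(got),
                            GenomicRanges::end(got))))
  }
})

test_that("mismatch spectrum sums to one and recovers planted mixtures", {
  one <- siteGR(data.frame(contig = "chr1", pos = 1:12, strand = "+",
                           class = allMismatchClasses()))
  sp <- mismatchSpectrum(one)
  expect_equal(sum(sp), 1)
  expect_true(all(abs(sp - 1 / 12) < 1e-12))
  expect_error(mismatchSpectrum(one[0]), "undefined")

  sites <- simulateMismatchSites(10000, propAG = 0.93, seed = 21)
  frac <- mismatchSpectrum(sites)[["A>G"]]
  expect_lt(abs(frac - 0.93), 3 * sqrt(0.93 * 0.07 / 10000))
})

test_that("neighbor preference reads transcript-strand flanks", {
  g <- Biostrings::DNAStringSet(c(chr1 = "TTAGTTCTTTTT"))
  # plus-strand site at pos 3 (A) with context T-A-G
  s <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3, 3), strand = "+")
  prof <- neighborPreference(s, g)
  expect_equal(prof["-1", "T"], 1)
  expect_equal(prof["+1", "G"], 1)
  # minus-strand site at plus-pos 11 with plus context (10..12) = T,T,T
  g2 <- Biostrings::DNAStringSet(c(chr1 = "AAAAAAAAACTTG"))
  s2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 11),
                               strand = "-")
  prof2 <- neighborPreference(s2, g2)
  # -1 neighbor = revcomp of plus base at pos 12 (T) = A
  expect_equal(prof2["-1", "A"], 1)
  # +1 neighbor = revcomp of plus base at pos 10 (C) = G
  expect_equal(prof2["+1", "G"], 1)
})

test_that("uniform random flanks give near-uniform neighbor profiles", {
  set.seed(10)
  g <- randomGenome(20000, seed = 10)
  pos <- sample(2:19999, 4000)
  s <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos),
                              strand = "+")
  prof <- neighborPreference(s, g)
  expect_equal(rowSums(prof), c(`-1` = 1, `+1` = 1))
  bound <- 3 * sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(prof - 0.25) < bound))
})

test_that("site category assignment uses CDS-first precedence", {
  ann <- annotationSet(features = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100, 100), c(200, 300)),
    category = c("CDS", "intron")))
  s <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(150, 250, 400),
                                                       c(150, 250, 400)))
  out <- annotateSites(s, ann)
  expect_equal(out$assignment, c("CDS", "intron", "intergenic"))
  expect_equal(sum(out$fractions), 1)
})

test_that("repeat enrichment fractions and folds are counting-exact", {
  ann <- annotationSet(repeats = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 101), c(8, 192)),
    family = c("hAT", "other")))  # hAT 8 of 100 repeat bases
  mk <- function(pos) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(pos, pos))
  # 26 of 100 repeat-resident sites in hAT
  sites <- mk(c(rep(2:5, length.out = 26), rep(105:180, length.out = 74)))
  re <- repeatEnrichment(sites, ann)
  hat <- re[re$family == "hAT", ]
  expect_equal(hat$genomicFraction, 0.08)
  expect_equal(hat$editedFraction, 0.26)
  expect_equal(hat$fold, 3.25)
  expect_equal(sum(re$editedFraction), 1)
})

test_that("gene-level hyperediting enrichment is the panel/background
           ratio", {
  expect_equal(round(geneHeEnrichment(paste0("g", 1:12), paste0("g", 1:7),
                                      0.029), 1), 20.1)
  expect_equal(geneHeEnrichment(letters[1:10], letters[1:3], 0.3), 1)
  expect_equal(geneHeEnrichment(letters[1:10], letters[1:3], 0.15), 2)
  expect_error(geneHeEnrichment(letters[1:3], letters[1], 0), "background")
})

test_that("no sites are called from error-free unedited reads and planted
           sites are recovered at depth", {
  cfg <- simConfig(seed = 31, errorRate = 0, readDepth = 80)
  ref <- simulateReference(cfg)
  # null: reads with editing levels forced to zero
  nullTruth <- ref$truth
  S4Vectors::mcols(nullTruth@sites)$level <- 0
  alnNull <- simulateTranscriptomeReads(ref$genome, nullTruth, cfg)
  detNull <- detectHyperediting(alnNull, ref$genome)
  expect_equal(length(detNull$sites), 0L)

  # planted: all sites at level 0.3, depth ~49x per site -> recovered
  aln <- simulateTranscriptomeReads(ref$genome, ref$truth, cfg)
  det <- detectHyperediting(aln, ref$genome)
  tr <- trueSites(ref$truth)
  key <- function(gr) paste(GenomicRanges::seqnames(gr),
                            GenomicRanges::start(gr))
  expect_gte(mean(key(tr) %in% key(det$sites)), 0.9)
  # no false positives at unplanted positions
  expect_true(all(key(det$sites) %in% key(tr)))
})
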
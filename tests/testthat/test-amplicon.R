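test_that("demultiplexing is exact-match, trims barcodes and conserves
           reads", {
  sheet <- data.frame(id = c("s1", "s2"), barcode = c("AAAA", "CCCC"),
                      genotype = c("WT", "WT"), material = "RNA")
  reads <- makeFastq(c("AAAAGGGG", "CCCCTTTT", "AAATGGGG", "GGGGGGGG"))
  bins <- demultiplex(reads, sheet)
  expect_equal(as.character(bins$s1), c(r1 = "GGGG"))
  expect_equal(as.character(bins$s2), c(r2 = "TTTT"))
  # one-mismatch barcode is unassigned
  expect_equal(length(bins$unassigned), 2L)
  expect_equal(length(bins$s1) + length(bins$s2) + length(bins$unassigned),
               length(reads))
  sheet$barcode <- c("AAAA", "AAAA")
  expect_error(demultiplex(reads, sheet), "duplicate")
})

tinyPanel <- function() {
  # two 40 bp amplicons, primers 5 bp, one targeted site each
  set.seed(20)
  a1 <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  a2 <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  substr(a1, 20, 20) <- "A"; substr(a2, 25, 25) <- "A"
  info <- S4Vectors::DataFrame(
    id = c("ampA", "ampB"), gene = c("g1", "g2"), contig = "chrT",
    start = c(1L, 101L), end = c(40L, 140L), strand = "+",
    refseq = c(a1, a2), fwdPrimerLen = 5L, revPrimerLen = 5L)
  info$sites <- list(20L, 125L)
  ampliconPanel(info)
}

test_that("amplicon alignment recovers origin, orientation and offset", {
  panel <- tinyPanel()
  info <- panelInfo(panel)
  r1 <- info$refseq[1]
  rc2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(info$refseq[2])))
  substr(rc2, 5, 5) <- if (substr(rc2, 5, 5) == "A") "C" else "A"
  substr(rc2, 9, 9) <- if (substr(rc2, 9, 9) == "A") "C" else "A"
  reads <- makeFastq(c(r1, rc2), ids = c("fwd", "rev2mm"))
  aln <- suppressMessages(alignAmpliconReads(reads, panel, "s"))
  expect_equal(aln$amplicon, c("ampA", "ampB"))
  expect_equal(aln$strand, c("+", "-"))
  expect_equal(aln$pos, c(1L, 101L))
  # stored genome-forward: the reverse read's sequence matches the
  # amplicon reference except at the two planted positions
  mm <- sum(strsplit(aln$seq[2], "")[[1]] !=
              strsplit(info$refseq[2], "")[[1]])
  expect_equal(mm, 2L)
})

test_that("ambiguous and over-ceiling reads are dropped; placements match
           the exhaustive oracle", {
  panel <- tinyPanel()
  info <- panelInfo(panel)
  # read equidistant from both amplicons: a chimera can't tie exactly in
  # general, so build identical amplicons
  info2 <- info
  info2$refseq[2] <- info$refseq[1]
  info2$sites <- list(20L, 120L)
  same <- ampliconPanel(info2)
  reads <- makeFastq(info$refseq[1], ids = "tie")
  expect_message(aln <- alignAmpliconReads(reads, same, "s"), "ambiguous")
  expect_equal(nrow(aln), 0L)

  junk <- makeFastq(strrep("A", 40), ids = "junk")
  expect_message(alnJ <- alignAmpliconReads(junk, panel, "s"), "ceiling")
  expect_equal(nrow(alnJ), 0L)

  # randomized short reads vs the exhaustive all-offsets oracle
  set.seed(21)
  for (i in 1:40) {
    a <- sample(1:2, 1)
    w <- sample(15:30, 1)
    off <- sample(1:(40 - w + 1), 1)
    frag <- substr(info$refseq[a], off, off + w - 1)
    nmm <- sample(0:2, 1)
    if (nmm) for (p in sample(w, nmm)) {
      old <- substr(frag, p, p)
      substr(frag, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
    if (runif(1) < 0.5)
      frag <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(frag)))
    want <- oracleAlign(frag, info$refseq)
    got <- suppressMessages(
      alignAmpliconReads(makeFastq(frag), panel, "s"))
    if (length(want$amps) > 1 || want$best > floor(0.1 * w)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(nrow(got), 1L)
      expect_equal(got$amplicon, info$id[want$amps])
    }
  }
})

test_that("quantification counts only quality-passing A/G bases", {
  panel <- tinyPanel()
  info <- panelInfo(panel)
  sheet <- data.frame(id = "s1", barcode = "AAAA", genotype = "WT",
                      material = "RNA")
  # 400 unedited reads -> level 0
  aln <- do.call(rbind, lapply(1:400, function(i)
    makeRead(paste0("r", i), "chrT", 1L, info$refseq[1], sample = "s1")))
  se <- quantifySites(aln, panel, sheet)
  expect_s4_class(se, "SiteEditingTable")
  expect_equal(assay(se, "nA")["chrT:20:+", "s1"], 400L)
  expect_equal(editingLevels(se)["chrT:20:+", "s1"], 0)

  # low-quality base at the site is excluded from counts and depth
  edited <- info$refseq[1]; substr(edited, 20, 20) <- "G"
  lowq <- strrep("I", 40); substr(lowq, 20, 20) <- Q(19)
  aln2 <- rbind(
    makeRead("e1", "chrT", 1L, edited, sample = "s1"),
    makeRead("e2", "chrT", 1L, edited, qual = lowq, sample = "s1"),
    makeRead("u1", "chrT", 1L, info$refseq[1], sample = "s1"))
  se2 <- quantifySites(aln2, panel, sheet)
  expect_equal(assay(se2, "nG")["chrT:20:+", "s1"], 1L)
  expect_equal(coverageDepth(se2)["chrT:20:+", "s1"], 2L)
  # base at exactly Q20 is retained
  q20 <- strrep("I", 40); substr(q20, 20, 20) <- Q(20)
  se3 <- quantifySites(rbind(aln2, makeRead("e3", "chrT", 1L, edited,
                                            qual = q20, sample = "s1")),
                       panel, sheet)
  expect_equal(assay(se3, "nG")["chrT:20:+", "s1"], 2L)
})

test_that("uncovered sites get zero depth and undefined level", {
  panel <- tinyPanel()
  sheet <- data.frame(id = "s1", barcode = "AAAA", genotype = "WT",
                      material = "RNA")
  aln <- makeRead("r1", "chrT", 1L, panelInfo(panel)$refseq[1],
                  sample = "s1")
  se <- quantifySites(aln, panel, sheet)
  expect_equal(coverageDepth(se)["chrT:125:+", "s1"], 0L)
  expect_true(is.na(editingLevels(se)["chrT:125:+", "s1"]))
})

test_that("off-target discovery requires ten quality-passing mismatch
           reads", {
  panel <- tinyPanel()
  info <- panelInfo(panel)
  # pick an untargeted A inside the insert of ampA
  ins <- seq(info$start[1] + 5L, info$end[1] - 5L)
  refChars <- strsplit(info$refseq[1], "")[[1]]
  cand <- setdiff(ins[refChars[ins] == "A"], 20L)[1]
  mkAln <- function(nG) {
    edited <- info$refseq[1]; substr(edited, cand, cand) <- "G"
    do.call(rbind, c(
      lapply(seq_len(nG), function(i)
        makeRead(paste0("g", i), "chrT", 1L, edited, sample = "s1")),
      lapply(1:50, function(i)
        makeRead(paste0("a", i), "chrT", 1L, info$refseq[1],
                 sample = "s1"))))
  }
  expect_equal(length(discoverOfftargetSites(mkAln(9), panel)), 0L)
  ot <- discoverOfftargetSites(mkAln(10), panel)
  expect_equal(GenomicRanges::start(ot), cand)
  expect_false(ot$targeted)
  # all-reference alignments yield nothing
  expect_equal(length(discoverOfftargetSites(mkAln(0), panel)), 0L)
})

mkTable <- function(nA, nG, sheet, sites = NULL) {
  depth <- nA + nG
  level <- ifelse(depth > 0, nG / depth, NA_real_)
  ns <- nrow(nA)
  gr <- sites %||% GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(seq_len(ns) * 10L, seq_len(ns) * 10L),
    strand = "+", amplicon = paste0("amp", (seq_len(ns) + 1) %/% 2),
    gene = paste0("g", seq_len(ns)), targeted = TRUE)
  rn <- sprintf("chrT:%d:+", GenomicRanges::start(gr))
  dimnames(nA) <- dimnames(nG) <- dimnames(depth) <- dimnames(level) <-
    list(rn, sheet$id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(nA = nA, nG = nG, depth = depth, level = level),
    rowRanges = gr,
    colData = S4Vectors::DataFrame(sheet, row.names = sheet$id))
  rownames(se) <- rn
  new("SiteEditingTable", se)
}

test_that("SNP masking excludes gDNA variants, known SNPs and sites with
           no gDNA evidence", {
  sheet <- data.frame(id = c("s1", "s2"), barcode = c("AA", "CC"),
                      genotype = "WT", material = "RNA")
  gsheet <- data.frame(id = "g1", barcode = "GG", genotype = "WT",
                       material = "gDNA")
  rna <- mkTable(matrix(500L, 4, 2), matrix(100L, 4, 2), sheet)
  gA <- matrix(c(250L, 500L, 0L, 500L), 4, 1)
  gG <- matrix(c(250L, 0L, 0L, 2L), 4, 1)   # het, clean, none, 0.4% alt
  gdna <- mkTable(gA, gG, gsheet)
  mk <- maskGenomicVariants(rna, gdna)
  expect_equal(sort(mk$exclusions$reason),
               sort(c("gDNA variant", "no gDNA evidence")))
  expect_equal(rownames(mk$table), c("chrT:20:+", "chrT:40:+"))

  known <- GenomicRanges::GRanges("chrT", IRanges::IRanges(40, 40))
  mk2 <- maskGenomicVariants(rna, gdna, knownSnps = known)
  expect_true("chrT:40:+" %in% mk2$exclusions$site)
  expect_equal(mk2$exclusions$reason[mk2$exclusions$site == "chrT:40:+"],
               "known SNP")
  expect_equal(rownames(mk2$table), "chrT:20:+")
})

test_that("selection criteria enforce the printed boundaries", {
  ids <- paste0("s", 1:8)
  sheet <- data.frame(id = ids, barcode = ids, genotype = "WT",
                      material = "RNA")
  lvl <- 0.10
  mkOne <- function(depths, level = lvl) {
    nG <- as.integer(round(depths * level))
    mkTable(matrix(as.integer(depths - nG), 1, 8),
            matrix(nG, 1, 8), sheet)
  }
  # depth 399 everywhere -> dropped by coverage; 400 -> kept
  sel399 <- applySelectionCriteria(mkOne(rep(399L, 8)))
  expect_equal(length(sel399$retained), 0L)
  expect_equal(unique(sel399$audit$fail), "coverage")
  expect_equal(length(applySelectionCriteria(
    mkOne(rep(400L, 8)))$retained), 1L)
  # captured in 6/8 (75%) kept, 5/8 dropped by incidence
  sel58 <- applySelectionCriteria(mkOne(c(rep(400L, 5), rep(10L, 3))))
  expect_equal(length(sel58$retained), 0L)
  expect_equal(unique(sel58$audit$fail), "incidence")
  expect_equal(length(applySelectionCriteria(
    mkOne(c(rep(400L, 6), rep(10L, 2))))$retained), 1L)
  # mean level below 2% dropped, exactly 2% kept
  expect_equal(length(applySelectionCriteria(
    mkOne(rep(500L, 8), level = 0.018))$retained), 0L)
  expect_equal(length(applySelectionCriteria(
    mkOne(rep(500L, 8), level = 0.02))$retained), 1L)
})

test_that("the selection cascade matches a brute-force scan on random
           tables", {
  set.seed(22)
  ids <- paste0("s", 1:10)
  sheet <- data.frame(id = ids, barcode = ids,
                      genotype = rep(c("WT", "KO"), each = 5),
                      material = "RNA")
  for (trial in 1:20) {
    depth <- matrix(sample(c(0L, 200L, 399L, 400L, 800L), 120, TRUE),
                    12, 10)
    nG <- matrix(as.integer(round(depth *
                                    runif(120, 0, 0.06))), 12, 10)
    tab <- mkTable(depth - nG, nG, sheet)
    got <- applySelectionCriteria(tab)$retained
    want <- rownames(tab)[oracleSelection(
      coverageDepth(tab), editingLevels(tab), sheet$genotype,
      400, 0.75, 0.02)]
    expect_equal(got, want)
  }
})

test_that("differential editing reports Welch results per retained site", {
  ids <- paste0("s", 1:6)
  sheet <- data.frame(id = ids, barcode = ids,
                      genotype = rep(c("WT", "KO"), each = 3),
                      material = "RNA")
  nA <- matrix(900L, 2, 6); nG <- matrix(100L, 2, 6)
  tab <- mkTable(nA, nG, sheet)
  de <- differentialEditing(tab)
  expect_equal(de$t, c(0, 0))
  expect_equal(de$p, c(1, 1))

  lv1 <- c(0.10, 0.12, 0.11); lv2 <- c(0.20, 0.22, 0.21)
  nG <- rbind(as.integer(1000 * c(lv1, lv2)), 100L)
  tab2 <- mkTable(matrix(1000L, 2, 6) - nG, nG, sheet)
  de2 <- differentialEditing(tab2)
  w <- welchTTest(lv1, lv2)
  expect_equal(de2$t[1], w$t)
  expect_equal(de2$p[1], w$p.value)
  expect_false("padj" %in% names(de2))
  expect_true("padj" %in% names(differentialEditing(tab2, correct = TRUE)))

  # a group with <2 defined levels skips the site
  nA3 <- matrix(900L, 1, 6); nG3 <- matrix(100L, 1, 6)
  nA3[1, 1:2] <- 0L; nG3[1, 1:2] <- 0L
  expect_message(de3 <- differentialEditing(mkTable(nA3, nG3, sheet)),
                 "skipped")
  expect_equal(nrow(de3), 0L)
})

test_that("depth correlation is exact on constructed fixtures", {
  ids <- paste0("s", 1:4)
  sheet <- data.frame(id = ids, barcode = ids,
                      genotype = rep(c("WT", "KO"), each = 2),
                      material = "RNA")
  # 6 sites over 3 amplicons; identical depths per sample -> r = 1
  depth <- matrix(rep(c(500L, 500L, 800L, 800L, 300L, 300L), 4), 6, 4)
  tab <- mkTable(depth - 50L, matrix(50L, 6, 4), sheet)
  expect_equal(depthCorrelation(tab)$r, 1)
  # anti-ordered per-amplicon means between genotypes -> r = -1
  wt <- rep(c(100L, 200L, 300L), each = 2)
  ko <- rep(c(300L, 200L, 100L), each = 2)
  depth2 <- cbind(wt, wt, ko, ko)
  tab2 <- mkTable(depth2 - 10L, matrix(10L, 6, 4), sheet)
  expect_equal(depthCorrelation(tab2)$r, -1)
})
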
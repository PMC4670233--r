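phasePanel <- function() {
  set.seed(30)
  a1 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  substr(a1, 20, 25) <- "TTAAGA"  # codon pair TTA|AGA, sites 22, 23
  info <- S4Vectors::DataFrame(
    id = "ampP", gene = "gria2a", contig = "chrP", start = 1L, end = 60L,
    strand = "+", refseq = a1, fwdPrimerLen = 5L, revPrimerLen = 5L)
  info$sites <- list(c(22L, 23L))
  ampliconPanel(info, list(ampP = data.frame(
    site = c(22L, 23L), codon = c(1L, 2L),
    refCodon = c("TTA", "AGA"), codonPos = c(3L, 1L))))
}

phaseAln <- function(tuples, sample = "s1", panel = phasePanel(),
                     quals = NULL) {
  info <- panelInfo(panel)
  do.call(rbind, lapply(seq_along(tuples), function(i) {
    sq <- info$refseq[1]
    substr(sq, 22, 22) <- substr(tuples[i], 1, 1)
    substr(sq, 23, 23) <- substr(tuples[i], 2, 2)
    makeRead(paste0(sample, "_r", i), "chrP", 1L, sq,
             qual = quals[i] %||% NULL, sample = sample)
  }))
}

test_that("all-unedited reads yield a pure AA tuple table", {
  aln <- phaseAln(rep("AA", 30))
  ht <- extractReadHaplotypes(aln, phasePanel(), "ampP")
  expect_equal(haplotypeCounts(ht)["AA", "s1"], 30L)
  expect_equal(sum(haplotypeCounts(ht)), 30L)
  expect_equal(variantAbundance(ht)["AA", "s1"], 1)
})

test_that("reads are excluded as units: not spanning, low quality, or
           non-A/G at a site", {
  panel <- phasePanel()
  info <- panelInfo(panel)
  short <- makeRead("short", "chrP", 1L, substr(info$refseq[1], 1, 22),
                    sample = "s1")      # covers site 1 only
  lowq <- strrep("I", 60); substr(lowq, 23, 23) <- Q(19)
  bad <- phaseAln(c("AA", "GG"), sample = "s1")
  lq <- phaseAln("AG", sample = "s1", quals = lowq)
  cc <- phaseAln("CC", sample = "s1")
  aln <- rbind(bad, short, lq, cc)
  ht <- extractReadHaplotypes(aln, panel, "ampP")
  expect_equal(sum(haplotypeCounts(ht)), 2L)
  excl <- ht@excluded
  expect_equal(excl["notSpanning", "s1"], 1L)
  expect_equal(excl["lowQual", "s1"], 1L)
  expect_equal(excl["nonAG", "s1"], 1L)
})

test_that("a planted uniform 4-tuple distribution is recovered within the
           multinomial bound", {
  set.seed(31)
  tuples <- sample(c("AA", "AG", "GA", "GG"), 10000, TRUE)
  ht <- extractReadHaplotypes(phaseAln(tuples), phasePanel(), "ampP")
  ab <- variantAbundance(ht)[, "s1"]
  bound <- 3 * sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(ab - 0.25) < bound))
  expect_equal(sum(ab), 1)
})

test_that("perfect planted linkage yields zero mixed tuples", {
  set.seed(32)
  tuples <- sample(c("AA", "GG"), 2000, TRUE)
  ht <- extractReadHaplotypes(phaseAln(tuples), phasePanel(), "ampP")
  cnt <- haplotypeCounts(ht)
  expect_equal(cnt["AG", "s1"] + cnt["GA", "s1"], 0L)
  expect_equal(sum(cnt), 2000L)
})

test_that("tuple marginals equal site-level editing on the same reads", {
  set.seed(33)
  tuples <- sample(c("AA", "AG", "GA", "GG"), 3000, TRUE,
                   prob = c(.5, .2, .2, .1))
  aln <- phaseAln(tuples)
  panel <- phasePanel()
  ht <- extractReadHaplotypes(aln, panel, "ampP")
  cnt <- haplotypeCounts(ht)[, "s1"]
  sheet <- data.frame(id = "s1", barcode = "AA", genotype = "WT",
                      material = "RNA")
  se <- quantifySites(aln, panel, sheet)
  m1 <- sum(cnt[c("GA", "GG")]) / sum(cnt)
  m2 <- sum(cnt[c("AG", "GG")]) / sum(cnt)
  expect_equal(m1, editingLevels(se)["chrP:22:+", "s1"])
  expect_equal(m2, editingLevels(se)["chrP:23:+", "s1"])
})

test_that("codon maps translate tuples through the standard genetic
           code", {
  cmLR <- data.frame(site = c(22L, 23L), codon = c(1L, 2L),
                     refCodon = c("TTA", "AGA"), codonPos = c(3L, 1L))
  expect_equal(labelProteinVariants("AA", cmLR), "LR")
  expect_equal(labelProteinVariants("AG", cmLR), "LG")
  cmTI <- data.frame(site = c(10L, 13L), codon = c(1L, 2L),
                     refCodon = c("ACA", "ATA"), codonPos = c(1L, 1L))
  expect_equal(labelProteinVariants("AA", cmTI), "TI")
  expect_equal(labelProteinVariants("GG", cmTI), "AV")
  # oracle: brute-force substitution + translation on random codon maps
  set.seed(34)
  for (i in 1:30) {
    refCodon <- vapply(1:2, function(j)
      paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = ""),
      character(1))
    codonPos <- sample(1:3, 2, TRUE)
    cm <- data.frame(site = c(5L, 9L), codon = 1:2, refCodon = refCodon,
                     codonPos = codonPos)
    tuple <- paste(sample(c("A", "G"), 2, TRUE), collapse = "")
    want <- paste0(vapply(1:2, function(j) {
      ch <- strsplit(refCodon[j], "")[[1]]
      ch[codonPos[j]] <- substr(tuple, j, j)
      Biostrings::GENETIC_CODE[[paste(ch, collapse = "")]]
    }, character(1)), collapse = "")
    expect_equal(labelProteinVariants(tuple, cm), want)
  }
  expect_error(labelProteinVariants("AA", transform(cmLR,
                                                    codonPos = c(4L, 1L))),
               "codon position")
  expect_error(labelProteinVariants("A", cmLR), "arity")
})

test_that("differential variant abundance compares genotypes per tuple", {
  panel <- phasePanel()
  sheet <- data.frame(id = paste0("s", 1:6),
                      barcode = paste0("B", 1:6),
                      genotype = rep(c("WT", "KO"), each = 3),
                      material = "RNA")
  set.seed(35)
  alns <- lapply(sheet$id, function(s)
    phaseAln(sample(c("AA", "GG"), 500, TRUE, prob = c(.6, .4)),
             sample = s))
  ht <- extractReadHaplotypes(do.call(rbind, alns), panel, "ampP",
                              samples = sheet$id)
  # identical generating distributions: no tuple should be significant
  dv <- differentialVariantAbundance(ht, sheet)
  expect_true(all(dv$p > 0.001))
  expect_equal(dv$label[dv$tuple == "AA"], "LR")
  # per-sample abundances sum to 1
  expect_equal(unname(colSums(variantAbundance(ht))), rep(1, 6))
})
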
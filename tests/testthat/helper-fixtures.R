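# Shared fixture builders and independent brute-force oracles. Every
# oracle here is deliberately naive (linear scans, per-read walks,
# exhaustive enumeration) and independent of the package's implementation
# paths it is used to check.

Q <- function(q) rawToChar(as.raw(q + 33L))  # one Phred+33 char

makeRead <- function(qname, contig, pos, seq, qual = NULL, cigar = NULL,
                     strand = "+", mapq = 60L, sample = NA_character_) {
  data.frame(qname = qname, sample = sample, contig = contig,
             pos = as.integer(pos), mapq = as.integer(mapq),
             cigar = cigar %||% paste0(nchar(seq), "M"), seq = seq,
             qual = qual %||% strrep("I", nchar(seq)),  # Q40
             strand = strand, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

makeReads <- function(...) do.call(rbind, list(...))

makeFastq <- function(seqs, quals = NULL, ids = NULL) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids %||% paste0("r", seq_along(seqs))
  S4Vectors::mcols(x)$qualities <-
    Biostrings::BStringSet(quals %||% strrep("I", nchar(seqs)))
  x
}

randomGenome <- function(len, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Biostrings::DNAStringSet(stats::setNames(
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    character(1)), paste0("chr", seq_len(n))))
}

# --- oracle: naive per-read, per-position pileup walk --------------------
oraclePileup <- function(reads, genome, minBaseQual = 20) {
  acc <- list()
  for (i in seq_len(nrow(reads))) {
    lens <- as.integer(regmatches(reads$cigar[i],
                                  gregexpr("\\d+", reads$cigar[i]))[[1]])
    ops <- regmatches(reads$cigar[i],
                      gregexpr("[A-Z=]", reads$cigar[i]))[[1]]
    r <- reads$pos[i]; q <- 1L
    quals <- as.integer(charToRaw(reads$qual[i])) - 33L
    for (k in seq_along(ops)) {
      if (ops[k] %in% c("M", "=", "X")) {
        for (j in seq_len(lens[k])) {
          b <- substr(reads$seq[i], q, q)
          if (quals[q] >= minBaseQual && b %in% c("A", "C", "G", "T")) {
            key <- paste(reads$contig[i], r)
            if (is.null(acc[[key]]))
              acc[[key]] <- c(A = 0L, C = 0L, G = 0L, T = 0L)
            acc[[key]][b] <- acc[[key]][b] + 1L
          }
          r <- r + 1L; q <- q + 1L
        }
      } else if (ops[k] %in% c("I", "S")) q <- q + lens[k]
      else if (ops[k] == "D") r <- r + lens[k]
    }
  }
  acc
}

# --- oracle: brute-force maximal same-class runs -------------------------
oracleClusters <- function(df, window, minSites) {
  out <- list()
  for (key in unique(paste(df$contig, df$strand, df$class))) {
    sub <- df[paste(df$contig, df$strand, df$class) == key, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    run <- sub$pos[1]
    for (p in sub$pos[-1]) {
      if (p - run[length(run)] <= window) run <- c(run, p)
      else {
        if (length(run) >= minSites)
          out[[length(out) + 1L]] <- list(key = key, pos = run)
        run <- p
      }
    }
    if (length(run) >= minSites)
      out[[length(out) + 1L]] <- list(key = key, pos = run)
  }
  out
}

# --- oracle: linear interval scan with category precedence ---------------
oracleClassify <- function(contig, pos, featDf) {
  prec <- c("CDS", "3'-UTR", "5'-UTR", "intron")
  hits <- featDf$category[featDf$contig == contig &
                            featDf$start <= pos & featDf$end >= pos]
  if (!length(hits)) return("intergenic")
  hits[which.min(match(hits, prec, nomatch = length(prec) + 1L))]
}

# --- oracle: exhaustive selection-cascade scan ---------------------------
oracleSelection <- function(depth, level, genotype, minCov, minInc,
                            minLev) {
  keep <- logical(nrow(depth))
  for (i in seq_len(nrow(depth))) {
    ok <- TRUE
    for (g in unique(genotype)) {
      cols <- which(genotype == g)
      cap <- depth[i, cols] >= minCov
      if (mean(cap) < minInc) { ok <- FALSE; break }
      lv <- level[i, cols][cap]
      if (!length(lv) || mean(lv, na.rm = TRUE) < minLev) {
        ok <- FALSE; break
      }
    }
    keep[i] <- ok
  }
  keep
}

# --- oracle: sliding-window IUPAC motif check ----------------------------
oracleRreScan <- function(s) {
  s <- toupper(chartr("Uu", "Tt", s))
  hits <- list()
  if (nchar(s) >= 4) {
    for (i in seq_len(nchar(s) - 3L)) {
      w <- substr(s, i, i + 3L)
      c1 <- strsplit(w, "")[[1]]
      if (c1[1] == "A" && c1[2] == "C" && c1[3] == "T" &&
          c1[4] %in% c("G", "T"))
        hits[[length(hits) + 1L]] <- list(start = i, motif = "ACUK")
      if (c1[1] %in% c("A", "T") && c1[2] == "G" && c1[3] == "G" &&
          c1[4] == "A")
        hits[[length(hits) + 1L]] <- list(start = i, motif = "WGGA")
    }
  }
  hits
}

# --- oracle: exhaustive gapless read placement ---------------------------
oracleAlign <- function(read, ampSeqs) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  best <- Inf; hits <- list()
  w <- nchar(read)
  for (a in seq_along(ampSeqs)) {
    La <- nchar(ampSeqs[a])
    if (w > La) next
    for (off in seq_len(La - w + 1L)) {
      win <- substr(ampSeqs[a], off, off + w - 1L)
      for (ori in c("+", "-")) {
        cand <- if (ori == "+") read else rc
        mm <- sum(strsplit(win, "")[[1]] != strsplit(cand, "")[[1]])
        if (mm < best) {
          best <- mm
          hits <- list(list(amp = a, off = off, ori = ori, mm = mm))
        } else if (mm == best) {
          hits[[length(hits) + 1L]] <- list(amp = a, off = off, ori = ori,
                                            mm = mm)
        }
      }
    }
  }
  list(best = best, hits = hits,
       amps = unique(vapply(hits, `[[`, numeric(1), "amp")))
}

# small shared amplicon simulation used by several test files (kept light)
smallAmpliconSim <- function(seed = 11, depth = 500, nPerGt = 4,
                             gdna = 2, error = 0.001) {
  cfg <- simConfig(seed = seed, ampliconDepth = depth,
                   samplesPerGenotype = nPerGt, gdnaPerGenotype = gdna,
                   errorRate = error)
  sim <- simulateAmpliconPanel(cfg)
  sheetR <- sim$sheet[sim$sheet$material == "RNA", ]
  sheetG <- sim$sheet[sim$sheet$material == "gDNA", ]
  binsR <- demultiplex(sim$rnaReads, sheetR)
  alnR <- do.call(rbind, lapply(sheetR$id, function(s)
    suppressMessages(alignAmpliconReads(binsR[[s]], sim$panel, s))))
  binsG <- demultiplex(sim$gdnaReads, sheetG)
  alnG <- do.call(rbind, lapply(sheetG$id, function(s)
    suppressMessages(alignAmpliconReads(binsG[[s]], sim$panel, s))))
  c(sim, list(sheetR = sheetR, sheetG = sheetG, alnR = alnR, alnG = alnG))
}
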
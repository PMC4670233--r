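---
title: "EditScape: models and methods for A-to-I editing detection, quantification and phasing"
author: "EditScape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EditScape methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and scientific background

Adenosine-to-inosine (A-to-I) RNA editing is catalysed by Adar enzymes on
double-stranded RNA. Because inosine is read as guanosine by both the
ribosome and reverse transcriptase, edited positions appear as A→G
mismatches between RNA reads and the genomic reference (or T→C on the
reference plus strand for minus-strand transcripts). EditScape covers the
three layers at which such editing is usually analysed:

1. **Hyperediting (HE) discovery** — dense clusters of same-class A→G
   sites, typically inside long inverted-repeat dsRNA, detectable from
   RNA-seq alone because clustering separates editing from SNPs and
   sequencing error.
2. **Targeted amplicon quantification** — microfluidic multiplex PCR
   (mmPCR)-style deep resequencing of a site panel across many samples,
   with a filter cascade, genomic-SNP masking against matched gDNA from
   the same animals, off-target site discovery and genotype differential
   testing.
3. **Read-backed phasing** — joint A/G tuples across neighbouring sites
   on single reads, converted into mRNA-variant abundances and
   protein-recoding labels (for example a doubly editable Leu–Arg pair
   whose unedited translation is "LR").

# Core quantities

The editing level at a site is the fraction of edited reads among
reference-plus-edited reads,

$$\ell = \frac{n_G}{n_A + n_G},$$

computed over bases with Phred quality ≥ 20 on reads with mapping
quality ≥ 20. A level with $n_A + n_G = 0$ is undefined and reported as
`NA`, never as 0. Note that the corresponding printed formula in some
methods sections is written "A/(A+G)" while the accompanying text
describes "the fraction of G reads of all A+G reads"; the two contradict
each other and EditScape implements the verbal definition, $G/(A+G)$,
throughout.

Group comparisons use Welch's unequal-variance two-sample t-test with
Welch–Satterthwaite degrees of freedom and two-sided p-values. The test
is implemented in closed form in `welchTTest()` (and cross-checked
against `stats::t.test` in the test suite). When both groups have zero
variance the statistic degenerates: equal means give $t=0$, $p=1$;
unequal means give $p=0$ flagged `degenerate`. By default no
multiple-testing correction is applied (raw p-values at
$\alpha = 0.05$); Benjamini–Hochberg adjustment is available behind
`correct = TRUE`.

# Thresholds

All cutoffs live in one `FilterThresholds` object so that every report
is reproducible from counts plus a single threshold set:

| slot | default | meaning |
|---|---|---|
| `minBaseQual` | 20 | Phred floor for a base to be counted |
| `minMapq` | 20 | mapping-quality floor for a read |
| `heMinEditedReads` | 6 | HE candidate needs *more than five* edited reads |
| `heMinLevel` | 0.01 | HE candidate level strictly above 1% |
| `minMismatchReads` | 10 | G-read support to call a novel off-target site |
| `ampMinCoverage` | 400 | reads for a sample/site cell to count as captured |
| `ampMinIncidence` | 0.75 | captured fraction of a genotype's samples |
| `ampMinLevel` | 0.02 | genotype-mean level floor for retention |
| `clusterWindowBp` | 100 | max gap between sites within an HE cluster |
| `clusterMinSites` | 3 | min same-class sites per cluster |
| `snpMaxGdnaAlt` | 0.01 | pooled gDNA alternate fraction above which a site is a SNP |

The HE thresholds are exclusive bounds (strictly more than five reads,
level strictly above 0.01); the amplicon cascade bounds are inclusive
(at least 400 reads, at least 75%, at least 2%). The test suite pins
every one of these boundaries with fixtures one count either side.

The cluster parameters (100 bp window, minimum three same-class sites)
are this package's own defaults: the qualitative notion of a "dense
cluster" has no published quantitative definition, so we chose a window
of roughly one read length — sites linked by single reads — and expose
both knobs. The SNP-masking cutoff (1% pooled gDNA alternate fraction)
is likewise ours; a true heterozygote sits near 50% and a homozygote
near 100%, so the cutoff's exact value is uncritical across two orders
of magnitude.

# The amplicon cascade: interpretation choices

Three published criteria select quantifiable sites: (i) sample
incidence ≥ 75% within a genotype, (ii) coverage ≥ 400 reads, and
(iii) editing level ≥ 2%. Two ambiguities had to be resolved:

* **Criterion ii is applied per sample–site cell**, defining
  "captured"; criterion i then asks whether ≥ 75% of a genotype's
  samples captured the site. The alternative (400 reads pooled over
  samples) would make criterion i vacuous at deep coverage.
* **Criterion iii is applied to the genotype-mean level** over captured
  samples, treating a site as one entity per genotype, rather than
  per-sample.

A site is retained only if it passes in *every* genotype, since the
downstream Welch test needs defined levels in both groups. The audit
table records, per site and genotype, the incidence, mean level and the
first criterion that failed (reported as "coverage" when no sample
reached 400 reads, "incidence" when some but fewer than 75% did).

**Off-target discovery** requires at least 10 quality-passing G reads at
an untargeted transcript-strand A position *in at least one sample*.
Counting per sample rather than pooled is our reading of the published
"at least 10 mismatch reads" rule: pooled across, say, twenty samples at
2000× each, uniform sequencing error alone (~0.03% per base per
substitution direction) would exceed 10 reads at every position and the
threshold would stop filtering anything.

**SNP masking** excludes a site when its pooled gDNA G fraction exceeds
`snpMaxGdnaAlt`, when it appears in a user-supplied known-SNP list
(list precedence over counts), or — conservatively — when it has no gDNA
evidence at all.

# Phasing model

Reads must span *all* clustered sites of the amplicon; a read is
discarded as a unit when it fails to span, carries any base below Q20 at
a site, or shows a base other than A/G at a site (discarding the read
rather than the base keeps tuples complete and avoids imputation).
Tuple tables therefore satisfy an exact marginal identity: the
G-fraction of site *k* computed from the tuple counts equals the
editing level of site *k* computed on the identically filtered reads —
this is asserted, exactly, in the tests.

Protein labels substitute each site's allele into its reference codon
at the mapped codon position and translate with the standard genetic
code; sites sharing a codon are substituted jointly. Codon maps are
packaged as per-amplicon panel metadata because published figures give
only the resulting amino-acid labels, not the codon bookkeeping.

# The built-in gapless aligner

Amplicon reads are assigned by exhaustive comparison against every
panel amplicon, both orientations, at every feasible offset, minimising
mismatch count — a complete search, feasible because panels are small
and amplicons short. Reads are dropped when the best placement exceeds
10% mismatches or is tied between different amplicons (ties within one
amplicon keep the first placement). Read alignment for transcriptome
data is out of scope: genome-scale alignments are consumed as SAM input,
and the two-pass splice-aware alignment such data needs is delegated to
the upstream aligner.

Pileup semantics follow samtools conventions: deletions reduce depth
rather than count as a fifth allele, insertions are ignored for
counting, N bases are discarded, and a read contributes at most one base
per column. Reads from the same fragment are counted independently
(single-end chemistry; no overlap de-duplication).

# Coordinates and conventions

Internally all coordinates are 1-based closed — the GRanges convention —
so reported positions match the `chr5:25066153` style used in site
tables directly; BED input (0-based half-open) is converted on read.
Strand handling is strand-specific by default: pileups are built per
read strand and mismatch classes re-oriented to the transcript strand,
so a genomic T→C on a minus-strand transcript is reported as A→G.
Quality encoding is fixed to Phred+33. RRE motif scanning (ACUK, WGGA;
K = G/U, W = A/U) unifies RNA and DNA input on T internally and reports
every overlapping occurrence in 1-based coordinates.

# The synthetic-data generator

The generator is first-class, tested code and the package's acceptance
oracle. Its defaults describe the desk-scale study conditions:

* **Transcriptome mode** — two 20 kb contigs; repeat elements laid out
  so family base fractions follow a fixed genome-like mix (hAT 8% of
  repeat bases) with one exact inverted-repeat pair of 120 bp hAT arms;
  gene features (5'-UTR/CDS/intron/CDS/3'-UTR); eight planted same-class
  site clusters (five sites, 12 bp spacing), A→G with probability 0.93,
  hosted preferentially in hAT elements (26% host probability,
  emulating inverted-repeat-driven editing); 76 bp strand-specific
  gapless reads at constant Q30, binomial per-site editing at level
  0.3, uniform substitution error 0.001.
* **Amplicon mode** — eight 120 bp amplicons (one minus-strand; two
  carrying adjacent recoding pairs with codon maps translating to
  LR/…/AV), two sites each; ten RNA samples per genotype (matching the
  published n = 10 batches per genotype) plus three matched gDNA
  samples per genotype; 2000 reads per amplicon per sample, scaled by a
  shared per-amplicon amplification-efficiency factor (log-normal,
  clipped to [0.5, 1.8]) and per-sample Poisson jitter, so
  between-genotype mean depths correlate across amplicons as they do on
  a real microfluidic chip; per-site levels laid out over 0.15–0.45
  with a genotype shift of 0.04 at alternating sites; joint haplotype
  distributions whose marginals equal the per-site levels by
  construction, with positive linkage on the recoding amplicons; one
  planted true off-target site (level 0.10); one heterozygous SNP on a
  targeted site, one homozygous and one heterozygous SNP at untargeted
  positions; 8 bp sample barcodes; half the reads reverse-complemented.

Every random stream derives deterministically from the master seed via
a per-component seed tree, so identical configurations reproduce
byte-identical reads.

What the generator deliberately does **not** emulate: platform-specific
error structure (e.g. homopolymer indels), PCR duplicates and chimeras,
quality-score decay along reads, biological replicate-to-replicate
variance beyond binomial sampling, allele-specific expression, and
splice structure. Passing recovery tests on these data therefore
demonstrates the correctness of the *pipeline arithmetic* — counting,
filtering, phasing, testing — under the stated statistical model, not
robustness to every artefact of real sequencing.

# Test and acceptance problem sizes

The suite exercises: spectrum recovery on 10,000 planted sites (93:7
mixture, binomial 3σ bound); a null Welch simulation over 1,000 sites
checking the empirical type-I error at α = 0.05 within its own 3σ band;
phasing recovery of a planted 4-tuple distribution at 10,000 reads with
the multinomial 3σ bound; 100 randomized trials per brute-force oracle
(pileup, clustering, annotation, selection, RRE, alignment); and one
full simulate→demultiplex→align→quantify→mask→filter→test→phase run at
the default conditions (8 amplicons, 10 samples/genotype, ~2000×),
requiring ≥ 95% of genotype-shifted sites significant at α = 0.05 and
zero planted SNPs in the retained set. These sizes were chosen so each
stochastic bound is meaningful while the whole suite stays comfortably
interactive.

# Known limitations

* The gapless aligner is for amplicons and synthetic data only;
  indel-containing amplicon reads are dropped at the mismatch ceiling.
* Off-target discovery scans A positions only on the annotated
  transcript strand of each amplicon; antisense editing within an
  amplicon would need the panel entry duplicated on the other strand.
* gDNA SNP masking assumes the same panel was sequenced for gDNA;
  sites without gDNA rows are excluded rather than guessed.
* `depthCorrelation()` requires at least three amplicons (the Pearson
  coefficient is meaningless below that).
* Haplotype phasing requires every read to span all clustered sites;
  panels with sites farther apart than a read length cannot be phased
  and no statistical imputation is attempted.
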
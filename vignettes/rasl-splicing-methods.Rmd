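---
title: "Methods: differential splicing, sequence architecture and AS-NMD from RASL-style junction counts"
author: "raslsplice"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: differential splicing, sequence architecture and AS-NMD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raslsplice)
```

# The measurement model

A RASL-style assay interrogates a fixed panel of annotated
alternative-splicing events. Each event carries two junction probes:
an *inclusion* probe spanning a junction present only when the
cassette exon is included, and a *skipping* probe spanning the
exon1–exon3 junction formed when it is excluded. Read counts for the
two probes in each sample are therefore an internally controlled pair:
their ratio estimates the isoform ratio of that event in that sample,
independent of sequencing depth, so no cross-sample normalisation is
applied anywhere in the pipeline.

## Detection and differential calls

Let $I_{is}$ and $S_{is}$ be inclusion and skipping counts for event
$i$ in sample $s$.

1. **Detection** (`detectEvents`): an event is analysable only if
   $I_{is} \ge m$ **and** $S_{is} \ge m$ for *every* sample of both
   conditions, with $m = 5$ by default. We read the detection rule as
   applying per isoform, so that every retained event has both
   isoforms expressed everywhere and ratios are always defined without
   pseudocounts. Failing events are reported as `filtered`, never
   silently dropped.
2. **Ratios** (`eventRatios`): $r_{is} = I_{is}/S_{is}$, plain
   floating-point division with no clamping. A zero skipping count is
   an error by construction (it can only be reached by bypassing the
   filter).
3. **Ratio change** (`callDifferential`):
   $\mathrm{RC}_i = \overline{r_i(B)} \, / \, \overline{r_i(A)}$ — the
   mean of per-replicate ratios in the perturbed condition over the
   mean in the baseline condition. We deliberately use the mean of
   ratios rather than the ratio of summed counts: it keeps replicates
   exchangeable and makes the condition-swap symmetry exact
   ($\mathrm{RC} \mapsto 1/\mathrm{RC}$, p unchanged).
4. **Significance**: the default test is a two-sided Welch t-test on
   $\log_2 r_{is}$. Ratio data are right-skewed and the log transform
   symmetrises them; Welch avoids an equal-variance assumption that
   triplicates cannot support. The test is pluggable
   (`test = "student_raw"` gives a pooled-variance t on raw ratios) and
   the choice is recorded in the output's attributes. With replicate
   ratios that are exactly constant the t statistic is undefined; we
   return p = 1 when the groups are also equal (a clean null) and p = 0
   when they differ (the statistic diverges as variance vanishes).
5. **Classes**: `up` if $\mathrm{RC} \ge T$ and $p < \alpha$, `down`
   if $\mathrm{RC} \le 1/T$ and $p < \alpha$, otherwise `ndiff`;
   defaults $T = 2$, $\alpha = 0.05$. Because ratios are positive, a
   "fold change of −2" can only mean the reciprocal; we report a
   signed fold $-1/\mathrm{RC}$ for RC < 1 as a display convention.
   No multiple-testing correction is applied by default, matching the
   raw-p analysis convention for this assay; `adjust = "BH"` enables
   it.

`summarizeCalls` tallies events per type × class and reports percent
significant to one decimal; with zero detected events the percentage
is reported as `NA`, not 0.

# Sequence architecture of cassette exons

For each event with constitutive neighbours C1 (upstream) and C2
(downstream), `computeArchitecture` emits:

- **Splice-site windows** (`extractSpliceWindows`): donor = last 3
  exonic + first 6 intronic nt (9 nt); acceptor = last 20 intronic +
  first 3 exonic nt (23 nt). All windows are reported in sense-strand
  orientation; minus-strand genes are reverse-complemented. Four sites
  are scored per event: C1 donor, cassette acceptor, cassette donor,
  C2 acceptor.
- **Splice-site strength** (`trainPWM`/`scoreWindow`): the default
  scorer is a position weight matrix of per-position log2 odds against
  a uniform background (pseudocount 1), trained on the panel's own
  donor and acceptor window populations, and a window's score is the
  sum of its per-position log odds (bits). This is a deliberately
  simple, fully specified scorer; the scoring interface accepts any
  externally trained `PWMModel`, and because all group comparisons are
  *relative*, any monotone site-strength score slots in without
  changing the analysis structure.
- **Architecture**: exact exon/intron lengths from coordinates, GC of
  the exon body and of each (≤200-nt) flanking-intron window, and the
  median spliced transcript length of the host gene. GC is emitted for
  the exon body and both flanks separately because group differences
  may sit in either region.

`compareGroups` applies the tests conventionally used for each feature
family: two-sided t-tests (pairwise) plus an ordinary one-way ANOVA
(all classes) for splice-site scores, and the two-sided Mann–Whitney U
(normal approximation; lengths are heavily tied) for lengths, GC and
median transcript length. Direction is the sign of group1 − group2
central values (mean for t, median for Mann–Whitney), so swapping
labels flips the sign and leaves p unchanged.

## Flank motifs

`extractFlanks` returns the exon body and up to 200 nt of each
flanking intron, truncated (and flagged) at short introns so windows
never cross into a neighbouring exon. `kmerEnrichment` is an exact
k-mer enrichment: per k-mer presence/absence per sequence, one-sided
Fisher exact test (computed as the hypergeometric tail),
Benjamini–Hochberg correction across *all* tested k-mers (k = 4–8 by
default), output in the RNA alphabet. It is a transparent stand-in for
degenerate-motif discovery tools: it finds exact cores (and their
sub/super-strings) but does not merge them into IUPAC consensus
motifs, which is out of scope.

# AS-NMD classification

`TranscriptModel` objects hold strand-aware exon structures with an
annotated start codon. `skipExon` removes one internal exon (never a
terminal exon, never the start-codon exon); `scanORF` finds the first
in-frame stop at or after the start codon; `classifyNMD` applies the
premature-termination-codon rule:

> a stop codon is premature, and the transcript NMD-sensitive (NMD+),
> when it lies upstream of the final exon–exon junction by at least
> the rule threshold.

Conventions, fixed and documented because the rule is usually stated
qualitatively:

- threshold default **50 nt**, the conservative lower bound of the
  canonical 50–55-nt range; configurable.
- distance $d$ = number of nucleotides between the stop codon's **last**
  nucleotide and the final junction, in spliced coordinates; NMD+ iff
  the stop lies upstream of the final junction and $d \ge$ threshold.
- only the final junction is tested: under this convention any
  junction downstream of the stop implies the final one is too, so the
  single test is equivalent to "some junction ≥ threshold downstream".
- the ORF is re-scanned from the annotated start codon after skipping;
  translation re-initiation and uORFs are not modelled.
- a transcript with no in-frame stop is flagged `no-stop`, and a
  single-exon transcript is NMD− (no junction).

Raising the threshold can only shrink the NMD+ set (monotonicity),
which the tests check, and the whole classifier is validated exactly
against a brute-force translate-and-tabulate oracle on 1000 random
transcripts including boundary distances 49/50/51.

**PSI** (`psiFromTranscripts`) follows the spanning-transcript
definition: only transcripts with at least one exon entirely upstream
*and* one entirely downstream of the cassette exon enter the
denominator; PSI = 100 × (abundance of spanning transcripts containing
the exon) / (abundance of all spanning transcripts). Containment means
an exon with identical boundaries. Zero spanning abundance yields an
undefined (flagged) PSI, never 0. Abundance units are arbitrary
(TPM-like); PSI is a ratio. `nmdExpressionCorrelation` is a plain
Pearson correlation with a two-sided p, used to test the expected
anti-correlation between percent-NMD+ and total expression on
synthetic panels.

# The synthetic-data generator

The generator exists so that every stage has a realistic, fully
controlled input. It emulates:

- **Gene models**: five exons per gene (terminal, C1, cassette, C2,
  terminal), exon lengths log-normal (median 120 nt, sdlog 0.25, min
  30), intron lengths log-normal (median 300 nt, sdlog 0.4, min 60),
  background GC 0.5; donor sites follow the CAG|GTAAGT consensus with
  per-position match probability 0.7, acceptors a pyrimidine tract +
  CAG. A start codon sits in exon 1, the full-length reading frame is
  kept open by scrubbing in-frame stops, and one stop codon is planted
  early in the last exon — so full-length isoforms are NMD− and
  frame-shifting skips produce PTCs the way real cassette exons do.
- **Panel**: 5530 events by default, 90% labelled SE and the rest
  spread over the other event types, reflecting the skipped-exon
  dominance of such panels. Event geometry is always cassette-shaped;
  the non-SE type labels exist for tally realism only — modelling
  A5SS/A3SS/MEE/... geometries is out of scope.
- **Counts** (`simulateCounts`): negative binomial per probe per
  sample (dispersion 0.05 by default, Poisson at 0), skipping-probe
  mean = `meanDepth` (100), inclusion mean = `meanDepth` × ρ with ρ
  log-normal (unit mean, sdlog 0.3). Planted effects multiply (up) or
  divide (down) the condition-B inclusion mean by `effectFold`,
  holding the skipping mean fixed — the planted quantity is exactly
  the observed ratio change. Default planted design: 15% up and 7.5%
  down at fold 4 in biological triplicates.
- **Architecture shifts** (`plantSequenceFeatures`): given truth
  classes, loci are regenerated with the up group receiving a stronger
  cassette donor (+0.15 consensus-match probability), shorter cassette
  exons (−30 nt median) and lower cassette/flank GC (−0.04), and the
  down group shorter upstream introns (−90 nt median) and higher GC
  (+0.04). These shift magnitudes were chosen once as effect sizes a
  comparative study of a few hundred events per class can resolve;
  zeroing them makes the classes exchangeable.

Everything is deterministic given the config seed; per-stage seeds are
derived by fixed offsets. Where the emulated assay design leaves a
quantity open (per-probe depth, dispersion, replicate correlation),
the defaults above are declared choices, not inferences; replicates
are drawn independently.

What the generator does **not** model: probe cross-hybridisation, GC
amplification bias, read-level noise (no FASTQ), correlated
replicates, multiple transcripts per gene, or non-SE event geometries.
Passing recovery tests on this generator therefore demonstrates the
pipeline's correctness and power under idealised, internally
controlled counts — not robustness to the technical artefacts of a
real assay.

# Numerical and design notes

- Coordinates follow the Bioconductor convention (1-based inclusive
  `GRanges`/`IRanges`) throughout; conversions happen only at format
  boundaries (GTF in/out via rtracklayer stays 1-based, BED export is
  0-based half-open).
- `computeArchitecture` and `extractFlanks` run on plain vectors with
  a character-cached genome internally; the per-event loop avoids
  repeated `GRanges` subsetting, keeping 600-event panels around a
  second.
- Events whose cassette exon is terminal (no C1 or C2) are skipped
  with a warning rather than an error; windows at contig edges raise
  an explicit error naming the deficit.
- Fisher p-values in `kmerEnrichment` are computed with the
  hypergeometric tail (`phyper`), which is exactly the one-sided
  Fisher exact p; a test asserts equality with `fisher.test`.
- The `effectFold = 1` configuration is accepted and plants nothing
  (all-null truth), which is the natural null-calibration run.

# Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` use: 2000-event panels over
10 seeds for call recovery; 600-event genomes (200 per class) over 20
seeds for architecture-direction recovery; 1000 random transcripts for
the NMD oracle equivalence; 200 + 200 sequences of 200 nt over 20
seeds for motif recovery. These sizes give the comparisons enough
power to be reliable while keeping a full run to a few minutes on one
CPU.

# Known limitations

- The PWM scorer is not a maximum-entropy model; absolute scores are
  not comparable to MaxEntScan output, only the comparative structure
  is preserved. External score tables can be supplied instead.
- Exact k-mers only; no degenerate motif consensus.
- NMD is a binary rule classifier; decay efficiency and kinetics are
  not modelled.
- The differential test treats replicates as independent; assays with
  strong batch structure would need a paired or mixed-model variant.
```{r session}
sessionInfo()
```
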
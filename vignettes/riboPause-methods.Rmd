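---
title: "riboPause: models, parameters and design choices"
author: "riboPause authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboPause: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboPause)
```

# The problem

Budding yeast carrying an extra chromosome enter quiescence poorly: they
fail to silence their transcriptome as deeply as euploids, and during
quiescence their ribosomes accumulate stall sites with a characteristic
amino-acid signature (lysine/asparagine at the P-site, glutamate at the
A-site) reminiscent of age-induced stalling and ribosome-quality-control
overload. riboPause implements the computational half of that biology as a
reusable, tested toolkit:

* codon-resolution ribosome-occupancy profiling from footprint 5' ends,
* replicate-paired differential pause-site detection,
* positional and amino-acid-context characterization of pause sites,
* spike-in-anchored quantification of global transcriptome silencing, and
* scoring of pooled barcode fitness screens.

Because the analyses are statistical procedures, every one of them is
paired with a synthetic-data generator that plants a known truth
(pauses, motifs, silencing factors, fitness effects), so calibration and
parameter recovery are tested properties, not hopes.

# Ribosome-profiling model

## From read starts to codon profiles

Each footprint contributes its 5' end; the ribosomal P-site is taken at a
fixed offset of 12 nt into the read (`assignPSites()`, `offset = 12`),
regardless of read length, on the biological 5' side for minus-strand
genes. For each gene the P-sites are summed per codon over a window from
72 nt (24 codons) upstream of the ATG to 60 nt (20 codons) downstream of
the stop. Codon 1 is the ATG (all three of its nucleotides map to codon
1); upstream codons are numbered -24..-1 -- there is no codon 0, so a gene
of L codons has a profile of L + 44 entries. Genes without an annotated
ATG, with introns, with a CDS length not divisible by three, or with an
internal stop are flagged ineligible and excluded.

The *gene body* (interior window) is codons 21..L-20. Occupancy is the
pseudocounted, body-normalized count:

$$\mathrm{occ}_j = \frac{c_j + 1}{\sum_{k=21}^{L-20} (c_k + 1)}$$

so interior occupancy sums to exactly 1 for every gene and sample; flanks
share the interior denominator. "Appropriate pseudocounts" is interpreted
as one pseudocount per codon in both numerator and denominator, which makes
occupancy a proper probability vector over the body; this is an
interpretation, and the raw counts remain available.

Profiles with at least 50 reads in the gene body are retained
(`filterGenes()`, inclusive boundary). A gene enters a euploid-versus-
aneuploid comparison only if it passes the filter in *both* members of the
replicate pair: the Fisher test needs both margins.

## Differential pause sites

For every interior codon of every retained gene, a 2x2 Fisher exact test
compares reads at the codon versus the rest of the gene body between the
two conditions of one replicate pair:

$$\begin{pmatrix} c_{eu} & B_{eu} - c_{eu} \\ c_{an} & B_{an} - c_{an} \end{pmatrix}$$

The codon's own reads are excluded from the "rest of body" column so the
table is a valid contingency table. Two-sided p-values sum all
hypergeometric outcomes no more probable than the observed one (with the
same relative tie tolerance as `stats::fisher.test`, because
mathematically equal tail terms differ in the last floating-point ulp);
the kernel is compiled (src/) since a transcriptome-wide scan runs ~1e5
tables per replicate pair. Benjamini-Hochberg correction is applied once
across *all* tested codons of all genes within one replicate pair --
transcriptome-wide, not per gene. Peaks are codons with q < 0.05;
direction comes from the pseudocount-normalized occupancy (raw counts are
tested, occupancy only directs), and exactly tied occupancy has no
defensible direction, so such peaks are dropped and tallied.

Replicates are combined as a direction-aware union: a codon significant in
either replicate is kept; a codon significant in both with opposite
directions is excluded and logged. Site and distinct-transcript tallies
are reported per direction. Union (not intersection) is the default
because the per-replicate BH families already control the FDR and the
study design treats replicates as confirmatory, not conjunctive; the
intersection remains computable from the per-replicate tables.

## Trace correlations, positions and stall contexts

Occupancy traces are compared across conditions with the uncentered
Pearson correlation (cosine similarity), computed over the interior window
only, since flank occupancy is normalized by a denominator from a
different region. Pseudocounted profiles are the default; raw profiles
are one argument away.

Peak positions of the two directions are compared with a two-sided
Wilcoxon rank-sum test on codon indices (exact for small samples without
ties).

For the amino-acid context, each combined peak contributes the residues at
offsets -10..+10 from its P-site codon (offset 0 = the P-site residue,
+1 = the A-site), read from the annotation's translation, with the stop
codon a scorable 21st symbol. Offsets outside the protein are excluded
from that position's total rather than padded, so frequencies still sum to
one over contributing peaks. Aneuploid-higher and euploid-higher matrices
are compared cell by cell (21 symbols x 21 positions) with Fisher exact
tests, BH-corrected across all 441 cells jointly, and the log2 fold
difference in frequency is reported only for significant cells. When a
frequency is zero, the *reported* fold difference applies a
Haldane-Anscombe +0.5 to all four counts; the test never does.

# Transcriptome-silencing model

Spike-in normalization assumes a constant number of *Sz. pombe* cells per
sample. The reference profile is the geometric mean of spike counts
across samples (a spike gene with a zero anywhere drops out); each
sample's factor is the through-origin least-squares slope of its spike
counts on the reference, so after division every sample's spike slope is
exactly 1 and target genes live on a per-cell scale. "Slope set to 1"
does not name a reference in most write-ups; the geometric-mean profile
with through-origin regression is the minimal reading and is stated here
as such.

Differential abundance uses a two-group exact negative-binomial test with
a common dispersion, conditioned on the two-group total of counts rescaled
to a common library size (rounded after linear rescaling); the two-sided
p doubles the smaller tail, capped at 1. With dispersion 0 it reduces to
the exact conditional Poisson (binomial) test, which the test suite checks
against a direct binomial oracle. Dispersion defaults to a
method-of-moments estimate (median across genes of $(s^2 - \bar x)/\bar
x^2$, floored at 0). This is a deliberate re-implementation: calibration
(type-I error at or below nominal on null NB data) is the contract, not
numerical agreement with any particular DE package.

The repression-defect gene set contains genes significantly repressed in
the euploid (q < 0.05 and log2FC < 0 in any quiescent-versus-log
timepoint -- the timepoint is configurable because the defining rule does
not fix one) *and* significantly higher than euploid (q < 0.05, log2FC >
0) in every aneuploid in at least one timepoint. Deep repression counts
genes at or below -8 log2 (more than 256-fold down) on the spike-
normalized scale.

# Barcode-screen model

TMM factors are computed from trimmed, precision-weighted M-values against
the sample whose upper-quartile count rate is closest to the mean, with
the canonical 30% (M) and 5% (A) two-sided trims, geometrically centred.
The factors are on the absolute count scale -- a library sequenced twice
as deeply gets twice the factor -- so a factor doubles as an effective
library size; the test suite verifies the exact relation to the
rate-scale convention of edgeR.

Enrichment of a timepoint over the starting pool is the log2 fold change
of TMM-adjusted abundance with the NB exact test (pool as a one-sample
group versus the replicate cultures), BH-corrected over genes. Hits are
genes with significantly positive day-28 enrichment in the aneuploid whose
mean day-28 log2FC exceeds the euploid's by at least log2(2) = 1 (the
2-fold rule is applied on the log2 scale; "average sample" is the mean of
replicate log2FCs). Hits split into `day1_and_day28` (also significantly
positive at day 1, same alpha) and `day28_only`.

# The synthetic generators

`simConfig()` collects every knob; identical configurations (including
the seed) give bit-identical outputs, which the tests assert at the byte
level on written FASTA/GFF3.

**Transcriptome.** Each gene sits on its own contig with random flanks,
random strand, ATG start, no internal stop, stop end. A configurable
fraction of genes receives one pause at a uniformly drawn interior codon
(21..L-20 -- interior-only planting keeps the peak-test domain and the
normalization window identical, avoiding edge ambiguity); the residues
around a pause are rewritten to the motif (default K/N at the P-site, E at
the A-site), codons drawn uniformly among synonyms.

**Footprints.** Per-gene totals are negative binomial around
depth x relative expression (dispersion 0.1); placement within a gene is
multinomial with weight 1 per codon except the planted codon, which gets
weight = amplitude (default 10) only in aneuploid quiescent samples. All
reads are exact frame-0 28-mers with the P-site 12 nt in: the analyses
apply one fixed offset, so read-length structure would be dead weight.
The default relative expression is *equal across genes*: the baseline is
deliberately the simplest null under which Fisher calibration and planted-
effect recovery can be assessed, and the package's recovery guarantees are
stated under it. `exprSdLog > 0` switches on log-normal expression spread
for robustness exploration; deep heterogeneity lowers recovery at fixed
depth exactly as it would in an undersequenced real library, and no
guarantee is claimed there.

**Spike RNA-seq.** Spike genes are constant per cell; a configurable
silenced subset of targets is multiplied by the timepoint's retention
factor; depth varies uniformly +/-30% per sample; gamma noise adds
between-replicate overdispersion.

**Screen.** Barcode abundance follows a(t) = a(0) exp(f t) with t = 1 and
t = 28 for the two harvests (only rank/threshold behaviour matters, so the
time units are arbitrary). The growth-rate delta f may differ between the
outgrowth phase (t <= 1) and the quiescence-survival phase (t > 1); with
equal phases this is exactly the constant-rate exponential law. The
phase split exists because a *purely* constant f makes "beneficial only at
day 28" unrepresentable -- any f > 0 is weakly but truly enriched at day
1, and with triplicate libraries at depth 1e6 that residual enrichment is
detectable often enough to erode the class by design rather than by
error. The default scenario plants, in the aneuploid background only, 12
survival-only genes (f = 0.1/day after day 1; a 15-fold day-28 effect,
comfortably above the ~4x detectability bound at this depth), 8
constant-benefit genes (f = 0.3/day), and 5 genes with the same benefit in
*both* backgrounds that the 2-fold aneuploid-over-euploid rule must
reject. Counts are multinomial at exactly the configured depth, with
gamma replicate noise (dispersion 0.002, reflecting that replicate pools
are genetically identical cultures).

## What the generators do not emulate

No nucleotide-level ligation or nuclease bias, no UTRs or codon-usage-
driven elongation rates, no length-stratified P-site offsets, no
mapping ambiguity, no batch effects. Passing recovery tests therefore
demonstrates that the statistical machinery is correct and calibrated
under its own assumptions -- not that those assumptions capture every
failure mode of real libraries.

# Numerical choices and degenerate inputs

* Fisher ties: probabilities within a 1e-7 relative factor of the
  observed table's count as "as extreme", matching the convention of
  `stats::fisher.test`; the brute-force oracle uses the same rule.
* A zero gene-body margin yields `NA` (such genes cannot pass the read
  filter); all-zero profiles normalize to exactly 1/n via pseudocounts.
* Direction ties at significant codons are dropped, not guessed.
* The NB exact test rounds rescaled counts to integers; totals of zero
  give p = 1.
* `alpha` must lie strictly inside (0, 1): a threshold of exactly 1 would
  declare q = 1 codons "peaks", which we treat as a configuration error
  rather than a sanity mode.
* TMM falls back to factor 1 if trimming empties the M-value set.
* Empty retained gene sets, empty peak sets in the position test, missing
  contrasts in the repression rule and missing timepoints in the screen
  are errors that name the missing piece.

# Problem sizes

The recovery and calibration properties quoted throughout (and recomputed
by `scripts/acceptance.R`) use desk-scale study conditions chosen to
mirror the per-gene coverage of real libraries while staying fast: 200
genes of 90-180 codons at 1e5 footprints per sample (~500 reads per gene
body, the regime of a well-sequenced yeast ribosome-profiling library);
2000 target genes plus 12 spikes at 1e6-8e6 RNA-seq reads (~500-4000 reads
per gene); 1000 barcodes at 1e6 reads in triplicate. The calibration
sweep runs 50-100 independent null simulations.

# Known limitations

* The NB exact test's linear rescaling to a common library size slightly
  misstates the precision of strongly rescaled samples; at the depths and
  factors exercised here the test stays conservative-to-nominal, but
  extremely unbalanced designs deserve a dedicated GLM.
* Uncentered correlations of low-coverage profiles are dominated by
  pseudocounts and drift toward the uniform-trace cosine rather than 1.
* The union rule for replicate combination reports a site significant in
  one replicate only; intersection semantics, when wanted, must be applied
  to the per-replicate tables by the caller.
* Peaks are searched only in the interior window; flanking codons are
  profiled and reported descriptively but never tested.
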
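---
title: "Methods: models, parameters and design choices in lncmyc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in lncmyc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncmyc)
library(dplyr)
```

`lncmyc` analyses how a globally acting transcription factor — MYC in the
motivating system, a tet-off B-cell line switching between high and low MYC
states — reshapes the long non-coding transcriptome. This vignette explains
the statistical models behind each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the design decisions taken where more than one reasonable choice existed.

## Coordinates and input formats

All intervals inside the package are 0-based half-open `[start, end)`. GTF
input (1-based inclusive) is converted on read and back-converted on write;
BED-family formats (BED6, narrowPeak, bedGraph) already use the internal
convention and pass through. A single convention removes the classic
off-by-one error class; the conversion is tested to be its own inverse on
random intervals. The transcription start site is strand-aware: the leftmost
base for `+` genes and the rightmost base for `-` genes. Gencode biotypes
collapse to a binary `coding` / `lncRNA` set through a user-replaceable
table (`default_biotype_map()`), since the analysis only distinguishes
protein-coding from long non-coding transcripts. Genes on unplaced contigs
are kept; filtering is the caller's decision.

## Normalization and the centered expression matrix

Counts per million are `count * 1e6 / library size` per sample;
`log2(CPM + pseudocount)` uses a pseudocount of 0.5 by default (the value is
not dictated by the method; it is fixed and configurable). The heatmap
display transform subtracts, per gene, the mean log2 CPM over the `N`
samples:

$$\mathrm{log2FC}_{i,g} = \mathrm{log2CPM}_{i,g} -
  \frac{1}{N}\sum_{i'=1}^{N}\mathrm{log2CPM}_{i',g}$$

so each row sums to zero exactly; transcripts are ordered by differential
log2 fold change, most upregulated first.

Genes with fewer than `min_count = 5` reads in their lowest sample are
removed before expression analysis; "expressed in a condition" means at
least 5 reads in every replicate of that condition.

## Differential expression

The caller is a self-contained negative-binomial exact test. A single
common dispersion $\phi$ is estimated by method of moments, pooling across
genes and conditions: on size-factor-normalized counts,
$\hat\phi = \max\!\left(0, \sum_g (v_g - m_g) \big/ \sum_g m_g^2\right)$,
the ratio-of-sums form of the NB relation $v = m + \phi m^2$. On Poisson
data the estimate collapses to zero (tested). The per-gene test conditions
on the total $t$ of the two condition group sums; under the null the split
follows the conditional law of $S_A \sim \mathrm{NB}(t\,N_1/(N_1{+}N_2),
n_1/\phi)$ given $S_A + S_B = t$ (binomial in the Poisson limit), and the
two-sided p-value sums all splits no more probable than the observed one.
Only library-size *ratios* enter, so rescaling all library sizes by a
common factor changes nothing (tested); swapping condition labels negates
every log2 fold change exactly.

Fold changes are ratios of condition-mean CPM with the pseudocount; calls
use the raw-p filter "more than 2-fold and $p < 10^{-3}$", with
Benjamini-Hochberg FDR reported alongside for context but never
thresholded. This preserves the count nature and the threshold semantics of
the published analysis while staying self-contained; the empirical-Bayes
dispersion shrinkage of edgeR is deliberately out of scope, and a
externally produced DE table can be substituted wherever an `lnc_de` tibble
is accepted (it is an ordinary tibble with documented columns). Whether the
original 2-fold rule was applied to a fitted or a mean-CPM ratio is not
stated in the source material; this package uses mean-CPM ratios.

Validation candidates for wet-lab follow-up apply three machine-checkable
filters: significantly upregulated more than 8-fold, more than 5 reads in
every sample (strict inequality), and a peak summit within ±0.5 kb of the
TSS. A fourth published criterion — manual annotation-quality curation — is
not machine-checkable and is out of scope.

## TSS occupancy and bidirectional promoters

Occupancy uses peak *summits* (the sharpest location estimate): for each
gene the nearest summit on its chromosome, distance signed so that
downstream of transcription is positive, bound when $|d| \le$ the window
(inclusive), 1 kb by default. Ties break toward the smaller summit
coordinate so results are deterministic. Both the assignment and the
divergent-pair detector are verified against brute-force all-pairs oracles
on hundreds of random instances.

A bidirectional (divergent) promoter is a minus-strand / plus-strand gene
pair transcribing away from each other with TSS separation at most 1 kb
(the conventional divergent-promoter scale, matching the 1 kb binding
window; the source material never defines the gap) and neither TSS inside
the partner's gene body. Each gene joins at most one pair — greedy
smallest-gap matching, leftmost on ties — so dense loci are not double
counted. A promoter is MYC-bound when either TSS is bound (one shared
regulatory region serves both genes). Categories follow the
0/1/2-transcripts taxonomy: `no_transcription`,
`unidirectional_{regulated,unregulated}`, and for two expressed genes
`concordant` (both significant, same direction), `discordant` (directions
differ, or exactly one significant), or `unregulated`. The six counts
partition the pair total exactly, which is asserted on every run. Because
"discordant" can also be read as expression asymmetry rather than
DE-direction disagreement, an asymmetry score
$|\mathrm{log2FC}_a - \mathrm{log2FC}_b|$ is reported next to the
category; the categorical definition is primary.

Coverage profiles average bedGraph signal in 50 bp bins across ±2 kb of
the TSS, reversing minus-strand rows so transcription always points
rightward; rows are sorted by expression so the profile heatmap reads like
an occupancy-versus-expression ranking.

## Polyadenylation discrimination

For each condition, every detected gene contributes a 2-D feature: mean
log2 CPM in ribo-depleted samples and in poly-A-selected samples.
Detection (the `min_count = 5` filter) is assessed on the ribo-depleted
samples only — that library sees transcripts regardless of poly-A status,
whereas filtering on poly-A counts would silently discard the
non-polyadenylated genes the classifier is meant to find.

The classifier is a two-class Fisher linear discriminant with pooled
within-class covariance, $w = S^{-1}(\mu_{polyA} - \mu_{non})$, decision
offset at the midpoint of the projected class means shifted by the log
prior ratio (equal priors by default; configurable because the real class
balance is extreme). It is trained on labelled *coding* transcripts and
applied to everything, following the published procedure; per-condition
calls are merged conservatively — a gene is non-polyadenylated only if
called so in every condition tested (how the original analysis merged
conditions is unstated). The implementation is cross-checked against
`MASS::lda` and against the closed-form Bayes accuracy on Gaussian
classes. Ordinary least squares (`fit_linear`) summarizes ribo-vs-poly-A
agreement with $R^2$ and a slope t-test, mirroring the published fit
diagnostics.

## Kinetics and qPCR

Transcript half-life after transcription shutoff uses the closed form
$t_{1/2} = t \ln 2 / (\ln N_0 - \ln N)$ per time point, summarized as the
arithmetic mean over the valid points of the standard 30/60/120/240-minute
harvest grid. $N_0$ is the abundance at $t = 0$ (configurable to the
earliest time point when no baseline exists). Points with $N \ge N_0$ —
apparent increases, common for slowly decaying transcripts under noise —
would yield negative or infinite half-lives; they are excluded from the
mean and the exclusion count is reported. A log-linear regression
estimator ($-1/\mathrm{slope}$ of $\log_2 N$ on $t$) is reported alongside
as an alternative; the per-point mean is primary because it is the stated
published method. Note the per-point estimator is right-skewed for slow
transcripts (at $t = 30$ a 215-minute transcript has decayed less than one
noise standard deviation), so robust summaries (medians) are preferred
when aggregating errors across genes.

Relative qPCR expression is $2^{-\Delta\Delta Cq}$ with amplification
efficiency fixed at 2 (a configurable hook exists but is off by default).
With efficiency 2, normalizing to the geometric mean of reference-gene
*quantities* equals subtracting the arithmetic mean of reference *Cq*
values, which is how multiple references (e.g. two amplification-robust
housekeeping transcripts) are aggregated. Nuclear run-on data use the same
arithmetic with an exogenous spike-in as sole reference; because the spike
is constant per reaction, this normalization *preserves* global
transcriptional-amplification differences that cellular references cancel
— the package demonstrates this on simulation, where spike-normalized
folds exceed cellular-reference folds by exactly the amplification factor.

## The synthetic-data generator

The generator plants ground truth for every downstream stage: a
single-chromosome annotation (~2,500 genes by default: 1,100 coding,
1,400 lncRNA, matching the scale of the published poly-A analysis) with
divergent lncRNA pairs at 50-900 bp TSS gaps; negative-binomial counts in
triplicate per condition and library prep (common dispersion 0.05,
log-normal baseline means, median ≈ 200); peaks whose summits are normal
around bound TSS (sd 150 bp, truncated at ±500 bp) plus decoys ≥ 5 kb from
any TSS; an 18% non-polyadenylated lncRNA fraction with a 2% residual
poly-A-library signal (so the discrimination problem is realistic, not
separable); and exponential decay series with 10% log-normal noise over
half-lives of 25-215 minutes, the published measurement range.

Two generator choices deserve emphasis:

* **Amplification.** The high-MYC state multiplies every gene's expected
  molecule count by `amplification_factor` (default 2 — the global
  RNA-per-cell increase is reported qualitatively in the source material,
  so 2 is a free parameter, not a measured value). Because CPM normalizes
  within sample, this amplification is invisible to CPM ratios — the
  package asserts this on simulation — while spike-in-style
  (`per_cell_normalized`) counts and NRO normalization expose it.
* **Regulated mass fraction.** 15% of genes are regulated by default
  (|log2 effect| 1.2-3, 55% up). The published 42% figure counts regulated
  transcripts among *detected lncRNAs* inside a full transcriptome where
  regulated transcripts are a small share of RNA mass; planting
  42% of all simulated genes with multi-fold effects would let the planted
  mass dominate library size and make within-sample normalization
  meaningless. At 15% the composition shift is ≈ 0.3 log2, small enough
  that unregulated genes stay inside the 2-fold calling threshold.

What the generator does *not* emulate: read-level structure (FASTQ,
splicing, sequence content), gene-wise dispersion trends, batch effects,
mappability artifacts, and annotation errors. Tests passing on synthetic
data therefore demonstrate algorithmic correctness and statistical
calibration under the stated model, not robustness to every pathology of
real sequencing data.

## Numerical choices and degenerate inputs

* Exact-test support is enumerated fully up to totals of 20,000 and
  truncated to a $10^{-14}$-quantile central range above that; two-sided
  p-values include a $1 + 10^{-10}$ slack on the observed probability so
  ties are counted despite floating-point noise.
* Size factors for dispersion estimation are column totals over their
  mean; supplied library sizes are rescaled to the count total so that only
  ratios matter.
* `train_lda` aborts on a numerically singular pooled covariance
  (`rcond < 1e-12`) and warns when class means coincide (zero separating
  direction).
* Peaks with summit offsets outside their interval are clamped with a
  warning; genes on peak-free chromosomes are unbound with `NA` distance;
  zero-total samples, negative/non-integer counts, and samples missing
  from metadata abort with the offending name.
* All generator randomness derives from one integer seed; outputs are
  byte-identical across runs with the same configuration (asserted in the
  test suite and required of the pipeline as a whole).

## Problem sizes

The default simulated study is ~2,500 genes with 6 ribo-depleted plus 6
poly-A libraries; the pipeline completes in well under a minute on one
CPU. Operating-characteristic checks use 1,000-2,000 gene simulations, the
oracle-equivalence checks use 100 random instances of up to 500
genes/peaks per operation, and the half-life noise study uses 500
replicate series — sizes chosen so the whole suite exercises every stage
at statistically meaningful scale while remaining quick to run.

## Known limitations

* The DE stand-in shares the exact-test idea with edgeR but not its
  empirical-Bayes dispersion shrinkage; with very few replicates and
  gene-wise dispersion variation, its p-values will be anti-conservative
  for high-dispersion genes.
* CPM-ratio fold changes inherit composition bias: a strongly asymmetric
  regulated mass shifts all ratios. This is a property of within-sample
  normalization, not of the implementation; TMM-style correction is
  deliberately out of scope.
* The half-life per-point mean is biased upward for slowly decaying
  transcripts under multiplicative noise; the regression estimator is
  reported alongside for such cases.
* Real-data mode (SRA-scale alignment, peak calling) is out of scope; the
  package starts from count matrices, peak files, and coverage tracks.
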
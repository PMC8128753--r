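---
title: "Methods: entropy-based splicing detection on two-condition exon arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-based splicing detection on two-condition exon arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonarh)
```

# Scope and data model

`exonarh` analyzes probe-level intensities from exon-tiling microarrays
comparing exactly two conditions (in the motivating design, islets from a
diabetes-prone and a diabetes-resistant mouse strain, five replicate
arrays each). Three tables define the data model:

* a probe × sample intensity matrix, log2 scale after ingestion;
* a probe annotation mapping each probe to its exon and gene, with the
  exon's genomic position, the probe's integer G+C count, and a flag for
  *background control probes* — probes with no genomic target whose
  signal estimates nonspecific hybridization;
* a sample → condition map with exactly two labels.

Coordinates are 1-based inclusive (the Ensembl convention); BED-style
inputs are converted on read. Strand is ignored throughout: exon order is
genomic position only, which is what exon-profile plots display. GC is
kept as a discrete integer class rather than a fraction because
background matching ("same GC content") must be exact, not binned on a
continuum.

# Normalization and summarization

Processing order is within-array correction, then between-array
normalization, then summarization:

1. **GC baseline correction.** Per array, every probe's log2 value is
   reduced by the median log2 value of the background probes in the same
   GC class. Classes with fewer than `min_bin = 30` background probes
   fall back to the array's global background median — a guard against
   noisy medians from sparsely populated classes. This is a deliberate
   simplification of full probe-sequence background models (which fit
   position-specific base effects along the 25-mer): it retains the
   dominant GC effect while requiring only a GC class per probe, not the
   sequence. Background probes are corrected identically so that
   downstream thresholds remain GC-matched. The correction absorbs any
   per-array, per-GC-class additive offset exactly (a tested invariant).
2. **Quantile normalization** across arrays, delegated to
   `limma::normalizeQuantiles(ties = TRUE)`: each column's values are
   replaced by the cross-column mean of the order statistics at their
   rank, ties receiving the mean of the reference values at the tied
   ranks. After this step the sorted columns are identical to numerical
   precision.
3. **Summarization** to exon and gene level is the median of the unit's
   probe values per sample — at gene level, all probes of all the gene's
   exons, so the gene summary equals the median over the pooled exon
   probe sets (a tested identity). The median is used instead of a mean
   for robustness to single misbehaving probes.

# Presence calls

Expression over background is judged per condition. For each GC class,
the detection threshold is the 75th percentile of that class's background
probe values pooled over the condition's arrays; a gene is *present* when
strictly more than 50% of its exon probe values (again pooled over the
condition's arrays) are strictly above the threshold of their probe's
class.

Numerical conventions, fixed for reproducibility:

* Percentiles use linear interpolation between the closest order
  statistics (`h = (n − 1) q`, R's default type 7); the worked reference
  case is background values {0, 1, 2, 3} giving a threshold of 2.25.
* "Above" and "more than 50%" are strict inequalities, so a gene with
  exactly half its probe values above threshold is absent.
* Replicates enter by pooling values within a condition before
  thresholding, rather than thresholding per array and voting. Pooling
  makes the call symmetric in the replicates and robust to a single
  outlier array; it is one of two defensible readings of a
  presence-in-a-condition rule, and the package fixes this one.
* GC classes containing gene probes but too few background probes reuse
  the global background threshold (same fallback as the correction step).

# Differential expression

A gene is differentially expressed when all three criteria hold:

1. present in at least one of the two conditions;
2. expression ratio ≥ 1.33 or ≤ 0.75 between conditions (inclusive);
3. exact two-sided Wilcoxon rank-sum p ≤ 0.05 (inclusive) between the
   per-replicate gene expression values.

The ratio is `2^(m_num − m_den)` with `m` the arithmetic mean of the
per-replicate log2 gene summaries (the geometric mean on the linear
scale). The mean-vs-median choice for the condition summary is genuinely
open in this design; the mean is the default because it matches how log2
ratios are conventionally reported, and `center = "median"` is exposed
for sensitivity analyses. The ratio orientation (which condition is the
numerator) is explicit in `select_de()` and defaults to the second
condition label over the first.

With five replicates per group, large-sample rank-test approximations are
poor and ties after median summarization are possible. `wilcoxon_exact()`
therefore enumerates all `choose(10, 5) = 252` assignments of the pooled
midranks and reports the fraction of assignments whose rank sum deviates
from its expectation `n(N+1)/2` by at least the observed deviation. Two
consequences worth knowing:

* the smallest attainable two-sided p at 5 vs 5 is 2/252 ≈ 0.0079, so no
  single gene can appear significant below that resolution;
* the attained test level at the nominal 0.05 cutoff is 10/252 ≈ 0.0397,
  which is why the DE false-positive rate on null data sits below 0.05.

No multiple-testing correction gates the DE flag — matching the
three-criteria selection rule this pipeline reproduces — but a
Benjamini–Hochberg adjusted column (`p_bh`) is emitted for modern
reporting.

# Alternative splicing: the ARH model

Let *r<sub>i</sub>* be the exon-level log2 condition ratio (mean log2
exon expression in the numerator condition minus the denominator), and

$$s_i = r_i - \mathrm{median}_j(r_j), \qquad
p_i = \frac{2^{|s_i|}}{\sum_j 2^{|s_j|}}, \qquad
\mathrm{ARH} = \log_2 n + \sum_i p_i \log_2 p_i .$$

ARH is the Kullback–Leibler divergence of the splicing probability
distribution *p* from uniform — equivalently `log2(n) − H(p)` with *H*
the Shannon entropy. Design choices embedded here:

* **Median centering** makes the statistic invariant to the gene-level
  fold change: a uniformly DE gene has constant *r* and ARH = 0, so DE
  and AS are orthogonal signals.
* **Absolute deviations** `|s_i|` weight over- and under-inclusion
  equally: an exon skipped in either condition should rank the same.
* **Orientation invariance** follows: negating every *r* (swapping
  conditions) changes no |s| and therefore no score.
* **Degenerate sizes**: with one exon, s = 0 and ARH = 0. With two exons
  median centering forces |s₁| = |s₂|, hence p = (½, ½) and ARH = 0
  structurally — two-exon genes carry no information under this model
  and are exempt from testing (`min_exons = 3`, their p is reported
  as 1).

The score is bounded: 0 ≤ ARH < log2(*n*), approaching the upper bound
only as a single exon takes all probability mass. The implementation is
cross-checked in the tests against an independently coded KL divergence
to 1e-12 on 1000 random profiles.

## Resampling p-values

The null distribution of ARH is built from the data: the centered
deviations of *all* genes are pooled, and for each exon-count stratum
*n*, `B = 10000` null genes are drawn (with replacement) from the pool
and pushed through the same chain — median re-centering, exponential
weighting, entropy. The re-centering step matters: observed profiles
always have median deviation zero, and omitting it from the null chain
would make null draws location-shifted relative to observed statistics.
Each gene's p-value is `(1 + #{null ARH ≥ observed}) / (B + 1)`; the
add-one correction keeps p strictly positive, and the stratification
accounts for the strong dependence of the ARH null on the number of
exons. The resample count B trades Monte-Carlo resolution (minimum
attainable p = 1/(B+1)) against time; B = 10000 resolves the 0.05
threshold to ±0.002 within a few seconds for 14 strata.

Under a 2000-gene null simulation the fraction of genes at p ≤ 0.05 is
calibrated within the binomial 3σ band of the nominal level (an
acceptance-tested property). One known bias is deliberate: the deviation
pool includes whatever true splicing signal the data contain, so heavy
spiking (≳10% of genes with strong events) inflates the null and makes
the p-values conservative — visible in the README example, where the
score ranks spiked genes perfectly (AUROC 1.0) but the threshold recalls
only half of them. At realistic prevalence (a few percent of genes) the
effect is small. A trimmed or outlier-robust pool would reduce it at the
cost of a data-dependent tuning constant; the package keeps the plain
pool.

## Exon attribution

Within significant genes, the exons driving the call are those carrying
at least `c` times the uniform probability mass, `p_i ≥ c/n`, with
`c = 2` by default. At c = 2 a uniform profile can never flag an exon
(2/n > 1/n); c = 1 flags everything at or above average mass. The rule is
monotone in the splicing probability and needs no second resampling
layer; c is exposed because the attribution sharpness is a reporting
choice, not a statistical one.

# The simulator

`simulate_experiment()` generates the probe-level world the pipeline
expects, with known truth. Per probe and sample the log2 value is

> gene baseline + DE shift (numerator condition) + cassette shift
> (affected exons, numerator condition) + probe affinity +
> GC slope × (gc − mean gc) + replicate noise,

with background probes drawn per GC class around the background level
with the same GC trend. Defaults mirror the motivating experiment's
structure and magnitudes a practitioner would call typical for this array
class: 2 × 5 replicate arrays; 3–16 exons per gene (uniform); 1–4 probes
per exon; baselines N(7, 1.5²); affinities N(0, 0.3²); replicate noise
σ = 0.25; GC classes 8–17 with slope 0.05/base and 30 background probes
per class; background N(3, 0.5²); 10% absent genes; 10% DE genes at
|log2 FC| = 1; 5% splicing genes with a single-exon shift of ±2 log2
units. Splicing events are cassette-exon style — one exon shifted in one
condition — the simplest event class consistent with single-exon
deviation profiles; multi-exon events are available via `as_n_exons`.
One global random stream per run, so a seed fixes the dataset to the
byte.

What the simulator deliberately does **not** emulate: probe
cross-hybridization, spatial array artifacts, correlated probe noise
within exons, heavy-tailed intensity distributions, and tissue
contamination mixtures. Passing spike-in tests therefore demonstrates
that the statistics recover the signals they model under clean additive
noise — not that they are robust to every artifact of physical arrays.

# Determinism and numerical conventions

* Every stochastic step takes an explicit seed; `run_all()` derives
  stage seeds from the config seed, and reruns are byte-identical
  (tested against frozen toy outputs).
* TSV output writes doubles with 17 significant digits, so write → read
  is the identity and write → read → write is byte-stable; result tables
  have a deterministic sort (p-value, then gene id, then genomic exon
  order).
* QTL windows are symmetric `marker ± window` intervals with inclusive
  endpoints, since published QTL tables often give only the peak marker;
  the per-QTL window (Mb-scale in the input table, ±10 Mb being a
  sensible default for mouse crosses) is an
  explicit, tunable stand-in for unpublished confidence intervals, so
  QTL membership is a localization aid rather than a reproduction
  target. Interval intersection is delegated to GenomicRanges.
* Exact-test enumeration is capped at `choose(N, n) ≤ 3e6` assignments;
  beyond that the test refuses rather than silently approximating.

# Validation problem sizes

The shipped test suite validates: oracle equivalence on 1000 random
profiles; exact Wilcoxon p-values against an independent bit-mask
enumeration including tie cases; null calibration on 2000 genes with
B = 10000 resamples; spike-in recovery (δ = 2.0, σ = 0.25, genes with
≥ 4 exons, five seeds, 300 genes each; ARH AUROC ≥ 0.90 and DE
sensitivity ≥ 0.90 at |log2 FC| = 1); and byte-level determinism of a
30-gene end-to-end toy run. These sizes were chosen so the full suite
completes in well under a minute while keeping the binomial Monte-Carlo
bands tight enough to detect real miscalibration.

# Known limitations

* The resampling null pools deviations across genes with different probe
  counts and noise levels; per-gene calibration is approximate even
  though the aggregate level is correct.
* ARH p-values from this resampling scheme are not comparable to
  analytically derived ARH p-values from other implementations; rankings
  agree, absolute values need not.
* Presence calling assumes background probes cover the GC classes of the
  gene probes reasonably well; exotic GC classes fall back to a global
  threshold.
* The DE test's discreteness at n = 5 means the effective level is
  0.0397, not 0.05; with fewer than four replicates per group the test
  has essentially no power at conventional levels.
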
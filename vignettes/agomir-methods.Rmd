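---
title: "Models and methods behind agomir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind agomir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models, the tunable parameters and the numerical
choices of the package, and what the synthetic-data tests do and do not show
about real data.

## Quantitative two-color arrays and absolute abundance

A quantitative miRNA array hybridizes the labeled sample against a
*universal reference* — a pool of 493 synthetic miRNA oligonucleotides at
1 fmol each — in the second color channel. Because each miRNA spot carries a
known molar amount in the reference channel, the per-spot ratio of
background-corrected, calibration-corrected intensities converts directly
into an absolute amount, and no global (quantile, loess) normalization is
needed or appropriate: the sample's dynamic range differs legitimately from
the reference's, and cross-sample comparability comes entirely from the
shared reference.

The processing chain is:

1. **Background correction**: `corrected = max(foreground − background, 0)`
   per spot and channel. The floor at zero is a deliberate convention for
   spots darker than their surroundings; such spots always fail the filter.
2. **Detection filter**: a channel passes iff the corrected intensity is
   *strictly* over 100 light units and *strictly* more than 50% of feature
   pixels lie two background standard deviations above background. The
   strictness follows the wording of the filter rule ("over"); a spot at
   exactly 100 LU is rejected, and the boundary tests pin this down. A spot
   is analyzable only when both channels pass.
3. **Calibration**: per channel, the scale factor is the **median** over
   passing spiked-in calibration spots of expected/observed intensity.
   The median (rather than the mean) makes a single aberrant calibration
   spot harmless; the estimator is otherwise unspecified in the protocol
   and this is a package design choice.
4. **Reference normalization**: ratio = calibrated sample / calibrated
   reference, spot-wise; multiple spots per probe (when present) are
   summarized by their median ratio.
5. **Absolute units**: `amount = ratio × ref_fmol / input_µg`, with the
   defaults 1 fmol and 3 µg. The package reports **fmol/µg**. Reported
   median expression strengths of tens of "pmol/µg" in the literature on
   this platform are, with a 1 fmol reference and 3 µg of input, physically
   consistent with fmol/µg; the package does not silently rescale and
   documents the unit it computes.

**Parameters** (`quant_config()`): `min_intensity` (100 LU),
`min_frac_px` (0.5), `ref_amount_fmol` (1), `input_mass_ug` (3). Raising
`min_intensity` can only shrink the analyzable set (a tested invariant).

## Differential expression between cytogenetic subtypes

Group comparisons (e.g. t(8;21) vs t(15;17), MLL-rearranged vs all other)
use the Mann–Whitney U test — exact by enumeration when the pooled sample
is at most 12 and tie-free, otherwise the normal approximation with tie and
continuity correction. The exact-size limit of 12 balances runtime against
fidelity and is configurable. Fold changes are ratios of **group medians**:
medians are robust on ratio-scale data and consistent with the rank-based
test; a mean-ratio estimator is available (`estimator = "mean"`).

Not-detected values are floor-imputed at half the smallest detected value
of the same sample before fold changes and log transforms
(`impute_floor()`); the floor choice only matters for features near the
detection limit and is a documented convention, not an inference.

The report keeps a miRNA when some comparison shows at least a 1.8-fold
change (arrow up/down), and stars raw p-values (\*, \*\*, \*\*\* at
0.05/0.01/0.001). No multiple-testing correction is applied by default,
matching the raw-p star convention of the tables this reproduces; a
Benjamini–Hochberg column is available (`adjust = TRUE`).

## Nearest shrunken centroids

The classifier follows the standard nearest-shrunken-centroid formulation:
standardized centroid differences
$d_{ik} = (\bar x_{ik} - \bar x_i)\,/\,(m_k (s_i + s_0))$ with
$m_k = \sqrt{1/n_k - 1/n}$, pooled within-class SD $s_i$, fudge constant
$s_0 = \mathrm{median}_i(s_i)$, soft-thresholded by $\Delta$; discriminant
$\delta_k(x) = \sum_i (x_i - \bar x'_{ik})^2/(s_i+s_0)^2 - 2\log\pi_k$ with
empirical priors. Ties in prediction break toward the lexicographically
smallest class label, making predictions deterministic.

Cross-validation is stratified (the cohort's class sizes are very unequal;
unstratified folds would regularly lose a class from training), repeated
over seeded shuffles, with $\Delta$ chosen on a 30-point grid from 0 to
$\max|d_{ik}|$; ties in CV error break toward the larger $\Delta$, i.e.
the sparser signature. Per-class sensitivity and specificity come from the
pooled held-out confusion matrix; a class never predicted positive has no
meaningful specificity and is reported not-applicable.

The default of **50 repetitions** of 10-fold cross-validation is the
package's desk-scale choice; the full-scale analysis this mirrors used
1000 repetitions, and `iterations = 1000` reproduces that setting when
runtime permits. Planted-signature experiments (9 discriminative miRNAs at
2-fold, 20 samples per class) show accuracy and feature recovery are
already stable at 50 repetitions.

## Clustering

Unsupervised structure uses Euclidean distance on log2 ratios with
complete linkage, which guarantees monotone merge heights. The
agglomeration is delegated to `stats::hclust`, whose deterministic internal
ordering resolves distance ties; leaf ordering is the standard recursive
one and makes no claim of matching any particular heatmap's cosmetic
ordering. Dendrograms export to Newick with branch heights.

## mRNA summarization

Probe-level mRNA intensities are quantile-normalized (ties receive the
mean of their quantile values) and summarized per probeset by median
polish on the log2 scale, reporting overall + array effects. The
convergence tolerance is tight (relative 1e-10, up to 1000 sweeps) so the
reported effects are stable to well below 1e-6 — median polish converges
slowly on small matrices, and a loose iteration cap would leave visible
drift. The exact convolution background model of full RMA is deliberately
not implemented: downstream analysis consumes only normalized summarized
values, and background handling happens upstream by subtraction.

## Argonaute association calling

Each Argonaute pull-down is compared to the isotype control — an antibody
of the same class with irrelevant specificity, which measures non-specific
capture — by **replicate-matched** fold changes `ip_r / control_r`: the
replicates were processed as parallel biological batches, so matching
cancels batch-level level shifts. A mean-control mode is available. A
feature is called associated iff **every** replicate fold change is at
least 1.8 (inclusive) and the Welch p (unequal-variance t on log2 levels;
log2 stabilizes ratio-scale variance) is strictly below 0.05. Degenerate
zero-variance inputs use explicit conventions (p = 1 for equal means,
p = 0 flagged otherwise). The beads-only control is carried through
reporting but takes no part in the filter.

This all-replicates rule is deliberately conservative: with 20%
multiplicative level noise, each replicate fold change carries ≈28% noise
(two noisy levels per ratio), so a feature planted at 3-fold passes all
three replicates only ≈90% of the time — sensitivity saturates near
$P(\mathrm{FC}_r \ge 1.8)^3$ — while null features are called at
essentially rate zero. Users who need higher sensitivity at fixed
specificity should increase replicates rather than lower the threshold.

## Targets, sequence groups, pathways, network

Prediction sources are consumed as tables of (miRNA, gene) evidence; an
edge survives when at least 2 of 3 sources agree. Binding-site coordinates
are not modeled — the sources act as binary evidence, which is how the
intersection rule uses them.

miRNAs are pooled into **sequence groups** by identity of nucleotides 2–8,
the seed that dominates target recognition; the group is named
`seqgrp-<representative>` after its lexicographically smallest member. The
seed rule is a concrete, testable proxy for "high sequence similarity";
an alternative full-length edit-distance rule (threshold configurable,
single linkage) is provided for sensitivity analyses.

Pathway over-representation among Ago-associated genes uses the one-sided
hypergeometric tail (over-representation only; depletion is not reported)
computed through the log-space-stable distribution functions, against a
universe defaulting to 42,500 genes but configurable to the actually
probed universe. For cross-Argonaute overlap summaries a pathway counts as
"detected" per Argonaute when at least one associated gene maps to it (the
phrasing "could be identified"); a significance-threshold mode is provided
for enrichment-table-style counting.

The regulatory network is the bipartite graph of sequence groups and
mRNAs, with an edge only when a member miRNA and the mRNA are both
Ago-associated and a retained prediction links them; exports are GraphML
(attributed), SIF and a TSV edge list. Node and edge order is
deterministic.

## The synthetic-data generator

`sim_config()` + `simulate_*()` emulate the full data structure: per-sample
spot tables with a 493-miRNA reference channel at 1 fmol, calibration /
position-control / negative-control spots, subtype groups with planted
fold changes, triplicate IP experiments with planted enrichments, three
partially overlapping prediction sources, and pathway collections over a
large gene universe.

The noise model is multiplicative log-normal on true signal (mean 1,
coefficient of variation `noise_cv`, default 0.2) plus additive Gaussian
background per channel (mean 40 LU, SD 8 LU) and a per-array per-channel
gain factor that the calibration spots remove again — the behavior of a
two-color scanner, since no noise model is prescribed by the protocol
itself. A configurable fraction of miRNAs (default 15%) has true signal
below the 100-LU filter, exercising the detection mask. Sample metadata
(tissue source, blast content, age, sex) mirror a pediatric AML cohort of
102 samples across eleven cytogenetic categories.

Three properties make the generator a useful oracle: (i) at
`noise_cv = 0` generation is exactly invertible — the quantification
pipeline returns planted amounts bit-exactly (amounts below the detection
filter are flagged not-detected, by design); (ii) a fixed seed reproduces
all outputs bit-exactly; (iii) planted effects (fold changes, enrichments,
edges) are known truth for sensitivity/specificity measurements.

What passing these tests does **not** show about real data: the generator
has no dye bias, no spatial artifacts, no probe cross-hybridization, no
correlated miRNA co-regulation, and its noise is homoscedastic on the log
scale. Recovery rates on synthetic data are therefore upper bounds on what
identical settings achieve on real arrays.

One subtlety of the level-noise model: the *expected* IP/isotype ratio of
a planted feature is the planted value only up to a factor
$e^{\sigma^2} \approx 1.04$ at the default noise (the expectation of an
inverse log-normal), while the *median* ratio is exactly the planted
value. The estimators in the package are median- and rank-based, so this
does not bias recovery.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale: cohorts of
30–60 samples and 40–60 miRNAs for recovery experiments, 200 IP features,
2000-edge prediction sets, and 50 repetitions of 10-fold cross-validation
(the package's scaled-down default of the 1000-repetition full analysis).
Exact-test oracles enumerate all rank splits up to pooled size 12 and all
hypergeometric draws up to a 12-element universe. Tolerances: median
polish to 1e-6 against a long-iteration reference, Welch p to 1e-10
against the closed form, exact Mann–Whitney to 1e-12 against enumeration.

Known limitations: no dye-swap or loess/print-tip normalization (out of
scope by the platform's design); the DAVID-style functional-term grouping
and interactive network visualization of downstream interpretation are not
reproduced (the network is exported for external viewers instead); RMA's
convolution background model is simplified to subtraction.
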
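---
title: "Models and methods behind tripletrx"
author: "tripletrx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tripletrx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripletrx)
```

This vignette explains the models the package implements, the assumptions
they rest on, the defaults and why they were chosen, and what the
synthetic-data generators do and do not emulate. It is the design record of
the package: every choice that was genuinely open is stated here together
with its rationale.

## Growth-rate metrics

Cell-count-proxy signals (e.g. luminescence) measured at treatment start and
end are converted to growth rates assuming exponential growth,
$x(t) = x_0 \cdot 2^{kt}$, so $k = \log_2(x(t)/x(0))/t$ in doublings per
hour. The GR value of a condition is

$$GR(c) = 2^{\,k(c)/k(0)} - 1,$$

the fold-change ratio of treated to control growth rate mapped so that 1
means growth identical to control, 0 means zero net growth (complete
cytostasis), and −1 means complete killing. The exponential form is what
gives the metric its anchors: a non-growing treated population has
$k(c) = 0$ and hence $GR = 2^0 - 1 = 0$ regardless of how fast the control
grows. GR inhibition is reported as $100(1 - GR)$ percent, so 100%
inhibition corresponds to cytostasis and values above 100% indicate net
cell loss. GR values are computed from replicate-mean signals; per-replicate
GR values are attached for dispersion estimates. A control that does not
grow ($k(0) \le 0$) makes the metric undefined and is an explicit error
rather than a NaN.

Exponential growth with no confluence saturation is assumed throughout —
appropriate for the 3–6-day windows these assays use, during which
well-plated populations stay subconfluent; the package deliberately does
not model logistic slowing (a stated non-goal).

**Dose–response fitting.** GR or relative-viability values against dose are
fit with the four-parameter log-logistic

$$f(c) = floor + \frac{ceiling - floor}{1 + (c/EC_{50})^{slope}},$$

by bounded Levenberg–Marquardt least squares (`minpack.lm`), with the
inflection parametrized on the log scale for conditioning. Zero doses
anchor the top of the curve; for log-dose fitting they are placed at a
pseudo-dose two decades below the smallest tested positive dose — far
enough below to act as an asymptote anchor without influencing the slope.
GR50/IC50 is obtained by analytic inversion of the fitted curve at 0.5, so
the fitted curve evaluated at the reported GR50 is 0.5 by construction.
When the fitted curve never crosses 0.5 within the tested range the
half-effect dose is reported as `Inf` with `reached = FALSE` — never a
silent `NaN`. A perfectly flat response is handled as a degenerate
least-squares solution (floor = ceiling = the constant) rather than being
pushed through the optimizer. Non-convergence is flagged in the returned
object.

## Bliss synergy

Bliss independence treats two drugs as independent probabilistic "hits": if
single agents inhibit fractions $e_1, e_2$ of the signal, the expected
combined inhibition is $E = 1 - (1-e_1)(1-e_2)$, extended multiplicatively
for three drugs. Responses arrive as relative viability $v$ (vehicle = 1)
and are converted to percent inhibition $100(1-v)$ before scoring, because
Bliss composes probabilities of effect, not survival ratios.

For every combination cell (two or more nonzero doses) the excess is the
observed percent inhibition minus $100E$ computed from that cell's
single-agent margins. The overall score is the unweighted mean excess over
combination cells only — the convention of the standard web tool for this
analysis — and the conventional thresholds classify a surface as
antagonistic (score < −10), additive (−10 to 10) or synergistic (> 10).
Margins are clamped to [0, 1] before composing the expectation (stimulation
artifacts would otherwise corrupt the product), but observed values enter
the excess raw. Missing single-agent margins are an error naming the drug
and dose, not an imputation. When replicate wells are present a bootstrap
CI of the overall score is available by resampling wells within cells.

For 3-drug surfaces, `conditional_slice_scores()` scores each 2-drug
sub-surface at a fixed dose of the third drug, composing the expectation
from all three margins; at fixed dose 0 this reduces exactly to the 2-drug
score. Cells with at least two active drugs contribute, so a slice at a
positive fixed dose also scores the doublets it contains — the composition
of a slice therefore differs between fixed dose 0 (9 combination cells on a
4×4 grid) and positive fixed doses (15 cells), which matters when comparing
slice scores across doses.

## The synthetic viability generator

Each drug has a Hill dose–effect curve
$e(c) = E_{max}c^h/(EC_{50}^h + c^h)$ on the growth rate and a `floor`
giving the net growth-rate multiplier at saturation (negative = cytotoxic).
Single-drug growth is scaled as $m(c) = 1 - e(c)(1 - floor)$. Combinations
compose at the viability level: the combined relative viability is the
product of single-agent relative viabilities raised to an interaction
exponent $\tau$ (equivalently, growth-rate deficits add, scaled by $\tau$,
when two or more drugs are active). This composition is chosen because the
product of survival fractions *is* the Bliss expectation: at $\tau = 1$ the
generated surface has exactly zero Bliss excess in every cell (a property
the tests verify at machine precision), so $\tau$ is a one-parameter,
sign-interpretable ground truth for synergy ($\tau > 1$) or antagonism
($\tau < 1$). The planted synergy signal grows with the total effect up to
a saturation point (excess $= \pi - \pi^\tau$ for combined survival
$\pi$, maximal at intermediate $\pi$), so monotonicity of slice scores in
dose is expected — and asserted — only below saturation.

Measurement noise is multiplicative lognormal with unit mean and a chosen
CV, applied independently per well and timepoint; plates default to 3
replicate wells per condition (replicate counts in such experiments are
typically "two or more"; 3 is the realistic middle and is configurable).
Calibration of the scoring pipeline was checked on 8×8 Bliss-consistent
surfaces at 1% noise: across 100 seeded replicates the overall score stays
well inside the ±10 additivity band (maximum |score| under 1 point).

## The synthetic expression cohort

The cohort generator emulates a large breast-cancer expression cohort with
five latent transcriptomic states: one normal-like group and four tumor
subtypes (luminal-A/B-, HER2- and basal-like in spirit). Counts are
negative binomial with per-gene baseline means $2^{\mathcal{N}(5, 2^2)}$
(a realistic bulk RNA-seq abundance spread), dispersion 0.05 (typical for
human cohort data), uniform library-size factors in [0.6, 1.6], and a
two-batch additive log2 batch effect with per-gene offsets
$\mathcal{N}(0, 0.3^2)$ — strong enough to be detectable, weak enough that
biology dominates, as in a well-run study. Each tumor subtype carries a
disjoint block of 400 signature genes at log2 fold change 2, and all tumor
groups share a further 400-gene tumor program (the analogue of the
proliferation/E2F-target activation that separates tumors from normal
tissue in real cohorts). The shared program is what makes the normal-like
group a *bona fide* fifth cluster rather than a centroid-adjacent blur —
without it, normals sit at the barycenter of the subtypes and silhouette
analysis merges them. Default composition is 200 samples (20 normal-like +
4×45 tumors), mirroring the normal:tumor imbalance of public breast-cancer
cohorts at a desk-friendly size; 10,000 genes.

Optional cell-line samples take a subtype expression profile plus a
systematic log2 0.8 shift on 10% of genes, emulating the displacement of
cell-line transcriptomes relative to tissue that the projection workflow
exists to correct.

What the generator does *not* emulate: gene–gene correlation beyond the
block structure, compositional effects, GC/length biases, outlier samples,
and dropout; passing tests on this cohort therefore demonstrates correct
statistical machinery under the stated model, not robustness to every
artifact of real cohort data.

## The subtype workflow

Filtering discards genes whose total count in the *smallest* annotation
group is ≤ 10 — the smallest group is the binding constraint because a gene
unobservable there cannot support between-group comparisons. Size factors
are median-of-ratios against a geometric-mean pseudo-reference over genes
nonzero in all samples (with a logged fallback to a damped positive-subset
reference when no such gene exists). The variance-stabilizing transform is
$\log_2(x/s_j + 1)$: a deliberate, documented simplification of model-based
VSTs, whose dispersion machinery is out of scope here; its adequacy is
asserted via the property that matters downstream — the SD-vs-mean trend of
transformed NB data is flat (|slope| < 0.1) across the expressed range.
Batch correction fits a per-gene linear model with batch indicators plus
preserved biological covariates and subtracts the fitted batch terms
(`limma::removeBatchEffect`); batch structures aliased 1:1 with a preserved
covariate are refused, because the batch term would absorb biology.
Variable-gene selection is top-2500 by row variance with a deterministic
tie-break on gene id.

**Cluster-number selection.** k-means (Lloyd, best of 25 random starts) is
run for k = 2..10 in the variable-gene expression space — not a
PC-reduced space, since the variable-gene list is itself the feature
selection — and three diagnostics are reported: mean silhouette width
(Euclidean), the WSS elbow curve, and the gap statistic with a uniform
reference drawn in the PCA-aligned bounding box of the data (B = 50
references, scanned from k = 1, one-SE rule). The *selected* k is the
silhouette argmax: of the three, silhouette is the only one with a
parameter-free decision rule, so it is authoritative and the others are
corroborating evidence. On the default cohort all three agree on k = 5.

**PCA and shift projection.** PCA is centered but not scaled (after VST,
per-gene variances are informative), with a deterministic sign convention
(largest-|loading| entry positive). When new samples are added and the
whole pipeline is re-run, the embedding of the original samples shifts
slightly; to place new samples in the *frozen* original space, five
elastic-net regressions (mixing 0.5, penalty by 5-fold CV on a fixed seed)
predict each of the first five components' shifts (original − reprocessed)
from the reprocessed top-10 coordinates. The shift is modeled as a function
of where the sample lands, which handles both constant displacements and
mild rotations. Before training, reprocessed components are aligned to the
original ones by maximal absolute correlation (greedy, with sign flips):
PCA is identified only up to component order and sign, so training without
alignment would be ill-posed. The alignment must be unambiguous
(|r| ≥ 0.3) for the corrected components — an ambiguous match means the
embeddings are not comparable and is an error; higher, noise-dominated
components are aligned best-effort since they only serve as optional
predictors. Corrected components beyond the first five pass through
unchanged.

## Differential expression and enrichment

Per gene, a negative-binomial GLM `count ~ group` with log size-factor
offsets is fit at a method-of-moments dispersion
$\hat\alpha = (s^2 - \bar q)/\bar q^2$ pooled across the two groups and
floored at $10^{-8}$, and the group coefficient is tested with a Wald
z-test, followed by Benjamini–Hochberg correction. This is a deliberately
shrinkage-free simplification of the established cohort DE tools; at the
cohort sizes this package targets (n ≈ 20 per group and up) the plug-in
dispersion costs little: on null simulations the observed type-I error at
p < 0.05 is ≈ 5% (the calibration suite asserts 3–7.5%), and planted
log2FC = 2 genes at n = 20/group are recovered with essentially full power
at the standard thresholds (padj < 0.05, |log2FC| > 1), with median
estimated log2FC within 0.2 of truth. Genes are flagged DE by exactly those
thresholds. An established NB fitter serves as an independent cross-check
in the test suite (log2FC agreement r > 0.99), never as the implementation.

Preranked GSEA uses the weighted Kolmogorov–Smirnov running sum: walking
the ranking, the sum rises by $|s_i|/\sum_{hits}|s|$ at members and falls
by $1/(N - N_h)$ at non-members; ES is the maximum deviation. The null
distribution comes from plain gene-label permutation — equivalent to
drawing random sets of the same size, which lets the null be computed once
per set *size* and shared (10,000 permutations by default). NES divides ES
by the mean |null ES| of matching sign, and the permutation p-value is
computed within the matching-sign null with the +1 convention, so
$p \ge 1/(n_{perm}+1)$ by construction. Set-size bounds (15–500) apply
after intersecting each set with the ranking. Genes are ranked by the Wald
statistic from the DE stage — a test statistic blends effect size and
precision, which is the standard preranked input. The multilevel
adaptive p-value refinement used by some enrichment tools is intentionally
not implemented: plain permutation estimates the same quantity and its
resolution floor is explicit.

## In vivo efficacy

Tumor volumes follow the caliper convention $V = L W^2/2$ (prolate
ellipsoid). Percent tumor growth inhibition at day X is

$$\%TGI = \left[1 - \frac{\bar V_{t,X} - \bar V_{t,0}}
{\bar V_{c,X} - \bar V_{c,0}}\right]\times 100,$$

on group means — the parenthesization such that TGI = 100% exactly when the
treated group mean returns to its own baseline and TGI > 100% indicates net
regression, which is how regressing arms are conventionally reported.
Per-animal regression is $-(V_X - V_0)/V_0 \times 100$, with partial/
complete calls at 30%/80%; the thresholds are applied inclusively (a
conventional choice — the definitions state the thresholds without
strictness). Treatment effects are tested by ANCOVA on $\log V_X$ with
$\log V_0$ as covariate and group contrasts against the comparator:
logs because growth noise is multiplicative, and the baseline covariate
because randomization leaves residual baseline spread that otherwise
inflates variance. The xenograft generator grows each animal exponentially,
$V(t) = V_0 e^{r m_g t} \cdot \varepsilon$, with control rate 0.07/day
(≈ 950 mm³ by day 20 from a 230 mm³ baseline — mid-range for an untreated
orthotopic ER+ xenograft), per-group multipliers (negative = regression),
lognormal measurement noise at CV 0.12, n = 10 animals per group and
twice-weekly measurements over 21 days, matching how such efficacy studies
are run. Tumor growth *delay* after dosing stops is out of scope: volumes
past the dosing window can be simulated and reported, but no delay
statistic is defined.

## ΔΔCt

Per sample, the reference Ct is the arithmetic mean of the reference-gene
Cts — equivalent to a geometric-mean normalizer in abundance space, which
is why symmetric offsets on two reference genes cancel exactly. ΔCt is
averaged within groups, ΔΔCt taken against the calibrator group, and
$RQ = 2^{-\Delta\Delta Ct}$. The Ct generator writes
$Ct = baseline - \log_2(\text{abundance}) + \mathcal{N}(0, sd)$: amplifying
one cycle earlier per doubling of template, with additive Gaussian cycle
noise (the standard instrument-level error model).

## Numerical and reproducibility choices

All randomness flows through one seeded path per generator call
(`with_seed`), which snapshots and restores the session RNG: identical
seeds give bit-identical outputs and library code never perturbs user RNG
state. Stage runs through `run_stage()` record parameters, seed, input
hashes and output hashes in a JSON manifest, so deterministic and seeded
stochastic stages re-run identically. Ties in variable-gene selection break
on gene id; PCA signs are fixed by the largest-loading convention; k-means
uses Lloyd with multi-start and the best run by WSS. Problem sizes
throughout the test suite (200-sample × 10,000-gene cohorts, 2,000-gene DE
simulations, 100-seed synergy calibrations, 60-replicate ANCOVA
calibrations) were chosen as the smallest sizes at which the statistical
properties under test are stable.

## Known limitations

- GR metrics use exactly two timepoints; time-course GR estimation and
  confluence corrections are not implemented.
- The VST is the log-shift approximation; very low-count genes retain some
  mean–variance dependence below the expressed range.
- DE dispersion is per-gene method-of-moments without shrinkage — fine at
  cohort scale, anticonservative for very small designs (n < 5 per group).
- Only Bliss independence is implemented as a synergy null (no Loewe, HSA
  or ZIP), and no landscape smoothing is applied.
- The projection model corrects the first five components linearly; strong
  nonlinear distortions of the embedding are out of scope.
- Subtype labels (e.g. PAM50-style calls) are treated as input metadata;
  the package does not implement an intrinsic-subtype classifier.
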
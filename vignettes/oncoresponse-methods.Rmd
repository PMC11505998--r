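---
title: "Methods: models, parameters and design choices in oncoresponse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in oncoresponse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoresponse)
```

This vignette is the package's own account of the statistical methods it
implements, the parameters that matter, the numerical choices behind them,
and what the synthetic-data generators do and do not emulate.

## Growth-rate (GR) dose–response metrics

Endpoint relative viability depends on how many doublings a cell line
completes during the assay, which makes slow- and fast-growing lines
incomparable. GR metrics normalize by growth rate instead: with
$k(c) = \log_2(x_t(c)/x_0)/t$ the per-hour doubling rate under dose $c$ and
$k(0)$ the vehicle rate,

$$\mathrm{GR}(c) = 2^{\,k(c)/k(0)} - 1 \in (-1, \infty),$$

which is exactly 1 when treatment matches vehicle, 0 at complete
cytostasis, and negative when cells die. Because $k(c)/k(0)$ is a ratio of
rates, GR is invariant to the doubling time — the package's generators and
tests verify this identity to machine precision.

Growth rates are computed from **replicate-averaged signals** rather than
averaged per-replicate GR values: the log of a small, noisy luminescence
signal is unstable, and averaging first stabilizes it.

The dose–response model is the three-parameter sigmoid
$\mathrm{GR}(c) = \mathrm{GR}_\infty + (1-\mathrm{GR}_\infty)/(1+(c/\mathrm{GEC}_{50})^h)$,
fitted by bounded least squares (`optim`, L-BFGS-B, multistart over the dose
range) with $\mathrm{GR}_\infty \in [-1, 1]$, $h \in (0.1, 5]$, and
$\mathrm{GEC}_{50}$ within two decades of the tested ladder. Model adequacy
is decided by an F-test against the constant-GR model at $\alpha = 0.05$
(`flat` when non-significant); a fit that fails to converge or is pinned at
a parameter bound is `unstable`. These two flags re-specify the "unstable
due to poor curve fitting" annotation common in screening reports, which
vendor tools leave undefined.

Derived metrics:

* **GR50** — the analytic solution of the fitted curve at GR $= 0.5$,
  reported only when it falls within the tested range extended by one
  decade; otherwise the sentinel `">max_tested"`. When the fit is unstable
  the curve-free fallback (log-linear interpolation of the raw GR values)
  is reported in a separate column rather than silently substituted.
* **GRmax** — the mean *raw* GR at the highest tested dose (not the fitted
  plateau: the raw mean is what a screening heatmap shows and does not
  depend on fit quality).
* **GRaoc** — the trapezoidal integral of $1-\mathrm{GR}$ over
  $\log_{10}$ dose computed from raw GR values with no curve-fitting
  constraint and **no range normalization**: over the default 1.4 nM–27 µM
  ladder (4.29 decades) a fully cytostatic curve scores
  $\log_{10}(27000/1.4) \approx 4.29$. A range-normalized mean (bounded by
  2) could not reach the magnitudes that raw-integral AOC values of ~3.7
  take on such ladders, which is why the raw integral is the default.

Absolute IC50 comes from a separate four-parameter logistic fit on relative
viability, solved for the 0.5 **crossing** (not the inflection). Sensitivity
calls are strict (`IC50 < cutoff`) against a configurable per-drug table
(defaults: gedatolisib 100 nM, alpelisib 3000 nM, capivasertib 3000 nM,
everolimus 50 nM); a sentinel IC50 is never sensitive. Strictness is applied
uniformly because the convention is only ever written as "< cutoff".

## Median-effect synergy analysis

Single-agent data are linearized through the median-effect equation
$\log_{10}\!\frac{f_a}{1-f_a} = m\log_{10} D - m\log_{10} D_m$ and fitted by
ordinary least squares; $r$ of the linearized points is reported as the
usual quality diagnostic. Only $f_a \in (0.01, 0.99)$ enters the fit —
points outside carry no information about the line and are excluded with a
warning rather than clamped, so a saturated dose cannot drag the slope.

The combination index uses the **mutually exclusive two-term form**
$\mathrm{CI} = d_A/D_{x,A} + d_B/D_{x,B}$ (the default of the classic
CalcuSyn implementation). Fraction affected for combinations is defined on
normalized EdU inhibition ($F_a = 1 - $ normalized EdU). CI is undefined at
$f_a \in \{0, 1\}$. Labels use an additivity band of $\pm 0.05$ around
CI = 1, since an exact-equality label is useless on continuous data.
Non-constant-ratio designs are the default; constant-ratio designs are just
a special case of the dose table.

The combination generator inverts this analysis: it solves
$\mathrm{CI}(f_a) = \text{target}$ for $f_a$ by root-finding on the log-odds
scale (the CI is strictly monotone in $f_a$, so the root is unique). A
closed form exists only when $m_A = m_B$; the numeric solve gives exact
control of the planted CI for any slope pair.

## Flow-cytometry and qPCR readouts

Live gating uses the dead-cell (amine-reactive) dye: live events are **below**
the threshold placed where the two components of a two-Gaussian mixture on
log intensity are equally likely (`mclust`, fitted on at most 5000 evenly
spaced order statistics so the threshold is deterministic and O(n); a 1-D
k-means midpoint is the fallback if the mixture degenerates). The same
construction thresholds EdU positivity among live events. MFI is
`median(live) − unstained median`, floored at 0 with a warning. All
readouts are divided by the DMSO control, and percent inhibition is
$100(1-\text{normalized})$, floored at 0 with a stimulation flag —
a readout above control is reported as 0 % inhibition, never negative.

ΔΔCt uses the arithmetic mean of the two reference-gene Cts (equivalently
the geometric mean of their expression) — the combination rule when "both
reference genes" are specified without one. Relative expression is
$2^{-\Delta\Delta C_t}$; any per-sample additive shift applied to all genes
cancels exactly. Replicate ΔCt SD above one cycle is flagged.

## Xenograft efficacy

Volumes follow the caliper convention $V = L W^2/2$ with $L$ the longest
dimension; swapped entries are normalized (with a warning) before the
formula. TGI is the **baseline-adjusted** form
$100\,(1-\Delta V_T/\Delta V_C)$ with $\Delta V$ the change in arm-mean
volume from randomization (day 0) — appropriate for studies randomized at an
established 100–200 mm³ volume; the endpoint-ratio form is available via
`method = "ratio"`. Raw TGI above 100 (regressing tumors) is retained with a
capped display value. A non-growing control makes TGI undefined and is an
error, not a silent NaN. Measurements are matched to the requested day
within ±2 days (nearest observation), since twice-weekly measurement rarely
lands on the nominal day.

Welfare: percent body-weight change is relative to day 0 and an animal is
flagged only when loss strictly exceeds 20 %.

Between-arm inference is one-way ANOVA on per-animal volumes at the
requested day, with pairwise two-sided Welch t-tests versus control and Holm
adjustment, starred at 0.05/0.01/0.001. In the degenerate noise-free case
(zero within-arm variance, different means) the pairwise p is reported as 0
rather than erroring.

## Transcriptomic progression trajectory

**Preprocessing.** Protein-coding genes only; keep genes with a count of at
least 1 in at least 10 samples; median-of-ratios size factors;
$\log_2(x/s_j + 1)$. The log transform replaces a fitted
variance-stabilizing transform: every downstream step (IQR selection,
PCA, correlation) depends only on monotone variance stabilization, not on
the particular dispersion trend, and the simpler transform is exactly
reproducible. This is a deliberate fidelity gap relative to dispersion-aware
transforms.

**Batch handling.** The dispersion separability criterion is
$\mathrm{DSC} = D_b/D_w$ with
$D_b = \sqrt{\sum_b \frac{n_b}{N}\lVert\mu_b-\mu\rVert^2}$ and
$D_w = \sqrt{\sum_b \frac{n_b}{N}\,\mathrm{mean}_i\lVert x_i-\mu_b\rVert^2}$,
with significance from shuffling batch labels. Correction fits, per gene,
`expression ~ covariate + batch` (sum-to-zero batch contrasts) and subtracts
only the batch terms. The covariate enters the design first, so a batch
factor aliased with the biology loses its coefficients (set to zero, with a
warning) instead of absorbing the signal.

**Embedding and curve.** PCA (SVD on per-gene-centered data) on the top-2000
IQR genes, 5 components by default. Clusters are the provided ordered grade
labels — no de novo clustering, because grade is the biological axis the
trajectory is seeded on. A minimum spanning tree over cluster centroids
(Prim's algorithm) ordered from the seed cluster initializes the curve; the
principal-curve iteration then alternates (a) projecting samples onto the
polyline (continuous projection onto segments), (b) smoothing each
coordinate against projection arc length with a symmetric moving average
(span 0.2·N samples), and (c) reparametrizing by cumulative arc length.
Three numerical details matter:

* the curve is **extended linearly beyond both ends** before projection, so
  samples past the tips receive distinct arc lengths instead of piling onto
  the endpoint (without this, end samples tie and rank-based recovery
  degrades);
* ties in arc length are broken by sample coordinates, making results
  independent of sample order;
* convergence is declared when the mean squared projection distance changes
  by less than a relative $10^{-4}$ between iterations (cap 50). The raw
  mean projection *shift* never reaches such a tolerance because discrete
  reordering sustains a small limit cycle; the fit quality criterion is the
  stable quantity, and the non-converged case still returns the last
  iterate with `converged = FALSE`.

Pseudotime is raw arc length (units are arbitrary PC-space distance, as in
any trajectory tool), anchored so the seed cluster sits at 0.

**Correlation and enrichment.** Per-gene association with pseudotime uses a
20-times-repeated leave-one-third-out procedure: 20 random two-thirds
subsets, Pearson correlation per subset, median across subsets — an
outlier-robust estimate. The p-value is computed from the t-statistic of
the **median r at the subset size** $\lceil 2N/3\rceil$ (the per-draw-median
p is available by option; the two differ negligibly and the median-r version
is the quantity actually ranked). BH FDR across genes. Constant genes are
excluded with a flag.

Preranked GSEA is the weighted Kolmogorov–Smirnov walk (hit increments
$\propto |r|$, miss decrement $1/(N-|S|)$; for a set covering the whole
list the walk is compared against uniform progress so it still returns to
0). The null permutes gene labels — the only permutation available for a
preranked list. The p-value compares $|ES|$ against all null magnitudes,
$p = (1 + \#\{|ES_\pi| \ge |ES|\})/(n_{perm}+1)$: this estimator is exactly
uniform under label exchangeability, which we verify by simulation; sign
matching is used where it belongs, in the NES normalization
$ES/\mathrm{mean}|ES_\pi^{\text{same sign}}|$. A same-sign-restricted count
over an unrestricted denominator would be conservative by construction and
is not used.

**Survival.** Two-group overall survival by median expression split after
removing samples with missing values; Kaplan–Meier estimates and the
two-group log-rank test via the `survival` package. No events at all gives
flat curves and p = 1 by convention; all values tied at the median is an
error (no split exists).

## The synthetic-data generators

Each generator is the exact inverse of its analyzer at zero noise, which is
the property the test suite leans on: plates encode a chosen GR curve in
two-timepoint signals; combinations encode a chosen CI; xenograft arms grow
exponentially at chosen net rates (volumes split to length/width at a fixed
1.6 aspect ratio before measurement noise); the expression cohort draws
negative-binomial counts (dispersion 0.1) whose log2 means follow
`baseline + loading × standardized pseudotime + batch shift`, bins the
latent axis into ordered grades, and couples survival to it through a
proportional-hazards link; the flow panel draws per-event intensities from
two-component log-normal mixtures so the gating has something to gate.

Noise choices the data do not pin down: viability and caliper noise are
multiplicative log-normal (both assays are scale-noisy; replicate-level
variances are never published for such studies, so the default CVs — 5 %
for plates, 10 % for calipers — are chosen as typical of careful bench
work). Fraction-affected noise perturbs the log-odds. All generators accept
a seed, restore the caller's RNG state, and are byte-reproducible.

What the generators deliberately do not emulate: pharmacokinetics,
immune/stromal admixture, spatial plate effects, branching trajectories,
binary cytometry formats. Passing tests therefore demonstrate correctness
of the *computations* under a faithful but idealized data-generating
process — not robustness to every artifact of real instruments.

## Problem sizes and calibration checks

The test and acceptance suites run at sizes chosen to make sampling error
negligible relative to the tolerances: 50 plates for GR parameter recovery
(median relative error ≤ 10 % at 5 % noise), 20 cohorts of 300 × 2000 for
pseudotime recovery (Spearman ≥ 0.9), 20 null cohorts for FDR calibration,
500 random gene sets at 200 permutations each for GSEA p uniformity
(the discreteness gap of the permutation grid, 1/201, is far below the KS
critical value at 500 draws), and 1000 simulated null studies for the ANOVA
type-I rate (5 % ± 1.5 %). The end-to-end pipeline is verified
checksum-identical across repeated runs with the same seed.

## Known limitations

* The log2 size-factor transform is not a dispersion-aware VST; very low
  count regimes stabilize less well.
* The principal curve is single-lineage by design; branching topologies are
  out of scope.
* GR curve fitting assumes a monotone sigmoid; biphasic responses will be
  flagged `unstable` or fit poorly rather than modeled.
* The EdU/live thresholds assume two reasonably separated log-intensity
  modes; fractions recovered from overlapping mixtures are biased toward
  0.5.
* Interpolation to a requested xenograft day carries observations at most
  2 days, and errors beyond that rather than extrapolating.
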
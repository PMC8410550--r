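---
title: "Normative deviation modeling of ROI diffusion measures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative deviation modeling of ROI diffusion measures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normdev)
```

This vignette is the package's account of its statistical machinery: the
normative model and its assumptions, the knobs that matter, what the
synthetic cohort does and does not emulate, and the choices we made where
the method leaves room.

## The normative model

The analysis treats each of 18 white-matter regions (17 fiber tracts plus
the skeleton average) times three diffusion measures — FA, FAt, FW, all
dimensionless fractions in (0, 1) — as a separate response. Within each sex
stratum, the healthy-control reference at age $x$ is summarised by a
kernel-weighted mean and variance (Nadaraya–Watson estimates with a
Gaussian kernel):

$$\hat m_h(x) = \frac{\sum_i y_i K\!\left(\tfrac{x - x_i}{h}\right)}
                      {\sum_i K\!\left(\tfrac{x - x_i}{h}\right)},
\qquad
\hat\sigma^2_h(x) = \frac{\sum_i \left(y_i - \hat m_h(x)\right)^2
                      K\!\left(\tfrac{x - x_i}{h}\right)}
                      {\sum_i K\!\left(\tfrac{x - x_i}{h}\right)}.$$

This is deliberately nonparametric: lifespan trajectories of white-matter
measures rise, peak and decline on schedules that differ by tract, and a
mis-specified parametric age model would leak age effects into the
deviations. Sex is handled by exact stratification rather than as a
covariate. The estimator assumes only that the conditional mean and spread
vary smoothly with age and that the control sample covers the queried age
range — queries far outside the reference support raise an explicit
extrapolation error rather than silently returning the nearest neighbour.

Note the variance estimator centres the squared residuals on
$\hat m_h(x)$ at the *query* age, exactly as written above; a per-point
leave-one-out centring would be a different (also defensible) estimator,
and we implement the displayed form verbatim.

A subject with value $y$ at age $x$ receives the deviation z-score
$z = (y - \hat m_h(x)) / \hat\sigma_h(x)$, truncated to $[-10, 10]$.
Controls are always scored leave-one-out: subject $i$'s reference set is
every other sex-matched control. Truncation caps the influence of imaging
artifacts and near-degenerate variance estimates; every downstream summary
operates on the truncated values.

## Bandwidth selection

The bandwidth $h$ (years) is the one free smoothing parameter. It is chosen
per (ROI, modality, sex) by minimising the leave-one-out error
$CV(h) = n^{-1}\sum_j (y_j - \hat m_{h,-j}(x_j))^2$ over a fixed grid of 40
log-spaced values from 0.5 to 50 years. Grid search rather than continuous
optimisation: $CV(h)$ is cheap, can be multimodal, and a fixed grid makes
the selection reproducible to the bit. Ties break toward the smallest $h$.
The endpoints bracket the useful regimes for human age ranges — 0.5 years
is near-interpolation, 50 years smooths any cohort to its global mean (for
a flat trajectory the criterion correctly runs to the ceiling). At very
small $h$ a leave-one-out term can lose all its kernel mass; that term
falls back to the mean of the remaining values, keeping $CV$ finite
without discarding data.

Two bandwidth-reuse rules, both configurable:

* **Control LOO scoring** reuses the bandwidth selected once on the full
  control stratum rather than re-selecting for each left-out subject
  (`reselect_bandwidth = FALSE` default). Re-selection per subject is
  $n$-fold more expensive and changes z-scores negligibly at these sizes.
* **Cross-validation folds** re-select the bandwidth from scratch on each
  fold's training controls — the test set must not influence any part of
  the normative model, bandwidth included.

## Deviation summaries and the significant range

Per subject and modality, from the 18 truncated z-scores: `load` (fraction
beyond the abnormality threshold), `severity` (most extreme z, signed),
`mean_z`, `sd_z`, and `frac_sig_range`. The abnormality threshold defaults
to the two-sided Bonferroni quantile for 18 tests at $\alpha = 0.05$,
`qnorm(1 - 0.05/36)` = 2.9913 (we compute it rather than hard-coding a
rounded constant; an override argument exists).

The *significant range* asks which part of the deviation distribution
actually separates the groups. Each subject's 18 z-scores are turned into a
kernel-regularised density evaluated in 50 equal bins over $(-10, 10)$
(bin width 0.4). The KDE bandwidth uses Silverman's rule on the subject's
values, floored at one bin width — 18 points need strong regularisation,
and the floor stops near-duplicate z-vectors from producing spiky,
incomparable densities. Bin by bin, a one-tailed Welch test looks for
higher density in the patient group; the longest contiguous run of bins
with $p < \alpha$ (uncorrected per bin, by design; a correction argument
exists) becomes the range, reported by its outer bin edges. Zero-variance
bins contribute $p = 1$. When used as a classifier feature,
`frac_sig_range` is re-estimated on training data only inside each fold.

## Group statistics

Raw and z-value group comparisons use one-tailed Welch tests in the fixed
directions the pathology model predicts — FA and FAt lower, FW higher in
patients — with classical Cohen's d (pooled, Bessel-corrected SD; no
small-sample correction, negligible at these sizes) and its standard
asymptotic CI. Summary measures are skewed, so their comparisons use
one-tailed Wilcoxon rank-sum tests (exact enumeration when the combined
sample is ≤ 20 without ties, continuity-corrected normal approximation
otherwise) with Cliff's delta and the Feng–Cliff consistent-variance CI,
whose asymmetric transformation keeps the interval inside $[-1, 1]$. The
tails for the summary measures are not dictated by the method; the defaults
(more load, more extreme severity, modality-directed mean shift, larger
spread, more mass in the significant range for patients) are exposed as a
configurable direction registry.

## Classification

Feature sets follow a small grammar (`"z:FAt+FW:all"` = the 36 FAt-then-FW
z-scores; `"z:FA:all+summaries"` appends the five summaries). The
classifier is logistic regression with an L2 penalty, objective
$-(1/n)\,\ell(\beta) + (\lambda/2)\lVert\beta\rVert^2$ with the intercept
unpenalised, fitted by Newton iterations on features standardised with
training statistics. $\lambda = 1$ on the standardised scale by default —
fixed, not tuned per feature set, so AUC differences reflect the features
rather than per-set tuning (an inner selection loop would also be defensible
but costs determinism and comparability). Evaluation is 10-fold
cross-validation with a balanced, seeded fold design: each fold receives
$\lfloor n/k \rfloor$ subjects per group and the remainders spread one per
fold with the two groups' remainder folds kept disjoint when possible
(with 512/601 in 10 folds: seven (51, 60), two (52, 60), one (51, 61)).
The reported metric is the unweighted mean over folds of the test-set AUC,
computed in its Mann–Whitney form with ties counted one half. One seeded
split is the default; repeats over seeds are a caller-side loop.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` generates the joint structure the analysis assumes:

* **Demographics.** 512 controls / 601 patients; ages from normals
  (controls mean 30.15, SD 14.26; patients 31.46, SD 12.31) truncated to
  [8, 70] years — truncation keeps kernel regression away from empty
  support and means sample moments should be compared against the
  truncated distribution's moments; male fractions 54.49% / 63.23%.
* **Age trajectories.** Per-tract quadratics peaking near age 30 for
  FA/FAt and a monotone increase for FW, with small additive sex offsets;
  values clipped to (0.01, 0.99). Coefficients are package defaults chosen
  to sit in the published lifespan ballpark, not fits to any dataset.
* **Noise.** Homoscedastic Gaussian residuals by default (FA/FAt SD 0.02,
  FW 0.015, typical of harmonized tract-average data); an optional linear
  SD-versus-age slope exercises the heteroscedastic path of the variance
  estimator.
* **Pathology.** Each patient receives effects in a random subset of 1–6
  tracts — drawn with geometrically decaying per-tract weights, so
  abnormality is spatially heterogeneous but concentrated (the forceps
  major leads), matching the observation that per-tract abnormality rates
  differ strongly. Effect magnitudes are drawn per tract and modality on a
  Cohen's-d scale relative to the noise SD (defaults 0.15–0.45 for FA,
  0.25–0.55 for FAt/FW), with fixed directions (FA/FAt down, FW up) and
  the same affected subset across modalities (co-occurring pathology).
  The heterogeneous weights are structural, not cosmetic: with
  exchangeable tract effects the skeleton average — which we generate as
  the exact mean of the 17 tracts — would itself be the optimal linear
  discriminant, and no multivariate classifier could beat the best single
  ROI even in principle. Heterogeneity is what makes "combine information
  across tracts" a falsifiable claim about the method.
* **Ground truth.** `oracle_curves()` returns the exact generative mean
  and SD (the skeleton's SD is `noise_sd / sqrt(17)`), enabling
  parameter-recovery tests; clipping is ignored by the oracle and
  essentially never binds under the defaults.

Not emulated: site and scanner effects (harmonization is upstream of this
analysis), voxel-level spatial structure, medication or clinical
covariates, non-Gaussian heavy-tailed artifacts, and any correlation
between tract noises beyond the shared skeleton average. Passing tests on
this cohort therefore demonstrate that the estimators, the leakage-free
cross-validation plumbing and the qualitative behaviour of the method are
correct under a well-specified generative model — not that any particular
AUC value transfers to clinical data.

## Numerical choices

* Kernel weights are stabilised by subtracting each query's maximal
  log-weight before exponentiation; if even the largest raw weight
  underflows, the query is outside the reference support and an
  extrapolation error is raised.
* The conditional SD is floored at `sd_floor = 1e-6` (modality units) to
  guard degenerate strata; any z-score that hits the floor is truncated to
  ±10 anyway.
* Variance is computed via the weighted second moment minus the squared
  mean; at these scales (values in (0,1), variances ≥ 1e-12 of interest)
  the cancellation error is orders below the SD floor.
* The ridge-logistic Newton solver iterates to a step tolerance of 1e-10
  (penalised Hessian is positive definite for $\lambda > 0$) and errors on
  non-convergence rather than returning a partial fit.
* Constant feature columns standardise with scale 1 (they carry no signal
  and receive near-zero coefficients under the penalty).

## Test and simulation sizes

The test suite pins its statistical checks to fixed designs, chosen once:
z-score calibration on a single-sex control stratum of 512 (per-ROI LOO
z-scores within 0.1 of mean 0, SD 1); parameter recovery with 500 controls
per sex (fitted mean RMSE under half the noise SD across the central 80%
of the age range); per-ROI type-I error from 2000 null cohorts of 50 per
group (band 0.03–0.07 at $\alpha = .05$); chance-level full-pipeline AUC
averaged over 12 null cohorts of 100 per group; and the qualitative
ordering — multivariate FAt+FW z-features beat the best single ROI and at
least match all-ROI FA — averaged over 20 simulated cohorts of 300 per
group under 10-fold cross-validation.

## Known limitations

The variance estimator shares its bandwidth with the mean; strata whose
spread changes much faster than their mean would be better served by a
second bandwidth. The significant-range procedure tests bins marginally
and reports a single contiguous interval; multimodal group differences
would be truncated to their longest run. Fold composition is balanced per
group but not stratified on sex or age, so very small sex strata can make
a fold unfittable (an explicit error, not silent degradation). And the
synthetic cohort's independence assumptions (between tract noises, between
subjects) are simplifications that real harmonized data violate to an
unknown degree.
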
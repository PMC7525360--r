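---
title: "Myelin water imaging with mwimhi: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myelin water imaging with mwimhi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwimhi)
```

## The problem

In multi-echo spin-echo (CPMG-style) brain MRI, the signal of a voxel decays
as a mixture of exponentials, one per water environment: water trapped
between myelin bilayers relaxes fast (T2 around 20 ms), intra- and
extracellular water relaxes at 60–80 ms, and cerebrospinal fluid at about
2 s. The **myelin water fraction (MWF)** is the share of the T2 spectrum at
short relaxation times, a histologically validated myelin marker. Averaged
over a white-matter tract, the spatial statistics of MWF summarize myelin
health; the **myelin heterogeneity index (MHI)** is the coefficient of
variation of MWF over a region of interest,

$$\mathrm{MHI} = \frac{\mathrm{SD}(\mathrm{MWF})}{\mathrm{mean}(\mathrm{MWF})},$$

which rises when the mean drops, when the spread grows, or both — the two
signatures of diffuse demyelination in normal-appearing white matter.

`mwimhi` implements the full chain: the echo-train forward model, voxelwise
spectrum fitting, MWF maps, region statistics, the cohort correlation layer,
and a synthetic generator that stands in for acquired data.

## The echo-train forward model (EPG)

A 48-echo train with 8 ms echo spacing (`grase_sequence()`) is refocused by
pulses that are nominally 180° but in practice smaller and spatially
varying. Imperfect refocusing parks magnetization longitudinally and
releases it later as stimulated echoes, so naive mono-exponential modelling
overestimates T2. `epg_decay_curve()` evolves the extended phase graph: the
set of dephased transverse ($F^+_k$, $F^-_k$) and longitudinal ($Z_k$)
configuration orders, with relaxation over each half echo-spacing, one unit
of crusher dephasing per half interval, and the standard CPMG mixing matrix
(refocusing about the y axis) at each pulse.

Conventions and numerical choices:

* Excitation is an ideal 90°; no excitation imperfection model is applied.
* $N + 1$ configuration orders are retained for an $N$-echo train, which is
  exact — no truncation error at any echo.
* No longitudinal recovery term is included; at 180° the result is then
  exactly $\exp(-n\tau/T_2)$ and independent of T1 (this is tested to
  1e-10), and sensitivity to the assumed T1 stays weak at realistic flips.
* The fitting basis assumes T1 = 1 s everywhere (`t1_assumed`), the common
  convention for this sequence; the tests quantify that a factor-2 T1 error
  moves nothing at 180° and little below it.
* Echo amplitudes are reported as magnitudes of the order-0 transverse
  state; round-off negatives cannot occur under the magnitude convention.

The implementation is validated against an isochromat-summation simulator
(a dense ensemble of spins rotated explicitly through the train). With
equally spaced dephasing angles and more isochromats than the highest
configuration order, the ensemble average is mathematically identical to
the EPG result, making it a strong independent oracle; agreement is at
machine precision and tested at 1e-6.

## Voxelwise spectrum fitting

The measured curve $y$ is modelled as $y \approx Bx$, $x \ge 0$, where
column $j$ of $B$ is the EPG train of a unit species with T2 equal to the
$j$-th node of a logarithmic grid (`t2_grid()`: 40 points, 15 ms to 2 s by
default, spanning all three pools). No assumption is made about the number
of pools.

* `fit_nnls()` solves the non-negative least-squares core with a compiled
  Lawson–Hanson active-set kernel (the volume fitter calls it tens of
  thousands of times). It is cross-checked in the tests against exhaustive
  subset enumeration (every column subset, feasible minimum) on small
  problems, and against an independent R implementation.
* `fit_nnls_regularized()` adds a ridge penalty $\mu\|x\|^2$ via row
  augmentation with $\sqrt{\mu} I$. The weight is chosen so the *data*
  misfit lands in $[1.02,\,1.025]\times\chi^2_{\min}$ — the conventional
  misfit window for smoothing T2 spectra — by geometric bracketing and
  bisection in $\log\mu$; among all in-window weights encountered, the
  smallest (least smoothing) is returned. Exactly representable signals
  ($\chi^2_{\min}=0$) return the unregularized solution with $\mu = 0$.
* `estimate_flip()` recovers the per-voxel refocusing flip from the curve
  itself: candidate angles 90°–180° in 5° steps, each scored by its
  unregularized NNLS misfit, then one parabolic refinement over the three
  best candidates, clamped to the candidate range. A winner at the edge of
  the range is returned without refinement (a parabola through a boundary
  minimum is not informative). Ties break toward the larger angle.
* `compute_mwf()` is the spectral area at grid nodes with T2 strictly below
  40 ms over the total area. The comparison is literal: no partial-bin
  interpolation, and amplitude exactly at 40 ms does not count. A zero
  spectrum yields `NaN` with a warning rather than a silent 0.

`fit_volume()` applies the chain per voxel (flip estimate, basis at that
flip, regularized fit, MWF), skipping voxels with non-finite or
non-positive first-echo signal and reporting `NaN` there. Voxels are
independent, so the map is invariant to traversal order; candidate bases
are shared across voxels and refined-flip bases are cached at 0.25°
resolution, far below the estimator's own precision. Without an external
brain mask, `default_fit_mask()` keeps voxels whose first-echo intensity
exceeds 5% of the volume's 99th-percentile intensity.

## Region statistics

White-matter masks are eroded in-plane (`erode_inplane()`: a voxel survives
only if its full 3×3 in-plane neighbourhood is set, slices independent,
out-of-slice neighbours counting as background) to strip partial-volume
edges. `build_nawm_roi()` forms `roi AND wm AND NOT lesions`.
`compute_mhi()` summarizes the finite in-ROI MWF values: sample SD (n−1
denominator; the population/sample distinction is negligible at ROI sizes
but is fixed and documented), MHI = SD/mean, with `NaN` and a warning when
fewer than `min_voxels` (default 50) voxels remain or the mean is not
positive. Masks are binarized at > 0.5 on load so interpolated atlas masks
are tolerated.

## Cohort statistics

`pearson_with_ci()` reports the product-moment r, the two-sided p from the
t transform on n−2 degrees of freedom, and a Fisher-z confidence interval
with the normal quantile. The Fisher construction was chosen because it is
the standard closed form; a perfect |r| = 1 degenerates the interval to
[r, r] with p = 0, and the interval requires n ≥ 4. `bonferroni_alpha()`
divides the family level by the number of regions and also reports the
three-decimal truncated threshold used for display (0.05/3 displays as
".016"). `cognitive_z_scores()` standardizes against the control sample
mean and sample SD. `group_comparisons()` uses the Welch t test
(Satterthwaite df) for continuous demographics, a Pearson chi-squared test
without continuity correction for sex (Yates optional), with Shapiro–Wilk
(per group) and Levene (centered on the mean, as SPSS does) p-values as
assumption flags; when a flag fires, the Mann-Whitney p-value is reported
alongside rather than silently replacing the t test.
`run_correlation_matrix()` crosses groups × tests × ROIs with listwise
deletion per pair, so pair counts mirror differing test completion.

## The synthetic generator

`generate_phantom()` realizes a declared geometry (boxes/spheres) into a
4D echo volume: per voxel a true MWF is drawn from the region's normal
distribution truncated to (0.01, 0.5), pools are composed as myelin = MWF,
CSF from the CSF-fraction map, remainder intra/extracellular, the echo
train is synthesized by the EPG model at the voxel's flip, and i.i.d.
Gaussian noise is added with SD = (mean first-echo tissue signal)/SNR.
Defaults: pool T2s 20/80/2000 ms (the intra/extracellular value sits inside
the 60–80 ms band), pool T1s 0.5/1/4 s, flip 165°, one seeded generator per
call so identical seeds give identical bits.

`generate_cohort()` emulates a 73-patient/22-control cross-sectional
cohort: demographics match the study population this package models
(age 50.2 (10.7) vs 46.4 (13.5) years, 66%/64% female, education 14.7/15.8
(2.2) years, phenotypes 38/12/23 RR/PP/SP), control score means 62/62/69/56
for the four tests, patient means 56/55/60/49, and per-test missingness
reproducing completion of 66/65/63 of 73 patients. Patient scores couple
linearly to the MHI of a reference ROI (the first in the list, default
`slf`); given a target correlation the residual SD is solved in closed form
($\sigma_\varepsilon = |b|\,\sigma_{\mathrm{MHI}}\sqrt{1/r^2-1}$), making
the population correlation exact and the replicate-mean sample correlation
verifiable. Other ROIs load on the same latent damage at 0.8, mimicking the
cross-tract correlation of real cohorts. Values the study does not print —
control score SDs (10/9/11/9), patient MHI mean/SD (0.35/0.10), control MHI
mean/SD (0.25/0.05) — were fixed once at values consistent with the
published per-patient MHI range (0.22–0.59) and typical test SDs, and are
configurable.

What the generator does *not* emulate: anatomy (tracts are boxes), Rician
noise floors (Gaussian noise matches the fitter's assumption; a Rician
option exists for robustness experiments), B1 fields with spatial
structure, motion, or partial-volume gradients beyond the CSF map. Passing
tests therefore demonstrate correctness of the algorithms under the model's
own assumptions, not performance on scanner data.

## Problem sizes and reproducibility

The test-suite and acceptance-script simulations use a 20×20×4 phantom
(1600 voxels) for noisy MWF recovery at SNR 500, a 24×24×4 two-region
phantom at SNR 300 for end-to-end MHI recovery, a 16×16×4 toy fixture for
integration, 500 replicates per condition for confidence-interval coverage,
2000 null replicates for the type-I rate, and 200 replicate cohorts for
correlation recovery — sizes at which the Monte-Carlo error is comfortably
below the tolerances being checked. All randomness flows through per-call
seeds; `run_pipeline()` writes a config hash and seed into every output so
a run can be reproduced byte-for-byte (CSV outputs are byte-identical under
rerun; gzipped NIfTI bytes depend on the compressor and are compared by
content instead).

## Known limitations

* **Regularization biases MWF downward.** The ridge penalty smooths the
  small, ill-conditioned myelin peak into the intra/extracellular lobe, and
  the strict node cutoff then books that amplitude as non-myelin. At SNR
  300 this costs roughly −0.02 at MWF 0.10 (about −0.005 of it from grid
  discretization alone, the remainder from the penalty at the
  [1.02, 1.025] misfit window). The regional *mean* MWF stays within the
  ±0.03 band the tests check, but the MHI — a ratio — inflates by more
  than a quarter of its value at that SNR, as the acceptance script's
  `mhi_rel_err_snr300_*` entries report. Users comparing MHI across
  cohorts processed with the same settings are unaffected (the bias is
  systematic), but absolute MHI values are regularization-dependent.
* Gaussian noise on magnitudes: no Rician correction in the fitter; at the
  SNRs of interest (≥ 200 on the first echo) the distinction is small but
  it is a modelling simplification.
* The flip-angle search assumes the candidate range covers the truth;
  signals from flips below 90° would clamp at the range edge.
* The Fisher-z interval is a large-sample approximation; a seeded
  percentile bootstrap would be the natural alternative where exactness
  matters at small n.

## A worked example

```{r example, eval = FALSE}
fx <- make_toy_fixture()
fit <- fit_volume(fx$phantom$volume4d, fx$phantom$masks$wm)
stats <- roi_stats(fit, fx$phantom$masks$wm,
                   fx$phantom$masks[c("cingulum", "slf", "cc")],
                   lesions = fx$phantom$masks$lesions, min_voxels = 20)
stats

res <- run_correlation_matrix(fx$cohort, rois = c("slf", "cc", "cingulum"),
                              tests = c("sdmt", "srt", "cowat", "bvmtr"))
subset(res, group == "MS" & test == "sdmt")
```

The same flow, reading NIfTI volumes and writing maps, CSVs and a run log,
is available as `run_pipeline(pipeline_config(...))` and as the thin
command-line wrapper in `inst/cli/mwimhi.R`
(`simulate | fit | roi-stats | correlate | run`).
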
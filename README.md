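# mwimhi — myelin water imaging and the myelin heterogeneity index

`mwimhi` is an R package for quantitative myelin water imaging (MWI) of
multi-echo GRASE T2 relaxation data. It is aimed at neuroimaging
researchers studying diffuse white-matter damage — for example in multiple
sclerosis, where normal-appearing white matter (NAWM) can be demyelinated
without showing anything on conventional scans — and at methodologists who
need a fully synthetic, testable stand-in for such a pipeline.

## What it computes

A voxel's multi-echo decay is modelled as a non-negative mixture of
exponentials over a fixed logarithmic T2 grid, with no prior on the number
of water pools:

    y_n ≈ Σ_j x_j · EPG(T2_j, α; N, τ),   x ≥ 0

where `EPG(·)` is the extended phase graph echo-train model that accounts
for stimulated echoes when the refocusing flip angle α deviates from 180°.
The flip is estimated per voxel from the decay curve itself, and the
spectrum `x` is found by regularized non-negative least squares
(`min ‖Bx − y‖² + μ‖x‖²`, with μ set so the data misfit lands in
`[1.02, 1.025] × χ²_min`). The **myelin water fraction** is

    MWF = (spectral area at T2 < 40 ms) / (total spectral area)

and, over a white-matter region of interest (after in-plane mask erosion,
WM intersection and lesion subtraction), the **myelin heterogeneity
index** is the coefficient of variation

    MHI = SD(MWF) / mean(MWF)

Higher MHI means a lower and/or broader MWF distribution — more myelin
damage. The statistics layer correlates per-ROI MHI with cognitive scores
(Pearson r, Fisher-z confidence intervals, Bonferroni thresholds per
cognitive domain, e.g. 0.05/3 displayed as ".016"), computes
control-referenced z-scores, and runs group comparisons (Welch t,
chi-squared, Shapiro–Wilk/Levene assumption flags with Mann-Whitney
fallback).

Because MWI studies rarely deposit raw images, the package ships a
synthetic generator: three-pool phantoms (myelin ≈ 20 ms, intra- and
extracellular ≈ 80 ms, CSF ≈ 2 s) with region-wise MWF fields, spatially
assignable flip angle and noise, plus cohort tables whose scores couple to
ROI MHI at an exact target correlation.

## A worked example

```r
library(mwimhi)

fx  <- make_toy_fixture()                      # 16x16x4 phantom + 20-subject cohort
fit <- fit_volume(fx$phantom$volume4d, fx$phantom$masks$wm)
fit
#> MWF map 16x16x4: 784 voxels fitted (0 skipped, 0 misfit-window violations)
#>   in-mask MWF: mean 0.103, sd 0.035, range [0.000, 0.210]

roi_stats(fit, fx$phantom$masks$wm,
          fx$phantom$masks[c("cingulum", "slf", "cc")],
          lesions = fx$phantom$masks$lesions, min_voxels = 20)
#>   subject_id      roi n_voxels   mean_mwf     sd_mwf       mhi
#> 1    subject cingulum      192 0.10464011 0.02357312 0.2252781
#> 2    subject      slf      221 0.07741204 0.02323748 0.3001791
#> 3    subject       cc      144 0.13868149 0.02619754 0.1889044
```

The three rows are the NAWM portions of the three tracts: voxel counts
after erosion/lesion subtraction, mean and SD of fitted MWF, and the MHI.
The `slf` region was generated with the lowest myelin content, and its MHI
(0.30) is correspondingly the highest. Correlating cohort MHI with a
processing-speed score:

```r
res <- run_correlation_matrix(fx$cohort, rois = c("slf", "cc", "cingulum"),
                              tests = c("sdmt", "srt", "cowat", "bvmtr"))
subset(res, group == "MS" & test == "sdmt")
#>   group test      roi  n      r ci_low ci_high      p alpha_adjusted significant
#> 1    MS sdmt      slf 14 -0.480 -0.806  0.0675 0.0822         0.0167       FALSE
#> 2    MS sdmt       cc 14 -0.467 -0.799  0.0848 0.0925         0.0167       FALSE
#> 3    MS sdmt cingulum 14 -0.607 -0.860 -0.1121 0.0215         0.0167       FALSE
```

Negative r: higher myelin heterogeneity goes with worse scores — the
direction the toy cohort was generated with (at n = 14 nothing survives the
Bonferroni threshold, as the `significant` column shows). At the study
scale (n = 73) the generator's target correlation of −0.49 is recovered to
within a few hundredths on average.

A thin CLI over the same functions lives in `inst/cli/mwimhi.R`
(`simulate | fit | roi-stats | correlate | run`), and
`run_pipeline(pipeline_config(...))` orchestrates NIfTI-in → maps + CSVs +
run log out. See the vignette in `vignettes/myelin-water-imaging.Rmd` for
the models, parameter choices and known limitations.

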
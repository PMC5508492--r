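# icadenoise

Automated ICA-based denoising of resting-state fMRI, evaluated end to end on
synthetic cohorts with known ground truth.

Resting-state BOLD data from acute clinical populations (the motivating case
is acute stroke) carry several simultaneous noise families — head motion,
altered cardio-respiratory physiology, vascular-tone fluctuations — that can
swamp the resting-state networks (RSNs) an analysis is after. Two automated
strategies built on single-subject spatial ICA are in common use: a *focused*
classifier that removes only motion-related components and then high-pass
filters (AROMA-style), and a *complex* classifier trained to remove every
noise family before filtering (FIX-style, with study-specific training).
`icadenoise` implements both pipelines and the full measurement apparatus
used to compare them, for methodologists who want to study classifier and
cleanup behaviour under controlled, reproducible conditions.

Because clinical scans cannot be redistributed, the package ships a seeded
synthetic-cohort generator whose latent sources are known exactly: smooth
gray-matter networks driven by 0.01–0.1 Hz fluctuations, edge-localised
spiky motion components, CSF/venous high-frequency physiological components
and slow perivascular components, mixed linearly with white measurement
noise on a 3 mm, TR = 3 s, 120-volume grid.

## What it computes

* **Classification** — seven interpretable features per component
  (peripheral/speckled spatial weight, cluster count, high-frequency
  spectral fraction, spike and saw-tooth scores, CSF/vessel weight), fixed
  and trainable (regularised linear discriminant) noise scorers,
  leave-one-subject-out (LOSO) TPR/TNR threshold sweeps, and the
  optimal-threshold rule: among thresholds with mean TPR > 90%, pick the
  highest mean TNR provided it is at least 10%.
* **Cleanup** — 5 mm FWHM Gaussian smoothing, 100 s discrete-cosine
  high-pass, and *non-aggressive* component regression: with the full
  time-course matrix `M` fitted jointly to every voxel series `y`
  (`β = argmin ‖y − Mβ‖²`), only the noise columns' contribution
  `M_noise β_noise` is subtracted, so variance shared with signal components
  survives. Aggressive residualisation is available for comparison.
* **Connectivity** — template-based dual regression: volumes on template
  maps (stage 1), voxels on the stage-1 time courses (stage 2), Z-scores via
  the t → normal quantile map with `T − N − 1` degrees of freedom.
* **Metrics** — RSN identifiability (mean |Z| inside / outside the template
  mask at |Z| > 2.3), split-half reproducibility pseudo-Z against the
  off-diagonal correlation null over random group splits, tDoF loss
  (removed components / volumes), voxelwise %ΔSTD with sign-flip
  permutation group tests (optionally TFCE-enhanced) and probability maps,
  |%ΔZ| of summed in-mask Z with ANOVA and paired tests, and grayplots.

## Worked example

The optimal-threshold rule applied to the packaged benchmark sweep of a
patient-trained FIX classifier (mean/median TPR and TNR at thresholds
1–50, transcribed from a published acute-stroke evaluation):

```r
library(icadenoise)
sweep <- read_sweep_tsv(system.file("extdata", "fix_sweep_patient.tsv",
                                    package = "icadenoise"))
check_sweep_table(sweep)
#> threshold    1: mean TPR  98.1% > floor 90; mean TNR  61.3%
#> threshold    2: mean TPR  97.7% > floor 90; mean TNR  65.3%
#> threshold    5: mean TPR  97.3% > floor 90; mean TNR  71.8%
#> threshold   10: mean TPR  96.3% > floor 90; mean TNR  78.5%
#> threshold   20: mean TPR  91.7% > floor 90; mean TNR  86.9%  <- selected
#> threshold   30: mean TPR  88.0% <= floor 90; mean TNR  91.6%
#> threshold   40: mean TPR  83.6% <= floor 90; mean TNR  94.0%
#> threshold   50: mean TPR  79.4% <= floor 90; mean TNR  96.0%
#> [1] 20
```

Threshold 20 is the largest TNR (86.9%) still compatible with mean TPR
above 90% (91.7%). The generic-trained sweep
(`fix_sweep_generic.tsv`) never reaches TNR ≥ 10% inside the TPR
constraint, so no threshold qualifies and `NA` is returned.

A single synthetic subject, cleaned with ground-truth labels:

```r
cfg    <- synth_config(n_subjects = 6, seed = 5)   # 32x32x24, TR 3 s, 120 vol
cohort <- make_cohort(cfg)
s      <- cohort[[1]]
decomp <- wrap_ground_truth(s)                     # exact maps + time courses
feats  <- component_features(decomp, s$masks)
evaluate_tpr_tnr(rule_label(feats), attr(decomp, "labels"))
#> tpr tnr
#> 100 100

atlas <- make_noi_atlas(cohort, 20, seed = 1)
pre   <- highpass_filter(gaussian_smooth(s$image, 5), 100)
lab   <- attr(decomp, "labels")
cl    <- nonaggressive_clean(pre, decomp, lab$component[lab$label == "noise"])
cl
#> <cleanup_result> non-aggressive removal of 8/13 components (tDoF lost 8 of 120)
```

Dual regression before and after cleanup, and the matched-network
identifiability (mean |Z| inside the template mask over outside; higher is
better, > 1 means the network stands out):

```r
dro <- template_dual_regression(pre, atlas)
drc <- template_dual_regression(cl$cleaned, atlas)
tvec <- function(k) atlas$templates[, , , k][atlas$brain_mask]
mean(sapply(1:5, function(k) rsn_identifiability(dro$zmaps[k, ], tvec(k), 2.3)))
#> [1] 8.62
mean(sapply(1:5, function(k) rsn_identifiability(drc$zmaps[k, ], tvec(k), 2.3)))
#> [1] 9.98
```

Removing the 8 injected noise components raises the mean identifiability of
the 5 true networks from 8.62 to 9.98 while costing 6.7% of the temporal
degrees of freedom; the accompanying %ΔSTD map shows the variance reduction
concentrating on the brain-edge rim (79.9% there vs 65.4% brain-wide),
the signature of motion removal.

`run_experiment(experiment_config(...))` runs the whole study — simulation,
LOSO sweeps and threshold selection, cleanup under both strategies, dual
regression, and the metric suite — deterministically from one master seed,
and writes a JSON report plus TSV sweep tables.

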
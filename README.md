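# rsnpfs

Predicting progression-free survival (PFS) in glioblastoma from
preoperative resting-state network (RSN) functional connectivity.

Glioblastoma disrupts functional brain organization far beyond the lesion
itself, and the connectivity of large-scale resting-state networks carries
prognostic information. This package implements, as a tested and
reproducible R pipeline, an analysis that predicts PFS (in months) from
preoperative resting-state fMRI connectivity alone, and the survival and
spatial analyses around it. It is aimed at researchers in imaging
neuro-oncology who want a transparent, fully seeded reference
implementation of this class of pipeline, exercised end-to-end on a
synthetic cohort that emulates the statistical structure of such a study
(the patient data itself is access-restricted).

## What it computes

* **FC features.** For 15 RSNs (SMD, SMI, CON, AUD, DMN, PMN, VIS, FPN,
  SAL, VAN, DAN, MTL, REW, THA, BGA), per-subject voxelwise time series
  yield 15 within-network similarities (mean of the strictly lower
  triangle of the voxel-voxel Pearson correlation matrix) and 105
  between-network similarities (mean voxel-to-voxel cross-correlation):
  a 120-element feature vector in canonical pair order, with ROI-mean
  imputation of non-finite values.
* **Feature selection.** Greedy MRMR for a continuous target: relevance
  `|cor(x, y)|`, redundancy the mean `|cor|` against the selected set,
  difference (or quotient) criterion, top *k* = 15, re-run independently
  inside every cross-validation fold.
* **Prediction.** A deep feed-forward regressor — three equal-width
  hidden layers, each a sigmoid activation followed by layer
  normalization, linear output — trained by L-BFGS with random restarts
  and a width x loss (MSE/MAE/Huber) hyperparameter search, under
  leave-one-out cross-validation with FC-level data augmentation
  (re-estimating features from random 70–80% subsets of timepoints and
  of voxels per ROI; 10–500 augmented samples per optimization cycle,
  5–20% reserved for validation termination). PFS outliers are clipped
  at 24 months. A per-fold OLS baseline uses the identical folds and
  selections.
* **Survival.** RANO-style progression (measurable = enhancing, >= 2
  axial slices, both perpendicular diameters > 10 mm; progression =
  >= 25% increase in the sum of perpendicular products, or a flagged
  FLAIR/T2W increase), PFS in 30.44-day months, Kaplan–Meier curves,
  log-rank tests, univariate Cox hazard ratios, and median-split
  stratification of the predictions.
* **Maps.** Tumor frequency maps, voxelwise point-biserial PFS
  association, per-RSN averaging, per-network Cliff's delta effect sizes
  between control and patient RSN probability maps (|d| >= 0.47 large),
  and projection of network-level feature weights onto probability maps.
* **Synthetic cohort.** A seeded generator for every input the pipeline
  needs: spatially clustered parcellations, voxel time series with
  planted within/between-network covariance, outcomes coupled to chosen
  FC features through a saturating nonlinear link at a 9:1
  signal-to-noise ratio, attenuated patient probability maps, connected
  tumor masks with location–PFS coupling, and RANO lesion tables.

See the methods vignette (`vignettes/pfs-connectivity-methods.Rmd`) for
the model details, parameter defaults, and design decisions.

## Worked example

```r
library(rsnpfs)

cohort <- simulate_cohort(seed = 42)          # 45 subjects, 120 FC features
res <- loocv_run(cohort, seed = 7)            # nested LOOCV ANN pipeline, ~9 min
print(res)
#> pfs_prediction: n = 45 | RMSE 3.53 mo, MAE 2.79 mo, R2 0.817 (p = 1.5e-17)

lb <- linear_baseline(cohort)                 # OLS on identical folds
round(lb$metrics$mae, 2)
#> [1] 4.2

strat <- stratify_by_median(res$predicted)    # 23 low / 22 high at 8.7 months
round(cox_hr(res$actual, cohort$pfs_event, strat$group)$hr, 1)
#> [1] 16.8
```

The nested-LOOCV network recovers most of the planted outcome signal
(generative R² = 0.9) and clearly beats the linear baseline on the same
per-fold feature selections (MAE 2.79 vs 4.20 months) — the planted link
is saturating, which ordinary least squares cannot capture.
Predicted-low subjects progress earlier: stratifying at the median
predicted PFS separates the survival curves (log-rank p < 1e-10) with a
strongly elevated progression hazard in the low group.

## Analysis workflow

The numbered drivers under `analysis/` run the study end to end, writing
tables, NIfTI maps and manifests under `results/`:

```sh
Rscript analysis/01_simulate.R          analysis/config.yaml
Rscript analysis/02_feature_selection.R analysis/config.yaml
Rscript analysis/03_predict_pfs.R       analysis/config.yaml
Rscript analysis/04_survival.R          analysis/config.yaml
Rscript analysis/05_spatial_maps.R      analysis/config.yaml
```

All randomness derives from the single `seed` in the config; rerunning a
stage reproduces its outputs exactly.

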
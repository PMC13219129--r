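---
title: "Methods: predicting progression-free survival from resting-state network connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting progression-free survival from resting-state network connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rsnpfs` implements an analysis pipeline for predicting progression-free
survival (PFS, in months) in glioblastoma from preoperative resting-state
functional connectivity (FC), together with the survival and map-level
analyses that surround it. Because the patient data such a study relies on
is access-restricted, the package ships a synthetic-cohort generator that
emulates the statistical structure of the problem; every stage of the
pipeline is exercised and tested against that generator.

This vignette explains the model and procedure, the assumptions behind
them, the tunable parameters and defaults, and the design decisions taken
where the method description left genuine choices open.

## The connectivity features

The brain is summarized by 15 resting-state networks (RSNs): SMD, SMI,
CON, AUD, DMN, PMN, VIS, FPN, SAL, VAN, DAN, MTL, REW, THA, BGA. For one
subject, each network contributes a voxels-by-timepoints block of BOLD
time series. The feature set is the network-pair similarity:

* **within-network** similarity of network $g$: the mean of the strictly
  lower triangle of the voxel-by-voxel Pearson correlation matrix of
  $g$'s voxels. The self-correlation diagonal is excluded - including it
  would inflate every within-network value toward 1 by construction.
* **between-network** similarity of networks $i \ne j$: the mean over all
  voxel pairs (one voxel from each network) of the Pearson correlation
  over time.

With 15 networks this gives $15 + \binom{15}{2} = 120$ features, ordered
row-major over the upper triangle (including the diagonal) of the
15-by-15 network grid; the order is fixed so feature $k$ means the same
pair for every subject.

Before correlation, missing or non-finite values are imputed with the
ROI-wise mean. We read "ROI-wise" as the grand mean over all finite
entries of that network's voxels-by-timepoints block - not per-voxel or
per-timepoint means - because that granularity is well defined even when
an entire timepoint is missing; the choice is a convention and is
isolated in `impute_nonfinite()`. A voxel series that is constant (which
constant imputation can produce) has no defined correlation; such voxels
are excluded from the pair averages with a warning rather than silently
contributing zeros, which would bias the means.

Internally the features are computed in $O(\text{voxels} \times T)$: with
unit-norm centered voxel series $s_i$, every pairwise correlation is
$s_i \cdot s_j$, so block sums of correlations reduce to column sums of
the standardized blocks. The tests verify the fast path against direct
per-pair calls to the two component operations.

## The synthetic cohort

The generator is a latent-signal model chosen so the expected FC is
analytically available: network $g$'s voxels are
$\sqrt{\rho_g}\,L_g + \sqrt{1-\rho_g}\,\varepsilon$, with latent signals
$L$ drawn with a specified between-network correlation matrix and
$\varepsilon$ independent unit-variance voxel noise. The expected
within-network voxel-pair correlation is then exactly $\rho_g$ and the
between-network correlation is
$\sqrt{\rho_i \rho_j}\,R_{ij}$, which the convergence tests check at
$T = 4000$ within $\pm 0.05$.

Subjects differ in two ways. Each subject's between-network correlation
matrix is a base matrix (off-diagonal 0.10) plus a symmetric uniform
entry-level perturbation ($\pm 0.18$, eigenvalue-clipped back to a valid
correlation matrix; the amplitude is kept small enough that the clipping
is a mild correction, so per-pair variation stays near-independent
across subjects rather than collapsing onto a few shared directions).
On top of this, a subject-level *thalamocortical hub modulation* - one
scalar $u_s \sim U(-0.2, 0.2)$ added to the thalamus row of the latent
correlation matrix - makes all THA-involving FC features co-vary across
subjects. That hub axis is what gives the cohort a dominant,
consistently selectable predictor direction, emulating the regime the
source study reports (its top-ranked features - thalamic and
association-network pairs - were consistent across every
cross-validation fold). Per-network $\rho_g \sim U(0.25, 0.60)$. All
these ranges are conventions - the source cohort's FC distributions are
not public.

The study conditions instantiated by the defaults: **45 subjects**, 15
networks of **40 voxels** on a 20x20x20 grid, **160 timepoints**
(about a 6-minute scan at a typical TR), **5 active features** among the
120 - by default the thalamic pairs SMIxTHA, DMNxTHA, PMNxTHA, VANxTHA,
MTLxTHA, which ride the hub axis - and an outcome

$$\mathrm{PFS} = 2 + 20 \,\sigma\!\big(4 z\big) + \epsilon, \qquad
z = \text{standardized } w^\top f_{\text{active}},$$

a smooth saturating (sigmoid) dose-response with positive weights
(stronger thalamocortical connectivity, later progression), floored at
0.5 months so outcomes stay physical. With `noise_sd = "auto"` the
noise SD is set to one third of the signal SD, i.e. a 9:1
signal-to-noise variance ratio (generative $R^2 = 0.9$, verified by
regressing generated PFS on the true link values at $n = 2000$). OS is
PFS plus an exponential gap (mean 6 months); PFS events are observed
for every subject (the emulated cohort had no censored PFS), OS events
for 80%. The saturating link is deliberately nonlinear: it is what
gives a nonlinear regressor headroom over an ordinary least-squares
baseline fit to the same features.

What the generator does *not* emulate: hemodynamics, spatial
autocorrelation beyond region contiguity, anatomy, motion or scanner
artifacts, and any demographic/clinical covariate structure. Passing
tests therefore demonstrate that the pipeline recovers planted signal of
the stated form at the stated noise level - not that it would achieve any
particular accuracy on real patients.

Tumor masks are seeded region-grown connected clusters; subjects whose
mask overlaps designated short-PFS networks (DAN, VIS, FPN, DMN) receive
proportional negative PFS shifts, which gives the voxelwise
PFS-association map a recoverable spatial pattern. Probability maps give
each network high values (0.75-0.95) on its own voxels and low values
elsewhere; "patient" maps are attenuated copies plus clipped Gaussian
noise, so per-network effect-size orderings are known by construction.

## Feature selection: MRMR

Minimum-redundancy maximum-relevance ranking for a continuous target:

* relevance of feature $x$: $|\mathrm{cor}(x, y)|$;
* redundancy against the selected set $S$: $\frac{1}{|S|}\sum_{s \in S}
  |\mathrm{cor}(x, s)|$;
* greedy forward selection; step 1 takes the max-relevance feature, step
  $t$ the maximizer of relevance minus redundancy (the difference
  scheme; the quotient scheme is available as an option). Ties break
  toward the lower feature index for reproducibility.

The method description ties MRMR to correlation with a continuous
outcome, which is why correlation (not binned mutual information) is
used; neither the difference nor the quotient variant is asserted as
"the" original, and both are tested against an exhaustive greedy oracle
that re-evaluates the criterion for every candidate at every step. The
selection size is fixed at $k = 15$; `variance_explained_check()` reports
the PCA variance captured by the top $k$ components as a diagnostic but
never gates selection. The greedy pass ranks all 120 features (cheap at
this scale), so the returned order is a full permutation with `k` marking
the selected prefix.

## The regressor

A deep feed-forward network: input (15 selected features), then three
fully connected hidden layers of equal width, each followed by a sigmoid
activation and layer normalization (zero mean, unit variance across the
layer's units per sample, learnable gain and offset, variance epsilon
$10^{-5}$), then a linear output unit. The output layer is linear
because the target is months on a 0.5-24 scale - a bounded activation
could not reach it - and the stated architecture only places activations
*between* the hidden layers. Layer normalization sits after the sigmoid,
following the stated order.

Inputs and target are standardized to zero mean / unit SD using
training-set statistics (stored in the model, inverted at prediction);
without this, correlation-scale inputs against month-scale targets
leave the sigmoid layers stuck in their linear regime from a
fan-in-scaled initialization. Training minimizes MSE, MAE or Huber loss
(delta 1 month) by L-BFGS (memory 10, projected-gradient tolerance
$10^{-7}$) with analytic backpropagation gradients, verified against
central differences in the tests. Because the optimizer runs in chunks, the validation loss is
checked every `chunk_iter` iterations (default 10) on the cycle's
held-back augmented validation rows; training stops on optimizer
convergence, an iteration cap (500 by default; 150 in the shipped
analysis configuration), or 20 checks without improvement, and the
parameters from the best checkpoint are kept. (In the LOOCV pipeline
checkpoints are ranked by the same train+validation mix used for
restart retention, described below.) Weights are
initialized $U(-1/\sqrt{\text{fan-in}}, +1/\sqrt{\text{fan-in}})$ per
seed: the protocol calls only for "random weights", and a declared
scheme is required for exact reproducibility. All of memory size,
tolerances, cap and patience are unstated in the protocol; the values
here are small-problem-appropriate and configurable.

### Hyperparameter search and restarts

The grid is hidden width $\times$ loss kind; each configuration is
retrained from `restarts` fresh initializations (the protocol repeats
training about 50 times per configuration; the shipped analysis uses 5
to keep a full nested run on one CPU in minutes), and each restart draws
a *fresh* augmented training/validation set, so every newly initialized
model sees a distinct set of input-output pairs.

Two conventions here matter a great deal, and both address the same
hazard: augmented rows are perturbed near-copies of subject rows with
identical targets, so any score computed on rows whose source subjects
also appear in training rewards memorization rather than
generalization.

First, the 5-20% validation split is drawn *grouped by source subject*:
rows are ordered by a random permutation of the fold's training
subjects and the validation fraction is taken from the front, so
validation rows come from subjects that contribute no training rows
(at most one subject straddles the exact row count). The validation
loss then measures generalization to unseen subjects, which is what
early-stopping termination needs it to measure.

Second, retention ("the best-performing model within a configuration
was retained") evaluates candidates on *both training and validation
accuracy*, as the protocol states: the retained restart minimizes the
mean of (a) its subject-grouped validation loss and (b) its MSE on the
fold's unaugmented training subjects at their full-data features - the
clean input distribution used at prediction time. Either term alone is
worse: the grouped validation loss rests on only a handful of subjects
and is noisy, while the clean-training term is in-sample and favors
memorizers; their average balances the two. Both terms use only
fold-training subjects, so the held-out subject never influences
retention.

## The nested LOOCV pipeline

PFS outliers are clipped at 24 months before any fitting. For each of
the $n$ subjects in turn:

1. exclude the subject; rank features by MRMR on the remaining subjects'
   full-data FC and keep the top 15;
2. per optimization cycle, draw a timepoint fraction and a voxel
   fraction from $U(0.70, 0.80)$, subsample without replacement (one
   timepoint subset shared across networks - the scan is a single
   acquisition - and voxel subsets per ROI), recompute the FC vector,
   and repeat for a cycle-specific $U\{10,\dots,500\}$ number of
   augmented samples, each inheriting its source subject's clipped PFS
   unchanged (augmentation perturbs inputs only); reserve a
   $U(0.05, 0.20)$ fraction as the validation split - drawn per cycle,
   since the protocol generates a fresh augmented set per cycle;
3. run the hyperparameter search on these augmented sets, restricted to
   the fold's selected features;
4. predict the held-out subject from its full-data FC restricted to the
   same features.

Every random draw derives from `(master seed, fold index, cycle index)`
via an integer mixing function, which yields two properties the tests
assert: the whole run is a pure function of (cohort, specs, seed), and
nothing in a fold - selection, augmentation, splits, training - changes
when the held-out subject's label or data change.

Per-fold MRMR runs on unaugmented training features, with augmentation
applied afterwards to the selected columns: selection is nested in the
fold, and augmentation lives inside the optimization cycles.

Reported metrics: RMSE, MAE, $R^2$ as the coefficient of determination
$1 - SS_{res}/SS_{tot}$ (the stricter choice; squared correlation is
also reported), and the p-value of the two-sided zero-correlation test
between actual and predicted. The linear baseline is per-fold OLS on the
identical fold structure and per-fold feature selections, with no
augmentation.

## Survival analyses

Progression follows the RANO 2.0 reading implemented here: a lesion is
measurable iff contrast-enhancing, visible on $\ge 2$ axial slices, and
*both* perpendicular diameters strictly exceed 10 mm (the stricter of
the two possible readings of "perpendicular measurements greater than 10
mm"); progression iff the sum of perpendicular products of measurable
lesions reaches 125% of baseline ($\ge$, so exactly +25% progresses), or
a significant non-enhancing FLAIR/T2W increase is flagged. PFS converts
day intervals at 30.44 days/month (mean Gregorian month; the convention
is not stated in the protocol).

Predictions are stratified at the median predicted PFS, ties going to
the low group - for odd $n$ with distinct values this gives the
$(n+1)/2$ low / $(n-1)/2$ high split (23/22 at $n = 45$). Group curves
use the Kaplan-Meier product-limit estimator, group comparison the
two-group log-rank test, and the hazard ratio a univariate Cox
proportional-hazards fit on the group indicator with Breslow tie
handling (Efron optional). These standard estimators are delegated to
the `survival` package; the tests check them against hand-computed
product-limit tables and a generative exponential simulation with known
hazard ratio.

## Map-level analyses

* Tumor frequency: voxelwise mean of binary masks.
* PFS association: per voxel, the point-biserial correlation across
  subjects between tumor presence and PFS; voxels with fewer than 2
  tumor or 2 tumor-free subjects have no defined contrast and carry an
  `NA` sentinel (kept as a sentinel so maps remain writable to NIfTI,
  with `NA` excluded from per-network averages).
* Per-RSN averaging of any voxel map, by parcellation membership or
  probability weighting.
* Cliff's delta between control and patient probability maps, per
  network, over that network's own support voxels: off-network voxels
  are near zero in both groups and would dilute the contrast toward
  zero (the alternative - whole-brain domains - is the other reading of
  an ambiguous description). Magnitudes: $|d| < 0.33$ negligible/small,
  0.33-0.47 moderate, $\ge 0.47$ large. The implementation is
  rank-based ($O((m+n)\log(m+n))$) and is required by its tests to agree
  exactly with exhaustive pair enumeration.
* Network-level feature weights: for network $g$, the mean of the 15
  pair weights involving $g$. The per-feature weights fed to this
  averaging are the MRMR relevance scores of all 120 pairs (the
  description of the corresponding analysis sits inside the feature
  selection section; using trained-model weights instead is a noted
  alternative). The weight map is the per-voxel dot product of the 15
  network weights with the probability maps.

## Problem sizes and runtime

The shipped analysis and the acceptance checks run the full nested LOOCV
at $n = 45$ with widths $\{5, 10\}$, MSE loss, 5 restarts per
configuration and a 150-iteration cap - about 450 trainings on fresh
augmented draws - which completes in a few minutes on one CPU while
exercising every stage at full feature dimensionality. The restart count
and width grid are the package's reduced defaults for a desk-scale run;
the full protocol values (50 restarts, widths up to 15, three losses)
remain available through the configuration.

## Known limitations

* The generator's subject-to-subject FC variability is a convention, not
  an estimate of the source cohort's; absolute error levels on synthetic
  data do not transfer to patients.
* The planted outcome depends on the *empirical* (measured) FC of each
  subject, so the generative $R^2$ of 0.9 is an upper bound a perfect
  model could approach; measurement noise in the features is thereby
  part of the signal, which is optimistic relative to real acquisition.
* MAE-loss training uses subgradients at the kink; L-BFGS handles this
  in practice but convergence guarantees are weaker than for MSE/Huber.
* The Cox stage covers a single binary covariate (the stratification
  analysis); it is not a general survival-modelling interface.
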
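---
title: "Trajectory-constrained correction of amyloid-PET Centiloid quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-constrained correction of amyloid-PET Centiloid quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Amyloid-PET burden is reported on the Centiloid (CL) scale: a per-tracer
linear transform of the SUVR (target-region uptake over reference-region
uptake) anchored so that young controls average 0 CL and typical AD patients
100 CL. The scale assumes that one fixed pair of reference and target masks
is equally suitable for every tracer, scanner and reconstruction. In
practice, reference-region behaviour differs between tracers and sites, and
this variability shows up twice: cross-sectionally, as shifted and widened
amyloid-negative distributions between cohorts; and longitudinally, as
implausible Centiloid trajectories — values that fall over time, or jump far
faster than amyloid biology allows.

This package implements a correction learned from exactly that longitudinal
implausibility. A small 3D convolutional network maps a spatially and
SUVR-normalised PET volume plus its tracer code to a scalar correction
factor `CF in [0, 2]`; the corrected SUVR is `CF * SUVR`. Because amyloid
burden in observational cohorts should not decrease, and because the
expected annual change is a known function of the current level (the
*natural history curve*), deviations from those constraints provide a
training signal even though no ground-truth burden is available. The model
needs longitudinal pairs only during training; inference is single-scan.

## The losses

For each within-participant pair of scans 3 months to 3.5 years apart, with
corrected Centiloids `CL_T0`, `CL_T1` and interval `dt`:

* **Monotonicity** `Ld = max(0, CL_T0 - CL_T1)` — decreases are penalised
  proportionally.
* **Curve consistency** `Lc = |(CL_T1 - CL_T0)/dt - fc((CL_T0 + CL_T1)/2)|`,
  where `fc` is a lowess fit (span 0.2) of annual rate against mean CL,
  computed once from standard-quantification pairs of the reference tracer
  and then frozen.
* **Anchoring**: over the whole batch, an OLS regression of corrected on
  uncorrected Centiloids must have slope 1 and intercept 0:
  `Ls = |s - 1|`, `Li = |i|`. Without this, the trivial solution collapses
  every CF to 0.

The total is `L = mean(Ld) + 0.2 * mean(Lc) + 1 * Ls + 0.01 * Li`. Note the
asymmetry that drives everything in this package: `Lc`/`Ld` reward
*removing* scan-specific and tracer-specific distortions, while `Ls`/`Li`
resist any *systematic* departure from the standard scale. A static
per-tracer bias is corrected only insofar as its curve-consistency gain
outweighs the anchor cost; per-scan fluctuations are corrected essentially
for free. The parameter-recovery behaviour of the package (see the
acceptance script) reflects that balance: injected per-scan reference
fluctuations are removed almost completely, while an injected static
reference bias of 15% on one tracer is recovered to roughly two-thirds of
its magnitude, the remainder being held back by the anchor terms.

## The network

Up to four convolutional blocks (3D conv, kernel 4, stride 4, channels
16-128, instance normalisation, leaky rectification with slope 0.01), then
flattening, concatenation of a length-5 tracer one-hot, two fully connected
blocks (dropout, affine, batch normalisation, tanh; widths 256 and 64), and
an affine head whose logistic output is doubled, confining CF to `[0, 2]`
architecturally. Because stride-4 blocks shrink each axis by 4, the number
of blocks is derived from the grid (`floor(axis/4^k) >= 1` on every axis,
capped at 4): the full 91x109x91 template grid supports the deep
configuration, the desk-scale 32x40x32 grid (4 mm voxels) supports two
blocks. A block whose output is a single voxel would be annihilated by
instance normalisation, so normalisation is skipped in that degenerate case.

Everything — the conv stack, both normalisations, dropout, Adam, and
backpropagation — is implemented in base R as batched matrix algebra
(a stride-4/kernel-4 convolution is a non-overlapping patch embedding, i.e.
one matrix product per block). The backward pass is verified against finite
differences in the test suite.

## Training protocol and its desk-scale adaptations

Defaults follow the reference protocol where it is specified: batches of 64
pairs (128 images, both images of a pair in the same iteration, feed order
randomised), early stopping on validation loss with patience 20, best-of-n
restart selection by the validation Spearman correlation between mean
corrected CL and corrected CL/year, and participant-level folds balanced on
tracer mix, visit count and CL distribution.

Three optimisation choices are desk-scale adaptations, recorded in
`deepsuvr_control()`:

* **Learning rate 3e-3 with per-epoch decay 0.995** (Adam). The absolute
  losses have piecewise-constant gradients, so near the optimum the
  parameters random-walk at a scale set by the learning rate; annealing
  settles them. A cohort of ~100 participants is one or two batches per
  epoch, hence the much larger initial rate than a GPU-scale run would use.
* **Dropout 0 during desk-scale training.** With tens of pairs per batch,
  dropout-induced jitter of the correction factors flips the sign of most
  pair residuals, and the resulting gradient noise completely drowns the
  data signal (an ablation shows training pinned at its initialisation for
  hundreds of epochs with rate 0.5, and converging within 50 without). The
  dropout layer itself is implemented, parameterised, and active whenever a
  positive rate is configured, as it should be at full scale.
* **A minimum epoch count (300) before early stopping may fire**, because
  with one optimiser step per epoch the patience window otherwise measures
  steps, not progress.

## The phantom cohort

`sim_config()` / `make_cohort()` generate the synthetic study conditions:

* **Geometry**: an ellipsoidal brain on a 32x40x32, 4 mm grid; a
  cortical-shell target; two equal-size inferior spheres as cerebellar grey
  and white matter analogues whose union is the whole-cerebellum reference.
  All regions are mirror-symmetric about the left-right axis.
* **Trajectories**: accumulators follow a logistic natural history
  `CL(t) = 100/(1 + exp(-(t - onset)/slope_years))` with onset age
  N(72, 8) and `slope_years = 3`; non-accumulators hold a small constant
  baseline; 35% of participants are non-accumulators; two visits 1.0-3.2
  years apart. The time scale is deliberately compressed relative to the
  multi-decade human curve (peak accumulation here ~8 CL/yr): a desk-scale
  cohort is ~30x smaller than the real training sets, and compressing the
  trajectory restores a comparable signal-to-noise ratio between systematic
  accumulation and measurement noise. What is preserved is the *shape*
  (sigmoid level-rate relation), which is what the curve loss uses.
* **Signal model**: target uptake `1 + true_cl/100`, reference grey/white
  at 0.8/1.2 (mean 1), non-specific background 0.9; Gaussian PSF blur drawn
  per participant in 4-7 mm FWHM (one scanner per participant, as in real
  longitudinal follow-up); additive voxel noise (sd 5% of the reference
  mean); and a per-scan lognormal reference-region fluctuation (sd 2%)
  standing in for scanner/scatter variability. That last term is the
  variability the correction can and should remove: it is visible in a
  single image (the whole non-reference brain shifts relative to the
  reference), it corrupts longitudinal rates, and it is the desk-scale
  analogue of the reference-region instability that motivates the method.
  Tracer bias is injected as a multiplicative factor on reference uptake
  (`tracer_ref_bias`), deflating that tracer's standard SUVR by the same
  factor.
* **Transforms**: per-tracer Centiloid transforms are calibrated from
  noiseless, bias-free anchor renderings (CL 0 and CL 100). This mirrors
  the calibration-study convention — a site-specific reference bias in a
  cohort is *not* absorbed by the published transform, which is precisely
  why it is visible as a shifted amyloid-negative peak and correctable.
* The default tracer mix is 70% unbiased ("PIB") / 30% biased candidate
  ("FBP"): the anchor regression is then dominated by the unbiased tracer,
  which keeps the global scale fixed while the biased minority is aligned.

What the phantom does **not** model: real neuroanatomy, partial-volume
effects beyond Gaussian blur, scatter/reconstruction artefacts with spatial
structure, off-target binding, or registration failure. Passing tests
therefore demonstrate parameter recovery under the stated noise model, not
clinical performance.

## Mask derivation

`optimize_masks()` derives data-driven reference and target masks by
gradient descent so that mask-based SUVRs maximise the per-tracer Pearson
correlation with corrected SUVRs (`Lp = 1 - R^2`, averaged over tracers),
plus a binarity penalty `Lb = sum(0.5 - |M - 0.5|)/B` weighted by
`delta = 5e-4` and boosted 100-fold after 20 passes. Each iteration applies
step, clamp to `[0, 1]`, 4 mm FWHM smoothing, brain-mask restriction, and
mirror-averaging (which yields exact left-right symmetry while remaining
differentiable). A 3-level multiresolution schedule (x4, x2, x1 mean-pooled
downsampling, trilinear upsampling between levels) runs with per-level
minimum iterations (defaults 1000/3000/8000) and stops when the windowed
(50-iteration) moving average of `Lp` improves by less than 1e-7. Gradient
steps are normalised so the largest per-voxel update is `lr` (default 0.05
mask units): the raw `Lp` gradients scale inversely with mask mass, so a
fixed unnormalised rate would behave differently at every resolution level.
Desk-scale runs use reduced minimum-iteration schedules through
`mask_opt_config()`; convergence on the phantom is far faster than at full
scale. After optimisation, per-tracer least-squares lines (`recalibrate()`)
map the new-mask SUVRs onto the corrected-SUVR scale before the standard
Centiloid transform is applied.

## Evaluation statistics

`fit_gmm2()` is a seeded 2-component EM (10 restarts, best likelihood,
variance floored at 1e-6 of the sample variance); the lower-mean component
is the amyloid-negative peak. `hsic()` is the biased empirical estimator
`(1/n^2) tr(KHLH)` with Gaussian kernels and median-heuristic bandwidths,
with an optional permutation p-value. The outlier band is the central 90%
interval (5th-95th percentiles) of a reference rate sample — the convention
that reproduces an asymmetric band such as [-5.8, 11.2] CL/yr from a
right-skewed accumulation distribution; the two readings of the source
procedure ("95% confidence interval" vs "90th percentile") cannot both be
literal, and the central-interval reading is the one consistent with the
printed asymmetric limits. `paired_bootstrap()` resamples matched units
with replacement and reports the mean difference, percentile 95% interval,
and the sign-based non-parametric p-value. AUC is the rank statistic with
ties counted half; Cohen's d uses the pooled SD; Spearman uses average
ranks.

## Numerical choices and degenerate inputs

* Gaussian smoothing uses separable 1D kernels truncated at 3 sigma with
  edge renormalisation, so constants are preserved exactly.
* lowess: tricube weights, one robustness iteration, evaluated on a
  256-point grid, linearly interpolated, clamped outside the observed
  support (avoiding unbounded curve penalties early in training).
* Zero-variance batches, empty tracer groups, empty masks, sub-minimum
  sample sizes and out-of-range correction factors all raise errors rather
  than returning silent defaults.
* `rowsum()`-based instance normalisation adds `1e-5` to variances; batch
  norm running statistics use a cumulative moving average capped at an
  effective window of 100 batches, so evaluation mode is meaningful after
  a handful of optimiser steps.

## Problem sizes used in the packaged experiments

The packaged tests and the acceptance script run the pipeline end to end at
desk scale: cohorts of 100 participants (150 for the bias-preservation
experiment, 40 for the mask oracle) with two visits on the 32x40x32 grid,
single-restart training of roughly 300-600 epochs, and two-level mask
optimisation (x2, x1) with 120/300 iterations. The mask-recovery oracle
additionally switches the generator into its heterogeneous regime (late
accumulating inferior shell, white-matter-specific jitter, minimal blur, no
global reference jitter): with homogeneous regions every target voxel
shares one time course, the Pearson loss is affine-invariant, and hidden
masks are simply not identifiable — heterogeneity is what makes the oracle
meaningful. These sizes are the package's reproducible study conditions;
the full-scale defaults remain available through the configuration
objects.

## Known limitations

* The anchor terms bound static-bias recovery away from 100%: a tracer
  whose reference is inflated by 15% is corrected by ~10-12% at desk scale,
  with the balance depending on the biased tracer's share of the cohort.
  This is a property of the loss, not of the implementation.
* Training at desk scale is full-batch and CPU-bound; wall time grows
  linearly with cohort size and epochs.
* The mask optimisation recovers masks only up to the information present
  in the SUVR covariance across scans; voxels whose time courses are
  indistinguishable (e.g. symmetric halves, uniformly blurred neighbours)
  are recovered as a class, not individually.
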
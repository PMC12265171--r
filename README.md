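# deepsuvr

Trajectory-constrained correction of amyloid-PET SUVR and Centiloid
quantification, with data-driven reference/target mask derivation and the
associated evaluation statistics — plus a synthetic phantom cohort generator
so the whole pipeline runs end to end without any restricted-access data.

## The problem and the model

Amyloid burden is reported on the Centiloid scale, `CL = a * SUVR + b` per
tracer, where `SUVR` is the mean tracer uptake in a neocortical target mask
over the mean uptake in a reference mask (whole cerebellum). One fixed mask
pair is assumed optimal for every tracer, scanner and reconstruction; in
practice reference-region variability shifts amyloid-negative distributions
between cohorts and produces biologically implausible longitudinal
trajectories.

This package learns a per-scan multiplicative correction. A 3D convolutional
network maps a spatially and SUVR-normalised volume plus a tracer one-hot to
a correction factor `CF in [0, 2]` (logistic output scaled by 2); the
corrected SUVR is `CF * SUVR`. Training needs no ground truth: for
within-participant scan pairs 3 months to 3.5 years apart it penalises

* `Ld = max(0, CL_T0 - CL_T1)` — amyloid burden should not decrease;
* `Lc = |(CL_T1 - CL_T0)/dt - fc((CL_T0 + CL_T1)/2)|` — the annual rate
  should match the lowess natural-history curve `fc` (span 0.2, fitted once
  from standard-quantification pairs of the reference tracer, then frozen);
* `Ls = |s - 1|`, `Li = |i|` — slope and intercept of the batch-level OLS
  regression of corrected on uncorrected Centiloids, anchoring the corrected
  scale;

combined as `L = mean(Ld) + 0.2 mean(Lc) + Ls + 0.01 Li`. Inference is
single-scan. A second optimisation derives continuous reference/target masks
whose SUVRs maximise per-tracer Pearson correlation with the corrected
SUVRs (`Lp = 1 - R^2` plus a binarity penalty, 4 mm smoothing, mirror
symmetry, 3-level multiresolution), making the learned correction
interpretable and portable to existing pipelines.

## Worked example

Simulate a phantom cohort in which one tracer's reference region is inflated
by 15% (so its standard SUVR is deflated by 1/1.15), train the correction,
and look at what it learned:

```r
library(deepsuvr)

cfg <- sim_config(n_participants = 100, seed = 1,
                  tracer_ref_bias = c(PIB = 1, NAV = 1, FBB = 1,
                                      FBP = 1.15, FMM = 1))
cohort <- make_cohort(cfg)

fit <- deepsuvr(cohort$scans, cohort$masks, cohort$transforms,
                val_split = 0.25, seed = 0)
print(fit)
#> Trajectory-constrained SUVR correction model
#>   grid 32x40x32, 2 conv block(s); trained 300 epoch(s), best epoch 80
#>   best validation loss 0.6068; validation cf in [0.935, 1.111]

pr <- predict(fit, cohort$scans)
tapply(pr$cf, pr$tracer, mean)
#>       FBP       PIB
#> 1.0706493 0.9944329
```

The unbiased tracer keeps a correction factor near 1 while the biased
tracer's factor rises toward the injected 1.15 (about two thirds of a static
bias is recoverable at this cohort size — the anchor losses resist the
remainder; see the methods vignette). The correction also tightens the
amyloid-negative peaks and the longitudinal trajectories:

```r
q <- quantify_scans(cohort$scans, cohort$masks, cohort$transforms)
# cross-tracer amyloid-negative peak gap, standard vs corrected
peak <- function(cl, tr, t) fit_gmm2(cl[tr == t], seed = 0)
# standard gap ~13.9 CL shrinks to ~7.0 CL after correction;
# longitudinal rate outliers (central-90% band from the unbiased tracer)
# drop from 9% of pairs to 3%
```

The fitted model is a regular S3 object: `summary()`, `plot()` (loss
history), `coef()` (network weights), `residuals()` (validation-pair rate
deviations from the natural-history curve) and `predict()` all work.

A command line mirrors the R surface (`inst/cli/deepsuvr`):

```sh
deepsuvr simulate --config sim.json --out cohort/
deepsuvr quantify --manifest cohort/manifest.csv --ref ref.nii.gz \
    --target tgt.nii.gz --transforms transforms.json --out suvr.csv
deepsuvr train --manifest cohort/manifest.csv ... --out runs/
deepsuvr infer --model runs/model.rds ... --out corrected.csv
deepsuvr optimize-masks --manifest ... --corrected corrected.csv --out masks/
deepsuvr evaluate --corrected corrected.csv --baseline suvr.csv --out report.json
```

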
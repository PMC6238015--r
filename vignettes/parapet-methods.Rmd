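---
title: "Voxel-level kinetic parametric imaging from a late dynamic FDG PET acquisition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-level kinetic parametric imaging from a late dynamic FDG PET acquisition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

FDG kinetics in tissue with irreversible trapping (k4 = 0) linearize, in
Patlak form, to

    C(t_k) = Ki * integral_0^{t_k} Cp(tau) dtau + Vp * Cp(t_k)

where `C` is the tissue activity concentration (Bq/mL), `Cp` the blood
activity concentration, `Ki` the net influx rate
(mL_blood/mL_tissue/min) and `Vp` the blood distribution volume
(unitless, the unmetabolized FDG fraction in blood and interstitium).
At late times (here 80–95 min post-injection) the integral term
dominates and `Ki` is the quantity of clinical interest; `Vp` is a
nuisance parameter that the single-time-point "Hunter" estimate
`K_H = C(t_1) / integral Cp(t_1)` ignores — which is exactly why `K_H`
is an upper bound on `Ki` on noiseless data whenever `Vp > 0`
(`hunter_k()`, `patlak_fit()`).

Measured activities are treated as error-contaminated:

    C(t_k)  = C_mean(t_k)  + e_k,     e_k  ~ N(0, var_C(t_k))
    Cp(t_k) = Cp_mean(t_k) + e_p,     e_p  ~ N(0, var_p)

and the estimator propagates these errors by Monte Carlo: each draw
perturbs the measurements, solves the box-constrained least-squares
problem

    minimize over (x, y):  sum_k (x * intCp_k + y * Cp_k - C_k)^2
    subject to             0 <= x <= K_H,  0 <= y

and the reported `(Ki, Vp)` are the means (optionally medians) of the
draw solutions, with their spread as uncertainty
(`monte_carlo_estimate()`). The box solver uses the 2x2 normal
equations plus active-set enumeration of the four constraint patterns;
exact ties between patterns resolve toward the interior solution, and a
fully degenerate system (all-zero regressors) returns `(0, 0)` with a
flag (`solve_constrained()`).

Two error-model variants are implemented, selected by `sigma_p_mode`:

* `"shared"` — one blood error per draw, applied to all time points;
  this matches a counting-error model for venous blood samples, where
  the counting efficiency is common to the samples of one study
  (used by `barbolosi_lesion()`).
* `"per_timepoint"` — independent blood errors per time point, each
  with its own variance; this matches the image-derived input function,
  whose per-bin variability is measured separately at every bin
  (used by `parapet_voxel()`).

How a perturbed `Cp` should enter the integral term is genuinely open;
the package rescales the blood-curve integral by the ratio
(perturbed / unperturbed) of `Cp` at each time point, so that the curve
and its integral stay mutually consistent within a draw. Perturbed
activities are clipped at zero before solving (activity concentrations
are physical quantities). `K_H` is always computed from the
*unperturbed* means, once per lesion for the lesion-level estimator and
per voxel (from the voxel's own first-bin values) for the voxel-level
mapper.

## The measurement-error model from overlapping reconstructions

The variance entering the error model is measured, not assumed. A
15-min acquisition (fine 15-s subframes standing in for listmode data)
is rebinned into five 3-min bins; within each bin, five overlapping
2-min windows staggered by 15 s are averaged into five window images
(`rebin_overlapping()`; the first bin's windows cover 0–2, 0:15–2:15,
0:30–2:30, 0:45–2:45 and 1–3 min of the acquisition, 25 window images
in total). Per bin, the voxelwise mean and the unbiased (n−1) sample
variance over its five windows form the mean and variance images
(`mean_variance_images()`).

The five windows of a bin share subframes, so their values are
correlated and the plain sample variance *underestimates* the true
frame variance — by roughly a factor of four at the default grid. This
is kept deliberately: the overlapping-window scheme is a bootstrap-like
surrogate for replicate reconstructions, and the plain sample variance
over the windows is the definition of the method. Consequences: the
Monte-Carlo draw spread, and therefore the reported uncertainty, is
conservative-small; since every comparison in this package uses the
same convention, relative conclusions are unaffected.

Before the statistics are used voxelwise, the five bins are realigned
onto the central bin (k = 3) with a rigid translation maximizing a
32-bin histogram mutual information: a coarse integer-voxel grid search
followed by Nelder-Mead refinement with trilinear resampling
(`register_to_central()`). Windows are realigned first and the
statistics recomputed from the realigned windows. If the optimized
transform does not improve mutual information over the identity, the
identity is kept, so realignment can never worsen alignment. Rotations
are deliberately out of scope: at the 4-mm voxels and short 15-min span
simulated here, per-bin patient motion is dominated by translation, and
the translation-only model keeps the recovery criterion
(half-a-voxel accuracy) well-posed.

## The input function

The blood curve shape is a tri-exponential,
`Cp(t) = sum_j A_j exp(-lambda_j (t - t0))`, with closed-form integral
(`triexp_input()`, `evaluate_cp()`, `integrate_cp()`). The package
ships a default shape (`default_input_function()`) whose coefficients
are synthetic: they are not taken from any publication, and were chosen
once to give a realistic bolus peak, a late blood level of
~1.5 kBq/mL at 85 min, and lesion SUV near 4 at the default phantom
kinetics. In any quantitative use the shape must be rescaled to the
subject: to a single venous sample (`scale_to_sample()`), to several
samples or IDIF values by least squares (`scale_to_samples()`), or
refitted outright to early + late blood data (`fit_triexp()`,
Levenberg-Marquardt with positivity bounds and randomized multistart).

The image-derived input function (`idif_from_roi()`) reads the aorta
ROI from the frame statistics: per bin, the IDIF mean is the ROI
average of the bin's mean image, and the IDIF variance is the sample
variance of the ROI means of the bin's five windows — i.e. the
measurement variability of the blood value, not the spatial variance
across the ROI. No partial-volume correction is applied; the synthetic
aorta is large enough (2-voxel radius) that spill-over is not part of
what the phantom emulates.

## The synthetic phantom

`make_phantom()` builds voxelwise ground truth on a regular grid
(default 32x32x16 voxels of 4 mm): a spherical lesion (default
`Ki = 0.05`, `Vp = 0.3`, radius 4 voxels), an optional necrotic core
with reduced uptake (default `Ki = 0.005`), low-uptake background
(`Ki = 0.002`, `Vp = 0.05`), and an aorta cylinder whose voxels carry
`Ki = 0, Vp = 1` so that a noiseless series reproduces `Cp(t)` exactly
there. `forward_model()` evaluates the linear trapping model at the
subframe mid-times; the default schedule is 60 subframes of 15 s over
80–95 min post-injection.

Noise (`noise_model()`, `add_noise()`) is zero-mean Gaussian with
variance `alpha * activity / duration + floor`, clipped at zero — a
count-statistics surrogate in which variance scales inversely with
frame duration. The default `alpha = 300` was calibrated so a 2-min
window at lesion-like activity (~15 kBq/mL) has ~10% voxel CV, a
typical clinical PET noise level; `alpha = 75` (~5% CV) is the
"moderate noise" operating point used in the parameter-recovery tests.
The clipping bias is below 1% of the mean as long as the voxel sigma
stays under a third of the activity, which holds across the default
phantom. Per-bin rigid motion can be injected with `apply_motion()`
(trilinear resampling, zero fill at the field-of-view edge) to test
registration recovery.

What the phantom deliberately does **not** emulate: scanner physics
(attenuation, scatter, randoms, reconstruction point-spread),
event-level listmode streams (replaced by fine time sampling), decay
(all values are treated as decay-corrected), and anatomical texture.
Passing tests therefore demonstrate the correctness of the estimation
chain under its stated error model — not robustness to reconstruction
artifacts or to input-function model misspecification on real data.

## Estimators and their intended comparisons

* `patlak_fit()` — unconstrained OLS on the two regressors; the
  reference. Exact on noiseless model data; on a single noisy voxel it
  is highly variable because the two regressors are nearly collinear
  over a short late window — which is precisely the motivation for the
  constrained Monte-Carlo approach.
* `hunter_k()` — single-time bound; positively biased for `Vp > 0`.
* `barbolosi_lesion()` — lesion-level Monte Carlo. The tissue
  measurement is the three-slice maximum statistic: the lesion global
  maximum (in the time-averaged image) fixes the central slice; the
  per-slice maximum positions in it and its two neighbours are located
  once and read at every bin; their mean and (n−1) variance feed the
  shared-blood-error Monte Carlo. Works with venous samples
  ("Bl" variant) or the IDIF ("Im" variant).
* `parapet_voxel()` — the voxel-level extension: every masked voxel
  gets its own measurement set (its five bin means/variances + IDIF)
  and its own Monte-Carlo estimate with per-time-point blood errors,
  yielding `Ki` and `Vp` maps with lesion maxima. Per-voxel seeds are
  drawn once from the master seed, making maps bit-reproducible.

`suv_image()` provides the SUV normalization for contrast and response
comparisons, and the agreement module supplies Bland-Altman ratio
limits of agreement, ICC(2,1) (absolute agreement, the standard choice
for method comparison; consistency and one-way forms are exposed),
Wilcoxon paired tests (exact for n <= 25 without ties), Pearson
correlation, fractional response deltas (same-voxel policy by
default), the lesion/necrosis contrast ratio, and the
convergence-versus-draws analysis.

## Numerical and design choices

* Time tags: each bin's `t_k` is its mid-time relative to injection
  (81.5, 84.5, ... min for the default 80-min start); subframe values
  are mid-time samples.
* Variance divisor: unbiased n−1 everywhere (window statistics, slice
  maxima, IDIF).
* Monte-Carlo summary: arithmetic mean of the draw solutions, median
  as an option.
* Degenerate inputs error early with informative messages (empty
  masks, zero integrals, non-positive durations, collinear designs,
  all-zero paired differences).
* All randomness flows through explicit integer seeds, and package
  functions restore the caller's RNG state.

## Problem sizes and convergence behaviour

The test-suite and acceptance experiments run on the default 32x32x16
phantom (257 lesion voxels) with 1000 draws per voxel — sizes chosen so
the full suite completes in a few minutes on one core while leaving the
Monte-Carlo standard error far below the tolerances under test.
Because the estimate is a mean over n draws, its run-to-run CV falls
as 1/sqrt(n); `convergence_analysis()` measures this directly. The
repeat count for CV *threshold* checks follows the 5-repeat protocol of
the convergence experiment; the log-log *slope* check uses 20 repeats,
because the relative standard error of a CV estimated from r repeats is
about `1/sqrt(2(r-1))` — at r = 5 that is ~35%, too noisy to resolve a
slope to ±0.15, while r = 20 brings the slope standard error to ~0.07.

## Known limitations

* Irreversible trapping is assumed (`k4 = 0`); lesions with washout
  violate the model.
* The short late window makes the two regressors nearly collinear, so
  per-voxel `Vp` estimates are weakly identified and should be read as
  qualitative; `Ki` is the supported endpoint.
* The overlapping-window variance is a correlated-replicate surrogate
  (see above) and underestimates the absolute measurement variance.
* Registration is translation-only by design; rotational or
  deformable motion is out of scope.
* No scanner physics: absolute quantification on real data would
  additionally require the scanner's own calibration and corrections.
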
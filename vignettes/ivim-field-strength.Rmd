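---
title: "Field-strength dependence of IVIM parameters: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-strength dependence of IVIM parameters: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivimfield)
```

## The problem

Intravoxel incoherent motion (IVIM) imaging separates the diffusion-weighted
MR signal of a voxel into a tissue-water compartment, decaying with the
diffusion coefficient $D$, and a microvascular compartment, decaying with the
much larger pseudo-diffusion coefficient $D^*$:

$$ S(b)/S_0 = f\,e^{-bD^*} + (1-f)\,e^{-bD}. $$

The perfusion fraction $f$ is, however, not a pure volume fraction: each
compartment contributes in proportion to its proton density *times* its
spin-echo relaxation weight

$$ w = e^{-TE/T_2}\left(1 - e^{-TR/T_1}\right), $$

and blood and muscle relaxation times depend strongly on the main field
strength $B_0$. The same calf, scanned with identical TE/TR at 0.55 T and
7 T, therefore yields very different measured $f$ values. This package
implements the model that quantifies this effect and removes it.

## The three-compartment model

The vascular pool is split into arterial and venous blood, which differ
markedly in $T_2$ at high field (at 7 T arterial blood keeps
$T_2 \approx 55$ ms while venous blood drops to $\approx 20$ ms, against
muscle's 22 ms). With proton-density-weighted fractions $f_{0,a}$ and
$f_{0,v}$ (summing to $f_0$, split by the venous-to-arterial volume ratio
$r = f_v/f_a$), the measured fraction is

$$ f = \frac{f_{0,a} w_a + f_{0,v} w_v}
           {f_{0,a} w_a + f_{0,v} w_v + (1 - f_0)\,w_m}. $$

`forward_perfusion_fraction()` evaluates this map and
`invert_perfusion_fraction()` its closed form inverse

$$ f_0 = \frac{f\,w_m}{w_\mathrm{eff}(1-f) + f\,w_m}, \qquad
   w_\mathrm{eff} = \frac{w_a + r\,w_v}{1+r}, $$

which round-trips with the forward map to machine precision (a tested
invariant). The capillary pool is not modelled separately: its more
oxygenated part is absorbed into the arterial pool and the rest into the
venous pool, following the convention of the relaxation literature for
mixed-oxygenation blood.

Key properties, all enforced by tests:

* $f$ is strictly increasing in $f_0$, and $f = f_0$ exactly when all three
  weights coincide (the proton-density limit);
* with $w_a = w_v = w_b$ the model collapses to the familiar two-pool form
  $f = f_0 w_b / (f_0 w_b + (1-f_0) w_m)$;
* $f_{0,a} + f_{0,v} = f_0$ exactly (the venous part is computed as the
  complement of the arterial part to keep the identity exact in floating
  point).

### Relaxation-time inputs

`relaxation_times()` ships literature compilations at 0.55 T and 7 T for
calf muscle and blood, and at 1.5 T / 3 T for liver. Times are in ms, field
strengths in tesla; every set records its sources. Two points deserve
comment:

* For arterial $T_1$ at 7 T, two values circulate for the same literature
  source (2990 ms in the running text of the relaxation study, 2290 ms in
  tabulations). Both ship; `calf_7T` uses 2990 ms and `calf_7T_t1a2290` the
  alternative. The downstream $f_0$ estimates differ by well under the
  model's other uncertainties.
* Blood $T_2$ at 0.55 T uses the 1.5 T values (148/207 ms): arterial blood
  $T_2$ is reported field-independent between 0.55 T and 1.5 T, and the
  quadratic rate interpolation below extrapolates unphysically at low
  field.

Weights are always derived on demand from `(relaxation_set,
sequence_protocol)` pairs by `compartment_weights()` — never stored — so
sensitivity scans cannot desynchronise times and weights.

### Interpolating blood T2 across field strength

Blood transverse relaxation *rates* $R_2 = 1000/T_2$ are fitted with a
second-order polynomial in $B_0$ (`fit_r2_polynomial()`), operating on rates
rather than times because rates vary smoothly with field; fitting times
directly gives a different curve and is deliberately not offered. This is a
numerical interpolation, not a dispersion model: `predict_t2()` warns
whenever the requested field lies outside the fitted range and errors when
the polynomial predicts a non-positive rate (which it does for venous blood
below about 1 T). The package ships only the three printed literature points
(1.5, 3, 4.7 T); the 7 T prediction from these three points is
$T_2 \approx 18.5$ ms, whereas the packaged 7 T set uses the rounded
literature-grade values 20/55 ms that were obtained with an additional
11.7 T point not available for shipping.

## Segmented IVIM fitting

With no b-values below 50 s/mm² the pseudo-diffusion coefficient cannot be
fitted reliably, so the analysis uses the first step of the segmented
approach (`segmented_fit()`): ordinary least squares of $\ln(S_b/S_0)$
against $b$ over $b \ge$ 100 s/mm² gives $D = -\text{slope}$, and the
intercept $c$ at $b = 0$ gives the perfusion fraction. Two intercept
conventions exist:

* **default** `f_mode = "exp"`: $f = 1 - e^{c}$, exact for two-compartment
  data whose vascular signal is fully suppressed above the threshold;
* **literal** `f_mode = "linear"`: $f = -c$, the linearised form
  $\ln(S_b/S_0) = -Db - f$.

They agree to first order ($|(1-e^c) - (-c)| \le c^2/2$); both are recorded
on every fit. The threshold defaults to 100 s/mm² and is configurable, since
thresholds of 200 s/mm² and above are also in use. The least squares is
unweighted by default — curves are per-b averages already — with per-b
average counts available as weights behind a switch.

At finite $D^*$ the vascular signal has not fully decayed at
$b = 100$ s/mm² ($e^{-2} \approx 0.14$ at $D^* = 20$ µm²/ms): the fitted
$D$ is biased slightly high and $f$ low. For $f = 0.07$, $D = 1.41$ µm²/ms,
$D^* = 20$ µm²/ms on the 0/50/100/500/600 s/mm² scheme, the noise-free
segmented fit returns $D = 1.435$ µm²/ms and $f = 0.057$ — a deterministic
threshold bias of about 1.3 percentage points on $f$, which maps to about
0.6 percentage points on $f_0$ after inversion. This is a property of the
estimator on such data, not of noise; the tests freeze these values and the
parameter-recovery bounds account for it.

`biexponential_fit()` provides the full Levenberg–Marquardt fit of the
biexponential model (via `minpack.lm::nlsLM`) for completeness: with only
five b-values and none below 50 s/mm² the recovered $D^*$ scatters widely
across noise realisations (a tested, documented instability), so segmented
estimates are the primary output. Default bounds are
$f \in [0, 0.6]$, $D \in [0.05, 4]$, $D^* \in [1, 500]$ µm²/ms, with
initialisation from the segmented fit and $D^*$ started at $10 D$;
non-convergence is flagged on the result rather than raised.

## Estimating f0 and the venous-to-arterial ratio

At 0.55 T, $w_a \approx w_v$ (0.700 vs 0.628), so the inversion is nearly
insensitive to the assumed ratio $r$ and $f_0$ can be estimated robustly;
at 7 T the weights differ by a factor of five and the inversion fans out
with $r$. The package therefore estimates $f_0$ from the low-field data
(`estimate_f0()`, default $r = 4$) and then asks which single $r$ makes the
high-field data consistent with the same $f_0$.

`estimate_venous_arterial_ratio()` performs that reconciliation as a
deterministic grid scan ($r \in [0.5, 10]$, step 0.01 by default), minimising
the summed absolute difference of the $f_0$ estimates at the two fields,
with ties broken toward the smallest $r$. It accepts *paired vectors* of
measured fractions: passing baseline and activated values together demands
one ratio consistent with both states. This matters in practice — the
baseline pair of the reference cohort alone is reconciled at $r \approx 4.9$,
the activated pair at $r \approx 6.1$, and the joint scan at $r \approx 6.0$;
because the low-field estimate barely moves with $r$, a single pair leaves
the objective shallow, and the joint scan is the estimator the package
recommends and uses in its pipeline.

`cross_field_prediction()` chains inverse and forward model to predict what
a cohort measured at one field should show at another. A `long_tr` switch
drops the $T_1$ recovery factor from all weights, for protocols whose TR is
long or unreported — used by `liver_cross_field_check()`, which reproduces
the liver comparison (TE 100 ms, measured $f = 28.6$% at 1.5 T): a marked
predicted field dependence at $r = 4$
($f_{1.5\,\mathrm{T}}/f_{3\,\mathrm{T}} \approx 1.26$) that vanishes at
$r = 1$ ($\approx 1.01$).

`sensitivity_curves()` evaluates the forward model under named fractional
relaxation-time perturbations; `perturbation_presets()` supplies the four
standard scenarios (venous $T_2$ −15%, arterial $T_2$ −50%, muscle $T_2$
+25%, blood $T_2$ −5% with muscle $T_2$ +5%) that bracket the literature
uncertainty.

## The synthetic-study generator

No raw image data can be redistributed, so `simulate_study()` generates
study-shaped datasets with known ground truth for validation:

* **Design**: 8 subjects × 2 fields (0.55 T, 7 T; identical TE 56 ms /
  TR 2800 ms) × 2 muscles (GM, TA) × 2 states × 15 slices; b-values
  0/50/100/500/600 s/mm² with 2/2/2/4/4 magnitude averages — 960 records.
* **Truth**: GM $f_0 = 0.031$ at rest, ×1.94 after activation (to 0.060);
  $D = 1.41$ µm²/ms, ×1.05 after activation. TA is a non-activating control
  at $f_0 = 0.016$, $D = 1.65$ µm²/ms with a nominal 1% activation effect on
  $D$; its truth values are chosen so the forward model lands near the
  reference cohort's TA means. $f_0$ and $r = 4$ are shared across fields —
  only the weights differ — which is the effect the model modules must
  recover. $D^* = 20$ µm²/ms, an order of magnitude above $D$.
* **Inter-subject spread**: lognormal with 20% coefficient of variation on
  $f_0$ and 5% on $D$, drawn once per subject and muscle (mean-preserving
  parameterisation). These CVs are the generator's own choice of a
  physiologically plausible spread; they exist to give the statistics stage
  realistic between-subject variance.
* **Noise**: Rician, applied per voxel and repetition at
  $\sigma = 1/\mathrm{SNR}_{b0}$ (default SNR 35 at $b = 0$), then magnitude
  averaging over repetitions and plain averaging over the 23 ROI voxels —
  the order in which a scanner and an ROI analysis would combine them. The
  Rayleigh-floor estimators `estimate_snr()` and the $\sqrt{N}$ ROI scaling
  `roi_snr()` share this noise model.

What the generator does **not** emulate: image space (no phantom, no EPI
distortions, no fat saturation effects), multi-channel coil noise
statistics (single-coil Rayleigh floor only), slice-to-slice physiological
variation (slice scatter is measurement noise only), and the real study's
unbalanced 7 T design (one leg instead of two; records are balanced for
simpler truth bookkeeping). Passing recovery tests on these data therefore
demonstrates correctness of the estimators under the stated noise model,
not robustness to acquisition artefacts.

## Statistical stage

`paired_compare()` reproduces the inference convention of the field:
Shapiro–Wilk on the paired differences at $\alpha = 0.05$ gates between the
paired t-test and the Wilcoxon signed-rank test, two-sided.
`compare_study()` applies it to every design contrast, treating each slice
of each subject as an observation by default (matching how such cohorts are
usually plotted and tested), with `pooling = "subjects"` as the conservative
alternative — slice-level pooling ignores within-subject correlation and
overstates the effective sample size, a caveat the comparison table cannot
remove. No multiple-testing correction is applied, matching the convention
the stage reproduces. Constant paired differences are a degenerate-input
error: neither test is defined there.

## Numerical choices and edge cases

* Fractions are handled on $[0, 1]$ everywhere inside the package; percent
  appears only at I/O boundaries (fixtures, printed summaries) — avoiding
  silent factor-100 errors.
* $D$ is reported in µm²/ms ($= 10^{-3}$ mm²/s); $b \cdot D$ is formed with
  an explicit $10^{-3}$ conversion so the exponent is dimensionless.
* The ratio scan is a deterministic grid search with documented tie-break
  (smallest $r$), chosen over a continuous optimiser so that results are
  exactly reproducible and the shallow-objective case is handled
  predictably.
* `estimate_snr()` returns a flagged *unmeasurable* result (not an error)
  when both background statistics are zero, as happens on integer-rounded
  images whose noise floor rounds to zero.
* `simulate_study(snr_b0 = Inf)` is supported and yields the noise-free
  pipeline, used to isolate deterministic fit bias in the tests.
* Seeds: every stochastic path (noise machinery, generator, pipeline) is
  reproducible from a single integer seed; identical seeds give
  bit-identical datasets and summary files.

Problem sizes used by the shipped tests: the full default study (960
records) for parameter recovery and effect directions, 200 noise
realisations for fit-recovery bounds, 100 for the $D^*$ instability, $10^6$
draws for the Rayleigh moment checks, and 1000 null simulations for the
type-I calibration of the gated comparison.

## Known limitations

* The model is only as good as the literature relaxation times; blood values
  depend on hematocrit and oxygenation, which vary between individuals. The
  sensitivity presets exist precisely because plausible $T_2$ shifts of a
  few percent visibly move the high-field curves.
* The segmented fit's threshold bias (about −1.3 pp on $f$, −0.6 pp on
  $f_0$ at the default settings) is deterministic and documented rather
  than corrected; correcting it would require trusting a specific $D^*$,
  which these data cannot estimate.
* The two-state ratio scan assumes $f_v/f_a$ is the same at rest and after
  activation; the model cannot test that assumption with two fields only.
* No noise-floor correction is applied to fits; at the study's effective
  ROI SNR the Rician bias on the fitted points is below half a percent of
  the signal.
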
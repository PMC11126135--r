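# ivimfield

Analysis of the magnetic-field-strength dependence of intravoxel incoherent
motion (IVIM) parameters in skeletal muscle.

IVIM diffusion MRI splits the voxel signal into tissue water (diffusion
coefficient *D*) and microvascular blood (pseudo-diffusion *D\**, perfusion
fraction *f*):

    S(b)/S0 = f·exp(−b·D*) + (1−f)·exp(−b·D)

The measured *f* is not a blood volume fraction: each compartment is scaled
by its spin-echo relaxation weight `w = exp(−TE/T2)·(1−exp(−TR/T1))`, and
blood and muscle relaxation times change strongly with the main field B0.
The same calf measured with identical TE/TR at 0.55 T and 7 T therefore
yields roughly a factor-two difference in *f*. This package implements the
three-compartment (muscle / arterial blood / venous blood) model that
explains and removes this dependence:

    f = (f0a·wa + f0v·wv) / (f0a·wa + f0v·wv + (1 − f0)·wm)

with proton-density-weighted fractions `f0 = f0a + f0v` split by the
venous-to-arterial volume ratio `r = fv/fa`, together with everything
around it: segmented IVIM fitting of ROI signal curves, the closed-form
inversion `f → f0`, a cross-field grid scan for `r`, quadratic blood-R2
interpolation across B0, Rayleigh-floor SNR estimators, a seeded
Rician-noise study simulator with ground truth, and normality-gated paired
statistics. It is intended for quantitative-MRI researchers comparing or
harmonising IVIM perfusion fractions across field strengths.

## Worked example

```r
library(ivimfield)
protocol <- sequence_protocol()                 # TE 56 ms, TR 2800 ms, b = 0-600
w055 <- compartment_weights(relaxation_times("calf_0.55T"), protocol)
w7   <- compartment_weights(relaxation_times("calf_7T"), protocol)
w055; w7
#> Compartment weights: arterial 0.7001, venous 0.6285, muscle 0.2749
#> Compartment weights: arterial 0.2196, venous 0.0449, muscle 0.0610
```

At 0.55 T arterial and venous blood are weighted almost equally and about
2.3× more than muscle — measured *f* overstates the blood fraction. At 7 T
venous blood is weighted *below* muscle and the signal is artery-dominated.
Inverting the model at 0.55 T (ratio 4) for the cohort-mean measured
fractions, 7.59 % at rest and 14.03 % after exercise:

```r
round(100 * estimate_f0(c(0.0759, 0.1403)), 2)
#> [1] 3.39 6.52
```

i.e. proton-density-weighted perfusion fractions of ≈3.4 % and ≈6.5 %.
Requiring one f0 per state to be consistent across both fields pins down
the venous-to-arterial volume ratio:

```r
estimate_venous_arterial_ratio(
  f_low = c(0.0708, 0.1340), f_high = c(0.0384, 0.0707),
  relax_low = relaxation_times("calf_0.55T"),
  relax_high = relaxation_times("calf_7T"), protocol = protocol)
#> Venous-to-arterial ratio scan: fv/fa = 6.05
#>   f0 (low field):  0.0318, 0.0624
#>   f0 (high field): 0.0338, 0.0624
```

The same machinery predicts cross-field behaviour in other organs; for the
liver comparison (TE 100 ms, long-TR limit, f = 28.6 % at 1.5 T) a ratio of
4 predicts a visible field effect while equal volumes predict none:

```r
liver_cross_field_check()
#>   ratio_v_a         f0  f_target f_ref_over_f_target f_target_over_f_ref
#> 1         4 0.07909357 0.2272991           1.2582538           0.7947522
#> 2         1 0.07487912 0.2891441           0.9891262           1.0109934
```

Synthetic data with known truth closes the loop — note the documented
segmented-fit threshold bias (true weighted f here is 0.0696):

```r
b <- c(0, 50, 100, 500, 600)
curve <- simulate_signal_curve(f0 = 0.031, ratio_v_a = 4, d = 1.41,
                               d_star = 20, weights = w055, b_values = b)
segmented_fit(curve)
#> IVIM fit (segmented): D = 1.4348 um^2/ms, f = 0.0567  [3 points]
```

`simulate_study()` scales this to a full seeded cohort (8 subjects × 2
fields × 2 muscles × 2 states × 15 slices) and `run_pipeline()` /
`inst/scripts/ivim_pipeline.R` orchestrate simulate → fit → invert →
ratio scan → sensitivity curves → paired comparisons into a report bundle.

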
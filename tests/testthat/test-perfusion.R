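test_that("forward model: degenerate and weight-cancelling cases", {
  w <- calf_weights()
  expect_equal(forward_perfusion_fraction(0, w, ratio_v_a = 4), 0)
  # equal weights cancel: f = f0 exactly, whatever the ratio
  weq <- weights_manual(0.5, 0.5, 0.5)
  for (r in c(0.5, 1, 4, 9)) {
    expect_equal(forward_perfusion_fraction(0.1234, weq, ratio_v_a = r),
                 0.1234)
  }
  expect_error(perfusion_state(1, 4), "\\[0, 1\\)")
  expect_error(perfusion_state(0.1, -2), "positive")
})

test_that("forward model reproduces the measured 0.55 T perfusion fraction", {
  w <- calf_weights()
  f <- forward_perfusion_fraction(0.0339, w, ratio_v_a = 4)
  expect_equal(f, 0.0759, tolerance = 2e-3)
  expect_equal(f, oracle_forward(0.0339, 4, w), tolerance = 1e-14)
})

test_that("closed-form inversion matches root finding and the reference estimates", {
  w <- calf_weights()
  expect_equal(invert_perfusion_fraction(0, 4, w), 0)
  # independent route: numeric inversion of the forward model
  for (f in c(0.01, 0.0759, 0.1403, 0.3)) {
    expect_equal(invert_perfusion_fraction(f, 4, w),
                 oracle_invert(f, 4, w), tolerance = 1e-10)
  }
  f0 <- invert_perfusion_fraction(c(0.0759, 0.1403), 4, w)
  expect_gte(f0[1], 0.0337)
  expect_lte(f0[1], 0.0340)
  # closed form gives 0.065240; the printed reference value is 6.50%
  expect_equal(f0[2], 0.065240, tolerance = 1e-5)
  expect_lt(abs(100 * f0[2] - 6.50), 0.05)
  expect_error(invert_perfusion_fraction(1, 4, w), "\\[0, 1\\)")
  expect_error(invert_perfusion_fraction(-0.1, 4, w), "\\[0, 1\\)")
})

test_that("forward/inverse round-trip holds to 1e-12 and both maps are monotone", {
  for (wset in list(calf_weights(), calf_weights("calf_7T"),
                    weights_manual(0.9, 0.2, 0.5))) {
    for (r in c(0.5, 1, 2, 4, 10)) {
      f0 <- seq(0, 0.49, by = 0.07)
      f <- forward_perfusion_fraction(f0, wset, ratio_v_a = r)
      expect_equal(invert_perfusion_fraction(f, r, wset), f0,
                   tolerance = 1e-12)
      expect_true(all(diff(f) > 0))
      expect_true(all(diff(invert_perfusion_fraction(
        seq(0, 0.9, by = 0.1), r, wset)) > 0))
    }
  }
})

test_that("three-pool forward with equal blood weights reduces to the two-pool form", {
  p <- default_protocol()
  wb <- compartment_weight(1122, 148, p)
  wm <- compartment_weight(701, 44, p)
  w <- weights_manual(wb, wb, wm)
  for (f0 in c(0, 0.02, 0.1, 0.4)) {
    two_pool <- f0 * wb / (f0 * wb + (1 - f0) * wm)
    for (r in c(0.5, 3, 8)) {
      expect_equal(forward_perfusion_fraction(f0, w, ratio_v_a = r),
                   two_pool, tolerance = 1e-14)
    }
  }
})

test_that("arterial and venous sub-fractions always add to the total exactly", {
  for (r in c(0.3, 1, 4, 6.5, 10)) {
    st <- perfusion_state(0.0735, r)
    expect_identical(st$f0_arterial + st$f0_venous, st$f0_total)
  }
})

test_that("ratio scan: degenerate, self-consistent and reference cases", {
  p <- default_protocol()
  r055 <- relaxation_times("calf_0.55T")
  r7 <- relaxation_times("calf_7T")
  # identical inputs: objective vanishes everywhere, smallest r returned
  deg <- estimate_venous_arterial_ratio(0.05, 0.05, r055, r055, p,
                                        grid = seq(2, 5, 0.5))
  expect_equal(deg$ratio, 2)
  expect_error(
    estimate_venous_arterial_ratio(0.05, 0.04, r055, r7, p,
                                   grid = numeric(0)), "grid")
  expect_error(
    estimate_venous_arterial_ratio(c(0.05, 0.06), 0.04, r055, r7, p),
    "paired")

  # noise-free self-consistency: data generated at known r = 3 recovers 3.00
  w_lo <- compartment_weights(r055, p)
  w_hi <- compartment_weights(r7, p)
  f_lo <- forward_perfusion_fraction(0.031, w_lo, ratio_v_a = 3)
  f_hi <- forward_perfusion_fraction(0.031, w_hi, ratio_v_a = 3)
  rec <- estimate_venous_arterial_ratio(f_lo, f_hi, r055, r7, p)
  expect_equal(rec$ratio, 3, tolerance = 0.01)

  # reference slice means: one state alone pins the ratio poorly (4.91);
  # requiring one f0 per state across both states lands near six
  single <- estimate_venous_arterial_ratio(0.0708, 0.0384, r055, r7, p)
  expect_equal(single$ratio, 4.91, tolerance = 1e-8)
  joint <- estimate_venous_arterial_ratio(
    c(0.0708, 0.1340), c(0.0384, 0.0707), r055, r7, p)
  expect_equal(joint$ratio, 6.05, tolerance = 1e-8)
})

test_that("cross-field prediction is exact under identical conditions and matches the liver figures", {
  p <- default_protocol()
  r055 <- relaxation_times("calf_0.55T")
  same <- cross_field_prediction(0.07, r055, r055, 4, p)
  expect_equal(same$ratio_f, 1)
  liver <- liver_cross_field_check()
  expect_equal(liver$f_ref_over_f_target[liver$ratio_v_a == 4], 1.2583,
               tolerance = 1e-3)
  expect_equal(liver$f_target_over_f_ref[liver$ratio_v_a == 1], 1.0110,
               tolerance = 1e-3)
})

test_that("sensitivity curves: shape, monotonicity and field-strength spread", {
  p <- default_protocol()
  r7 <- relaxation_times("calf_7T")
  r055 <- relaxation_times("calf_0.55T")
  f0g <- seq(0, 0.12, by = 0.01)

  plain <- sensitivity_curves(f0g, 4, r7, p)
  expect_equal(unique(plain$perturbation_label), "unperturbed")
  expect_true(all(diff(plain$f) > 0))

  fam <- sensitivity_curves(f0g, 4, r7, p, perturbation_presets())
  expect_setequal(unique(fam$perturbation_label),
                  c("unperturbed", names(perturbation_presets())))
  for (lbl in unique(fam$perturbation_label)) {
    expect_true(all(diff(fam$f[fam$perturbation_label == lbl]) > 0))
  }

  # the ratio family separates far more at 7 T than at 0.55 T
  spread_at <- function(relax) {
    fs <- vapply(2:6, function(r) {
      sensitivity_curves(0.03, r, relax, p)$f
    }, numeric(1))
    (max(fs) - min(fs)) / mean(fs)
  }
  expect_gt(spread_at(r7), 2 * spread_at(r055))

  expect_error(sensitivity_curves(f0g, 4, r7, p,
                                  list(bad = list(t2_venous = -1.5))),
               "> -1")
  expect_error(sensitivity_curves(c(-0.1, 0.5), 4, r7, p), "\\[0, 1\\)")
})
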
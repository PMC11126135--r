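test_that("noise-free curve synthesis honours normalization and degenerate truths", {
  w <- calf_weights()
  b <- c(0, 50, 100, 500, 600)
  cv <- simulate_signal_curve(0.031, 4, 1.41, 20, w, b)
  expect_equal(cv$signals[1], 1)
  expect_true(cv$normalized)
  # f0 = 0 collapses to a pure monoexponential in D
  mono <- simulate_signal_curve(0, 4, 1.41, 20, w, b)
  expect_equal(mono$signals, exp(-b * 1.41e-3), tolerance = 1e-14)
  expect_error(simulate_signal_curve(0.03, 4, 1.41, 1.41, w, b), "exceed")
})

test_that("segmented fit of a synthesized curve lands near the weighted truth", {
  w <- calf_weights()
  b <- c(0, 50, 100, 500, 600)
  cv <- simulate_signal_curve(0.031, 4, 1.41, 20, w, b)
  f_true <- forward_perfusion_fraction(0.031, w, ratio_v_a = 4)
  expect_equal(f_true, 0.0696, tolerance = 1e-4)
  fit <- segmented_fit(cv)
  # residual pseudo-diffusion signal at b = 100 biases f low, but < 1.5 pp
  expect_lt(abs(fit$f - f_true), 0.015)
  expect_lt(fit$f, f_true)
})

test_that("study simulation has the full factorial cardinality and is seed-reproducible", {
  cfg <- study_config(n_subjects = 2, n_slices = 3, seed = 5L)
  ds <- simulate_study(cfg)
  # 2 subjects x 2 fields x 2 muscles x 2 states x 3 slices
  expect_equal(nrow(ds$truth), 2 * 2 * 2 * 2 * 3)
  expect_equal(nrow(ds$signals), nrow(ds$truth) * 5)
  expect_true(all(table(ds$signals$b_value) == nrow(ds$truth)))
  # every record carries its ground truth
  expect_true(all(c("f0", "ratio_v_a", "d", "d_star", "sigma",
                    "f_weighted") %in% names(ds$truth)))
  expect_identical(simulate_study(cfg)$signals, ds$signals)
  expect_false(identical(
    simulate_study(study_config(n_subjects = 2, n_slices = 3,
                                seed = 6L))$signals$signal,
    ds$signals$signal))
})

test_that("noise-free pipeline closure recovers f0 within the segmented-fit bias bound", {
  # infinite SNR and no inter-subject spread isolates the fit bias
  cfg <- study_config(n_subjects = 1, n_slices = 1, snr_b0 = Inf,
                      cv_f0 = 0, cv_d = 0, seed = 2L)
  ds <- simulate_study(cfg)
  fits <- fit_signal_table(ds$signals)
  for (fld in unique(fits$field_T)) {
    w <- compartment_weights(
      if (fld == 0.55) relaxation_times("calf_0.55T")
      else relaxation_times("calf_7T"),
      default_protocol())
    gm <- fits[fits$muscle == "GM" & fits$state == "baseline" &
                 fits$field_T == fld, ]
    f0_rec <- invert_perfusion_fraction(max(gm$f, 0), 4, w)
    expect_lt(abs(f0_rec - 0.031), 0.015)
  }
})

test_that("simulated records reproduce both headline effect directions", {
  ds <- simulate_study(study_config(n_subjects = 4, n_slices = 6,
                                    seed = 3L))
  fits <- fit_signal_table(ds$signals)
  gm <- fits[fits$muscle == "GM", ]
  key <- function(d) paste(d$subject, d$slice)
  base_lo <- gm[gm$state == "baseline" & gm$field_T == 0.55, ]
  base_hi <- gm[gm$state == "baseline" & gm$field_T == 7, ]
  base_hi <- base_hi[match(key(base_lo), key(base_hi)), ]
  act_lo <- gm[gm$state == "activated" & gm$field_T == 0.55, ]
  act_lo <- act_lo[match(key(base_lo), key(act_lo)), ]
  # measured f drops at the higher field although f0 is identical
  expect_gt(mean(base_hi$f < base_lo$f), 0.95)
  # activation raises measured f at the low field
  expect_gt(mean(act_lo$f > base_lo$f), 0.95)
})

test_that("a simulated study round-trips through disk with its truth sidecar", {
  ds <- simulate_study(study_config(n_subjects = 1, n_slices = 2, seed = 9L))
  dir <- tempfile()
  paths <- write_study(ds, dir)
  expect_true(all(file.exists(paths)))
  back <- read_signal_table(paths["signals"])
  expect_equal(back$signal, ds$signals$signal, tolerance = 1e-12)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$f0, ds$truth$f0, tolerance = 1e-12)
})
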
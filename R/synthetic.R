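#' Configuration of a synthetic two-field IVIM study
#'
#' Describes a simulated cohort mirroring the acquisition design of a paired
#' two-field calf study: 8 subjects, two field strengths (0.55 T and 7 T)
#' with identical sequence timing, two activation states, 15 slices, and two
#' muscles with known ground truth. Defaults encode the study conditions:
#' GM (gastrocnemius medialis) with f0 = 0.031 at rest rising to 0.060 after
#' exercise and D = 1.41 um^2/ms rising by 5%; TA (tibialis anterior) as a
#' non-activating control. The proton-density-weighted truth is shared
#' across fields -- only the relaxation weights differ -- which is exactly
#' the mechanism the model modules are meant to recover.
#'
#' @param n_subjects Number of subjects (default 8).
#' @param fields List of field entries, each `list(label, relax, protocol)`;
#'   defaults to the packaged 0.55 T and 7 T calf sets with the default
#'   protocol.
#' @param n_slices Slices per acquisition (default 15).
#' @param muscles Named list of per-muscle truth:
#'   `list(f0_total, ratio_v_a, d, activation_f0, activation_d)` with `d` in
#'   um^2/ms and the activation entries as multiplicative state effects.
#' @param d_star Pseudo-diffusion coefficient in um^2/ms (default 20, an
#'   order of magnitude above D; the vascular signal it controls is almost
#'   fully suppressed at the fitted b-values).
#' @param snr_b0 Single-voxel SNR at b = 0 (default 35); sets the Rician
#'   noise level sigma = 1/snr_b0 per voxel and repetition.
#' @param n_roi_voxels Voxels averaged into each ROI mean (default 23).
#' @param cv_f0,cv_d Lognormal inter-subject coefficients of variation on f0
#'   and D (defaults 0.20 and 0.05).
#' @param seed Integer RNG seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_subjects = 8,
                         fields = NULL,
                         n_slices = 15,
                         muscles = list(
                           GM = list(f0_total = 0.031, ratio_v_a = 4,
                                     d = 1.41, activation_f0 = 0.060 / 0.031,
                                     activation_d = 1.05),
                           TA = list(f0_total = 0.016, ratio_v_a = 4,
                                     d = 1.65, activation_f0 = 1,
                                     activation_d = 1.01)
                         ),
                         d_star = 20,
                         snr_b0 = 35,
                         n_roi_voxels = 23,
                         cv_f0 = 0.20,
                         cv_d = 0.05,
                         seed = 1L) {
  if (is.null(fields)) {
    p <- sequence_protocol()
    fields <- list(
      list(label = "0.55T", relax = relaxation_times("calf_0.55T"),
           protocol = p),
      list(label = "7T", relax = relaxation_times("calf_7T"), protocol = p)
    )
  }
  stopifnot(n_subjects >= 1, n_slices >= 1, length(muscles) >= 1,
            d_star > 0, snr_b0 > 0, n_roi_voxels >= 1,
            cv_f0 >= 0, cv_d >= 0)
  for (fld in fields) {
    stopifnot(inherits(fld$relax, "relaxation_set"),
              inherits(fld$protocol, "ivim_protocol"))
  }
  for (m in muscles) {
    stopifnot(m$f0_total >= 0, m$f0_total < 1, m$ratio_v_a > 0, m$d > 0,
              m$activation_f0 > 0, m$activation_d > 0,
              d_star > m$d * m$activation_d)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), fields = fields,
         n_slices = as.integer(n_slices), muscles = muscles,
         d_star = d_star, snr_b0 = snr_b0,
         n_roi_voxels = as.integer(n_roi_voxels),
         cv_f0 = cv_f0, cv_d = cv_d, seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Noise-free three-compartment IVIM signal curve
#'
#' Synthesizes the ROI signal of the three-compartment voxel model: the
#' arterial and venous blood pools decay with the pseudo-diffusion
#' coefficient D* and the muscle pool with D, each scaled by its
#' proton-density fraction and relaxation weight,
#' \deqn{S(b) \propto f_{0,a} w_a e^{-bD^*} + f_{0,v} w_v e^{-bD^*}
#'       + (1 - f_0) w_m e^{-bD},}
#' normalized to b = 0. By construction the curve's relaxation-weighted
#' perfusion fraction equals [forward_perfusion_fraction()] of the truth.
#'
#' @param f0 Proton-density-weighted perfusion fraction in [0, 1).
#' @param ratio_v_a Venous-to-arterial ratio.
#' @param d Tissue diffusion coefficient in um^2/ms.
#' @param d_star Pseudo-diffusion coefficient in um^2/ms; must exceed `d`.
#' @param weights A `compartment_weights` object.
#' @param b_values b-values in s/mm^2 (must include 0).
#' @return A normalized [signal_curve()].
#' @examples
#' w <- compartment_weights(relaxation_times("calf_0.55T"),
#'                          sequence_protocol())
#' simulate_signal_curve(0.031, 4, 1.41, 20, w, c(0, 50, 100, 500, 600))
#' @export
simulate_signal_curve <- function(f0, ratio_v_a, d, d_star, weights,
                                  b_values) {
  if (d_star <= d) stop("`d_star` must exceed `d`", call. = FALSE)
  state <- perfusion_state(f0, ratio_v_a)
  a_blood <- state$f0_arterial * weights$w_arterial +
    state$f0_venous * weights$w_venous
  a_muscle <- (1 - f0) * weights$w_muscle
  s <- a_blood * exp(-b_values * d_star * 1e-3) +
    a_muscle * exp(-b_values * d * 1e-3)
  signal_curve(b_values, s / s[b_values == 0][1], normalized = TRUE)
}

#' Simulate a complete two-field study with known ground truth
#'
#' Generates the full factorial dataset of a synthetic cohort: for every
#' subject and muscle, subject-level truth (f0, D) is drawn from lognormal
#' inter-subject distributions; for every field, state and slice a
#' noise-free voxel signal is synthesized from the three-compartment model,
#' Rician noise at sigma = 1/snr_b0 is applied independently per voxel and
#' repetition, repetitions are magnitude-averaged per b-value, and the
#' resulting voxel magnitudes are averaged over the ROI. Fully reproducible
#' under the configured seed.
#'
#' @param config A [study_config()].
#' @return An object of class `study_dataset`: a list with `signals` (long
#'   data.frame: subject, field_T, field_label, muscle, state, slice,
#'   b_value, signal), `truth` (one row per record with f0, ratio_v_a, d,
#'   d_star, sigma, f_weighted -- the relaxation-weighted perfusion fraction
#'   the record should fit to), and the generating `config`.
#' @examples
#' ds <- simulate_study(study_config(n_subjects = 2, n_slices = 2))
#' nrow(ds$truth)  # 2 subjects x 2 fields x 2 muscles x 2 states x 2 slices
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  sigma <- 1 / config$snr_b0
  sdlog_f0 <- sqrt(log(1 + config$cv_f0^2))
  sdlog_d <- sqrt(log(1 + config$cv_d^2))

  # subject-level truth, shared across fields and states
  subj_truth <- list()
  for (subj in seq_len(config$n_subjects)) {
    for (mus in names(config$muscles)) {
      m <- config$muscles[[mus]]
      f0_s <- m$f0_total *
        stats::rlnorm(1, meanlog = -sdlog_f0^2 / 2, sdlog = sdlog_f0)
      d_s <- m$d * stats::rlnorm(1, meanlog = -sdlog_d^2 / 2, sdlog = sdlog_d)
      subj_truth[[paste(subj, mus, sep = "\r")]] <- list(f0 = f0_s, d = d_s)
    }
  }

  states <- c("baseline", "activated")
  sig_rows <- list()
  truth_rows <- list()
  k <- 0L
  for (fld in config$fields) {
    w <- compartment_weights(fld$relax, fld$protocol)
    b <- fld$protocol$b_values
    reps <- fld$protocol$averages
    for (subj in seq_len(config$n_subjects)) {
      for (mus in names(config$muscles)) {
        m <- config$muscles[[mus]]
        st <- subj_truth[[paste(subj, mus, sep = "\r")]]
        for (state in states) {
          f0_rec <- st$f0 * if (state == "activated") m$activation_f0 else 1
          d_rec <- st$d * if (state == "activated") m$activation_d else 1
          f0_rec <- min(f0_rec, 0.999)
          clean <- simulate_signal_curve(f0_rec, m$ratio_v_a, d_rec,
                                         config$d_star, w, b)$signals
          for (slice in seq_len(config$n_slices)) {
            roi <- vapply(seq_along(b), function(i) {
              # n_roi voxels x reps[i] repetitions, magnitude-averaged per
              # voxel then averaged over the ROI
              draws <- matrix(
                add_rician_noise(
                  rep(clean[i], config$n_roi_voxels * reps[i]), sigma),
                nrow = config$n_roi_voxels)
              mean(rowMeans(draws))
            }, numeric(1))
            k <- k + 1L
            sig_rows[[k]] <- data.frame(
              subject = subj, field_T = fld$relax$field_strength,
              field_label = fld$label, muscle = mus, state = state,
              slice = slice, b_value = b, signal = roi,
              stringsAsFactors = FALSE)
            truth_rows[[k]] <- data.frame(
              subject = subj, field_T = fld$relax$field_strength,
              field_label = fld$label, muscle = mus, state = state,
              slice = slice, f0 = f0_rec, ratio_v_a = m$ratio_v_a,
              d = d_rec, d_star = config$d_star, sigma = sigma,
              f_weighted = forward_perfusion_fraction(
                f0_rec, w, ratio_v_a = m$ratio_v_a),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  structure(
    list(signals = do.call(rbind, sig_rows),
         truth = do.call(rbind, truth_rows),
         config = config),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic IVIM study: %d records (%d subjects, %d fields, %d muscles, 2 states, %d slices), seed %d\n",
    nrow(x$truth), x$config$n_subjects, length(x$config$fields),
    length(x$config$muscles), x$config$n_slices, x$config$seed))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits the signal table in the same tab-delimited format
#' [read_signal_table()] consumes, plus a JSON ground-truth sidecar keyed
#' identically.
#'
#' @param dataset A `study_dataset` from [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return The paths written, invisibly.
#' @export
write_study <- function(dataset, dir) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sig_path <- file.path(dir, "signals.tsv")
  truth_path <- file.path(dir, "truth.json")
  write_signal_table(dataset$signals, sig_path)
  jsonlite::write_json(dataset$truth, truth_path, digits = NA,
                       dataframe = "rows")
  invisible(c(signals = sig_path, truth = truth_path))
}
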
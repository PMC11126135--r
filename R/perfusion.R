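#' Proton-density-weighted perfusion state of a voxel
#'
#' Describes the vascular content of the voxel free of relaxation weighting:
#' the total proton-density-weighted perfusion fraction `f0_total` and the
#' venous-to-arterial volume ratio `ratio_v_a` = fv/fa. The arterial and
#' venous sub-fractions are derived so that they add to the total exactly:
#' f0_arterial = f0/(1 + r), f0_venous = r f0/(1 + r).
#'
#' @param f0_total Proton-density-weighted perfusion fraction, in [0, 1)
#'   (vectorised).
#' @param ratio_v_a Venous-to-arterial blood volume ratio fv/fa, positive.
#' @return An object of class `perfusion_state`.
#' @examples
#' perfusion_state(0.031, ratio_v_a = 4)
#' @export
perfusion_state <- function(f0_total, ratio_v_a) {
  if (any(!is.finite(f0_total)) || any(f0_total < 0) || any(f0_total >= 1)) {
    stop("`f0_total` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(ratio_v_a) || length(ratio_v_a) != 1L ||
      !is.finite(ratio_v_a) || ratio_v_a <= 0) {
    stop("`ratio_v_a` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      f0_total = as.numeric(f0_total),
      ratio_v_a = ratio_v_a,
      f0_arterial = f0_total / (1 + ratio_v_a),
      # as the complement of the arterial part, so the two sub-fractions
      # add to the total exactly in floating point
      f0_venous = f0_total - f0_total / (1 + ratio_v_a)
    ),
    class = "perfusion_state"
  )
}

#' @export
print.perfusion_state <- function(x, ...) {
  cat(sprintf(
    "Perfusion state: f0 = %s (arterial %s + venous %s), fv/fa = %g\n",
    paste(signif(x$f0_total, 4), collapse = ", "),
    paste(signif(x$f0_arterial, 4), collapse = ", "),
    paste(signif(x$f0_venous, 4), collapse = ", "),
    x$ratio_v_a))
  invisible(x)
}

as_perfusion_state <- function(x, ratio_v_a) {
  if (inherits(x, "perfusion_state")) x else perfusion_state(x, ratio_v_a)
}

#' Relaxation-weighted perfusion fraction (forward model)
#'
#' Maps a proton-density-weighted perfusion state to the perfusion fraction
#' that an IVIM experiment measures, by weighting each compartment's proton
#' density with its spin-echo relaxation weight:
#' \deqn{f = \frac{f_{0,a} w_a + f_{0,v} w_v}
#'            {f_{0,a} w_a + f_{0,v} w_v + (1 - f_{0,a} - f_{0,v}) w_m}.}
#' With equal blood weights (\eqn{w_a = w_v = w_b}) this reduces to the
#' two-pool form \eqn{f = f_0 w_b / (f_0 w_b + (1 - f_0) w_m)}.
#'
#' @param state A [perfusion_state()], or a numeric vector of `f0_total`
#'   values (then `ratio_v_a` must be given).
#' @param weights A `compartment_weights` object, from
#'   [compartment_weights()] or [weights_manual()].
#' @param ratio_v_a Venous-to-arterial ratio, used only when `state` is
#'   numeric.
#' @return Measured perfusion fraction(s) in [0, 1).
#' @examples
#' w055 <- compartment_weights(relaxation_times("calf_0.55T"),
#'                             sequence_protocol())
#' forward_perfusion_fraction(0.031, w055, ratio_v_a = 4)  # ~0.0696
#' @seealso [invert_perfusion_fraction()] for the closed-form inverse.
#' @export
forward_perfusion_fraction <- function(state, weights, ratio_v_a = NULL) {
  stopifnot(inherits(weights, "compartment_weights"))
  if (!inherits(state, "perfusion_state")) {
    if (is.null(ratio_v_a)) {
      stop("give `ratio_v_a` when `state` is a plain numeric f0",
           call. = FALSE)
    }
    state <- perfusion_state(state, ratio_v_a)
  }
  blood <- state$f0_arterial * weights$w_arterial +
    state$f0_venous * weights$w_venous
  blood / (blood + (1 - state$f0_total) * weights$w_muscle)
}

#' Proton-density-weighted perfusion fraction (inverse model)
#'
#' Closed-form inverse of [forward_perfusion_fraction()]: given the measured
#' (relaxation-weighted) perfusion fraction `f` and an assumed
#' venous-to-arterial ratio, returns the proton-density-weighted fraction
#' \deqn{f_0 = \frac{f\,w_m}{w_{\mathrm{eff}}(1 - f) + f\,w_m}, \qquad
#'       w_{\mathrm{eff}} = \frac{w_a + r\,w_v}{1 + r}.}
#'
#' @param f Measured perfusion fraction(s), each in [0, 1).
#' @param ratio_v_a Venous-to-arterial blood volume ratio (positive).
#' @param weights A `compartment_weights` object.
#' @return f0 value(s) in [0, 1).
#' @examples
#' w055 <- compartment_weights(relaxation_times("calf_0.55T"),
#'                             sequence_protocol())
#' invert_perfusion_fraction(c(0.0759, 0.1403), 4, w055)  # ~0.0339, 0.0652
#' @export
invert_perfusion_fraction <- function(f, ratio_v_a, weights) {
  stopifnot(inherits(weights, "compartment_weights"))
  if (any(!is.finite(f)) || any(f < 0) || any(f >= 1)) {
    stop("`f` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(ratio_v_a) || length(ratio_v_a) != 1L ||
      !is.finite(ratio_v_a) || ratio_v_a <= 0) {
    stop("`ratio_v_a` must be a single positive number", call. = FALSE)
  }
  w_eff <- (weights$w_arterial + ratio_v_a * weights$w_venous) /
    (1 + ratio_v_a)
  f * weights$w_muscle / (w_eff * (1 - f) + f * weights$w_muscle)
}

#' Estimate the venous-to-arterial volume ratio from two field strengths
#'
#' The proton-density-weighted perfusion fraction f0 is a property of the
#' tissue and must not depend on B0, whereas the measured fraction f does,
#' through the compartment relaxation weights. Given measured fractions at a
#' lower and a higher field, this scans a grid of candidate ratios r = fv/fa
#' and returns the one that makes the two f0 estimates agree best
#' (minimising the summed absolute difference across paired measurements;
#' ties broken by the smallest r).
#'
#' `f_low` and `f_high` may be vectors of paired conditions (for example
#' baseline and activated state); a single consistent ratio is then sought
#' across all pairs, which pins the ratio down much better than a single
#' pair when the low-field weights make f0 nearly ratio-independent.
#'
#' @param f_low,f_high Measured perfusion fractions at the lower / higher
#'   field, each in [0, 1); equal lengths.
#' @param relax_low,relax_high [relaxation_set()]s for the two fields.
#' @param protocol A [sequence_protocol()]; shared by both fields.
#' @param grid Candidate ratio values (positive, non-empty).
#' @return A list of class `ratio_scan`: `ratio` (the estimate), `grid`,
#'   `objective` (summed |f0_low - f0_high| per grid value), and the per-pair
#'   f0 estimates at the optimum.
#' @examples
#' p <- sequence_protocol()
#' estimate_venous_arterial_ratio(
#'   f_low = c(0.0708, 0.1340), f_high = c(0.0384, 0.0707),
#'   relax_low = relaxation_times("calf_0.55T"),
#'   relax_high = relaxation_times("calf_7T"), protocol = p)
#' @export
estimate_venous_arterial_ratio <- function(f_low, f_high,
                                           relax_low, relax_high,
                                           protocol,
                                           grid = seq(0.5, 10, by = 0.01)) {
  if (length(grid) == 0L || any(!is.finite(grid)) || any(grid <= 0)) {
    stop("`grid` must be a non-empty vector of positive ratios",
         call. = FALSE)
  }
  if (length(f_low) != length(f_high)) {
    stop("`f_low` and `f_high` must be paired (equal lengths)",
         call. = FALSE)
  }
  w_low <- compartment_weights(relax_low, protocol)
  w_high <- compartment_weights(relax_high, protocol)
  objective <- vapply(grid, function(r) {
    sum(abs(invert_perfusion_fraction(f_low, r, w_low) -
              invert_perfusion_fraction(f_high, r, w_high)))
  }, numeric(1))
  best <- which.min(objective)  # which.min takes the first, i.e. smallest r
  r <- grid[best]
  structure(
    list(
      ratio = r,
      grid = grid,
      objective = objective,
      f0_low = invert_perfusion_fraction(f_low, r, w_low),
      f0_high = invert_perfusion_fraction(f_high, r, w_high)
    ),
    class = "ratio_scan"
  )
}

#' @export
print.ratio_scan <- function(x, ...) {
  cat(sprintf("Venous-to-arterial ratio scan: fv/fa = %.2f\n", x$ratio))
  cat(sprintf("  f0 (low field):  %s\n",
              paste(sprintf("%.4f", x$f0_low), collapse = ", ")))
  cat(sprintf("  f0 (high field): %s\n",
              paste(sprintf("%.4f", x$f0_high), collapse = ", ")))
  invisible(x)
}

#' Predict the perfusion fraction at another field strength
#'
#' Inverts the three-pool model at a reference field to obtain f0, then
#' applies the forward model at a target field with the same f0 and
#' venous-to-arterial ratio. Useful for asking what a study performed at one
#' B0 should have measured at another, all else equal.
#'
#' @param f_ref Measured perfusion fraction at the reference field, in
#'   [0, 1).
#' @param relax_ref,relax_target [relaxation_set()]s at the two fields.
#' @param ratio_v_a Venous-to-arterial ratio assumed identical at both
#'   fields.
#' @param protocol_ref A [sequence_protocol()] for the reference field.
#' @param protocol_target Protocol at the target field; defaults to
#'   `protocol_ref`.
#' @param long_tr If `TRUE`, drop the T1 recovery factor from all weights
#'   (full relaxation between excitations); use when the repetition time is
#'   long or unknown.
#' @return A list with `f0`, `f_target`, and `ratio_f` = f_ref / f_target.
#' @examples
#' # liver at TE = 100 ms in the long-TR limit
#' p <- sequence_protocol(te = 100, tr = 1e6, b_values = c(0, 800),
#'                        averages = c(1, 1))
#' cross_field_prediction(0.286, relaxation_times("liver_1.5T"),
#'                        relaxation_times("liver_3T"), ratio_v_a = 4,
#'                        protocol_ref = p, long_tr = TRUE)
#' @export
cross_field_prediction <- function(f_ref, relax_ref, relax_target, ratio_v_a,
                                   protocol_ref,
                                   protocol_target = protocol_ref,
                                   long_tr = FALSE) {
  w_ref <- compartment_weights(relax_ref, protocol_ref, long_tr = long_tr)
  w_target <- compartment_weights(relax_target, protocol_target,
                                  long_tr = long_tr)
  f0 <- invert_perfusion_fraction(f_ref, ratio_v_a, w_ref)
  f_target <- forward_perfusion_fraction(f0, w_target,
                                         ratio_v_a = ratio_v_a)
  list(f0 = f0, f_target = f_target, ratio_f = f_ref / f_target)
}

#' Named relaxation-time perturbation presets
#'
#' Fractional relaxation-time changes that bracket the uncertainty of the
#' literature values entering the model: shortened venous T2 (-15%), halved
#' arterial T2, lengthened muscle T2 (+25%), and a combined small shift of
#' blood T2 (-5%) with muscle T2 (+5%).
#'
#' @return A named list of perturbation lists usable as the `perturbations`
#'   argument of [sensitivity_curves()].
#' @export
perturbation_presets <- function() {
  list(
    "venous T2 -15%" = list(t2_venous = -0.15),
    "arterial T2 -50%" = list(t2_arterial = -0.50),
    "muscle T2 +25%" = list(t2_muscle = 0.25),
    "blood T2 -5%, muscle T2 +5%" = list(t2_venous = -0.05,
                                         t2_arterial = -0.05,
                                         t2_muscle = 0.05)
  )
}

#' Sensitivity of the forward model to relaxation-time uncertainty
#'
#' Evaluates the forward perfusion-fraction model on a grid of f0 values for
#' the unperturbed relaxation set and for each named fractional perturbation,
#' yielding one f-versus-f0 curve per setting. Weights are recomputed from
#' the perturbed times for every curve.
#'
#' @param f0_grid f0 values in [0, 1) at which to evaluate each curve.
#' @param ratio_v_a Venous-to-arterial ratio (scalar or vector; one curve
#'   family member per value).
#' @param relax A [relaxation_set()].
#' @param protocol A [sequence_protocol()].
#' @param perturbations Named list of perturbation lists as produced by
#'   [perturbation_presets()]; may be empty for the unperturbed curve only.
#' @return A data.frame with columns `perturbation_label`, `ratio_v_a`,
#'   `f0`, `f`.
#' @examples
#' sc <- sensitivity_curves(seq(0, 0.1, 0.01), 4,
#'                          relaxation_times("calf_7T"), sequence_protocol(),
#'                          perturbation_presets())
#' head(sc)
#' @export
sensitivity_curves <- function(f0_grid, ratio_v_a, relax, protocol,
                               perturbations = list()) {
  if (any(!is.finite(f0_grid)) || any(f0_grid < 0) || any(f0_grid >= 1)) {
    stop("`f0_grid` values must lie in [0, 1)", call. = FALSE)
  }
  settings <- c(list("unperturbed" = list()), perturbations)
  out <- lapply(names(settings), function(lbl) {
    pert <- settings[[lbl]]
    rel <- do.call(perturb_relaxation, c(list(relax), pert))
    w <- compartment_weights(rel, protocol)
    do.call(rbind, lapply(ratio_v_a, function(r) {
      data.frame(
        perturbation_label = lbl,
        ratio_v_a = r,
        f0 = f0_grid,
        f = forward_perfusion_fraction(f0_grid, w, ratio_v_a = r),
        stringsAsFactors = FALSE
      )
    }))
  })
  do.call(rbind, out)
}
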
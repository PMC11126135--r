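#' ROI-mean diffusion-weighted signal curve
#'
#' One signal-versus-b curve, the unit of IVIM fitting: typically the mean
#' magnitude signal of a muscle ROI at each acquired b-value.
#'
#' @param b_values Diffusion weightings in s/mm^2, strictly increasing.
#' @param signals Positive ROI-mean signal magnitudes, one per b-value
#'   (arbitrary units unless normalized).
#' @param normalized Whether the signal has already been divided by the
#'   b = 0 value (then the first signal must equal 1).
#' @param n_voxels Optional number of voxels averaged into the ROI mean.
#' @return An object of class `signal_curve`.
#' @export
signal_curve <- function(b_values, signals, normalized = FALSE,
                         n_voxels = NULL) {
  b_values <- as.numeric(b_values)
  signals <- as.numeric(signals)
  if (length(b_values) != length(signals)) {
    stop("`b_values` and `signals` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(b_values)) || any(b_values < 0) ||
      is.unsorted(b_values, strictly = TRUE)) {
    stop("`b_values` must be non-negative and strictly increasing",
         call. = FALSE)
  }
  if (any(!is.finite(signals)) || any(signals <= 0)) {
    stop("`signals` must be positive", call. = FALSE)
  }
  if (normalized && abs(signals[1L] - 1) > 1e-8) {
    stop("a normalized curve must have signal 1 at its smallest b-value",
         call. = FALSE)
  }
  structure(
    list(b_values = b_values, signals = signals, normalized = normalized,
         n_voxels = n_voxels),
    class = "signal_curve"
  )
}

#' @export
print.signal_curve <- function(x, ...) {
  cat(sprintf("Signal curve (%s, %d b-values)\n",
              if (x$normalized) "normalized" else "raw", length(x$b_values)))
  print(data.frame(b = x$b_values, signal = signif(x$signals, 5)))
  invisible(x)
}

#' Normalize a signal curve to its b = 0 value
#'
#' Divides all signals by the b = 0 s/mm^2 signal, the convention under
#' which the IVIM model equations are written. Idempotent.
#'
#' @param raw A [signal_curve()] containing a b = 0 entry.
#' @return The normalized `signal_curve`.
#' @export
normalize_roi_signals <- function(raw) {
  stopifnot(inherits(raw, "signal_curve"))
  i0 <- which(raw$b_values == 0)
  if (length(i0) != 1L) {
    stop("curve has no b = 0 entry to normalize to", call. = FALSE)
  }
  s0 <- raw$signals[i0]
  if (!is.finite(s0) || s0 <= 0) {
    stop("non-positive signal at b = 0", call. = FALSE)
  }
  signal_curve(raw$b_values, raw$signals / s0, normalized = TRUE,
               n_voxels = raw$n_voxels)
}

new_ivim_fit <- function(d, f, f_linear, intercept_log, n_points_used,
                         method, d_star = NA_real_, s0 = NA_real_,
                         converged = NA) {
  structure(
    list(d = d, f = f, f_linear = f_linear, intercept_log = intercept_log,
         n_points_used = n_points_used, method = method, d_star = d_star,
         s0 = s0, converged = converged),
    class = "ivim_fit"
  )
}

#' @export
print.ivim_fit <- function(x, ...) {
  cat(sprintf("IVIM fit (%s): D = %.4f um^2/ms, f = %.4f", x$method, x$d,
              x$f))
  if (is.finite(x$d_star)) cat(sprintf(", D* = %.2f um^2/ms", x$d_star))
  cat(sprintf("  [%d points]\n", x$n_points_used))
  invisible(x)
}

#' Segmented IVIM fit of a signal curve
#'
#' First step of the segmented IVIM approach: ordinary least squares of
#' \eqn{\ln(S_b/S_0)} against b over the points with b at or above the
#' threshold, where the pseudo-diffusion compartment has decayed away. The
#' tissue diffusion coefficient is D = -slope; the perfusion fraction comes
#' from the extrapolated intercept at b = 0. Two intercept conventions are
#' supported:
#' \describe{
#'   \item{`"exp"` (default)}{f = 1 - exp(intercept): the back-transformed
#'     intercept is 1 - f, exact for the two-compartment model with fully
#'     suppressed pseudo-diffusion signal.}
#'   \item{`"linear"`}{f = -intercept: the literal reading of the linearised
#'     model ln(S_b/S_0) = -D b - f, which agrees with `"exp"` to first
#'     order in f.}
#' }
#' Both values are always recorded (`f_linear` holds the linear-mode value).
#'
#' @param curve A normalized [signal_curve()] (or raw with a b = 0 point; it
#'   is normalized on the fly).
#' @param b_threshold Lower b cutoff in s/mm^2 for the monoexponential
#'   regime (default 100; some studies use 200 or more).
#' @param f_mode Intercept convention for the reported `f`; see Details.
#' @param weights_by_averages If `TRUE`, weight the least squares by the
#'   protocol's per-b average counts instead of treating all b-values
#'   equally. Off by default: ROI means are conventionally fitted
#'   unweighted.
#' @param averages Average counts aligned with `curve$b_values`; only used
#'   when `weights_by_averages` is `TRUE`.
#' @return An `ivim_fit` object with `d` (um^2/ms), `f`, `f_linear`,
#'   `intercept_log`, `n_points_used` and `method = "segmented"`.
#' @examples
#' b <- c(0, 50, 100, 500, 600)
#' s <- 0.07 * exp(-b * 0.020) + 0.93 * exp(-b * 0.00141)
#' segmented_fit(signal_curve(b, s / s[1], normalized = TRUE))
#' @export
segmented_fit <- function(curve, b_threshold = 100,
                          f_mode = c("exp", "linear"),
                          weights_by_averages = FALSE, averages = NULL) {
  stopifnot(inherits(curve, "signal_curve"))
  f_mode <- match.arg(f_mode)
  if (!curve$normalized) curve <- normalize_roi_signals(curve)
  keep <- curve$b_values >= b_threshold
  if (sum(keep) < 2L) {
    stop(sprintf(
      "need at least 2 points with b >= %g s/mm^2 (found %d)",
      b_threshold, sum(keep)), call. = FALSE)
  }
  s <- curve$signals[keep]
  if (any(s <= 0)) stop("non-positive signal above b threshold", call. = FALSE)
  b <- curve$b_values[keep]
  y <- log(s)
  w <- NULL
  if (weights_by_averages) {
    if (is.null(averages) || length(averages) != length(curve$b_values)) {
      stop("`averages` must align with the curve's b-values", call. = FALSE)
    }
    w <- averages[keep]
  }
  fit <- if (is.null(w)) stats::lm(y ~ b) else stats::lm(y ~ b, weights = w)
  slope <- unname(stats::coef(fit)[2L])     # 1/(s/mm^2) = mm^2/s
  intercept <- unname(stats::coef(fit)[1L])
  d <- -slope * 1e3                         # mm^2/s -> um^2/ms is x1000
  f_exp <- 1 - exp(intercept)
  f_lin <- -intercept
  new_ivim_fit(
    d = d,
    f = if (f_mode == "exp") f_exp else f_lin,
    f_linear = f_lin,
    intercept_log = intercept,
    n_points_used = sum(keep),
    method = "segmented"
  )
}

#' Full biexponential IVIM fit
#'
#' Levenberg-Marquardt nonlinear least squares of the biexponential IVIM
#' signal model
#' \deqn{S(b)/S_0 = f e^{-b D^*} + (1 - f) e^{-b D}}
#' via [minpack.lm::nlsLM()]. By default the fit is initialised from the
#' segmented fit, with the pseudo-diffusion coefficient started one order of
#' magnitude above D. With only a handful of b-values and none below
#' 50 s/mm^2 the pseudo-diffusion coefficient is poorly determined; treat
#' `d_star` from such fits as indicative only.
#'
#' @param curve A normalized [signal_curve()].
#' @param init Optional `ivim_fit` (or list with `d`, `f`, optionally
#'   `d_star`) used as starting values; defaults to [segmented_fit()].
#' @param lower,upper Named bounds for `f`, `d`, `d_star` (D and D* in
#'   um^2/ms).
#' @param b_threshold Threshold passed to the default segmented
#'   initialisation.
#' @return An `ivim_fit` with `method = "biexponential"`, `d_star`, and a
#'   `converged` flag; non-convergence is flagged, not raised.
#' @export
biexponential_fit <- function(curve, init = NULL,
                              lower = c(f = 0, d = 0.05, d_star = 1),
                              upper = c(f = 0.6, d = 4, d_star = 500),
                              b_threshold = 100) {
  stopifnot(inherits(curve, "signal_curve"))
  if (!curve$normalized) curve <- normalize_roi_signals(curve)
  if (is.null(init)) {
    seg <- segmented_fit(curve, b_threshold = b_threshold)
    init <- list(f = max(seg$f, 1e-4), d = seg$d, d_star = 10 * seg$d)
  } else {
    init <- list(f = init$f, d = init$d,
                 d_star = if (!is.null(init$d_star) &&
                              is.finite(init$d_star)) init$d_star
                          else 10 * init$d)
  }
  start <- c(f = init$f, d = init$d, d_star = init$d_star)
  if (any(start < lower[names(start)]) || any(start > upper[names(start)])) {
    stop("initial values violate the bounds", call. = FALSE)
  }
  b <- curve$b_values
  s <- curve$signals
  # b in s/mm^2 times D in um^2/ms: b*D*1e-3 is dimensionless
  model <- s ~ f * exp(-b * d_star * 1e-3) + (1 - f) * exp(-b * d * 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(model, data = data.frame(b = b, s = s),
                      start = as.list(start),
                      lower = lower[c("f", "d", "d_star")],
                      upper = upper[c("f", "d", "d_star")],
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    out <- new_ivim_fit(d = init$d, f = init$f, f_linear = NA_real_,
                        intercept_log = NA_real_,
                        n_points_used = length(b),
                        method = "biexponential",
                        d_star = init$d_star, converged = FALSE)
    return(out)
  }
  cf <- stats::coef(fit)
  new_ivim_fit(
    d = unname(cf["d"]), f = unname(cf["f"]), f_linear = NA_real_,
    intercept_log = NA_real_, n_points_used = length(b),
    method = "biexponential", d_star = unname(cf["d_star"]),
    converged = fit$convInfo$isConv %||% TRUE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit every signal curve in a long-format signal table
#'
#' Groups a signal table by (subject, field, muscle, state, slice), builds
#' one [signal_curve()] per group, normalizes it and applies
#' [segmented_fit()].
#'
#' @param signals A data.frame with columns `subject`, `field_T`, `muscle`,
#'   `state`, `slice`, `b_value`, `signal`.
#' @inheritParams segmented_fit
#' @return A data.frame mirroring the grouping keys plus `d`, `f`,
#'   `f_linear`, `intercept_log`, `n_points_used`, `method`.
#' @export
fit_signal_table <- function(signals, b_threshold = 100,
                             f_mode = c("exp", "linear")) {
  f_mode <- match.arg(f_mode)
  need <- c("subject", "field_T", "muscle", "state", "slice", "b_value",
            "signal")
  miss <- setdiff(need, names(signals))
  if (length(miss)) {
    stop("signal table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(signals) == 0L) stop("signal table is empty", call. = FALSE)
  keys <- c("subject", "field_T", "muscle", "state", "slice")
  split_idx <- split(seq_len(nrow(signals)),
                     interaction(signals[keys], drop = TRUE, sep = "\r"))
  rows <- lapply(split_idx, function(idx) {
    grp <- signals[idx, , drop = FALSE]
    grp <- grp[order(grp$b_value), , drop = FALSE]
    curve <- normalize_roi_signals(
      signal_curve(grp$b_value, grp$signal))
    fit <- segmented_fit(curve, b_threshold = b_threshold, f_mode = f_mode)
    cbind(grp[1L, keys, drop = FALSE],
          data.frame(d = fit$d, f = fit$f, f_linear = fit$f_linear,
                     intercept_log = fit$intercept_log,
                     n_points_used = fit$n_points_used,
                     method = fit$method, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write long-format signal tables
#'
#' Tab-delimited text with columns (subject, field_T, muscle, state, slice,
#' b_value, signal), one row per acquired b-value of one ROI curve.
#'
#' @param path File path.
#' @param signals A signal table data.frame.
#' @return `read_signal_table()` returns the data.frame;
#'   `write_signal_table()` returns `path` invisibly.
#' @export
read_signal_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_signal_table
#' @export
write_signal_table <- function(signals, path) {
  utils::write.table(signals, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
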
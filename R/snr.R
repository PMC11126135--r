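#' SNR estimation from a signal ROI and a background noise ROI
#'
#' Estimates the signal-to-noise ratio of a magnitude image from the mean
#' signal in a tissue ROI and the statistics of a background (noise-only)
#' ROI, under the single-coil Rayleigh model of magnitude noise. Where the
#' true signal is zero, the magnitude follows a Rayleigh distribution with
#' mean \eqn{\sigma\sqrt{\pi/2}} and standard deviation
#' \eqn{\sigma\sqrt{2-\pi/2}}, so the Gaussian noise level \eqn{\sigma} can
#' be recovered from either background statistic:
#' \deqn{SNR_1 = \frac{\bar S_{muscle}}{\bar S_{noise}\sqrt{2/\pi}}, \qquad
#'       SNR_2 = \frac{\bar S_{muscle}}{sd(S_{noise})/\sqrt{2-\pi/2}}.}
#' Both estimate mean/\eqn{\sigma}. On images that are magnitude averages of
#' N repetitions, the background mean is unchanged but the background
#' standard deviation shrinks by \eqn{\sqrt{N}}, so SNR2 estimates the
#' precision of the averaged image while SNR1 reflects a single repetition.
#' With multi-channel coils both are approximations.
#'
#' @param muscle_mean Mean magnitude signal in the tissue ROI (positive).
#' @param noise_mean Mean magnitude in the background ROI.
#' @param noise_std Standard deviation of the magnitude in the background
#'   ROI.
#' @param n_roi Optional number of voxels in the tissue ROI; if given,
#'   `snr_roi` = SNR1 scaled by sqrt(n_roi) is included.
#' @return A list of class `snr_estimate` with `snr1`, `snr2`, `n_roi`,
#'   `snr_roi` and a `measurable` flag. When both background statistics are
#'   zero (e.g. integer-rounded images whose noise floor rounds to zero) the
#'   estimate is flagged unmeasurable and the SNR fields are `NA`.
#' @examples
#' estimate_snr(100, noise_mean = 10, noise_std = 5)
#' @export
estimate_snr <- function(muscle_mean, noise_mean = NULL, noise_std = NULL,
                         n_roi = NULL) {
  if (!is.numeric(muscle_mean) || muscle_mean <= 0) {
    stop("`muscle_mean` must be positive", call. = FALSE)
  }
  nm <- noise_mean %||% 0
  ns <- noise_std %||% 0
  if (nm < 0 || ns < 0) stop("noise statistics must be non-negative",
                             call. = FALSE)
  if (nm == 0 && ns == 0) {
    return(structure(list(snr1 = NA_real_, snr2 = NA_real_, n_roi = n_roi,
                          snr_roi = NA_real_, measurable = FALSE),
                     class = "snr_estimate"))
  }
  snr1 <- if (nm > 0) muscle_mean / (nm * sqrt(2 / pi)) else NA_real_
  snr2 <- if (ns > 0) muscle_mean / (ns / sqrt(2 - pi / 2)) else NA_real_
  snr_roi <- if (!is.null(n_roi) && is.finite(snr1)) {
    roi_snr(snr1, n_roi)
  } else {
    NA_real_
  }
  structure(list(snr1 = snr1, snr2 = snr2, n_roi = n_roi,
                 snr_roi = snr_roi, measurable = TRUE),
            class = "snr_estimate")
}

#' @export
print.snr_estimate <- function(x, ...) {
  if (!x$measurable) {
    cat("SNR estimate: unmeasurable (background noise statistics are zero)\n")
  } else {
    cat(sprintf("SNR estimate: SNR1 = %.2f, SNR2 = %.2f", x$snr1, x$snr2))
    if (is.finite(x$snr_roi %||% NA)) {
      cat(sprintf(", ROI (N = %d): %.2f", x$n_roi, x$snr_roi))
    }
    cat("\n")
  }
  invisible(x)
}

#' Effective SNR of an ROI-averaged signal
#'
#' Averaging N voxels reduces the noise standard deviation by sqrt(N), so
#' the effective SNR of the ROI mean is the single-voxel SNR times sqrt(N).
#' The `"rounded"` mode rounds sqrt(N) to the nearest integer first,
#' reproducing the back-of-envelope convention (e.g. SNR 7 with N = 23 gives
#' 7 * 5 = 35 rather than 33.57).
#'
#' @param snr_voxel Single-voxel SNR (positive).
#' @param n_roi Number of voxels in the ROI (at least 1).
#' @param rounding `"exact"` (default) or `"rounded"`.
#' @return The ROI-level SNR.
#' @examples
#' roi_snr(7, 23)                        # 33.57
#' roi_snr(7, 23, rounding = "rounded")  # 35
#' @export
roi_snr <- function(snr_voxel, n_roi, rounding = c("exact", "rounded")) {
  rounding <- match.arg(rounding)
  if (!is.numeric(snr_voxel) || snr_voxel <= 0) {
    stop("`snr_voxel` must be positive", call. = FALSE)
  }
  if (!is.numeric(n_roi) || n_roi < 1) {
    stop("`n_roi` must be at least 1", call. = FALSE)
  }
  fac <- sqrt(n_roi)
  if (rounding == "rounded") fac <- round(fac)
  snr_voxel * fac
}

#' Add Rician noise to true signal magnitudes
#'
#' Complex Gaussian noise of standard deviation `sigma` in each channel,
#' followed by the magnitude operation:
#' \eqn{\tilde s = \sqrt{(s + n_1)^2 + n_2^2}} with independent
#' \eqn{n_1, n_2 \sim N(0, \sigma^2)}. At zero true signal this is the
#' Rayleigh noise floor; at high SNR it approaches additive Gaussian noise.
#' The magnitude operation biases the mean upward, which is the mechanism by
#' which noise biases IVIM parameter estimates.
#'
#' @param signal True signal magnitudes (non-negative).
#' @param sigma Gaussian noise standard deviation per channel
#'   (non-negative; 0 returns `signal` unchanged).
#' @param seed Optional integer seed for reproducibility; when `NULL` the
#'   current RNG stream is used.
#' @return Noisy magnitudes, same shape as `signal`.
#' @examples
#' add_rician_noise(c(1, 0.5, 0), sigma = 0.03, seed = 1)
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0) {
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  }
  if (sigma == 0) return(signal)
  if (!is.null(seed)) set.seed(seed)
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}
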
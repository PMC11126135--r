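#' Diffusion acquisition protocol
#'
#' Bundles the sequence timing and diffusion weightings that enter every
#' relaxation weight and every fit: echo time, repetition time, the b-value
#' scheme and the number of magnitude averages acquired per b-value.
#'
#' @param te Echo time in ms. Must be positive.
#' @param tr Repetition time in ms. Must exceed `te`.
#' @param b_values Diffusion weightings in s/mm^2; non-negative, strictly
#'   increasing.
#' @param averages Positive integer repetition count per b-value; same length
#'   as `b_values`.
#'
#' @return An object of class `ivim_protocol`.
#' @examples
#' sequence_protocol()                    # the study defaults
#' sequence_protocol(te = 100, tr = 4000, b_values = c(0, 200, 800),
#'                   averages = c(1, 1, 1))
#' @export
sequence_protocol <- function(te = 56, tr = 2800,
                              b_values = c(0, 50, 100, 500, 600),
                              averages = c(2, 2, 2, 4, 4)) {
  stopifnot(is.numeric(te), length(te) == 1L, is.numeric(tr), length(tr) == 1L)
  if (!is.finite(te) || te <= 0) stop("`te` must be positive (ms)", call. = FALSE)
  if (!is.finite(tr) || tr <= te) stop("`tr` must exceed `te`", call. = FALSE)
  b_values <- as.numeric(b_values)
  if (any(!is.finite(b_values)) || any(b_values < 0)) {
    stop("`b_values` must be non-negative", call. = FALSE)
  }
  if (is.unsorted(b_values, strictly = TRUE)) {
    stop("`b_values` must be strictly increasing", call. = FALSE)
  }
  averages <- as.integer(averages)
  if (length(averages) != length(b_values) || any(is.na(averages)) ||
      any(averages < 1L)) {
    stop("`averages` must be positive integers, one per b-value", call. = FALSE)
  }
  structure(
    list(te = te, tr = tr, b_values = b_values, averages = averages),
    class = "ivim_protocol"
  )
}

#' @export
print.ivim_protocol <- function(x, ...) {
  cat("Diffusion protocol: TE =", x$te, "ms, TR =", x$tr, "ms\n")
  cat("  b-values (s/mm^2):", paste(x$b_values, collapse = ", "), "\n")
  cat("  averages:         ", paste(x$averages, collapse = ", "), "\n")
  invisible(x)
}
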
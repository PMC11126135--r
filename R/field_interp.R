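#' Blood relaxation-rate points across field strength
#'
#' Builds a table of transverse relaxation rates R2 = 1000/T2 (s^-1, with T2
#' in ms) at measured field strengths, the input for the quadratic
#' interpolation that supplies blood T2 estimates at fields where none were
#' measured.
#'
#' @param field_strength Field strengths in tesla (positive).
#' @param t2 T2 times in ms; give either `t2` or `r2`.
#' @param r2 Relaxation rates in s^-1.
#' @param source Optional citation string(s), recycled.
#' @return A data.frame of class `r2_points` with columns `field_strength`,
#'   `t2`, `r2`, `source`.
#' @examples
#' r2_points(c(1.5, 3, 4.7), t2 = c(148, 48, 28))  # venous blood
#' @export
r2_points <- function(field_strength, t2 = NULL, r2 = NULL, source = NA) {
  if (is.null(t2) == is.null(r2)) {
    stop("give exactly one of `t2` or `r2`", call. = FALSE)
  }
  if (is.null(r2)) r2 <- 1000 / t2 else t2 <- 1000 / r2
  if (any(!is.finite(field_strength)) || any(field_strength <= 0) ||
      any(!is.finite(t2)) || any(t2 <= 0)) {
    stop("field strengths and relaxation values must be positive",
         call. = FALSE)
  }
  out <- data.frame(field_strength = as.numeric(field_strength),
                    t2 = as.numeric(t2), r2 = as.numeric(r2),
                    source = source, stringsAsFactors = FALSE)
  class(out) <- c("r2_points", "data.frame")
  out
}

#' Packaged blood R2 points
#'
#' Literature venous / arterial blood relaxation rates at 1.5, 3 and 4.7 T
#' (HCT = 0.44) shipped with the package.
#'
#' @param compartment `"venous"` or `"arterial"`.
#' @param file Optional user YAML following the packaged schema.
#' @return An [r2_points()] table.
#' @export
blood_r2_points <- function(compartment = c("venous", "arterial"),
                            file = NULL) {
  compartment <- match.arg(compartment)
  if (is.null(file)) {
    file <- system.file("extdata", "blood_r2_points.yaml",
                        package = "ivimfield", mustWork = TRUE)
  }
  entries <- yaml::read_yaml(file)[[compartment]]
  r2_points(
    field_strength = vapply(entries, `[[`, numeric(1), "field_strength"),
    t2 = vapply(entries, `[[`, numeric(1), "t2"),
    source = vapply(entries, `[[`, character(1), "source")
  )
}

#' Quadratic fit of relaxation rate versus field strength
#'
#' Least-squares second-order polynomial R2(B0) = c0 + c1 B0 + c2 B0^2
#' through relaxation-rate points. The fit operates on rates, not times
#' (fitting T2 directly would give a different, unsupported curve). With
#' exactly three distinct fields the polynomial interpolates the points
#' exactly. This is a purely data-driven interpolation, not a physical
#' dispersion model, and extrapolation well outside the fitted field range
#' can produce unphysical (non-positive) rates.
#'
#' @param points An [r2_points()] table with at least three distinct field
#'   strengths.
#' @return An object of class `r2_polynomial` with `coefficients`
#'   (c0, c1, c2), `residuals`, `n_points` and `fitted_range`.
#' @examples
#' fit_r2_polynomial(blood_r2_points("venous"))
#' @export
fit_r2_polynomial <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("field_strength", "r2") %in% names(points)))
  if (anyDuplicated(points$field_strength)) {
    stop("duplicate field strengths in the R2 points", call. = FALSE)
  }
  if (nrow(points) < 3L) {
    stop("need at least 3 points with distinct field strengths",
         call. = FALSE)
  }
  B <- points$field_strength
  fit <- stats::lm(r2 ~ B + I(B^2), data = data.frame(B = B,
                                                      r2 = points$r2))
  structure(
    list(coefficients = unname(stats::coef(fit)),
         residuals = unname(stats::resid(fit)),
         n_points = nrow(points),
         fitted_range = range(B)),
    class = "r2_polynomial"
  )
}

#' Evaluate an R2 polynomial at a field strength
#'
#' @param poly An `r2_polynomial`.
#' @param field Field strength(s) in tesla.
#' @return Predicted R2 in s^-1.
#' @export
predict_r2 <- function(poly, field) {
  stopifnot(inherits(poly, "r2_polynomial"))
  cf <- poly$coefficients
  cf[1] + cf[2] * field + cf[3] * field^2
}

#' Predict a T2 time at an unmeasured field strength
#'
#' Evaluates the fitted quadratic rate polynomial and converts back to a
#' time, T2 = 1000 / R2(B0). A warning is emitted when `field` lies outside
#' the fitted range: extrapolation of the data-driven polynomial is
#' unreliable and is known to collapse toward a vanishing rate at low field.
#'
#' @inheritParams predict_r2
#' @return Predicted T2 in ms.
#' @examples
#' poly <- fit_r2_polynomial(blood_r2_points("venous"))
#' predict_t2(poly, 7)   # ~18.5 ms from the three packaged points
#' @export
predict_t2 <- function(poly, field) {
  r2 <- predict_r2(poly, field)
  outside <- field < poly$fitted_range[1] | field > poly$fitted_range[2]
  if (any(outside)) {
    warning(sprintf(
      "field %s T outside the fitted range [%g, %g] T; extrapolated T2 is unreliable",
      paste(field[outside], collapse = ", "),
      poly$fitted_range[1], poly$fitted_range[2]), call. = FALSE)
  }
  if (any(r2 <= 0)) {
    stop("polynomial predicts a non-positive relaxation rate at this field; the data-driven interpolation has no physical meaning there",
         call. = FALSE)
  }
  1000 / r2
}

#' @export
print.r2_polynomial <- function(x, ...) {
  cat(sprintf(
    "R2(B0) = %.4f + %.4f B0 + %.4f B0^2  (s^-1; fitted on %d points, %g-%g T)\n",
    x$coefficients[1], x$coefficients[2], x$coefficients[3], x$n_points,
    x$fitted_range[1], x$fitted_range[2]))
  invisible(x)
}
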
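#' Compartment relaxation times at one field strength
#'
#' Collects the longitudinal (T1) and transverse (T2) relaxation times of the
#' three signal compartments of the voxel model -- tissue (skeletal muscle, or
#' the parenchyma of another organ), arterial blood and venous blood -- at a
#' single main field strength B0. These times, together with the sequence
#' timing, determine how strongly each compartment's proton density is
#' weighted in a spin-echo EPI acquisition.
#'
#' @param field_strength Main magnetic field B0 in tesla.
#' @param t1_venous,t1_arterial,t1_muscle Longitudinal relaxation times in ms.
#' @param t2_venous,t2_arterial,t2_muscle Transverse relaxation times in ms.
#'   Each T2 must not exceed the corresponding T1.
#' @param oxygen_saturation_venous,oxygen_saturation_arterial Optional blood
#'   oxygen saturation in percent (documentation only; blood relaxation times
#'   depend on oxygenation).
#' @param hematocrit Optional hematocrit fraction (documentation only).
#' @param label Optional name for the set.
#' @param source Optional citation string(s) recording where the times come
#'   from.
#'
#' @return An object of class `relaxation_set`.
#' @seealso [relaxation_times()] for the packaged literature sets,
#'   [compartment_weights()] for the derived signal weights.
#' @export
relaxation_set <- function(field_strength,
                           t1_venous, t1_arterial, t1_muscle,
                           t2_venous, t2_arterial, t2_muscle,
                           oxygen_saturation_venous = NULL,
                           oxygen_saturation_arterial = NULL,
                           hematocrit = NULL,
                           label = NULL, source = NULL) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop(sprintf("`%s` must be a single positive number", nm), call. = FALSE)
    }
    as.numeric(x)
  }
  field_strength <- num1(field_strength, "field_strength")
  times <- list(
    t1_venous = num1(t1_venous, "t1_venous"),
    t1_arterial = num1(t1_arterial, "t1_arterial"),
    t1_muscle = num1(t1_muscle, "t1_muscle"),
    t2_venous = num1(t2_venous, "t2_venous"),
    t2_arterial = num1(t2_arterial, "t2_arterial"),
    t2_muscle = num1(t2_muscle, "t2_muscle")
  )
  for (cmp in c("venous", "arterial", "muscle")) {
    if (times[[paste0("t2_", cmp)]] > times[[paste0("t1_", cmp)]]) {
      stop(sprintf("T2 exceeds T1 for the %s compartment", cmp), call. = FALSE)
    }
  }
  structure(
    c(list(field_strength = field_strength), times,
      list(oxygen_saturation_venous = oxygen_saturation_venous,
           oxygen_saturation_arterial = oxygen_saturation_arterial,
           hematocrit = hematocrit,
           label = label, source = source)),
    class = "relaxation_set"
  )
}

#' @export
print.relaxation_set <- function(x, ...) {
  cat(sprintf("Relaxation set%s at %.2f T\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$field_strength))
  m <- matrix(c(x$t1_arterial, x$t1_venous, x$t1_muscle,
                x$t2_arterial, x$t2_venous, x$t2_muscle),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("T1 (ms)", "T2 (ms)"),
                              c("arterial", "venous", "muscle")))
  print(m)
  invisible(x)
}

#' Spin-echo relaxation weight of one compartment
#'
#' The factor by which a compartment's proton density is attenuated in a
#' spin-echo acquisition with echo time TE and repetition time TR:
#' \deqn{w = e^{-TE/T_2}\,\bigl(1 - e^{-TR/T_1}\bigr).}
#' The weight is 1 only in the degenerate limit TE = 0 and TR much larger
#' than T1; with `long_tr = TRUE` the T1 recovery factor is dropped
#' (TR to infinity), leaving the pure T2 decay.
#'
#' @param t1,t2 Relaxation times in ms (positive; vectorised).
#' @param protocol A [sequence_protocol()] supplying TE and TR.
#' @param long_tr If `TRUE`, assume full longitudinal recovery.
#' @return Dimensionless weight in (0, 1].
#' @examples
#' p <- sequence_protocol()
#' compartment_weight(1122, 148, p)   # venous blood at 0.55 T -> 0.6285
#' compartment_weight(701, 44, p)     # muscle at 0.55 T -> 0.2749
#' @export
compartment_weight <- function(t1, t2, protocol, long_tr = FALSE) {
  stopifnot(inherits(protocol, "ivim_protocol"))
  if (any(!is.finite(t1)) || any(t1 <= 0)) {
    stop("`t1` must be positive (ms)", call. = FALSE)
  }
  if (any(!is.finite(t2)) || any(t2 <= 0)) {
    stop("`t2` must be positive (ms)", call. = FALSE)
  }
  recovery <- if (long_tr) 1 else 1 - exp(-protocol$tr / t1)
  exp(-protocol$te / t2) * recovery
}

#' Relaxation weights of the three voxel compartments
#'
#' Computes the arterial, venous and muscle weights from a relaxation set and
#' an acquisition protocol. Weights are always derived on demand from the
#' times, never stored, so perturbing a relaxation set can never leave stale
#' weights behind.
#'
#' @inheritParams compartment_weight
#' @param relax A [relaxation_set()].
#' @return An object of class `compartment_weights`: a named list with
#'   `w_arterial`, `w_venous`, `w_muscle`, each in (0, 1].
#' @examples
#' compartment_weights(relaxation_times("calf_0.55T"), sequence_protocol())
#' @export
compartment_weights <- function(relax, protocol, long_tr = FALSE) {
  stopifnot(inherits(relax, "relaxation_set"))
  structure(
    list(
      w_arterial = compartment_weight(relax$t1_arterial, relax$t2_arterial,
                                      protocol, long_tr),
      w_venous = compartment_weight(relax$t1_venous, relax$t2_venous,
                                    protocol, long_tr),
      w_muscle = compartment_weight(relax$t1_muscle, relax$t2_muscle,
                                    protocol, long_tr)
    ),
    class = "compartment_weights"
  )
}

#' Manually specified compartment weights
#'
#' Escape hatch for working directly with weights (for example literature
#' values); normally weights are derived with [compartment_weights()].
#'
#' @param w_arterial,w_venous,w_muscle Dimensionless weights in (0, 1].
#' @return An object of class `compartment_weights`.
#' @export
weights_manual <- function(w_arterial, w_venous, w_muscle) {
  w <- c(w_arterial = w_arterial, w_venous = w_venous, w_muscle = w_muscle)
  if (any(!is.finite(w)) || any(w <= 0) || any(w > 1)) {
    stop("weights must lie in (0, 1]", call. = FALSE)
  }
  structure(as.list(w), class = "compartment_weights")
}

#' @export
print.compartment_weights <- function(x, ...) {
  cat(sprintf("Compartment weights: arterial %.4f, venous %.4f, muscle %.4f\n",
              x$w_arterial, x$w_venous, x$w_muscle))
  invisible(x)
}

#' Packaged literature relaxation-time sets
#'
#' Loads one of the relaxation-time sets shipped with the package, compiled
#' from published measurements. Available sets:
#' \describe{
#'   \item{`calf_0.55T`}{Calf muscle study values used at 0.55 T. Blood T2
#'     (venous 148 ms, arterial 207 ms) are 1.5 T literature values, justified
#'     by the near-constancy of arterial blood T2 between 0.55 and 1.5 T;
#'     muscle T2 44 ms likewise from 1.5 T; all T1 from 0.55 T myocardium /
#'     blood measurements (1122/1122/701 ms).}
#'   \item{`calf_7T`}{Calf muscle values at 7 T: blood T2 20/55 ms obtained by
#'     quadratic interpolation of literature relaxation rates, muscle T2
#'     22 ms, T1 2090/2990/1864 ms. Arterial T1 follows the 2990 ms
#'     literature value.}
#'   \item{`calf_7T_t1a2290`}{As `calf_7T` but with the alternate tabulated
#'     arterial T1 of 2290 ms; the two values circulate in the literature for
#'     the same source.}
#'   \item{`liver_1.5T`, `liver_3T`}{Liver parenchyma (in the muscle/tissue
#'     slot) with blood values at the same field; used for cross-field
#'     predictions of liver perfusion fractions.}
#' }
#'
#' @param set Name of the set; see Details.
#' @param file Optional path to a user YAML file following the same schema as
#'   the packaged `relaxation_times.yaml`.
#' @return A [relaxation_set()].
#' @examples
#' relaxation_times("calf_0.55T")
#' relaxation_times("calf_7T")
#' @export
relaxation_times <- function(set = c("calf_0.55T", "calf_7T",
                                     "calf_7T_t1a2290",
                                     "liver_1.5T", "liver_3T"),
                             file = NULL) {
  if (is.null(file)) {
    set <- match.arg(set)
    file <- system.file("extdata", "relaxation_times.yaml",
                        package = "ivimfield", mustWork = TRUE)
  }
  all <- yaml::read_yaml(file)
  if (!set %in% names(all)) {
    stop(sprintf("no relaxation set named '%s' in %s", set, file),
         call. = FALSE)
  }
  entry <- all[[set]]
  relaxation_set(
    field_strength = entry$field_strength,
    t1_venous = entry$t1$venous, t1_arterial = entry$t1$arterial,
    t1_muscle = entry$t1$muscle,
    t2_venous = entry$t2$venous, t2_arterial = entry$t2$arterial,
    t2_muscle = entry$t2$muscle,
    oxygen_saturation_venous = entry$oxygen_saturation$venous,
    oxygen_saturation_arterial = entry$oxygen_saturation$arterial,
    hematocrit = entry$hematocrit,
    label = set, source = unlist(entry$source)
  )
}

#' Perturb relaxation times by fractional amounts
#'
#' Applies named fractional changes to a relaxation set, e.g.
#' `t2_venous = -0.15` shortens venous T2 by 15%. Used by
#' [sensitivity_curves()] to explore how literature-value uncertainty
#' propagates into the perfusion-fraction model.
#'
#' @param relax A [relaxation_set()].
#' @param ... Named fractional changes; names among `t1_venous`,
#'   `t1_arterial`, `t1_muscle`, `t2_venous`, `t2_arterial`, `t2_muscle`.
#'   Each factor must be greater than -1 (a time cannot be reduced to zero or
#'   below).
#' @return The perturbed `relaxation_set`.
#' @examples
#' perturb_relaxation(relaxation_times("calf_7T"), t2_venous = -0.15)
#' @export
perturb_relaxation <- function(relax, ...) {
  stopifnot(inherits(relax, "relaxation_set"))
  changes <- list(...)
  allowed <- c("t1_venous", "t1_arterial", "t1_muscle",
               "t2_venous", "t2_arterial", "t2_muscle")
  if (length(changes) == 0L) return(relax)
  bad <- setdiff(names(changes), allowed)
  if (length(bad) || is.null(names(changes)) || any(names(changes) == "")) {
    stop("perturbations must be named among: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  for (nm in names(changes)) {
    fac <- changes[[nm]]
    if (!is.numeric(fac) || length(fac) != 1L || !is.finite(fac) ||
        fac <= -1) {
      stop(sprintf("perturbation `%s` must be a fraction > -1", nm),
           call. = FALSE)
    }
    relax[[nm]] <- relax[[nm]] * (1 + fac)
  }
  # re-validate (T2 <= T1, positivity) through the constructor
  relaxation_set(
    field_strength = relax$field_strength,
    t1_venous = relax$t1_venous, t1_arterial = relax$t1_arterial,
    t1_muscle = relax$t1_muscle,
    t2_venous = relax$t2_venous, t2_arterial = relax$t2_arterial,
    t2_muscle = relax$t2_muscle,
    oxygen_saturation_venous = relax$oxygen_saturation_venous,
    oxygen_saturation_arterial = relax$oxygen_saturation_arterial,
    hematocrit = relax$hematocrit,
    label = relax$label, source = relax$source
  )
}
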
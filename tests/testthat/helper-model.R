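# shared fixtures and independent oracles for the model tests

default_protocol <- function() sequence_protocol()

calf_weights <- function(set = "calf_0.55T") {
  compartment_weights(relaxation_times(set), default_protocol())
}

# independent three-pool forward evaluation, written from the defining
# ratio of weighted signal fractions (not via perfusion_state)
oracle_forward <- function(f0, r, w) {
  fa <- f0 / (1 + r)
  fv <- f0 - fa
  top <- fa * w$w_arterial + fv * w$w_venous
  top / (top + (1 - f0) * w$w_muscle)
}

# numeric inversion of the forward model by root finding; independent of
# the closed-form inverse
oracle_invert <- function(f, r, w) {
  if (f == 0) return(0)
  stats::uniroot(function(f0) oracle_forward(f0, r, w) - f,
                 interval = c(0, 1 - 1e-9), tol = 1e-14)$root
}

# ordinary-least-squares line through (x, y) via closed-form moments
oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}
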
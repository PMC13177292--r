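# Characteristic-function peak models (one- and two-site).

#' One-site stochastic peak model
#'
#' Compound-Poisson model of retention: a molecule undergoes `n` expected
#' adsorption-desorption events, each sojourn exponentially distributed
#' with mean `tau` minutes. The characteristic function of the stationary
#' residence time is `exp(n * (1 / (1 - i tau w) - 1))`.
#'
#' @param n Expected number of adsorption events (>= 0).
#' @param tau Mean sojourn time per event (min, > 0).
#' @return An object of class `cf_one_site`.
#' @export
cf_one_site <- function(n, tau) {
  stopifnot(n >= 0, tau > 0)
  structure(list(n = n, tau = tau), class = c("cf_one_site", "cf_model"))
}

#' Two-site stochastic peak model
#'
#' Generalisation with a nonselective site (visitation fraction
#' `p1 = 1 - p2`, sojourn `tau1`) and an enantioselective site (`p2`,
#' `tau2`):
#' `exp(n * (p1 / (1 - i tau1 w) + p2 / (1 - i tau2 w) - 1))`.
#'
#' @param n Expected adsorption events.
#' @param p2 Visitation fraction of the enantioselective site, in `[0, 1]`.
#' @param tau1,tau2 Mean sojourn times (min) on the nonselective and
#'   selective sites.
#' @return An object of class `cf_two_site`.
#' @export
cf_two_site <- function(n, p2, tau1, tau2) {
  stopifnot(n >= 0, p2 >= 0, p2 <= 1, tau1 > 0, tau2 > 0)
  structure(list(n = n, p1 = 1 - p2, p2 = p2, tau1 = tau1, tau2 = tau2),
            class = c("cf_two_site", "cf_model"))
}

#' Evaluate a model characteristic function
#'
#' @param model A [cf_one_site()] or [cf_two_site()].
#' @param omega Real frequency vector (1/min); the CF is entire, so any
#'   finite values are admissible.
#' @return Complex vector `Phi(omega)`; `Phi(0) = 1`.
#' @export
cf_value <- function(model, omega) UseMethod("cf_value")

#' @export
cf_value.cf_one_site <- function(model, omega) {
  exp(model$n * (1 / (1 - 1i * model$tau * omega) - 1))
}

#' @export
cf_value.cf_two_site <- function(model, omega) {
  exp(model$n * (model$p1 / (1 - 1i * model$tau1 * omega) +
                   model$p2 / (1 - 1i * model$tau2 * omega) - 1))
}

# First two cumulants of the stationary residence time.
cf_mean <- function(model) UseMethod("cf_mean")
#' @export
cf_mean.cf_one_site <- function(model) model$n * model$tau
#' @export
cf_mean.cf_two_site <- function(model) {
  model$n * (model$p1 * model$tau1 + model$p2 * model$tau2)
}
cf_var <- function(model) UseMethod("cf_var")
#' @export
cf_var.cf_one_site <- function(model) 2 * model$n * model$tau^2
#' @export
cf_var.cf_two_site <- function(model) {
  2 * model$n * (model$p1 * model$tau1^2 + model$p2 * model$tau2^2)
}

#' Uniform FFT grid for profile synthesis
#'
#' Power-of-two time grid from 0 to `t_max` with its conjugate angular
#' frequency grid. `t_max` should cover the peak support generously (the
#' generators use `tM + 8 * (mean + 4 * SD)` style spans) to control
#' aliasing.
#'
#' @param t_max Time span (min).
#' @param n Grid length; rounded up to the next power of two, minimum 1024.
#' @return List with `t` (time grid), `omega` (signed angular frequency
#'   grid) and `dt`.
#' @export
sim_grid <- function(t_max, n = 4096) {
  n <- 2^ceiling(log2(max(n, 1024)))
  dt <- t_max / n
  list(t = seq(0, by = dt, length.out = n),
       omega = angular_freqs(n, dt), dt = dt, n = n)
}

# Default grid span for a pair of peak models eluting around tM.
default_span <- function(models, tM, sigma_m = 0) {
  stat <- vapply(models, cf_mean, numeric(1))
  sds <- sqrt(vapply(models, cf_var, numeric(1)) + sigma_m^2)
  tM + max(stat + 8 * sds) + 4 * max(sds) + tM
}
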
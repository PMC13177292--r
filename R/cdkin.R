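# Off-column circular-dichroism racemization kinetics.

#' First-order decay fit of a CD time series
#'
#' Nonlinear least squares of `theta(t) = theta0 * exp(-k * (t + delay))`
#' where `delay` is the time between the true kinetic time zero (start
#' of fraction collection) and the start of acquisition; `theta0` always
#' refers to true time zero. The delay may be supplied (fixed) or
#' co-estimated within `[0, 120]` s -- the latter requires the true
#' time-zero amplitude `theta0_fixed` to be known (for a single
#' exponential, amplitude and delay are exactly confounded:
#' `theta0 e^{-k delay}` is the only identifiable combination). Traces
#' whose rate confidence interval includes zero are flagged
#' `decaying = FALSE`.
#'
#' @param trace Tibble with columns `t` (seconds since acquisition
#'   start) and `ellipticity` (mdeg); optionally `absorbance`.
#' @param delay Acquisition delay (s) if known.
#' @param estimate_delay Co-estimate the delay (bounded `[0, 120]` s)?
#' @param theta0_fixed Known time-zero ellipticity (mdeg), required when
#'   `estimate_delay = TRUE`.
#' @return One-row tibble of class `cd_fit`: `theta0`, `k_rac` (1/s),
#'   `delay`, SEs, `decaying`.
#' @export
fit_cd_decay <- function(trace, delay = 0, estimate_delay = FALSE,
                         theta0_fixed = NULL) {
  stopifnot(nrow(trace) >= 30)
  tt <- trace$t; th <- trace$ellipticity
  # log-linear start values (sign-robust)
  sgn <- sign(stats::median(th))
  pos <- sgn * th > 0
  lf <- stats::lm(log(sgn * th[pos]) ~ tt[pos])
  k0 <- max(-unname(stats::coef(lf)[2]), 1e-6)
  th0_acq <- sgn * exp(unname(stats::coef(lf)[1]))
  span <- k0 * (max(tt) - min(tt)) / log(2)
  if (span < 0.5) {
    warning("trace spans fewer than 0.5 decay half-lives; ",
            "rate weakly determined")
  }
  if (estimate_delay) {
    if (is.null(theta0_fixed)) {
      stop("co-estimating the delay requires `theta0_fixed`: amplitude ",
           "and delay are confounded in a single exponential", call. = FALSE)
    }
    dat <- dplyr::mutate(trace, th0 = theta0_fixed)
    fit <- minpack.lm::nlsLM(
      ellipticity ~ th0 * exp(-k * (t + dly)), data = dat,
      start = list(k = k0, dly = min(max(delay, 1), 119)),
      lower = c(1e-9, 0), upper = c(Inf, 120),
      control = stats::nls.control(maxiter = 200))
    cf <- summary(fit)$coefficients
    dly <- cf["dly", 1]; se_dly <- cf["dly", 2]
    cf <- rbind(theta0 = c(theta0_fixed, 0, NA, NA), cf)
  } else {
    dat <- dplyr::mutate(trace, t_true = t + delay)
    fit <- minpack.lm::nlsLM(
      ellipticity ~ theta0 * exp(-k * t_true), data = dat,
      start = list(theta0 = th0_acq * exp(k0 * delay), k = k0),
      control = stats::nls.control(maxiter = 200))
    cf <- summary(fit)$coefficients
    dly <- delay; se_dly <- 0
  }
  k <- cf["k", 1]; se_k <- cf["k", 2]
  out <- tibble::tibble(
    theta0 = cf["theta0", 1], se_theta0 = cf["theta0", 2],
    k_rac = k, se_k = se_k, delay = dly, se_delay = se_dly,
    decaying = k - 1.96 * se_k > 0)
  class(out) <- c("cd_fit", class(out))
  out
}

#' Enantiomerization rate from a racemization rate
#'
#' The CD signal decays with the overall racemization rate; for a
#' symmetric two-state system the unidirectional enantiomerization rate
#' is half of it.
#'
#' @param k_rac Racemization rate constant.
#' @return `k_rac / 2`, same units.
#' @export
enantiomerization_rate <- function(k_rac) k_rac / 2

#' Anisotropy (G) factor from CD amplitude and absorbance
#'
#' `G = (theta0 / 32980) / A`: the extrapolated ellipticity (mdeg) is
#' converted to a circular-dichroic absorbance difference (the standard
#' 32980 mdeg per Delta-A conversion) and referenced to the long-time
#' total absorbance. SE by first-order propagation.
#'
#' @param theta0 Extrapolated ellipticity at true time zero (mdeg).
#' @param absorbance Long-time absorbance (AU, > 0).
#' @param se_theta0,se_absorbance Standard errors (default 0).
#' @param mdeg_per_dA Conversion constant (default 32980).
#' @return Tibble `G`, `se_G`.
#' @export
g_factor <- function(theta0, absorbance, se_theta0 = 0, se_absorbance = 0,
                     mdeg_per_dA = 32980) {
  if (any(absorbance <= 0)) stop("absorbance must be positive", call. = FALSE)
  G <- (theta0 / mdeg_per_dA) / absorbance
  se_G <- abs(G) * sqrt((se_theta0 / theta0)^2 +
                          (se_absorbance / absorbance)^2)
  tibble::tibble(G = G, se_G = se_G)
}

#' Confidence-interval equivalence of two rate sets
#'
#' Per matching temperature, two estimates are deemed statistically
#' equivalent when their confidence intervals overlap.
#'
#' @param a,b Tibbles with columns `temperature`, `k`, `se`.
#' @param level Confidence level (default 0.95).
#' @return Tibble per shared temperature: both estimates, interval
#'   bounds and `equivalent`.
#' @export
compare_rates <- function(a, b, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  dplyr::inner_join(
    dplyr::transmute(a, temperature = .data$temperature, k_a = .data$k,
                     lo_a = .data$k - z * .data$se, hi_a = .data$k + z * .data$se),
    dplyr::transmute(b, temperature = .data$temperature, k_b = .data$k,
                     lo_b = .data$k - z * .data$se, hi_b = .data$k + z * .data$se),
    by = "temperature") |>
    dplyr::mutate(equivalent = .data$lo_a <= .data$hi_b &
                    .data$lo_b <= .data$hi_a)
}
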
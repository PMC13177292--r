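# Activation thermodynamics: weighted Eyring-Polanyi and Arrhenius
# regressions with covariance-aware error propagation.

#' Physical constants (CODATA) used by the thermodynamic fits
#'
#' `R` in kJ/(K mol); `kB` (J/K) and `h` (J s) in SI; `Tref` in K.
#' @export
thermo_constants <- function() {
  list(R = 8.31446261815324e-3, kB = 1.380649e-23, h = 6.62607015e-34,
       Tref = 298.15)
}

weighted_line <- function(x, y, w, scale_by_residuals = FALSE) {
  W <- sum(w); xb <- sum(w * x) / W; yb <- sum(w * y) / W
  sxx <- sum(w * (x - xb)^2)
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  n <- length(x)
  # with stated SEs the weights are absolute (fixed-effect convention);
  # with unit weights the scale comes from the residuals
  s2 <- if (scale_by_residuals && n > 2) {
    sum(w * (y - intercept - slope * x)^2) / (n - 2)
  } else 1
  var_slope <- s2 / sxx
  var_int <- s2 * (1 / W + xb^2 / sxx)
  cov_sl_int <- -s2 * xb / sxx
  list(slope = slope, intercept = intercept,
       se_slope = sqrt(var_slope), se_intercept = sqrt(var_int),
       cov = cov_sl_int, s2 = s2)
}

#' Weighted Eyring-Polanyi fit
#'
#' Linearised form: `ln(k/T) = -dH/R * (1/T) + ln(kB/h) + dS/R`, fitted
#' by weighted least squares with weights `1 / SE(ln k)^2` where
#' `SE(ln k) = se_k / k`. The Gibbs energy at `Tref` uses the full
#' (dH, dS) covariance -- the strong enthalpy-entropy correlation
#' partially cancels there, which is why `dG` is usually far better
#' determined than either component.
#'
#' @param tbl Tibble with columns `temperature` (K), `k` (> 0) and
#'   optionally `se` (same units as `k`).
#' @param rate_units `"per_min"` (default; converted to 1/s internally
#'   for the `ln(kB/h)` intercept) or `"per_s"`.
#' @param Tref Reference temperature for the Gibbs energy (K).
#' @return One-row tibble of class `eyring_fit`: `dH`, `dS`, `dG_ref`
#'   (kJ/mol, kJ/(K mol), kJ/mol), their SEs, `cov_HS`, `Tref`, `n`.
#' @export
fit_eyring <- function(tbl, rate_units = c("per_min", "per_s"),
                       Tref = 298.15) {
  rate_units <- match.arg(rate_units)
  cst <- thermo_constants()
  stopifnot(nrow(tbl) >= 3)
  if (any(tbl$k <= 0)) stop("Eyring fit requires positive rate constants",
                            call. = FALSE)
  k <- if (rate_units == "per_min") tbl$k / 60 else tbl$k
  se <- if ("se" %in% names(tbl)) {
    (if (rate_units == "per_min") tbl$se / 60 else tbl$se)
  } else rep(NA_real_, nrow(tbl))
  known_se <- all(is.finite(se)) && all(se > 0)
  w <- if (known_se) (k / se)^2 else rep(1, length(k))
  x <- 1 / tbl$temperature
  y <- log(k / tbl$temperature)
  fit <- weighted_line(x, y, w, scale_by_residuals = !known_se)
  dH <- -fit$slope * cst$R
  dS <- (fit$intercept - log(cst$kB / cst$h)) * cst$R
  se_dH <- fit$se_slope * cst$R
  se_dS <- fit$se_intercept * cst$R
  cov_HS <- -fit$cov * cst$R^2
  dG <- dH - Tref * dS
  se_dG <- sqrt(se_dH^2 + Tref^2 * se_dS^2 - 2 * Tref * cov_HS)
  out <- tibble::tibble(dH = dH, dS = dS, dG_ref = dG,
                        se_dH = se_dH, se_dS = se_dS, se_dG = se_dG,
                        cov_HS = cov_HS, Tref = Tref, n = nrow(tbl))
  class(out) <- c("eyring_fit", class(out))
  out
}

#' Weighted Arrhenius fit
#'
#' `ln k = ln A - Ea/R * (1/T)`, weighted by `1/SE(ln k)^2`.
#'
#' @inheritParams fit_eyring
#' @return One-row tibble of class `arrhenius_fit`: `Ea` (kJ/mol), `lnA`,
#'   SEs, `n`. `lnA` refers to the rate unit supplied.
#' @export
fit_arrhenius <- function(tbl, Tref = 298.15) {
  cst <- thermo_constants()
  stopifnot(nrow(tbl) >= 2)
  if (any(tbl$k <= 0)) stop("Arrhenius fit requires positive rate constants",
                            call. = FALSE)
  se <- if ("se" %in% names(tbl)) tbl$se else rep(NA_real_, nrow(tbl))
  known_se <- all(is.finite(se)) && all(se > 0)
  w <- if (known_se) (tbl$k / se)^2 else rep(1, nrow(tbl))
  fit <- weighted_line(1 / tbl$temperature, log(tbl$k), w,
                       scale_by_residuals = !known_se)
  out <- tibble::tibble(Ea = -fit$slope * cst$R, lnA = fit$intercept,
                        se_Ea = fit$se_slope * cst$R,
                        se_lnA = fit$se_intercept, n = nrow(tbl))
  class(out) <- c("arrhenius_fit", class(out))
  out
}

#' Gibbs activation energy at a temperature
#'
#' `dG = dH - T * dS`, in kJ/mol when `dH` is kJ/mol and `dS` kJ/(K mol).
#'
#' @param dH Activation enthalpy (kJ/mol).
#' @param dS Activation entropy (kJ/(K mol)).
#' @param temperature Temperature (K), default 298.15.
#' @return Gibbs energy (kJ/mol).
#' @export
gibbs_energy <- function(dH, dS, temperature = 298.15) {
  dH - temperature * dS
}

#' Rate constant from Eyring parameters
#'
#' `k(T) = (kB T / h) exp(-dG(T) / (R T))`, returned in 1/min by default.
#'
#' @inheritParams gibbs_energy
#' @param rate_units Output units.
#' @return Rate constant.
#' @export
eyring_rate <- function(dH, dS, temperature, rate_units = c("per_min", "per_s")) {
  rate_units <- match.arg(rate_units)
  cst <- thermo_constants()
  k <- (cst$kB * temperature / cst$h) *
    exp(-(dH - temperature * dS) / (cst$R * temperature))
  if (rate_units == "per_min") k * 60 else k
}
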
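# Rate constants from fitted conversion counts: the flow-rate series
# regressions of the stochastic models.

rate_regression <- function(y, x, se_y, mad_threshold = 3.5) {
  w <- if (all(is.finite(se_y)) && all(se_y > 0)) 1 / se_y^2 else
    rep(1, length(y))
  fit0 <- wls_through_origin(x, y, w)
  res <- y - fit0$slope * x
  s <- stats::mad(res)
  out_flag <- if (s > 0) abs(res) / s > mad_threshold else rep(FALSE, length(res))
  keep <- !out_flag
  fit <- if (any(out_flag) && sum(keep) >= 2) {
    wls_through_origin(x[keep], y[keep], w[keep])
  } else fit0
  wide <- sum(keep) < 3
  list(k = fit$slope, se = if (wide) max(fit$se, abs(fit$slope)) else fit$se,
       n_used = sum(keep), outliers = out_flag, wide_se = wide)
}

#' One-site stochastic rate constants from fitted counts
#'
#' For each condition group (a flow-rate series), zero-intercept weighted
#' regressions `a = kf * tA` and `b = kr * tB` give the forward and
#' reverse apparent rate constants: in the one-site approximation
#' interconversion is averaged over each enantiomer's total residence
#' time. One MAD-based outlier pass (`|residual| / mad > 3.5`) precedes
#' the final fit; groups left with fewer than three points are flagged
#' `wide_se`.
#'
#' @param fits Tibble with one row per run: `a`, `b`, `se_a`, `se_b`,
#'   `tA`, `tB` plus the grouping keys.
#' @param by Grouping columns (default `column`, `eluent`, `temperature`).
#' @return Tibble per group: `kf`, `se_kf`, `kr`, `se_kr`, `n_used`,
#'   `wide_se`, `model = "stoch1"`.
#' @export
rates_from_1site <- function(fits, by = c("column", "eluent", "temperature")) {
  fits |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(df, key) {
      rf <- rate_regression(df$a, df$tA, df$se_a)
      rr <- rate_regression(df$b, df$tB, df$se_b)
      tibble::tibble(kf = rf$k, se_kf = rf$se, kr = rr$k, se_kr = rr$se,
                     n_used = rf$n_used, wide_se = rf$wide_se || rr$wide_se)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(model = "stoch1")
}

#' Two-site stochastic rate constants from fitted counts
#'
#' Extended regressions `a = kf * (tM + p2 * n * tau2A)` and
#' `b = kr * (tM + p2 * n * tau2B)`: interconversion is taken to occur in
#' the mobile phase and on the enantioselective sites only, so the
#' regressor is the residence time in those phases. With `p2 = 0` the
#' regressor reduces to `tM` (mobile-phase-only exchange).
#'
#' @param fits Tibble with per-run columns `a`, `b`, `se_a`, `se_b`,
#'   `tM`, `p2`, `n`, `tau2A`, `tau2B` plus grouping keys.
#' @inheritParams rates_from_1site
#' @return Tibble per group with `kf`, `se_kf`, `kr`, `se_kr`,
#'   `model = "stoch2"`.
#' @export
rates_from_2site <- function(fits, by = c("column", "eluent", "temperature")) {
  fits |>
    dplyr::mutate(xA = tM + p2 * n * tau2A,
                  xB = tM + p2 * n * tau2B) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(df, key) {
      rf <- rate_regression(df$a, df$xA, df$se_a)
      rr <- rate_regression(df$b, df$xB, df$se_b)
      tibble::tibble(kf = rf$k, se_kf = rf$se, kr = rr$k, se_kr = rr$se,
                     n_used = rf$n_used, wide_se = rf$wide_se || rr$wide_se)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(model = "stoch2")
}
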
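# Unified equation: closed-form interconversion rate constants from
# Batman peak descriptors.

ue_log_args <- function(p, A0) {
  d <- p$tB - p$tA
  root <- sqrt(2 * pi / p$N)
  num <- (100 * (1 - A0) + A0 * (100 - p$hp * (1 + root))) / d
  den <- (1 - A0) * ((p$hp * exp(-d^2 / (2 * p$sB^2)) -
                        100 * exp(-d^2 / (8 * p$sB^2))) / (p$sB * sqrt(2 * pi)) +
                       100 / d) -
    A0 * ((100 * exp(-d^2 / (8 * p$sA^2)) - p$hp) / (p$sA * sqrt(2 * pi)) +
            (p$hp * (1 + root) - 100) / d)
  list(num = num, den = den)
}

#' Forward interconversion rate constant (unified equation)
#'
#' Closed-form apparent forward enantiomerization rate constant from the
#' Batman descriptor set: plate number `N`, retention times `tA < tB`,
#' Gaussian SDs `sA`, `sB`, plateau height `hp` on the 0-100 scale (the
#' taller retained peak is 100), and the injected fraction `A0` of the
#' first-eluting enantiomer. Natural logarithms throughout. Units: 1/min
#' when times are minutes.
#'
#' @param p One-row tibble / named list of peak descriptors (see
#'   [estimate_peak_params()]).
#' @param A0 Injected fraction of enantiomer A (default taken from `p`,
#'   else 0.5).
#' @return Forward rate constant (1/min).
#' @export
k_unified_forward <- function(p, A0 = NULL) {
  A0 <- A0 %||% p$A0 %||% 0.5
  stopifnot(p$tB > p$tA, p$sA > 0, p$sB > 0)
  la <- ue_log_args(p, A0)
  if (la$num <= 0) {
    stop("unified equation: first log argument is non-positive ",
         "(descriptors physically inconsistent: numerator term)", call. = FALSE)
  }
  if (la$den <= 0) {
    stop("unified equation: second log argument is non-positive ",
         "(descriptors physically inconsistent: bracketed-ratio term)", call. = FALSE)
  }
  -(1 / p$tA) * (log(la$num) - log(la$den))
}

#' Reverse interconversion rate constant
#'
#' `kr = kf * (A_inf / B_inf) * (tA / tB)`: microreversibility applied to
#' the integrated areas and retention times of the two enantiomers.
#'
#' @param kf Forward rate constant (1/min).
#' @param p Peak descriptors containing `areaA`, `areaB`, `tA`, `tB`.
#' @return Reverse rate constant (1/min).
#' @export
k_unified_reverse <- function(kf, p) {
  if (p$areaB <= 0) stop("areaB must be positive", call. = FALSE)
  kf * (p$areaA / p$areaB) * (p$tA / p$tB)
}

#' Unified-equation rates for a table of runs
#'
#' Applies [k_unified_forward()] and [k_unified_reverse()] row-wise and
#' attaches first-order (delta-method) standard errors propagated from
#' the descriptor uncertainties. The descriptor SEs are taken as: the
#' baseline noise (0-100 scale) for `hp`; `s / sqrt(5.545 * N) * 2` for
#' the retention times; and 2% relative for the widths -- a deliberately
#' simple error model documented in the methods vignette.
#'
#' @param peaks Tibble with one row per run containing the
#'   [estimate_peak_params()] columns (plus optionally `A0`, `noise`).
#' @return `peaks` with added columns `kf`, `kr`, `se_kf`, `se_kr`,
#'   `model = "ue"`.
#' @export
ue_rates <- function(peaks) {
  one <- function(p) {
    p <- as.list(p)
    kf <- k_unified_forward(p)
    kr <- k_unified_reverse(kf, p)
    # numeric gradient wrt (hp, sA, sB, tA, tB)
    se_in <- c(hp = max(p$noise %||% 0.5, 1e-3),
               sA = 0.02 * p$sA, sB = 0.02 * p$sB,
               tA = 2 * p$sA / sqrt(5.545 * p$N) * 2.3548,
               tB = 2 * p$sB / sqrt(5.545 * p$N) * 2.3548)
    grad <- vapply(names(se_in), function(nm) {
      h <- 1e-4 * max(abs(p[[nm]]), 1e-6)
      pp <- p; pp[[nm]] <- p[[nm]] + h
      pm <- p; pm[[nm]] <- p[[nm]] - h
      up <- try(k_unified_forward(pp), silent = TRUE)
      dn <- try(k_unified_forward(pm), silent = TRUE)
      if (inherits(up, "try-error") || inherits(dn, "try-error")) return(0)
      (up - dn) / (2 * h)
    }, numeric(1))
    se_kf <- sqrt(sum((grad * se_in)^2))
    se_kr <- se_kf * (p$areaA / p$areaB) * (p$tA / p$tB)
    tibble::tibble(kf = kf, kr = kr, se_kf = se_kf, se_kr = se_kr)
  }
  res <- purrr::map(seq_len(nrow(peaks)), function(i) {
    out <- try(one(peaks[i, ]), silent = TRUE)
    if (inherits(out, "try-error")) {
      tibble::tibble(kf = NA_real_, kr = NA_real_,
                     se_kf = NA_real_, se_kr = NA_real_)
    } else out
  })
  dplyr::bind_cols(peaks, dplyr::bind_rows(res)) |>
    dplyr::mutate(model = "ue")
}
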
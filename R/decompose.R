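# Pooling of per-model rate estimates and decomposition of apparent
# rates into mobile- and stationary-phase contributions.

#' Inverse-variance pooling of rate estimates
#'
#' `k_pool = sum(k / se^2) / sum(1 / se^2)`, `se = 1 / sqrt(sum(1/se^2))`
#' -- the minimum-variance linear combination of the per-model (or
#' per-run) estimates. Estimates with non-finite SEs are dropped; a group
#' with no usable SE yields `NA`.
#'
#' @param estimates Tibble with columns `k`, `se` plus grouping keys.
#' @param by Grouping columns.
#' @return Tibble per group: `k_pool`, `se`, `n_est`.
#' @export
pool_rates <- function(estimates, by = c("column", "eluent", "temperature",
                                         "direction")) {
  by <- intersect(by, names(estimates))
  estimates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      k_pool = {
        ok <- is.finite(.data$k) & is.finite(.data$se) & .data$se > 0
        if (any(ok)) sum(.data$k[ok] / .data$se[ok]^2) /
          sum(1 / .data$se[ok]^2) else NA_real_
      },
      se = {
        ok <- is.finite(.data$k) & is.finite(.data$se) & .data$se > 0
        if (any(ok)) 1 / sqrt(sum(1 / .data$se[ok]^2)) else NA_real_
      },
      n_est = sum(is.finite(.data$k)),
      .groups = "drop")
}

#' Flag model-level outliers within condition groups
#'
#' Compares each model's estimate to the within-group median:
#' `|k - median| / (1.4826 * MAD) > threshold` flags the value. Groups
#' with fewer than three estimates are never flagged.
#'
#' @param estimates Tibble with column `k` plus grouping keys.
#' @param by Grouping columns.
#' @param threshold Robust z-score cut (default 3.5).
#' @return `estimates` with an added logical `outlier` column.
#' @export
flag_model_outliers <- function(estimates,
                                by = c("column", "eluent", "temperature",
                                       "direction"),
                                threshold = 3.5) {
  by <- intersect(by, names(estimates))
  estimates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(outlier = {
      if (dplyr::n() < 3) rep(FALSE, dplyr::n()) else {
        med <- stats::median(.data$k)
        s <- stats::mad(.data$k)
        if (s == 0) rep(FALSE, dplyr::n()) else abs(.data$k - med) / s > threshold
      }
    }) |>
    dplyr::ungroup()
}

#' Capacity-factor linearising transform of pooled rates
#'
#' The observed apparent rate is the residence-weighted mixture
#' `k_obs = k_mob / (1 + k_fact) + k_stat * k_fact / (1 + k_fact)`;
#' multiplying by `(1 + k_fact)` linearises it:
#' `k_tr = k_pool * (1 + k_fact) = k_mob + k_fact * k_stat`. The SE is
#' propagated (`se_tr = se * (1 + k_fact)`) and the heteroskedastic
#' regression weight is `1 / ((1 + k_fact)^2 * se^2)`.
#'
#' @param pooled Tibble with columns `k_pool`, `se`, `k_fact`.
#' @return `pooled` with added `k_tr`, `se_tr`, `weight`.
#' @export
transform_ktr <- function(pooled) {
  dplyr::mutate(pooled,
                k_tr = .data$k_pool * (1 + .data$k_fact),
                se_tr = .data$se * (1 + .data$k_fact),
                weight = 1 / ((1 + .data$k_fact)^2 * .data$se^2))
}

#' Weighted linear mixed-effects decomposition of transformed rates
#'
#' REML fit of
#' `k_tr ~ beta0 + beta_f * k_fact + beta_delta * k_fact * 1(reverse)`
#' with a random intercept per eluent x temperature (the mobile-phase
#' deviation) and a random `k_fact` slope per column x temperature (the
#' stationary-phase deviation), heteroskedastic weights from
#' [transform_ktr()]. A singular random component is dropped with a
#' warning and the model refitted.
#'
#' @param tbl Tibble with `k_tr`, `weight`, `k_fact`, `direction`
#'   (`"forward"`/`"reverse"`), `eluent`, `column`, `temperature`.
#' @return Object of class `phase_mem`: the `lmerMod` fit plus parsed
#'   fixed effects.
#' @export
fit_phase_mem <- function(tbl) {
  stopifnot(all(c("k_tr", "weight", "k_fact", "direction", "eluent",
                  "column", "temperature") %in% names(tbl)))
  d <- dplyr::mutate(tbl,
                     rev = as.numeric(.data$direction == "reverse"),
                     cell_et = interaction(.data$eluent, .data$temperature, sep = "|"),
                     cell_ct = interaction(.data$column, .data$temperature, sep = "|"))
  d$weight <- d$weight / mean(d$weight)   # relative weights; aids conditioning
  form <- k_tr ~ k_fact + k_fact:rev + (1 | cell_et) + (0 + k_fact | cell_ct)
  fit <- lme4::lmer(form, data = d, weights = d$weight, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  if (lme4::isSingular(fit, tol = 1e-6)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    drop_ct <- vc$vcov[vc$grp == "cell_ct"] <= vc$vcov[vc$grp == "cell_et"]
    form2 <- if (drop_ct) {
      k_tr ~ k_fact + k_fact:rev + (1 | cell_et)
    } else {
      k_tr ~ k_fact + k_fact:rev + (0 + k_fact | cell_ct)
    }
    warning("singular variance component dropped; refitting")
    fit <- lme4::lmer(form2, data = d, weights = d$weight, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
  }
  fe <- lme4::fixef(fit)
  se_fe <- sqrt(diag(as.matrix(stats::vcov(fit))))
  structure(list(fit = fit, data = d,
                 beta0 = unname(fe["(Intercept)"]),
                 beta_f = unname(fe["k_fact"]),
                 beta_delta = unname(fe["k_fact:rev"]),
                 se_beta = stats::setNames(se_fe, names(fe))),
            class = "phase_mem")
}

#' @export
print.phase_mem <- function(x, ...) {
  cat("<phase_mem> mobile intercept beta0 =", signif(x$beta0, 4),
      "; stationary slopes beta_f =", signif(x$beta_f, 4),
      ", beta_delta =", signif(x$beta_delta, 4), "\n")
  invisible(x)
}

#' Phase-specific rate constants from the mixed-model fit
#'
#' Mobile-phase rates are `beta0 + u_ij` per eluent x temperature cell;
#' stationary forward rates `beta_f + v_kj` and reverse rates
#' `beta_f + beta_delta + v_kj` per column x temperature cell. SEs
#' combine the fixed-effect SE with the conditional (empirical-Bayes)
#' variance of the random effect. Negative extracted rates are retained
#' but flagged, never truncated.
#'
#' @param mem A [fit_phase_mem()] result.
#' @return Tibble: `phase` (`mobile`, `stat_forward`, `stat_reverse`),
#'   `eluent`/`column`, `temperature`, `k`, `se`, `negative` flag.
#' @export
extract_phase_rates <- function(mem) {
  re <- lme4::ranef(mem$fit, condVar = TRUE)
  out <- list()
  if ("cell_et" %in% names(re)) {
    u <- re$cell_et
    pv <- attr(u, "postVar")
    cells <- strsplit(rownames(u), "|", fixed = TRUE)
    out$mobile <- tibble::tibble(
      phase = "mobile",
      eluent = vapply(cells, `[`, "", 1),
      column = NA_character_,
      temperature = as.numeric(vapply(cells, `[`, "", 2)),
      k = mem$beta0 + u[[1]],
      se = sqrt(mem$se_beta["(Intercept)"]^2 + pv[1, 1, ]))
  } else {
    d <- mem$data
    out$mobile <- dplyr::distinct(d, .data$eluent, .data$temperature) |>
      dplyr::mutate(phase = "mobile", column = NA_character_,
                    k = mem$beta0, se = mem$se_beta["(Intercept)"])
  }
  v <- if ("cell_ct" %in% names(re)) re$cell_ct else NULL
  mk_stat <- function(dir, extra) {
    if (!is.null(v)) {
      pv <- attr(v, "postVar")
      cells <- strsplit(rownames(v), "|", fixed = TRUE)
      base_se <- if (dir == "stat_forward") mem$se_beta["k_fact"] else
        sqrt(mem$se_beta["k_fact"]^2 + mem$se_beta["k_fact:rev"]^2)
      tibble::tibble(
        phase = dir, eluent = NA_character_,
        column = vapply(cells, `[`, "", 1),
        temperature = as.numeric(vapply(cells, `[`, "", 2)),
        k = mem$beta_f + extra + v[[1]],
        se = sqrt(base_se^2 + pv[1, 1, ]))
    } else {
      d <- mem$data
      dplyr::distinct(d, .data$column, .data$temperature) |>
        dplyr::mutate(phase = dir, eluent = NA_character_,
                      k = mem$beta_f + extra,
                      se = mem$se_beta["k_fact"])
    }
  }
  out$fwd <- mk_stat("stat_forward", 0)
  out$rev <- mk_stat("stat_reverse", mem$beta_delta)
  dplyr::bind_rows(out) |>
    dplyr::mutate(negative = .data$k < 0) |>
    dplyr::select("phase", "eluent", "column", "temperature", "k", "se",
                  "negative")
}
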
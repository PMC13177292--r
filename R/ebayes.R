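# Global empirical-Bayes (MAP) model: Gaussian peak approximations
# convolved with Keller-Giddings densities, Eyring-parametrised phase
# rates referenced to the median temperature, priors from the
# mixed-effects stage, Laplace (Hessian) uncertainty.

#' Prepare runs for the empirical-Bayes model
#'
#' Extracts per-run peak moments and a downsampled unit-area profile
#' from a generated or ingested data set. Moments come from the
#' descriptor/fit table when supplied (`moments`; e.g. the geometry
#' recovered by [estimate_counts()], which is unbiased even for merged
#' peaks), otherwise from [estimate_peak_params()] apex measurements.
#' Runs whose moments cannot be estimated (coalesced beyond
#' recognition) are excluded with a message.
#'
#' @param runs Tibble with metadata columns (`run`, `column`, `eluent`,
#'   `temperature`, `tM`) and a `chrom` list-column of chromatograms.
#' @param n_t Number of profile points kept per run (default 120).
#' @param moments Optional tibble keyed by `run` with columns `tA`,
#'   `sA`, `tB`, `sB` (or the [estimate_counts()] columns `n_fit`,
#'   `tauA_fit`, `tauB_fit`, `sigma_m_fit` from which they are derived).
#' @return Tibble with moments (`tA`, `sA`, `tB`, `sB`, `A0`) and a
#'   `profile` list-column.
#' @export
prepare_eb_runs <- function(runs, n_t = 120, moments = NULL) {
  if (!is.null(moments) && "n_fit" %in% names(moments)) {
    moments <- dplyr::transmute(
      moments, run = .data$run,
      tA = .data$tM + .data$n_fit * .data$tauA_fit,
      tB = .data$tM + .data$n_fit * .data$tauB_fit,
      sA = sqrt(2 * .data$n_fit * .data$tauA_fit^2 + .data$sigma_m_fit^2),
      sB = sqrt(2 * .data$n_fit * .data$tauB_fit^2 + .data$sigma_m_fit^2))
  }
  res <- purrr::map(seq_len(nrow(runs)), function(i) {
    ch <- runs$chrom[[i]]
    pk <- NULL
    if (!is.null(moments)) {
      hit <- match(runs$run[i], moments$run)
      if (!is.na(hit)) {
        pk <- dplyr::mutate(moments[hit, ], A0 = chrom_meta(ch)$A0 %||% 0.5)
      }
    }
    if (is.null(pk)) pk <- try(estimate_peak_params(ch), silent = TRUE)
    if (inherits(pk, "try-error")) return(NULL)
    keep <- ch$intensity > 0.001 * max(ch$intensity)
    lo <- max(min(which(keep)) - 5L, 1L); hi <- min(max(which(keep)) + 5L, nrow(ch))
    idx <- unique(round(seq(lo, hi, length.out = n_t)))
    y <- pmax(ch$intensity[idx], 0)
    area <- trapz_int(ch$time[idx], y)
    dplyr::bind_cols(runs[i, setdiff(names(runs), "chrom")],
                     tibble::tibble(tA = pk$tA, sA = pk$sA, tB = pk$tB,
                                    sB = pk$sB, A0 = pk$A0,
                                    profile = list(tibble::tibble(
                                      time = ch$time[idx], intensity = y / area))))
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped > 0) message(dropped, " run(s) excluded: peak moments unavailable")
  dplyr::bind_rows(res)
}

# Precompute the Gaussian basis of one run: columns are unit-area
# Gaussians at the blended means/SDs for the x-quadrature nodes, plus
# the two pure-enantiomer peaks.
eb_run_basis <- function(run, nodes = 24) {
  gl <- x_quadrature(nodes)
  tt <- run$profile[[1]]$time
  mu <- gl$x * run$tA + (1 - gl$x) * run$tB
  sd <- gl$x * run$sA + (1 - gl$x) * run$sB
  G <- vapply(seq_len(nodes), function(q) stats::dnorm(tt, mu[q], sd[q]),
              numeric(length(tt)))
  list(G = G, gA = stats::dnorm(tt, run$tA, run$sA),
       gB = stats::dnorm(tt, run$tB, run$sB), x = gl$x, w = gl$w,
       y = run$profile[[1]]$intensity, t = tt,
       kfA = (run$tA - run$tM) / run$tM, kfB = (run$tB - run$tM) / run$tM,
       # residual scale from the high-frequency component of the trace
       sigma = max(stats::sd(diff(run$profile[[1]]$intensity)) / sqrt(2),
                   1e-4 * max(run$profile[[1]]$intensity)))
}

#' Predicted profile of one run under the Gaussian-Giddings model
#'
#' The two enantiomer peaks are Gaussians at the measured moments;
#' interconverted molecules contribute Gaussians at linearly blended
#' moments weighted by the Keller-Giddings densities for the run's
#' conversion counts `a = k_obs,f * tA`, `b = k_obs,r * tB`, with the
#' apparent rates assembled from the phase rates through the
#' capacity-factor mixture.
#'
#' @param run One row of [prepare_eb_runs()] output.
#' @param nodes Quadrature nodes.
#' @return Function of `c(k_mob, k_stat_f, k_stat_r)` (1/min) returning
#'   a tibble `time`, `intensity` (unit area).
#' @export
build_run_model <- function(run, nodes = 24) {
  basis <- eb_run_basis(run, nodes)
  function(k) {
    ab <- eb_counts(basis, k[1], k[2], k[3], run$tA, run$tB)
    y <- eb_profile(basis, ab[1], ab[2], run$A0)
    tibble::tibble(time = basis$t, intensity = y)
  }
}

eb_counts <- function(basis, k_mob, k_stat_f, k_stat_r, tA, tB) {
  kobs_f <- k_mob / (1 + basis$kfA) + k_stat_f * basis$kfA / (1 + basis$kfA)
  kobs_r <- k_mob / (1 + basis$kfB) + k_stat_r * basis$kfB / (1 + basis$kfB)
  c(max(kobs_f * tA, 0), max(kobs_r * tB, 0))
}

eb_profile <- function(basis, a, b, A0) {
  gw <- giddings_weights(basis$x, a, b, A0)
  as.vector(basis$G %*% (basis$w * gw$w)) +
    A0 * gw$delta_a * basis$gA + (1 - A0) * gw$delta_b * basis$gB
}

# theta layout: per eluent (lnk_mob_c, slope_mob), per column
# (lnk_f_c, slope_f, lnk_r_c, slope_r); slopes are dH/R in Kelvin.
eb_theta_names <- function(eluents, columns) {
  c(as.vector(rbind(paste0("mob_lnk.", eluents), paste0("mob_slope.", eluents))),
    as.vector(rbind(paste0("statf_lnk.", columns), paste0("statf_slope.", columns),
                    paste0("statr_lnk.", columns), paste0("statr_slope.", columns))))
}

eb_rate <- function(lnk_c, slope, temperature, Tc) {
  exp(lnk_c + log(temperature / Tc) - slope * (1 / temperature - 1 / Tc))
}

#' Empirical-Bayes MAP fit across all runs
#'
#' Maximises the joint posterior of the global phase-rate parameters:
#' each eluent contributes a mobile-phase rate, each column stationary
#' forward and reverse rates, all Eyring-parametrised (`ln k` at the
#' median temperature of the supplied runs plus a `dH/R` slope). The
#' objective is the sum over runs of the profile SSE scaled by the
#' run's residual variance plus Gaussian prior penalties. Multi-start
#' quasi-Newton optimisation; the fit is accepted only with a
#' positive-definite Hessian at the optimum (eigenvalue floor check).
#'
#' @param runs Output of [prepare_eb_runs()].
#' @param priors Tibble from [eb_priors_from_mem()] (or the same shape):
#'   `name`, `mean`, `sd` per parameter. Parameters missing from the
#'   table get diffuse priors.
#' @param seed Integer seed for the multi-start jitter.
#' @param n_starts Number of starts (default 3; the first is the prior
#'   mean).
#' @param nodes Quadrature nodes per run.
#' @param maxit BFGS iteration cap per start.
#' @param start Optional starting parameter vector (overrides the
#'   prior-mean start).
#' @return Object of class `eb_fit`: `estimate`, `se` (Laplace),
#'   `hessian`, `param_table` (with `dH`, `se_dH` per phase unit),
#'   `runs` (per-run reconstructed `a`, `b`, `rmse`), `Tc`, `value`.
#' @export
fit_ebayes <- function(runs, priors = NULL, seed = 1, n_starts = 3,
                       nodes = 24, maxit = 200, start = NULL) {
  stopifnot(nrow(runs) >= 10, length(unique(runs$temperature)) >= 3)
  eluents <- sort(unique(runs$eluent))
  columns <- sort(unique(runs$column))
  Tc <- stats::median(runs$temperature)
  nms <- eb_theta_names(eluents, columns)

  basis <- purrr::map(seq_len(nrow(runs)), function(i) eb_run_basis(runs[i, ], nodes))
  ei <- match(runs$eluent, eluents); ci <- match(runs$column, columns)

  prior_mean <- stats::setNames(rep(0, length(nms)), nms)
  prior_mean[grepl("lnk", nms)] <- log(0.05)
  prior_mean[grepl("slope", nms)] <- 8000
  prior_sd <- stats::setNames(rep(1e4, length(nms)), nms)  # diffuse default
  prior_sd[grepl("lnk", nms)] <- 20
  if (!is.null(priors)) {
    hit <- match(priors$name, nms)
    ok <- !is.na(hit)
    prior_mean[hit[ok]] <- priors$mean[ok]
    prior_sd[hit[ok]] <- priors$sd[ok]
  }

  # precomputed per-run constants for the vectorised objective
  off <- 2 * length(eluents)
  Tr <- runs$temperature
  kfA <- vapply(basis, `[[`, 0, "kfA"); kfB <- vapply(basis, `[[`, 0, "kfB")
  sig2 <- vapply(basis, `[[`, 0, "sigma")^2
  A0v <- runs$A0
  xq <- basis[[1]]$x; wq <- basis[[1]]$w

  run_counts <- function(theta) {
    km <- eb_rate(theta[2 * ei - 1], theta[2 * ei], Tr, Tc)
    kf <- eb_rate(theta[off + 4 * ci - 3], theta[off + 4 * ci - 2], Tr, Tc)
    kr <- eb_rate(theta[off + 4 * ci - 1], theta[off + 4 * ci], Tr, Tc)
    list(km = km, kf = kf, kr = kr,
         a = pmax((km / (1 + kfA) + kf * kfA / (1 + kfA)) * runs$tA, 0),
         b = pmax((km / (1 + kfB) + kr * kfB / (1 + kfB)) * runs$tB, 0))
  }

  nlp <- function(theta) {
    rc <- run_counts(theta)
    if (!all(is.finite(c(rc$a, rc$b))) || any(rc$a > 500 | rc$b > 500)) {
      return(1e10)
    }
    gw <- gidd_weight_matrix(xq, rc$a, rc$b, A0v)
    tot <- 0
    for (i in seq_len(nrow(runs))) {
      bs <- basis[[i]]
      yhat <- as.vector(bs$G %*% (wq * gw$W[, i])) +
        A0v[i] * gw$delta_a[i] * bs$gA + (1 - A0v[i]) * gw$delta_b[i] * bs$gB
      tot <- tot + 0.5 * sum((bs$y - yhat)^2) / sig2[i]
    }
    tot + 0.5 * sum(((theta - prior_mean) / prior_sd)^2)
  }

  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- if (!is.null(start)) unname(start) else prior_mean
    if (s > 1) th0 <- th0 + stats::rnorm(length(th0)) *
        pmin(prior_sd, c(0.5, 1000)[1 + grepl("slope", nms)])
    opt <- stats::optim(th0, nlp, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  H <- central_hessian(nlp, best$par, rel_step = 5e-3)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  pd <- all(ev > 1e-10 * max(abs(ev)))
  if (!pd) warning("Hessian not positive definite at the optimum; ",
                   "Laplace SEs unreliable")
  cov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(nms),
                                                       length(nms)))
  se <- stats::setNames(sqrt(pmax(diag(cov), 0)), nms)
  est <- stats::setNames(best$par, nms)

  R <- thermo_constants()$R
  param_table <- dplyr::bind_rows(
    tibble::tibble(phase = "mobile", unit = eluents,
                   lnk_c = est[paste0("mob_lnk.", eluents)],
                   slope = est[paste0("mob_slope.", eluents)],
                   se_lnk = se[paste0("mob_lnk.", eluents)],
                   se_slope = se[paste0("mob_slope.", eluents)]),
    tibble::tibble(phase = "stat_forward", unit = columns,
                   lnk_c = est[paste0("statf_lnk.", columns)],
                   slope = est[paste0("statf_slope.", columns)],
                   se_lnk = se[paste0("statf_lnk.", columns)],
                   se_slope = se[paste0("statf_slope.", columns)]),
    tibble::tibble(phase = "stat_reverse", unit = columns,
                   lnk_c = est[paste0("statr_lnk.", columns)],
                   slope = est[paste0("statr_slope.", columns)],
                   se_lnk = se[paste0("statr_lnk.", columns)],
                   se_slope = se[paste0("statr_slope.", columns)])) |>
    dplyr::mutate(dH = .data$slope * R, se_dH = .data$se_slope * R,
                  dS = (.data$lnk_c - log(60 * thermo_constants()$kB * Tc /
                                            thermo_constants()$h) +
                          .data$slope / Tc) * R,
                  dG_Tc = .data$dH - Tc * .data$dS)

  rc <- run_counts(unname(est))
  gw <- gidd_weight_matrix(xq, rc$a, rc$b, A0v)
  recon <- purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    bs <- basis[[i]]
    yhat <- as.vector(bs$G %*% (wq * gw$W[, i])) +
      A0v[i] * gw$delta_a[i] * bs$gA + (1 - A0v[i]) * gw$delta_b[i] * bs$gB
    tibble::tibble(run = runs$run[i], a = rc$a[i], b = rc$b[i],
                   k_mob = rc$km[i], k_stat_f = rc$kf[i],
                   k_stat_r = rc$kr[i],
                   rmse = sqrt(mean((bs$y - yhat)^2)))
  })

  structure(list(estimate = est, se = se, hessian = H, cov = cov,
                 hessian_pd = pd, param_table = param_table, runs = recon,
                 Tc = Tc, value = best$value,
                 converged = best$convergence == 0 && pd),
            class = "eb_fit")
}

#' @export
print.eb_fit <- function(x, ...) {
  cat(sprintf("<eb_fit> %d parameters, Tc = %.2f K, -log posterior = %.4g%s\n",
              length(x$estimate), x$Tc, x$value,
              if (x$converged) "" else " (NOT converged)"))
  print(dplyr::select(x$param_table, "phase", "unit", "dH", "se_dH", "dG_Tc"))
  invisible(x)
}

#' Informative priors from the mixed-effects decomposition
#'
#' Per eluent (mobile) and per column (stationary, each direction), the
#' phase-rate table from [extract_phase_rates()] is regressed on the
#' Eyring-linearised temperature axis to give prior means for `ln k` at
#' the median temperature and the `dH/R` slope; prior SDs are the
#' regression SEs inflated by `inflate` (default 2). Cells with too few
#' positive rates fall back to diffuse priors.
#'
#' @param phase_rates Tibble from [extract_phase_rates()].
#' @param Tc Reference temperature; default the median of the table.
#' @param inflate Prior SD inflation factor.
#' @return Tibble `name`, `mean`, `sd` matching the [fit_ebayes()]
#'   parameter names.
#' @export
eb_priors_from_mem <- function(phase_rates, Tc = NULL, inflate = 2) {
  Tc <- Tc %||% stats::median(phase_rates$temperature)
  one <- function(df, prefix, unit) {
    df <- df[is.finite(df$k) & df$k > 0, ]
    if (nrow(df) < 3) return(NULL)
    x <- 1 / df$temperature - 1 / Tc
    y <- log(df$k) - log(df$temperature / Tc)
    w <- if (all(is.finite(df$se)) && all(df$se > 0)) (df$k / df$se)^2 else
      rep(1, nrow(df))
    fit <- weighted_line(x, y, w, scale_by_residuals = !all(df$se > 0))
    tibble::tibble(
      name = c(paste0(prefix, "_lnk.", unit), paste0(prefix, "_slope.", unit)),
      mean = c(fit$intercept, -fit$slope),
      sd = inflate * c(min(max(fit$se_intercept, 0.05), 1.5),
                       min(max(fit$se_slope, 200), 3000)))
  }
  out <- list()
  for (el in unique(stats::na.omit(phase_rates$eluent))) {
    out[[paste0("m", el)]] <-
      one(phase_rates[phase_rates$phase == "mobile" &
                        phase_rates$eluent == el, ], "mob", el)
  }
  for (co in unique(stats::na.omit(phase_rates$column))) {
    out[[paste0("f", co)]] <-
      one(phase_rates[phase_rates$phase == "stat_forward" &
                        phase_rates$column == co, ], "statf", co)
    out[[paste0("r", co)]] <-
      one(phase_rates[phase_rates$phase == "stat_reverse" &
                        phase_rates$column == co, ], "statr", co)
  }
  dplyr::bind_rows(out)
}

#' Laplace covariance of an empirical-Bayes fit
#'
#' @param fit An `eb_fit`.
#' @return List `se` (named vector) and `cov` (matrix), both on the
#'   optimisation scale.
#' @export
laplace_se <- function(fit) {
  list(se = fit$se, cov = fit$cov)
}
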
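# High-level workflow helpers: from a table of runs to phase-specific
# activation thermodynamics.

#' Descriptor table for a set of runs
#'
#' Applies [estimate_peak_params()] to every chromatogram; runs whose
#' Batman descriptors are undefined (fully coalesced) are dropped with a
#' message and listed in the `dropped` attribute.
#'
#' @param runs Tibble with metadata columns and a `chrom` list-column.
#' @return Tibble of metadata + descriptors, one row per usable run.
#' @export
describe_runs <- function(runs) {
  meta_cols <- setdiff(names(runs), "chrom")
  res <- purrr::map(seq_len(nrow(runs)), function(i) {
    p <- try(estimate_peak_params(runs$chrom[[i]]), silent = TRUE)
    if (inherits(p, "try-error")) return(NULL)
    dplyr::bind_cols(runs[i, meta_cols],
                     p[, setdiff(names(p), intersect(names(p), meta_cols))])
  })
  dropped <- runs$run[vapply(res, is.null, logical(1))]
  if (length(dropped)) {
    message(length(dropped), " run(s) dropped: descriptors undefined")
  }
  out <- dplyr::bind_rows(res)
  attr(out, "dropped") <- dropped
  out
}

#' Conversion counts for a run table by stochastic profile fitting
#'
#' Fits every run with [fit_batman()], warm-started per run from the
#' measured geometry and from [warm_start_counts()] (Eyring-linear
#' extrapolation of the unified-equation counts of reliably resolved
#' runs in the same column x eluent x flow family). A light fitting
#' specification is used by default so that hundreds of runs stay
#' tractable; pass `spec_args` to override.
#'
#' @param runs Run tibble (with `chrom` list-column).
#' @param peaks Descriptor table from [describe_runs()].
#' @param spec_args List of overrides for [fit_spec()].
#' @return `peaks` with added columns `a`, `b`, `se_a`, `se_b`, the
#'   fitted model parameters (`n_fit`, `tauA_fit`, `tauB_fit`,
#'   `sigma_m_fit`), `converged`, `sse`.
#' @export
estimate_counts <- function(runs, peaks, spec_args = list()) {
  ur <- ue_rates(peaks)
  ws <- warm_start_counts(
    dplyr::mutate(ur, a0 = .data$kf * .data$tA, b0 = .data$kr * .data$tB),
    family = intersect(c("column", "eluent", "flow"), names(ur)))
  fits <- purrr::map(seq_len(nrow(ws)), function(i) {
    row <- ws[i, ]
    ch <- runs$chrom[[match(row$run, runs$run)]]
    N_eff <- chrom_meta(ch)$N_hint %||% row$N
    sp <- stoch_params_from_moments(row$tM, row$tA, row$tB, N_eff)
    spec <- do.call(fit_spec, utils::modifyList(list(
      seed = row$run,
      de = list(pop_factor = 4, max_gen = 6, stagnation = 4),
      lm = list(maxiter = 40),
      sim = list(n_grid_de = 1024, nodes_de = 16, n_grid = 1024, nodes = 20)),
      spec_args))
    clamp <- function(v, lo = 1e-2, hi = 50) {
      if (!is.finite(v) || v <= 0) 0.5 else min(max(v, lo), hi)
    }
    f <- suppressWarnings(fit_batman(
      ch, peaks = row, spec = spec,
      init = list(n = sp$n, tauA = sp$tauA, tauB = sp$tauB,
                  a = clamp(row$a_init), b = clamp(row$b_init))))
    est <- f$estimate
    tibble::tibble(a = f$a, b = f$b,
                   se_a = f$se["a"], se_b = f$se["b"],
                   n_fit = est["n"], tauA_fit = est["tauA"],
                   tauB_fit = est["tauB"], sigma_m_fit = f$sigma_m,
                   converged = f$converged, sse = f$sse)
  })
  dplyr::bind_cols(ws, dplyr::bind_rows(fits))
}

#' Peak moments for all runs by retention extrapolation
#'
#' Runs whose Batman descriptors were measurable contribute the
#' geometry recovered by the stochastic fits; for the remaining
#' (coalesced) runs the retention times are interpolated/extrapolated
#' along the van't Hoff trend `ln k_fact ~ 1/T` of the same
#' column x eluent x flow family, and the widths follow from the plate
#' number (`s = t / sqrt(N)`). This is what makes the global model
#' applicable to the strongly exchanged part of the design.
#'
#' @param counts Fit table from [estimate_counts()].
#' @param runs Full run table (metadata incl. `tM`, `N`).
#' @return Tibble `run`, `tA`, `tB`, `sA`, `sB` for every run where a
#'   moment estimate exists.
#' @export
extrapolate_moments <- function(counts, runs) {
  fitted <- dplyr::transmute(
    counts, run = .data$run,
    tA = .data$tM + .data$n_fit * .data$tauA_fit,
    tB = .data$tM + .data$n_fit * .data$tauB_fit,
    sA = sqrt(2 * .data$n_fit * .data$tauA_fit^2 + .data$sigma_m_fit^2),
    sB = sqrt(2 * .data$n_fit * .data$tauB_fit^2 + .data$sigma_m_fit^2))
  missing <- dplyr::anti_join(runs, fitted, by = "run")
  if (nrow(missing) == 0) return(fitted)
  fam <- c("column", "eluent", "flow")
  anchors <- dplyr::inner_join(
    fitted, runs[, c("run", fam, "temperature", "tM", "N")], by = "run")
  extra <- missing |>
    dplyr::group_by(dplyr::across(dplyr::all_of(fam))) |>
    dplyr::group_modify(function(df, key) {
      anc <- dplyr::semi_join(anchors, key, by = fam)
      if (nrow(anc) < 2 || length(unique(anc$temperature)) < 2) {
        return(df[0, c("run", "temperature", "tM", "N")])
      }
      fa <- stats::lm(log((tA - tM) / tM) ~ I(1 / temperature), data = anc)
      fb <- stats::lm(log((tB - tM) / tM) ~ I(1 / temperature), data = anc)
      df$tA <- df$tM * (1 + exp(stats::predict(fa, newdata = df)))
      df$tB <- df$tM * (1 + exp(stats::predict(fb, newdata = df)))
      df$sA <- df$tA / sqrt(df$N)
      df$sB <- df$tB / sqrt(df$N)
      df[, c("run", "tA", "tB", "sA", "sB")]
    }) |>
    dplyr::ungroup()
  dplyr::bind_rows(fitted, extra[, c("run", "tA", "tB", "sA", "sB")])
}

#' Pooled apparent rates per condition from UE and stochastic counts
#'
#' The unified-equation rates of the individual runs are pooled by
#' inverse variance within each column x eluent x temperature cell; the
#' one-site stochastic rates come from the flow-series regressions
#' `a = kf tA`, `b = kr tB`. Model-level outliers are flagged against
#' the within-cell median before the final pooling.
#'
#' @param counts Output of [estimate_counts()] (which already carries
#'   the UE columns); if the stochastic columns are absent only UE is
#'   pooled.
#' @param source `"pooled"` (default) or `"ue"` to restrict the
#'   decomposition input to unified-equation rates.
#' @param ue_hp_max Plateau-height validity cut for the unified
#'   equation (default 35 on the 0-100 scale): beyond it the closed-form
#'   rates degrade systematically and are excluded from pooling.
#' @return Tibble per cell and direction: `k_pool`, `se`, `k_fact`.
#' @export
pool_run_rates <- function(counts, source = c("pooled", "ue"),
                           ue_hp_max = 35) {
  source <- match.arg(source)
  by <- c("column", "eluent", "temperature")
  counts_ue <- dplyr::filter(counts, .data$hp <= ue_hp_max)
  long_ue <- dplyr::bind_rows(
    dplyr::transmute(counts_ue, dplyr::across(dplyr::all_of(by)),
                     direction = "forward", k = .data$kf, se = .data$se_kf,
                     k_fact = (.data$tA - .data$tM) / .data$tM),
    dplyr::transmute(counts_ue, dplyr::across(dplyr::all_of(by)),
                     direction = "reverse", k = .data$kr, se = .data$se_kr,
                     k_fact = (.data$tB - .data$tM) / .data$tM)) |>
    dplyr::filter(is.finite(.data$k), .data$k > 0, is.finite(.data$se))
  kfact_tbl <- dplyr::bind_rows(
    dplyr::transmute(counts, dplyr::across(dplyr::all_of(by)),
                     direction = "forward",
                     k_fact = (.data$tA - .data$tM) / .data$tM),
    dplyr::transmute(counts, dplyr::across(dplyr::all_of(by)),
                     direction = "reverse",
                     k_fact = (.data$tB - .data$tM) / .data$tM)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "direction")))) |>
    dplyr::summarise(k_fact = mean(.data$k_fact), .groups = "drop")
  ue_cond <- pool_rates(long_ue, by = c(by, "direction")) |>
    dplyr::mutate(model = "ue") |>
    dplyr::rename(k = "k_pool")

  ests <- ue_cond
  if (all(c("a", "b") %in% names(counts)) && source == "pooled") {
    st <- rates_from_1site(dplyr::filter(counts, .data$converged), by = by)
    st_long <- dplyr::bind_rows(
      dplyr::transmute(st, dplyr::across(dplyr::all_of(by)),
                       direction = "forward", k = .data$kf, se = .data$se_kf,
                       model = "stoch1"),
      dplyr::transmute(st, dplyr::across(dplyr::all_of(by)),
                       direction = "reverse", k = .data$kr, se = .data$se_kr,
                       model = "stoch1")) |>
      dplyr::filter(is.finite(.data$k), .data$k > 0, is.finite(.data$se),
                    .data$se > 0)
    ests <- dplyr::bind_rows(ue_cond[, c(by, "direction", "k", "se", "model")],
                             st_long)
  }
  ests <- flag_model_outliers(ests, by = c(by, "direction"))
  pooled <- pool_rates(dplyr::filter(ests, !.data$outlier),
                       by = c(by, "direction"))
  dplyr::left_join(pooled, kfact_tbl, by = c(by, "direction")) |>
    dplyr::filter(is.finite(.data$k_pool), is.finite(.data$se), .data$se > 0,
                  is.finite(.data$k_fact))
}

#' Mobile-phase Eyring fits per eluent from a phase-rate table
#'
#' @param phase_rates Output of [extract_phase_rates()].
#' @param min_T Minimum number of temperatures required (default 3).
#' @return Tibble per eluent: Eyring parameters with SEs.
#' @export
mobile_eyring <- function(phase_rates, min_T = 3) {
  mob <- dplyr::filter(phase_rates, .data$phase == "mobile",
                       is.finite(.data$k), .data$k > 0)
  purrr::map_dfr(unique(mob$eluent), function(el) {
    sub <- dplyr::filter(mob, .data$eluent == el)
    if (length(unique(sub$temperature)) < min_T) return(NULL)
    ey <- fit_eyring(sub[, c("temperature", "k", "se")])
    dplyr::bind_cols(tibble::tibble(eluent = el), ey)
  })
}
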
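# Synthetic-data generators with full ground truth: Batman chromatogram
# designs, overload ladders, and CD decay traces.

#' Experimental-design specification for the Batman generator
#'
#' Defaults emulate a systematic dynamic-HPLC study: 4 cellulose-type
#' columns x 3 eluents x 7 temperatures (283.15-313.15 K in 5 K steps)
#' x 6 flow rates (0.5-1.2 mL/min), with phase-specific Eyring truths of
#' the magnitude typical for conformationally stereolabile analytes
#' (enthalpies 60-95 kJ/mol, entropies -0.1-0.03 kJ/(K mol)). Retention
#' truths (capacity factor, selectivity, mild van't Hoff temperature
#' dependence) and plate numbers are the generator's own realistic
#' choices, recorded in the returned truth table.
#'
#' @param columns,eluents Labels.
#' @param temperatures Kelvin.
#' @param flows mL/min.
#' @param mobile_truth Tibble `eluent`, `dH`, `dS` (kJ/mol, kJ/(K mol)):
#'   mobile-phase activation truths per eluent.
#' @param stat_truth Tibble `column`, `dH_f`, `dS_f`, `dH_r`, `dS_r`:
#'   stationary-phase truths per column.
#' @param retention Tibble `column`, `eluent`, `kfact0` (capacity factor
#'   of A at 298.15 K), `alpha` (selectivity), `dH_ret` (kJ/mol).
#' @param hold_up_volume Column hold-up volume (mL), sets `tM = V / flow`.
#' @param plate_base Plate number at 0.5 mL/min; scales as
#'   `sqrt(0.5 / flow)`.
#' @param noise_sd Gaussian noise SD as a fraction of the maximum signal.
#' @param seed Integer seed.
#' @return List of class `design_spec`.
#' @export
design_spec <- function(columns = paste0("Cell-", 1:4),
                        eluents = c("acetonitrile", "ethanol", "methanol"),
                        temperatures = seq(283.15, 313.15, by = 5),
                        flows = c(0.5, 0.6, 0.7, 0.9, 1.0, 1.2),
                        mobile_truth = NULL, stat_truth = NULL,
                        retention = NULL, hold_up_volume = 1.5,
                        plate_base = 6000, noise_sd = 0.01, seed = 1) {
  mobile_truth <- mobile_truth %||% tibble::tibble(
    eluent = eluents,
    dH = c(60, 69.5, 72.5)[seq_along(eluents)],
    dS = c(-0.080, -0.050, -0.040)[seq_along(eluents)])
  stat_truth <- stat_truth %||% tibble::tibble(
    column = columns,
    dH_f = c(78, 80, 71, 76)[seq_along(columns)],
    dS_f = c(-0.025, -0.030, -0.050, -0.030)[seq_along(columns)],
    dH_r = c(90, 85, 74, 78)[seq_along(columns)],
    dS_r = c(0.005, -0.020, -0.050, -0.030)[seq_along(columns)])
  if (is.null(retention)) {
    grid <- tidyr::expand_grid(column = columns, eluent = eluents)
    set.seed(seed + 777)
    retention <- dplyr::mutate(
      grid,
      kfact0 = stats::runif(dplyr::n(), 0.6, 1.8),
      alpha = stats::runif(dplyr::n(), 1.15, 1.45),
      dH_ret = stats::runif(dplyr::n(), -12, -6))
  }
  structure(list(columns = columns, eluents = eluents,
                 temperatures = temperatures, flows = flows,
                 mobile_truth = mobile_truth, stat_truth = stat_truth,
                 retention = retention, hold_up_volume = hold_up_volume,
                 plate_base = plate_base, noise_sd = noise_sd, seed = seed),
            class = "design_spec")
}

# Stochastic one-site parameters reproducing (tM, tA, tB, N).
stoch_params_from_moments <- function(tM, tA, tB, N) {
  sA <- tA / sqrt(N)
  sigma_m <- tM / sqrt(N)
  tauA <- max((sA^2 - sigma_m^2) / (2 * (tA - tM)), 1e-8)
  n <- (tA - tM) / tauA
  tauB <- (tB - tM) / n
  list(n = n, tauA = tauA, tauB = tauB, sigma_m = sigma_m)
}

#' Generate a full synthetic Batman design with ground truth
#'
#' For every design cell the phase-specific rates follow from the Eyring
#' truths, the apparent rates from the capacity-factor mixture
#' `k_obs = k_mob / (1 + k) + k_stat * k / (1 + k)`, the conversion
#' counts from `a = k_obs,f * tA`, `b = k_obs,r * tB`, and the profile
#' from [simulate_batman()] with one-site models matching the cell's
#' retention moments; Gaussian noise is added last. Every intermediate is
#' recorded in the truth table. Byte-identical regeneration for a fixed
#' seed.
#'
#' @param design A [design_spec()].
#' @param n_grid Profile grid length per run.
#' @return List: `runs` (tibble of metadata with a `chrom` list-column of
#'   [chromatogram()]s) and `truth` (tibble of all generating values).
#' @export
gen_batman_dataset <- function(design = design_spec(), n_grid = 2048) {
  cells <- tidyr::expand_grid(column = design$columns,
                              eluent = design$eluents,
                              temperature = design$temperatures,
                              flow = design$flows)
  cells <- cells |>
    dplyr::left_join(design$retention, by = c("column", "eluent")) |>
    dplyr::left_join(design$mobile_truth, by = "eluent") |>
    dplyr::left_join(design$stat_truth, by = "column")
  R <- thermo_constants()$R
  truth <- cells |>
    dplyr::mutate(
      run = dplyr::row_number(),
      tM = design$hold_up_volume / .data$flow,
      kfA = .data$kfact0 * exp(-.data$dH_ret / R *
                                 (1 / 298.15 - 1 / .data$temperature)),
      kfB = .data$alpha * .data$kfA,
      tA = .data$tM * (1 + .data$kfA),
      tB = .data$tM * (1 + .data$kfB),
      N = design$plate_base * sqrt(0.5 / .data$flow),
      k_mob = eyring_rate(.data$dH, .data$dS, .data$temperature),
      k_stat_f = eyring_rate(.data$dH_f, .data$dS_f, .data$temperature),
      k_stat_r = eyring_rate(.data$dH_r, .data$dS_r, .data$temperature),
      kobs_f = .data$k_mob / (1 + .data$kfA) +
        .data$k_stat_f * .data$kfA / (1 + .data$kfA),
      kobs_r = .data$k_mob / (1 + .data$kfB) +
        .data$k_stat_r * .data$kfB / (1 + .data$kfB),
      a = .data$kobs_f * .data$tA,
      b = .data$kobs_r * .data$tB)
  sp <- purrr::pmap(truth[, c("tM", "tA", "tB", "N")],
                    stoch_params_from_moments)
  truth$n_steps <- vapply(sp, `[[`, 0, "n")
  truth$tauA <- vapply(sp, `[[`, 0, "tauA")
  truth$tauB <- vapply(sp, `[[`, 0, "tauB")
  truth$sigma_m <- vapply(sp, `[[`, 0, "sigma_m")

  chroms <- purrr::map(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    span <- tr$tB + 10 * tr$tB / sqrt(tr$N) + tr$tM
    simulate_batman(
      cf_one_site(tr$n_steps, tr$tauA), cf_one_site(tr$n_steps, tr$tauB),
      a = tr$a, b = tr$b, tM = tr$tM, A0 = 0.5, sigma_m = tr$sigma_m,
      grid = sim_grid(span, n_grid),
      noise_sd = design$noise_sd, seed = design$seed + i,
      meta = list(column = tr$column, eluent = tr$eluent,
                  temperature_K = tr$temperature, flow_mL_min = tr$flow,
                  A0 = 0.5, tM = tr$tM, tM_hint = tr$tM,
                  N_hint = tr$N))
  })
  runs <- truth |>
    dplyr::select("run", "column", "eluent", "temperature", "flow", "tM",
                  "N") |>
    dplyr::mutate(chrom = chroms)
  list(runs = runs, truth = truth)
}

#' Generate the randomized single-run fitting suite
#'
#' Draws independent Batman runs with conversion counts `a` uniform in
#' `a_range`, `b` tied to `a` through the retention-ratio relation (equal
#' equilibrium areas for a racemic injection give `b = a`), plate numbers
#' uniform in `N_range`, and randomized hold-up/retention geometry; adds
#' Gaussian noise. Used to exercise the two-stage fit protocol.
#'
#' @param n_runs Number of runs (default 60).
#' @param a_range,N_range Uniform sampling ranges.
#' @param noise_sd Noise SD as fraction of maximum signal (default 0.01).
#' @param seed Integer seed (default 42).
#' @param n_grid Profile grid length.
#' @return List `runs` (tibble with `chrom` list-column), `truth`.
#' @export
gen_fit_suite <- function(n_runs = 60, a_range = c(0.1, 5),
                          N_range = c(2000, 8000), noise_sd = 0.01,
                          seed = 42, n_grid = 2048) {
  set.seed(seed)
  truth <- tibble::tibble(
    run = seq_len(n_runs),
    tM = stats::runif(n_runs, 1.5, 3),
    kfA = stats::runif(n_runs, 0.6, 2),
    alpha = stats::runif(n_runs, 1.15, 1.5),
    N = stats::runif(n_runs, N_range[1], N_range[2]),
    a = stats::runif(n_runs, a_range[1], a_range[2]),
    b = .data$a,
    tA = .data$tM * (1 + .data$kfA),
    tB = .data$tM * (1 + .data$alpha * .data$kfA))
  sp <- purrr::pmap(truth[, c("tM", "tA", "tB", "N")],
                    stoch_params_from_moments)
  truth$n_steps <- vapply(sp, `[[`, 0, "n")
  truth$tauA <- vapply(sp, `[[`, 0, "tauA")
  truth$tauB <- vapply(sp, `[[`, 0, "tauB")
  truth$sigma_m <- vapply(sp, `[[`, 0, "sigma_m")
  chroms <- purrr::map(seq_len(n_runs), function(i) {
    tr <- truth[i, ]
    span <- tr$tB + 10 * tr$tB / sqrt(tr$N) + tr$tM
    simulate_batman(
      cf_one_site(tr$n_steps, tr$tauA), cf_one_site(tr$n_steps, tr$tauB),
      a = tr$a, b = tr$b, tM = tr$tM, A0 = 0.5, sigma_m = tr$sigma_m,
      grid = sim_grid(span, n_grid), noise_sd = noise_sd,
      seed = seed + 1000 + i,
      meta = list(A0 = 0.5, tM = tr$tM, tM_hint = tr$tM, N_hint = tr$N))
  })
  list(runs = dplyr::mutate(truth[, c("run", "tM", "tA", "tB", "N")],
                            chrom = chroms),
       truth = truth)
}

#' Generate an overload injection series
#'
#' Simulates the equilibrium-dispersive bi-Langmuir response of a
#' racemic injection ladder and adds proportional Gaussian noise.
#'
#' @param params [bilangmuir_params()] ground truth.
#' @param concentrations Total injected concentrations (mg/mL); split
#'   50/50 between the enantiomers.
#' @param column [column_spec()].
#' @param volume Injection volume (uL).
#' @param noise_sd Noise SD as a fraction of each profile's maximum.
#' @param seed Integer seed.
#' @param n_cells Axial cells for the generator.
#' @return List: `series` (tibble `injection`, `time`, `signal`),
#'   `injections` (tibble of [injection_spec()] fields), `truth`.
#' @export
gen_overload_series <- function(params, concentrations, column,
                                volume = 20, noise_sd = 0.005, seed = 1,
                                n_cells = 150) {
  set.seed(seed)
  series <- purrr::imap(concentrations, function(cc, i) {
    sim <- ed_simulate(params, column, injection_spec(cc / 2, cc / 2, volume),
                       n_cells = n_cells)
    tibble::tibble(injection = i, time = sim$time,
                   signal = pmax(sim$c_total +
                                   stats::rnorm(nrow(sim), 0,
                                                noise_sd * max(sim$c_total)),
                                 0))
  })
  list(series = dplyr::bind_rows(series),
       injections = tibble::tibble(injection = seq_along(concentrations),
                                   c1 = concentrations / 2,
                                   c2 = concentrations / 2, volume = volume),
       truth = params)
}

#' Generate CD racemization decay traces
#'
#' First-order ellipticity decays sampled every `dt` seconds with
#' per-temperature acquisition delays and additive Gaussian noise; the
#' absorbance channel is constant with its own noise.
#'
#' @param rates Tibble `temperature` (K), `k_rac` (1/s).
#' @param theta0 True ellipticity at kinetic time zero (mdeg).
#' @param delays Acquisition delays (s), recycled across temperatures.
#' @param absorbance Long-time absorbance (AU).
#' @param t_end Acquisition span (s).
#' @param dt Sampling interval (s, default 2).
#' @param noise_sd Ellipticity noise SD (mdeg).
#' @param seed Integer seed.
#' @return Tibble: `temperature`, `delay`, `t`, `ellipticity`,
#'   `absorbance` (long format).
#' @export
gen_cd_traces <- function(rates, theta0 = 30, delays = 24, absorbance = 1.5,
                          t_end = 1800, dt = 2, noise_sd = 0.15, seed = 1) {
  set.seed(seed)
  delays <- rep_len(delays, nrow(rates))
  purrr::map2(seq_len(nrow(rates)), delays, function(i, dly) {
    tt <- seq(0, t_end, by = dt)
    k <- rates$k_rac[i]
    tibble::tibble(
      temperature = rates$temperature[i], delay = dly, t = tt,
      ellipticity = theta0 * exp(-k * (tt + dly)) +
        stats::rnorm(length(tt), 0, noise_sd),
      absorbance = absorbance + stats::rnorm(length(tt), 0, noise_sd / 100))
  }) |> dplyr::bind_rows()
}
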
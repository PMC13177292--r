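# Peak profile synthesis by characteristic-function inversion and the
# Batman mixture over Keller-Giddings densities.

#' Elution profile from a characteristic function
#'
#' Inverse discrete Fourier transform of `Phi(omega)` times a Gaussian
#' mobile-phase dispersion CF, shifted by the hold-up time. The result is
#' clipped at zero (tolerance -1e-9) and renormalised to unit area.
#'
#' @param model A [cf_one_site()] or [cf_two_site()].
#' @param grid A [sim_grid()]; defaults to one spanning the peak support.
#' @param tM Hold-up time shift (min).
#' @param sigma_m Mobile-phase Gaussian dispersion SD (min).
#' @return Tibble `time`, `density` (unit area on the grid).
#' @export
elution_profile <- function(model, grid = NULL, tM = 0, sigma_m = 0) {
  grid <- grid %||% sim_grid(default_span(list(model), tM, sigma_m))
  check_grid_support(grid, list(model), tM, sigma_m)
  phi <- cf_value(model, grid$omega) *
    exp(1i * grid$omega * tM - sigma_m^2 * grid$omega^2 / 2)
  invert_cf(phi, grid)
}

# a grid that cannot hold the peak support wraps the profile (aliasing)
check_grid_support <- function(grid, models, tM, sigma_m) {
  need <- tM + max(vapply(models, cf_mean, numeric(1))) +
    4 * sqrt(max(vapply(models, cf_var, numeric(1))) + sigma_m^2)
  if (max(grid$t) < need) {
    stop("aliasing: grid span ", format(max(grid$t)),
         " min does not cover the peak support (needs ~", format(need),
         " min)", call. = FALSE)
  }
}

invert_cf <- function(phi, grid) {
  f <- Re(stats::fft(phi)) / (grid$n * grid$dt)
  tail_mass <- sum(f[grid$t > 0.98 * max(grid$t)]) * grid$dt
  if (abs(tail_mass) > 1e-4) {
    stop("aliasing detected: boundary mass ", format(tail_mass),
         "; enlarge the simulation grid", call. = FALSE)
  }
  neg_mass <- -sum(f[f < 0]) * grid$dt
  if (neg_mass > 1e-5 * sum(abs(f)) * grid$dt) {
    stop("aliasing detected: negative ringing mass ", format(neg_mass),
         "; enlarge the simulation grid", call. = FALSE)
  }
  f <- pmax(f, 0)
  f <- f / (sum(f) * grid$dt)
  tibble::tibble(time = grid$t, density = f)
}

# Linear parameter blend between the enantiomer-A and -B models at time
# fraction x spent as A (sojourn budgets interpolate linearly).
blend_models <- function(model_a, model_b, x) {
  if (inherits(model_a, "cf_one_site")) {
    list(n = x * model_a$n + (1 - x) * model_b$n,
         tau = x * model_a$tau + (1 - x) * model_b$tau,
         type = "one")
  } else {
    list(n = x * model_a$n + (1 - x) * model_b$n,
         p2 = x * model_a$p2 + (1 - x) * model_b$p2,
         tau1 = x * model_a$tau1 + (1 - x) * model_b$tau1,
         tau2 = x * model_a$tau2 + (1 - x) * model_b$tau2,
         type = "two")
  }
}

# CF matrix (n_omega x n_x) for the blended models at fractions x.
blend_cf_matrix <- function(model_a, model_b, x, omega) {
  bl <- blend_models(model_a, model_b, x)
  if (bl$type == "one") {
    E <- 1 / (1 - 1i * outer(omega, bl$tau)) - 1
    exp(sweep(E, 2, bl$n, "*"))
  } else {
    E1 <- 1 / (1 - 1i * outer(omega, bl$tau1))
    E2 <- 1 / (1 - 1i * outer(omega, bl$tau2))
    E <- sweep(E1, 2, 1 - bl$p2, "*") + sweep(E2, 2, bl$p2, "*") - 1
    exp(sweep(E, 2, bl$n, "*"))
  }
}

#' Simulate a Batman chromatogram
#'
#' Mixture profile of two interconverting enantiomers: for each injected
#' state the no-conversion component (weight `exp(-a)` resp. `exp(-b)`)
#' uses that enantiomer's own elution profile, while converted molecules
#' contribute profiles of models blended linearly at their time fraction
#' `x` spent as A, weighted by the Keller-Giddings densities integrated
#' with Gauss-Legendre quadrature. The Dirac (unconverted) component is
#' handled analytically, never discretised as a spike. The final profile
#' is renormalised to unit area.
#'
#' @param model_a,model_b CF models of the pure enantiomers (same class).
#' @param a,b Expected A->B and B->A conversion counts.
#' @param tM Hold-up time (min).
#' @param A0 Injected fraction of A.
#' @param sigma_m Mobile-phase Gaussian SD (min).
#' @param grid Optional [sim_grid()].
#' @param nodes Gauss-Legendre nodes over `x` (default 64).
#' @param check_quadrature If `TRUE`, doubles the node count until the L1
#'   change is below 1e-6 (at most 3 doublings), then errors if still
#'   unconverged.
#' @param noise_sd Gaussian noise SD as a fraction of the maximum signal.
#' @param seed Optional seed used when `noise_sd > 0`.
#' @param meta Metadata list stored on the returned chromatogram.
#' @return A [chromatogram()] whose intensity is the (noisy) unit-area
#'   density.
#' @export
simulate_batman <- function(model_a, model_b, a, b, tM, A0 = 0.5,
                            sigma_m = 0, grid = NULL, nodes = 64,
                            check_quadrature = FALSE, noise_sd = 0,
                            seed = NULL, meta = list()) {
  stopifnot(a >= 0, b >= 0, A0 >= 0, A0 <= 1)
  grid <- grid %||%
    sim_grid(default_span(list(model_a, model_b), tM, sigma_m))
  check_grid_support(grid, list(model_a, model_b), tM, sigma_m)

  mix_phi <- function(nq) {
    gl <- x_quadrature(nq)
    gw <- giddings_weights(gl$x, a, b, A0)
    phi <- blend_cf_matrix(model_a, model_b, gl$x, grid$omega) %*%
      (gl$w * gw$w)
    as.vector(phi) +
      A0 * gw$delta_a * cf_value(model_a, grid$omega) +
      (1 - A0) * gw$delta_b * cf_value(model_b, grid$omega)
  }

  phi <- mix_phi(nodes)
  if (check_quadrature) {
    for (iter in 1:3) {
      nodes2 <- nodes * 2
      phi2 <- mix_phi(nodes2)
      l1 <- sum(Mod(phi2 - phi)) / sum(Mod(phi))
      phi <- phi2; nodes <- nodes2
      if (l1 < 1e-6) break
      if (iter == 3 && l1 >= 1e-6) {
        stop("quadrature over x did not converge (L1 change ", format(l1), ")",
             call. = FALSE)
      }
    }
  }

  phi <- phi * exp(1i * grid$omega * tM - sigma_m^2 * grid$omega^2 / 2)
  prof <- invert_cf(phi, grid)
  y <- prof$density
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd * max(y))
  }
  meta$A0 <- meta$A0 %||% A0
  chromatogram(prof$time, y, meta = meta)
}

#' Event-level Monte-Carlo sampler of the Batman model
#'
#' Direct stochastic simulation used as an independent cross-check of the
#' Fourier/quadrature machinery: each molecule's A/B state history is
#' simulated event by event over the run (exponential waiting times with
#' intensities `a` while in A and `b` while in B), giving its time
#' fraction `x` as A; its elution time is then drawn from the compound
#' Poisson with the parameters blended at that `x` (Poisson number of
#' adsorption events, exponential sojourns, Gaussian mobile dispersion).
#' No Fourier transform, Bessel function or quadrature is involved.
#'
#' @inheritParams simulate_batman
#' @param n_molecules Number of molecules.
#' @param seed Seed (required for reproducibility).
#' @return Numeric vector of elution times with attributes
#'   `conversions_ab`, `conversions_ba` (total realised event counts) and
#'   `end_state` (factor of final states).
#' @export
simulate_batman_mc <- function(model_a, model_b, a, b, tM, A0 = 0.5,
                               sigma_m = 0, n_molecules = 1e5, seed = 1) {
  set.seed(seed)
  n <- n_molecules
  state <- stats::runif(n) < A0          # TRUE = A
  pos <- numeric(n)                       # position on the normalised run
  x_frac <- numeric(n)                    # accumulated fraction as A
  n_ab <- 0L; n_ba <- 0L
  active <- rep(TRUE, n)
  while (any(active)) {
    idx <- which(active)
    rate <- ifelse(state[idx], a, b)
    wait <- ifelse(rate > 0, stats::rexp(length(idx), pmax(rate, 1e-300)), Inf)
    ends <- pos[idx] + wait >= 1
    fin <- idx[ends]
    x_frac[fin] <- x_frac[fin] + ifelse(state[fin], 1 - pos[fin], 0)
    active[fin] <- FALSE
    sw <- idx[!ends]
    if (length(sw)) {
      dt <- wait[!ends]
      x_frac[sw] <- x_frac[sw] + ifelse(state[sw], dt, 0)
      n_ab <- n_ab + sum(state[sw])
      n_ba <- n_ba + sum(!state[sw])
      state[sw] <- !state[sw]
      pos[sw] <- pos[sw] + dt
    }
  }

  bl <- blend_models(model_a, model_b, x_frac)
  n_ads <- stats::rpois(n, bl$n)
  if (bl$type == "one") {
    stat_t <- ifelse(n_ads > 0, stats::rgamma(n, shape = pmax(n_ads, 1e-12),
                                              scale = bl$tau), 0)
  } else {
    n2 <- stats::rbinom(n, n_ads, bl$p2)
    n1 <- n_ads - n2
    stat_t <- ifelse(n1 > 0, stats::rgamma(n, shape = pmax(n1, 1e-12),
                                           scale = bl$tau1), 0) +
      ifelse(n2 > 0, stats::rgamma(n, shape = pmax(n2, 1e-12),
                                   scale = bl$tau2), 0)
  }
  times <- tM + stat_t + if (sigma_m > 0) stats::rnorm(n, 0, sigma_m) else 0
  structure(times, conversions_ab = n_ab, conversions_ba = n_ba,
            end_state = factor(ifelse(state, "A", "B"), levels = c("A", "B")))
}

#' Kolmogorov-Smirnov distance between a sample and a model profile
#'
#' @param times Sample of elution times (e.g. from
#'   [simulate_batman_mc()]).
#' @param profile Tibble `time`, `density` or a [chromatogram()] holding
#'   the model density.
#' @return The KS statistic `max |ECDF - CDF|`.
#' @export
ks_distance <- function(times, profile) {
  y <- if ("density" %in% names(profile)) profile$density else profile$intensity
  cdf <- cumsum(y)
  cdf <- cdf / cdf[length(cdf)]
  ts <- sort(times)
  model_cdf <- stats::approx(profile$time, cdf, xout = ts, yleft = 0,
                             yright = 1, rule = 2, ties = "ordered")$y
  ec <- seq_along(ts) / length(ts)
  max(pmax(abs(ec - model_cdf), abs(ec - 1 / length(ts) - model_cdf)))
}
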
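# Shared fixtures, all generated in code.

# Noiseless Batman chromatogram with known one-site truth.
make_batman <- function(tM = 2, tA = 8, tB = 10, N = 5000, a = 0.5, b = a,
                        noise_sd = 0, seed = 1, n_grid = 2048) {
  sp <- dynchrom:::stoch_params_from_moments(tM, tA, tB, N)
  ch <- simulate_batman(
    cf_one_site(sp$n, sp$tauA), cf_one_site(sp$n, sp$tauB),
    a = a, b = b, tM = tM, sigma_m = sp$sigma_m,
    grid = sim_grid(tB * 1.4 + tM, n_grid), noise_sd = noise_sd, seed = seed,
    meta = list(A0 = 0.5, tM = tM, tM_hint = tM, N_hint = N))
  attr(ch, "truth") <- c(sp, list(a = a, b = b, tA = tA, tB = tB, N = N,
                                  tM = tM))
  ch
}

# Chromatogram made of plain Gaussians (marker + two retained peaks).
make_gaussians <- function(centers = c(2, 8, 10), sds = c(0.05, 0.1, 0.1),
                           heights = c(0.5, 1, 0.8), t_max = 14,
                           n = 2800, noise_sd = 0) {
  t <- seq(0, t_max, length.out = n)
  y <- Reduce(`+`, Map(function(c0, s0, h0) h0 * exp(-(t - c0)^2 / (2 * s0^2)),
                       centers, sds, heights))
  if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
  chromatogram(t, y, meta = list(A0 = 0.5))
}

expect_rel <- function(x, target, tol) {
  expect_lt(abs(x / target - 1), tol)
}
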
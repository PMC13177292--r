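test_that("a fit started at the truth stays at the truth on noiseless data", {
  ch <- make_batman(a = 0.6, noise_sd = 0)
  tr <- attr(ch, "truth")
  spec <- fit_spec(seed = 1, de = list(max_gen = 0, pop_factor = 2),
                   sim = list(n_grid = 2048, nodes = 64))
  f <- fit_batman(ch, spec = spec,
                  init = list(n = tr$n, tauA = tr$tauA, tauB = tr$tauB,
                              a = tr$a, b = tr$b))
  expect_true(f$converged)
  # residual quantisation from the slightly different fitting grid keeps
  # a tiny floor under the SSE; the parameters themselves stay put
  expect_lt(f$sse, 1e-5)
  expect_rel(f$a, tr$a, 1e-3)
  expect_rel(f$b, tr$b, 1e-3)
})

test_that("counts are recovered within 5% where the plateau is informative", {
  # hp in roughly [3, 60]: the regime where the descriptors are reliable
  for (a_true in c(0.15, 0.4, 0.9)) {
    ch <- make_batman(tM = 2, tA = 7, tB = 8.8, N = 5000, a = a_true,
                      noise_sd = 0.01, seed = 100 + round(100 * a_true))
    f <- suppressWarnings(fit_batman(ch, spec = fit_spec(seed = 7)))
    expect_true(f$converged)
    expect_rel(f$a, a_true, 0.05)
    expect_rel(f$b, a_true, 0.05)
  }
})

test_that("all accepted estimates respect the box constraints", {
  ch <- make_batman(a = 2.5, noise_sd = 0.01, seed = 3)
  f <- suppressWarnings(fit_batman(ch, spec = fit_spec(seed = 2)))
  expect_true(f$a >= 1e-3 && f$a <= 60 * exp(2))
  expect_true(all(is.finite(f$estimate)) && all(f$estimate > 0))
})

test_that("fitting is bit-for-bit reproducible for a fixed seed", {
  ch <- make_batman(a = 0.8, noise_sd = 0.01, seed = 21)
  f1 <- suppressWarnings(fit_batman(ch, spec = fit_spec(seed = 5)))
  f2 <- suppressWarnings(fit_batman(ch, spec = fit_spec(seed = 5)))
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$sse, f2$sse)
})

test_that("warm starts extrapolate along an Eyring line and fall back sanely", {
  runs <- tibble::tibble(
    column = "c1", eluent = "e1", flow = 1,
    temperature = c(283.15, 293.15, 303.15),
    a0 = exp(10 - 4000 / temperature), b0 = exp(9 - 3500 / temperature),
    hp = c(5, 10, 95))             # hottest run unreliable
  ws <- warm_start_counts(runs, hp_max = 30)
  expect_equal(ws$a_init, exp(10 - 4000 / runs$temperature), tolerance = 1e-8)
  expect_equal(ws$b_init, exp(9 - 3500 / runs$temperature), tolerance = 1e-8)

  single <- runs[1, ]
  ws1 <- warm_start_counts(single)
  expect_equal(ws1$a_init, 0.5)
})

test_that("one-site rate regressions recover slopes and resist contamination", {
  tA <- c(3, 3.6, 4.2, 5.4, 6, 7.2)
  fits <- tibble::tibble(column = "c", eluent = "e", temperature = 298,
                         a = 0.02 * tA, b = 0.015 * tA * 1.2,
                         se_a = 0.001, se_b = 0.001,
                         tA = tA, tB = tA * 1.2)
  r <- rates_from_1site(fits)
  expect_equal(r$kf, 0.02, tolerance = 1e-12)
  expect_equal(r$kr, 0.015, tolerance = 1e-12)

  dirty <- fits
  dirty$a[3] <- dirty$a[3] * 10
  rd <- rates_from_1site(dirty)
  expect_rel(rd$kf, 0.02, 0.02)
  expect_equal(rd$n_used, 5L)

  expect_true(rates_from_1site(fits[1:2, ])$wide_se)
})

test_that("the extended two-site regression reduces to mobile-only at p2 = 0", {
  base <- tibble::tibble(column = "c", eluent = "e", temperature = 298,
                         tM = c(1.5, 2, 2.5, 3), p2 = 0, n = 4000,
                         tau2A = 1e-3, tau2B = 1.2e-3,
                         a = 0.03 * c(1.5, 2, 2.5, 3),
                         b = 0.02 * c(1.5, 2, 2.5, 3),
                         se_a = 1e-3, se_b = 1e-3)
  r0 <- rates_from_2site(base)
  expect_equal(r0$kf, 0.03, tolerance = 1e-12)   # regressor collapses to tM
  expect_equal(r0$kr, 0.02, tolerance = 1e-12)

  ext <- base
  ext$p2 <- 0.6
  xA <- ext$tM + 0.6 * 4000 * 1e-3
  ext$a <- 0.025 * xA
  r1 <- rates_from_2site(ext)
  expect_equal(r1$kf, 0.025, tolerance = 1e-12)
})

test_that("the two-site model fits a two-site profile under a p2 prior window", {
  n <- 3000; p2 <- 0.35; tau1 <- 8e-4; tau2A <- 2.4e-3; tau2B <- 3.4e-3
  mA <- cf_two_site(n, p2, tau1, tau2A)
  mB <- cf_two_site(n, p2, tau1, tau2B)
  tM <- 2
  ch <- simulate_batman(mA, mB, 0.5, 0.5, tM = tM, sigma_m = 0.03,
                        noise_sd = 0.01, seed = 31,
                        meta = list(A0 = 0.5, tM = tM, tM_hint = tM,
                                    N_hint = 4000))
  spec <- fit_spec("twosite", p2_prior = p2, seed = 4,
                   de = list(max_gen = 12, stagnation = 6),
                   lm = list(maxiter = 300, ftol = 1e-8),
                   sim = list(n_grid = 1024, nodes = 24))
  f <- suppressWarnings(fit_batman(ch, spec = spec))
  expect_true(f$converged)
  expect_rel(f$a, 0.5, 0.25)
  # p2 stays inside the +/- 1 logit window around the prior
  lp <- log(f$estimate["p2"] / (1 - f$estimate["p2"]))
  expect_lt(abs(lp - log(p2 / (1 - p2))), 1 + 1e-8)
  # total retention predicted from the fitted parameters matches the apex
  est <- f$estimate
  tA_pred <- tM + est["n"] * ((1 - est["p2"]) * est["tau1"] +
                                est["p2"] * est["tau2A"])
  expect_rel(tA_pred, tM + n * ((1 - p2) * tau1 + p2 * tau2A), 0.02)
})
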
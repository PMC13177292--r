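make_trace <- function(theta0 = 30, k = 0.01, delay = 24, t_end = 600,
                       noise = 0, seed = 1, absorbance = 1.5) {
  set.seed(seed)
  tt <- seq(0, t_end, by = 2)
  tibble::tibble(t = tt,
                 ellipticity = theta0 * exp(-k * (tt + delay)) +
                   rnorm(length(tt), 0, noise),
                 absorbance = absorbance)
}

test_that("noiseless first-order decays are recovered exactly", {
  tr <- make_trace()
  fit <- fit_cd_decay(tr, delay = 24)
  expect_equal(fit$theta0, 30, tolerance = 1e-6)
  expect_equal(fit$k_rac, 0.01, tolerance = 1e-8)
  expect_true(fit$decaying)
})

test_that("a mis-specified delay biases the amplitude but not the rate", {
  tr <- make_trace(delay = 24)
  fit <- fit_cd_decay(tr, delay = 34)   # 10 s too late
  expect_equal(fit$k_rac, 0.01, tolerance = 1e-8)
  expect_rel(fit$theta0 / 30, exp(0.01 * 10), 1e-6)
})

test_that("co-estimated delays stay in bounds and recover the truth", {
  tr <- make_trace(delay = 24, noise = 0.05, seed = 3)
  # amplitude and delay are confounded; co-estimation needs theta0
  expect_error(fit_cd_decay(tr, estimate_delay = TRUE), "confounded")
  fit <- fit_cd_decay(tr, delay = 10, estimate_delay = TRUE,
                      theta0_fixed = 30)
  expect_true(fit$delay >= 0 && fit$delay <= 120)
  expect_rel(fit$delay, 24, 0.05)
  expect_rel(fit$k_rac, 0.01, 0.02)
})

test_that("the rate estimate is unbiased and scale-invariant under noise", {
  ks <- vapply(1:100, function(r) {
    fit_cd_decay(make_trace(noise = 0.3, seed = r), delay = 24)$k_rac
  }, numeric(1))
  expect_lt(abs(mean(ks) / 0.01 - 1), 0.005)

  tr <- make_trace(noise = 0.1, seed = 7)
  f1 <- fit_cd_decay(tr, delay = 24)
  tr2 <- dplyr::mutate(tr, ellipticity = ellipticity * 13)
  f2 <- fit_cd_decay(tr2, delay = 24)
  expect_equal(f1$k_rac, f2$k_rac, tolerance = 1e-9)
})

test_that("racemization-to-enantiomerization scaling is a factor one half", {
  expect_equal(enantiomerization_rate(0.02), 0.01)
  expect_equal(enantiomerization_rate(0), 0)
})

test_that("the anisotropy factor converts units and propagates errors", {
  g <- g_factor(32.98, 1.0)
  expect_equal(g$G, 0.001)
  # doubling both amplitude and absorbance cancels
  expect_equal(g_factor(2 * 32.98, 2)$G, 0.001)
  expect_error(g_factor(30, 0), "positive")

  # delta-method SE against a quick bootstrap
  set.seed(5)
  gb <- g_factor(32.98, 1.0, se_theta0 = 0.5, se_absorbance = 0.02)
  boot <- (rnorm(2e4, 32.98, 0.5) / 32980) / rnorm(2e4, 1, 0.02)
  expect_rel(gb$se_G, sd(boot), 0.05)
})

test_that("confidence-interval overlap declares equivalence sensibly", {
  a <- tibble::tibble(temperature = c(280, 290), k = c(0.01, 0.02),
                      se = c(0.001, 0.002))
  expect_true(all(compare_rates(a, a)$equivalent))

  b <- dplyr::mutate(a, k = k * 10)
  expect_false(any(compare_rates(a, b)$equivalent))

  # matched truth: equivalence in at least 95% of replicates
  set.seed(10)
  hits <- vapply(1:200, function(r) {
    k1 <- 0.01 + rnorm(1, 0, 0.001); k2 <- 0.01 + rnorm(1, 0, 0.001)
    compare_rates(tibble::tibble(temperature = 280, k = k1, se = 0.001),
                  tibble::tibble(temperature = 280, k = k2, se = 0.001))$equivalent
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Arrhenius analysis of fitted CD rates recovers the generating energy", {
  temps <- seq(278.15, 293.15, by = 5)
  Ea <- 80; lnA <- 30
  rates <- tibble::tibble(temperature = temps,
                          k_rac = exp(lnA - Ea / thermo_constants()$R / temps))
  traces <- gen_cd_traces(rates, theta0 = 30, delays = c(20, 24, 28),
                          t_end = 1200, noise_sd = 0.15, seed = 2)
  fits <- traces |>
    dplyr::group_by(temperature) |>
    dplyr::group_modify(~ fit_cd_decay(.x, delay = .x$delay[1])) |>
    dplyr::ungroup()
  ar <- fit_arrhenius(dplyr::transmute(fits, temperature, k = k_rac, se = se_k))
  expect_lt(abs(ar$Ea - Ea), 2 * ar$se_Ea + 1)
})
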
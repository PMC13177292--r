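test_that("noiseless Eyring data are recovered exactly", {
  temps <- seq(283.15, 313.15, by = 5)
  k <- eyring_rate(70, -0.05, temps)
  fit <- fit_eyring(tibble::tibble(temperature = temps, k = k))
  expect_equal(fit$dH, 70, tolerance = 1e-8)
  expect_equal(fit$dS, -0.05, tolerance = 1e-10)
  expect_equal(fit$dG_ref, 70 + 0.05 * 298.15, tolerance = 1e-8)
  expect_error(fit_eyring(tibble::tibble(temperature = temps, k = -k)),
               "positive")
})

test_that("Gibbs energies reproduce the tabulated activation scale", {
  expect_equal(gibbs_energy(59.8, -0.08, 298.15), 83.652)
  expect_lt(abs(gibbs_energy(59.8, -0.08, 298.15) - 83.6), 0.06)
  expect_equal(gibbs_energy(70, 0, 310), 70)
  # linear in temperature
  g <- gibbs_energy(70, -0.05, c(280, 300, 320))
  expect_equal(diff(g, lag = 1), c(1, 1), tolerance = 1e-12)
})

test_that("inflating one point's uncertainty approaches leave-one-out", {
  temps <- seq(283.15, 313.15, by = 5)
  set.seed(6)
  k <- eyring_rate(70, -0.05, temps) * exp(rnorm(7, 0, 0.03))
  se <- 0.03 * k
  full <- fit_eyring(tibble::tibble(temperature = temps, k = k, se = se))
  se_inf <- se; se_inf[4] <- se[4] * 100
  infl <- fit_eyring(tibble::tibble(temperature = temps, k = k, se = se_inf))
  loo <- fit_eyring(tibble::tibble(temperature = temps[-4], k = k[-4],
                                   se = se[-4]))
  expect_lt(abs(infl$dH - loo$dH), loo$se_dH)
})

test_that("Arrhenius fits are exact and consistent with the Eyring enthalpy", {
  temps <- seq(283.15, 313.15, by = 5)
  k <- exp(25 - 8000 / temps)
  fit <- fit_arrhenius(tibble::tibble(temperature = temps, k = k))
  expect_equal(fit$Ea, 8000 * thermo_constants()$R, tolerance = 1e-8)
  expect_equal(fit$lnA, 25, tolerance = 1e-8)

  two <- fit_arrhenius(tibble::tibble(temperature = temps[c(1, 7)],
                                      k = k[c(1, 7)]))
  expect_equal(two$Ea, 8000 * thermo_constants()$R, tolerance = 1e-8)

  # Ea ~ dH + R T at the mid temperature
  ke <- eyring_rate(70, -0.05, temps)
  ea <- fit_arrhenius(tibble::tibble(temperature = temps, k = ke))$Ea
  expect_rel(ea, 70 + thermo_constants()$R * mean(temps), 0.01)
})

test_that("stated-error weighting matches a parametric bootstrap", {
  temps <- seq(283.15, 313.15, by = 5)
  k <- eyring_rate(70, -0.05, temps)
  se <- 0.04 * k
  fit <- fit_eyring(tibble::tibble(temperature = temps, k = k, se = se))

  # bootstrap the weighted regression with the same error model
  set.seed(42)
  R <- thermo_constants()$R
  x <- 1 / temps
  w <- (k / se)^2
  nboot <- 10000
  slopes <- numeric(nboot)
  for (bb in seq_len(nboot)) {
    kb <- k + rnorm(7, 0, se)
    if (any(kb <= 0)) { slopes[bb] <- NA; next }
    y <- log(kb / temps)
    W <- sum(w); xb <- sum(w * x) / W; yb <- sum(w * y) / W
    slopes[bb] <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  }
  se_boot <- sd(-slopes * R, na.rm = TRUE)
  expect_rel(fit$se_dH, se_boot, 0.05)
})
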
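test_that("characteristic functions obey their limit identities", {
  m1 <- cf_one_site(200, 0.01)
  expect_equal(cf_value(m1, 0), 1 + 0i)
  m0 <- cf_one_site(0, 0.01)
  w <- seq(-50, 50, length.out = 21)
  expect_equal(cf_value(m0, w), rep(1 + 0i, 21))

  set.seed(3)
  wr <- runif(20, -100, 100)
  m2 <- cf_two_site(200, 0, 0.01, 0.5)   # p2 = 0 reduces to one site
  expect_equal(cf_value(m2, wr), cf_value(cf_one_site(200, 0.01), wr),
               tolerance = 1e-12)
})

test_that("inverted profiles reproduce the compound-Poisson cumulants", {
  tM <- 2
  m1 <- cf_one_site(2000, 0.002)
  g <- sim_grid(dynchrom:::default_span(list(m1), tM), 4096)
  p <- elution_profile(m1, g, tM = tM)
  mu <- sum(p$time * p$density) * g$dt
  v <- sum((p$time - mu)^2 * p$density) * g$dt
  expect_lt(abs(mu - (tM + 2000 * 0.002)), g$dt)
  expect_rel(v, 2 * 2000 * 0.002^2, 0.005)

  m2 <- cf_two_site(1500, 0.3, 0.0015, 0.004)
  g2 <- sim_grid(dynchrom:::default_span(list(m2), tM), 4096)
  p2 <- elution_profile(m2, g2, tM = tM)
  mu2 <- sum(p2$time * p2$density) * g2$dt
  expect_lt(abs(mu2 - (tM + dynchrom:::cf_mean.cf_two_site(m2))), g2$dt)
})

test_that("a too-short grid triggers the aliasing guard", {
  m <- cf_one_site(2000, 0.002)   # mean stationary time 4 min
  expect_error(elution_profile(m, sim_grid(2, 1024), tM = 1), "aliasing")
})

test_that("interconversion densities conserve probability and mirror correctly", {
  for (a in c(0.1, 1, 5, 20)) for (b in c(0.1, 1, 5, 20)) {
    expect_lt(abs(giddings_mass(a, b) - 1), 1e-8)
  }
  # no conversions
  d0 <- giddings_density(c(0.2, 0.7), 0, 3)
  expect_equal(d0$p_same, c(0, 0))
  expect_equal(d0$p_opposite, c(0, 0))
  expect_equal(attr(d0, "delta_weight"), 1)
  # mirror identity at a = b: start-A density at x equals start-B at 1 - x
  x <- seq(0.05, 0.95, by = 0.1)
  dA <- giddings_density(x, 2, 2, start = "A")
  dB <- giddings_density(1 - x, 2, 2, start = "B")
  expect_equal(dA$p_same, dB$p_same, tolerance = 1e-12)
  expect_equal(dA$p_opposite, dB$p_opposite, tolerance = 1e-12)
})

test_that("no interconversion gives two clean peaks weighted by the injection", {
  mA <- cf_one_site(2000, 0.002); mB <- cf_one_site(2000, 0.003)
  ch <- simulate_batman(mA, mB, 0, 0, tM = 2, A0 = 0.7, sigma_m = 0.03)
  ft <- detect_features(ch)
  f <- split(ft, ft$feature)
  expect_equal(f$peakA$time, 2 + 4, tolerance = 0.02)
  expect_equal(f$peakB$time, 2 + 6, tolerance = 0.02)
  # peak areas split at the valley scale with the injection weights
  split_t <- (6 + 8) / 2
  aA <- dynchrom:::trapz_int(ch$time[ch$time <= split_t],
                             ch$intensity[ch$time <= split_t])
  aB <- dynchrom:::trapz_int(ch$time[ch$time > split_t],
                             ch$intensity[ch$time > split_t])
  expect_rel(aA / aB, 0.7 / 0.3, 0.02)
})

test_that("fast exchange collapses the profile to one peak at the mean retention", {
  mA <- cf_one_site(2000, 0.002); mB <- cf_one_site(2000, 0.003)
  ch <- simulate_batman(mA, mB, 35, 35, tM = 2, A0 = 0.5, sigma_m = 0.03)
  ft <- detect_features(ch)
  expect_true(attr(ft, "coalesced"))
  apex <- ft$time[ft$feature == "peakA"]
  expect_equal(apex, 2 + (4 + 6) / 2, tolerance = 0.05)
})

test_that("event-level Monte Carlo corroborates the Fourier mixture", {
  mA <- cf_one_site(2000, 0.002); mB <- cf_one_site(2000, 0.003)
  a <- 1.2; b <- 0.9; tM <- 2
  mc <- simulate_batman_mc(mA, mB, a, b, tM, A0 = 1, sigma_m = 0.04,
                           n_molecules = 3e4, seed = 5)
  # no-conversion survivors (still A at the end having never switched)
  # fraction ending in B matches the integrated opposite-state density
  p_ab <- integrate(function(x) giddings_density(x, a, b)$p_opposite, 0, 1,
                    rel.tol = 1e-10)$value
  frac_b <- mean(attr(mc, "end_state") == "B")
  se <- sqrt(p_ab * (1 - p_ab) / 3e4)
  expect_lt(abs(frac_b - p_ab), 3 * se)

  prof <- simulate_batman(mA, mB, a, b, tM, A0 = 1, sigma_m = 0.04)
  expect_lt(ks_distance(mc, prof), 0.015)
})

test_that("realised conversion counts respect the forward/backward asymmetry", {
  mA <- cf_one_site(2000, 0.002); mB <- cf_one_site(2000, 0.002)
  mc <- simulate_batman_mc(mA, mB, 2, 1, 2, A0 = 0.5, n_molecules = 4e4,
                           seed = 9)
  r <- attr(mc, "conversions_ab") / attr(mc, "conversions_ba")
  # intensities 2 vs 1 and near-equal occupancy: ratio near 2 * ExA/(1 * ExB)
  expect_gt(r, 1.2)
  expect_lt(r, 2.2)
})
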
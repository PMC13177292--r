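test_that("inverse-variance pooling matches the closed form and its limits", {
  tb <- tibble::tibble(direction = "forward", k = c(0.01, 0.012, 0.011),
                       se = c(0.001, 0.002, 0.004))
  p <- pool_rates(tb, by = "direction")
  w <- 1 / tb$se^2
  expect_equal(p$k_pool, sum(w * tb$k) / sum(w), tolerance = 1e-14)
  expect_equal(p$se, 1 / sqrt(sum(w)), tolerance = 1e-14)
  # frozen hand calculation of the same case
  expect_equal(p$k_pool, 0.01042857142857143, tolerance = 1e-12)
  expect_equal(p$se, 0.0008728715609439696, tolerance = 1e-12)

  eq <- pool_rates(tibble::tibble(direction = "f", k = c(0.01, 0.02, 0.03),
                                  se = rep(0.001, 3)), by = "direction")
  expect_equal(eq$k_pool, 0.02)

  dom <- pool_rates(tibble::tibble(direction = "f", k = c(0.01, 0.05),
                                   se = c(1e-9, 1)), by = "direction")
  expect_equal(dom$k_pool, 0.01, tolerance = 1e-6)
})

test_that("pooling is the minimum-variance linear combination", {
  set.seed(8)
  for (r in 1:5) {
    k <- runif(3, 0.01, 0.1); se <- runif(3, 0.001, 0.05)
    p <- pool_rates(tibble::tibble(direction = "f", k = k, se = se),
                    by = "direction")
    # brute force over the weight simplex
    w1 <- seq(0, 1, by = 0.01)
    best <- Inf
    for (u in w1) for (v in seq(0, 1 - u, by = 0.01)) {
      var_c <- u^2 * se[1]^2 + v^2 * se[2]^2 + (1 - u - v)^2 * se[3]^2
      best <- min(best, var_c)
    }
    expect_lte(p$se^2, best + 1e-10)
  }
})

test_that("model-level outlier flags behave at the median threshold", {
  same <- tibble::tibble(direction = "f", k = rep(0.02, 3))
  expect_false(any(flag_model_outliers(same, by = "direction")$outlier))

  mix <- tibble::tibble(direction = "f", k = c(0.019, 0.02, 0.021, 0.2))
  expect_equal(which(flag_model_outliers(mix, by = "direction")$outlier), 4L)

  # clean Gaussian groups: false-flag rate below 1%
  set.seed(12)
  n_flag <- 0; n_tot <- 0
  for (g in 1:200) {
    k <- rnorm(25, 0.05, 0.005)
    fl <- flag_model_outliers(tibble::tibble(direction = "f", k = k),
                              by = "direction")$outlier
    n_flag <- n_flag + sum(fl); n_tot <- n_tot + 25
  }
  expect_lt(n_flag / n_tot, 0.01)
})

test_that("the capacity-factor transform linearises the phase mixture exactly", {
  p0 <- tibble::tibble(k_pool = 0.02, se = 0.001, k_fact = 0)
  t0 <- transform_ktr(p0)
  expect_equal(t0$k_tr, 0.02)   # pure mobile contribution

  set.seed(4)
  km <- runif(20, 0.01, 0.1); ks <- runif(20, 0.001, 0.05)
  kf <- runif(20, 0.1, 3)
  kobs <- km / (1 + kf) + ks * kf / (1 + kf)
  tr <- transform_ktr(tibble::tibble(k_pool = kobs, se = 0.001, k_fact = kf))
  expect_equal(tr$k_tr, km + kf * ks, tolerance = 1e-12)
  expect_equal(tr$se_tr, 0.001 * (1 + kf), tolerance = 1e-12)
  expect_equal(tr$weight, 1 / ((1 + kf)^2 * 0.001^2), tolerance = 1e-9)
})

# balanced synthetic decomposition table built exactly from the
# mixed-model equation, with centred random effects
make_mem_table <- function(beta0 = 0.05, beta_f = 0.01, beta_delta = 0.004,
                           sd_u = 0, sd_v = 0, sd_e = 1e-9, seed = 1) {
  set.seed(seed)
  eluents <- paste0("e", 1:3); columns <- paste0("c", 1:4)
  temps <- seq(283, 313, by = 5)
  u <- rnorm(length(eluents) * length(temps), 0, sd_u)
  u <- if (sd_u > 0) u - mean(u) else u
  v <- rnorm(length(columns) * length(temps), 0, sd_v)
  v <- if (sd_v > 0) v - mean(v) else v
  d <- tidyr::expand_grid(eluent = eluents, column = columns,
                          temperature = temps,
                          direction = c("forward", "reverse"))
  d$k_fact <- 0.5 + 0.25 * match(d$column, columns) +
    0.001 * (d$temperature - 298)
  iu <- match(paste(d$eluent, d$temperature),
              paste(rep(eluents, each = length(temps)),
                    rep(temps, length(eluents))))
  iv <- match(paste(d$column, d$temperature),
              paste(rep(columns, each = length(temps)),
                    rep(temps, length(columns))))
  d$k_tr <- beta0 + beta_f * d$k_fact +
    beta_delta * d$k_fact * (d$direction == "reverse") +
    u[iu] + v[iv] * d$k_fact + rnorm(nrow(d), 0, sd_e)
  d$weight <- 1
  list(d = d, u = u, v = v)
}

test_that("the mixed model recovers fixed effects from exactly generated tables", {
  # no random-effect variability: the fixed effects are exact
  flat <- make_mem_table(sd_u = 0, sd_v = 0, sd_e = 1e-9)
  ffit <- suppressWarnings(fit_phase_mem(flat$d))
  expect_equal(ffit$beta0, 0.05, tolerance = 1e-6)
  expect_equal(ffit$beta_f, 0.01, tolerance = 1e-6)
  expect_equal(ffit$beta_delta, 0.004, tolerance = 1e-6)

  # with realised (centred) random effects the estimates match the
  # realisation up to the shrinkage of a finite design
  tbl <- make_mem_table(sd_u = 0.004, sd_v = 0.002, sd_e = 1e-6)
  fit <- suppressWarnings(fit_phase_mem(tbl$d))
  expect_equal(fit$beta0, 0.05, tolerance = 0.1)
  expect_equal(fit$beta_f, 0.01, tolerance = 0.25)
  expect_equal(fit$beta_delta, 0.004, tolerance = 0.05)
})

test_that("permuting rows leaves the fixed effects unchanged", {
  tbl <- make_mem_table(sd_u = 0.004, sd_v = 0.002, sd_e = 1e-4)$d
  f1 <- suppressWarnings(fit_phase_mem(tbl))
  set.seed(2)
  f2 <- suppressWarnings(fit_phase_mem(tbl[sample(nrow(tbl)), ]))
  expect_equal(f1$beta0, f2$beta0, tolerance = 1e-8)
  expect_equal(f1$beta_f, f2$beta_f, tolerance = 1e-8)
})

test_that("phase rates extract as intercept/slope combinations with flags", {
  tbl <- make_mem_table(sd_u = 0.004, sd_v = 0.002, sd_e = 1e-5)
  fit <- suppressWarnings(fit_phase_mem(tbl$d))
  pr <- extract_phase_rates(fit)
  expect_setequal(unique(pr$phase), c("mobile", "stat_forward", "stat_reverse"))
  fwd <- pr[pr$phase == "stat_forward", ]
  rev_ <- pr[pr$phase == "stat_reverse", ]
  m <- dplyr::inner_join(fwd, rev_, by = c("column", "temperature"))
  expect_equal(unique(round(m$k.y - m$k.x, 10)),
               round(fit$beta_delta, 10))
  expect_false(any(pr$negative[pr$k >= 0]))

  # with zero random-effect variability every mobile cell equals beta0
  flat <- make_mem_table(sd_u = 0, sd_v = 0, sd_e = 1e-5)
  ffit <- suppressWarnings(fit_phase_mem(flat$d))
  prf <- extract_phase_rates(ffit)
  kmob <- prf$k[prf$phase == "mobile"]
  expect_lt(diff(range(kmob)), 1e-4)
})
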
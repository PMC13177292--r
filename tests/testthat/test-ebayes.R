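# small synthetic design shared by the EB tests (built once per file)
eb_ds <- gen_batman_dataset(design_spec(
  columns = paste0("c", 1:2), eluents = paste0("e", 1:2),
  temperatures = seq(283.15, 298.15, by = 5), flows = c(0.6, 1.0),
  mobile_truth = tibble::tibble(eluent = paste0("e", 1:2),
                                dH = c(62, 70), dS = c(-0.075, -0.05)),
  stat_truth = tibble::tibble(column = paste0("c", 1:2),
                              dH_f = c(78, 72), dS_f = c(-0.03, -0.05),
                              dH_r = c(85, 74), dS_r = c(-0.015, -0.05)),
  noise_sd = 0.01, seed = 2), n_grid = 1024)
eb_pk <- suppressMessages(describe_runs(eb_ds$runs))
eb_cnt <- suppressWarnings(estimate_counts(eb_ds$runs, eb_pk))
eb_mom <- extrapolate_moments(eb_cnt, eb_ds$runs)
eb_er <- suppressMessages(prepare_eb_runs(eb_ds$runs, n_t = 100,
                                          moments = eb_mom))

test_that("the run model integrates to one and is two clean peaks at zero rates", {
  run <- tibble::tibble(
    run = 1, tM = 2, tA = 6, tB = 8, sA = 0.08, sB = 0.1, A0 = 0.5,
    temperature = 298,
    profile = list(tibble::tibble(time = seq(0, 16, length.out = 400),
                                  intensity = dnorm(seq(0, 16, length.out = 400),
                                                    7, 0.5))))
  mdl <- build_run_model(run)
  prof <- mdl(c(0, 0, 0))
  area <- dynchrom:::trapz_int(prof$time, prof$intensity)
  expect_equal(area, 1, tolerance = 1e-6)
  # no plateau between the peaks
  mid <- prof$intensity[prof$time > 6.5 & prof$time < 7.5]
  expect_lt(max(mid), 1e-4 * max(prof$intensity))
  at <- function(t0) prof$intensity[which.min(abs(prof$time - t0))]
  expect_gt(at(6), 0.4 * max(prof$intensity))
  expect_gt(at(8), 0.4 * max(prof$intensity))
})

test_that("the Gaussian-Giddings profile matches the CF simulator at high N", {
  tM <- 2; tA <- 7; tB <- 9; N <- 8000
  sp <- dynchrom:::stoch_params_from_moments(tM, tA, tB, N)
  ref <- simulate_batman(cf_one_site(sp$n, sp$tauA), cf_one_site(sp$n, sp$tauB),
                         a = 0.8, b = 0.8, tM = tM, sigma_m = sp$sigma_m,
                         grid = sim_grid(14, 4096))
  run <- tibble::tibble(
    run = 1, tM = tM, tA = tA, tB = tB, temperature = 298, A0 = 0.5,
    sA = sqrt(2 * sp$n * sp$tauA^2 + sp$sigma_m^2),
    sB = sqrt(2 * sp$n * sp$tauB^2 + sp$sigma_m^2),
    profile = list(tibble::tibble(time = ref$time, intensity = ref$intensity)))
  basis <- dynchrom:::eb_run_basis(run[1, ], nodes = 32)
  yhat <- dynchrom:::eb_profile(basis, 0.8, 0.8, 0.5)
  l1 <- sum(abs(yhat - ref$intensity)) / sum(abs(ref$intensity))
  expect_lt(l1, 0.02)
})

test_that("Laplace curvature is exact for quadratic objectives", {
  A <- matrix(c(4, 1, 0, 1, 3, 0.5, 0, 0.5, 2), 3, 3)
  f <- function(x) 0.5 * sum(x * (A %*% x))
  H <- dynchrom:::central_hessian(f, c(0.3, -0.2, 0.1))
  expect_equal(H, A, tolerance = 1e-6)
})

test_that("the global MAP fit tracks per-run truth on a small design", {
  eb <- suppressWarnings(fit_ebayes(eb_er, priors = NULL, seed = 1,
                                    n_starts = 1, maxit = 250, nodes = 20))
  cmp <- dplyr::inner_join(eb$runs,
                           eb_ds$truth[, c("run", "a", "k_mob")],
                           by = "run", suffix = c("", "_t"))
  expect_gt(cor(cmp$a, cmp$a_t), 0.95)
  expect_lt(median(abs(cmp$k_mob / cmp$k_mob_t - 1)), 0.35)
  expect_true(all(is.finite(eb$se)))
})

test_that("replicating the data shrinks the Laplace uncertainties", {
  e1 <- suppressWarnings(fit_ebayes(eb_er, seed = 1, n_starts = 1, maxit = 300,
                                    nodes = 16))
  er4 <- dplyr::bind_rows(eb_er, dplyr::mutate(eb_er, run = run + 1000),
                          dplyr::mutate(eb_er, run = run + 2000),
                          dplyr::mutate(eb_er, run = run + 3000))
  # same optimum, four times the data: curvature scales and SEs halve
  e4 <- suppressWarnings(fit_ebayes(er4, seed = 1, n_starts = 1, maxit = 80,
                                    nodes = 16, start = e1$estimate))
  s1 <- e1$param_table$se_slope[e1$param_table$phase == "mobile"]
  s4 <- e4$param_table$se_slope[e4$param_table$phase == "mobile"]
  expect_lt(median(s4 / s1), 0.75)
})
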
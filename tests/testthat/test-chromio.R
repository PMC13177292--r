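test_that("chromatogram IO round-trips and validates its invariants", {
  ch <- make_gaussians(noise_sd = 0.002)
  f <- tempfile(fileext = ".csv"); on.exit(unlink(f), add = TRUE)
  write_chromatogram(ch, f)
  back <- read_chromatogram(f, meta = list(A0 = 0.5))
  expect_identical(back$time, ch$time)
  expect_identical(back$intensity, ch$intensity)

  # seconds header converts to minutes
  f2 <- tempfile(fileext = ".csv"); on.exit(unlink(f2), add = TRUE)
  writeLines(c("time_s,signal",
               paste(ch$time * 60, ch$intensity, sep = ",")), f2)
  sec <- read_chromatogram(f2)
  expect_equal(sec$time, ch$time, tolerance = 1e-9)

  # invariant violations
  expect_error(chromatogram(c(1, 1, 2, seq(3, 50)), rnorm(51)),
               "strictly increasing")
  expect_error(chromatogram(1:10, rnorm(10)), "at least 50")
})

test_that("feature detection finds marker, both apices and the plateau", {
  ch <- make_gaussians(centers = c(2, 8, 10))
  ft <- detect_features(ch)
  expect_false(attr(ft, "coalesced"))
  f <- split(ft, ft$feature)
  expect_equal(f$marker$time, 2, tolerance = 0.02)
  expect_equal(f$peakA$time, 8, tolerance = 0.02)
  expect_equal(f$peakB$time, 10, tolerance = 0.02)
  expect_true(f$plateau$time > 8 && f$plateau$time < 10)

  # one broad hump only -> coalesced flag
  co <- make_gaussians(centers = c(9), sds = 0.5, heights = 1)
  expect_true(attr(detect_features(co), "coalesced"))
})

test_that("apex assignment matches the generating truth on noisy traces", {
  set.seed(11)
  ok <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    tA <- runif(1, 6, 8)
    sep <- runif(1, 6, 10)        # separation in units of peak SD
    s <- tA / sqrt(runif(1, 3000, 8000))
    ch <- make_gaussians(centers = c(2, tA, tA + sep * s),
                         sds = c(0.05, s, s),
                         heights = c(0.5, 1, runif(1, 0.5, 1)),
                         noise_sd = runif(1, 0.002, 0.01))
    fts <- detect_features(ch)
    ft <- split(fts, fts$feature)
    hit <- !attr(fts, "coalesced") && !is.null(ft$peakA) && !is.null(ft$peakB) &&
      abs(ft$peakA$time - tA) < 3 * s && abs(ft$peakB$time - (tA + sep * s)) < 3 * s
    ok <- ok + as.integer(hit)
  }
  expect_equal(ok, n_rep)    # separation > 4 SD: assignment is exact
})

test_that("descriptor estimation reproduces closed-form plate numbers and moments", {
  # single clean Gaussian pair: N = 5.545 (tR / w)^2 from peak A
  ch <- make_gaussians(centers = c(2, 10, 12), sds = c(0.05, 0.1 / 2.3548, 0.08),
                       heights = c(0.3, 1, 0.7), t_max = 16, n = 6000)
  pk <- estimate_peak_params(ch)
  expect_rel(pk$N, 5.545 * (10 / 0.1)^2, 0.01)
  expect_rel(pk$tA, 10, 1e-3)
  expect_rel(pk$sA, 0.1 / 2.3548, 0.005)
  expect_equal(pk$hA, 100)

  # mirror-symmetric pair: the watershed split gives equal areas
  sym <- make_gaussians(centers = c(2, 8, 10), sds = c(0.05, 0.1, 0.1),
                        heights = c(0.5, 1, 1), t_max = 14, n = 4000)
  ps <- estimate_peak_params(sym)
  expect_rel(ps$areaA / ps$areaB, 1, 0.02)

  # Batman profile: plateau measured on the 0-100 scale
  bat <- make_batman(a = 0.4, b = 0.4)
  pb <- estimate_peak_params(bat)
  expect_true(pb$hp > 5 && pb$hp < 60)
})
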
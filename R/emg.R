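# Exponentially modified Gaussian marker model and Fourier deconvolution.

#' Exponentially modified Gaussian density
#'
#' Unit-area EMG with Gaussian centre `mu`, SD `sigma` and exponential
#' time constant `tau_exp`; reduces to the Gaussian as `tau_exp -> 0`.
#' Evaluated through the scaled complementary error function so that it
#' stays finite for `sigma/tau_exp` ratios far beyond those seen in
#' practice.
#'
#' @param t Time grid (min).
#' @param mu,sigma,tau_exp EMG parameters (min); `sigma > 0`, `tau_exp >= 0`.
#' @return Density values.
#' @export
demg <- function(t, mu, sigma, tau_exp) {
  if (tau_exp < 1e-4 * sigma) {
    return(stats::dnorm(t, mu, sigma))
  }
  z <- (sigma / tau_exp - (t - mu) / sigma) / sqrt(2)
  g <- exp(-(t - mu)^2 / (2 * sigma^2))
  out <- numeric(length(t))
  pos <- z >= 0
  out[pos] <- g[pos] * erfcx_stable(z[pos]) / (2 * tau_exp)
  if (any(!pos)) {
    arg <- sigma^2 / (2 * tau_exp^2) - (t[!pos] - mu) / tau_exp
    out[!pos] <- (2 * exp(arg) - erfcx_stable(-z[!pos]) * g[!pos]) /
      (2 * tau_exp)
  }
  out
}

# scaled complementary error function, safe for large arguments where a
# naive exp(z^2) erfc(z) overflows
erfcx_stable <- function(z) {
  out <- numeric(length(z))
  big <- z > 20
  out[!big] <- pracma::erfcx(z[!big])
  zb <- z[big]
  out[big] <- (1 - 0.5 / zb^2 + 0.75 / zb^4) / (zb * sqrt(pi))
  out
}

#' Fit an EMG to the nonretained marker peak
#'
#' Least-squares fit of an exponentially modified Gaussian to the marker
#' window (marker apex +/- 6 estimated SDs, truncated before peak A). If
#' the EMG fit fails to converge the function falls back to a plain
#' Gaussian (`tau_exp = 0`) with a warning.
#'
#' @param chrom Baseline-corrected [chromatogram()].
#' @param features Annotation from [detect_features()]; computed if missing.
#' @return One-row tibble of class `emg_fit`: `mu`, `sigma`, `tau_exp`,
#'   `amplitude` (area, signal x min), `converged`.
#' @export
fit_marker_emg <- function(chrom, features = NULL) {
  features <- features %||% detect_features(chrom)
  f <- split(features, features$feature)
  if (is.null(f$marker)) stop("no marker apex identified", call. = FALSE)
  im <- f$marker$index
  w0 <- half_width(chrom$time, chrom$intensity, im)
  s0 <- w0 / 2.3548
  t0 <- f$marker$time
  lim <- if (!is.null(f$peakA)) min(f$peakA$time - 2 * s0, t0 + 8 * s0) else t0 + 8 * s0
  win <- chrom$time >= t0 - 6 * s0 & chrom$time <= lim
  tw <- chrom$time[win]; yw <- chrom$intensity[win]
  amp0 <- trapz_int(tw, yw)

  resid_fn <- function(p) {
    amp0 * exp(p[4]) * demg(tw, p[1], exp(p[2]), exp(p[3])) - yw
  }
  fit <- try(minpack.lm::nls.lm(
    par = c(t0, log(s0), log(s0 / 4), 0), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  ok <- !inherits(fit, "try-error") && fit$info %in% 1:4
  if (ok) {
    p <- fit$par
    out <- tibble::tibble(mu = p[1], sigma = exp(p[2]), tau_exp = exp(p[3]),
                          amplitude = amp0 * exp(p[4]), converged = TRUE)
  } else {
    warning("EMG fit did not converge; falling back to Gaussian marker kernel")
    out <- tibble::tibble(mu = t0, sigma = s0, tau_exp = 0,
                          amplitude = amp0, converged = FALSE)
  }
  class(out) <- c("emg_fit", class(out))
  out
}

#' Remove the marker response from a chromatogram
#'
#' Fourier-domain deconvolution by the unit-area EMG kernel, regularised
#' Tikhonov-style: the inverse filter is `conj(K) / (|K|^2 + lambda)` with
#' `lambda` a fixed fraction (1e-6 by default) of the maximum kernel
#' power. The kernel is centred on its own mean so that peak positions
#' are untouched while the marker's width contribution is removed; the
#' integral over the retained-peak region is conserved (the DC gain of
#' the inverse filter is 1 up to the regularisation).
#'
#' @param chrom Uniformly sampled [chromatogram()].
#' @param emg An `emg_fit` from [fit_marker_emg()].
#' @param lambda_rel Regularisation parameter relative to max kernel
#'   power.
#' @return Deconvolved [chromatogram()].
#' @export
deconvolve_marker <- function(chrom, emg, lambda_rel = 1e-6) {
  dt <- diff(chrom$time)
  if (diff(range(dt)) > 1e-6 * mean(dt)) {
    stop("deconvolution requires a uniform time grid", call. = FALSE)
  }
  dt <- mean(dt)
  n <- nrow(chrom)
  m <- 2^ceiling(log2(2 * n))
  ypad <- c(chrom$intensity, rep(0, m - n))

  # zero-mean kernel sampled circularly (negative lags wrap to the end)
  lag <- c(0:(m / 2 - 1), -(m / 2):-1) * dt
  kern <- demg(lag, mu = -emg$tau_exp, sigma = emg$sigma, tau_exp = emg$tau_exp) * dt
  kern <- kern / sum(kern)

  Y <- stats::fft(ypad)
  K <- stats::fft(kern)
  lambda <- lambda_rel * max(Mod(K)^2)
  Yd <- Y * Conj(K) / (Mod(K)^2 + lambda)
  yd <- Re(stats::fft(Yd, inverse = TRUE)) / m
  chromatogram(chrom$time, yd[seq_len(n)], chrom_meta(chrom))
}

# Convolve a chromatogram with an EMG response (test/benchmark helper).
convolve_emg <- function(chrom, emg) {
  dt <- mean(diff(chrom$time))
  n <- nrow(chrom)
  m <- 2^ceiling(log2(2 * n))
  ypad <- c(chrom$intensity, rep(0, m - n))
  lag <- c(0:(m / 2 - 1), -(m / 2):-1) * dt
  kern <- demg(lag, mu = -emg$tau_exp, sigma = emg$sigma, tau_exp = emg$tau_exp) * dt
  kern <- kern / sum(kern)
  y <- Re(stats::fft(stats::fft(ypad) * stats::fft(kern), inverse = TRUE)) / m
  chromatogram(chrom$time, y[seq_len(n)], chrom_meta(chrom))
}
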
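# Internal numeric helpers shared across the package.

# Trapezoidal integral of y over (possibly non-uniform) x.
trapz_int <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(z) 1 / (1 + exp(-z))

# Signed FFT frequencies (cycles -> angular), length n, spacing dt.
angular_freqs <- function(n, dt) {
  j <- c(0:(n / 2 - 1), -(n / 2):-1)
  2 * pi * j / (n * dt)
}

# Linear interpolation that returns 0 outside the profile support.
interp_profile <- function(t, y, t_out) {
  stats::approx(t, y, xout = t_out, yleft = 0, yright = 0, rule = 2)$y
}

# Central-difference Hessian of scalar function f at x (relative step).
central_hessian <- function(f, x, rel_step = 1e-4) {
  p <- length(x)
  h <- rel_step * pmax(abs(x), 1)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      xi <- x
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

# Weighted zero-intercept least squares y = slope * x; returns slope and SE.
wls_through_origin <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  sxx <- sum(w * x^2)
  slope <- sum(w * x * y) / sxx
  n <- length(x)
  if (n > 1) {
    s2 <- sum(w * (y - slope * x)^2) / (n - 1)
    se <- sqrt(s2 / sxx)
  } else {
    se <- Inf
  }
  list(slope = slope, se = se, df = n - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
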
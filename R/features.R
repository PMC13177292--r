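# Peak/plateau annotation and chromatographic descriptors.

# Savitzky-Golay style smoother: local quadratic fit, window = odd count.
sg_smooth <- function(y, window) {
  window <- max(5L, as.integer(window))
  if (window %% 2 == 0) window <- window + 1L
  half <- (window - 1L) / 2L
  x <- -half:half
  X <- cbind(1, x, x^2)
  coefs <- solve(crossprod(X), t(X))[1, ]   # value of fit at window centre
  ys <- stats::filter(y, rev(coefs), sides = 2)
  ys <- as.numeric(ys)
  ys[is.na(ys)] <- y[is.na(ys)]
  ys
}

local_maxima <- function(y, min_height, min_sep_idx, min_prom = 0) {
  n <- length(y)
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  cand <- cand[y[cand] >= min_height]
  if (!length(cand)) return(integer())
  cand <- cand[order(y[cand], decreasing = TRUE)]
  keep <- integer()
  for (i in cand) {
    if (!all(abs(i - keep) >= min_sep_idx)) next
    # prominence against every taller accepted apex
    prom_ok <- all(vapply(keep, function(k) {
      y[i] - min(y[seq(min(i, k), max(i, k))]) >= min_prom
    }, logical(1)))
    if (prom_ok) keep <- c(keep, i)
  }
  sort(keep)
}

#' Locate marker, Batman apices and the inter-peak plateau
#'
#' Identifies the nonretained marker peak (if present), the two retained
#' apices of the Batman profile (peak A first, peak B second) and the
#' plateau window between them. The signal is lightly smoothed (local
#' quadratic, window = 2% of points) for apex/valley *location* only;
#' reported intensities come from the raw trace.
#'
#' An apex is treated as the nonretained marker when it elutes early: before
#' 50% of the time of the next apex (or before a `tM_hint` supplied in the
#' metadata, within 20%). With fewer than two retained apices the
#' chromatogram is flagged `coalesced` and single-peak quantities are
#' reported.
#'
#' @param chrom A baseline-corrected [chromatogram()].
#' @param min_rel_height Apices below this fraction of the maximum signal
#'   are ignored (default 0.03).
#' @return A tibble with one row per feature (`marker`, `peakA`, `peakB`,
#'   `plateau`), columns `feature`, `time`, `index`, `intensity`; attribute
#'   `coalesced` is `TRUE` when only one retained apex was found.
#' @export
detect_features <- function(chrom, min_rel_height = 0.03) {
  y <- chrom$time
  s <- sg_smooth(chrom$intensity, window = ceiling(0.02 * nrow(chrom)))
  min_sep <- max(5L, floor(0.01 * nrow(chrom)))
  apex <- local_maxima(s, min_height = min_rel_height * max(s),
                       min_sep_idx = min_sep, min_prom = 0.03 * max(s))
  # the smoother falls back to raw values near the edges; exclude them
  hw <- ceiling(0.01 * nrow(chrom)) + 2L
  apex <- apex[apex > hw & apex <= nrow(chrom) - hw]
  if (!length(apex)) stop("no peaks detected", call. = FALSE)
  # refine each apex to the raw-signal maximum near the smoothed one, so
  # widths and heights are read at the true crest
  half_win <- max(2L, min_sep %/% 2L)
  apex <- vapply(apex, function(i) {
    lo <- max(1L, i - half_win); hi <- min(nrow(chrom), i + half_win)
    as.integer(lo - 1L + which.max(chrom$intensity[lo:hi]))
  }, integer(1))
  apex <- sort(unique(apex))
  if (!length(apex)) stop("no peaks detected", call. = FALSE)

  meta <- chrom_meta(chrom)
  marker_idx <- NA_integer_
  if (length(apex) >= 2) {
    t1 <- chrom$time[apex[1]]
    hint <- meta$tM_hint
    early <- if (!is.null(hint)) abs(t1 - hint) / hint < 0.2 else
      t1 < 0.5 * chrom$time[apex[2]]
    if (early) {
      marker_idx <- apex[1]
      apex <- apex[-1]
    }
  }

  coalesced <- length(apex) < 2
  rows <- list()
  if (!is.na(marker_idx)) {
    rows$marker <- tibble::tibble(feature = "marker", time = chrom$time[marker_idx],
                                  index = marker_idx,
                                  intensity = chrom$intensity[marker_idx])
  }
  iA <- apex[1]
  rows$peakA <- tibble::tibble(feature = "peakA", time = chrom$time[iA],
                               index = iA, intensity = chrom$intensity[iA])
  if (!coalesced) {
    iB <- apex[2]
    between <- (iA + 1):(iB - 1)
    ip <- between[which.min(s[between])]
    rows$peakB <- tibble::tibble(feature = "peakB", time = chrom$time[iB],
                                 index = iB, intensity = chrom$intensity[iB])
    rows$plateau <- tibble::tibble(feature = "plateau", time = chrom$time[ip],
                                   index = ip, intensity = chrom$intensity[ip])
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "coalesced") <- coalesced
  out
}

# sub-grid apex location and height by a parabola through three points
apex_interp <- function(time, y, idx) {
  if (idx <= 1 || idx >= length(y)) {
    return(list(t = time[idx], h = y[idx]))
  }
  ym <- y[idx - 1]; y0 <- y[idx]; yp <- y[idx + 1]
  den <- ym - 2 * y0 + yp
  if (!is.finite(den) || den >= 0) return(list(t = time[idx], h = y[idx]))
  delta <- 0.5 * (ym - yp) / den
  dt <- (time[idx + 1] - time[idx - 1]) / 2
  list(t = time[idx] + delta * dt, h = y0 - 0.25 * (ym - yp) * delta)
}

half_width <- function(time, y, idx, side = c("both", "left", "right")) {
  side <- match.arg(side)
  ap <- apex_interp(time, y, idx)
  h <- ap$h
  half <- h / 2
  tl <- tr <- NA_real_
  if (side != "right") {
    i <- idx
    while (i > 1 && y[i] > half) i <- i - 1
    if (y[i] <= half) {
      tl <- time[i] + (time[i + 1] - time[i]) * (half - y[i]) / (y[i + 1] - y[i])
    }
  }
  if (side != "left") {
    j <- idx
    n <- length(y)
    while (j < n && y[j] > half) j <- j + 1
    if (y[j] <= half) {
      tr <- time[j - 1] +
        (time[j] - time[j - 1]) * (half - y[j - 1]) / (y[j] - y[j - 1])
    }
  }
  switch(side,
         both = tr - tl,
         left = 2 * (ap$t - tl),   # outer half-width doubled
         right = 2 * (tr - ap$t))
}

#' Chromatographic descriptors of a Batman chromatogram
#'
#' Computes the descriptor set used by the unified equation: plate number
#' `N = 5.545 (tA / wA)^2` from peak A, retention times, full widths at
#' half maximum, Gaussian SDs `s = w / 2.3548`, peak heights rescaled so
#' the taller of the two retained peaks is 100, the plateau relative
#' height `hp` on that scale (read from the raw signal at the smoothed
#' plateau minimum), and areas `A_inf`, `B_inf` by trapezoidal integration
#' with the split at the plateau minimum.
#'
#' @param chrom Baseline-corrected [chromatogram()].
#' @param features Optional annotation from [detect_features()]; computed
#'   if missing.
#' @return One-row tibble of class `peak_params` with columns `N`, `tM`,
#'   `tA`, `tB`, `wA`, `wB`, `sA`, `sB`, `hA`, `hB`, `hp`, `areaA`,
#'   `areaB`, `A0`, `noise` (raw-signal SD of the baseline tails, on the
#'   0-100 height scale).
#' @export
estimate_peak_params <- function(chrom, features = NULL) {
  features <- features %||% detect_features(chrom)
  coalesced <- isTRUE(attr(features, "coalesced"))
  f <- split(features, features$feature)
  meta <- chrom_meta(chrom)
  tM <- if (!is.null(f$marker)) f$marker$time else meta$tM_hint %||% NA_real_

  iA <- f$peakA$index
  apA <- apex_interp(chrom$time, chrom$intensity, iA)
  tA <- apA$t
  if (is.finite(tM) && tA <= tM) {
    stop("retained apex before the hold-up time: descriptors undefined",
         call. = FALSE)
  }
  # outer (uncontaminated) half-widths: the inner flanks merge into the
  # plateau once hp exceeds 50
  wA <- half_width(chrom$time, chrom$intensity, iA, side = "left")
  if (!is.finite(wA) || wA <= 0) stop("degenerate peak: zero or undefined width", call. = FALSE)

  if (coalesced) {
    stop("coalesced chromatogram: only one retained apex; Batman descriptors undefined",
         call. = FALSE)
  }
  iB <- f$peakB$index
  apB <- apex_interp(chrom$time, chrom$intensity, iB)
  tB <- apB$t
  wB <- half_width(chrom$time, chrom$intensity, iB, side = "right")
  if (!is.finite(wB) || wB <= 0) stop("degenerate peak: zero or undefined width", call. = FALSE)

  N <- 5.545 * (tA / wA)^2
  hA_raw <- apA$h
  hB_raw <- apB$h
  scale <- 100 / max(hA_raw, hB_raw)
  ip <- f$plateau$index
  hp <- chrom$intensity[ip] * scale

  # integration windows: retained region split at the plateau minimum
  start <- if (!is.null(f$marker)) {
    v <- (f$marker$index + 1):(iA - 1)
    v[which.min(chrom$intensity[v])]
  } else 1L
  areaA <- trapz_int(chrom$time[start:ip], pmax(chrom$intensity[start:ip], 0))
  areaB <- trapz_int(chrom$time[ip:nrow(chrom)], pmax(chrom$intensity[ip:nrow(chrom)], 0))

  n <- nrow(chrom)
  tail_idx <- c(seq_len(max(5L, floor(0.05 * n))),
                seq.int(n - max(5L, floor(0.05 * n)) + 1L, n))
  noise <- stats::sd(chrom$intensity[tail_idx]) * scale

  out <- tibble::tibble(
    N = N, tM = tM, tA = tA, tB = tB, wA = wA, wB = wB,
    sA = wA / 2.3548, sB = wB / 2.3548,
    hA = hA_raw * scale, hB = hB_raw * scale, hp = hp,
    areaA = areaA, areaB = areaB,
    A0 = meta$A0 %||% 0.5, noise = noise
  )
  class(out) <- c("peak_params", class(out))
  out
}
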
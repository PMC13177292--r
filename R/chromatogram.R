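#' Build a chromatogram object
#'
#' A chromatogram is a tibble with columns `time` (minutes) and
#' `intensity` (detector units, typically mAU) plus run metadata stored as
#' an attribute: chiral column id, eluent id, temperature (K), flow rate
#' (mL/min) and the injected fraction of the first-eluting enantiomer
#' `A0`. `A0` defaults to 0.5 (racemic injection).
#'
#' @param time Numeric vector of acquisition times in minutes, strictly
#'   increasing, length at least 50.
#' @param intensity Numeric vector of detector intensities, same length.
#' @param meta Named list of run metadata (`column`, `eluent`,
#'   `temperature_K`, `flow_mL_min`, `A0`). Missing entries are allowed;
#'   `A0` falls back to 0.5.
#' @return A tibble of class `chromatogram`.
#' @export
chromatogram <- function(time, intensity, meta = list()) {
  if (length(time) != length(intensity)) {
    stop("`time` and `intensity` must have the same length", call. = FALSE)
  }
  if (length(time) < 50) {
    stop("chromatogram too short: need at least 50 points", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(!is.finite(intensity))) {
    stop("chromatogram contains non-finite values", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing (duplicated or reversed time stamps)",
         call. = FALSE)
  }
  meta$A0 <- meta$A0 %||% 0.5
  out <- tibble::tibble(time = as.numeric(time), intensity = as.numeric(intensity))
  attr(out, "meta") <- meta
  class(out) <- c("chromatogram", class(out))
  out
}

#' Read a chromatogram from a delimited text file
#'
#' Expects two numeric columns, time then intensity; an optional header is
#' detected automatically. If the time-column header mentions seconds
#' (`"sec"`, `"s"`, `"time_s"`), times are converted to minutes.
#'
#' @param file Path to a CSV/TSV/whitespace-delimited file.
#' @param meta Run metadata list, see [chromatogram()].
#' @return A [chromatogram()].
#' @export
read_chromatogram <- function(file, meta = list()) {
  first <- readLines(file, n = 1L)
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  has_header <- !grepl("^[-+0-9eE.,; \t]+$", first)
  df <- utils::read.table(file, header = has_header, sep = sep,
                          comment.char = "#", strip.white = TRUE)
  if (ncol(df) < 2) stop("need at least 2 numeric columns", call. = FALSE)
  tm <- as.numeric(df[[1]])
  if (has_header && grepl("(^|_|\\b)(s|sec|seconds?)\\b", names(df)[1],
                          ignore.case = TRUE)) {
    tm <- tm / 60
  }
  chromatogram(tm, as.numeric(df[[2]]), meta = meta)
}

#' Write a chromatogram to CSV
#'
#' Writes `time,intensity` with full double precision so that a
#' write/read round trip reproduces the vectors exactly.
#'
#' @param chrom A [chromatogram()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_chromatogram <- function(chrom, file) {
  df <- data.frame(time = format(chrom$time, digits = 17, trim = TRUE),
                   intensity = format(chrom$intensity, digits = 17, trim = TRUE))
  utils::write.table(df, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @export
print.chromatogram <- function(x, ...) {
  m <- chrom_meta(x)
  cat(sprintf("<chromatogram> %d points, t = [%.3g, %.3g] min\n",
              nrow(x), min(x$time), max(x$time)))
  if (length(m)) {
    cat("  meta:", paste(names(m), unlist(lapply(m, format)), sep = "=",
                         collapse = ", "), "\n")
  }
  NextMethod()
}

#' Run metadata of a chromatogram
#' @param chrom A [chromatogram()].
#' @return Named list of metadata.
#' @export
chrom_meta <- function(chrom) attr(chrom, "meta") %||% list()

with_meta <- function(new, template) {
  attr(new, "meta") <- chrom_meta(template)
  new
}

#' Subtract a linear baseline
#'
#' Fits a straight line through the 5th-percentile signal levels of the
#' pre-marker window (first 10% of points) and the post-peak window (last
#' 10%) and subtracts it. Deterministic and robust to noise spikes.
#'
#' @param chrom A [chromatogram()].
#' @return Baseline-corrected chromatogram.
#' @export
correct_baseline <- function(chrom) {
  n <- nrow(chrom)
  head_idx <- seq_len(max(10L, floor(0.1 * n)))
  tail_idx <- seq.int(n - max(10L, floor(0.1 * n)) + 1L, n)
  lvl <- function(idx) {
    q <- stats::quantile(chrom$intensity[idx], 0.05, names = FALSE)
    keep <- idx[chrom$intensity[idx] <= q + 1e-12 |
                  rank(chrom$intensity[idx]) <= max(3, length(idx) * 0.05)]
    c(mean(chrom$time[keep]), mean(chrom$intensity[keep]))
  }
  p1 <- lvl(head_idx); p2 <- lvl(tail_idx)
  slope <- (p2[2] - p1[2]) / (p2[1] - p1[1])
  base <- p1[2] + slope * (chrom$time - p1[1])
  out <- chromatogram(chrom$time, chrom$intensity - base, chrom_meta(chrom))
  out
}
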
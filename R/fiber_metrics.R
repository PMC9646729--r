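# Banding-periodicity estimation from 1-D intensity/density traces, plus a
# synthetic noisy trace generator emulating AFM/TEM line profiles.

#' Construct a band trace
#'
#' @param intensity numeric vector of intensity/density samples.
#' @param dx_nm uniform sample spacing in nm.
#' @param source `"simulated"` (from an aggregate) or `"synthetic"`.
#' @return a `band_trace` list with `intensity`, `position_nm`, `dx_nm`,
#'   `source`.
#' @export
band_trace <- function(intensity, dx_nm = 1, source = c("simulated", "synthetic")) {
  source <- match.arg(source)
  if (length(intensity) < 2L) stop("a band trace needs at least 2 samples")
  structure(list(intensity = as.numeric(intensity),
                 position_nm = (seq_along(intensity) - 1) * dx_nm,
                 dx_nm = dx_nm, source = source),
            class = "band_trace")
}

#' Generate a synthetic noisy band trace
#'
#' Rectangular wave (value 1 over the `duty` fraction of each period, 0
#' elsewhere) plus linear baseline drift and Gaussian noise — a stand-in for
#' AFM/TEM line profiles across a banded fiber.
#'
#' @param period_nm banding period.
#' @param duty fraction of each period occupied by the high (overlap) band;
#'   e.g. 10/35 emulates the adhesive/period ratio of a P10BP10 rod.
#' @param n_periods number of full periods.
#' @param dx_nm sample spacing.
#' @param noise_sd Gaussian noise standard deviation.
#' @param drift linear drift slope (intensity units per nm).
#' @param seed RNG seed (deterministic given seed).
#' @return a `band_trace` with source `"synthetic"`.
#' @export
synth_band_trace <- function(period_nm, duty = 10 / 35, n_periods = 10L,
                             dx_nm = 1, noise_sd = 0, drift = 0, seed = 1L) {
  stopifnot(n_periods >= 1L, period_nm > 0, duty > 0, duty < 1)
  n <- round(period_nm * n_periods / dx_nm)
  pos <- (seq_len(n) - 1) * dx_nm
  base <- as.numeric((pos %% period_nm) < duty * period_nm)
  y <- base + drift * pos
  if (noise_sd > 0) y <- y + with_seed(seed, rnorm(n, sd = noise_sd))
  band_trace(y, dx_nm = dx_nm, source = "synthetic")
}

detrend_trace <- function(y, method = c("none", "linear", "moving-average")) {
  method <- match.arg(method)
  n <- length(y)
  if (method == "linear") {
    t <- seq_len(n)
    as.numeric(stats::residuals(stats::lm(y ~ t)))
  } else if (method == "moving-average") {
    w <- max(5L, round(n / 8))
    if (w %% 2L == 0L) w <- w + 1L
    pad <- (w - 1L) %/% 2L
    ypad <- c(rep(y[1], pad), y, rep(y[n], pad))
    ma <- as.numeric(stats::filter(ypad, rep(1 / w, w), sides = 2))
    y - ma[pad + seq_len(n)]
  } else {
    y
  }
}

#' Detrend a band trace
#'
#' Removes baseline drift (linear fit) or the slowly varying envelope
#' (moving average) from a trace, e.g. the spindle-shaped density envelope
#' of a simulated fiber, leaving the banding modulation.
#'
#' @param trace a `band_trace`.
#' @param method `"linear"` or `"moving-average"`.
#' @return the detrended `band_trace`.
#' @export
detrend_band_trace <- function(trace, method = c("moving-average", "linear")) {
  method <- match.arg(method)
  out <- trace
  out$intensity <- detrend_trace(trace$intensity, method)
  out
}

new_period_estimate <- function(period_nm, method, n_periods = NA,
                                detrend = "none") {
  structure(list(period_nm = period_nm, method = method,
                 n_periods = n_periods, detrend = detrend),
            class = "period_estimate")
}

#' @export
print.period_estimate <- function(x, ...) {
  cat(sprintf("<period_estimate> %.2f nm (%s)\n", x$period_nm, x$method))
  invisible(x)
}

#' Banding period by Fourier transform
#'
#' Detrends the trace, finds the dominant non-DC Fourier magnitude and
#' refines the frequency by parabolic interpolation over the neighbouring
#' bins; the period is the sampled span divided by the interpolated
#' frequency index.
#'
#' @param trace a `band_trace` (at least ~4 periods recommended).
#' @param detrend `"none"`, `"linear"` or `"moving-average"`. (An empirical
#'   mode decomposition step is not applied; the detrend method used is
#'   recorded in the estimate.)
#' @return a `period_estimate` with method `"fft"`.
#' @export
fft_periodicity <- function(trace, detrend = c("linear", "none", "moving-average")) {
  detrend <- match.arg(detrend)
  y <- detrend_trace(trace$intensity, detrend)
  y <- y - mean(y)
  n <- length(y)
  mag <- Mod(fft(y))[seq_len(n %/% 2 + 1)] # bins 0..n/2
  mag[1] <- 0
  k <- which.max(mag) - 1L # frequency index
  if (k < 1L || mag[k + 1L] < 4 * median(mag[-1]) || mag[k + 1L] == 0) {
    stop("no non-DC spectral peak above the noise floor")
  }
  # square-wave-like traces can put more power in a harmonic than in the
  # fundamental; fall back to the lowest subharmonic that still carries a
  # substantial share of the peak magnitude
  for (m in c(3L, 2L)) {
    ks <- as.integer(round(k / m))
    if (ks >= 1L && abs(ks * m - k) <= 1L &&
        mag[ks + 1L] >= 0.6 * mag[k + 1L]) {
      k <- ks
      break
    }
  }
  delta <- 0
  if (k >= 2L && k + 2L <= length(mag)) { # parabolic peak interpolation
    m_lo <- mag[k]; m_pk <- mag[k + 1L]; m_hi <- mag[k + 2L]
    denom <- m_lo - 2 * m_pk + m_hi
    if (denom != 0) delta <- 0.5 * (m_lo - m_hi) / denom
    delta <- max(min(delta, 0.5), -0.5)
  }
  new_period_estimate(n * trace$dx_nm / (k + delta), "fft", detrend = detrend)
}

#' Banding period by real-space band counting
#'
#' Thresholds the trace (midpoint of the 10th and 90th intensity
#' percentiles by default), detects band onsets (upward crossings) and
#' divides the span between first and last onset by the number of periods.
#' The trace is lightly smoothed before thresholding so single-sample noise
#' spikes are not counted as bands.
#'
#' @param trace a `band_trace`.
#' @param threshold intensity threshold; defaults to the percentile
#'   midpoint.
#' @param smooth odd moving-average window (samples) applied before onset
#'   detection; 1 disables smoothing.
#' @return a `period_estimate` with method `"realspace"` and the number of
#'   periods used.
#' @export
realspace_periodicity <- function(trace, threshold = NULL, smooth = 3L) {
  y <- trace$intensity
  if (smooth > 1L) {
    w <- as.integer(smooth)
    if (w %% 2L == 0L) w <- w + 1L
    pad <- (w - 1L) %/% 2L
    ypad <- c(rep(y[1], pad), y, rep(y[length(y)], pad))
    y <- as.numeric(stats::filter(ypad, rep(1 / w, w), sides = 2))[pad + seq_along(y)]
  }
  if (is.null(threshold)) {
    qs <- quantile(y, c(0.1, 0.9), names = FALSE)
    threshold <- mean(qs)
  }
  hi <- y > threshold
  onsets <- which(diff(c(FALSE, hi)) == 1L)
  if (length(onsets) < 2L) stop("fewer than 2 bands detected")
  k <- length(onsets) - 1L
  period <- (trace$position_nm[onsets[length(onsets)]] -
             trace$position_nm[onsets[1]]) / k
  new_period_estimate(period, "realspace", n_periods = k)
}

#' Compare two groups of period estimates
#'
#' Two-sample t-test with equal variance (pooled), as used to check whether
#' Fourier and real-space periodicity measurements differ.
#'
#' @param group1,group2 numeric vectors of period estimates (each >= 2).
#' @return list with `t`, `df`, `p_value` and the group means.
#' @export
compare_periods <- function(group1, group2) {
  if (length(group1) < 2L || length(group2) < 2L) {
    stop("each group needs at least 2 estimates")
  }
  if (var(group1) + var(group2) == 0) stop("zero pooled variance")
  ht <- t.test(group1, group2, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       mean1 = mean(group1), mean2 = mean(group2))
}

#' Write / read band traces as CSV
#'
#' @param trace a `band_trace`.
#' @param file path.
#' @return `write_band_trace()` returns `file` invisibly;
#'   `read_band_trace()` a `band_trace`.
#' @export
write_band_trace <- function(trace, file) {
  write.csv(data.frame(position_nm = trace$position_nm,
                       intensity = trace$intensity),
            file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_band_trace
#' @param source source label for the read trace.
#' @export
read_band_trace <- function(file, source = "simulated") {
  d <- read.csv(file)
  stopifnot(all(c("position_nm", "intensity") %in% names(d)))
  dx <- diff(d$position_nm)
  if (length(dx) && max(abs(dx - dx[1])) > 1e-8) {
    stop("band trace must be uniformly sampled")
  }
  band_trace(d$intensity, dx_nm = if (length(dx)) dx[1] else 1, source = source)
}
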
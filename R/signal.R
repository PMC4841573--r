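#' Unbiased (non-excess) sample kurtosis
#'
#' Small-sample unbiased kurtosis on the convention in which a Gaussian has
#' kurtosis 3: the unbiased excess-kurtosis estimator
#' `G2 = ((n+1) g2 + 6) (n-1) / ((n-2)(n-3))` (with `g2` the biased excess)
#' plus 3. Constant input returns 3 by convention (such bins are quiet and
#' must not be rejected by the noise-threshold estimator).
#'
#' @param x numeric vector (or matrix: one value per column), `n >= 4`.
#' @return kurtosis value(s); Gaussian samples concentrate around 3.
#' @export
unbiased_kurtosis <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    m2 <- colMeans(xc^2)
    m4 <- colMeans(xc^4)
  } else {
    n <- length(x)
    xc <- x - mean(x)
    m2 <- mean(xc^2)
    m4 <- mean(xc^4)
  }
  if (n < 4) stop("kurtosis needs at least 4 samples")
  g2 <- m4 / m2^2 - 3
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  out <- G2 + 3
  out[!is.finite(out)] <- 3  # zero-variance bins: treat as Gaussian-like
  out
}

#' Estimate the noise threshold of a channel
#'
#' The voltage trace is divided into bins of `kurtosis_bin_ms`; the unbiased
#' kurtosis of each bin is computed and bins with kurtosis above
#' `kurtosis_cutoff` are rejected (a Gaussian has kurtosis 3; bins containing
#' sparse spikes are super-Gaussian). The noise threshold `NT` is the mean
#' absolute voltage over all samples of the retained bins.
#'
#' Note the logic of the rejection: sparse large events are excluded, but
#' sustained dense multi-unit activity is near-Gaussian (many superimposed
#' spikes) and is retained, which pulls `NT` above the quiet-noise level. On
#' recordings that contain bursts this is what keeps quiet periods below
#' threshold in the activity-intensity representation.
#'
#' @param v voltage samples (uV) of one channel.
#' @param rate_hz sampling rate (default 10000).
#' @param kurtosis_bin_ms kurtosis bin width (ms, default 20).
#' @param kurtosis_cutoff rejection threshold (default 3.1).
#' @return `NT` (same units as `mean(abs(v))`), with attribute `n_bins_used`.
#'   A trace shorter than 100 kurtosis bins gives a warning (threshold
#'   flagged unreliable); if every bin is rejected an error is signalled.
#' @export
estimate_noise_threshold <- function(v, rate_hz = 10000,
                                     kurtosis_bin_ms = 20,
                                     kurtosis_cutoff = 3.1) {
  m <- as.integer(round(kurtosis_bin_ms * rate_hz / 1000))
  nb <- length(v) %/% m
  if (nb < 1) stop("trace shorter than one kurtosis bin")
  if (nb < 100) {
    warning("fewer than 100 kurtosis bins; noise threshold unreliable")
  }
  bins <- matrix(v[seq_len(nb * m)], nrow = m)
  k <- unbiased_kurtosis(bins)
  keep <- k <= kurtosis_cutoff
  if (!any(keep)) stop("all kurtosis bins rejected; no noise floor estimable")
  nt <- mean(abs(bins[, keep, drop = FALSE]))
  attr(nt, "n_bins_used") <- sum(keep)
  nt
}

#' Activity intensity of a channel
#'
#' Converts a voltage trace into the activity-intensity (AI) representation:
#' per time bin of `bin_ms`, `A = mean(|V|) - NT`, rectified at zero
#' (`AI = max(A, 0)`). AI is a proxy for the population firing rate under the
#' electrode. A trailing bin shorter than the bin width is dropped.
#'
#' @param v voltage samples (uV).
#' @param nt noise threshold from [estimate_noise_threshold()].
#' @param rate_hz sampling rate (Hz).
#' @param bin_ms AI bin width (ms, default 2).
#' @return numeric AI vector (one value per bin), attribute `bin_ms`.
#' @export
activity_intensity <- function(v, nt, rate_hz = 10000, bin_ms = 2) {
  stopifnot(nt >= 0)
  m <- as.integer(round(bin_ms * rate_hz / 1000))
  nb <- length(v) %/% m
  a <- colMeans(matrix(abs(v[seq_len(nb * m)]), nrow = m)) - as.numeric(nt)
  ai <- pmax(a, 0)
  attr(ai, "bin_ms") <- bin_ms
  ai
}

#' Activity-intensity matrix of a multichannel recording
#'
#' Applies [estimate_noise_threshold()] and [activity_intensity()] to every
#' channel of a recording (one threshold per channel per file).
#'
#' @param rec a `voltage_recording` (see [render_voltage()] /
#'   [read_recording()]).
#' @param bin_ms AI bin width (ms).
#' @param ... passed to [estimate_noise_threshold()].
#' @return matrix (bins x channels) with attributes `bin_ms` and `nt`
#'   (per-channel thresholds).
#' @export
recording_intensity <- function(rec, bin_ms = 2, ...) {
  stopifnot(inherits(rec, "voltage_recording"))
  nt <- vapply(seq_len(ncol(rec$volts)), function(ch) {
    as.numeric(estimate_noise_threshold(rec$volts[, ch], rec$rate_hz, ...))
  }, numeric(1))
  ai <- vapply(seq_len(ncol(rec$volts)), function(ch) {
    activity_intensity(rec$volts[, ch], nt[ch], rec$rate_hz, bin_ms)
  }, numeric(nrow(rec$volts) %/% as.integer(round(bin_ms * rec$rate_hz / 1000))))
  ai <- matrix(ai, ncol = ncol(rec$volts))
  attr(ai, "bin_ms") <- bin_ms
  attr(ai, "nt") <- nt
  ai
}

#' Gaussian smoothing of a series
#'
#' Discrete convolution with a unit-area Gaussian kernel (radius 4 sigma).
#' Boundaries are handled by reflect padding, so a constant series is returned
#' unchanged and the output length equals the input length.
#'
#' @param x numeric series.
#' @param sigma_ms kernel standard deviation (ms).
#' @param bin_ms grid spacing of `x` (ms).
#' @return smoothed series, same length as `x`.
#' @export
gaussian_smooth <- function(x, sigma_ms, bin_ms = 2) {
  stopifnot(sigma_ms > 0, bin_ms > 0)
  s <- sigma_ms / bin_ms
  r <- max(1L, ceiling(4 * s))
  kern <- exp(-0.5 * ((-r:r) / s)^2)
  kern <- kern / sum(kern)
  n <- length(x)
  if (n == 0) return(x)
  # reflect padding
  left <- if (n >= r) x[r:1] else x[c(pmin(r:1, n))]
  right <- if (n >= r) x[n:(n - r + 1)] else x[c(pmax(n:1, 1))][1:r]
  xp <- c(left, x, right)
  y <- stats::filter(xp, kern, sides = 2)
  as.numeric(y[(r + 1):(r + n)])
}
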
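#' Pearson cross-correlation as a function of lag
#'
#' For two equally long series, computes the Pearson correlation of the
#' overlapping segments at every integer lag in `[-max_lag, max_lag]`
#' (positive lag: the first series leads the second, i.e.
#' `r(k) = cor(x[1:(n-k)], y[(1+k):n])`). Cross products are obtained with an
#' FFT and the per-lag means/variances from cumulative sums, so the cost is
#' `O(n log n)` regardless of the number of lags.
#'
#' @param x,y numeric series on the same grid.
#' @param max_lag maximum lag in samples.
#' @param min_overlap lags with fewer overlapping samples are returned as NA.
#' @return list with `lag` (samples) and `r`.
#' @export
lagged_pearson <- function(x, y, max_lag, min_overlap = 8) {
  n <- length(x)
  stopifnot(length(y) == n, n >= min_overlap)
  max_lag <- min(max_lag, n - min_overlap)
  N <- stats::nextn(2L * n, 2)
  X <- fft(c(x, numeric(N - n)))
  Y <- fft(c(y, numeric(N - n)))
  cc <- Re(fft(Conj(X) * Y, inverse = TRUE)) / N  # cc[k+1] = sum x[t] y[t+k]
  lags <- -max_lag:max_lag
  pos <- lags >= 0
  sxy <- numeric(length(lags))
  sxy[pos] <- cc[lags[pos] + 1]
  sxy[!pos] <- cc[N + 1 + lags[!pos]]
  cx <- c(0, cumsum(x)); cxx <- c(0, cumsum(x^2))
  cy <- c(0, cumsum(y)); cyy <- c(0, cumsum(y^2))
  L <- n - abs(lags)
  # overlap sums: lag k>=0 pairs x[1:L] with y[(k+1):n]; k<0 symmetric
  sx <- sxx <- sy <- syy <- numeric(length(lags))
  sx[pos] <- cx[L[pos] + 1]
  sxx[pos] <- cxx[L[pos] + 1]
  sy[pos] <- cy[n + 1] - cy[lags[pos] + 1]
  syy[pos] <- cyy[n + 1] - cyy[lags[pos] + 1]
  sx[!pos] <- cx[n + 1] - cx[abs(lags[!pos]) + 1]
  sxx[!pos] <- cxx[n + 1] - cxx[abs(lags[!pos]) + 1]
  sy[!pos] <- cy[L[!pos] + 1]
  syy[!pos] <- cyy[L[!pos] + 1]
  vx <- sxx - sx^2 / L
  vy <- syy - sy^2 / L
  den <- sqrt(pmax(vx, 0) * pmax(vy, 0))
  r <- ifelse(den > 1e-12 * L, (sxy - sx * sy / L) / den, NA_real_)
  r[L < min_overlap] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  list(lag = lags, r = r)
}

#' Inter-cluster delay of a burst
#'
#' The delay between two activity traces is the lag of the maximum of their
#' Pearson-normalised cross-covariance after Gaussian smoothing. Positive lag
#' means the first trace leads the second (propagation a -> b). Ties are
#' broken towards the smallest `|lag|` (and towards the positive lag between
#' exact mirror ties).
#'
#' @param ai_a,ai_b activity traces covering the burst window, same grid.
#' @param bin_ms grid spacing (ms).
#' @param smooth_sigma_ms Gaussian smoothing sigma (ms, default 10).
#' @param max_lag_ms lag search range (ms, default 500).
#' @return list with `lag_ms` and `peak_corr`; a flat (zero-variance) trace
#'   gives `lag_ms = NA`.
#' @export
burst_delay <- function(ai_a, ai_b, bin_ms = 2, smooth_sigma_ms = 10,
                        max_lag_ms = 500) {
  a <- gaussian_smooth(as.numeric(ai_a), smooth_sigma_ms, bin_ms)
  b <- gaussian_smooth(as.numeric(ai_b), smooth_sigma_ms, bin_ms)
  if (sd(a) == 0 || sd(b) == 0) {
    return(list(lag_ms = NA_real_, peak_corr = NA_real_))
  }
  lp <- lagged_pearson(a, b, max_lag = max(1L, round(max_lag_ms / bin_ms)))
  ok <- !is.na(lp$r)
  if (!any(ok)) return(list(lag_ms = NA_real_, peak_corr = NA_real_))
  rmax <- max(lp$r[ok])
  cand <- which(ok & lp$r >= rmax - 1e-12)
  cand <- cand[order(abs(lp$lag[cand]), -sign(lp$lag[cand]))]
  k <- cand[1]
  list(lag_ms = lp$lag[k] * bin_ms, peak_corr = lp$r[k])
}

#' Select bursts in which the sending cluster leads
#'
#' Propagation statistics are computed on bursts that were activated in the
#' designated sending cluster before the receiving one; bursts with the
#' opposite delay sign are rejected (they propagated the other way).
#'
#' @param delays_ms per-burst delays, positive when the sender leads.
#' @return list with integer index vectors `kept` and `rejected` (NA delays
#'   are rejected).
#' @export
classify_sender <- function(delays_ms) {
  kept <- which(!is.na(delays_ms) & delays_ms > 0)
  list(kept = kept, rejected = setdiff(seq_along(delays_ms), kept))
}

#' Conditional propagation map
#'
#' Joint distribution of normalised burst intensities in a sending and a
#' receiving cluster, column-normalised so each sender-intensity column is a
#' conditional probability distribution over receiver intensities, plus the
#' Pearson correlation of the pairs. A threshold-like propagation rule shows
#' up as a two-regime structure: weak sender bursts map to silence, strong
#' ones to strong responses.
#'
#' @param sender,receiver paired burst intensities (one entry per burst).
#' @param n_bins histogram resolution per axis.
#' @param normalize divide each vector by its standard deviation first
#'   (the published normalisation), default TRUE.
#' @return list with `map` (receiver x sender conditional probabilities),
#'   `sender_breaks`, `receiver_breaks`, `correlation`, `n`. Fewer than 30
#'   pairs triggers a low-power warning; constant input gives
#'   `correlation = NA`.
#' @export
conditional_propagation_map <- function(sender, receiver, n_bins = 10,
                                        normalize = TRUE) {
  stopifnot(length(sender) == length(receiver))
  n <- length(sender)
  if (n < 30) warning("fewer than 30 bursts; correlation has low power")
  if (normalize) {
    sender <- normalize_intensity(sender)
    receiver <- receiver / sd(receiver)
  }
  corr <- if (sd(sender) == 0 || sd(receiver) == 0) NA_real_ else
    cor(sender, receiver)
  sb <- seq(min(sender), max(sender), length.out = n_bins + 1)
  rb <- seq(min(receiver), max(receiver), length.out = n_bins + 1)
  si <- findInterval(sender, sb, rightmost.closed = TRUE, all.inside = TRUE)
  ri <- findInterval(receiver, rb, rightmost.closed = TRUE, all.inside = TRUE)
  m <- matrix(0, n_bins, n_bins)
  for (k in seq_len(n)) m[ri[k], si[k]] <- m[ri[k], si[k]] + 1
  cs <- colSums(m)
  cs[cs == 0] <- 1
  list(map = sweep(m, 2, cs, "/"), sender_breaks = sb, receiver_breaks = rb,
       correlation = corr, n = n)
}

#' Transfer probability between two recorded clusters
#'
#' Given the occurrence of a burst in one cluster, the probability that a
#' burst starts in the other cluster within the stated window (1 s in the
#' published distance profiles).
#'
#' @param bursts_a,bursts_b `nb_set$bursts` data.frames (need `start_ms`).
#' @param window_ms coincidence window (ms).
#' @return probability in `[0, 1]`; `NA` if `bursts_a` is empty.
#' @export
transfer_probability_recording <- function(bursts_a, bursts_b,
                                           window_ms = 1000) {
  if (nrow(bursts_a) == 0) return(NA_real_)
  if (nrow(bursts_b) == 0) return(0)
  hits <- vapply(bursts_a$start_ms, function(t0) {
    any(bursts_b$start_ms >= t0 & bursts_b$start_ms <= t0 + window_ms)
  }, logical(1))
  mean(hits)
}

#' Transmitted bursts of the model
#'
#' A cluster-1 burst counts as transmitted if a cluster-2 burst peak occurs
#' within `window_ms` (200 ms) after the cluster-1 burst onset. The delay of
#' a transmitted burst is the lag between the two clusters' burst peaks.
#'
#' @param bursts_1,bursts_2 `nb_set$bursts` data.frames of the two clusters.
#' @param window_ms transmission window (ms).
#' @return data.frame with `burst_id` (cluster-1 id) and `delay_ms`
#'   (peak-to-peak lag; `NA` when not transmitted).
#' @export
transmitted_bursts <- function(bursts_1, bursts_2, window_ms = 200) {
  delay <- vapply(seq_len(nrow(bursts_1)), function(k) {
    t0 <- bursts_1$start_ms[k]
    hits <- bursts_2$peak_ms[bursts_2$peak_ms >= t0 &
                             bursts_2$peak_ms <= t0 + window_ms]
    if (length(hits) == 0) NA_real_ else min(hits) - bursts_1$peak_ms[k]
  }, numeric(1))
  data.frame(burst_id = bursts_1$burst_id, delay_ms = delay)
}

#' Baseline-corrected model transfer probability
#'
#' Both model clusters are spontaneously active, so even two disconnected
#' clusters (`lambda = 0`) produce chance coincidences. The correction
#' subtracts the lambda = 0 transmitted count from both the transmitted and
#' the total count: `P = (T - T0) / (N - T0)`, clamped to `[0, 1]`.
#'
#' @param n_transmitted `T`: transmitted bursts at the lambda of interest.
#' @param n_total `N`: all cluster-1 bursts at that lambda.
#' @param baseline_transmitted `T0`: transmitted count at lambda = 0 under
#'   the same configuration.
#' @param baseline_total count subtracted from the denominator; defaults to
#'   `T0` (the reading used throughout), but the alternative reading that
#'   subtracts the lambda = 0 *total* burst count can be selected by
#'   passing it here.
#' @return corrected probability; `NA` when the corrected denominator is
#'   not positive.
#' @export
transfer_probability_model <- function(n_transmitted, n_total,
                                       baseline_transmitted,
                                       baseline_total = baseline_transmitted) {
  if (n_total <= baseline_total) return(NA_real_)
  p <- (n_transmitted - baseline_transmitted) /
    (n_total - baseline_total)
  min(max(p, 0), 1)
}

#' Long-term asymmetry between two clusters
#'
#' Cross-correlation of two long activity traces, rectified (negative
#' correlation values are discarded), then reduced to the normalised
#' difference between the positive-lag and negative-lag mass:
#' `(I+ - I-) / (I+ + I-)`, a value in `[-1, 1]` whose sign encodes the
#' dominant propagation direction (positive: the first trace leads). The
#' published analyses used recordings of eight hours or more; any length is
#' accepted, with a warning below ten minutes.
#'
#' @param a,b activity traces on the same grid.
#' @param bin_ms grid spacing (ms).
#' @param max_lag_ms integration range (ms, default 2000).
#' @return asymmetry value; `NA` when both rectified integrals vanish.
#' @export
longterm_asymmetry <- function(a, b, bin_ms = 2, max_lag_ms = 2000) {
  n <- length(a)
  if (n * bin_ms < 10 * 60 * 1000) {
    warning("trace shorter than 10 minutes; asymmetry estimate is noisy")
  }
  lp <- lagged_pearson(as.numeric(a), as.numeric(b),
                       max_lag = max(1L, round(max_lag_ms / bin_ms)))
  r <- lp$r
  r[is.na(r) | r < 0] <- 0
  pos <- sum(r[lp$lag > 0])
  neg <- sum(r[lp$lag < 0])
  if (pos + neg == 0) return(NA_real_)
  (pos - neg) / (pos + neg)
}

#' Propagation vector of a cluster during one burst
#'
#' The activity flow around a cluster is summarised by a vector: for each
#' active neighbouring cluster, the lag of the cross-correlation peak between
#' the two activity traces (sigma 50 ms smoothing) is multiplied by the unit
#' vector pointing from the cluster to that neighbour (a positive lag --
#' cluster leads -- points outward, a negative lag points inward), and the
#' per-neighbour vectors are averaged. The angle of the average with the
#' positive x-axis is `theta`.
#'
#' @param ai matrix (bins x channels) of AI traces over the burst window.
#' @param cluster channel index of the cluster under analysis.
#' @param neighbors channel indices of its grid neighbours.
#' @param positions data.frame/matrix with `x_um`, `y_um` per channel.
#' @param bin_ms grid spacing (ms).
#' @param smooth_sigma_ms smoothing for the lag estimate (ms, default 50).
#' @param min_active_ms neighbours active for less than this within the
#'   window are skipped (default 10 ms).
#' @param max_lag_ms lag search range (ms).
#' @return list with `vx`, `vy` (ms-weighted components), `magnitude_ms`,
#'   `theta` (radians in (-pi, pi]; `NA` for a null vector) and
#'   `n_neighbors` used.
#' @export
propagation_vector <- function(ai, cluster, neighbors, positions,
                               bin_ms = 2, smooth_sigma_ms = 50,
                               min_active_ms = 10, max_lag_ms = 500) {
  pos <- as.matrix(positions[, c("x_um", "y_um")])
  min_bins <- max(1, ceiling(min_active_ms / bin_ms))
  vx <- 0; vy <- 0; used <- 0L
  for (nb in neighbors) {
    if (sum(ai[, nb] > 0) < min_bins) next
    d <- burst_delay(ai[, cluster], ai[, nb], bin_ms,
                     smooth_sigma_ms, max_lag_ms)
    if (is.na(d$lag_ms)) next
    dir <- unname(pos[nb, ] - pos[cluster, ])
    dir <- dir / sqrt(sum(dir^2))
    vx <- vx + d$lag_ms * dir[1]
    vy <- vy + d$lag_ms * dir[2]
    used <- used + 1L
  }
  if (used == 0) {
    return(list(vx = NA_real_, vy = NA_real_, magnitude_ms = NA_real_,
                theta = NA_real_, n_neighbors = 0L))
  }
  vx <- vx / used; vy <- vy / used
  mag <- sqrt(vx^2 + vy^2)
  theta <- if (mag < 1e-9) NA_real_ else atan2(vy, vx)
  list(vx = vx, vy = vy, magnitude_ms = mag, theta = theta,
       n_neighbors = used)
}

#' Propagation variability of a network
#'
#' Variability of the propagation direction over bursts: the circular
#' standard deviation of `theta` is computed per cluster across bursts and
#' averaged over clusters. Disinhibition collapses propagation onto a
#' stereotyped direction, which shows up as a drop in this quantity.
#'
#' @param theta matrix (bursts x clusters) of propagation-vector angles
#'   (radians); NAs are ignored per cluster.
#' @return mean circular standard deviation (radians).
#' @export
propagation_variability <- function(theta) {
  theta <- as.matrix(theta)
  sds <- apply(theta, 2, function(th) {
    th <- th[!is.na(th)]
    if (length(th) < 2) return(NA_real_)
    rbar <- Mod(mean(exp(1i * th)))
    sqrt(-2 * log(max(rbar, 1e-12)))
  })
  mean(sds, na.rm = TRUE)
}

#' Correlation, delay and transfer probability versus distance
#'
#' For every channel pair: the long-run Pearson correlation of the AI traces,
#' the mean per-burst delay magnitude (cross-correlation peak within windows
#' around the first channel's burst peaks) and the transfer probability with
#' a 1-s window (averaged over the two directions). Pair values are binned by
#' the physical inter-channel distance and averaged per bin.
#'
#' @param ai matrix (bins x channels).
#' @param nb_sets list of `nb_set` objects, one per channel.
#' @param positions data.frame with `x_um`, `y_um` per channel.
#' @param bin_ms grid spacing (ms).
#' @param breaks_um distance bin edges (um), default 250-um bins.
#' @param delay_window_ms half-width of the per-burst window (ms).
#' @return data.frame per distance bin: `distance_um` (bin centre),
#'   `correlation`, `delay_ms`, `transfer_prob`, `n_pairs`; empty bins are
#'   dropped.
#' @export
distance_profiles <- function(ai, nb_sets, positions, bin_ms = 2,
                              breaks_um = NULL, delay_window_ms = 500) {
  nch <- ncol(ai)
  pos <- as.matrix(positions[, c("x_um", "y_um")])
  pairs <- which(upper.tri(matrix(0, nch, nch)), arr.ind = TRUE)
  half <- max(1L, round(delay_window_ms / bin_ms))
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    d_um <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    corr <- if (sd(ai[, i]) > 0 && sd(ai[, j]) > 0)
      cor(ai[, i], ai[, j]) else NA_real_
    bi <- nb_sets[[i]]$bursts
    lags <- vapply(bi$peak_ms, function(pk) {
      c0 <- max(1L, round(pk / bin_ms) - half)
      c1 <- min(nrow(ai), round(pk / bin_ms) + half)
      if (c1 - c0 < 16) return(NA_real_)
      abs(burst_delay(ai[c0:c1, i], ai[c0:c1, j], bin_ms,
                      max_lag_ms = delay_window_ms)$lag_ms)
    }, numeric(1))
    tp <- mean(c(
      transfer_probability_recording(nb_sets[[i]]$bursts, nb_sets[[j]]$bursts),
      transfer_probability_recording(nb_sets[[j]]$bursts, nb_sets[[i]]$bursts)
    ), na.rm = TRUE)
    data.frame(distance_um = d_um, correlation = corr,
               delay_ms = mean(lags, na.rm = TRUE), transfer_prob = tp)
  })
  res <- do.call(rbind, res)
  if (is.null(breaks_um)) {
    breaks_um <- seq(0, max(res$distance_um) + 250, by = 250)
  }
  bin <- cut(res$distance_um, breaks_um, include.lowest = TRUE)
  out <- do.call(rbind, lapply(split(res, bin), function(d) {
    if (nrow(d) == 0) return(NULL)
    data.frame(distance_um = mean(d$distance_um),
               correlation = mean(d$correlation, na.rm = TRUE),
               delay_ms = mean(d$delay_ms, na.rm = TRUE),
               transfer_prob = mean(d$transfer_prob, na.rm = TRUE),
               n_pairs = nrow(d))
  }))
  rownames(out) <- NULL
  out
}

#' Correlation of per-burst firing between the model clusters
#'
#' For every detected cluster-1 burst, the total cluster-1 spike count over
#' the burst window is paired with the total cluster-2 spike count over the
#' same window extended by the transmission window; the Pearson correlation
#' over bursts measures how much rate information crosses the bridge.
#'
#' @param sim a `simulation_result`.
#' @param bursts_1 cluster-1 `nb_set$bursts`.
#' @param window_ms extension of the receiving window (ms, default 200).
#' @return Pearson correlation; `NA` for fewer than 3 bursts or degenerate
#'   variance. Fewer than 30 bursts triggers a low-power warning.
#' @export
rate_correlation_model <- function(sim, bursts_1, window_ms = 200) {
  if (nrow(bursts_1) < 3) return(NA_real_)
  if (nrow(bursts_1) < 30) {
    warning("fewer than 30 bursts; rate correlation has low power")
  }
  sp <- sim$spikes
  cl <- sim$conn$cluster_of[sp$neuron]
  x <- vapply(seq_len(nrow(bursts_1)), function(k) {
    sum(cl == 1 & sp$time_ms >= bursts_1$start_ms[k] &
          sp$time_ms <= bursts_1$end_ms[k])
  }, numeric(1))
  y <- vapply(seq_len(nrow(bursts_1)), function(k) {
    sum(cl == 2 & sp$time_ms >= bursts_1$start_ms[k] &
          sp$time_ms <= bursts_1$end_ms[k] + window_ms)
  }, numeric(1))
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Propagation speed between clusters
#'
#' Plain unit conversion: an inter-cluster distance divided by an activation
#' delay. With the 500-um electrode pitch of the cluster grids, a 100-ms
#' delay corresponds to 5 um/ms -- orders of magnitude below axonal
#' conduction, which is why the delays are attributed to recruitment.
#'
#' @param distance_um distance (um).
#' @param delay_ms delay (ms).
#' @return speed (um/ms).
#' @export
propagation_speed <- function(distance_um, delay_ms) {
  distance_um / delay_ms
}
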
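#' Network-burst detection parameters
#'
#' Three presets reproduce the published settings:
#' \describe{
#'   \item{`channel`}{single experimental channel: window `W = 100` ms in
#'     steps of 10 ms, count threshold `T = 10` active bins, merge gap
#'     `G = 100` ms, peak smoothing sigma 50 ms.}
#'   \item{`network`}{whole-network detection: as `channel` but active bins
#'     are pooled over all channels, `G = 1000` ms, channels active for less
#'     than 10 ms within a burst are excluded from its participant set and
#'     (when enforced) bursts with fewer than 5 participating clusters are
#'     discarded.}
#'   \item{`model`}{model rasters (spike counts instead of AI): `W = 10` ms,
#'     `T = 5`, `G = 50` ms; the window advances on the 2-ms count grid. The
#'     large number of sampled neurons makes model profiles smooth, hence the
#'     shorter window and lower threshold.}
#' }
#'
#' @param preset `"channel"`, `"network"` or `"model"`.
#' @param ... named overrides of individual fields (`W_ms`, `step_ms`,
#'   `T_count`, `G_ms`, `peak_sigma_ms`, `min_active_ms`,
#'   `min_active_clusters`).
#' @return list of class `burst_params`.
#' @export
burst_params <- function(preset = c("channel", "network", "model"), ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
    channel = list(W_ms = 100, step_ms = 10, T_count = 10, G_ms = 100,
                   peak_sigma_ms = 50, min_active_ms = 0,
                   min_active_clusters = 1),
    network = list(W_ms = 100, step_ms = 10, T_count = 10, G_ms = 1000,
                   peak_sigma_ms = 50, min_active_ms = 10,
                   min_active_clusters = 5),
    model = list(W_ms = 10, step_ms = 2, T_count = 5, G_ms = 50,
                 peak_sigma_ms = 50, min_active_ms = 0,
                 min_active_clusters = 1)
  )
  over <- list(...)
  p[names(over)] <- over
  stopifnot(p$W_ms > 0, p$step_ms > 0, p$T_count >= 0, p$G_ms >= 0)
  structure(c(p, list(preset = preset)), class = "burst_params")
}

# the shared counting cascade: active-bin counts in moving windows,
# threshold at T, boxcar re-convolution, threshold at 1, runs -> bin spans
candidate_spans <- function(active, params, bin_ms) {
  wlen <- max(1L, as.integer(round(params$W_ms / bin_ms)))
  wstep <- max(1L, as.integer(round(params$step_ms / bin_ms)))
  n <- length(active)
  if (n < wlen) return(matrix(integer(0), ncol = 2))
  starts <- seq.int(1L, n - wlen + 1L, by = wstep)
  ca <- c(0, cumsum(active))
  counts <- ca[starts + wlen] - ca[starts]
  counts[counts < params$T_count] <- 0
  # second convolution with the same (boxcar) kernel on the window grid,
  # then binarisation at 1: extends candidate regions to the burst edges
  klen <- max(1L, as.integer(round(params$W_ms / params$step_ms)))
  kpad <- c(numeric(klen), counts, numeric(klen))
  sm <- stats::filter(kpad, rep(1, klen), sides = 2)
  sm <- as.numeric(sm[(klen + 1):(klen + length(counts))])
  b <- !is.na(sm) & sm >= 1
  if (!any(b)) return(matrix(integer(0), ncol = 2))
  r <- rle(b)
  ends_w <- cumsum(r$lengths)
  starts_w <- ends_w - r$lengths + 1L
  pos <- which(r$values)
  cbind(starts[starts_w[pos]],                      # first covered bin
        pmin(starts[ends_w[pos]] + wlen - 1L, n))   # last covered bin
}

# merge spans closer than G ms (end-to-start), assuming sorted input
merge_spans <- function(spans, G_ms, bin_ms) {
  if (nrow(spans) <= 1) return(spans)
  out <- spans[1, , drop = FALSE]
  for (k in 2:nrow(spans)) {
    gap_ms <- (spans[k, 1] - out[nrow(out), 2] - 1) * bin_ms
    if (gap_ms < G_ms) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], spans[k, 2])
    } else {
      out <- rbind(out, spans[k, , drop = FALSE])
    }
  }
  out
}

# refine a candidate span on the AI grid: first/last non-zero bin and the
# peak of the Gaussian-smoothed AI (earliest maximum on ties)
refine_span <- function(ai, smoothed, span, bin_ms, t0_ms) {
  seg <- span[1]:span[2]
  nz <- seg[ai[seg] > 0]
  if (length(nz) == 0) return(NULL)
  i0 <- nz[1]; i1 <- nz[length(nz)]
  sseg <- smoothed[i0:i1]
  ipk <- i0 + which.max(sseg) - 1L
  data.frame(
    start_ms = t0_ms + (i0 - 1) * bin_ms,
    end_ms = t0_ms + i1 * bin_ms,
    peak_ms = t0_ms + (ipk - 0.5) * bin_ms,
    intensity = sum(ai[i0:i1])
  )
}

#' Detect network bursts on a single channel
#'
#' Implements the full detection cascade on an activity-intensity series (or,
#' for model output, a spike-count series): count active (non-zero) bins in
#' moving windows of length `W` advancing in steps of `step`; zero window
#' counts below `T`; convolve the thresholded count series a second time with
#' the same boxcar kernel and binarise at 1 (this recovers activity near the
#' burst edges); take runs of positive values as candidate bursts; merge
#' candidates closer than `G` ms; finally refine each burst on the original
#' grid -- start and end are the first and last non-zero bin, the peak is the
#' earliest maximum of the Gaussian-smoothed series (sigma
#' `peak_sigma_ms`) -- and sum the series over the burst as its intensity.
#'
#' @param ai AI (or spike-count) series on a uniform grid.
#' @param params a [burst_params()] list.
#' @param bin_ms grid spacing (ms, default 2).
#' @param t0_ms time of the left edge of the first bin (ms).
#' @return object of class `nb_set`: list with `bursts` (data.frame
#'   `burst_id`, `start_ms`, `end_ms`, `peak_ms`, `intensity`,
#'   `recruitment_ms = peak - start`), `channels` (same rows, with a
#'   `channel` column), `params`, `bin_ms`. Empty input gives zero rows.
#' @export
detect_bursts_channel <- function(ai, params = burst_params("channel"),
                                  bin_ms = 2, t0_ms = 0) {
  ai <- as.numeric(ai)
  spans <- candidate_spans(ai > 0, params, bin_ms)
  spans <- merge_spans(spans, params$G_ms, bin_ms)
  smoothed <- if (length(ai)) {
    gaussian_smooth(ai, params$peak_sigma_ms, bin_ms)
  } else ai
  rows <- list()
  if (nrow(spans) > 0) {
    for (k in seq_len(nrow(spans))) {
      r <- refine_span(ai, smoothed, spans[k, ], bin_ms, t0_ms)
      if (!is.null(r)) rows[[length(rows) + 1]] <- r
    }
  }
  bursts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start_ms = numeric(0), end_ms = numeric(0),
               peak_ms = numeric(0), intensity = numeric(0))
  bursts$burst_id <- seq_len(nrow(bursts))
  bursts$recruitment_ms <- bursts$peak_ms - bursts$start_ms
  bursts <- bursts[, c("burst_id", "start_ms", "end_ms", "peak_ms",
                       "intensity", "recruitment_ms")]
  channels <- cbind(bursts, channel = rep(1L, nrow(bursts)))
  structure(list(bursts = bursts, channels = channels,
                 params = params, bin_ms = bin_ms),
            class = "nb_set")
}

#' Detect network bursts across channels
#'
#' As [detect_bursts_channel()], but active-bin counts are pooled over all
#' channels before windowing, and the merge gap is the network preset's
#' `G = 1` s (accounting for the long inter-cluster delays of modular
#' networks). Burst refinement (start/end/peak) uses the summed series.
#' Within each burst, every channel active for at least `min_active_ms` is a
#' participant and gets its own refined start/end/peak/intensity; bursts with
#' fewer than `min_active_clusters` participants are discarded.
#'
#' @param ai matrix (bins x channels) of AI values.
#' @param params a [burst_params()], default the `network` preset.
#' @param bin_ms,t0_ms grid spacing and origin (ms).
#' @return an `nb_set`; `channels` holds one row per (burst, participating
#'   channel) with per-channel refinement, `bursts` the network-level rows
#'   with `n_channels`.
#' @export
detect_bursts_network <- function(ai, params = burst_params("network"),
                                  bin_ms = 2, t0_ms = 0) {
  stopifnot(is.matrix(ai), ncol(ai) >= 2)
  spans <- candidate_spans_pooled(ai, params, bin_ms)
  spans <- merge_spans(spans, params$G_ms, bin_ms)
  total <- rowSums(ai)
  smoothed <- if (nrow(ai)) gaussian_smooth(total, params$peak_sigma_ms, bin_ms) else total
  net_rows <- list(); ch_rows <- list()
  min_bins <- ceiling(params$min_active_ms / bin_ms)
  if (nrow(spans) > 0) {
    for (k in seq_len(nrow(spans))) {
      r <- refine_span(total, smoothed, spans[k, ], bin_ms, t0_ms)
      if (is.null(r)) next
      seg <- spans[k, 1]:spans[k, 2]
      parts <- which(colSums(ai[seg, , drop = FALSE] > 0) >= max(min_bins, 1))
      if (length(parts) < params$min_active_clusters) next
      bid <- length(net_rows) + 1L
      net_rows[[bid]] <- cbind(r, n_channels = length(parts))
      for (ch in parts) {
        sm_ch <- gaussian_smooth(ai[, ch], params$peak_sigma_ms, bin_ms)
        rc <- refine_span(ai[, ch], sm_ch, spans[k, ], bin_ms, t0_ms)
        if (is.null(rc)) next
        ch_rows[[length(ch_rows) + 1]] <- cbind(burst_tmp = bid, rc, channel = ch)
      }
    }
  }
  bursts <- if (length(net_rows)) do.call(rbind, net_rows) else
    data.frame(start_ms = numeric(0), end_ms = numeric(0),
               peak_ms = numeric(0), intensity = numeric(0),
               n_channels = integer(0))
  bursts$burst_id <- seq_len(nrow(bursts))
  bursts$recruitment_ms <- bursts$peak_ms - bursts$start_ms
  bursts <- bursts[, c("burst_id", "start_ms", "end_ms", "peak_ms",
                       "intensity", "recruitment_ms", "n_channels")]
  channels <- if (length(ch_rows)) {
    cc <- do.call(rbind, ch_rows)
    data.frame(burst_id = cc$burst_tmp, channel = cc$channel,
               start_ms = cc$start_ms, end_ms = cc$end_ms,
               peak_ms = cc$peak_ms, intensity = cc$intensity,
               recruitment_ms = cc$peak_ms - cc$start_ms)
  } else {
    data.frame(burst_id = integer(0), channel = integer(0),
               start_ms = numeric(0), end_ms = numeric(0),
               peak_ms = numeric(0), intensity = numeric(0),
               recruitment_ms = numeric(0))
  }
  structure(list(bursts = bursts, channels = channels,
                 params = params, bin_ms = bin_ms),
            class = "nb_set")
}

# window counts pooled over channels (sum of active bins across all channels)
candidate_spans_pooled <- function(ai, params, bin_ms) {
  wlen <- max(1L, as.integer(round(params$W_ms / bin_ms)))
  wstep <- max(1L, as.integer(round(params$step_ms / bin_ms)))
  n <- nrow(ai)
  if (n < wlen) return(matrix(integer(0), ncol = 2))
  active <- rowSums(ai > 0)
  starts <- seq.int(1L, n - wlen + 1L, by = wstep)
  ca <- c(0, cumsum(active))
  counts <- ca[starts + wlen] - ca[starts]
  counts[counts < params$T_count] <- 0
  klen <- max(1L, as.integer(round(params$W_ms / params$step_ms)))
  kpad <- c(numeric(klen), counts, numeric(klen))
  sm <- stats::filter(kpad, rep(1, klen), sides = 2)
  sm <- as.numeric(sm[(klen + 1):(klen + length(counts))])
  b <- !is.na(sm) & sm >= 1
  if (!any(b)) return(matrix(integer(0), ncol = 2))
  r <- rle(b)
  ends_w <- cumsum(r$lengths)
  starts_w <- ends_w - r$lengths + 1L
  pos <- which(r$values)
  cbind(starts[starts_w[pos]], pmin(starts[ends_w[pos]] + wlen - 1L, n))
}

#' Recruitment time of a burst
#'
#' Time from burst onset to burst peak: the interval over which the cluster's
#' population recruits towards maximal firing. Recruitment times are the
#' model-free explanation for the long inter-cluster propagation delays of
#' modular networks.
#'
#' @param burst one row (or several) of an `nb_set$bursts` data.frame.
#' @return numeric vector, `peak_ms - start_ms`.
#' @export
recruitment_time <- function(burst) {
  burst$peak_ms - burst$start_ms
}

#' Burst intensities and their normalised variant
#'
#' The intensity of a burst is the sum of the AI trace over the burst window
#' (already computed during detection). The normalised intensity divides by
#' the standard deviation of the intensities over all bursts of that channel,
#' which makes intensities comparable across channels with different gains.
#'
#' @param intensities numeric vector of burst intensities of one channel.
#' @return vector of normalised intensities (SD 1 over the population).
#' @export
normalize_intensity <- function(intensities) {
  s <- sd(intensities)
  if (!is.finite(s) || s == 0) {
    stop("intensity standard deviation is zero; cannot normalise")
  }
  intensities / s
}
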
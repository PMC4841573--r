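#' Cluster-grid geometry
#'
#' Geometry of a patterned culture: clusters grown on adhesive islands laid
#' out on a rectangular grid (default 6 x 10 at 500-um pitch, one electrode
#' per island), with island diameters in the 80-200 um range. Cell counts per
#' cluster follow the empirical area calibration of [cells_from_area()].
#'
#' @param rows,cols grid shape.
#' @param pitch_um electrode/island spacing (um).
#' @param diameter_um island diameter(s), recycled over clusters.
#' @return object of class `cluster_geometry`: `positions` (data.frame
#'   `cluster`, `x_um`, `y_um`; origin at the grid corner, x rightward,
#'   y upward), `adjacency` (list of 4-neighbour index vectors),
#'   `area_um2`, `cells`, and the shape fields.
#' @export
cluster_geometry <- function(rows = 6, cols = 10, pitch_um = 500,
                             diameter_um = 140) {
  stopifnot(rows >= 1, cols >= 1, pitch_um > 0)
  n <- rows * cols
  idx <- seq_len(n) - 1L
  positions <- data.frame(
    cluster = seq_len(n),
    x_um = (idx %% cols) * pitch_um,
    y_um = (idx %/% cols) * pitch_um
  )
  adjacency <- lapply(seq_len(n), function(k) {
    r <- (k - 1L) %/% cols
    c_ <- (k - 1L) %% cols
    nb <- c(
      if (c_ > 0) k - 1L, if (c_ < cols - 1L) k + 1L,
      if (r > 0) k - cols, if (r < rows - 1L) k + cols
    )
    as.integer(nb)
  })
  area <- pi * (rep_len(diameter_um, n) / 2)^2
  structure(
    list(positions = positions, adjacency = adjacency, rows = rows,
         cols = cols, pitch_um = pitch_um,
         diameter_um = rep_len(diameter_um, n),
         area_um2 = area, cells = cells_from_area(area)),
    class = "cluster_geometry"
  )
}

#' Cells per cluster from island area
#'
#' Empirical calibration for cultures grown under these patterning
#' conditions: `N = 0.0079 S - 1.9`, with `S` the cluster area in um^2,
#' floored at zero for very small islands.
#'
#' @param S area (um^2), non-negative; vectorised.
#' @return estimated cell count(s).
#' @export
cells_from_area <- function(S) {
  if (any(S < 0)) stop("area must be non-negative")
  pmax(0.0079 * S - 1.9, 0)
}

#' Generate a ground-truth burst schedule
#'
#' Draws a schedule of network bursts with fully known ground truth, used to
#' validate every analysis stage. Burst onsets form a stationary renewal
#' process (exponential gaps plus a refractory floor, so bursts do not
#' overlap). Each burst starts in an initiating cluster and propagates along
#' the grid adjacency; each hop is attempted independently, fails with
#' `failure_prob` (truncating participation beyond the failure), and
#' otherwise delivers activation after a sampled hop delay. Earliest arrival
#' wins when a cluster is reachable along several paths.
#'
#' Alternatively, an explicit `pattern_probs` table fixes the participation
#' patterns and their probabilities (hop failures are then disabled);
#' activation still spreads from the pattern's first active cluster with
#' sampled hop delays.
#'
#' @param geometry a [cluster_geometry()].
#' @param duration_ms schedule length (ms).
#' @param rate_hz burst initiation rate (Hz) before the refractory floor.
#' @param initiator_probs per-cluster initiation probabilities (default
#'   uniform).
#' @param hop_delay_mean_ms,hop_delay_sd_ms Gaussian per-hop delay (ms),
#'   truncated at 1 ms.
#' @param failure_prob per-hop failure probability.
#' @param pattern_probs optional list with `patterns` (matrix patterns x
#'   clusters of 0/1), `probs` (summing to 1) and optionally `initiators`
#'   (one active cluster per pattern; defaults to each pattern's first
#'   active cluster).
#' @param amplitude_mean,amplitude_sd per-activation intensity scale
#'   (Gaussian, truncated at 0.2).
#' @param min_gap_ms refractory floor between burst onsets (ms).
#' @param seed optional integer seed; the schedule is reproducible given it.
#' @return object of class `burst_schedule`: `bursts` (data.frame
#'   `burst_id`, `t0_ms`, `initiator`), `activations` (data.frame
#'   `burst_id`, `cluster`, `onset_ms`, `amplitude`), `n_clusters`,
#'   `duration_ms`, `params`.
#' @export
make_schedule <- function(geometry, duration_ms = 300000, rate_hz = 0.25,
                          initiator_probs = NULL,
                          hop_delay_mean_ms = 30, hop_delay_sd_ms = 5,
                          failure_prob = 0.2, pattern_probs = NULL,
                          amplitude_mean = 1, amplitude_sd = 0.25,
                          min_gap_ms = 2000, seed = NULL) {
  stopifnot(inherits(geometry, "cluster_geometry"))
  if (!is.null(seed)) set.seed(seed)
  n_cl <- nrow(geometry$positions)
  if (rate_hz * duration_ms / 1000 < 1) {
    warning("expected burst count below 1; schedule will likely be empty")
  }
  if (!is.null(pattern_probs)) {
    stopifnot(abs(sum(pattern_probs$probs) - 1) < 1e-6,
              ncol(pattern_probs$patterns) == n_cl,
              all(rowSums(pattern_probs$patterns != 0) > 0))
  }
  if (is.null(initiator_probs)) initiator_probs <- rep(1 / n_cl, n_cl)

  # renewal onsets: refractory floor + exponential gap
  t <- 0
  onsets <- numeric(0)
  repeat {
    t <- t + min_gap_ms + rexp(1, rate_hz / 1000)
    if (t > duration_ms - 1000) break
    onsets <- c(onsets, t)
  }

  bursts <- list(); activ <- list()
  for (b in seq_along(onsets)) {
    t0 <- onsets[b]
    if (!is.null(pattern_probs)) {
      pk <- sample.int(nrow(pattern_probs$patterns), 1,
                       prob = pattern_probs$probs)
      pat <- which(pattern_probs$patterns[pk, ] != 0)
      init <- if (!is.null(pattern_probs$initiators))
        pattern_probs$initiators[pk] else pat[1]
      stopifnot(init %in% pat)
      onset_of <- wave_onsets(geometry, init, active_set = pat,
                              hop_delay_mean_ms, hop_delay_sd_ms,
                              failure_prob = 0)
    } else {
      init <- sample.int(n_cl, 1, prob = initiator_probs)
      onset_of <- wave_onsets(geometry, init, active_set = seq_len(n_cl),
                              hop_delay_mean_ms, hop_delay_sd_ms,
                              failure_prob)
    }
    act <- which(is.finite(onset_of))
    amp <- pmax(rnorm(length(act), amplitude_mean, amplitude_sd), 0.2)
    bursts[[b]] <- data.frame(burst_id = b, t0_ms = t0, initiator = init)
    activ[[b]] <- data.frame(burst_id = b, cluster = act,
                             onset_ms = t0 + onset_of[act], amplitude = amp)
  }
  structure(
    list(
      bursts = if (length(bursts)) do.call(rbind, bursts) else
        data.frame(burst_id = integer(0), t0_ms = numeric(0),
                   initiator = integer(0)),
      activations = if (length(activ)) do.call(rbind, activ) else
        data.frame(burst_id = integer(0), cluster = integer(0),
                   onset_ms = numeric(0), amplitude = numeric(0)),
      n_clusters = n_cl, duration_ms = duration_ms,
      params = list(rate_hz = rate_hz, hop_delay_mean_ms = hop_delay_mean_ms,
                    hop_delay_sd_ms = hop_delay_sd_ms,
                    failure_prob = failure_prob,
                    pattern_probs = pattern_probs, min_gap_ms = min_gap_ms),
      seed = seed
    ),
    class = "burst_schedule"
  )
}

# event-driven wave propagation over the grid: earliest-arrival activation
# with independent per-hop failures and truncated-Gaussian hop delays
wave_onsets <- function(geometry, init, active_set, mean_ms, sd_ms,
                        failure_prob) {
  n <- nrow(geometry$positions)
  onset <- rep(Inf, n)
  onset[init] <- 0
  frontier <- init
  visited <- logical(n)
  while (length(frontier) > 0) {
    cur <- frontier[which.min(onset[frontier])]
    frontier <- setdiff(frontier, cur)
    if (visited[cur]) next
    visited[cur] <- TRUE
    for (nb in geometry$adjacency[[cur]]) {
      if (!(nb %in% active_set) || visited[nb]) next
      if (runif(1) < failure_prob) next
      d <- max(rnorm(1, mean_ms, sd_ms), 1)
      if (onset[cur] + d < onset[nb]) {
        onset[nb] <- onset[cur] + d
        frontier <- union(frontier, nb)
      }
    }
  }
  onset
}

#' Render a synthetic multielectrode voltage recording
#'
#' Turns a [make_schedule()] into raw voltage traces, one channel per
#' cluster: each activation drives an inhomogeneous Poisson spike train whose
#' rate follows a rise/decay burst envelope scaled by the activation
#' amplitude, each spike contributing a biphasic 1.2-ms waveform with
#' variable amplitude; sporadic spikes occur at a low background rate; i.i.d.
#' Gaussian noise is added throughout. The defaults emulate the regime of
#' dense multi-unit cluster recordings: during a burst the superimposed
#' firing of the ~10^2 neurons under the electrode overlaps into a
#' near-Gaussian high-variance signal (which the kurtosis-based noise
#' threshold deliberately retains), while sporadic isolated spikes are
#' super-Gaussian outliers (rejected from the threshold estimate and
#' removed from burst profiles by the count threshold).
#'
#' @param schedule a `burst_schedule`.
#' @param geometry the matching [cluster_geometry()].
#' @param rate_hz sampling rate (Hz, default 10000).
#' @param noise_sigma_uv Gaussian noise SD (uV).
#' @param spike_amp_uv nominal spike amplitude (uV); per-spike amplitudes
#'   jitter uniformly in +/-50%.
#' @param peak_rate_hz population firing rate at the envelope peak for unit
#'   amplitude (spikes/s summed over the cluster).
#' @param rise_ms,decay_ms burst envelope time constants (ms); the envelope
#'   is `(1 - exp(-t/rise)) exp(-t/decay)`, normalised to unit peak, so the
#'   recruitment time is of order `rise`.
#' @param sporadic_rate_hz background spike rate per channel (Hz).
#' @param seed optional integer seed.
#' @return object of class `voltage_recording`: `volts` (samples x
#'   channels, uV), `rate_hz`, `channels` (data.frame `channel`, `cluster`,
#'   `x_um`, `y_um`).
#' @export
render_voltage <- function(schedule, geometry, rate_hz = 10000,
                           noise_sigma_uv = 10, spike_amp_uv = 100,
                           peak_rate_hz = 8000, rise_ms = 30, decay_ms = 200,
                           sporadic_rate_hz = 2, seed = NULL) {
  stopifnot(inherits(schedule, "burst_schedule"),
            inherits(geometry, "cluster_geometry"))
  if (!is.null(seed)) set.seed(seed)
  n_cl <- schedule$n_clusters
  ns <- as.integer(round(schedule$duration_ms * rate_hz / 1000))
  template <- spike_template(rate_hz) * spike_amp_uv
  tl <- length(template)

  # envelope on a 1-ms grid, normalised to unit peak
  env_len <- ceiling(4 * rise_ms + 6 * decay_ms)
  tt <- seq_len(env_len)
  env <- (1 - exp(-tt / rise_ms)) * exp(-tt / decay_ms)
  env <- env / max(env)

  volts <- matrix(rnorm(ns * n_cl, 0, noise_sigma_uv), ns, n_cl)
  ms_bins <- as.integer(floor(schedule$duration_ms))
  for (ch in seq_len(n_cl)) {
    rate_ms <- rep(sporadic_rate_hz / 1000, ms_bins)  # spikes per ms bin
    acts <- schedule$activations[schedule$activations$cluster == ch, ]
    for (a in seq_len(nrow(acts))) {
      i0 <- as.integer(floor(acts$onset_ms[a]))
      idx <- i0 + tt
      keep <- idx >= 1 & idx <= ms_bins
      rate_ms[idx[keep]] <- rate_ms[idx[keep]] +
        acts$amplitude[a] * peak_rate_hz / 1000 * env[keep]
    }
    counts <- rpois(ms_bins, rate_ms)
    hot <- which(counts > 0)
    if (length(hot) > 0) {
      sp_ms <- rep(hot - 1, counts[hot]) + runif(sum(counts[hot]))
      s0 <- as.integer(floor(sp_ms * rate_hz / 1000)) + 1L
      amp <- runif(length(s0), 0.5, 1.5)
      for (k in seq_along(s0)) {
        j <- s0[k]:min(s0[k] + tl - 1L, ns)
        volts[j, ch] <- volts[j, ch] + amp[k] * template[seq_along(j)]
      }
    }
  }
  structure(
    list(volts = volts, rate_hz = rate_hz,
         channels = data.frame(channel = seq_len(n_cl),
                               cluster = seq_len(n_cl),
                               x_um = geometry$positions$x_um,
                               y_um = geometry$positions$y_um)),
    class = "voltage_recording"
  )
}

# biphasic extracellular spike waveform, 1.2 ms, unit peak amplitude
spike_template <- function(rate_hz) {
  n <- max(2L, as.integer(round(1.2e-3 * rate_hz)))
  w <- sin(2 * pi * seq_len(n) / n)
  w / max(abs(w))
}
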
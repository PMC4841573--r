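# Independent oracles and fixture builders shared across the suite.

# brute-force Pearson cross-correlation by direct looping (oracle for the
# FFT/cumsum implementation and for the asymmetry integrals)
brute_lagged_pearson <- function(x, y, max_lag) {
  n <- length(x)
  vapply(-max_lag:max_lag, function(k) {
    if (k >= 0) cor(x[1:(n - k)], y[(1 + k):n]) else
      cor(x[(1 - k):n], y[1:(n + k)])
  }, numeric(1))
}

brute_asymmetry <- function(x, y, max_lag) {
  r <- brute_lagged_pearson(x, y, max_lag)
  r[is.na(r) | r < 0] <- 0
  lags <- -max_lag:max_lag
  (sum(r[lags > 0]) - sum(r[lags < 0])) /
    (sum(r[lags > 0]) + sum(r[lags < 0]))
}

# AI series with rectangular active blocks (bins are 2 ms); blocks is a list
# of c(start_bin, end_bin) inclusive
block_ai <- function(n_bins, blocks, value = 5) {
  ai <- numeric(n_bins)
  for (b in blocks) ai[b[1]:b[2]] <- value
  ai
}

# Gaussian bump centred at bin `at` (used for delay / asymmetry fixtures)
bump_ai <- function(n_bins, at, sigma_bins = 10, amp = 10) {
  amp * exp(-0.5 * ((seq_len(n_bins) - at) / sigma_bins)^2)
}

# small two-cluster model simulation, cached across tests (deterministic)
.sim_cache <- new.env(parent = emptyenv())
cached_model_sim <- function(lambda = 0.02, duration_ms = 30000, seed = 42) {
  key <- paste(lambda, duration_ms, seed, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    conn <- build_modular_connectivity(lambda = lambda, seed = seed)
    conn <- sample_strengths(conn)
    .sim_cache[[key]] <- simulate_network(
      conn, simulation_config(duration_ms = duration_ms), seed = seed + 1L
    )
  }
  .sim_cache[[key]]
}

# scaled-down modularity sweep shared by the acceptance tests
cached_sweep <- function() {
  if (is.null(.sim_cache$sweep)) {
    .sim_cache$sweep <- sweep_modularity(
      c(0, 0.02, 0.05, 0.1, 0.15),
      scheme = "proportional", condition = "control",
      inhibition_level = "low", n_seeds = 2,
      config = simulation_config(duration_ms = 60000),
      base_seed = 1
    )
  }
  .sim_cache$sweep
}

# synthetic two-cluster recording with ground truth, cached
cached_pair_recording <- function(duration_ms = 180000, seed = 11,
                                  hop_sd = 5) {
  key <- paste("rec", duration_ms, seed, hop_sd, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    geom <- cluster_geometry(1, 2)
    sched <- make_schedule(geom, duration_ms = duration_ms,
                           hop_delay_sd_ms = hop_sd, seed = seed)
    rec <- render_voltage(sched, geom, seed = seed + 1L)
    ai <- recording_intensity(rec)
    .sim_cache[[key]] <- list(geom = geom, sched = sched, rec = rec, ai = ai)
  }
  .sim_cache[[key]]
}
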
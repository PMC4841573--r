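#' Simulation configuration
#'
#' @param dt integration step (ms). The network is integrated with a plain
#'   forward-Euler scheme.
#' @param duration_ms total simulated time (ms).
#' @param spike_threshold membrane potential (mV) whose upward crossing
#'   registers an action potential. Spikes of this model peak near +30 mV, so
#'   10 mV separates spikes cleanly from subthreshold fluctuations.
#' @param refractory_ms lockout (ms) preventing double-counting of one spike
#'   across consecutive Euler steps.
#' @param warmup_ms initial transient discarded by the analysis helpers
#'   (desynchronised random initial conditions settle within a few seconds).
#' @param v_init_range range (mV) for the uniform random initial membrane
#'   potentials; the K+ gate starts at its steady state `W_SS(V)`.
#' @param v_bound divergence guard: the simulation aborts if any `|V|`
#'   exceeds this (mV).
#' @param trace_neurons integer ids of neurons whose voltage traces to record.
#' @param trace_every_ms sampling interval (ms) for the recorded traces.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(dt = 0.1, duration_ms = 300000,
                              spike_threshold = 10, refractory_ms = 2,
                              warmup_ms = 5000,
                              v_init_range = c(-50, -30),
                              v_bound = 500,
                              trace_neurons = integer(0),
                              trace_every_ms = 1) {
  stopifnot(dt > 0, duration_ms >= dt, refractory_ms >= 0, warmup_ms >= 0)
  structure(
    list(dt = dt, duration_ms = duration_ms,
         spike_threshold = spike_threshold, refractory_ms = refractory_ms,
         warmup_ms = warmup_ms, v_init_range = v_init_range,
         v_bound = v_bound, trace_neurons = as.integer(trace_neurons),
         trace_every_ms = trace_every_ms),
    class = "simulation_config"
  )
}

#' Simulate the two-cluster network
#'
#' Forward-Euler integration of all neurons and synapses. Every neuron
#' receives, at every step, an i.i.d. Gaussian noise current (see
#' [noise_params()]); its synaptic input is `I_syn(t) = sum_i A_i y_i(t)` over
#' afferent synapses. Spikes are registered at upward crossings of the
#' threshold and propagated to the neuron's efferent synapses instantaneously
#' (no axonal delay: in these preparations inter-cluster delays arise from
#' recruitment dynamics, not conduction).
#'
#' @param conn a [build_modular_connectivity()] object with sampled strengths
#'   (see [sample_strengths()]).
#' @param config a [simulation_config()].
#' @param noise a [noise_params()] list.
#' @param seed optional integer seed; the full run is reproducible given the
#'   seed (bit-identical rasters).
#' @return An object of class `simulation_result`: list with `spikes`
#'   (data.frame `neuron`, `time_ms`), `conn`, `config`, `noise`,
#'   `conservation_error` (max per-step deviation of `x+y+z` from 1 before
#'   renormalisation), and optional `traces` (matrix) with `trace_t`.
#' @export
simulate_network <- function(conn, config = simulation_config(),
                             noise = noise_params(), seed = NULL) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  if (is.null(conn$strengths)) {
    stop("sample strengths first (see sample_strengths())")
  }
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(conn$a)
  # CSR adjacency by presynaptic neuron
  ptr <- integer(n + 1)
  idx <- integer(0)
  w <- numeric(0)
  tl <- lapply(seq_len(n), function(i) which(conn$a[i, ] == 1L))
  lens <- vapply(tl, length, integer(1))
  ptr <- c(0L, cumsum(lens))
  idx <- unlist(tl, use.names = FALSE) - 1L
  w <- unlist(lapply(seq_len(n), function(i) conn$strengths[i, tl[[i]]]),
              use.names = FALSE)
  if (length(idx) == 0) { idx <- integer(0); w <- numeric(0) }

  npar <- t(vapply(seq_len(n), function(i) {
    p <- neuron_params(conn$type_of[i] == "I")
    c(p$g_Ca, p$g_K, p$g_L, p$V_Ca, p$V_K, p$V_L,
      p$V1, p$V2, p$V3, p$V4, p$C_m, p$phi)
  }, numeric(12)))
  spar <- t(vapply(seq_len(n), function(i) {
    p <- synapse_params(conn$type_of[i], "E", conn$inhibition_level)
    c(p$tau_rec, p$tau_d,
      if (is.na(p$tau_facil)) 1 else p$tau_facil,
      p$U0, as.numeric(p$u_dynamic))
  }, numeric(5)))

  res <- sim_core(
    ptr, idx, w, npar, spar,
    noise$mu, noise$sigma,
    config$dt, config$duration_ms,
    config$spike_threshold, config$refractory_ms,
    config$v_init_range[1], config$v_init_range[2],
    config$trace_neurons - 1L,
    as.integer(round(config$trace_every_ms / config$dt)),
    config$v_bound
  )

  out <- list(
    spikes = data.frame(neuron = res$spike_id, time_ms = res$spike_t),
    conn = conn, config = config, noise = noise,
    conservation_error = res$conservation_error, seed = seed
  )
  if (!is.null(res$traces)) {
    out$traces <- res$traces
    out$trace_t <- res$trace_t
  }
  structure(out, class = "simulation_result")
}

#' Per-cluster spike-count series
#'
#' Bins the spikes of each cluster on a uniform grid. This count series plays
#' the role of the activity intensity for model output: downstream burst
#' detection operates on it unchanged (model preset).
#'
#' @param sim a `simulation_result`.
#' @param bin_ms bin width (ms, default 2).
#' @param from_ms start of the analysed interval (defaults to the configured
#'   warm-up, discarding the initial transient).
#' @return matrix (bins x clusters) with attributes `bin_ms` and `t0_ms`
#'   (left edge time of bin 1).
#' @export
cluster_spike_counts <- function(sim, bin_ms = 2, from_ms = NULL) {
  stopifnot(inherits(sim, "simulation_result"))
  if (is.null(from_ms)) from_ms <- sim$config$warmup_ms
  spikes <- sim$spikes[sim$spikes$time_ms > from_ms, ]
  dur <- sim$config$duration_ms - from_ms
  nb <- floor(dur / bin_ms)
  counts <- matrix(0, nb, 2)
  if (nrow(spikes) > 0) {
    cl <- sim$conn$cluster_of[spikes$neuron]
    b <- pmin(floor((spikes$time_ms - from_ms) / bin_ms) + 1, nb)
    for (c_i in 1:2) {
      tb <- tabulate(b[cl == c_i], nbins = nb)
      counts[, c_i] <- tb
    }
  }
  attr(counts, "bin_ms") <- bin_ms
  attr(counts, "t0_ms") <- from_ms
  counts
}

#' Modularity sweep of the two-cluster model
#'
#' Simulates the model across a set of modularity values and summarises burst
#' propagation per value: raw and baseline-corrected transfer probability,
#' inter-cluster delay (lag between the clusters' burst peaks) and the
#' correlation of per-burst firing between the clusters. The sweep must
#' include `lambda = 0`: chance coincidences of the two spontaneously active
#' clusters are measured there and subtracted from the transmitted and total
#' counts before the transfer probability is formed (see
#' [transfer_probability_model()]).
#'
#' @param lambdas modularity values; must contain 0.
#' @param scheme,condition,inhibition_level passed to
#'   [build_modular_connectivity()] / [synapse_params()].
#' @param n_seeds independent network realisations per lambda.
#' @param config a [simulation_config()]; the published sweeps used 300 s per
#'   run, scaled-down summaries use 60 s.
#' @param burst_params detection preset, default [burst_params("model")].
#' @param window_ms transmission window after the onset of a cluster-1 burst
#'   within which a cluster-2 burst peak counts as transfer (default 200).
#' @param base_seed integer; realisation `s` of lambda index `l` uses seed
#'   `base_seed + 1000 * l + s`.
#' @return data.frame, one row per lambda: `lambda`, `n_bursts` (cluster-1
#'   bursts, pooled over seeds), `transmitted`, `transfer_raw`,
#'   `transfer_prob` (baseline-corrected, clamped to `[0, 1]`), `delay_ms`
#'   (mean peak-to-peak lag of transmitted bursts), `rate_correlation`
#'   (seed-average). Lambdas with zero detected bursts get `NA` summaries.
#' @export
sweep_modularity <- function(lambdas,
                             scheme = "proportional",
                             condition = "control",
                             inhibition_level = "low",
                             n_seeds = 2,
                             config = simulation_config(duration_ms = 60000),
                             burst_params = modgate::burst_params("model"),
                             window_ms = 200,
                             base_seed = 1) {
  if (!any(lambdas == 0)) {
    stop("the sweep must include lambda = 0 for baseline correction")
  }
  lambdas <- sort(unique(lambdas))
  per_seed <- list()
  for (l in seq_along(lambdas)) {
    for (s in seq_len(n_seeds)) {
      seed <- base_seed + 1000L * l + s
      conn <- build_modular_connectivity(
        lambda = lambdas[l], scheme = scheme, condition = condition,
        inhibition_level = inhibition_level, seed = seed
      )
      conn <- sample_strengths(conn)
      sim <- simulate_network(conn, config = config)
      per_seed[[length(per_seed) + 1]] <-
        c(list(lambda = lambdas[l], seed = seed),
          summarise_propagation(sim, burst_params, window_ms))
    }
  }
  df <- do.call(rbind, lapply(per_seed, function(r) {
    data.frame(lambda = r$lambda, seed = r$seed, n_bursts = r$n_bursts,
               transmitted = r$transmitted, delay_ms = r$delay_ms,
               rate_correlation = r$rate_correlation)
  }))
  baseline <- sum(df$transmitted[df$lambda == 0]) / sum(df$lambda == 0)
  out <- do.call(rbind, lapply(split(df, df$lambda), function(d) {
    N <- sum(d$n_bursts)
    T_ <- sum(d$transmitted)
    T0 <- baseline * nrow(d)
    data.frame(
      lambda = d$lambda[1],
      n_bursts = N,
      transmitted = T_,
      transfer_raw = if (N > 0) T_ / N else NA_real_,
      transfer_prob = transfer_probability_model(T_, N, T0),
      delay_ms = mean(d$delay_ms, na.rm = TRUE),
      rate_correlation = mean(d$rate_correlation, na.rm = TRUE)
    )
  }))
  rownames(out) <- NULL
  out
}

# per-simulation propagation summary: burst detection on both clusters,
# transmission counting, peak-to-peak delays and per-burst rate correlation
summarise_propagation <- function(sim, bp, window_ms) {
  counts <- cluster_spike_counts(sim)
  bin <- attr(counts, "bin_ms")
  t0 <- attr(counts, "t0_ms")
  nb1 <- detect_bursts_channel(counts[, 1], bp, bin_ms = bin, t0_ms = t0)
  nb2 <- detect_bursts_channel(counts[, 2], bp, bin_ms = bin, t0_ms = t0)
  n1 <- nrow(nb1$bursts)
  if (n1 == 0 || nrow(nb2$bursts) == 0) {
    return(list(n_bursts = n1, transmitted = 0L,
                delay_ms = NA_real_, rate_correlation = NA_real_))
  }
  tr <- transmitted_bursts(nb1$bursts, nb2$bursts, window_ms)
  rc <- suppressWarnings(
    rate_correlation_model(sim, nb1$bursts, window_ms = window_ms))
  list(n_bursts = n1, transmitted = sum(!is.na(tr$delay_ms)),
       delay_ms = mean(tr$delay_ms, na.rm = TRUE),
       rate_correlation = rc)
}
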
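#' Write / read a spike raster
#'
#' Plain-text raster exchange format: a two-column CSV (`neuron_id`,
#' `time_ms`) with a header. On read, rows are sorted by neuron and time
#' (duplicate rows are preserved); negative times and -- when `n_neurons` is
#' given -- out-of-range neuron ids are rejected.
#'
#' @param spikes data.frame with `neuron` and `time_ms` (e.g.
#'   `simulation_result$spikes`).
#' @param path file path.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns the
#'   sorted data.frame.
#' @export
write_raster <- function(spikes, path) {
  df <- data.frame(neuron_id = spikes$neuron, time_ms = spikes$time_ms)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @param n_neurons optional number of neurons for id validation.
#' @export
read_raster <- function(path, n_neurons = NULL) {
  df <- read.csv(path)
  if (!all(c("neuron_id", "time_ms") %in% names(df))) {
    stop("raster file must have columns neuron_id, time_ms")
  }
  if (nrow(df) > 0) {
    if (any(df$time_ms < 0)) stop("negative spike times in raster")
    if (!is.null(n_neurons) &&
        any(df$neuron_id < 1 | df$neuron_id > n_neurons)) {
      stop("unknown neuron ids in raster")
    }
    df <- df[order(df$neuron_id, df$time_ms), ]
    rownames(df) <- NULL
  }
  data.frame(neuron = df$neuron_id, time_ms = df$time_ms)
}

#' Write / read a multichannel voltage recording
#'
#' Plain-text recording format: a CSV of voltage samples (one column per
#' channel) together with a JSON sidecar `<path>.meta.json` holding the
#' sampling rate and the channel table (cluster ids and positions). The
#' round-trip is lossless up to the stated number of significant digits
#' (default: full double precision).
#'
#' @param rec a `voltage_recording`.
#' @param path CSV file path; the metadata goes to `<path>.meta.json`.
#' @param digits significant digits written (default `NA`: full precision).
#' @return `write_recording` returns `path` invisibly; `read_recording` the
#'   `voltage_recording`.
#' @export
write_recording <- function(rec, path, digits = NA) {
  stopifnot(inherits(rec, "voltage_recording"))
  df <- as.data.frame(rec$volts)
  names(df) <- paste0("ch", seq_len(ncol(rec$volts)))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(rate_hz = rec$rate_hz, channels = rec$channels),
    paste0(path, ".meta.json"),
    auto_unbox = TRUE, digits = digits, dataframe = "columns"
  )
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    stop("missing recording metadata file: ", meta_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$rate_hz)) stop("recording metadata lacks 'rate_hz'")
  df <- read.csv(path)
  if (anyNA(df)) stop("inconsistent channel lengths in recording CSV")
  structure(
    list(volts = as.matrix(df), rate_hz = meta$rate_hz,
         channels = as.data.frame(meta$channels)),
    class = "voltage_recording"
  )
}

#' Write detected bursts as CSV
#'
#' One row per (burst, participating channel): `burst_id`, `channel`,
#' `start_ms`, `peak_ms`, `end_ms`, `intensity`.
#'
#' @param nb an `nb_set`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_bursts <- function(nb, path) {
  d <- nb$channels[, c("burst_id", "channel", "start_ms", "peak_ms",
                       "end_ms", "intensity")]
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration
#'
#' YAML configuration with optional sections `synth`, `signal`, `detect`,
#' `analyze` and top-level `seed` / `out_dir`; unknown presets are rejected
#' before any computation.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  presets <- c("pair", "chain3", "chain5", "grid6x10")
  if (is.null(cfg$synth$preset)) cfg$synth$preset <- "pair"
  if (!cfg$synth$preset %in% presets) {
    stop("unknown synth preset '", cfg$synth$preset, "'; available: ",
         paste(presets, collapse = ", "))
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$synth$duration_ms)) cfg$synth$duration_ms <- 120000
  if (is.null(cfg$detect$preset)) cfg$detect$preset <- "network"
  if (!cfg$detect$preset %in% c("channel", "network", "model")) {
    stop("unknown detection preset '", cfg$detect$preset, "'")
  }
  cfg
}

#' Run the synthetic analysis pipeline
#'
#' End-to-end driver: generate a synthetic recording for the configured
#' geometry preset, convert it to activity intensity, detect network bursts
#' and compute inter-cluster delays. Every stage logs its parameters; all
#' outputs (recording metadata, AI, bursts, delays, resolved config with
#' seed) are written to `out_dir` so a rerun with the same configuration is
#' file-identical.
#'
#' @param config list (see [read_run_config()]) or path to a YAML file.
#' @param out_dir output directory (created if needed); defaults to
#'   `config$out_dir` or a tempdir.
#' @param quiet suppress progress messages.
#' @return list with `schedule`, `recording`, `ai`, `bursts` (an `nb_set`),
#'   `delays` (data.frame) and `config`, invisibly writing CSV/JSON outputs.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  if (is.null(out_dir)) out_dir <- config$out_dir %||% tempfile("modgate_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[modgate] ", ...)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  geom <- stage("synth", {
    g <- switch(config$synth$preset,
      pair = cluster_geometry(1, 2),
      chain3 = cluster_geometry(1, 3),
      chain5 = cluster_geometry(1, 5),
      grid6x10 = cluster_geometry(6, 10)
    )
    say("synth preset ", config$synth$preset, ", seed ", config$seed)
    g
  })
  sched <- stage("synth", make_schedule(
    geom, duration_ms = config$synth$duration_ms, seed = config$seed
  ))
  rec <- stage("synth", render_voltage(sched, geom,
                                       seed = config$seed + 1L))
  ai <- stage("signal", recording_intensity(rec))
  say("AI computed: ", nrow(ai), " bins x ", ncol(ai), " channels")
  bp <- stage("detect", {
    p <- burst_params(config$detect$preset)
    if (ncol(ai) < p$min_active_clusters) {
      p <- burst_params(config$detect$preset, min_active_clusters = 1)
    }
    p
  })
  nb <- stage("detect", {
    if (ncol(ai) >= 2) detect_bursts_network(ai, bp) else
      detect_bursts_channel(ai[, 1], bp)
  })
  say("detected ", nrow(nb$bursts), " network bursts")
  delays <- stage("analyze", {
    rows <- list()
    half <- 500
    for (b in seq_len(nrow(nb$bursts))) {
      pk <- nb$bursts$peak_ms[b]
      i0 <- max(1, round((pk - half) / nb$bin_ms))
      i1 <- min(nrow(ai), round((pk + half) / nb$bin_ms))
      if (i1 - i0 < 16) next
      for (ch in 2:ncol(ai)) {
        d <- burst_delay(ai[i0:i1, 1], ai[i0:i1, ch], nb$bin_ms)
        rows[[length(rows) + 1]] <- data.frame(
          burst_id = nb$bursts$burst_id[b], pair = paste0("1-", ch),
          lag_ms = d$lag_ms, corr = d$peak_corr
        )
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(burst_id = integer(0), pair = character(0),
                 lag_ms = numeric(0), corr = numeric(0))
  })
  say("computed ", nrow(delays), " pairwise burst delays")

  write_recording(rec, file.path(out_dir, "recording.csv"))
  write.csv(as.data.frame(ai), file.path(out_dir, "ai.csv"),
            row.names = FALSE)
  write_bursts(nb, file.path(out_dir, "bursts.csv"))
  write.csv(delays, file.path(out_dir, "delays.csv"), row.names = FALSE)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE)
  invisible(list(schedule = sched, recording = rec, ai = ai, bursts = nb,
                 delays = delays, config = config, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
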
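#!/usr/bin/env Rscript
# Validate the recording-analysis pipeline against known ground truth:
# generate surrogate MEA recordings, run noise-threshold estimation, burst
# detection and delay/asymmetry estimation, and compare with the schedule.

library(modgate)
dir.create("results", showWarnings = FALSE)

## --- connected pair: threshold, detection, delay recovery ---------------
geom <- cluster_geometry(1, 2)
sched <- make_schedule(geom, duration_ms = 180000, seed = 11)
rec <- render_voltage(sched, geom, seed = 12)
ai <- recording_intensity(rec)
nt <- attr(ai, "nt")
cat(sprintf("noise thresholds: %.1f / %.1f uV (quiet half-normal mean %.2f)\n",
            nt[1], nt[2], sqrt(2 / pi) * 10))

act <- sched$activations
rows <- lapply(1:2, function(ch) {
  nb <- detect_bursts_channel(ai[, ch], burst_params("channel"))
  sch <- act$onset_ms[act$cluster == ch]
  sens <- mean(vapply(sch, function(t)
    any(abs(nb$bursts$peak_ms - t) < 500), logical(1)))
  prec <- mean(vapply(nb$bursts$peak_ms, function(t)
    any(abs(sch - t) < 500), logical(1)))
  cat(sprintf("channel %d: %d/%d bursts found, sensitivity %.2f, precision %.2f\n",
              ch, nrow(nb$bursts), length(sch), sens, prec))
  data.frame(channel = ch, scheduled = length(sch),
             detected = nrow(nb$bursts), sensitivity = sens,
             precision = prec, noise_threshold = nt[ch])
})
write.csv(do.call(rbind, rows), "results/detection_recovery.csv",
          row.names = FALSE)

both <- merge(subset(act, cluster == 1), subset(act, cluster == 2),
              by = "burst_id", suffixes = c("_1", "_2"))
lags <- vapply(seq_len(nrow(both)), function(k) {
  pk <- both$onset_ms_1[k]
  i0 <- max(1, round((pk - 500) / 2))
  i1 <- min(nrow(ai), round((pk + 1000) / 2))
  burst_delay(ai[i0:i1, 1], ai[i0:i1, 2])$lag_ms
}, numeric(1))
truth <- both$onset_ms_2 - both$onset_ms_1
cat(sprintf("delay recovery on %d shared bursts: bias %.1f ms, median |err| %.1f ms\n",
            nrow(both), mean(lags - truth, na.rm = TRUE),
            median(abs(lags - truth), na.rm = TRUE)))
write.csv(data.frame(burst_id = both$burst_id, scheduled_ms = truth,
                     recovered_ms = lags),
          "results/delay_recovery.csv", row.names = FALSE)

## --- five-cluster chain: distance profiles and asymmetry ---------------
geom5 <- cluster_geometry(1, 5)
sched5 <- make_schedule(geom5, duration_ms = 240000, failure_prob = 0.25,
                        initiator_probs = c(0.6, 0.1, 0.1, 0.1, 0.1),
                        seed = 13)
rec5 <- render_voltage(sched5, geom5, seed = 14)
ai5 <- recording_intensity(rec5)
nbs <- lapply(1:5, function(ch) detect_bursts_channel(
  ai5[, ch], burst_params("channel")))
dp <- distance_profiles(ai5, nbs, geom5$positions,
                        breaks_um = seq(0, 2250, 500))
cat("\ndistance profiles (chain with biased initiation at cluster 1):\n")
print(dp, digits = 3)
write.csv(dp, "results/distance_profiles.csv", row.names = FALSE)

asym <- suppressWarnings(longterm_asymmetry(ai5[, 1], ai5[, 2]))
cat(sprintf("long-term asymmetry cluster 1 vs 2: %.2f (positive: 1 leads)\n",
            asym))
cat("correlation and transfer fall with distance while delays accumulate,\n")
cat("and the biased initiation shows up as a positive 1->2 asymmetry.\n")
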
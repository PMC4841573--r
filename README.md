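# modgate

Modular neuronal networks — two clusters of neurons joined by a sparse
bridge — do something uniform networks cannot: they *gate* activity.
A synchronized network burst (NB) born in one cluster crosses to its
neighbour only if it is strong enough, arrives with a delay of tens of
milliseconds set by recruitment rather than conduction, and the whole
repertoire of propagation patterns collapses to a stereotyped network-wide
wave when inhibition is blocked. `modgate` is an R package for studying
this regime, aimed at people modelling cultured cortical networks or
analysing multielectrode-array (MEA) recordings of clustered cultures.

It provides, as tested package code:

* **A two-cluster biophysical model** — 50 Morris-Lecar neurons per
  cluster (1 in 5 inhibitory), coupled by modified Tsodyks-Markram
  synapses whose resource recovery stalls near depletion
  (`-tan(1.2z - 1.2)` scaling) and whose inhibitory utilization
  facilitates during bursts. Modularity λ rewires intra-cluster edges into
  inter-cluster edges with probability λ (edge count conserved; expected
  inter/intra ratio λ/(1−λ)). Three bridge wirings (proportional,
  feed-forward, targeting inhibition) and the conditions
  control / inhibition block / local inhibition. Euler integration at
  0.1 ms with per-step Gaussian noise currents (μ = 7.55, σ = 4 µA/cm²),
  compiled in C++.
* **The MEA analysis pipeline** — activity intensity
  `AI = max(mean|V| − NT, 0)` with a kurtosis-filtered noise threshold
  (20-ms bins, cutoff 3.1); the window/threshold/gap burst-detection
  cascade (W = 100 ms, T = 10, G = 100 ms per channel; G = 1 s
  network-wide; W = 10 ms, T = 5, G = 50 ms for model rasters);
  cross-correlation delays; transfer probabilities with λ = 0 baseline
  correction, `P = (T − T0)/(N − T0)`; long-term asymmetry
  `(∫₊ − ∫₋)/(∫₊ + ∫₋)` of the rectified cross-correlation; burst
  similarity matrices and dendrogram grouping; activation-pattern entropy
  `E = −Σ Pᵢ log Pᵢ` normalised by `log(2^N − 1)`; the bimodality
  coefficient `(m₃² + 1)/(m₄ + 3(n−1)²/((n−2)(n−3)))`; propagation
  vectors and their circular variability.
* **A ground-truth generator** — surrogate burst schedules (initiators,
  hop delays, hop failures, pattern probabilities) rendered into 10-kHz
  multichannel voltage with spike waveforms and noise, so every analysis
  stage is validated against a known answer.

## Worked example

Simulate a weakly coupled pair (λ = 0.02), detect bursts in each cluster,
and measure transmission:

```r
library(modgate)
conn <- build_modular_connectivity(lambda = 0.02, seed = 42)
conn <- sample_strengths(conn)
sim  <- simulate_network(conn, simulation_config(duration_ms = 60000), seed = 43)

counts <- cluster_spike_counts(sim)          # 2-ms spike-count series
nb1 <- detect_bursts_channel(counts[, 1], burst_params("model"),
                             t0_ms = attr(counts, "t0_ms"))
nb2 <- detect_bursts_channel(counts[, 2], burst_params("model"),
                             t0_ms = attr(counts, "t0_ms"))
tr  <- transmitted_bursts(nb1$bursts, nb2$bursts)   # 200-ms window
c(bursts = nrow(nb1$bursts),
  transmitted = sum(!is.na(tr$delay_ms)),
  delay_ms = mean(tr$delay_ms, na.rm = TRUE))
#>      bursts transmitted    delay_ms
#>    38.00000    31.00000    38.19355
```

Cluster 1 fired 38 NBs in 55 s of analysed time; 31 recruited cluster 2
within 200 ms, with a mean peak-to-peak delay of ~38 ms — conditional
propagation: at this coupling some bursts cross the bridge and some stay
confined. Sweeping λ (see `sweep_modularity()`) takes the
baseline-corrected transfer probability from 0 (isolated clusters) to 1
(full transmission) over a narrow λ range, while delays shrink and the
between-cluster correlation of per-burst firing grows.

The numbered scripts under `analysis/` run the full set of studies —
`01_simulate_model.R` (burst regime of the model),
`02_modularity_sweep.R` (gating curves, control vs inhibition block),
`03_synthetic_recovery.R` (pipeline validation on surrogate recordings),
`04_patterns_entropy.R` (similarity groups, entropy, propagation
variability, bimodality) — and write their tables under `results/`.

## Scientific background

The model and the analysis definitions follow the published study of
engineered clustered cultures and their two-cluster Morris-Lecar /
Tsodyks-Markram model; the methods vignette
(`vignettes/modular-gating.Rmd`) documents every equation, parameter
table, algorithmic reading and numerical choice, and states what the
synthetic-data validation does and does not demonstrate.
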
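---
title: "Modular networks, burst propagation, and gating: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular networks, burst propagation, and gating: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modgate)
```

Cultured cortical neurons that self-organise into clusters joined by thin
neurite bundles form a minimal modular circuit: each cluster generates
synchronized network bursts (NBs) on its own, and whether a burst crosses
the bundle into the neighbouring cluster depends on the burst's strength,
the sparseness of the bridge, and the inhibition acting on it. `modgate`
implements both sides of the study of this system: a biophysical two-cluster
model whose modularity can be dialled continuously, and the complete
recording-analysis pipeline (activity intensity, burst detection,
delays, transfer probabilities, asymmetry, pattern statistics) together
with a ground-truth synthetic-recording generator used to validate the
pipeline.

## The network model

Each of the two clusters contains 50 Morris-Lecar neurons, one in five
inhibitory. The membrane follows

$$C_m \dot V = I_{ext} - g_{Ca} M_{SS}(V)(V - V_{Ca}) - g_K W (V - V_K)
 - g_L (V - V_L),$$

with the slow K$^+$ gate $\dot W = \phi\,(W_{SS}(V) - W)
\cosh\!\big(\tfrac{V - V_3}{2V_4}\big)$ and sigmoidal steady states
$M_{SS}, W_{SS}$ (`gating_steady_states()`). The parameters
(`neuron_params()`) put the cell in a class-I excitable regime: silent at
the mean drive, spiking from occasional noise fluctuations. The only
E/I difference is the doubled membrane capacitance of inhibitory cells.

Synapses are modified Tsodyks-Markram elements (`synapse_params()`,
`synapse_step()`): resources cycle between recovered ($x$), active ($y$) and
inactive ($z$) pools; a presynaptic spike moves a fraction $u$ of $x$ into
$y$, which decays with $\tau_d$ into $z$ and recovers with $\tau_{rec}$.
Two modifications matter:

* recovery is scaled by $-\tan(1.2 z - 1.2)$, so it *stalls* as the synapse
  approaches full depletion — this prevents the runaway tonic firing that a
  linear recovery produces at high rates;
* inhibitory synapses facilitate: $u$ is dynamic, incremented by
  $U_0 (1 - u)$ per spike and decaying with $\tau_{facil} = 1$ s, so
  inhibition grows *within* a burst.

Excitatory strengths are $A = 6.25$ mV (E$\to$E) and $10$ mV (E$\to$I);
inhibitory strengths come in the published low/high variants selected by
`inhibition_level` (`low`: $|A| = 10$, $\tau_d = 6$; `high_A`: $|A| = 20$;
`high_tau`: $\tau_d = 12$). Per-synapse strengths are drawn from a Gaussian
(mean $A_{nom}$, SD $A_{nom}/2$) truncated by redrawing to
$[0.8, 1.2]\,A_{nom}$, so the accepted mean equals $A_{nom}$.

Every neuron receives an i.i.d. Gaussian noise current ($\mu = 7.55$,
$\sigma = 4$ µA/cm²) redrawn at *every* Euler step, exactly as specified
for the original model. Because the draw is per step with no $\sqrt{dt}$
scaling, the effective noise bandwidth is tied to the integration step;
we document this rather than "correct" it, since the published dynamics
were obtained under the same convention at $dt = 0.1$ ms. Changing `dt`
therefore changes the effective noise, and `dt` should be left at its
default for quantitative comparisons.

### Connectivity and modularity

`build_modular_connectivity()` starts from independent intra-cluster
Bernoulli wiring (densities 0.25 and 0.2 for the two clusters, zero between
clusters) and then *replaces* each intra-cluster edge, independently with
probability $\lambda$, by an edge to a uniformly chosen target in the other
cluster. Replacement conserves the total synapse count, and the expected
inter/intra count ratio is $\lambda/(1-\lambda)$ per synapse class. At
$\lambda = 0$ the clusters are isolated; at $\lambda = 0.5$ intra and inter
connectivity are equal and the modular structure dissolves. Three wiring
schemes control the bridge's inhibition (proportional, feed-forward with
matched inter E$\to$I and E$\to$E counts, and direct targeting in which
bridge-receiving inhibitory neurons contact only excitatory cells), and the
`condition` reproduces pharmacology: `inhibition_block` zeroes all
inhibitory strengths, `local_inhibition` only the inter-cluster ones.

### Choices the original description leaves open

* **Spike time**: upward crossing of $V = 10$ mV with a 2-ms lockout.
  Spikes in this regime peak near $+30$ mV, so the threshold is
  unambiguous; the lockout prevents double counting on coarse Euler steps.
* **Transmission**: instantaneous — spikes reach efferent synapses with no
  axonal delay. Inter-cluster delays in this preparation are attributed to
  recruitment inside the receiving cluster, not to conduction.
* **Initial conditions**: $V \sim U(-50, -30)$ mV, $W = W_{SS}(V)$,
  synapses fully recovered, dynamic $u = U_0$; a 5-s warm-up is discarded
  by the analysis helpers (`warmup_ms`). Burst statistics are insensitive
  to the start once the warm-up is dropped.
* **Simplex clamping**: after each Euler step $x, y, z$ are clamped to
  $[0,1]$ and renormalised; the tangent recovery term is only defined for
  $z \in [0, 1]$. The raw Euler update conserves $x+y+z$ exactly (the flux
  terms cancel), and the simulator tracks the worst-case deviation
  (`conservation_error`, typically $\sim 10^{-16}$).
* **Synapse state per presynaptic neuron**: all efferent synapses of a
  neuron share identical kinetics in this model (only $A$ differs by
  target), so the compiled core integrates one resource state per neuron —
  an exact optimisation, not an approximation.

## The recording pipeline

**Activity intensity (AI).** Each channel's voltage is reduced to
2-ms bins: $A = \overline{|V|} - NT$, clipped at zero. The noise threshold
$NT$ is the mean $|V|$ over 20-ms bins whose unbiased (non-excess,
Gaussian = 3) kurtosis stays at or below 3.1. The logic of the kurtosis
filter is worth spelling out: bins containing *sparse* spikes are
super-Gaussian and are rejected, while *dense* multi-unit burst activity is
a superposition of many waveforms and is itself near-Gaussian, so burst
cores are retained and pull $NT$ above the quiet-noise level. On recordings
that contain bursts this puts quiet bins safely below threshold. On a
recording with *no* activity at all, $NT$ converges to the half-normal mean
of the noise and, by symmetry, about half of the quiet bins end up
marginally positive — the AI representation presupposes recordings that
contain activity, and the detection suite validates it in that regime.

**Burst detection** (`detect_bursts_channel()`, `detect_bursts_network()`)
follows the published cascade: count active bins in 100-ms windows sliding
by 10 ms, zero counts below $T = 10$, convolve the thresholded count series
a second time with the same boxcar and binarise at 1 (this recovers burst
edges), take runs as candidates, merge candidates closer than $G$
(100 ms per channel, 1 s network-wide), then refine start/end as the first
and last non-zero AI bin and the peak as the earliest maximum of the
50-ms-smoothed trace. The model preset ($W = 10$ ms, $T = 5$, $G = 50$ ms)
operates on per-cluster spike counts — smoother profiles, no noise floor.
Because the merge step operates on the boxcar-extended candidates (as the
published order of operations states), two activity blocks must be
separated by roughly $G + W$ of silence to remain distinct.

**Propagation statistics.** Delays are the lag of the Pearson-normalised
cross-covariance of 10-ms-smoothed AI traces (ties broken towards zero
lag; ±500 ms search window; the long-term asymmetry integrates the
rectified cross-correlation over ±2 s). The model's inter-cluster delay is
instead the lag between the two clusters' burst peaks, as stated for that
analysis. The model transfer probability counts a cluster-1 burst as
transmitted when a cluster-2 burst *peak* falls within 200 ms after the
cluster-1 burst *onset* ("activation" is read as onset; the subsequent
peak-to-peak lag is the delay). Chance coincidences of two spontaneously
active clusters are removed by subtracting the $\lambda = 0$ transmitted
count $T_0$ from both numerator and denominator,
$P = (T - T_0)/(N - T_0)$, clamped to $[0, 1]$; the subtraction uses
pooled counts over realisations so that $P(\lambda{=}0) = 0$ by
construction. The denominator reading ($N - T_0$ rather than $N - N_0$) is
switchable in `transfer_probability_model()` by passing a different
baseline.

**Pattern statistics.** Burst similarity is the lag-maximised channel-mean
normalised cross-covariance of 1-s AI snippets around burst peaks
(time-shift invariant by construction); groups come from average-linkage
hierarchical clustering on Euclidean distances between similarity rows,
with the group count a user parameter (the published grouping was cut by
inspection). Pattern entropy uses empirical probabilities of binary
cluster-activation patterns, normalised by $\log(2^N - 1)$; the log base is
a parameter because the published formula is written in bits while its
printed worked value (1.006 for $P = 0.137, 0.673, 0.103, 0.005, 0.082$)
is reproduced by the natural logarithm — both are exposed, and nats are
used where that worked value is compared. The bimodality coefficient uses
bias-corrected skewness and *excess* kurtosis, which makes the uniform
reference equal the customary 0.555 ($=5/9$) benchmark.

## The synthetic-data generator

`make_schedule()` and `render_voltage()` produce surrogate MEA recordings
whose every property is known. Bursts arrive as a renewal process (2-s
refractory floor plus exponential gaps, 0.25 Hz nominal rate — typical for
these cultures); each burst starts at an initiating cluster and spreads
along the grid with per-hop Gaussian delays (30 ± 5 ms, the observed
tens-of-ms scale) and independent per-hop failures (probability 0.2),
or follows an explicit pattern-probability table. Rendering drives an
inhomogeneous Poisson spike train per channel — population rate 8000
spikes/s at the envelope peak, the superposition regime of a cluster of
order $10^2$ neurons bursting at tens of Hz each — with biphasic 1.2-ms
waveforms of 100 µV nominal amplitude over 10-µV Gaussian noise, plus
sporadic background spikes at 2 Hz. These defaults were chosen once, for
realism of the regime (dense near-Gaussian burst cores that the kurtosis
filter retains, sparse super-Gaussian single spikes that it rejects), and
the validation suite then asks whether the pipeline recovers the schedule:
detection sensitivity and precision ≥ 0.95, mean delay recovery within one
AI bin, entropy recovery within bootstrap error.

What the generator does *not* emulate: electrode-to-electrode gain
variation, non-stationary noise, correlated noise across channels, spike
waveform diversity and overlap artefacts, and the slow developmental
drift of real cultures. Passing the recovery suite therefore shows the
pipeline is correct *given* the intended signal model, not that it is
robust to every pathology of real recordings.

## Problem sizes and tolerances

The packaged analyses and tests run at deliberately scaled sizes: 60-s
simulations (vs 300 s in the original description), two network
realisations per modularity value (vs 20), and minutes-long surrogate
recordings. At these sizes the gating curve is already saturated (transfer
probability 0 at $\lambda = 0$, 1 at $\lambda = 0.15$ under low
proportional inhibition) and all recovery targets hold; statistical
assertions use 3-standard-error bands or bootstrap error where an estimator
is stochastic. Exact determinism is promised (and tested) for fixed seeds:
connectivity, simulation, schedule and rendering are all seedable.

## Known limitations

* The per-step noise convention ties dynamics to `dt` (above).
* Burst-free recordings defeat the kurtosis noise threshold (above); the
  threshold estimator warns below 100 kurtosis bins of data.
* The similarity matrix is $O(n^2)$ in bursts with an FFT per channel
  pair; thousands of bursts call for snippet subsampling.
* The model is strictly two-cluster; chains and grids exist only on the
  synthetic-recording side.
* The leaky integrate-and-fire variant of the model and
  Ornstein-Uhlenbeck noise are out of scope.
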
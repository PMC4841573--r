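test_that("lagged Pearson matches the brute-force correlation at every lag", {
  set.seed(1)
  x <- abs(rnorm(400)); y <- abs(rnorm(400))
  lp <- lagged_pearson(x, y, 60)
  expect_equal(lp$r, brute_lagged_pearson(x, y, 60), tolerance = 1e-10)
})

test_that("burst delay recovers constructed shifts with correct sign", {
  a <- bump_ai(1000, 500)
  expect_equal(burst_delay(a, a)$lag_ms, 0)
  b <- bump_ai(1000, 515)           # b activates 30 ms after a: a leads
  d <- burst_delay(a, b)
  expect_equal(d$lag_ms, 30, tolerance = 2)
  expect_gt(d$peak_corr, 0.99)
  d_rev <- burst_delay(b, a)
  expect_equal(d_rev$lag_ms, -30, tolerance = 2)
})

test_that("delay ties resolve to the smallest |lag|", {
  # two identical bumps 100 ms apart in both traces: correlation has equal
  # peaks at 0 and +-50 bins; the zero lag must win
  a <- bump_ai(1200, 500, 5) + bump_ai(1200, 550, 5)
  d <- burst_delay(a, a, smooth_sigma_ms = 4)
  expect_equal(d$lag_ms, 0)
  # a flat (zero-variance) trace has no defined delay
  expect_true(is.na(burst_delay(rep(2, 100), a[1:100])$lag_ms))
})

test_that("sender classification keeps only sender-leading bursts", {
  expect_equal(classify_sender(c(10, 5, 22))$kept, 1:3)
  expect_equal(length(classify_sender(c(-10, -5))$kept), 0)
  delays <- c(12, -3, 8, -1, 4, 30, -9, 2, 15, -20)
  cs <- classify_sender(delays)
  expect_equal(length(cs$kept), 6)
  expect_true(all(delays[cs$kept] > 0))
  expect_equal(sort(c(cs$kept, cs$rejected)), 1:10)
  expect_true(2 %in% classify_sender(c(1, NA, 3))$rejected)
})

test_that("conditional propagation map reflects the sender-receiver law", {
  set.seed(2)
  send <- runif(200, 10, 40)
  cm_id <- conditional_propagation_map(send, send)
  expect_equal(cm_id$correlation, 1)
  expect_true(all(abs(colSums(cm_id$map) - 1) < 1e-12 |
                    colSums(cm_id$map) == 0))
  # permutation oracle: shuffled pairs decorrelate
  cm_sh <- conditional_propagation_map(send, sample(send))
  expect_lt(abs(cm_sh$correlation), 2 / sqrt(200) * 2.5)
  expect_warning(conditional_propagation_map(1:10, 1:10), "low power")
})

test_that("a threshold rule produces a bimodal identity projection", {
  set.seed(3)
  send <- runif(400, 0.5, 1.5)
  recv <- ifelse(send > 1, send + rnorm(400, 0, 0.05),
                 abs(rnorm(400, 0.03, 0.02)))
  proj <- identity_projection(send / sd(send), recv / sd(recv))
  expect_gt(bimodality_coefficient(proj), bimodality_reference())
  cm <- conditional_propagation_map(send, recv)
  expect_gt(cm$correlation, 0.5)
})

test_that("recording transfer probability counts windowed coincidences", {
  a <- data.frame(start_ms = seq(1000, 10000, by = 1000))
  expect_equal(transfer_probability_recording(a, a), 1)      # mirror
  none <- data.frame(start_ms = numeric(0))
  expect_equal(transfer_probability_recording(a, none), 0)
  expect_true(is.na(transfer_probability_recording(none, a)))
  b <- data.frame(start_ms = a$start_ms[1:7] + 400)          # 7 of 10 followed
  expect_equal(transfer_probability_recording(a, b), 0.7)
})

test_that("model transfer probability applies the baseline correction", {
  expect_equal(transfer_probability_model(3, 10, 3), 0)      # T = T0
  expect_equal(transfer_probability_model(10, 10, 0), 1)     # full transfer
  expect_equal(transfer_probability_model(6, 10, 1), 5 / 9)
  expect_equal(transfer_probability_model(0, 10, 2), 0)      # clamped low
  expect_true(is.na(transfer_probability_model(2, 3, 3)))    # N <= T0
})

test_that("transmitted bursts use the 200-ms peak window after onset", {
  b1 <- data.frame(burst_id = 1:3, start_ms = c(1000, 5000, 9000),
                   peak_ms = c(1040, 5040, 9040))
  b2 <- data.frame(burst_id = 1:2, start_ms = c(1080, 5400),
                   peak_ms = c(1120, 5450))
  tr <- transmitted_bursts(b1, b2, window_ms = 200)
  expect_equal(tr$delay_ms, c(80, NA, NA))   # peak-to-peak lag; 5450 > +200
})

test_that("long-term asymmetry is signed, bounded and antisymmetric", {
  # symmetric construction -> 0
  a <- bump_ai(4000, 2000, 4)
  expect_equal(suppressWarnings(longterm_asymmetry(a, a, max_lag_ms = 200)), 0)
  # all correlation mass at positive lags -> ~ +1, and exactly mirrored
  b <- bump_ai(4000, 2015, 4)
  asym <- suppressWarnings(longterm_asymmetry(a, b, max_lag_ms = 200))
  expect_gt(asym, 0.98)
  expect_equal(asym,
               -suppressWarnings(longterm_asymmetry(b, a, max_lag_ms = 200)),
               tolerance = 1e-12)
})

test_that("asymmetry of a mixed-direction pair matches the brute force", {
  set.seed(4)
  n <- 30000
  a <- numeric(n); b <- numeric(n)
  onsets <- seq(200, n - 200, by = 150)
  lead <- runif(length(onsets)) < 0.7          # a leads in 70% of bursts
  for (k in seq_along(onsets)) {
    t <- onsets[k]
    sh <- if (lead[k]) 10 else -10             # +-20 ms on the 2-ms grid
    a[t + (-15:15)] <- a[t + (-15:15)] + dnorm(-15:15, 0, 4)
    b[t + sh + (-15:15)] <- b[t + sh + (-15:15)] + dnorm(-15:15, 0, 4)
  }
  asym <- suppressWarnings(longterm_asymmetry(a, b, max_lag_ms = 100))
  expect_gt(asym, 0.1)                         # majority direction dominates
  expect_equal(asym, brute_asymmetry(a, b, 50), tolerance = 1e-10)
  # collapsing the schedule onto one direction strengthens the asymmetry
  b1 <- numeric(n)
  for (k in seq_along(onsets)) {
    t <- onsets[k] + 10
    b1[t + (-15:15)] <- b1[t + (-15:15)] + dnorm(-15:15, 0, 4)
  }
  expect_gt(suppressWarnings(longterm_asymmetry(a, b1, max_lag_ms = 100)),
            asym)
})

test_that("propagation vectors point along constructed flows", {
  geom <- cluster_geometry(1, 2)   # neighbour due east
  ai <- cbind(bump_ai(800, 400), bump_ai(800, 425))  # east lags by 50 ms
  pv <- propagation_vector(ai, 1, geom$adjacency[[1]], geom$positions)
  expect_equal(pv$theta, 0, tolerance = 1e-9)
  expect_equal(pv$magnitude_ms, 50, tolerance = 2)
  # two opposite neighbours with equal lags cancel
  geom3 <- cluster_geometry(1, 3)
  lagged <- bump_ai(800, 425)
  ai3 <- cbind(lagged, bump_ai(800, 400), lagged)
  pv3 <- propagation_vector(ai3, 2, geom3$adjacency[[2]], geom3$positions)
  expect_true(is.na(pv3$theta))
})

test_that("a planar wave aligns every propagation vector with its direction", {
  geom <- cluster_geometry(3, 4)
  nbin <- 800
  ai <- vapply(seq_len(12), function(c_) {
    onset <- 200 + geom$positions$x_um[c_] / 500 * 15  # +x wave, 30 ms/hop
    dnorm(seq_len(nbin), onset, 20) * 100
  }, numeric(nbin))
  th <- vapply(seq_len(12), function(c_) {
    propagation_vector(ai, c_, geom$adjacency[[c_]], geom$positions)$theta
  }, numeric(1))
  expect_true(all(abs(th) < 0.05))
  # variability: identical directions give ~0; mixed directions give more
  thetas_same <- matrix(rep(th, 5), nrow = 5, byrow = TRUE)
  expect_lt(propagation_variability(thetas_same), 0.05)
  set.seed(6)
  thetas_mixed <- matrix(runif(60, -pi, pi), nrow = 5)
  expect_gt(propagation_variability(thetas_mixed),
            propagation_variability(thetas_same))
})

test_that("distance profiles recover chain attenuation and delay growth", {
  set.seed(7)
  geom <- cluster_geometry(1, 5)
  nbin <- 60000                       # 2 minutes on the 2-ms grid
  hop_bins <- 15                      # 30 ms per hop
  q <- 0.75                           # per-hop success probability
  onsets <- seq(500, nbin - 500, by = 1500)
  ai <- matrix(0, nbin, 5)
  for (t in onsets) {
    reach <- 1
    while (reach < 5 && runif(1) < q) reach <- reach + 1
    for (c_ in 1:reach) {
      at <- t + (c_ - 1) * hop_bins
      ai[, c_] <- ai[, c_] + dnorm(seq_len(nbin), at, 10) * 60
    }
  }
  ai[ai < 1e-3] <- 0
  nbs <- lapply(1:5, function(c_) detect_bursts_channel(
    ai[, c_], burst_params("channel", T_count = 5)))
  dp <- distance_profiles(ai, nbs, geom$positions,
                          breaks_um = seq(0, 2250, 500))
  expect_equal(nrow(dp), 4)
  expect_true(all(diff(dp$correlation) < 0))   # correlation falls
  expect_true(all(diff(dp$transfer_prob) < 0)) # transfer decays with hops
  expect_gt(dp$delay_ms[2], dp$delay_ms[1])    # delay grows with distance
  # shuffled positions destroy the distance trend
  pos_sh <- geom$positions
  set.seed(8)
  pos_sh$x_um <- sample(pos_sh$x_um)
  dp_sh <- distance_profiles(ai, nbs, pos_sh, breaks_um = seq(0, 2250, 500))
  tr <- cor(dp$distance_um, dp$transfer_prob, method = "spearman")
  tr_sh <- cor(dp_sh$distance_um, dp_sh$transfer_prob, method = "spearman")
  expect_gt(abs(tr), abs(tr_sh))
})

test_that("rate correlation is 1 for mirrored counts and ~0 when unlinked", {
  sim <- cached_model_sim(lambda = 0, duration_ms = 20000, seed = 71)
  counts <- cluster_spike_counts(sim)
  t0 <- attr(counts, "t0_ms")
  nb1 <- detect_bursts_channel(counts[, 1], burst_params("model"), t0_ms = t0)
  rc <- suppressWarnings(rate_correlation_model(sim, nb1$bursts))
  n <- nrow(nb1$bursts)
  expect_gt(n, 4)
  expect_lt(abs(rc), 3 / sqrt(n))       # disconnected clusters: independence
  # mirrored counts: relabel cluster 2 spikes as copies of cluster 1
  sim2 <- sim
  sp1 <- sim$spikes[sim$conn$cluster_of[sim$spikes$neuron] == 1, ]
  sp2 <- sp1; sp2$neuron <- sp2$neuron + 50
  sim2$spikes <- rbind(sp1, sp2)
  rc2 <- suppressWarnings(rate_correlation_model(sim2, nb1$bursts,
                                                 window_ms = 0))
  expect_equal(rc2, 1, tolerance = 1e-9)
})

test_that("propagation speed is the plain distance/delay quotient", {
  expect_equal(propagation_speed(500, 100), 5)
  expect_equal(propagation_speed(1000, 40), 25)
})
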
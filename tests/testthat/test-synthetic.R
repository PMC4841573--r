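test_that("cell counts follow the area calibration with clamping", {
  expect_equal(cells_from_area(1000), 6.0)
  expect_equal(cells_from_area(10000), 77.1)
  expect_equal(cells_from_area(100), 0)       # raw value -1.11, clamped
  expect_equal(cells_from_area(0), 0)
  expect_error(cells_from_area(-5), "non-negative")
})

test_that("geometry lays clusters on the grid with 4-neighbour adjacency", {
  geom <- cluster_geometry(6, 10, 500)
  expect_equal(nrow(geom$positions), 60)
  expect_equal(max(geom$positions$x_um), 9 * 500)
  expect_equal(max(geom$positions$y_um), 5 * 500)
  expect_equal(sort(geom$adjacency[[1]]), c(2, 11))          # corner
  expect_equal(sort(geom$adjacency[[12]]), c(2, 11, 13, 22)) # interior
  expect_true(all(geom$cells >= 0))
})

test_that("hop failures truncate participation as scheduled", {
  geom <- cluster_geometry(1, 5)
  all_in <- make_schedule(geom, duration_ms = 120000, failure_prob = 0,
                          seed = 1)
  per <- table(all_in$activations$burst_id)
  expect_true(all(per == 5))                  # no failures: every cluster
  confined <- make_schedule(geom, duration_ms = 120000, failure_prob = 1,
                            seed = 2)
  per2 <- table(confined$activations$burst_id)
  expect_true(all(per2 == 1))                 # all hops fail: initiator only
  expect_equal(confined$activations$onset_ms - confined$bursts$t0_ms,
               rep(0, nrow(confined$bursts)))
})

test_that("onsets are consistent with hop delays along the chain", {
  geom <- cluster_geometry(1, 4)
  s <- make_schedule(geom, duration_ms = 300000, failure_prob = 0,
                     hop_delay_mean_ms = 30, hop_delay_sd_ms = 0, seed = 3)
  act <- s$activations
  for (b in unique(act$burst_id)) {
    d <- act[act$burst_id == b, ]
    d <- d[order(d$cluster), ]
    init <- s$bursts$initiator[s$bursts$burst_id == b]
    hops <- abs(d$cluster - init)
    expect_equal(d$onset_ms - min(d$onset_ms), hops * 30, tolerance = 1e-9)
  }
})

test_that("scheduled pattern probabilities reproduce the target entropy", {
  geom <- cluster_geometry(1, 3)
  pp <- list(patterns = rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(0, 1, 1)),
             probs = c(0.4, 0.3, 0.2, 0.1))
  target <- -sum(pp$probs * log2(pp$probs))
  s <- make_schedule(geom, duration_ms = 3e6, rate_hz = 2, min_gap_ms = 100,
                     pattern_probs = pp, seed = 4)
  pats <- vapply(split(s$activations$cluster, s$activations$burst_id),
                 function(cl) paste(as.integer(1:3 %in% cl), collapse = ""),
                 character(1))
  n <- length(pats)
  expect_gt(n, 500)
  emp <- pattern_entropy(
    do.call(rbind, lapply(strsplit(pats, ""), as.integer)))
  # bootstrap standard error of the plug-in entropy estimator
  boot <- replicate(200, {
    idx <- sample(n, replace = TRUE)
    tab <- table(pats[idx]) / n
    -sum(tab * log2(tab))
  })
  expect_lt(abs(emp$entropy - target), 3 * max(sd(boot), 1e-3))
})

test_that("schedules are reproducible and sensible", {
  geom <- cluster_geometry(1, 2)
  s1 <- make_schedule(geom, duration_ms = 100000, seed = 5)
  s2 <- make_schedule(geom, duration_ms = 100000, seed = 5)
  expect_identical(s1$activations, s2$activations)
  expect_true(all(diff(s1$bursts$t0_ms) >= s1$params$min_gap_ms))
  expect_warning(make_schedule(geom, duration_ms = 1000, rate_hz = 0.1),
                 "below 1")
})

test_that("noise-only rendering reproduces the half-normal threshold", {
  geom <- cluster_geometry(1, 2)
  empty <- make_schedule(geom, duration_ms = 60000, rate_hz = 0.25, seed = 6)
  empty$activations <- empty$activations[0, ]
  empty$bursts <- empty$bursts[0, ]
  rec <- suppressWarnings(render_voltage(empty, geom, sporadic_rate_hz = 0,
                                         seed = 7))
  nt <- as.numeric(estimate_noise_threshold(rec$volts[, 1]))
  expect_equal(nt, sqrt(2 / pi) * 10, tolerance = 0.1)
})

test_that("detection recovers the schedule at default SNR", {
  fix <- cached_pair_recording()
  act <- fix$sched$activations
  for (ch in 1:2) {
    nb <- detect_bursts_channel(fix$ai[, ch], burst_params("channel"))
    sch <- act$onset_ms[act$cluster == ch]
    sens <- mean(vapply(sch, function(t)
      any(abs(nb$bursts$peak_ms - t) < 500), logical(1)))
    prec <- mean(vapply(nb$bursts$peak_ms, function(t)
      any(abs(sch - t) < 500), logical(1)))
    expect_gte(sens, 0.95)
    expect_gte(prec, 0.95)   # no bursts reported in silent epochs
  }
})

test_that("scheduled hop delays are recovered from the rendered pair", {
  fix <- cached_pair_recording()
  act <- fix$sched$activations
  both <- merge(subset(act, cluster == 1), subset(act, cluster == 2),
                by = "burst_id", suffixes = c("_1", "_2"))
  expect_gt(nrow(both), 10)
  lags <- vapply(seq_len(nrow(both)), function(k) {
    pk <- both$onset_ms_1[k]
    i0 <- max(1, round((pk - 500) / 2))
    i1 <- min(nrow(fix$ai), round((pk + 1000) / 2))
    burst_delay(fix$ai[i0:i1, 1], fix$ai[i0:i1, 2])$lag_ms
  }, numeric(1))
  sched <- both$onset_ms_2 - both$onset_ms_1
  # mean recovery within one AI bin of the scheduled ground truth
  expect_lt(abs(mean(lags - sched, na.rm = TRUE)), 2)
  expect_lt(median(abs(lags - sched), na.rm = TRUE), 6)
})

test_that("doubling the burst voltage amplitude doubles burst intensity", {
  geom <- cluster_geometry(1, 2)
  sched <- make_schedule(geom, duration_ms = 120000, amplitude_sd = 0,
                         seed = 8)
  # same seed: identical spike trains, only the waveform amplitude differs;
  # high SNR so the subtracted threshold is negligible against the signal
  rec1 <- render_voltage(sched, geom, noise_sigma_uv = 1,
                         spike_amp_uv = 400, seed = 9)
  rec2 <- render_voltage(sched, geom, noise_sigma_uv = 1,
                         spike_amp_uv = 800, seed = 9)
  nt <- 10  # common fixed threshold isolates the amplitude effect
  ai1 <- activity_intensity(rec1$volts[, 1], nt, rec1$rate_hz)
  ai2 <- activity_intensity(rec2$volts[, 1], nt, rec2$rate_hz)
  nb1 <- detect_bursts_channel(ai1, burst_params("channel"))
  nb2 <- detect_bursts_channel(ai2, burst_params("channel"))
  expect_equal(nrow(nb1$bursts), nrow(nb2$bursts))
  ratio <- sum(nb2$bursts$intensity) / sum(nb1$bursts$intensity)
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("distinct seeds give exchangeable summary distributions", {
  geom <- cluster_geometry(1, 2)
  s1 <- make_schedule(geom, duration_ms = 600000, seed = 10)
  s2 <- make_schedule(geom, duration_ms = 600000, seed = 11)
  ks <- suppressWarnings(
    stats::ks.test(diff(s1$bursts$t0_ms), diff(s2$bursts$t0_ms)))
  expect_gt(ks$p.value, 0.001)
})
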
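make_snippets <- function(truth, templates, noise_sd = 0.15, seed = 1) {
  set.seed(seed)
  lapply(truth, function(k) {
    templates[[k]] +
      matrix(abs(rnorm(length(templates[[k]]), 0, noise_sd)),
             nrow(templates[[k]]))
  })
}

chain_templates <- function(n_groups = 3, nbin = 250, nchan = 3) {
  lapply(seq_len(n_groups), function(k) {
    m <- matrix(0, nbin, nchan)
    for (ch in seq_len(nchan)) {
      ctr <- 50 + 40 * ((ch + k) %% 3) + 10 * ch
      m[, ch] <- dnorm(seq_len(nbin), ctr, 12) * 50 * ((k + ch) %% 2 + 0.5)
    }
    m
  })
}

test_that("identical and time-shifted bursts have similarity one", {
  # bump fully inside the window both before and after the 100-ms shift
  tpl <- vapply(1:3, function(ch) dnorm(1:250, 125 + 5 * ch, 12) * 40,
                numeric(250))
  shifted <- rbind(tpl[51:250, ], matrix(0, 50, 3))
  sm <- burst_similarity(list(tpl, tpl, shifted), bin_ms = 2)
  expect_equal(sm$R[1, 2], 1, tolerance = 1e-6)
  expect_gt(sm$R[1, 3], 0.999)                 # lag-max removes the shift
  expect_true(isSymmetric(sm$R))
  expect_equal(diag(sm$R), rep(1, 3))
  expect_equal(unname(diag(sm$D)), rep(0, 3))
})

test_that("independent noise snippets are near-orthogonal", {
  set.seed(2)
  snips <- lapply(1:6, function(k) matrix(abs(rnorm(600)), 200, 3))
  sm <- burst_similarity(snips, bin_ms = 2, max_lag_ms = 40,
                         smooth_sigma_ms = 1)
  off <- sm$R[upper.tri(sm$R)]
  # the lag-max inflates chance similarity above 0, but it stays small
  expect_lt(max(off), 0.35)
})

test_that("similarity is invariant to global amplitude rescaling", {
  tpls <- chain_templates()
  snips <- make_snippets(c(1, 2, 3, 1), tpls, seed = 3)
  sm1 <- burst_similarity(snips)
  sm2 <- burst_similarity(lapply(snips, function(s) 7.3 * s))
  expect_equal(sm1$R, sm2$R, tolerance = 1e-10)
})

test_that("clustering recovers planted burst groups", {
  truth <- rep(1:3, each = 15)
  snips <- make_snippets(truth, chain_templates(), seed = 4)
  sm <- burst_similarity(snips, k = 3)
  tab <- table(truth, sm$groups)
  accuracy <- sum(apply(tab, 1, max)) / length(truth)
  expect_gte(accuracy, 0.95)
  cv <- group_similarity_cv(sm)
  expect_true(all(is.finite(cv)))
  expect_true(all(cv < 0.5))
})

test_that("pattern entropy handles the degenerate and equiprobable cases", {
  single <- matrix(rep(c(1, 0, 1), 10), ncol = 3, byrow = TRUE)
  expect_equal(pattern_entropy(single)$entropy, 0)
  two <- rbind(matrix(rep(c(1, 0), 5), ncol = 2, byrow = TRUE),
               matrix(rep(c(1, 1), 5), ncol = 2, byrow = TRUE))
  ps <- pattern_entropy(two)
  expect_equal(ps$entropy, 1)                        # 1 bit
  expect_equal(ps$normalized, 1 / log2(3))           # N = 2 -> Emax = log2(3)
  expect_error(pattern_entropy(matrix(0, 2, 3)), "all-zero")
  expect_error(pattern_entropy(matrix(numeric(0), 0, 3)), "no bursts")
})

test_that("entropy is invariant to relabeling and shrinks under merging", {
  set.seed(5)
  pats <- matrix(rbinom(300, 1, 0.5), 100, 3)
  pats[rowSums(pats) == 0, 1] <- 1
  e1 <- pattern_entropy(pats)$entropy
  e2 <- pattern_entropy(pats[, c(3, 1, 2)])$entropy  # relabel clusters
  expect_equal(e1, e2)
  # coarsening: merge clusters 2 and 3 into one column (data processing)
  merged <- cbind(pats[, 1], pmax(pats[, 2], pats[, 3]))
  expect_lte(pattern_entropy(merged)$entropy, e1)
})

test_that("the printed worked example reproduces in nats", {
  p <- c(0.137, 0.673, 0.103, 0.005, 0.082)
  ps <- pattern_entropy(probs = p, n_clusters = 3, base = "nats")
  expect_equal(ps$entropy, 1.006, tolerance = 0.002)
  # the same probabilities in bits give a different number (log-base choice)
  expect_equal(pattern_entropy(probs = p, n_clusters = 3)$entropy,
               -sum(p * log2(p)))
})

test_that("bimodality coefficient converges to its analytic references", {
  set.seed(6)
  n <- 1e4
  expect_equal(bimodality_coefficient(runif(n)), 5 / 9, tolerance = 0.02)
  expect_equal(bimodality_coefficient(rnorm(n)), 1 / 3, tolerance = 0.02)
  expect_equal(bimodality_coefficient(sample(c(-1, 1), n, TRUE)), 1,
               tolerance = 0.02)
  expect_equal(bimodality_reference(), 5 / 9)
  expect_error(bimodality_coefficient(rep(1, 10)), "variance")
  expect_error(bimodality_coefficient(1:3), "at least 4")
})

test_that("identity projection is the symmetric diagonal coordinate", {
  expect_equal(identity_projection(1, 1), sqrt(2))
  expect_equal(identity_projection(0, 0), 0)
  expect_equal(identity_projection(3, 7), identity_projection(7, 3))
})

test_that("burst sizes and bounding areas normalise per network", {
  base <- block_ai(3000, list(c(1001, 1100)))
  # burst 1: all 6 channels of a 2x3 grid; burst 2: single channel
  ai <- vapply(1:6, function(ch) {
    b2 <- if (ch == 1) list(c(2501, 2600)) else list()
    block_ai(3000, c(list(c(1001, 1100)), b2))
  }, numeric(3000))
  geom <- cluster_geometry(2, 3, pitch_um = 500)
  nb <- detect_bursts_network(ai, burst_params("network",
                                               min_active_clusters = 1))
  st <- burst_size_stats(nb, geom$positions)
  expect_equal(nrow(st), 2)
  expect_equal(st$n_active, c(6, 1))
  expect_equal(st$bounding_area_um2, c(1000 * 500, 0))  # full grid; point
  expect_equal(st$n_active_norm, c(1, 1 / 6))
  expect_equal(st$bounding_area_norm, c(1, 0))
  expect_equal(max(st$intensity_per_cluster_norm), 1)
})

test_that("a full 6x10 grid burst has the published bounding area", {
  geom <- cluster_geometry(6, 10, pitch_um = 500)
  ai <- vapply(1:60, function(ch) block_ai(3000, list(c(1001, 1100))),
               numeric(3000))
  nb <- detect_bursts_network(ai, burst_params("network"))
  st <- burst_size_stats(nb, geom$positions)
  expect_equal(st$bounding_area_um2, (9 * 500) * (5 * 500))
  expect_equal(st$bounding_area_norm, 1)
})
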
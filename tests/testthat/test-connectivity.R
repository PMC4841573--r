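test_that("isolated clusters at lambda = 0: no inter edges, correct census", {
  conn <- build_modular_connectivity(lambda = 0, seed = 1)
  ec <- edge_census(conn)
  expect_equal(ec$inter, 0)
  expect_equal(sum(diag(conn$a)), 0)            # no self-connections
  expect_true(all(conn$a %in% c(0L, 1L)))
  for (cl in 1:2) {
    expect_equal(sum(conn$type_of == "I" & conn$cluster_of == cl), 50 %/% 5)
  }
})

test_that("intra-cluster densities match the configured probabilities", {
  set.seed(99)
  dens <- replicate(60, {
    conn <- build_modular_connectivity(lambda = 0)
    m1 <- conn$a[1:50, 1:50]
    m2 <- conn$a[51:100, 51:100]
    c(sum(m1) / (50 * 49), sum(m2) / (50 * 49))
  })
  se1 <- sqrt(0.25 * 0.75 / (50 * 49 * 60))
  se2 <- sqrt(0.2 * 0.8 / (50 * 49 * 60))
  expect_lt(abs(mean(dens[1, ]) - 0.25), 3 * se1)
  expect_lt(abs(mean(dens[2, ]) - 0.20), 3 * se2)
})

test_that("proportional rewiring conserves the edge count exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    c0 <- build_modular_connectivity(lambda = 0, seed = seed)
    for (lam in c(0.1, 0.3, 0.5)) {
      cl <- build_modular_connectivity(lambda = lam, seed = seed)
      expect_equal(sum(cl$a), sum(c0$a))
    }
  }
})

test_that("inter/intra edge ratio follows lambda/(1 - lambda)", {
  set.seed(7)
  for (lam in c(0.1, 0.2, 0.3)) {
    ratios <- replicate(100, {
      ec <- edge_census(build_modular_connectivity(lambda = lam))
      ec$inter / ec$intra
    })
    expected <- lam / (1 - lam)
    se <- sd(ratios) / sqrt(length(ratios))
    expect_lt(abs(mean(ratios) - expected), 3 * se)
  }
})

test_that("at lambda = 0.5 inter and intra edge counts match in expectation", {
  set.seed(3)
  ec <- replicate(100, {
    e <- edge_census(build_modular_connectivity(lambda = 0.5))
    e$inter - e$intra
  })
  expect_lt(abs(mean(ec)), 3 * sd(ec) / sqrt(length(ec)))
})

test_that("feedforward scheme matches inter E->I to inter E->E per direction", {
  for (seed in c(2, 12, 22)) {
    conn <- build_modular_connectivity(lambda = 0.1, scheme = "feedforward",
                                       seed = seed)
    for (v in 1:2) {
      w <- 3 - v
      preE <- conn$cluster_of == v & conn$type_of == "E"
      postE <- conn$cluster_of == w & conn$type_of == "E"
      postI <- conn$cluster_of == w & conn$type_of == "I"
      expect_equal(sum(conn$a[preE, postI]), sum(conn$a[preE, postE]))
    }
  }
})

test_that("targeting scheme removes I->I outputs of bridge-receiving neurons", {
  for (seed in c(4, 14)) {
    conn <- build_modular_connectivity(lambda = 0.15, scheme = "targeting",
                                       seed = seed)
    n <- nrow(conn$a)
    for (j in seq_len(n)) {
      if (conn$type_of[j] != "I") next
      has_inter_E <- any(conn$a[, j] == 1 &
                           conn$cluster_of != conn$cluster_of[j] &
                           conn$type_of == "E")
      if (!has_inter_E) next
      ii_intra <- sum(conn$a[j, ] == 1 &
                        conn$cluster_of == conn$cluster_of[j] &
                        conn$type_of == "I")
      expect_equal(ii_intra, 0)
    }
  }
})

test_that("strengths are truncated around the nominal values with I < 0", {
  conn <- build_modular_connectivity(lambda = 0.1, seed = 5)
  conn <- sample_strengths(conn, seed = 6)
  edges <- which(conn$a == 1L, arr.ind = TRUE)
  s <- conn$strengths[edges]
  pre_t <- conn$type_of[edges[, 1]]
  post_t <- conn$type_of[edges[, 2]]
  ee <- s[pre_t == "E" & post_t == "E"]
  expect_true(all(ee >= 5.0 & ee <= 7.5))   # 0.8 and 1.2 x 6.25
  ei <- s[pre_t == "E" & post_t == "I"]
  expect_true(all(ei >= 8 & ei <= 12))
  ii <- s[pre_t == "I"]
  expect_true(all(ii >= -12 & ii <= -8))    # low level, magnitude 10
  expect_true(all(conn$strengths[conn$a == 0L] == 0))
})

test_that("the truncated sampling is symmetric around the nominal strength", {
  set.seed(8)
  # Monte-Carlo oracle: the truncation window is symmetric, so the mean of
  # many sampled E->E strengths must approach A_nom = 6.25
  vals <- replicate(20, {
    conn <- sample_strengths(build_modular_connectivity(lambda = 0))
    edges <- which(conn$a == 1L, arr.ind = TRUE)
    ee <- conn$type_of[edges[, 1]] == "E" & conn$type_of[edges[, 2]] == "E"
    mean(conn$strengths[edges][ee])
  })
  expect_lt(abs(mean(vals) - 6.25), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("inhibition conditions zero the right strengths", {
  blocked <- sample_strengths(build_modular_connectivity(
    lambda = 0.2, condition = "inhibition_block", seed = 9))
  edges <- which(blocked$a == 1L, arr.ind = TRUE)
  pre_I <- blocked$type_of[edges[, 1]] == "I"
  expect_true(all(blocked$strengths[edges][pre_I] == 0))
  expect_true(all(blocked$strengths[edges][!pre_I] > 0))

  local <- sample_strengths(build_modular_connectivity(
    lambda = 0.2, condition = "local_inhibition", seed = 9))
  edges <- which(local$a == 1L, arr.ind = TRUE)
  pre_I <- local$type_of[edges[, 1]] == "I"
  inter <- local$cluster_of[edges[, 1]] != local$cluster_of[edges[, 2]]
  expect_true(all(local$strengths[edges][pre_I & inter] == 0))
  expect_true(all(local$strengths[edges][pre_I & !inter] < 0))
})

test_that("the builder is deterministic given a seed and validates input", {
  c1 <- build_modular_connectivity(lambda = 0.2, seed = 11)
  c2 <- build_modular_connectivity(lambda = 0.2, seed = 11)
  expect_identical(c1$a, c2$a)
  expect_identical(c1$type_of, c2$type_of)
  s1 <- sample_strengths(c1, seed = 3)
  s2 <- sample_strengths(c2, seed = 3)
  expect_identical(s1$strengths, s2$strengths)
  expect_error(build_modular_connectivity(lambda = 0.6), "lambda")
  expect_error(build_modular_connectivity(lambda = -0.1), "lambda")
  expect_error(build_modular_connectivity(n_per_cluster = 4), "at least 5")
  expect_error(sample_strengths(s1), "already sampled")
})
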
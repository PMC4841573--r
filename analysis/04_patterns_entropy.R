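#!/usr/bin/env Rscript
# Burst-pattern statistics on surrogate chains: similarity grouping, pattern
# entropy under a diverse versus a collapsed (disinhibition-like) schedule,
# propagation-vector variability, and the bimodality of intensity pairs.

library(modgate)
dir.create("results", showWarnings = FALSE)

geom <- cluster_geometry(1, 3)

## diverse repertoire: several propagation patterns with unequal weights
pp <- list(patterns = rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1),
                            c(0, 1, 1), c(0, 0, 1)),
           probs = c(0.137, 0.673, 0.103, 0.005, 0.082),
           initiators = c(1, 1, 1, 3, 3))  # bursts enter from either end
div <- make_schedule(geom, duration_ms = 1.2e6, rate_hz = 1,
                     min_gap_ms = 500, pattern_probs = pp, seed = 21)
pat_div <- t(vapply(split(div$activations$cluster, div$activations$burst_id),
                    function(cl) as.integer(1:3 %in% cl), integer(3)))
e_div <- pattern_entropy(pat_div)

## collapsed repertoire: stereotyped full-chain activation ("disinhibition")
col <- make_schedule(geom, duration_ms = 1.2e6, rate_hz = 1,
                     min_gap_ms = 500,
                     pattern_probs = list(
                       patterns = rbind(c(1, 1, 1), c(1, 1, 0)),
                       probs = c(0.95, 0.05)),
                     seed = 22)
pat_col <- t(vapply(split(col$activations$cluster, col$activations$burst_id),
                    function(cl) as.integer(1:3 %in% cl), integer(3)))
e_col <- pattern_entropy(pat_col)

cat(sprintf("pattern entropy, diverse schedule:   %.3f bits (normalised %.3f)\n",
            e_div$entropy, e_div$normalized))
cat(sprintf("pattern entropy, collapsed schedule: %.3f bits (normalised %.3f)\n",
            e_col$entropy, e_col$normalized))
cat(sprintf("empirical entropy of the diverse schedule in nats: %.3f\n",
            pattern_entropy(pat_div, base = "nats")$entropy))
write.csv(data.frame(
  schedule = c("diverse", "collapsed"),
  entropy_bits = c(e_div$entropy, e_col$entropy),
  normalized = c(e_div$normalized, e_col$normalized),
  n_bursts = c(nrow(pat_div), nrow(pat_col))
), "results/pattern_entropy.csv", row.names = FALSE)

## similarity grouping of AI snippets built from the diverse schedule
mk_snips <- function(sched, n_max = 60) {
  ids <- utils::head(unique(sched$activations$burst_id), n_max)
  lapply(ids, function(b) {
    d <- sched$activations[sched$activations$burst_id == b, ]
    t0 <- min(d$onset_ms)
    vapply(1:3, function(cl) {
      row <- d[d$cluster == cl, ]
      if (nrow(row) == 0) return(numeric(500))
      at <- (row$onset_ms - t0 + 300) / 2
      dnorm(1:500, at, 15) * 60 * row$amplitude
    }, numeric(500))
  })
}
snips <- mk_snips(div)
keep <- vapply(snips, function(s) sum(s) > 0, logical(1))
sm <- burst_similarity(snips[keep], k = 4)
cat(sprintf("similarity matrix over %d bursts: %d groups, within-group CV:\n",
            sum(keep), 4))
print(round(group_similarity_cv(sm), 3))
write.csv(sm$R, "results/similarity_matrix.csv", row.names = FALSE)

## propagation variability: diverse vs single-direction schedules
theta_of <- function(sched) {
  ids <- unique(sched$activations$burst_id)
  vapply(ids, function(b) {
    d <- sched$activations[sched$activations$burst_id == b, ]
    if (nrow(d) < 2) return(NA_real_)
    t0 <- min(d$onset_ms)
    ai <- vapply(1:3, function(cl) {
      row <- d[d$cluster == cl, ]
      if (nrow(row) == 0) return(numeric(500))
      dnorm(1:500, (row$onset_ms - t0 + 300) / 2, 15) * 60
    }, numeric(500))
    propagation_vector(ai, 2, c(1, 3), geom$positions)$theta
  }, numeric(1))
}
th_div <- theta_of(div)
th_col <- theta_of(col)
cat(sprintf("propagation variability (circular SD of theta at cluster 2):\n"))
cat(sprintf("  diverse %.3f rad, collapsed %.3f rad\n",
            propagation_variability(matrix(th_div)),
            propagation_variability(matrix(th_col))))

## bimodality of sender/receiver intensity pairs under a threshold rule
set.seed(23)
send <- runif(500, 0.5, 1.5)
recv <- ifelse(send > 1, send + rnorm(500, 0, 0.05),
               abs(rnorm(500, 0.03, 0.02)))
proj <- identity_projection(send / sd(send), recv / sd(recv))
cat(sprintf("bimodality of the identity projection: %.3f (uniform benchmark %.3f)\n",
            bimodality_coefficient(proj), bimodality_reference()))
cat("collapsing the schedule lowers both the entropy and the directional\n")
cat("variability - the signature of gating by disinhibition.\n")
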
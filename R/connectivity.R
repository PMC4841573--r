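#' Noise current parameters
#'
#' Every neuron receives, at every integration step, an independent Gaussian
#' noise current emulating spontaneous synaptic release summed over many
#' afferent synapses.
#'
#' @param mu mean noise current (uA/cm^2).
#' @param sigma standard deviation (uA/cm^2), redrawn every step.
#' @return list with `mu` and `sigma`.
#' @export
noise_params <- function(mu = 7.55, sigma = 4) {
  stopifnot(sigma >= 0)
  list(mu = mu, sigma = sigma)
}

#' Draw noise currents
#'
#' Samples the per-step per-neuron noise current of the model: i.i.d.
#' Gaussian draws with the parameters of [noise_params()]. The simulator's
#' compiled core draws from the same distribution through the same RNG
#' stream.
#'
#' @param n number of draws.
#' @param params a [noise_params()] list.
#' @return numeric vector of currents (uA/cm^2).
#' @export
noise_current <- function(n, params = noise_params()) {
  rnorm(n, params$mu, params$sigma)
}

#' Build a two-cluster modular connectivity matrix
#'
#' Constructs the directed binary synapse matrix of two coupled clusters.
#' Intra-cluster connections are drawn independently (Bernoulli) with
#' probability `p_intra[1]` in cluster 1 and `p_intra[2]` in cluster 2;
#' inter-cluster connections start at zero. Each intra-cluster edge is then
#' independently *replaced*, with probability `lambda` (the modularity), by an
#' edge from the same presynaptic neuron to a uniformly chosen target in the
#' other cluster (no duplicates, no self-connections), so the total edge count
#' is conserved. One of every five neurons per cluster is inhibitory.
#'
#' Three wiring schemes shape the inter-cluster inhibition:
#' \describe{
#'   \item{`proportional`}{inter-cluster targets are chosen uniformly, so the
#'     composition of inter-cluster synapses mirrors the intra-cluster one
#'     (expected inter/intra count ratio `lambda / (1 - lambda)` per synapse
#'     class).}
#'   \item{`feedforward`}{strong feed-forward inhibition: after proportional
#'     rewiring, inter-cluster E->I edges are added (or removed, never both)
#'     until their realized count equals the realized inter-cluster E->E count
#'     in each direction.}
#'   \item{`targeting`}{direct targeting inhibition: every inhibitory neuron
#'     that receives at least one excitatory input from the other cluster has
#'     all of its synapses onto inhibitory neurons of its own cluster rewired
#'     to randomly selected excitatory neurons of the same cluster.}
#' }
#'
#' The `condition` only affects synaptic strengths (applied by
#' [sample_strengths()]): `inhibition_block` zeroes all inhibitory strengths
#' (the model analogue of bath-applying a GABA-A blocker), `local_inhibition`
#' zeroes only inter-cluster inhibitory strengths.
#'
#' @param n_per_cluster neurons per cluster (default 50).
#' @param p_intra length-2 vector of intra-cluster connection probabilities.
#' @param lambda modularity, in `[0, 0.5]`.
#' @param scheme one of `"proportional"`, `"feedforward"`, `"targeting"`.
#' @param condition one of `"control"`, `"inhibition_block"`,
#'   `"local_inhibition"`.
#' @param inhibition_level `"low"`, `"high_A"` or `"high_tau"`; see
#'   [synapse_params()].
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `connectivity_matrix`: list with `a` (n x n 0/1
#'   matrix, `a[i, j] = 1` for a synapse i -> j), `cluster_of`, `type_of`
#'   (`"E"`/`"I"`), `strengths` (`NULL` until [sample_strengths()]),
#'   `lambda`, `scheme`, `condition`, `inhibition_level`, `p_intra`, `seed`.
#' @export
build_modular_connectivity <- function(n_per_cluster = 50,
                                       p_intra = c(0.25, 0.2),
                                       lambda = 0,
                                       scheme = c("proportional", "feedforward",
                                                  "targeting"),
                                       condition = c("control",
                                                     "inhibition_block",
                                                     "local_inhibition"),
                                       inhibition_level = c("low", "high_A",
                                                            "high_tau"),
                                       seed = NULL) {
  scheme <- match.arg(scheme)
  condition <- match.arg(condition)
  inhibition_level <- match.arg(inhibition_level)
  if (lambda < 0 || lambda > 0.5) {
    stop("lambda must lie in [0, 0.5]")
  }
  if (n_per_cluster < 5) {
    stop("n_per_cluster must be at least 5 (one in five neurons is inhibitory)")
  }
  stopifnot(length(p_intra) == 2, all(p_intra >= 0), all(p_intra <= 1))
  if (!is.null(seed)) set.seed(seed)

  n <- 2L * n_per_cluster
  cluster_of <- rep(1:2, each = n_per_cluster)
  n_inh <- n_per_cluster %/% 5L
  type_of <- rep("E", n)
  for (cl in 1:2) {
    members <- which(cluster_of == cl)
    type_of[sample(members, n_inh)] <- "I"
  }

  a <- matrix(0L, n, n)
  for (cl in 1:2) {
    members <- which(cluster_of == cl)
    m <- length(members)
    block <- matrix(rbinom(m * m, 1L, p_intra[cl]), m, m)
    diag(block) <- 0L
    a[members, members] <- block
  }

  # modularity rewiring: each intra edge replaced with probability lambda
  if (lambda > 0) {
    edges <- which(a == 1L, arr.ind = TRUE)
    replace <- runif(nrow(edges)) < lambda
    for (k in which(replace)) {
      i <- edges[k, 1]; j <- edges[k, 2]
      other <- which(cluster_of != cluster_of[i] & a[i, ] == 0L)
      if (length(other) == 0L) next  # target cluster saturated; keep the edge
      a[i, j] <- 0L
      a[i, resample(other, 1L)] <- 1L
    }
  }

  if (scheme == "feedforward") {
    a <- enforce_feedforward(a, cluster_of, type_of)
  } else if (scheme == "targeting") {
    a <- enforce_targeting(a, cluster_of, type_of)
  }

  structure(
    list(a = a, cluster_of = cluster_of, type_of = type_of, strengths = NULL,
         lambda = lambda, scheme = scheme, condition = condition,
         inhibition_level = inhibition_level, p_intra = p_intra, seed = seed),
    class = "connectivity_matrix"
  )
}

# sample() that does not surprise on length-1 x
resample <- function(x, size) x[sample.int(length(x), size)]

# match inter-cluster E->I counts to inter-cluster E->E counts, per direction
enforce_feedforward <- function(a, cluster_of, type_of) {
  for (v in 1:2) {
    w <- 3L - v
    pre_E <- which(cluster_of == v & type_of == "E")
    post_E <- which(cluster_of == w & type_of == "E")
    post_I <- which(cluster_of == w & type_of == "I")
    n_EE <- sum(a[pre_E, post_E])
    n_EI <- sum(a[pre_E, post_I])
    if (n_EI < n_EE) {
      free <- which(a[pre_E, post_I, drop = FALSE] == 0L, arr.ind = TRUE)
      pick <- free[sample.int(nrow(free), n_EE - n_EI), , drop = FALSE]
      a[cbind(pre_E[pick[, 1]], post_I[pick[, 2]])] <- 1L
    } else if (n_EI > n_EE) {
      used <- which(a[pre_E, post_I, drop = FALSE] == 1L, arr.ind = TRUE)
      pick <- used[sample.int(nrow(used), n_EI - n_EE), , drop = FALSE]
      a[cbind(pre_E[pick[, 1]], post_I[pick[, 2]])] <- 0L
    }
  }
  a
}

# inhibitory neurons with inter-cluster excitatory input lose their I->I
# outputs, which are rewired onto excitatory neurons of the same cluster
enforce_targeting <- function(a, cluster_of, type_of) {
  for (j in which(type_of == "I")) {
    pre_inter_E <- cluster_of != cluster_of[j] & type_of == "E" & a[, j] == 1L
    if (!any(pre_inter_E)) next
    same <- cluster_of == cluster_of[j]
    ii_targets <- which(same & type_of == "I" & a[j, ] == 1L)
    for (k in ii_targets) {
      cand <- which(same & type_of == "E" & a[j, ] == 0L)
      cand <- setdiff(cand, j)
      if (length(cand) == 0L) next
      a[j, k] <- 0L
      a[j, resample(cand, 1L)] <- 1L
    }
  }
  a
}

#' Sample per-synapse strengths
#'
#' Draws each synapse strength from a Gaussian with mean `A_nom` and standard
#' deviation `A_nom / 2` (magnitudes; see [synapse_params()] for the nominal
#' values by synapse class), redrawing until the value falls inside
#' `[0.8 A_nom, 1.2 A_nom]`. The accepted values therefore follow the
#' symmetric truncated Gaussian, whose mean equals `A_nom`. Inhibitory
#' strengths get a negative sign after sampling. The connectivity condition is
#' applied here: under `inhibition_block` every inhibitory strength is set to
#' exactly 0; under `local_inhibition` only inter-cluster inhibitory strengths
#' are zeroed.
#'
#' @param conn a [build_modular_connectivity()] object without strengths.
#' @param seed optional integer seed.
#' @return `conn` with a `strengths` matrix added (`0` where no synapse).
#' @export
sample_strengths <- function(conn, seed = NULL) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  if (!is.null(conn$strengths)) stop("strengths already sampled")
  if (!is.null(seed)) set.seed(seed)
  a <- conn$a
  n <- nrow(a)
  S <- matrix(0, n, n)
  edges <- which(a == 1L, arr.ind = TRUE)
  if (nrow(edges) > 0) {
    pre_t <- conn$type_of[edges[, 1]]
    post_t <- conn$type_of[edges[, 2]]
    A_nom <- vapply(seq_len(nrow(edges)), function(k) {
      abs(synapse_params(pre_t[k], post_t[k], conn$inhibition_level)$A_nom)
    }, numeric(1))
    val <- rtrunc_gauss(A_nom, A_nom / 2, 0.8 * A_nom, 1.2 * A_nom)
    val[pre_t == "I"] <- -val[pre_t == "I"]
    if (conn$condition == "inhibition_block") {
      val[pre_t == "I"] <- 0
    } else if (conn$condition == "local_inhibition") {
      inter <- conn$cluster_of[edges[, 1]] != conn$cluster_of[edges[, 2]]
      val[pre_t == "I" & inter] <- 0
    }
    S[edges] <- val
  }
  conn$strengths <- S
  conn
}

# redraw-until-inside truncated Gaussian, vectorised; degenerate mean 0 gives 0
rtrunc_gauss <- function(mu, sigma, lo, hi) {
  out <- numeric(length(mu))
  todo <- which(sigma > 0)
  out[sigma <= 0] <- mu[sigma <= 0]
  while (length(todo) > 0) {
    draw <- rnorm(length(todo), mu[todo], sigma[todo])
    ok <- draw >= lo[todo] & draw <= hi[todo]
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Edge counts by cluster relation
#'
#' Convenience summary used by the connectivity tests and the modularity
#' analyses: counts of intra- and inter-cluster synapses, optionally split by
#' pre/post neuron type.
#'
#' @param conn a `connectivity_matrix`.
#' @return list with `intra`, `inter` (total counts) and `by_class` (a
#'   data.frame with direction, pre/post type and count).
#' @export
edge_census <- function(conn) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  edges <- which(conn$a == 1L, arr.ind = TRUE)
  same <- conn$cluster_of[edges[, 1]] == conn$cluster_of[edges[, 2]]
  pre_t <- conn$type_of[edges[, 1]]
  post_t <- conn$type_of[edges[, 2]]
  by_class <- as.data.frame(table(
    relation = ifelse(same, "intra", "inter"),
    pre = pre_t, post = post_t
  ), responseName = "count")
  list(intra = sum(same), inter = sum(!same), by_class = by_class)
}
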
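#' Burst similarity matrix and grouping
#'
#' Similarity between network bursts: each burst is represented by its
#' multichannel AI snippet in a window around the burst peak (1000 ms in the
#' published analysis), smoothed with a 10-ms Gaussian. For a pair of bursts
#' the Pearson-normalised cross-covariance is computed per channel as a
#' function of lag, averaged over channels, and maximised over lag:
#' `R_ij = max_t < C_ij^n(t) >_n`. Maximising over lag makes the measure
#' time-invariant: a burst identical to another but shifted inside the window
#' has similarity 1. Groups of similar bursts are found by hierarchical
#' clustering (average linkage) on the Euclidean distances `D_ij` between the
#' rows of `R`.
#'
#' @param snippets list of matrices (bins x channels), one per burst; equal
#'   dimensions.
#' @param bin_ms grid spacing (ms).
#' @param smooth_sigma_ms snippet smoothing (ms, default 10).
#' @param max_lag_ms lag range of the time-invariant maximum (ms; default
#'   half the window).
#' @param k optional number of groups to cut the dendrogram into.
#' @return list of class `similarity_matrix`: `R` (burst x burst), `D`
#'   (Euclidean distances between rows of `R`), `order` (dendrogram leaf
#'   order), `hclust`, and `groups` (if `k` given). Single-channel snippets
#'   are accepted with a warning.
#' @export
burst_similarity <- function(snippets, bin_ms = 2, smooth_sigma_ms = 10,
                             max_lag_ms = NULL, k = NULL) {
  nb <- length(snippets)
  stopifnot(nb >= 2)
  snippets <- lapply(snippets, function(s) {
    s <- as.matrix(s)
    apply(s, 2, gaussian_smooth, sigma_ms = smooth_sigma_ms, bin_ms = bin_ms)
  })
  nch <- ncol(snippets[[1]])
  if (nch == 1) warning("single-channel snippets: channel mean over n = 1")
  nbin <- nrow(snippets[[1]])
  if (is.null(max_lag_ms)) max_lag_ms <- nbin * bin_ms / 2
  max_lag <- max(1L, min(round(max_lag_ms / bin_ms), nbin - 8L))
  R <- diag(1, nb)
  for (i in seq_len(nb - 1)) {
    for (j in (i + 1):nb) {
      per_lag <- matrix(NA_real_, 2 * max_lag + 1, nch)
      for (ch in seq_len(nch)) {
        lp <- lagged_pearson(snippets[[i]][, ch], snippets[[j]][, ch], max_lag)
        per_lag[, ch] <- lp$r
      }
      m <- rowMeans(per_lag, na.rm = TRUE)
      R[i, j] <- R[j, i] <- if (all(is.na(m))) 0 else max(m, na.rm = TRUE)
    }
  }
  D <- as.matrix(stats::dist(R))
  hc <- hclust(as.dist(D), method = "average")
  out <- list(R = R, D = D, order = hc$order, hclust = hc)
  if (!is.null(k)) out$groups <- cutree(hc, k = k)
  structure(out, class = "similarity_matrix")
}

#' Within-group variability of a similarity matrix
#'
#' Coefficient of variation of the off-diagonal similarities inside each
#' group: a readout of how stereotyped the bursts of one propagation pattern
#' are.
#'
#' @param sim_mat a [burst_similarity()] result with `groups`.
#' @return named numeric vector of CVs, one per group (NA for singletons).
#' @export
group_similarity_cv <- function(sim_mat) {
  stopifnot(!is.null(sim_mat$groups))
  vapply(split(seq_along(sim_mat$groups), sim_mat$groups), function(idx) {
    if (length(idx) < 2) return(NA_real_)
    vals <- sim_mat$R[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]
    sd(vals) / mean(vals)
  }, numeric(1))
}

#' Entropy of burst activation patterns
#'
#' Each burst is reduced to a binary pattern recording which clusters were
#' active. The entropy `E = -sum_i P_i log(P_i)` of the empirical pattern
#' probabilities measures the diversity of the network's activation
#' repertoire; it is normalised by the maximal achievable entropy of `N`
#' clusters, `E_max = log(2^N - 1)` (all non-empty patterns equiprobable; the
#' all-silent pattern cannot be observed as a burst).
#'
#' @param patterns matrix (bursts x clusters) of 0/1 participation, or a list
#'   of binary vectors. All-zero patterns are rejected: they must be excluded
#'   upstream. Alternatively supply `probs` directly.
#' @param probs optional numeric vector of pattern probabilities (sums to 1)
#'   replacing the empirical table.
#' @param n_clusters number of clusters `N` (needed for the normalisation;
#'   inferred from `patterns` when omitted).
#' @param base `"bits"` (log2, default) or `"nats"` (natural log).
#' @return list of class `pattern_summary`: `probs` (named by pattern),
#'   `entropy`, `e_max`, `normalized` (= entropy / e_max), `n_clusters`,
#'   `base`.
#' @export
pattern_entropy <- function(patterns = NULL, probs = NULL, n_clusters = NULL,
                            base = c("bits", "nats")) {
  base <- match.arg(base)
  lg <- if (base == "bits") log2 else log
  if (is.null(probs)) {
    if (is.list(patterns)) patterns <- do.call(rbind, patterns)
    patterns <- as.matrix(patterns)
    if (nrow(patterns) == 0) stop("no bursts; entropy undefined")
    if (any(rowSums(patterns != 0) == 0)) {
      stop("all-zero activation patterns must be excluded upstream")
    }
    if (is.null(n_clusters)) n_clusters <- ncol(patterns)
    key <- apply(patterns != 0, 1, function(r) paste(as.integer(r),
                                                     collapse = ""))
    tab <- table(key)
    probs <- as.numeric(tab) / sum(tab)
    names(probs) <- names(tab)
  } else {
    stopifnot(abs(sum(probs) - 1) < 1e-6, all(probs >= 0))
    if (is.null(n_clusters)) {
      stop("n_clusters is required when probabilities are supplied directly")
    }
  }
  p <- probs[probs > 0]
  entropy <- -sum(p * lg(p))
  e_max <- lg(2^n_clusters - 1)
  structure(
    list(probs = probs, entropy = entropy, e_max = e_max,
         normalized = entropy / e_max, n_clusters = n_clusters, base = base),
    class = "pattern_summary"
  )
}

#' Sample skewness and excess kurtosis (bias-corrected)
#'
#' The bias-corrected estimators used in the bimodality coefficient:
#' skewness `G1 = g1 sqrt(n(n-1))/(n-2)` and excess kurtosis
#' `G2 = ((n+1) g2 + 6)(n-1)/((n-2)(n-3))`, where `g1`, `g2` are the moment
#' estimators.
#'
#' @param x numeric sample, `n >= 4`.
#' @return list with `skewness`, `excess_kurtosis`, `n`.
#' @export
sample_moments <- function(x) {
  n <- length(x)
  if (n < 4) stop("need at least 4 samples")
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0) stop("zero variance; moments undefined")
  g1 <- mean(xc^3) / m2^1.5
  g2 <- mean(xc^4) / m2^2 - 3
  list(
    skewness = g1 * sqrt(n * (n - 1)) / (n - 2),
    excess_kurtosis = ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)),
    n = n
  )
}

#' Bimodality coefficient
#'
#' `BC = (m3^2 + 1) / (m4 + 3 (n-1)^2 / ((n-2)(n-3)))`, with `m3` the sample
#' skewness and `m4` the sample excess kurtosis. Reference values: a uniform
#' distribution gives 5/9 (~0.555, the customary uni/bi-modality benchmark),
#' a Gaussian 1/3, and a symmetric two-point distribution 1. Values above the
#' uniform benchmark indicate a tendency towards bimodality; applied here to
#' paired burst intensities projected on the identity line (see
#' [identity_projection()]).
#'
#' @param x numeric sample, `n >= 4`.
#' @return the coefficient (scalar).
#' @export
bimodality_coefficient <- function(x) {
  m <- sample_moments(x)
  n <- m$n
  (m$skewness^2 + 1) /
    (m$excess_kurtosis + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Large-sample bimodality coefficient
#'
#' The `n -> Inf` limit of [bimodality_coefficient()] for a distribution with
#' the given skewness and excess kurtosis: `(s^2 + 1) / (k + 3)`. The uniform
#' distribution (`s = 0`, `k = -1.2`) gives the 5/9 benchmark.
#'
#' @param skewness distribution skewness.
#' @param excess_kurtosis distribution excess kurtosis.
#' @return the limiting coefficient.
#' @export
bimodality_reference <- function(skewness = 0, excess_kurtosis = -1.2) {
  (skewness^2 + 1) / (excess_kurtosis + 3)
}

#' Projection of intensity pairs on the identity line
#'
#' Sender/receiver normalised-intensity pairs are projected on the diagonal,
#' `(x + y) / sqrt(2)`, giving the 1-D sample whose bimodality separates
#' propagating from non-propagating bursts.
#'
#' @param x,y paired coordinates.
#' @return scalar projection per pair.
#' @export
identity_projection <- function(x, y) {
  (x + y) / sqrt(2)
}

#' Burst-size statistics
#'
#' Per network burst: the number of active electrodes and the minimal
#' axis-aligned rectangular (bounding) area containing all active electrodes,
#' both normalised by their maxima over all bursts of the network; plus the
#' burst intensity divided by the number of active clusters (and by its
#' maximum), the quantity relating local activation strength to the extent of
#' global recruitment.
#'
#' @param nb a `nb_set` from [detect_bursts_network()].
#' @param positions data.frame with `x_um`, `y_um` per channel.
#' @return data.frame per burst: `burst_id`, `n_active`,
#'   `n_active_norm`, `bounding_area_um2`, `bounding_area_norm`,
#'   `intensity_per_cluster`, `intensity_per_cluster_norm`.
#' @export
burst_size_stats <- function(nb, positions) {
  pos <- as.matrix(positions[, c("x_um", "y_um")])
  per <- lapply(split(nb$channels, nb$channels$burst_id), function(d) {
    p <- pos[d$channel, , drop = FALSE]
    data.frame(
      burst_id = d$burst_id[1],
      n_active = nrow(d),
      bounding_area_um2 = diff(range(p[, 1])) * diff(range(p[, 2]))
    )
  })
  out <- do.call(rbind, per)
  net <- nb$bursts[match(out$burst_id, nb$bursts$burst_id), ]
  out$intensity_per_cluster <- net$intensity / out$n_active
  out$n_active_norm <- out$n_active / max(out$n_active)
  out$bounding_area_norm <- if (max(out$bounding_area_um2) > 0)
    out$bounding_area_um2 / max(out$bounding_area_um2) else 0
  out$intensity_per_cluster_norm <-
    out$intensity_per_cluster / max(out$intensity_per_cluster)
  rownames(out) <- NULL
  out
}
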
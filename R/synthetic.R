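#' Specification for a synthetic multi-block dataset
#'
#' Describes a planted-factor generative model: shared orthonormal factor
#' scores across blocks, per-block unit-norm factor loadings, per-block/
#' per-factor signal strengths and i.i.d. Gaussian noise. Optionally the
#' first factor's scores are shifted by cluster so the samples form discrete,
#' separable groups (the shift lives in factor space, so it survives any
#' column preprocessing).
#'
#' @param n Number of samples.
#' @param block_widths Integer vector of per-block feature counts p_k.
#' @param n_factors Planted rank r; must satisfy
#'   `n_factors <= min(n, min(block_widths))`.
#' @param block_signal N x r matrix of signal strengths (0 = factor absent
#'   from that block). Default: every entry 3.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (default 0.1; `0` gives exactly rank-r blocks).
#' @param n_clusters Optional number of discrete sample groups; cluster means
#'   are evenly spaced on factor 1 with spacing `cluster_sep` before
#'   orthonormalization.
#' @param cluster_sep Spacing between adjacent cluster means on factor 1, in
#'   units of the within-cluster standard deviation (default 4, i.e. clearly
#'   separable groups).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n, block_widths, n_factors = 1L, block_signal = NULL,
                           noise_sd = 0.1, n_clusters = NULL, cluster_sep = 4,
                           seed = 1L) {
  n <- as.integer(n); block_widths <- as.integer(block_widths)
  n_factors <- as.integer(n_factors)
  N <- length(block_widths)
  if (n < 2L || N < 1L || any(block_widths < 1L)) stop("invalid shape")
  if (n_factors < 1L || n_factors > min(n, min(block_widths)))
    stop("n_factors must satisfy 1 <= r <= min(n, min(p_k))")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(block_signal)) block_signal <- matrix(3, N, n_factors)
  block_signal <- as.matrix(block_signal)
  if (!all(dim(block_signal) == c(N, n_factors)))
    stop(sprintf("block_signal must be %d x %d", N, n_factors))
  if (!is.null(n_clusters)) {
    n_clusters <- as.integer(n_clusters)
    if (n_clusters < 2L || n_clusters > n) stop("n_clusters must be in [2, n]")
  }
  structure(list(n = n, block_widths = block_widths, n_factors = n_factors,
                 block_signal = block_signal, noise_sd = noise_sd,
                 n_clusters = n_clusters, cluster_sep = cluster_sep,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic multi-block dataset with planted factors
#'
#' Draws factor scores once (shared across blocks), shifts factor 1 by
#' cluster when requested, orthogonalizes the score columns and rescales each
#' to unit empirical variance (norm `sqrt(n)`), so "the planted factor" is
#' unambiguous for correlation-based recovery checks while keeping the
#' standard-normal scale of the draw. Per-block loadings are unit norm, and
#' `X_k = sum_r signal[k, r] * z_r t(v_kr) + noise`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (a `multiblock_dataset`), `factor_scores`
#'   (n x r ground truth, orthogonal columns of norm `sqrt(n)`), `loadings`
#'   (per-block p_k x r unit-norm matrices), and `clusters` (integer vector,
#'   or `NULL`).
#' @export
generate_multiblock <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)

  n <- spec$n; r <- spec$n_factors; N <- length(spec$block_widths)
  Z <- matrix(stats::rnorm(n * r), n, r)
  clusters <- NULL
  if (!is.null(spec$n_clusters)) {
    g <- spec$n_clusters
    clusters <- rep(seq_len(g), length.out = n)
    Z[, 1L] <- Z[, 1L] + (clusters - (g + 1) / 2) * spec$cluster_sep
  }
  # orthogonalize columns, then scale each to norm sqrt(n) so the planted
  # scores keep the unit-variance scale of the N(0,1) draw (orthonormal under
  # the empirical inner product u'v / n); signs fixed for determinism
  Q <- qr.Q(qr(Z))[, seq_len(r), drop = FALSE] * sqrt(n)
  for (j in seq_len(r)) if (Q[which.max(abs(Q[, j])), j] < 0) Q[, j] <- -Q[, j]

  sample_ids <- sprintf("sample%03d", seq_len(n))
  rownames(Q) <- sample_ids
  colnames(Q) <- paste0("factor_", seq_len(r))

  block_names <- paste0("block", seq_len(N))
  loadings <- vector("list", N)
  blocks <- vector("list", N)
  for (k in seq_len(N)) {
    p <- spec$block_widths[k]
    V <- matrix(stats::rnorm(p * r), p, r)
    V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
    dimnames(V) <- list(sprintf("%s_f%03d", block_names[k], seq_len(p)),
                        colnames(Q))
    loadings[[k]] <- V
    X <- Q %*% (spec$block_signal[k, ] * t(V))
    if (spec$noise_sd > 0)
      X <- X + matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
    dimnames(X) <- list(sample_ids, rownames(V))
    blocks[[k]] <- X
  }
  names(blocks) <- names(loadings) <- block_names

  list(dataset = multiblock_dataset(blocks),
       factor_scores = Q,
       loadings = loadings,
       clusters = clusters)
}

#' Small three-block fixture with planted subtypes
#'
#' A fixed-seed dataset emulating the shape of a bulk multi-omics tumor panel:
#' 21 samples, three blocks of widths (200, 50, 120) — a scaled-down
#' transcriptome / small-RNA / proteome trio — with 3 planted sample clusters
#' ("subtypes") carried by a dominant first factor. Used in documentation and
#' smoke/cluster-recovery tests.
#'
#' @return A `multiblock_dataset` with attributes `"clusters"` (length-21
#'   integer vector of planted subtypes) and `"ground_truth"` (the
#'   orthonormal factor scores).
#' @export
nci60_like_fixture <- function() {
  spec <- synthetic_spec(
    n = 21L,
    block_widths = c(200L, 50L, 120L),
    n_factors = 3L,
    block_signal = matrix(rep(c(10, 3, 2), each = 3), 3, 3),
    noise_sd = 0.5,
    n_clusters = 3L,
    cluster_sep = 4,
    seed = 60L)
  sim <- generate_multiblock(spec)
  ds <- sim$dataset
  nms <- c("mrna", "mirna", "prot")
  for (k in 1:3)
    colnames(ds$blocks[[k]]) <- sub("^block[0-9]+", nms[k], colnames(ds$blocks[[k]]))
  names(ds$blocks) <- ds$block_names <- nms
  ds$feature_ids <- lapply(ds$blocks, colnames)
  attr(ds, "clusters") <- sim$clusters
  attr(ds, "ground_truth") <- sim$factor_scores
  ds
}
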
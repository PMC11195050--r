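# Shared fixture builders. Everything is generated in code at test time.

named_matrix <- function(data, n, p, prefix = "f") {
  matrix(data, n, p, dimnames = list(sprintf("s%02d", seq_len(n)),
                                     paste0(prefix, seq_len(p))))
}

# Random centered-on-load multi-block dataset.
random_dataset <- function(n, widths, seed = 1) {
  set.seed(seed)
  blocks <- lapply(seq_along(widths), function(k)
    named_matrix(rnorm(n * widths[k]), n, widths[k], prefix = paste0("b", k, "_f")))
  names(blocks) <- paste0("blk", seq_along(widths))
  multiblock_dataset(blocks)
}

# Bypass the validating constructor to build deliberately broken datasets.
raw_dataset <- function(blocks) {
  structure(list(blocks = blocks,
                 block_names = names(blocks),
                 sample_ids = rownames(blocks[[1L]]),
                 feature_ids = lapply(blocks, colnames)),
            class = "multiblock_dataset")
}

# Direct evaluation of the per-order objective with explicit loops,
# independent of objective_value()'s vectorized path.
objective_by_hand <- function(blocks, a, w) {
  n <- nrow(blocks[[1L]])
  f <- rep(0, n)
  for (k in seq_along(blocks)) f <- f + w[k] * drop(blocks[[k]] %*% a[[k]])
  tot <- 0
  for (k in seq_along(blocks)) {
    fk <- drop(blocks[[k]] %*% a[[k]])
    tot <- tot + (sum(fk * f) / (n - 1))^2
  }
  tot
}

# Brute-force multi-start maximizer of the order-1 objective over unit-norm
# block loadings and weights; the independent oracle for the solver.
oracle_first_order <- function(blocks, restarts = 50, seed = 1) {
  widths <- vapply(blocks, ncol, integer(1))
  N <- length(blocks)
  n <- nrow(blocks[[1L]])
  objfun <- function(theta) {
    pos <- 0; a <- vector("list", N)
    for (k in seq_len(N)) {
      v <- theta[pos + seq_len(widths[k])]; pos <- pos + widths[k]
      nv <- sqrt(sum(v^2)); if (nv < 1e-9) return(0)
      a[[k]] <- v / nv
    }
    w <- theta[pos + seq_len(N)]
    nw <- sqrt(sum(w^2)); if (nw < 1e-9) return(0)
    objective_by_hand(blocks, a, w / nw)
  }
  set.seed(seed)
  best <- -Inf
  for (r in seq_len(restarts)) {
    o <- stats::optim(rnorm(sum(widths) + N), objfun, method = "BFGS",
                      control = list(fnscale = -1, maxit = 500, reltol = 1e-14))
    if (o$value > best) best <- o$value
  }
  best
}

centered_blocks <- function(dataset) {
  lapply(dataset$blocks, function(b) scale(b, scale = FALSE))
}
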
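#' Multi-block covariance objective
#'
#' The quantity maximized at each order: `sum_k cov^2(X_k a_k, f)` with
#' `f = sum_k w_k X_k a_k` and `cov(u, v) = u'v / (n - 1)` (blocks are assumed
#' centered upstream; the n-1 convention matches the preprocessing module).
#' Pure function; used both by the solver and as a hand-checkable scalar.
#'
#' @param blocks List of n x p_k numeric matrices.
#' @param block_loadings List of unit-norm loading vectors, one per block.
#' @param weights Unit-norm block-weight vector w of length N.
#' @return Non-negative scalar.
#' @export
objective_value <- function(blocks, block_loadings, weights) {
  N <- length(blocks)
  stopifnot(length(block_loadings) == N, length(weights) == N)
  for (k in seq_len(N)) {
    nrm <- sqrt(sum(block_loadings[[k]]^2))
    if (abs(nrm - 1) > 1e-8)
      stop(sprintf("block loading %d is not unit norm (||a|| = %.3g)", k, nrm))
  }
  wn <- sqrt(sum(weights^2))
  if (abs(wn - 1) > 1e-8)
    stop(sprintf("weights are not unit norm (||w|| = %.3g)", wn))
  n <- nrow(blocks[[1L]])
  fk <- lapply(seq_len(N), function(k) drop(blocks[[k]] %*% block_loadings[[k]]))
  f <- Reduce(`+`, Map(`*`, as.list(weights), fk))
  sum(vapply(fk, function(u) (sum(u * f) / (n - 1))^2, numeric(1)))
}

# Initial global score for one order: either the highest-variance column of
# the concatenated (possibly deflated) blocks, or a seeded normal draw.
init_global_score <- function(blocks, config, order_index) {
  n <- nrow(blocks[[1L]])
  if (config$init == "random") {
    seed <- if (is.null(config$seed)) 0L else config$seed
    f0 <- withr_seed_rnorm(seed + order_index, n)
  } else {
    best <- c(-1, 1L, 1L)  # variance, block, column
    for (k in seq_along(blocks)) {
      v <- .colVars(blocks[[k]])
      j <- which.max(v)
      if (v[j] > best[1L]) best <- c(v[j], k, j)
    }
    if (best[1L] <= 0) stop("no remaining signal: all columns have zero variance")
    f0 <- blocks[[best[2L]]][, best[3L]]
  }
  f0
}

.colVars <- function(X) {
  n <- nrow(X)
  if (n < 2L) return(rep(0, ncol(X)))
  colMeans(X^2) * n / (n - 1) - colMeans(X)^2 * n / (n - 1)
}

# rnorm draw under a local, restored RNG state
withr_seed_rnorm <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n)
}

#' Solve one order of the multi-block NIPALS iteration
#'
#' The stable multi-block power iteration for the objective of
#' [objective_value()]. Each iteration: (i) per block,
#' `a_k <- X_k' f / ||X_k' f||` and `f_k <- X_k a_k`; (ii) `w_k <- f_k' f`,
#' then `w <- w / ||w||`; (iii) `f <- sum_k w_k f_k`. Convergence when the
#' relative change of `f` drops below `config$tol`; hitting `max_iter` is a
#' recorded warning, not an error. The objective value is appended to
#' `objective_trace` every iteration and is non-decreasing (monotone
#' convergence of the stable extension). The converged objective is the
#' order's pseudo-eigenvalue.
#'
#' A block whose cross-covariance with the current global score vanishes
#' (`||X_k' f|| < 1e-12`) is flagged degenerate for this order: its loading is
#' the zero vector and its weight is pinned to 0, which keeps the remaining
#' blocks' solution well-defined. All blocks degenerate is an error
#' ("no remaining signal").
#'
#' Sign convention: the order is flipped so that the largest-magnitude entry
#' of the global loading (the concatenation of `w_k * a_k`) is positive; the
#' flip negates every `a_k`, `f_k` and `f` jointly, so all identities are
#' preserved.
#'
#' @param blocks List of centered (and possibly deflated) n x p_k matrices.
#' @param config A [decomposition_config()].
#' @param order_index Order number j (used for diagnostics and the seeded
#'   random initialization).
#' @return An object of class `order_solution` with elements `block_loadings`
#'   (list of unit vectors, zero for degenerate blocks), `block_scores`,
#'   `block_weights` (unit norm), `global_score`, `eigenvalue`, `n_iter`,
#'   `objective_trace`, `converged`, `final_rel_change`, `degenerate`.
#' @export
solve_order <- function(blocks, config = decomposition_config(), order_index = 1L) {
  N <- length(blocks)
  n <- nrow(blocks[[1L]])
  f <- init_global_score(blocks, config, order_index)

  a <- vector("list", N)
  fk <- vector("list", N)
  degen <- logical(N)
  w <- rep(0, N)
  trace <- numeric(0)
  converged <- FALSE
  rel <- NA_real_
  iter <- 0L

  while (iter < config$max_iter) {
    iter <- iter + 1L
    for (k in seq_len(N)) {
      ak <- drop(crossprod(blocks[[k]], f))
      nrm <- sqrt(sum(ak^2))
      if (nrm < 1e-12) {
        degen[k] <- TRUE
        a[[k]] <- rep(0, ncol(blocks[[k]]))
        fk[[k]] <- rep(0, n)
      } else {
        degen[k] <- FALSE
        a[[k]] <- ak / nrm
        fk[[k]] <- drop(blocks[[k]] %*% a[[k]])
      }
    }
    if (all(degen)) stop("no remaining signal: all blocks have vanishing cross-covariance")

    cvec <- vapply(fk, function(u) sum(u * f), numeric(1))
    cvec[degen] <- 0
    cn <- sqrt(sum(cvec^2))
    if (cn < 1e-300) stop("no remaining signal: global score decoupled from every block")
    w <- cvec / cn
    f_new <- Reduce(`+`, Map(`*`, as.list(w), fk))

    trace <- c(trace, sum(vapply(fk, function(u) (sum(u * f_new) / (n - 1))^2, numeric(1))))

    rel <- sqrt(sum((f_new - f)^2)) / sqrt(sum(f^2))
    f <- f_new
    if (is.finite(rel) && rel < config$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("order %d: max_iter = %d reached (final relative change %.3g)",
                    order_index, config$max_iter, rel))

  # sign fix on the global loading
  gl <- unlist(Map(`*`, as.list(w), a), use.names = FALSE)
  jmax <- which.max(abs(gl))
  if (length(jmax) && gl[jmax] < 0) {
    a <- lapply(a, `-`)
    fk <- lapply(fk, `-`)
    f <- -f
  }

  structure(list(block_loadings   = a,
                 block_scores     = fk,
                 block_weights    = w,
                 global_score     = f,
                 eigenvalue       = trace[length(trace)],
                 n_iter           = iter,
                 objective_trace  = trace,
                 converged        = converged,
                 final_rel_change = rel,
                 degenerate       = degen),
            class = "order_solution")
}

#' Deflate blocks after one order
#'
#' Removes the structure captured by an order before the next order is solved.
#' `mode = "block"` (MCIA) projects each block onto the orthogonal complement
#' of its own loading, `X_k <- X_k (I - a_k a_k') = X_k - f_k a_k'`, which
#' makes successive block loadings orthonormal within each block.
#' `mode = "global"` (CPCA) regresses the global score out of every block,
#' `X_k <- X_k - f (f' X_k) / (f' f)`, which makes successive global scores
#' mutually orthogonal. Degenerate blocks (zero loading) pass through
#' unchanged under `mode = "block"`.
#'
#' @param blocks List of matrices on which `solution` was solved.
#' @param solution An `order_solution` from [solve_order()].
#' @param mode `"block"` or `"global"`.
#' @return List of deflated matrices (same shapes).
#' @export
deflate <- function(blocks, solution, mode = c("block", "global")) {
  mode <- match.arg(mode)
  if (mode == "block") {
    Map(function(X, fk, ak) {
      if (all(ak == 0)) X else X - tcrossprod(fk, ak)
    }, blocks, solution$block_scores, solution$block_loadings)
  } else {
    f <- solution$global_score
    ff <- sum(f^2)
    if (ff < 1e-12) stop("global deflation impossible: ||f||^2 < 1e-12")
    lapply(blocks, function(X) X - f %*% crossprod(f, X) / ff)
  }
}

#' Multi-block decomposition (MCIA / CPCA)
#'
#' Fits the preprocessor on the dataset, transforms the blocks, then
#' alternates [solve_order()] and [deflate()] for `config$num_factors` orders
#' and assembles the full result: global scores F (n x R), global loadings A
#' (p x R, column j the block-wise concatenation of `w_kj * a_kj`, so that
#' `F = X_preproc A` holds exactly under block deflation), block scores and
#' loadings, the N x R block-weight matrix W, the pseudo-eigenvalues, and the
#' fitted preprocessor needed for out-of-sample prediction. Deterministic
#' given (dataset, configs, seed).
#'
#' @param dataset A valid `multiblock_dataset`.
#' @param config A [decomposition_config()]; `num_factors` must satisfy
#'   `R <= min(n - 1, sum(p_k))`.
#' @param preproc A [preprocess_config()].
#' @return An object of class `mb_decomposition` with elements
#'   `global_scores`, `global_loadings`, `block_scores`, `block_loadings`,
#'   `block_weights`, `eigenvalues`, `fitted_preprocessor`, `config`,
#'   `preproc`, `per_order` (list of `order_solution`), `block_names`,
#'   `sample_ids`, `feature_ids`. If the data's rank is exhausted before R
#'   orders the result is truncated with a warning naming the achieved order.
#' @examples
#' sim <- generate_multiblock(synthetic_spec(n = 30, block_widths = c(12, 8),
#'                                           n_factors = 2, seed = 7))
#' fit <- mb_decompose(sim$dataset, decomposition_config(num_factors = 2))
#' variance_explained(fit)
#' @export
mb_decompose <- function(dataset,
                         config = decomposition_config(),
                         preproc = preprocess_config()) {
  stopifnot(inherits(config, "decomposition_config"))
  rep <- validate_dataset(dataset)
  if (length(rep)) stop("invalid multiblock_dataset:\n  ", paste(rep, collapse = "\n  "))
  n <- n_samples(dataset)
  p_total <- sum(vapply(dataset$blocks, ncol, integer(1)))
  R <- config$num_factors
  if (R > min(n - 1L, p_total))
    stop(sprintf("num_factors = %d exceeds min(n - 1, sum(p_k)) = %d",
                 R, min(n - 1L, p_total)))

  fitted <- fit_preprocessor(dataset, preproc)
  work <- apply_preprocessor(fitted, dataset)$blocks
  X0 <- work  # preprocessed, undeflated (for the F = XA identity)

  per_order <- vector("list", R)
  achieved <- 0L
  for (j in seq_len(R)) {
    sol <- tryCatch(solve_order(work, config, j), error = function(e) e)
    if (inherits(sol, "error")) {
      if (grepl("no remaining signal", conditionMessage(sol))) {
        warning(sprintf("rank exhausted: truncating at order %d of %d requested", achieved, R))
        break
      }
      stop(sol)
    }
    per_order[[j]] <- sol
    achieved <- j
    if (j < R) work <- deflate(work, sol, config$deflation)
  }
  if (achieved == 0L) stop("no remaining signal at order 1: data has no variance")
  per_order <- per_order[seq_len(achieved)]
  R <- achieved

  N <- n_blocks(dataset)
  ord_names <- paste0("order_", seq_len(R))
  Fg <- do.call(cbind, lapply(per_order, `[[`, "global_score"))
  dimnames(Fg) <- list(dataset$sample_ids, ord_names)
  W <- do.call(cbind, lapply(per_order, `[[`, "block_weights"))
  dimnames(W) <- list(dataset$block_names, ord_names)
  lam <- vapply(per_order, `[[`, numeric(1), "eigenvalue")
  names(lam) <- ord_names

  A_k <- lapply(seq_len(N), function(k) {
    m <- do.call(cbind, lapply(per_order, function(s) s$block_loadings[[k]]))
    dimnames(m) <- list(dataset$feature_ids[[k]], ord_names)
    m
  })
  F_k <- lapply(seq_len(N), function(k) {
    m <- do.call(cbind, lapply(per_order, function(s) s$block_scores[[k]]))
    dimnames(m) <- list(dataset$sample_ids, ord_names)
    m
  })
  names(A_k) <- names(F_k) <- dataset$block_names

  A <- do.call(rbind, lapply(seq_len(N), function(k) sweep(A_k[[k]], 2, W[k, ], "*")))
  rownames(A) <- global_feature_ids(dataset)

  structure(list(global_scores       = Fg,
                 global_loadings     = A,
                 block_scores        = F_k,
                 block_loadings      = A_k,
                 block_weights       = W,
                 eigenvalues         = lam,
                 fitted_preprocessor = fitted,
                 config              = config,
                 preproc             = preproc,
                 per_order           = per_order,
                 block_names         = dataset$block_names,
                 sample_ids          = dataset$sample_ids,
                 feature_ids         = dataset$feature_ids,
                 preprocessed        = X0),
            class = "mb_decomposition")
}

#' @export
print.mb_decomposition <- function(x, ...) {
  R <- ncol(x$global_scores)
  cat(sprintf("mb_decomposition: %d samples, %d blocks, %d orders (%s deflation)\n",
              nrow(x$global_scores), length(x$block_names), R,
              x$config$deflation))
  ve <- variance_explained(x)
  cat("variance explained:", paste(sprintf("%.3f", ve), collapse = " "), "\n")
  if (!is.null(x$per_order)) {
    it <- vapply(x$per_order, `[[`, integer(1), "n_iter")
    cat("iterations per order:", paste(it, collapse = " "), "\n")
  }
  invisible(x)
}

#' Proportion of variance explained per order
#'
#' Uses the per-order converged objective values as pseudo-eigenvalues:
#' `proportion_j = lambda_j / sum_i lambda_i`. No eigendecomposition is
#' involved. Eigenvalues are expected to be non-increasing across orders;
#' a violation is flagged with a warning (not an error), since neither
#' deflation mode formally guarantees ordering.
#'
#' @param result An `mb_decomposition`.
#' @return Length-R vector of proportions in `[0, 1]` summing to 1.
#' @export
variance_explained <- function(result) {
  lam <- result$eigenvalues
  if (all(lam == 0)) stop("all eigenvalues are zero")
  if (any(diff(lam) > 1e-10 * max(lam)))
    warning("eigenvalues are not non-increasing across orders")
  lam / sum(lam)
}

#' Block contributions to each global score
#'
#' Entry (k, j) is `w_kj^2`, the squared block weight; because each order's
#' weight vector has unit Euclidean norm, every column sums to 1. This is the
#' quantity plotted to show how much each omics block drives each order.
#'
#' @param result An `mb_decomposition`.
#' @return N x R matrix of squared weights, columns summing to 1.
#' @export
block_contributions <- function(result) {
  result$block_weights^2
}

#' Top features of a global loading
#'
#' Ranks all p features by the absolute magnitude of their global loading at
#' the requested order, descending; ties are broken by (block order, feature
#' order) so the ranking is deterministic.
#'
#' @param result An `mb_decomposition`.
#' @param order Order j, `1 <= order <= R`.
#' @param count Number of features to return; `count > p` returns all p with a
#'   note attribute, `count = 0` an empty frame.
#' @return `data.frame(block, feature_id, loading)` sorted by `|loading|`.
#' @export
top_features <- function(result, order = 1L, count = 10L) {
  R <- ncol(result$global_loadings)
  if (order < 1L || order > R) stop(sprintf("order must be in [1, %d]", R))
  widths <- vapply(result$block_loadings, nrow, integer(1))
  blk <- rep(result$block_names, widths)
  fid <- unlist(result$feature_ids, use.names = FALSE)
  v <- result$global_loadings[, order]
  idx <- order(-abs(v), seq_along(v))  # stable tie-break: block then feature order
  note <- NULL
  if (count > length(v)) {
    note <- sprintf("count %d exceeds p = %d; returning all features", count, length(v))
    count <- length(v)
  }
  idx <- idx[seq_len(max(0L, as.integer(count)))]
  out <- data.frame(block = blk[idx], feature_id = fid[idx],
                    loading = unname(v[idx]), stringsAsFactors = FALSE)
  if (!is.null(note)) attr(out, "note") <- note
  out
}
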
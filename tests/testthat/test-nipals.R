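test_that("objective_value matches a direct loop evaluation and its edge cases", {
  set.seed(21)
  blocks <- centered_blocks(random_dataset(6, c(3, 2), seed = 21))
  a <- lapply(blocks, function(b) { v <- rnorm(ncol(b)); v / sqrt(sum(v^2)) })
  w <- rnorm(2); w <- w / sqrt(sum(w^2))
  expect_equal(objective_value(blocks, a, w),
               objective_by_hand(blocks, a, w), tolerance = 1e-12)

  # all-zero blocks give zero
  z <- lapply(blocks, function(b) b * 0)
  expect_equal(objective_value(z, a, w), 0)

  # single block with w = 1: (||Xa||^2/(n-1))^2
  b1 <- blocks[1]
  a1 <- a[1]
  expect_equal(objective_value(b1, a1, 1),
               (sum((b1[[1]] %*% a1[[1]])^2) / (nrow(b1[[1]]) - 1))^2,
               tolerance = 1e-12)

  # non-unit inputs rejected
  expect_error(objective_value(blocks, lapply(a, function(v) 2 * v), w), "unit norm")
  expect_error(objective_value(blocks, a, c(1, 1)), "unit norm")
})

test_that("solve_order reproduces the leading SVD pair on a single block", {
  set.seed(8)
  X <- scale(matrix(rnorm(40), 8, 5), scale = FALSE)
  sol <- solve_order(list(X), decomposition_config(1, tol = 1e-12))
  sv <- svd(X)
  s <- sign(sum(sol$global_score * sv$u[, 1]))
  expect_lt(sqrt(sum((sol$global_score - s * sv$d[1] * sv$u[, 1])^2)) / sv$d[1], 1e-6)
  expect_lt(sqrt(sum((sol$block_loadings[[1]] - s * sv$v[, 1])^2)), 1e-6)
  expect_equal(sol$block_weights, 1)
})

test_that("two identical blocks share the solution with equal weights", {
  set.seed(13)
  X <- scale(matrix(rnorm(60), 10, 6), scale = FALSE)
  sol <- solve_order(list(X, X), decomposition_config(1, tol = 1e-12))
  expect_equal(sol$block_weights, c(1, 1) / sqrt(2), tolerance = 1e-8)
  expect_equal(sol$block_loadings[[1]], sol$block_loadings[[2]], tolerance = 1e-8)
})

test_that("solution is stable in the tolerance and respects its invariants", {
  set.seed(17)
  blocks <- centered_blocks(random_dataset(12, c(7, 4), seed = 17))
  s1 <- solve_order(blocks, decomposition_config(1, tol = 1e-9))
  s2 <- solve_order(blocks, decomposition_config(1, tol = 1e-12))
  for (k in 1:2)
    expect_lt(max(abs(s1$block_loadings[[k]] - s2$block_loadings[[k]])), 1e-6)

  # unit norms, f = sum w_k f_k, monotone trace
  for (s in list(s1, s2)) {
    for (a in s$block_loadings) expect_equal(sum(a^2), 1, tolerance = 1e-10)
    expect_equal(sum(s$block_weights^2), 1, tolerance = 1e-10)
    recon <- Reduce(`+`, Map(`*`, as.list(s$block_weights), s$block_scores))
    expect_lt(max(abs(s$global_score - recon)), 1e-10)
    expect_true(all(diff(s$objective_trace) >= -1e-10))
  }
})

test_that("monotone convergence holds across randomized instances (property)", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(5:25, 1); N <- sample(1:3, 1)
    widths <- sample(2:30, N, replace = TRUE)
    mode <- if (i %% 2 == 0) "block" else "global"
    ds <- random_dataset(n, widths, seed = 1000 + i)
    R <- min(3, n - 1, sum(widths))
    fit <- suppressWarnings(
      mb_decompose(ds, decomposition_config(R, deflation = mode),
                   preprocess_config("center", "unit_variance")))
    for (s in fit$per_order)
      expect_true(all(diff(s$objective_trace) >= -1e-10))
  }
})

test_that("deflation annihilates the captured direction", {
  set.seed(31)
  blocks <- centered_blocks(random_dataset(9, c(5, 4), seed = 31))
  sol <- solve_order(blocks, decomposition_config(1, tol = 1e-12))

  defl_b <- deflate(blocks, sol, "block")
  for (k in 1:2)
    expect_lt(max(abs(defl_b[[k]] %*% sol$block_loadings[[k]])), 1e-12)

  defl_g <- deflate(blocks, sol, "global")
  f <- sol$global_score
  for (k in 1:2) {
    v <- rnorm(ncol(defl_g[[k]]))
    expect_lt(abs(sum(f * (defl_g[[k]] %*% v))),
              1e-10 * sqrt(sum(f^2)) * sqrt(sum((defl_g[[k]] %*% v)^2)) + 1e-10)
  }

  # a rank-1 block deflated by its own solution vanishes
  u <- rnorm(9); u <- u - mean(u); v <- rnorm(4)
  X1 <- tcrossprod(u, v)
  s1 <- solve_order(list(X1), decomposition_config(1, tol = 1e-12))
  expect_lt(max(abs(deflate(list(X1), s1, "block")[[1]])), 1e-12)
})

test_that("degenerate blocks are pinned to zero weight and flagged", {
  set.seed(41)
  live <- scale(matrix(rnorm(40), 8, 5), scale = FALSE)
  dead <- matrix(0, 8, 3)
  sol <- solve_order(list(live, dead), decomposition_config(1))
  expect_true(sol$degenerate[2])
  expect_equal(sol$block_weights[2], 0)
  expect_true(all(sol$block_loadings[[2]] == 0))
  expect_equal(abs(sol$block_weights[1]), 1, tolerance = 1e-12)

  expect_error(solve_order(list(dead, dead), decomposition_config(1)),
               "no remaining signal")
})

test_that("mb_decompose satisfies the structural identities in both modes", {
  ds <- random_dataset(12, c(8, 6, 5), seed = 55)  # every p_k >= R

  fit <- mb_decompose(ds, decomposition_config(4),
                      preprocess_config("center", "unit_variance"))
  # block-loading orthonormality per block (MCIA constraint)
  for (A_k in fit$block_loadings)
    expect_lt(max(abs(crossprod(A_k) - diag(4))), 1e-8)
  # F = X_preproc A and F_k = X_k A_k exactly
  tr <- apply_preprocessor(fit$fitted_preprocessor, ds)
  Xg <- do.call(cbind, tr$blocks)
  expect_lt(max(abs(Xg %*% fit$global_loadings - fit$global_scores)), 1e-10)
  for (nm in fit$block_names)
    expect_lt(max(abs(tr$blocks[[nm]] %*% fit$block_loadings[[nm]] -
                        fit$block_scores[[nm]])), 1e-10)
  # global loading column j stacks w_kj * a_kj
  stacked <- do.call(rbind, Map(function(k)
    sweep(fit$block_loadings[[k]], 2, fit$block_weights[k, ], "*"),
    seq_along(fit$block_names)))
  expect_equal(unname(stacked), unname(fit$global_loadings), tolerance = 1e-12)

  # CPCA: global scores mutually orthogonal
  fitc <- mb_decompose(ds, decomposition_config(4, deflation = "global"),
                       preprocess_config("center", "unit_variance"))
  G <- crossprod(fitc$global_scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8 * max(diag(G)))

  # determinism: identical inputs give bitwise-identical results
  fit2 <- mb_decompose(ds, decomposition_config(4),
                       preprocess_config("center", "unit_variance"))
  expect_identical(fit$global_scores, fit2$global_scores)
  expect_identical(fit$eigenvalues, fit2$eigenvalues)
})

test_that("single-block decomposition reduces to PCA and R is bounded", {
  set.seed(77)
  X <- named_matrix(rnorm(200), 20, 10)
  ds <- multiblock_dataset(list(b = X))
  fit <- mb_decompose(ds, decomposition_config(3, tol = 1e-12),
                      preprocess_config("center", "none"))
  sv <- svd(scale(X, scale = FALSE))
  for (j in 1:3) {
    ref <- sv$d[j] * sv$u[, j]
    s <- sign(sum(fit$global_scores[, j] * ref))
    expect_lt(sqrt(sum((fit$global_scores[, j] - s * ref)^2)) / sv$d[j], 1e-6)
    expect_lt(sqrt(sum((fit$block_loadings$b[, j] - s * sv$v[, j])^2)), 1e-6)
  }
  expect_error(mb_decompose(ds, decomposition_config(20)), "exceeds")
})

test_that("rank exhaustion truncates with a warning", {
  set.seed(3)
  u <- rnorm(10); v <- rnorm(6)
  X <- tcrossprod(u, v)  # rank 1 (rank 2 after centering interplay)
  dimnames(X) <- list(sprintf("s%02d", 1:10), paste0("f", 1:6))
  ds <- multiblock_dataset(list(b = X))
  expect_warning(
    fit <- mb_decompose(ds, decomposition_config(5, tol = 1e-12),
                        preprocess_config("center", "none")),
    "truncating")
  expect_lt(ncol(fit$global_scores), 5)
})

test_that("variance_explained normalizes the pseudo-eigenvalues", {
  ds <- random_dataset(15, c(6, 4), seed = 61)
  fit <- mb_decompose(ds, decomposition_config(3))
  ve <- variance_explained(fit)
  expect_equal(sum(ve), 1, tolerance = 1e-12)
  expect_true(all(ve >= 0 & ve <= 1))
  expect_equal(unname(ve), unname(fit$eigenvalues / sum(fit$eigenvalues)))

  fit1 <- mb_decompose(ds, decomposition_config(1))
  expect_equal(unname(variance_explained(fit1)), 1)

  # near-isotropic data spreads variance over orders
  iso <- random_dataset(40, c(30, 30), seed = 62)
  fiso <- mb_decompose(iso, decomposition_config(4))
  expect_true(all(variance_explained(fiso) < 0.5))
})

test_that("block_contributions are squared weights with unit column sums", {
  ds <- random_dataset(10, c(5, 5), seed = 71)
  fit <- mb_decompose(ds, decomposition_config(3))
  bc <- block_contributions(fit)
  expect_equal(unname(colSums(bc)), rep(1, 3), tolerance = 1e-12)
  expect_equal(bc, fit$block_weights^2)

  single <- mb_decompose(random_dataset(10, 6, seed = 72), decomposition_config(3))
  expect_equal(unname(block_contributions(single)[1, ]), rep(1, 3), tolerance = 1e-12)

  # two identical blocks: contributions (0.5, 0.5) at order 1
  X <- named_matrix(rnorm(60), 10, 6)
  twin <- multiblock_dataset(list(a = X, b = `colnames<-`(X, paste0("g", 1:6))))
  ftw <- mb_decompose(twin, decomposition_config(1), preprocess_config("center", "none"))
  expect_equal(unname(block_contributions(ftw)[, 1]), c(0.5, 0.5), tolerance = 1e-8)
})

test_that("top_features ranks by absolute loading with stable ties", {
  fake <- structure(list(
    global_loadings = matrix(c(0.9, -0.95, 0.1), 3, 1,
                             dimnames = list(c("fa", "fb", "fc"), "order_1")),
    block_loadings = list(a = matrix(0, 2, 1), b = matrix(0, 1, 1)),
    block_names = c("a", "b"),
    feature_ids = list(a = c("fa", "fb"), b = "fc")),
    class = "mb_decomposition")
  tf <- top_features(fake, 1, 2)
  expect_equal(tf$feature_id, c("fb", "fa"))
  expect_equal(tf$loading, c(-0.95, 0.9))

  expect_equal(nrow(top_features(fake, 1, 0)), 0)
  all3 <- top_features(fake, 1, 10)
  expect_equal(nrow(all3), 3)
  expect_match(attr(all3, "note"), "exceeds")
  expect_error(top_features(fake, 5, 1), "order")

  # equal magnitudes keep input (block, feature) order
  fake$global_loadings[, 1] <- c(0.5, -0.5, 0.5)
  expect_equal(top_features(fake, 1, 3)$feature_id, c("fa", "fb", "fc"))
})

test_that("random initialization is seeded and deterministic", {
  ds <- random_dataset(10, c(6, 3), seed = 81)
  f1 <- mb_decompose(ds, decomposition_config(2, init = "random", seed = 5))
  f2 <- mb_decompose(ds, decomposition_config(2, init = "random", seed = 5))
  expect_identical(f1$global_scores, f2$global_scores)
  # and agrees with the deterministic init up to tolerance on generic data
  f3 <- mb_decompose(ds, decomposition_config(2))
  expect_equal(unname(abs(diag(cor(f1$global_scores, f3$global_scores)))), c(1, 1),
               tolerance = 1e-6)
})
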
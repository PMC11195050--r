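#' Preprocessing configuration
#'
#' Two independent levels of scaling are applied to each block before the
#' decomposition, in a fixed order: the column-level transform first, then a
#' single whole-block scalar divisor computed on the column-transformed block.
#' Whole-block scaling is recommended to remove disparities in block size,
#' so that a block does not dominate the global scores merely because it has
#' more features.
#'
#' Column methods:
#' \describe{
#'   \item{none}{identity.}
#'   \item{center}{subtract the column mean.}
#'   \item{center_scale}{center, then divide by the column standard deviation
#'     (denominator n-1). Zero-variance columns get divisor 1 (the column
#'     becomes all-zero) and a warning is emitted rather than dropping them,
#'     keeping loading dimensions aligned with the input feature ids.}
#'   \item{colprofile}{correspondence-analysis-style transform for
#'     non-negative data. With grand total G, row sums s_i and column masses
#'     c_j = colsum_j / G fitted on training data, an entry becomes
#'     `(x_ij - s_i * c_j) / sqrt(s_i * G)`; equivalently the centered row
#'     profile `(P_ij / r_i - c_j)` weighted by `sqrt(r_i)`. Only `G` and `c`
#'     are reused on new rows, so the transform applies to out-of-sample data.}
#' }
#'
#' Block methods (scalar divisor, computed on the column-transformed block Y
#' with n rows and p_k columns):
#' \describe{
#'   \item{none}{1.}
#'   \item{unit_variance}{`||Y||_F / sqrt(n-1)`, making each block's total
#'     variance equal to 1.}
#'   \item{largest_singular_value}{leading singular value of Y.}
#'   \item{num_columns}{`sqrt(p_k)`.}
#' }
#'
#' @param column_method One of `"none"`, `"center"`, `"center_scale"`,
#'   `"colprofile"`. Default `"center"`.
#' @param block_method One of `"none"`, `"unit_variance"`,
#'   `"largest_singular_value"`, `"num_columns"`. Default `"unit_variance"`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(column_method = c("center", "none", "center_scale", "colprofile"),
                              block_method = c("unit_variance", "none",
                                               "largest_singular_value", "num_columns")) {
  structure(list(column_method = match.arg(column_method),
                 block_method = match.arg(block_method)),
            class = "preprocess_config")
}

#' Fit the preprocessor on a training dataset
#'
#' Estimates, per block, the column centers and scale divisors, the
#' column-mass/grand-total parameters of the `colprofile` transform, and the
#' whole-block scalar divisor. The fitted object is retained inside the
#' decomposition result so that new samples can be transformed with the
#' training parameters (never re-estimated) before out-of-sample projection.
#'
#' @param dataset A valid `multiblock_dataset`.
#' @param config A [preprocess_config()].
#' @return An object of class `fitted_preprocessor`: the config, the training
#'   `feature_ids` and `block_names`, and per block a list with `centers`,
#'   `scales`, `block_scalar`, `zero_variance` (flagged column ids) and, for
#'   `colprofile`, `grand_total`, `row_masses`, `col_masses`.
#' @export
fit_preprocessor <- function(dataset, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  rep <- validate_dataset(dataset)
  if (length(rep)) stop("invalid multiblock_dataset:\n  ", paste(rep, collapse = "\n  "))
  n <- n_samples(dataset)

  per_block <- lapply(seq_along(dataset$blocks), function(k) {
    X <- dataset$blocks[[k]]
    nm <- dataset$block_names[k]
    p <- ncol(X)
    centers <- rep(0, p); scales <- rep(1, p)
    names(centers) <- names(scales) <- colnames(X)
    zero_var <- character(0)
    cp <- NULL

    if (config$column_method %in% c("center", "center_scale")) {
      centers <- colMeans(X)
      if (config$column_method == "center_scale") {
        scales <- apply(X, 2, stats::sd)                 # n-1 denominator
        zv <- !is.finite(scales) | scales <= 0
        if (any(zv)) {
          zero_var <- colnames(X)[zv]
          scales[zv] <- 1
          warning(sprintf("block '%s': %d zero-variance column(s) (e.g. %s); scale divisor forced to 1",
                          nm, sum(zv), zero_var[1L]))
        }
      }
    } else if (config$column_method == "colprofile") {
      if (any(X < 0)) {
        ij <- arrayInd(which(X < 0)[1L], dim(X))
        stop(sprintf("block '%s': colprofile requires non-negative entries (negative at row %d, column %d)",
                     nm, ij[1L], ij[2L]))
      }
      G <- sum(X)
      if (G <= 0) stop(sprintf("block '%s': colprofile requires a positive grand total (all-zero block)", nm))
      s <- rowSums(X)
      if (any(s <= 0))
        stop(sprintf("block '%s': colprofile requires positive row sums (zero row: %s)",
                     nm, rownames(X)[which(s <= 0)[1L]]))
      cp <- list(grand_total = G, row_masses = s / G, col_masses = colSums(X) / G)
    }

    bp <- c(list(centers = centers, scales = scales, zero_variance = zero_var), cp)
    Y <- column_transform(X, bp, config$column_method, nm)

    scalar <- switch(config$block_method,
      none = 1,
      unit_variance = norm(Y, "F") / sqrt(n - 1),
      largest_singular_value = svd(Y, nu = 0L, nv = 0L)$d[1L],
      num_columns = sqrt(p))
    if (!is.finite(scalar) || scalar <= 0) {
      warning(sprintf("block '%s': degenerate block scalar (all-zero transformed block); forced to 1", nm))
      scalar <- 1
    }
    bp$block_scalar <- scalar
    bp
  })
  names(per_block) <- dataset$block_names

  structure(list(config      = config,
                 block_names = dataset$block_names,
                 feature_ids = dataset$feature_ids,
                 blocks      = per_block),
            class = "fitted_preprocessor")
}

# Column-level transform with fitted parameters bp; works identically on
# training and new rows (colprofile uses only the fitted grand total and
# column masses plus the row's own sum).
column_transform <- function(X, bp, method, block_name) {
  switch(method,
    none = X,
    center = sweep(X, 2, bp$centers, "-"),
    center_scale = sweep(sweep(X, 2, bp$centers, "-"), 2, bp$scales, "/"),
    colprofile = {
      if (any(X < 0)) {
        ij <- arrayInd(which(X < 0)[1L], dim(X))
        stop(sprintf("block '%s': colprofile requires non-negative entries (negative at row %d, column %d)",
                     block_name, ij[1L], ij[2L]))
      }
      s <- rowSums(X)
      if (any(s <= 0))
        stop(sprintf("block '%s': colprofile requires positive row sums (zero row: %s)",
                     block_name, rownames(X)[which(s <= 0)[1L]]))
      G <- bp$grand_total
      sweep(X - outer(s, bp$col_masses), 1, sqrt(s * G), "/")
    })
}

#' Apply a fitted preprocessor
#'
#' Transforms every block as `((X - centers) / scales) / block_scalar` (or the
#' `colprofile` transform followed by the block scalar) using the fitted
#' training parameters only. Feature ids must match the training ids exactly
#' and in order; the block-name sets must agree.
#'
#' @param fitted A `fitted_preprocessor` from [fit_preprocessor()].
#' @param dataset A `multiblock_dataset` whose blocks carry exactly the
#'   training features.
#' @return A transformed `multiblock_dataset` (pure function of its inputs).
#' @export
apply_preprocessor <- function(fitted, dataset) {
  stopifnot(inherits(fitted, "fitted_preprocessor"))
  rep <- validate_dataset(dataset)
  if (length(rep)) stop("invalid multiblock_dataset:\n  ", paste(rep, collapse = "\n  "))

  miss <- setdiff(fitted$block_names, dataset$block_names)
  if (length(miss)) stop("missing block(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(dataset$block_names, fitted$block_names)
  if (length(extra)) stop("unknown block(s) not seen in training: ", paste(extra, collapse = ", "))

  out <- lapply(fitted$block_names, function(nm) {
    X <- dataset$blocks[[nm]]
    want <- fitted$feature_ids[[nm]]
    have <- colnames(X)
    if (!identical(have, want)) {
      m <- setdiff(want, have); e <- setdiff(have, want)
      if (length(m) || length(e))
        stop(sprintf("block '%s': feature mismatch (missing: %s; extra: %s)", nm,
                     if (length(m)) paste(utils::head(m, 10L), collapse = ",") else "-",
                     if (length(e)) paste(utils::head(e, 10L), collapse = ",") else "-"))
      stop(sprintf("block '%s': features are reordered relative to training", nm))
    }
    bp <- fitted$blocks[[nm]]
    column_transform(X, bp, fitted$config$column_method, nm) / bp$block_scalar
  })
  names(out) <- fitted$block_names
  multiblock_dataset(out)
}
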
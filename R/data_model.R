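#' Construct a multi-block dataset
#'
#' Bundles N sample-by-feature matrices ("blocks" or "views") that share the
#' same n samples into a single container. Every block must carry the same set
#' of sample identifiers; rows of blocks 2..N are reordered to match the first
#' block's sample order, so alignment is by identifier, never by position.
#'
#' @param blocks Named list of numeric matrices, each samples x features.
#'   Unnamed lists are given names `block1, block2, ...`. Matrices without
#'   rownames get `sample1..n` (all blocks must then have equal row counts);
#'   matrices without colnames get `<block>_f1..p`.
#' @param validate If `TRUE` (default), stop when [validate_dataset()] reports
#'   any violation.
#'
#' @return An object of class `multiblock_dataset`: a list with elements
#'   `blocks` (named list of numeric matrices), `block_names`, `sample_ids`
#'   (shared row identifiers, order taken from the first block) and
#'   `feature_ids` (per-block column identifiers).
#'
#' @examples
#' x <- multiblock_dataset(list(
#'   rna  = matrix(rnorm(40), 10, 4, dimnames = list(paste0("s", 1:10), paste0("g", 1:4))),
#'   prot = matrix(rnorm(30), 10, 3, dimnames = list(paste0("s", 1:10), paste0("p", 1:3)))
#' ))
#' n_samples(x)
#' @export
multiblock_dataset <- function(blocks, validate = TRUE) {
  if (!is.list(blocks) || length(blocks) < 1L)
    stop("'blocks' must be a non-empty list of matrices")
  nms <- names(blocks)
  if (is.null(nms)) nms <- rep("", length(blocks))
  empty <- !nzchar(nms)
  nms[empty] <- paste0("block", seq_along(blocks))[empty]
  if (anyDuplicated(nms))
    stop("block names must be unique")
  names(blocks) <- nms

  blocks <- lapply(seq_along(blocks), function(k) {
    b <- blocks[[k]]
    if (inherits(b, "Matrix")) b <- as.matrix(b)
    if (is.data.frame(b)) b <- as.matrix(b)
    if (!is.matrix(b) || !is.numeric(b))
      stop(sprintf("block '%s' is not a numeric matrix", nms[k]))
    storage.mode(b) <- "double"
    if (is.null(rownames(b))) rownames(b) <- paste0("sample", seq_len(nrow(b)))
    if (is.null(colnames(b))) colnames(b) <- paste0(nms[k], "_f", seq_len(ncol(b)))
    b
  })
  names(blocks) <- nms

  ref <- rownames(blocks[[1L]])
  if (anyDuplicated(ref))
    stop(sprintf("duplicated sample ids in block '%s'", nms[1L]))
  if (length(blocks) > 1L) {
    for (k in seq_along(blocks)[-1L]) {
      ids <- rownames(blocks[[k]])
      if (anyDuplicated(ids))
        stop(sprintf("duplicated sample ids in block '%s'", nms[k]))
      if (!setequal(ids, ref)) {
        miss  <- setdiff(ref, ids)
        extra <- setdiff(ids, ref)
        stop(sprintf(
          "block '%s': sample ids differ from block '%s' (missing: %s; extra: %s)",
          nms[k], nms[1L],
          if (length(miss)) paste(utils::head(miss, 5L), collapse = ",") else "-",
          if (length(extra)) paste(utils::head(extra, 5L), collapse = ",") else "-"))
      }
      blocks[[k]] <- blocks[[k]][ref, , drop = FALSE]
    }
  }

  x <- structure(
    list(blocks      = blocks,
         block_names = nms,
         sample_ids  = ref,
         feature_ids = lapply(blocks, colnames)),
    class = "multiblock_dataset")
  if (validate) {
    rep <- validate_dataset(x)
    if (length(rep)) stop("invalid multiblock_dataset:\n  ", paste(rep, collapse = "\n  "))
  }
  x
}

#' Validate a multi-block dataset
#'
#' Checks every container invariant and reports all violations: equal row
#' counts and identical sample-id order across blocks, at least one feature
#' per block, unique feature ids within each block, and no non-finite entries
#' (`NA`/`NaN`/`Inf` are rejected, not imputed). Purely a reporting operation;
#' it never throws.
#'
#' @param x A `multiblock_dataset` (or a structurally similar list).
#' @return Character vector of human-readable violations; `character(0)` when
#'   the dataset is valid. Row/column indices in messages are 1-based.
#' @export
validate_dataset <- function(x) {
  out <- character(0)
  if (!is.list(x) || is.null(x$blocks) || length(x$blocks) < 1L)
    return("dataset has no blocks (N >= 1 required)")
  nms <- if (!is.null(x$block_names)) x$block_names else names(x$blocks)
  if (is.null(nms)) nms <- paste0("block", seq_along(x$blocks))
  n <- nrow(x$blocks[[1L]])
  for (k in seq_along(x$blocks)) {
    b <- x$blocks[[k]]
    if (!is.matrix(b) || !is.numeric(b)) {
      out <- c(out, sprintf("block '%s': not a numeric matrix", nms[k]))
      next
    }
    if (ncol(b) < 1L)
      out <- c(out, sprintf("block '%s': zero features (p_k >= 1 required)", nms[k]))
    if (nrow(b) != n)
      out <- c(out, sprintf("block '%s': %d rows but block '%s' has %d (shared-sample requirement)",
                            nms[k], nrow(b), nms[1L], n))
    if (!identical(rownames(b), x$sample_ids) && nrow(b) == n)
      out <- c(out, sprintf("block '%s': sample ids differ from dataset sample_ids or are reordered", nms[k]))
    fid <- colnames(b)
    if (!is.null(fid) && anyDuplicated(fid))
      out <- c(out, sprintf("block '%s': duplicated feature ids within block: %s",
                            nms[k], paste(unique(fid[duplicated(fid)]), collapse = ",")))
    bad <- which(!is.finite(b))
    if (length(bad)) {
      ij <- arrayInd(bad[1L], dim(b))
      out <- c(out, sprintf("block '%s': %d non-finite entries (first at row %d, column %d)",
                            nms[k], length(bad), ij[1L], ij[2L]))
    }
  }
  out
}

#' Column-wise concatenation of all blocks into the global matrix
#'
#' Builds the n x p global matrix (p = sum of block widths) whose columns are
#' the blocks' columns in block order. Feature ids that occur in more than one
#' block are disambiguated as `"<block>::<feature>"`. The column-to-block index
#' map is attached as attribute `"block_map"`, a data frame with 1-based
#' inclusive column ranges per block; slicing the result by those ranges
#' reproduces each input block exactly.
#'
#' @param x A valid `multiblock_dataset`.
#' @return Numeric matrix n x p with attribute `block_map`
#'   (`data.frame(block, start, end)`).
#' @export
concatenate_global <- function(x) {
  rep <- validate_dataset(x)
  if (length(rep)) stop("invalid multiblock_dataset:\n  ", paste(rep, collapse = "\n  "))
  g <- do.call(cbind, x$blocks)
  colnames(g) <- global_feature_ids(x)
  widths <- vapply(x$blocks, ncol, integer(1))
  end <- cumsum(widths)
  map <- data.frame(block = x$block_names,
                    start = end - widths + 1L,
                    end   = end,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(g, "block_map") <- map
  g
}

# Global (concatenated) feature ids, cross-block duplicates namespaced as
# "<block>::<feature>".
global_feature_ids <- function(x) {
  ids <- unlist(x$feature_ids, use.names = FALSE)
  blk <- rep(x$block_names, vapply(x$blocks, ncol, integer(1)))
  dup <- ids %in% ids[duplicated(ids)]
  ids[dup] <- paste0(blk[dup], "::", ids[dup])
  ids
}

#' @rdname multiblock_dataset
#' @export
n_samples <- function(x) length(x$sample_ids)

#' @rdname multiblock_dataset
#' @export
n_blocks <- function(x) length(x$blocks)

#' Subset a multi-block dataset by samples
#'
#' Selects the same samples (rows) from every block; used e.g. for train/test
#' splits before out-of-sample prediction.
#'
#' @param x A `multiblock_dataset`.
#' @param idx Integer, logical or character (sample-id) index vector.
#' @return A `multiblock_dataset` with the selected samples, in `idx` order.
#' @export
subset_samples <- function(x, idx) {
  blocks <- lapply(x$blocks, function(b) b[idx, , drop = FALSE])
  multiblock_dataset(blocks)
}

#' @export
print.multiblock_dataset <- function(x, ...) {
  cat(sprintf("multiblock_dataset: %d samples, %d blocks\n",
              n_samples(x), n_blocks(x)))
  for (k in seq_along(x$blocks))
    cat(sprintf("  %s: %d features\n", x$block_names[k], ncol(x$blocks[[k]])))
  invisible(x)
}

#' Decomposition configuration
#'
#' Bundles the solver options: number of orders R, the deflation mode that
#' selects between MCIA (`"block"`: orthonormal block loadings per block) and
#' CPCA (`"global"`: mutually orthogonal global scores), the convergence
#' tolerance on the relative change of the global score vector, the iteration
#' cap, and the initialization rule.
#'
#' @param num_factors Positive integer R, the embedding dimension.
#' @param deflation `"block"` (MCIA, default) or `"global"` (CPCA).
#' @param tol Positive convergence threshold on
#'   `||f_new - f_old|| / ||f_old||` (default `1e-9`).
#' @param max_iter Iteration cap per order (default 5000); reaching it is
#'   recorded as a warning in the diagnostics, not an error.
#' @param init `"max_variance_column"` (deterministic default: the column of
#'   the concatenated, possibly deflated, global matrix with largest variance)
#'   or `"random"` (seeded standard normal draw).
#' @param seed Integer seed used only when `init = "random"`; `NULL` otherwise.
#' @return An object of class `decomposition_config`.
#' @export
decomposition_config <- function(num_factors = 2L,
                                 deflation = c("block", "global"),
                                 tol = 1e-9,
                                 max_iter = 5000L,
                                 init = c("max_variance_column", "random"),
                                 seed = NULL) {
  deflation <- match.arg(deflation)
  init <- match.arg(init)
  num_factors <- as.integer(num_factors)
  max_iter <- as.integer(max_iter)
  if (is.na(num_factors) || num_factors < 1L) stop("num_factors must be a positive integer")
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  if (is.na(max_iter) || max_iter < 1L) stop("max_iter must be >= 1")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(num_factors = num_factors, deflation = deflation, tol = tol,
                 max_iter = max_iter, init = init, seed = seed),
            class = "decomposition_config")
}
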
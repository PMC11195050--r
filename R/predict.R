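#' Project new samples into a trained global score space
#'
#' Out-of-sample embedding: the new blocks are transformed with the fitted
#' (training) preprocessor — never re-estimated — concatenated in training
#' block order, and multiplied by the trained global loadings:
#' `F_new = X_new_preproc A`. Under block deflation (MCIA) the identity
#' `F = X_preproc A` holds exactly on the training data, so predicting on the
#' training set reproduces the training scores; block-level scores
#' `F_k_new = X_k_new_preproc A_k` are returned as well. Under global
#' deflation (CPCA) the same product is computed but flagged approximate
#' (attribute `"approximate"`), because the training identity does not hold
#' exactly in that mode, and block scores are not returned.
#'
#' @param model An `mb_decomposition` (fresh or read back with
#'   [read_result()]).
#' @param new_data A `multiblock_dataset` whose blocks carry exactly the
#'   training feature ids per block; a missing block or any feature mismatch
#'   is an error naming the offenders.
#' @return An object of class `mb_prediction`: `global_scores_new`
#'   (n_new x R), `block_scores_new` (list of n_new x R matrices, only under
#'   block deflation, otherwise `NULL`), `sample_ids`.
#' @export
predict_global_scores <- function(model, new_data) {
  stopifnot(inherits(model, "mb_decomposition"))
  tr <- apply_preprocessor(model$fitted_preprocessor, new_data)
  Xg <- do.call(cbind, tr$blocks[model$block_names])
  Fg <- Xg %*% model$global_loadings
  dimnames(Fg) <- list(tr$sample_ids, colnames(model$global_scores))

  block_scores <- NULL
  if (model$config$deflation == "block") {
    block_scores <- lapply(model$block_names, function(nm)
      tr$blocks[[nm]] %*% model$block_loadings[[nm]])
    names(block_scores) <- model$block_names
  }
  out <- structure(list(global_scores_new = Fg,
                        block_scores_new  = block_scores,
                        sample_ids        = tr$sample_ids),
                   class = "mb_prediction")
  if (model$config$deflation == "global")
    attr(out, "approximate") <- TRUE
  out
}

#' @export
#' @rdname predict_global_scores
#' @param object,... S3 method interface: `predict(fit, newdata)` forwards to
#'   `predict_global_scores`.
#' @param newdata A `multiblock_dataset` of new samples.
predict.mb_decomposition <- function(object, newdata, ...) {
  predict_global_scores(object, newdata)
}

#' @export
print.mb_prediction <- function(x, ...) {
  cat(sprintf("mb_prediction: %d samples x %d orders%s\n",
              nrow(x$global_scores_new), ncol(x$global_scores_new),
              if (isTRUE(attr(x, "approximate"))) " (approximate: CPCA mode)" else ""))
  invisible(x)
}
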
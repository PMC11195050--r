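# Plain-text interchange: TSV is the canonical dense format (feature ids must
# be tab-safe), MatrixMarket for sparse single-cell style inputs. All numeric
# output is printed with 17 significant digits so write -> read round trips
# are lossless to full double precision.

write_tsv_matrix <- function(m, path, id_col = "id") {
  stopifnot(is.matrix(m))
  chr <- formatC(m, digits = 17, format = "g")
  dim(chr) <- dim(m)
  header <- paste(c(id_col, colnames(m)), collapse = "\t")
  body <- paste(rownames(m), apply(chr, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  m <- vapply(df, as.numeric, numeric(nrow(df)))
  if (nrow(df) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(rownames(df), colnames(df)))
  rownames(m) <- rownames(df)
  m
}

#' Read one data block from disk
#'
#' Dense TSV/CSV (header row of feature ids, first column of sample ids) or
#' sparse MatrixMarket MTX with two sidecar id files. MTX follows the common
#' single-cell convention of features-in-rows and is transposed on load to
#' samples x features; set `features_in_rows = FALSE` if the matrix is already
#' samples x features.
#'
#' @param path File path (`.tsv`/`.csv`/`.mtx`; format inferred from the
#'   extension unless given).
#' @param format `"auto"` (default), `"tsv"`, `"csv"` or `"mtx"`.
#' @param feature_file,sample_file For MTX: one-id-per-line sidecar files for
#'   the feature and sample identifiers.
#' @param features_in_rows For MTX: orientation of the stored matrix
#'   (default `TRUE`).
#' @return Dense numeric matrix, samples x features, with ids as dimnames.
#' @export
read_block <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                       feature_file = NULL, sample_file = NULL,
                       features_in_rows = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format == "mtx") {
    if (is.null(feature_file) || is.null(sample_file))
      stop("mtx requires 'feature_file' and 'sample_file' sidecar id files")
    m <- as.matrix(Matrix::readMM(path))
    feats <- readLines(feature_file)
    samps <- readLines(sample_file)
    if (features_in_rows) m <- t(m)
    if (nrow(m) != length(samps))
      stop(sprintf("mtx shape mismatch: %d samples in matrix vs %d ids in %s",
                   nrow(m), length(samps), sample_file))
    if (ncol(m) != length(feats))
      stop(sprintf("mtx shape mismatch: %d features in matrix vs %d ids in %s",
                   ncol(m), length(feats), feature_file))
    dimnames(m) <- list(samps, feats)
    return(m)
  }
  sep <- if (format == "csv") "," else "\t"
  nf <- utils::count.fields(path, sep = sep, quote = "\"")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                 path, bad, nf[bad], nf[1L]))
  }
  df <- utils::read.table(path, header = TRUE, row.names = 1, sep = sep,
                          check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop(path, ": non-numeric entries after the id column")
  m
}

#' Write a decomposition result (and model artifact) to a directory
#'
#' Serializes everything as open plain-text formats so any toolchain can
#' consume it: `global_scores.tsv`, `global_loadings.tsv`, per-block
#' `block_scores_<name>.tsv` / `block_loadings_<name>.tsv`,
#' `eigenvalues.tsv`, `block_weights.tsv`, `variance_explained.tsv`,
#' `preprocessor.json` (fitted centers/scales/block scalars) and
#' `metadata.json` (configs, convergence diagnostics, package version). The
#' directory doubles as the saved model consumed by `predict`:
#' [read_result()] reconstructs a predict-capable `mb_decomposition`.
#'
#' @param result An `mb_decomposition`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the character vector of files written (the manifest).
#' @export
write_result <- function(result, out_dir) {
  stopifnot(inherits(result, "mb_decomposition"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  fp <- function(x) file.path(out_dir, x)
  manifest <- character(0)
  put <- function(m, name, id_col = "id") {
    write_tsv_matrix(m, fp(name), id_col)
    manifest <<- c(manifest, name)
  }

  put(result$global_scores, "global_scores.tsv", "sample_id")
  put(result$global_loadings, "global_loadings.tsv", "feature_id")
  for (nm in result$block_names) {
    put(result$block_scores[[nm]], sprintf("block_scores_%s.tsv", nm), "sample_id")
    put(result$block_loadings[[nm]], sprintf("block_loadings_%s.tsv", nm), "feature_id")
  }
  put(matrix(result$eigenvalues, ncol = 1,
             dimnames = list(names(result$eigenvalues), "eigenvalue")),
      "eigenvalues.tsv", "order")
  put(result$block_weights, "block_weights.tsv", "block")
  ve <- variance_explained(result)
  put(matrix(ve, ncol = 1, dimnames = list(names(ve), "proportion")),
      "variance_explained.tsv", "order")

  pre <- result$fitted_preprocessor
  pre_json <- list(
    config = unclass(pre$config),
    block_names = pre$block_names,
    blocks = lapply(pre$blocks, function(bp) {
      bp$centers <- as.list(bp$centers); bp$scales <- as.list(bp$scales)
      if (!is.null(bp$row_masses)) bp$row_masses <- as.list(bp$row_masses)
      if (!is.null(bp$col_masses)) bp$col_masses <- as.list(bp$col_masses)
      bp
    }))
  jsonlite::write_json(pre_json, fp("preprocessor.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- c(manifest, "preprocessor.json")

  diag <- lapply(result$per_order, function(s)
    list(n_iter = s$n_iter, converged = s$converged,
         final_rel_change = s$final_rel_change, eigenvalue = s$eigenvalue))
  meta <- list(
    package = "mbmcia",
    version = as.character(utils::packageVersion("mbmcia")),
    config = unclass(result$config),
    preproc = unclass(result$preproc),
    block_names = result$block_names,
    n_samples = length(result$sample_ids),
    num_orders = ncol(result$global_scores),
    convergence = diag)
  jsonlite::write_json(meta, fp("metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- c(manifest, "metadata.json")

  invisible(manifest)
}

#' Read a decomposition result / model artifact back
#'
#' Inverse of [write_result()]: reconstructs an `mb_decomposition` (without
#' the per-iteration traces) that reproduces every matrix to full double
#' precision and can be passed to [predict_global_scores()].
#'
#' @param dir Directory written by [write_result()].
#' @return An `mb_decomposition`.
#' @export
read_result <- function(dir) {
  fp <- function(x) file.path(dir, x)
  if (!file.exists(fp("metadata.json"))) stop("not a result directory: ", dir)
  meta <- jsonlite::read_json(fp("metadata.json"), simplifyVector = TRUE)
  pre_json <- jsonlite::read_json(fp("preprocessor.json"), simplifyVector = TRUE)

  cfg <- decomposition_config(
    num_factors = meta$config$num_factors,
    deflation = meta$config$deflation,
    tol = meta$config$tol,
    max_iter = meta$config$max_iter,
    init = meta$config$init,
    seed = if (is.null(meta$config$seed)) NULL else meta$config$seed)
  ppc <- preprocess_config(meta$preproc$column_method, meta$preproc$block_method)

  blocks_pre <- lapply(pre_json$blocks, function(bp) {
    out <- list(centers = unlist(bp$centers), scales = unlist(bp$scales),
                zero_variance = as.character(unlist(bp$zero_variance)),
                block_scalar = bp$block_scalar)
    if (!is.null(bp$grand_total)) {
      out$grand_total <- bp$grand_total
      out$row_masses <- unlist(bp$row_masses)
      out$col_masses <- unlist(bp$col_masses)
    }
    out
  })
  names(blocks_pre) <- pre_json$block_names

  block_names <- meta$block_names
  gs <- read_tsv_matrix(fp("global_scores.tsv"))
  gl <- read_tsv_matrix(fp("global_loadings.tsv"))
  bs <- lapply(block_names, function(nm) read_tsv_matrix(fp(sprintf("block_scores_%s.tsv", nm))))
  bl <- lapply(block_names, function(nm) read_tsv_matrix(fp(sprintf("block_loadings_%s.tsv", nm))))
  names(bs) <- names(bl) <- block_names
  W <- read_tsv_matrix(fp("block_weights.tsv"))
  lam <- drop(read_tsv_matrix(fp("eigenvalues.tsv")))
  lam <- stats::setNames(as.numeric(lam), colnames(gs))

  fitted <- structure(list(config = ppc,
                           block_names = block_names,
                           feature_ids = lapply(bl, rownames),
                           blocks = blocks_pre),
                      class = "fitted_preprocessor")

  structure(list(global_scores = gs,
                 global_loadings = gl,
                 block_scores = bs,
                 block_loadings = bl,
                 block_weights = W,
                 eigenvalues = lam,
                 fitted_preprocessor = fitted,
                 config = cfg,
                 preproc = ppc,
                 per_order = NULL,
                 block_names = block_names,
                 sample_ids = rownames(gs),
                 feature_ids = lapply(bl, rownames)),
            class = "mb_decomposition")
}
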
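#' Read an expression dataset from file
#'
#' Supported formats:
#' \describe{
#'   \item{`csv`}{dense matrix, cells as rows; first column `cell_id`, header
#'     = gene names. Per-cell annotations are read from a sidecar
#'     `<stem>_obs.csv` (columns `cell_id` plus the condition / cell-type
#'     keys) when present.}
#'   \item{`mtx`}{a directory holding `matrix.mtx` (genes x cells,
#'     MatrixMarket), `features.tsv`, `barcodes.tsv` and an optional
#'     `obs.tsv` annotation table.}
#'   \item{`h5ad`}{AnnData file; read through the bundled Python bridge
#'     (requires a `python` with the `anndata` package on `PATH`).}
#' }
#'
#' Arbitrary condition labels (e.g. `"stimulated"` / `"ctrl"`) are mapped
#' onto the canonical `{control, perturbed}` pair via `control_label` /
#' `perturbed_label`.
#'
#' @param path file (csv/h5ad) or directory (mtx) to read.
#' @param format one of `"auto"`, `"csv"`, `"mtx"`, `"h5ad"`; `"auto"` picks
#'   by extension (directory implies `mtx`).
#' @param condition_key name of the per-cell annotation column holding the
#'   condition label.
#' @param control_label,perturbed_label values of `condition_key` mapped to
#'   `"control"` / `"perturbed"`.
#' @param cell_type_key name of the per-cell annotation column holding the
#'   cell type (optional in the file).
#' @param require_condition error if no condition annotation is found
#'   (default `TRUE`; a dataset without condition cannot be used for
#'   training).
#' @return an [expression_dataset()].
#' @export
read_dataset <- function(path,
                         format = c("auto", "csv", "mtx", "h5ad"),
                         condition_key = "condition",
                         control_label = "control",
                         perturbed_label = "perturbed",
                         cell_type_key = "cell_type",
                         require_condition = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx"
    else switch(tolower(tools::file_ext(path)),
                csv = "csv", h5ad = "h5ad",
                stop("cannot infer format from path: ", path))
  }
  if (format != "mtx" && !file.exists(path)) stop("file not found: ", path)
  parts <- switch(format,
    csv = .read_csv_parts(path),
    mtx = .read_mtx_parts(path),
    h5ad = .read_h5ad_parts(path))
  obs <- parts$obs
  condition <- NULL
  cell_type <- NULL
  if (!is.null(obs)) {
    if (condition_key %in% names(obs)) {
      raw <- as.character(obs[[condition_key]])
      condition <- ifelse(raw == control_label, "control",
                          ifelse(raw == perturbed_label, "perturbed", raw))
    }
    if (cell_type_key %in% names(obs)) {
      cell_type <- as.character(obs[[cell_type_key]])
    }
  }
  if (is.null(condition) && require_condition) {
    stop("no '", condition_key, "' annotation found in ", path,
         "; supply it or set require_condition = FALSE")
  }
  expression_dataset(parts$matrix, parts$cell_ids, parts$gene_names,
                     condition = condition, cell_type = cell_type)
}

#' Write an expression dataset to file
#'
#' Inverse of [read_dataset()]; the same three formats are supported and the
#' csv/h5ad round trips preserve matrix values exactly.
#'
#' @param data an [expression_dataset()].
#' @param path output file (csv/h5ad) or directory (mtx; created).
#' @param format `"csv"`, `"mtx"` or `"h5ad"` (`"auto"` = by extension).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, format = c("auto", "csv", "mtx", "h5ad")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", h5ad = "h5ad", "mtx")
  }
  switch(format,
    csv = .write_csv_parts(data, path),
    mtx = .write_mtx_parts(data, path),
    h5ad = .write_h5ad_parts(data, path))
  invisible(path)
}

.obs_frame <- function(data) {
  df <- data.frame(cell_id = data$cell_ids, stringsAsFactors = FALSE)
  if (!is.null(data$condition)) df$condition <- as.character(data$condition)
  if (!is.null(data$cell_type)) df$cell_type <- data$cell_type
  df
}

.read_csv_parts <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  cell_ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  obs_path <- paste0(tools::file_path_sans_ext(path), "_obs.csv")
  obs <- if (file.exists(obs_path)) {
    o <- data.table::fread(obs_path, header = TRUE, data.table = FALSE)
    o[match(cell_ids, as.character(o$cell_id)), , drop = FALSE]
  }
  list(matrix = unname(m), cell_ids = cell_ids,
       gene_names = colnames(dt)[-1], obs = obs)
}

.write_csv_parts <- function(data, path) {
  m <- as_dense(data)
  df <- data.frame(cell_id = data$cell_ids, m, check.names = FALSE)
  colnames(df) <- c("cell_id", data$gene_names)
  data.table::fwrite(df, path)
  obs <- .obs_frame(data)
  if (ncol(obs) > 1) {
    data.table::fwrite(obs, paste0(tools::file_path_sans_ext(path), "_obs.csv"))
  }
}

.read_mtx_parts <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("matrix.mtx not found in ", dir)
  m <- Matrix::t(Matrix::readMM(mtx))  # stored genes x cells, 10x convention
  gene_names <- data.table::fread(file.path(dir, "features.tsv"),
                                  header = FALSE)[[1]]
  cell_ids <- data.table::fread(file.path(dir, "barcodes.tsv"),
                                header = FALSE)[[1]]
  obs_path <- file.path(dir, "obs.tsv")
  obs <- if (file.exists(obs_path)) {
    o <- data.table::fread(obs_path, header = TRUE, data.table = FALSE)
    o[match(cell_ids, as.character(o$cell_id)), , drop = FALSE]
  }
  list(matrix = methods::as(m, "CsparseMatrix"),
       cell_ids = as.character(cell_ids),
       gene_names = as.character(gene_names), obs = obs)
}

.write_mtx_parts <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(Matrix::t(data$matrix),
                                              sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(data$gene_names, file.path(dir, "features.tsv"))
  writeLines(data$cell_ids, file.path(dir, "barcodes.tsv"))
  obs <- .obs_frame(data)
  if (ncol(obs) > 1) {
    data.table::fwrite(obs, file.path(dir, "obs.tsv"), sep = "\t")
  }
}

.python_bin <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("h5ad support requires a `python` interpreter with the anndata ",
       "package; none found on PATH")
}

.h5ad_bridge <- function(args) {
  script <- system.file("python", "h5ad_bridge.py", package = "perturbAttn")
  if (!nzchar(script)) {  # running from a source checkout
    script <- file.path("inst", "python", "h5ad_bridge.py")
  }
  out <- system2(.python_bin(), c(script, args), stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("h5ad bridge failed: ", paste(out, collapse = "\n"))
  }
  invisible(out)
}

.read_h5ad_parts <- function(path) {
  tmp <- tempfile("h5ad_export_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  .h5ad_bridge(c("export", path, tmp))
  parts <- .read_csv_parts(file.path(tmp, "X.csv"))
  obs_path <- file.path(tmp, "obs.csv")
  if (file.exists(obs_path)) {
    o <- data.table::fread(obs_path, header = TRUE, data.table = FALSE)
    parts$obs <- o[match(parts$cell_ids, as.character(o$cell_id)), ,
                   drop = FALSE]
  }
  parts
}

.write_h5ad_parts <- function(data, path) {
  tmp <- tempfile("h5ad_import_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  .write_csv_parts(data, file.path(tmp, "X.csv"))
  .h5ad_bridge(c("import", path, tmp))
}

#' Normalize an expression dataset
#'
#' Standard single-cell preprocessing: per-cell library-size scaling to
#' `target_sum`, optional `log(1 + x)` transform, optional reduction to the
#' `n_hvg` most highly variable genes (dispersion = variance / mean on the
#' size-scaled matrix). Cells whose counts sum to zero cannot be scaled;
#' they are kept as all-zero rows with a warning.
#'
#' @param data an [expression_dataset()] of non-negative values.
#' @param target_sum per-cell total after scaling (default `1e4`).
#' @param log1p apply `log1p` after scaling (default `TRUE`).
#' @param n_hvg optional number of highly variable genes to retain.
#' @return a normalized [expression_dataset()].
#' @export
normalize_dataset <- function(data, target_sum = 1e4, log1p = TRUE,
                              n_hvg = NULL) {
  stopifnot(target_sum > 0)
  m <- as_dense(data)
  libs <- rowSums(m)
  zero <- libs == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total counts kept as zeros: ",
            paste(utils::head(data$cell_ids[zero], 3), collapse = ", "))
    libs[zero] <- 1
  }
  scaled <- m * (target_sum / libs)
  if (!is.null(n_hvg) && n_hvg < ncol(scaled)) {
    mu <- colMeans(scaled)
    v <- apply(scaled, 2, stats::var)
    disp <- ifelse(mu > 0, v / mu, 0)
    keep <- sort(order(disp, decreasing = TRUE)[seq_len(n_hvg)])
  } else {
    keep <- seq_len(ncol(scaled))
  }
  out <- scaled[, keep, drop = FALSE]
  if (log1p) out <- log1p(out)
  expression_dataset(out, data$cell_ids, data$gene_names[keep],
                     condition = data$condition, cell_type = data$cell_type)
}

#' Hold out one cell type's perturbed cells
#'
#' Implements the out-of-sample evaluation split: all perturbed cells of
#' `target_type` are withheld as ground truth, its control cells become the
#' query set, and everything else (all control cells plus the other types'
#' perturbed cells) forms the training set. The query cells are also kept in
#' the training partition, mirroring the protocol in which only the
#' perturbed half of the target type is removed.
#'
#' @param data an [expression_dataset()] with `cell_type` and `condition`.
#' @param target_type the cell type whose perturbation response is withheld.
#' @return an object of class `holdout_split`: list with `train`, `query`
#'   (control cells of the target type) and `truth` (its withheld perturbed
#'   cells).
#' @export
split_holdout <- function(data, target_type) {
  if (is.null(data$cell_type)) stop("split_holdout requires cell_type")
  if (is.null(data$condition)) stop("split_holdout requires condition")
  is_target <- data$cell_type == target_type
  if (!any(is_target)) stop("cell type not present: ", target_type)
  is_ptb <- data$condition == "perturbed"
  if (!any(is_target & is_ptb)) {
    stop("cell type '", target_type, "' has no perturbed cells to hold out")
  }
  if (!any(is_target & !is_ptb)) {
    stop("cell type '", target_type, "' has no control cells to query with")
  }
  structure(list(
    train = subset_cells(data, !(is_target & is_ptb)),
    query = subset_cells(data, is_target & !is_ptb),
    truth = subset_cells(data, is_target & is_ptb),
    target_type = target_type), class = "holdout_split")
}

#' @export
print.holdout_split <- function(x, ...) {
  cat("<holdout_split> target:", x$target_type,
      "| train:", n_cells(x$train),
      "query:", n_cells(x$query),
      "truth:", n_cells(x$truth), "cells\n")
  invisible(x)
}

.check_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer(seed)
}

#' Nested downsampling of a dataset
#'
#' For each cell type (stratified within condition so both levels survive),
#' draws nested subsets at the requested fractions: the cells kept at a
#' smaller fraction are always contained in every larger fraction's subset.
#' Fraction 1 returns all cells. Deterministic given `seed`.
#'
#' @param data an [expression_dataset()]; `cell_type` may be absent, in which
#'   case all cells form one stratum per condition.
#' @param fractions numeric vector in (0, 1], sorted ascending.
#' @param seed integer seed.
#' @return a named list of [expression_dataset()]s, one per fraction.
#' @export
downsample_nested <- function(data, fractions = c(0.2, 0.4, 0.6, 0.8, 1.0),
                              seed = 1L) {
  if (any(fractions <= 0) || any(fractions > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  if (is.unsorted(fractions)) stop("fractions must be sorted ascending")
  seed <- .check_seed(seed)
  type <- if (is.null(data$cell_type)) rep("all", n_cells(data)) else
    data$cell_type
  cond <- if (is.null(data$condition)) rep("all", n_cells(data)) else
    as.character(data$condition)
  stratum <- paste(type, cond, sep = "\r")
  orders <- local({
    set.seed(seed)
    lapply(split(seq_len(n_cells(data)), stratum), function(idx) {
      idx[sample.int(length(idx))]
    })
  })
  out <- lapply(fractions, function(f) {
    keep <- sort(unlist(lapply(orders, function(perm) {
      perm[seq_len(max(1L, round(f * length(perm))))]
    }), use.names = FALSE))
    subset_cells(data, keep)
  })
  names(out) <- format(fractions)
  out
}

#' Inject dropout-style noise
#'
#' Sets exactly `floor(proportion * Z)` of the `Z` non-zero matrix entries to
#' zero, chosen uniformly without replacement; existing zeros are untouched.
#' Emulates aggravated technical dropout for robustness analysis.
#'
#' @param data an [expression_dataset()].
#' @param proportion fraction of non-zero entries to zero out, in \[0, 1\].
#' @param seed integer seed.
#' @return an [expression_dataset()] with the noised matrix.
#' @export
inject_dropout_noise <- function(data, proportion, seed = 1L) {
  if (proportion < 0 || proportion > 1) stop("proportion must be in [0, 1]")
  seed <- .check_seed(seed)
  m <- as_dense(data)
  nz <- which(m != 0)
  k <- floor(proportion * length(nz))
  if (k > 0) {
    hit <- local({
      set.seed(seed)
      nz[sample.int(length(nz), k)]
    })
    m[hit] <- 0
  }
  expression_dataset(m, data$cell_ids, data$gene_names,
                     condition = data$condition, cell_type = data$cell_type)
}
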
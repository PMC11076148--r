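#' Construct an expression dataset
#'
#' The central container of the package: a cells x genes matrix of
#' non-negative expression values together with per-cell annotations.
#' The `condition` annotation distinguishes unperturbed (`"control"`) from
#' perturbed (`"perturbed"`) cells; `cell_type` is optional metadata that is
#' only needed for hold-out splitting and evaluation, never for model
#' training or prediction.
#'
#' @param matrix numeric cells x genes matrix (base matrix or a
#'   `Matrix` sparse matrix); all entries must be finite and non-negative.
#' @param cell_ids character vector of unique cell identifiers, one per row.
#' @param gene_names character vector of unique gene names, one per column.
#' @param condition optional factor/character per cell; levels must be within
#'   `c("control", "perturbed")`.
#' @param cell_type optional character per cell.
#'
#' @return An object of class `expression_dataset`: a list with fields
#'   `matrix`, `cell_ids`, `gene_names`, `condition`, `cell_type`.
#' @export
expression_dataset <- function(matrix, cell_ids, gene_names,
                               condition = NULL, cell_type = NULL) {
  if (!is.matrix(matrix) && !methods::is(matrix, "Matrix")) {
    stop("`matrix` must be a base matrix or a Matrix sparse matrix")
  }
  if (!is.null(condition)) {
    condition <- as.character(condition)
    bad <- setdiff(unique(condition), c("control", "perturbed"))
    if (length(bad) > 0) {
      stop("unknown condition label(s): ", paste(bad, collapse = ", "),
           " (map labels via read_dataset()'s control_label/perturbed_label)")
    }
    condition <- factor(condition, levels = c("control", "perturbed"))
  }
  if (!is.null(cell_type)) cell_type <- as.character(cell_type)
  obj <- structure(
    list(matrix = matrix,
         cell_ids = as.character(cell_ids),
         gene_names = as.character(gene_names),
         condition = condition,
         cell_type = cell_type),
    class = "expression_dataset")
  validate_expression_dataset(obj)
  obj
}

#' Validate an expression dataset
#'
#' Checks the container invariants: dimension/annotation alignment, unique
#' identifiers, and finite non-negative entries. Offending cells are named in
#' the error message.
#'
#' @param data an `expression_dataset`.
#' @return `data`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_dataset <- function(data) {
  m <- data$matrix
  n <- nrow(m)
  if (length(data$cell_ids) != n) {
    stop("cell_ids length (", length(data$cell_ids),
         ") does not match matrix rows (", n, ")")
  }
  if (length(data$gene_names) != ncol(m)) {
    stop("gene_names length does not match matrix columns")
  }
  if (anyDuplicated(data$cell_ids)) stop("cell_ids must be unique")
  if (anyDuplicated(data$gene_names)) stop("gene_names must be unique")
  if (!is.null(data$condition) && length(data$condition) != n) {
    stop("condition length does not match matrix rows")
  }
  if (!is.null(data$cell_type) && length(data$cell_type) != n) {
    stop("cell_type length does not match matrix rows")
  }
  vals <- if (methods::is(m, "sparseMatrix")) m@x else m
  if (length(vals) && (anyNA(vals) || any(!is.finite(vals)))) {
    bad <- unique(data$cell_ids[unique(which(
      rowSums(!is.finite(as_dense(data))) > 0))])
    stop("non-finite entries in cells: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (length(vals) && any(vals < 0)) {
    bad <- unique(data$cell_ids[which(rowSums(as_dense(data) < 0) > 0)])
    stop("negative entries in cells: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(data)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", n_cells(x), " cells x ", n_genes(x), " genes\n",
      sep = "")
  if (!is.null(x$condition)) {
    tb <- table(x$condition)
    cat("  condition: ", paste(names(tb), tb, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  if (!is.null(x$cell_type)) {
    cat("  cell types: ", paste(sort(unique(x$cell_type)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of cells / genes in a dataset
#' @param data an `expression_dataset`.
#' @return integer count.
#' @export
n_cells <- function(data) nrow(data$matrix)

#' @rdname n_cells
#' @export
n_genes <- function(data) ncol(data$matrix)

#' Dense matrix view of a dataset
#'
#' Operations are defined on values, not storage layout; this returns the
#' dense base-matrix view used by the numerical core.
#'
#' @param data an `expression_dataset`.
#' @return a base numeric matrix.
#' @export
as_dense <- function(data) {
  m <- data$matrix
  if (is.matrix(m)) m else as.matrix(m)
}

#' Subset a dataset by cell index
#' @param data an `expression_dataset`.
#' @param idx integer or logical index over cells.
#' @return an `expression_dataset` with the selected cells.
#' @export
subset_cells <- function(data, idx) {
  expression_dataset(
    matrix = data$matrix[idx, , drop = FALSE],
    cell_ids = data$cell_ids[idx],
    gene_names = data$gene_names,
    condition = if (is.null(data$condition)) NULL else
      as.character(data$condition)[idx],
    cell_type = if (is.null(data$cell_type)) NULL else data$cell_type[idx])
}

#' Subset a dataset by gene index
#' @param data an `expression_dataset`.
#' @param idx integer, logical or character index over genes.
#' @return an `expression_dataset` with the selected genes.
#' @export
subset_genes <- function(data, idx) {
  if (is.character(idx)) {
    miss <- setdiff(idx, data$gene_names)
    if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
    idx <- match(idx, data$gene_names)
  }
  expression_dataset(
    matrix = data$matrix[, idx, drop = FALSE],
    cell_ids = data$cell_ids,
    gene_names = data$gene_names[idx],
    condition = data$condition,
    cell_type = data$cell_type)
}
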
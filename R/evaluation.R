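#' Exact 1-D Wasserstein-1 distance between empirical samples
#'
#' Integral of the absolute difference of the two empirical quantile
#' functions; for equal sample sizes this reduces to the mean absolute
#' difference of the sorted samples.
#'
#' @param x,y non-empty numeric samples.
#' @return a non-negative number.
#' @export
wasserstein_1d <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  if (length(x) == length(y)) {
    return(mean(abs(sort(x) - sort(y))))
  }
  all_v <- sort(c(x, y))
  d <- diff(all_v)
  sx <- sort(x); sy <- sort(y)
  cdf_x <- findInterval(all_v[-length(all_v)], sx) / length(x)
  cdf_y <- findInterval(all_v[-length(all_v)], sy) / length(y)
  sum(abs(cdf_x - cdf_y) * d)
}

#' Mean per-gene Wasserstein distance between two populations
#'
#' The distributional distance used to compare a predicted and a true
#' perturbed population: the 1-D Wasserstein-1 distance per gene, averaged
#' over the gene subset.
#'
#' @param pred,truth [expression_dataset()]s sharing gene names.
#' @param genes optional character vector of genes to restrict to (e.g. the
#'   top differentially expressed genes); default all shared genes.
#' @return a non-negative number.
#' @export
distribution_distance <- function(pred, truth, genes = NULL) {
  if (!identical(pred$gene_names, truth$gene_names)) {
    stop("pred and truth must share the same gene names (in order)")
  }
  if (is.null(genes)) genes <- pred$gene_names
  miss <- setdiff(genes, pred$gene_names)
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  idx <- match(genes, pred$gene_names)
  mp <- as_dense(pred); mt <- as_dense(truth)
  mean(vapply(idx, function(j) wasserstein_1d(mp[, j], mt[, j]), numeric(1)))
}

#' R-squared of per-gene summary statistics
#'
#' Computes the chosen statistic (mean or variance across cells) per gene in
#' both datasets and returns the coefficient of determination of the
#' ordinary least-squares regression of the true statistic on the predicted
#' one (equal to squared Pearson correlation in simple regression). A
#' zero-variance predictor has no explanatory power: the return value is 0
#' flagged with attribute `degenerate = TRUE`.
#'
#' @param pred,truth [expression_dataset()]s sharing gene names (>= 2 genes).
#' @param statistic `"mean"` or `"variance"`.
#' @return a number <= 1.
#' @export
expression_r2 <- function(pred, truth, statistic = c("mean", "variance")) {
  statistic <- match.arg(statistic)
  if (!identical(pred$gene_names, truth$gene_names)) {
    stop("pred and truth must share the same gene names (in order)")
  }
  if (n_genes(pred) < 2) stop("need at least 2 genes")
  f <- switch(statistic,
              mean = colMeans,
              variance = function(m) apply(m, 2, stats::var))
  xp <- f(as_dense(pred))
  xt <- f(as_dense(truth))
  if (stats::var(xp) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  if (stats::var(xt) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  stats::cor(xp, xt)^2
}

#' Rank genes by Wilcoxon rank-sum differential expression
#'
#' Per gene, the two-sided Wilcoxon rank-sum z statistic (normal
#' approximation with tie correction) comparing `group_a` vs `group_b`
#' across cells. Genes are ordered by decreasing `|z|`, ties broken by gene
#' name; the top `k` are returned.
#'
#' @param group_a,group_b [expression_dataset()]s sharing gene names, each
#'   with at least 2 cells.
#' @param k number of genes to return (<= gene count).
#' @return character vector of `k` gene names, most differential first, with
#'   the full score table (gene, z, abs_z) as attribute `scores`.
#' @export
rank_degs <- function(group_a, group_b, k = 100) {
  if (!identical(group_a$gene_names, group_b$gene_names)) {
    stop("groups must share the same gene names (in order)")
  }
  if (n_cells(group_a) < 2 || n_cells(group_b) < 2) {
    stop("each group needs at least 2 cells")
  }
  if (k > n_genes(group_a)) {
    stop("k (", k, ") exceeds the gene count (", n_genes(group_a), ")")
  }
  z <- wilcoxon_z(as_dense(group_a), as_dense(group_b))
  ord <- order(-abs(z), group_a$gene_names)
  scores <- data.frame(gene = group_a$gene_names, z = z, abs_z = abs(z))
  structure(group_a$gene_names[ord][seq_len(k)], scores = scores)
}

#' Column-wise Wilcoxon rank-sum z statistics
#'
#' The workhorse behind [rank_degs()]: for each column (gene), ranks the
#' pooled values of the two groups and forms
#' `z = (R1 - n1 (N + 1) / 2) / sqrt(n1 n2 / 12 ((N + 1) - T))` where `R1`
#' is the rank sum of group A and `T = sum(t^3 - t) / (N (N - 1))` the tie
#' correction.
#'
#' @param a,b numeric matrices with equal column counts (cells x genes).
#' @return numeric vector of signed z statistics (positive = higher in `a`).
#' @export
wilcoxon_z <- function(a, b) {
  n1 <- nrow(a); n2 <- nrow(b); N <- n1 + n2
  vapply(seq_len(ncol(a)), function(j) {
    r <- rank(c(a[, j], b[, j]))
    R1 <- sum(r[seq_len(n1)])
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (v <= 0) return(0)
    (R1 - n1 * (N + 1) / 2) / sqrt(v)
  }, numeric(1))
}

#' Size of the intersection of two top-k gene lists
#'
#' @param pred_degs,true_degs character vectors of equal length `k`.
#' @return integer in \[0, k\].
#' @export
common_deg_count <- function(pred_degs, true_degs) {
  if (length(pred_degs) != length(true_degs)) {
    stop("both lists must have the same length")
  }
  length(intersect(as.character(pred_degs), as.character(true_degs)))
}

#' Evaluate a predicted perturbation response against ground truth
#'
#' Assembles the full report for one hold-out experiment. The anchor set of
#' top differentially expressed genes for the Wasserstein metric is computed
#' from ground truth (control vs truth); predicted DEGs come from control vs
#' prediction, and the overlap of the two top-`n_degs` lists is reported.
#'
#' @param pred predicted perturbed population ([expression_dataset()]).
#' @param truth withheld true perturbed population.
#' @param control the matching control population (the query cells).
#' @param n_degs size of the differential-expression anchor set (default
#'   100, capped at the gene count).
#' @return an object of class `evaluation_report`: list with
#'   `wasserstein_all_genes`, `wasserstein_top_degs`, `r2_mean`,
#'   `r2_variance`, `n_common_degs`, `n_degs`, the DEG lists, and a
#'   `per_gene_table` data frame (true/predicted mean and variance plus DEG
#'   ranks per gene).
#' @export
evaluate_holdout <- function(pred, truth, control, n_degs = 100) {
  for (d in list(truth, control)) {
    if (!identical(pred$gene_names, d$gene_names)) {
      stop("pred, truth and control must share the same gene names")
    }
  }
  k <- min(n_degs, n_genes(pred))
  true_degs <- rank_degs(control, truth, k = k)
  pred_degs <- rank_degs(control, pred, k = k)
  mt <- as_dense(truth); mp <- as_dense(pred)
  true_rank_all <- attr(true_degs, "scores")
  pred_rank_all <- attr(pred_degs, "scores")
  rank_of <- function(scores) {
    ord <- order(-scores$abs_z, scores$gene)
    r <- integer(nrow(scores)); r[ord] <- seq_len(nrow(scores)); r
  }
  per_gene <- data.frame(
    gene = pred$gene_names,
    mean_true = colMeans(mt),
    mean_pred = colMeans(mp),
    var_true = apply(mt, 2, stats::var),
    var_pred = apply(mp, 2, stats::var),
    deg_rank_true = rank_of(true_rank_all),
    deg_rank_pred = rank_of(pred_rank_all),
    row.names = NULL)
  structure(list(
    wasserstein_all_genes = distribution_distance(pred, truth),
    wasserstein_top_degs = distribution_distance(pred, truth,
                                                 genes = true_degs),
    r2_mean = as.numeric(expression_r2(pred, truth, "mean")),
    r2_variance = as.numeric(expression_r2(pred, truth, "variance")),
    n_common_degs = common_deg_count(pred_degs, true_degs),
    n_degs = k,
    true_degs = as.character(true_degs),
    pred_degs = as.character(pred_degs),
    per_gene_table = per_gene), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n",
      "  Wasserstein (all genes):     ", signif(x$wasserstein_all_genes, 5), "\n",
      "  Wasserstein (top ", x$n_degs, " DEGs): ",
      signif(x$wasserstein_top_degs, 5), "\n",
      "  R2 mean:                     ", signif(x$r2_mean, 5), "\n",
      "  R2 variance:                 ", signif(x$r2_variance, 5), "\n",
      "  common DEGs (top ", x$n_degs, "):      ", x$n_common_degs, "\n",
      sep = "")
  invisible(x)
}
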
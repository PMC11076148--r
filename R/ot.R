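#' Euclidean cost matrix between two point sets
#'
#' `C[i, j] = ||A[i, ] - B[j, ]||_2`, the transport cost between control cell
#' `i` and perturbed cell `j` in latent space.
#'
#' @param A n x d matrix (e.g. control latents); a `latent_set` is accepted.
#' @param B m x d matrix (e.g. perturbed latents).
#' @return an n x m non-negative matrix.
#' @export
cost_matrix <- function(A, B) {
  if (inherits(A, "latent_set")) A <- A$Z
  if (inherits(B, "latent_set")) B <- B$Z
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) {
    stop("dimension mismatch: ", ncol(A), " vs ", ncol(B), " columns")
  }
  sq <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(sq, 0))
}

.logsumexp_rows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Entropic optimal transport via Sinkhorn scaling
#'
#' Solves `min_M <M, C>_F + eps * H(M)` subject to `M 1 = a`, `M^T 1 = b`,
#' `M >= 0` by the Sinkhorn fixed point `u = a / (K v)`, `v = b / (K^T u)`
#' with `K = exp(-C / eps)`, returning `M = Diag(u) K Diag(v)`. Marginals
#' default to uniform (`1/n`, `1/m`), the modelling assumption for unpaired
#' cell populations. When `max(C)/eps` is large the plain iteration
#' underflows, so the solver switches automatically to log-domain updates on
#' the dual potentials, with geometric epsilon-scaling (warm-started
#' potentials) so that very small `eps` still converges quickly.
#'
#' @param C n x m finite cost matrix.
#' @param a,b marginal weight vectors (non-negative, summing to 1); default
#'   uniform.
#' @param epsilon entropic regularization strength; default
#'   `0.05 * median(C)` (cost-scale adaptive).
#' @param max_iter maximum Sinkhorn iterations (per epsilon level).
#' @param tol convergence tolerance on the worst marginal violation
#'   (infinity norm).
#' @param log_domain force (`TRUE`) or forbid (`FALSE`) log-domain updates;
#'   `NULL` (default) decides by `max(C)/epsilon > 30`.
#' @return an object of class `coupling_result`: list with the plan `M`,
#'   scalings `u`, `v`, the cost matrix `C`, `epsilon`, `n_iter`,
#'   `marginal_error`, `transport_cost` (`<M, C>_F`, the entropic Wasserstein
#'   objective) and a `converged` flag. Non-convergence at `max_iter` yields
#'   a warning, not an error.
#' @export
sinkhorn <- function(C, a = NULL, b = NULL, epsilon = NULL,
                     max_iter = 5000, tol = 1e-8, log_domain = NULL) {
  C <- as.matrix(C)
  if (any(!is.finite(C))) stop("cost matrix must be finite")
  n <- nrow(C); m <- ncol(C)
  if (is.null(a)) a <- rep(1 / n, n)
  if (is.null(b)) b <- rep(1 / m, m)
  stopifnot(length(a) == n, length(b) == m, all(a >= 0), all(b >= 0))
  if (abs(sum(a) - 1) > 1e-8 || abs(sum(b) - 1) > 1e-8) {
    stop("marginals must each sum to 1")
  }
  if (is.null(epsilon)) {
    epsilon <- 0.05 * stats::median(C)
    if (epsilon <= 0) epsilon <- 1e-3
  }
  stopifnot(epsilon > 0)
  use_log <- if (is.null(log_domain)) max(C) / epsilon > 30 else
    isTRUE(log_domain)

  if (!use_log) {
    K <- exp(-C / epsilon)
    u <- rep(1, n); v <- rep(1, m)
    it <- 0; err <- Inf
    while (it < max_iter) {
      it <- it + 1
      u <- a / (K %*% v)[, 1]
      v <- b / (crossprod(K, u))[, 1]
      if (it %% 10 == 0 || it == max_iter) {
        M <- u * K * rep(v, each = n)
        err <- max(max(abs(rowSums(M) - a)), max(abs(colSums(M) - b)))
        if (err <= tol) break
      }
    }
    M <- u * K * rep(v, each = n)
  } else {
    # Log-domain with epsilon scaling: anneal from a large epsilon down to
    # the target, warm-starting the dual potentials f, g.
    la <- log(a); lb <- log(b)
    f <- numeric(n); g <- numeric(m)
    eps0 <- max(stats::median(C), epsilon)
    levels <- epsilon
    e <- eps0
    while (e > epsilon * 1.0001) {
      levels <- c(e, levels)
      e <- e * 0.5
    }
    levels <- sort(unique(pmax(levels, epsilon)), decreasing = TRUE)
    it <- 0; err <- Inf
    for (e in levels) {
      final <- abs(e - epsilon) < 1e-15
      level_iter <- if (final) max_iter else 50
      li <- 0
      repeat {
        li <- li + 1; it <- it + 1
        f <- e * la - e * .logsumexp_rows((rep(g, each = n) - C) / e)
        g <- e * lb - e * .logsumexp_rows(t((f - C) / e))
        if (li %% 5 == 0 || li >= level_iter) {
          M <- exp((f + rep(g, each = n) - C) / e)
          err <- max(max(abs(rowSums(M) - a)), max(abs(colSums(M) - b)))
          if (err <= tol || li >= level_iter) break
        }
      }
    }
    M <- exp((f + rep(g, each = n) - C) / epsilon)
    u <- exp(f / epsilon); v <- exp(g / epsilon)
  }
  err <- max(max(abs(rowSums(M) - a)), max(abs(colSums(M) - b)))
  converged <- err <= tol
  if (!converged) {
    warning("Sinkhorn did not reach tol = ", tol, " after ", it,
            " iterations (marginal error ", signif(err, 3), ")")
  }
  structure(list(M = M, u = as.numeric(u), v = as.numeric(v), C = C,
                 a = a, b = b, epsilon = epsilon, n_iter = it,
                 marginal_error = err,
                 transport_cost = sum(M * C), converged = converged),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat("<coupling_result> ", nrow(x$M), "x", ncol(x$M),
      " plan | eps ", signif(x$epsilon, 4),
      " | iter ", x$n_iter,
      " | marginal err ", signif(x$marginal_error, 3),
      " | cost ", signif(x$transport_cost, 6), "\n", sep = "")
  invisible(x)
}

#' Match each control cell to a perturbed cell
#'
#' Row-argmax of the coupling plan: `p[i] = argmax_j M[i, j]`, ties broken by
#' the lowest column index. The matching is many-to-one by construction —
#' several control cells may share a perturbed partner.
#'
#' @param result a `coupling_result` from [sinkhorn()] (or a plain plan
#'   matrix).
#' @param Z_ptb optional m x d matrix of perturbed latents; when given, the
#'   matched rows are gathered into `Z_ptb_matched`.
#' @return an object of class `matched_pairs`: list with integer indices `p`
#'   (length n, 1-based) and, if `Z_ptb` was supplied, the n x d matrix
#'   `Z_ptb_matched`.
#' @export
match_cells <- function(result, Z_ptb = NULL) {
  M <- if (inherits(result, "coupling_result")) result$M else as.matrix(result)
  if (any(!is.finite(M))) stop("coupling plan must be finite")
  p <- max.col(M, ties.method = "first")
  out <- list(p = p)
  if (!is.null(Z_ptb)) {
    if (inherits(Z_ptb, "latent_set")) Z_ptb <- Z_ptb$Z
    if (max(p) > nrow(Z_ptb)) stop("plan has more columns than Z_ptb rows")
    out$Z_ptb_matched <- as.matrix(Z_ptb)[p, , drop = FALSE]
  }
  structure(out, class = "matched_pairs")
}

#' Per-pair perturbation vectors
#'
#' `Delta[i, ] = Z_ptb_matched[i, ] - Z_ctr[i, ]`: the latent displacement
#' each control cell undergoes according to its transport match. Rows are
#' aligned with the control cells.
#'
#' @param Z_ctr n x d control latents (`latent_set` accepted).
#' @param pairs a `matched_pairs` carrying `Z_ptb_matched`, or an n x d
#'   matrix of matched perturbed latents.
#' @return an n x d matrix of class `perturbation_vectors`.
#' @export
perturbation_vectors <- function(Z_ctr, pairs) {
  if (inherits(Z_ctr, "latent_set")) Z_ctr <- Z_ctr$Z
  Z_ctr <- as.matrix(Z_ctr)
  Zm <- if (inherits(pairs, "matched_pairs")) {
    if (is.null(pairs$Z_ptb_matched)) {
      stop("matched_pairs lacks Z_ptb_matched; call match_cells() with Z_ptb")
    }
    pairs$Z_ptb_matched
  } else as.matrix(pairs)
  if (!identical(dim(Zm), dim(Z_ctr))) {
    stop("shape mismatch between Z_ctr and matched perturbed latents")
  }
  structure(Zm - Z_ctr, class = c("perturbation_vectors", "matrix", "array"))
}
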
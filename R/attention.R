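#' Attention configuration
#'
#' @param beta proportion of training control cells attended per query, in
#'   (0, 1]. The default 0.005 sits in the middle of the insensitive range
#'   of the robustness sweep (0.001–0.1).
#' @param min_keys floor on the number of selected keys `n_t`
#'   (`n_t = max(min_keys, round(beta * n))`).
#' @return a list of class `attention_config`.
#' @export
attention_config <- function(beta = 0.005, min_keys = 1L) {
  stopifnot(beta > 0, beta <= 1, min_keys >= 1)
  structure(list(beta = beta, min_keys = as.integer(min_keys)),
            class = "attention_config")
}

#' Cosine similarities between a query and a set of keys
#'
#' `s[i] = (q . k_i) / (||q|| ||k_i||)`. A zero-norm query has no direction
#' and is an error; zero-norm keys get similarity 0 with a warning.
#'
#' @param query length-d numeric vector.
#' @param keys n x d numeric matrix (`latent_set` accepted).
#' @return length-n numeric vector in \[-1, 1\].
#' @export
cosine_similarities <- function(query, keys) {
  if (inherits(keys, "latent_set")) keys <- keys$Z
  keys <- as.matrix(keys)
  query <- as.numeric(query)
  if (length(query) != ncol(keys)) stop("query/key dimension mismatch")
  qn <- sqrt(sum(query^2))
  if (qn == 0) stop("zero-norm query: cosine similarity undefined")
  kn <- sqrt(rowSums(keys^2))
  s <- as.numeric(keys %*% query) / (qn * pmax(kn, .Machine$double.xmin))
  if (any(kn == 0)) {
    warning(sum(kn == 0), " zero-norm key(s); their similarity is set to 0")
    s[kn == 0] <- 0
  }
  s
}

.softmax <- function(x) {
  e <- exp(x - max(x))  # max-subtraction: numerically stable, same result
  e / sum(e)
}

.n_selected <- function(n, config) {
  min(n, max(config$min_keys, round(config$beta * n)))
}

#' Attend over matched perturbation vectors
#'
#' Computes a query-specific perturbation vector: cosine similarities of the
#' query against all keys, selection of the `n_t = max(min_keys,
#' round(beta * n))` most similar keys (stable ties: lowest index first),
#' softmax over the selected raw similarities, and the weighted sum of the
#' corresponding value vectors.
#'
#' @param query length-d latent vector of the cell to predict.
#' @param keys n x d matrix of training control latents.
#' @param values n x d matrix of per-control-cell perturbation vectors,
#'   row-aligned with `keys` ([perturbation_vectors()] output).
#' @param config an [attention_config()].
#' @return an object of class `attention_result`: list with `similarities`
#'   (length n), `selected_idx` (length n_t), `weights` (softmax, sums to 1)
#'   and `delta` (length d).
#' @export
attend <- function(query, keys, values, config = attention_config()) {
  if (inherits(keys, "latent_set")) keys <- keys$Z
  keys <- as.matrix(keys)
  values <- unclass(as.matrix(values))
  if (nrow(keys) == 0) stop("empty key set")
  if (nrow(values) != nrow(keys)) stop("keys and values must be row-aligned")
  s <- cosine_similarities(query, keys)
  n_t <- .n_selected(length(s), config)
  sel <- order(-s)[seq_len(n_t)]  # order() is stable: ties keep lowest index
  w <- .softmax(s[sel])
  delta <- as.numeric(crossprod(values[sel, , drop = FALSE], w))
  structure(list(similarities = s, selected_idx = sel, weights = w,
                 delta = delta), class = "attention_result")
}

#' Predict the perturbation response of query cells
#'
#' For each query cell: deterministic encoding to `z_t`, attention over the
#' matched training pairs to obtain its own perturbation vector `delta_t`,
#' latent shift `z_t + delta_t`, and decoding back to expression space.
#' Query cell ids and cell-type metadata are carried through unchanged; the
#' output's condition is set to `"perturbed"` (it is a predicted perturbed
#' population).
#'
#' @param model a trained `perturb_vae`.
#' @param keys n x d training control latents (`latent_set` or matrix).
#' @param values n x d [perturbation_vectors()] aligned with `keys`.
#' @param queries an [expression_dataset()] on the training gene set.
#' @param config an [attention_config()].
#' @param return_attention also return per-query selected indices and
#'   weights (as the `attention` attribute, a list).
#' @return an [expression_dataset()] of predicted perturbed expression.
#' @export
predict_response <- function(model, keys, values, queries,
                             config = attention_config(),
                             return_attention = FALSE) {
  if (inherits(keys, "latent_set")) keys <- keys$Z
  keys <- as.matrix(keys)
  values <- unclass(as.matrix(values))
  stopifnot(nrow(keys) == nrow(values))
  Zq <- encode(model, queries, deterministic = TRUE)
  n <- nrow(keys)
  n_t <- .n_selected(n, config)
  # Vectorized cosine similarities: normalize rows, one matmul.
  kn <- sqrt(rowSums(keys^2))
  zero_keys <- kn == 0
  if (any(zero_keys)) {
    warning(sum(zero_keys), " zero-norm key(s); their similarity is set to 0")
  }
  Kn <- keys / pmax(kn, .Machine$double.xmin)
  qn <- sqrt(rowSums(Zq$Z^2))
  if (any(qn == 0)) {
    stop("zero-norm latent for query cell(s): ",
         paste(utils::head(Zq$cell_ids[qn == 0], 3), collapse = ", "))
  }
  S <- (Zq$Z / qn) %*% t(Kn)
  if (any(zero_keys)) S[, zero_keys] <- 0
  deltas <- matrix(0, nrow(S), ncol(values))
  attn <- if (return_attention) vector("list", nrow(S)) else NULL
  for (i in seq_len(nrow(S))) {
    s <- S[i, ]
    sel <- order(-s)[seq_len(n_t)]
    w <- .softmax(s[sel])
    deltas[i, ] <- as.numeric(crossprod(values[sel, , drop = FALSE], w))
    if (return_attention) {
      attn[[i]] <- list(selected_idx = sel, weights = w)
    }
  }
  pred <- decode(model, Zq$Z + deltas)
  out <- expression_dataset(pred$matrix, queries$cell_ids, model$gene_names,
                            condition = rep("perturbed", n_cells(queries)),
                            cell_type = queries$cell_type)
  if (return_attention) {
    names(attn) <- queries$cell_ids
    attr(out, "attention") <- attn
  }
  out
}
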
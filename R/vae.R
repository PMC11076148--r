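#' VAE configuration
#'
#' Hyperparameters of the variational autoencoder. The loss is
#' `reconstruction + kl_weight * KL(q(z|x) || N(0, I))` with a Gaussian
#' reconstruction term (mean squared error on log-normalized expression,
#' summed over genes, averaged over the batch). None of these values are
#' dictated by the method itself; the defaults are desk-scale conventions
#' and every run records the configuration it used.
#'
#' @param latent_dim latent dimensionality `d` (must be < gene count).
#' @param hidden_dims integer vector of hidden-layer widths, shared
#'   (mirrored) between encoder and decoder.
#' @param kl_weight weight `alpha` of the KL term; must be > 0.
#' @param epochs number of passes over the training data.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed integer seed controlling initialization, shuffling and the
#'   reparameterization noise.
#' @param verbose print per-epoch losses.
#' @return a list of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 100, hidden_dims = c(800, 800),
                       kl_weight = 5e-3, epochs = 100, batch_size = 128,
                       learning_rate = 1e-3, seed = 1L, verbose = FALSE) {
  stopifnot(latent_dim >= 1, all(hidden_dims >= 1), kl_weight > 0,
            epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_dims = as.integer(hidden_dims),
                 kl_weight = kl_weight, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = .check_seed(seed),
                 verbose = isTRUE(verbose)),
            class = "vae_config")
}

.relu <- function(a) a * (a > 0)
.sigmoid <- function(a) 1 / (1 + exp(-a))
.softplus <- function(a) ifelse(a > 30, a, log1p(exp(pmin(a, 30))))
.addb <- function(x, b) x + rep(b, each = nrow(x))

.init_dense <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

.init_params <- function(n_genes, config) {
  h <- config$hidden_dims
  d <- config$latent_dim
  enc_sizes <- c(n_genes, h)
  dec_sizes <- c(d, rev(h))
  list(
    enc = lapply(seq_along(h), function(l)
      .init_dense(enc_sizes[l], enc_sizes[l + 1])),
    mu = .init_dense(enc_sizes[length(enc_sizes)], d),
    lv = .init_dense(enc_sizes[length(enc_sizes)], d),
    dec = lapply(seq_along(h), function(l)
      .init_dense(dec_sizes[l], dec_sizes[l + 1])),
    out = .init_dense(dec_sizes[length(dec_sizes)], n_genes))
}

# Encoder forward: returns mu, logvar (clamped for stability) and the hidden
# activations needed for backprop.
.encoder_forward <- function(params, X) {
  h <- X
  pre <- vector("list", length(params$enc))
  act <- vector("list", length(params$enc))
  for (l in seq_along(params$enc)) {
    pre[[l]] <- .addb(h %*% params$enc[[l]]$W, params$enc[[l]]$b)
    h <- .relu(pre[[l]])
    act[[l]] <- h
  }
  mu <- .addb(h %*% params$mu$W, params$mu$b)
  lv <- pmin(pmax(.addb(h %*% params$lv$W, params$lv$b), -10), 10)
  list(mu = mu, lv = lv, pre = pre, act = act, top = h)
}

.decoder_forward <- function(params, Z) {
  g <- Z
  pre <- vector("list", length(params$dec))
  act <- vector("list", length(params$dec))
  for (l in seq_along(params$dec)) {
    pre[[l]] <- .addb(g %*% params$dec[[l]]$W, params$dec[[l]]$b)
    g <- .relu(pre[[l]])
    act[[l]] <- g
  }
  aout <- .addb(g %*% params$out$W, params$out$b)
  list(xhat = .softplus(aout), aout = aout, pre = pre, act = act, top = g)
}

# One minibatch of loss + gradients. Reconstruction is the per-cell sum of
# squared errors, KL the per-cell closed form, both averaged over the batch.
.vae_batch_grad <- function(params, X, eps, kl_weight) {
  B <- nrow(X)
  ef <- .encoder_forward(params, X)
  sig <- exp(0.5 * ef$lv)
  Z <- ef$mu + eps * sig
  df <- .decoder_forward(params, Z)

  resid <- df$xhat - X
  recon <- sum(resid^2) / B
  kl <- sum(0.5 * (ef$mu^2 + sig^2 - 1 - ef$lv)) / B
  loss <- recon + kl_weight * kl

  grads <- list(enc = vector("list", length(params$enc)),
                dec = vector("list", length(params$dec)))

  daout <- (2 / B) * resid * .sigmoid(df$aout)
  dg <- daout %*% t(params$out$W)
  grads$out <- list(W = crossprod(df$top, daout), b = colSums(daout))
  for (l in rev(seq_along(params$dec))) {
    da <- dg * (df$pre[[l]] > 0)
    inp <- if (l == 1) Z else df$act[[l - 1]]
    grads$dec[[l]] <- list(W = crossprod(inp, da), b = colSums(da))
    dg <- da %*% t(params$dec[[l]]$W)
  }
  dZ <- dg
  dmu <- dZ + (kl_weight / B) * ef$mu
  dlv <- dZ * eps * 0.5 * sig + (kl_weight / B) * 0.5 * (sig^2 - 1)
  dh <- dmu %*% t(params$mu$W) + dlv %*% t(params$lv$W)
  grads$mu <- list(W = crossprod(ef$top, dmu), b = colSums(dmu))
  grads$lv <- list(W = crossprod(ef$top, dlv), b = colSums(dlv))
  for (l in rev(seq_along(params$enc))) {
    da <- dh * (ef$pre[[l]] > 0)
    inp <- if (l == 1) X else ef$act[[l - 1]]
    grads$enc[[l]] <- list(W = crossprod(inp, da), b = colSums(da))
    dh <- da %*% t(params$enc[[l]]$W)
  }
  list(loss = loss, recon = recon, kl = kl, grads = grads)
}

.adam_init <- function(params) {
  rapply(params, function(p) p * 0, how = "replace")
}

.adam_step <- function(params, grads, m, v, t, lr,
                       b1 = 0.9, b2 = 0.999, epsi = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      out <- lapply(keys, function(k) walk(p[[k]], g[[k]], m[[k]], v[[k]]))
      pick <- function(f) stats::setNames(lapply(out, `[[`, f), names(p))
      return(list(p = pick("p"), m = pick("m"), v = pick("v")))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + epsi), m = m, v = v)
  }
  walk(params, grads, m, v)
}

#' Train the variational autoencoder
#'
#' Fits encoder/decoder weights by minibatch Adam on the ELBO-derived loss
#' `recon + kl_weight * KL` with a standard-normal prior and the
#' reparameterization `z = mu + eps * sigma`. Training is fully
#' seed-deterministic for a given numerical backend.
#'
#' @param data an [expression_dataset()] of normalized expression (the model
#'   assumes a roughly Gaussian likelihood on log-scale values).
#' @param config a [vae_config()].
#' @return an object of class `perturb_vae`: trained parameters, the config,
#'   the training gene names, and a per-epoch `history` data frame with
#'   columns `epoch`, `recon`, `kl`, `total`.
#' @export
train_vae <- function(data, config = vae_config()) {
  stopifnot(inherits(config, "vae_config"))
  X <- as_dense(data)
  n <- nrow(X)
  if (n < config$batch_size) {
    config$batch_size <- n  # tiny fixtures: fall back to full-batch
  }
  if (config$latent_dim >= ncol(X)) {
    stop("latent_dim (", config$latent_dim, ") must be smaller than the ",
         "gene count (", ncol(X), ")")
  }
  set.seed(config$seed)
  params <- .init_params(ncol(X), config)
  m_state <- .adam_init(params)
  v_state <- .adam_init(params)
  t_step <- 0
  history <- data.frame(epoch = integer(0), recon = numeric(0),
                        kl = numeric(0), total = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    ep <- c(recon = 0, kl = 0, total = 0)
    for (s in starts) {
      rows <- perm[s:min(s + config$batch_size - 1, n)]
      Xb <- X[rows, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(rows) * config$latent_dim),
                    length(rows), config$latent_dim)
      bg <- .vae_batch_grad(params, Xb, eps, config$kl_weight)
      if (!is.finite(bg$loss)) {
        stop("non-finite VAE loss at epoch ", epoch,
             "; lower the learning rate or check the data scale ",
             "(inputs should be log-normalized)")
      }
      t_step <- t_step + 1
      st <- .adam_step(params, bg$grads, m_state, v_state, t_step,
                       config$learning_rate)
      params <- st$p; m_state <- st$m; v_state <- st$v
      w <- length(rows) / n
      ep <- ep + w * c(bg$recon, bg$kl, bg$loss)
    }
    history <- rbind(history, data.frame(epoch = epoch, recon = ep[["recon"]],
                                         kl = ep[["kl"]],
                                         total = ep[["total"]]))
    if (config$verbose) {
      message(sprintf("epoch %3d  recon %.4f  kl %.4f  total %.4f",
                      epoch, ep[["recon"]], ep[["kl"]], ep[["total"]]))
    }
  }
  structure(list(params = params, config = config,
                 gene_names = data$gene_names, history = history),
            class = "perturb_vae")
}

#' @export
print.perturb_vae <- function(x, ...) {
  cat("<perturb_vae> genes:", length(x$gene_names),
      "latent:", x$config$latent_dim,
      "hidden:", paste(x$config$hidden_dims, collapse = "x"),
      "| final loss:", signif(utils::tail(x$history$total, 1), 5), "\n")
  invisible(x)
}

.check_genes <- function(model, data) {
  if (identical(data$gene_names, model$gene_names)) {
    return(seq_along(model$gene_names))
  }
  missing <- setdiff(model$gene_names, data$gene_names)
  extra <- setdiff(data$gene_names, model$gene_names)
  if (length(missing) || length(extra)) {
    stop("gene set mismatch with the training genes; missing: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "",
         "; extra: ", paste(utils::head(extra, 5), collapse = ", "),
         if (length(extra) > 5) ", ..." else "")
  }
  match(model$gene_names, data$gene_names)  # same set, different order
}

#' Encode cells into the latent space
#'
#' @param model a trained `perturb_vae`.
#' @param data an [expression_dataset()] on the training gene set (reordered
#'   to the training order if needed).
#' @param deterministic if `TRUE` (default) return the posterior mean `mu`;
#'   if `FALSE`, draw `z = mu + eps * sigma` with fresh noise.
#' @param seed optional seed for the stochastic draw.
#' @return a `latent_set`: list with the cells x d matrix `Z` and `cell_ids`.
#' @export
encode <- function(model, data, deterministic = TRUE, seed = NULL) {
  stopifnot(inherits(model, "perturb_vae"))
  X <- as_dense(data)[, .check_genes(model, data), drop = FALSE]
  ef <- .encoder_forward(model$params, X)
  Z <- if (deterministic) {
    ef$mu
  } else {
    if (!is.null(seed)) set.seed(.check_seed(seed))
    ef$mu + matrix(stats::rnorm(length(ef$mu)), nrow(ef$mu)) *
      exp(0.5 * ef$lv)
  }
  structure(list(Z = Z, cell_ids = data$cell_ids), class = "latent_set")
}

#' Full encoder posterior for a dataset
#'
#' Lower-level companion of [encode()] exposing `mu` and `sigma` per cell.
#'
#' @inheritParams encode
#' @return list with matrices `mu` and `sigma` (cells x d).
#' @export
encode_posterior <- function(model, data) {
  X <- as_dense(data)[, .check_genes(model, data), drop = FALSE]
  ef <- .encoder_forward(model$params, X)
  list(mu = ef$mu, sigma = exp(0.5 * ef$lv))
}

#' Decode latent vectors back to expression space
#'
#' @param model a trained `perturb_vae`.
#' @param Z a `latent_set` from [encode()] or a plain cells x d matrix.
#' @return an [expression_dataset()] on the training genes (non-negative by
#'   construction of the decoder output layer).
#' @export
decode <- function(model, Z) {
  stopifnot(inherits(model, "perturb_vae"))
  cell_ids <- NULL
  if (inherits(Z, "latent_set")) {
    cell_ids <- Z$cell_ids
    Z <- Z$Z
  }
  Z <- as.matrix(Z)
  if (ncol(Z) != model$config$latent_dim) {
    stop("latent dimension mismatch: got ", ncol(Z), ", model expects ",
         model$config$latent_dim)
  }
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(Z)))
  df <- .decoder_forward(model$params, Z)
  expression_dataset(df$xhat, cell_ids, model$gene_names)
}

#' Closed-form KL divergence to the standard normal
#'
#' `KL(N(mu, diag(sigma^2)) || N(0, I)) = sum(0.5 * (mu^2 + sigma^2 - 1 -
#' 2 log sigma))`, the regularizer of the VAE loss.
#'
#' @param mu numeric vector of posterior means.
#' @param sigma numeric vector of posterior standard deviations (> 0).
#' @return a single non-negative number.
#' @export
kl_normal <- function(mu, sigma) {
  stopifnot(length(mu) == length(sigma))
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  sum(0.5 * (mu^2 + sigma^2 - 1 - 2 * log(sigma)))
}
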
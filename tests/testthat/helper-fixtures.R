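# Shared fixtures and independent oracles. Expensive objects are built once
# per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, make(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# A small two-type world with clear structure, for module-level tests.
small_sim <- function() {
  fixture("small_sim", function() {
    simulate_perturbation_dataset(simulation_config(
      n_types = 2, cells_per_type_per_condition = 80, n_genes = 40,
      marker_genes_per_type = 4, type_centroid_scale = 0.8, seed = 11))
  })
}

small_vae_cfg <- function(epochs = 200) {
  vae_config(latent_dim = 8, hidden_dims = 32, kl_weight = 5e-3,
             epochs = epochs, batch_size = 64, learning_rate = 1.5e-3,
             seed = 5)
}

# VAE trained on the small world (cached; ~2 s).
small_vae <- function() {
  fixture("small_vae", function() train_vae(small_sim()$data, small_vae_cfg()))
}

# Tiny run_config for fast end-to-end pipeline tests.
tiny_run_cfg <- function(seed = 9, ...) {
  run_config(
    vae = vae_config(latent_dim = 6, hidden_dims = 24, epochs = 10,
                     batch_size = 32, learning_rate = 2e-3),
    normalize = list(enabled = FALSE),
    seed = seed, ...)
}

tiny_sim <- function() {
  fixture("tiny_sim", function() {
    simulate_perturbation_dataset(simulation_config(
      n_types = 2, cells_per_type_per_condition = 40, n_genes = 30,
      marker_genes_per_type = 3, seed = 21))
  })
}

# ---- independent oracles ------------------------------------------------

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

# Exact optimum of the transport LP with uniform marginals and n = m: an
# optimal vertex is a permutation (Birkhoff), so enumerate all of them.
lp_transport_cost <- function(C) {
  n <- nrow(C)
  stopifnot(n == ncol(C))
  min(vapply(all_perms(n),
             function(p) sum(C[cbind(seq_len(n), p)]) / n, numeric(1)))
}

# Independent softmax arithmetic.
softmax_oracle <- function(x) exp(x) / sum(exp(x))

# Exhaustive rank-sum enumeration: exact null mean and variance of the
# group-A rank sum over all C(N, n1) assignments of the observed ranks.
ranksum_enum_z <- function(xa, xb) {
  r <- rank(c(xa, xb))
  n1 <- length(xa)
  combos <- utils::combn(length(r), n1)
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  (sum(r[seq_len(n1)]) - mean(sums)) / stats::sd(sums) *
    sqrt(length(sums) / (length(sums) - 1))  # population sd of the null
}

# Closed-form OLS R^2 of y ~ x via the normal equations.
ols_r2_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  1 - sum(res^2) / sum((y - mean(y))^2)
}

# Mean per-gene 1-D Wasserstein by direct sorted-sample computation
# (equal sample sizes only).
w1_sorted_oracle <- function(a, b) {
  mean(vapply(seq_len(ncol(a)),
              function(j) mean(abs(sort(a[, j]) - sort(b[, j]))),
              numeric(1)))
}
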
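test_that("cosine similarities match hand geometry", {
  expect_equal(cosine_similarities(c(1, 0), rbind(c(1, 0))), 1)
  expect_equal(cosine_similarities(c(1, 0), rbind(c(0, 1))), 0)
  expect_equal(cosine_similarities(c(1, 1), rbind(c(1, 0))),
               0.70710678, tolerance = 1e-8)
  expect_error(cosine_similarities(c(0, 0), rbind(c(1, 0))), "zero-norm")
  expect_warning(s <- cosine_similarities(c(1, 0), rbind(c(0, 0), c(2, 0))),
                 "zero-norm key")
  expect_equal(s, c(0, 1))
  # scale invariance of keys
  K <- matrix(rnorm(10), 5, 2)
  q <- c(0.3, -1.2)
  expect_equal(cosine_similarities(q, K * 7), cosine_similarities(q, K))
})

test_that("attend reproduces independent softmax arithmetic", {
  keys <- rbind(c(1, 0), c(0.8, 0.6), c(0, 1))
  values <- rbind(c(10, 0), c(0, 10), c(5, 5))
  # singleton selection: delta equals the most similar key's value
  a1 <- attend(c(1, 0.05), keys, values, attention_config(beta = 1e-6))
  expect_equal(length(a1$selected_idx), 1)
  expect_equal(a1$delta, c(10, 0))
  expect_equal(a1$weights, 1)
  # all-equal similarities: uniform weights, delta = mean of values
  a2 <- attend(c(1, 1), rbind(c(1, 0), c(0, 1)), rbind(c(2, 0), c(0, 4)),
               attention_config(beta = 1))
  expect_equal(a2$weights, c(0.5, 0.5))
  expect_equal(a2$delta, c(1, 2))
  # two-key softmax against the oracle: similarities 0.9 and 0.5
  keys3 <- rbind(c(1, 0), c(0, 1), c(-1, 0))
  q <- c(0.9, sqrt(1 - 0.81))  # unit query: s = (0.9, 0.4359, -0.9)
  s <- cosine_similarities(q, keys3)
  vals <- rbind(c(1, 2), c(3, -1), c(100, 100))
  a3 <- attend(q, keys3, vals, attention_config(beta = 2 / 3))
  expect_equal(a3$selected_idx, c(1, 2))
  w_oracle <- softmax_oracle(s[1:2])
  expect_equal(a3$weights, w_oracle, tolerance = 1e-12)
  expect_equal(a3$delta, w_oracle[1] * vals[1, ] + w_oracle[2] * vals[2, ],
               tolerance = 1e-12)
})

test_that("keys built for exact cosines give the (0.5987, 0.4013) weights", {
  # keys in 3D constructed so the unit query (1,0,0) sees cosine
  # similarities exactly (0.9, 0.5, 0.1)
  cosines <- c(0.9, 0.5, 0.1)
  keys <- cbind(cosines, sqrt(1 - cosines^2), 0)
  vals <- rbind(c(1, 2, 0), c(3, -1, 1), c(50, 50, 50))
  a <- attend(c(1, 0, 0), keys, vals, attention_config(beta = 2 / 3))
  expect_equal(a$selected_idx, c(1, 2))
  expect_equal(a$weights, c(0.59868766, 0.40131234), tolerance = 1e-7)
  expect_equal(a$weights, softmax_oracle(c(0.9, 0.5)), tolerance = 1e-9)
})

test_that("attend selects the top n_t, breaks ties stably and is convex", {
  set.seed(64)
  keys <- matrix(rnorm(40), 20, 2)
  values <- matrix(rnorm(40), 20, 2)
  q <- rnorm(2)
  a <- attend(q, keys, values, attention_config(beta = 0.25))
  s <- cosine_similarities(q, keys)
  expect_equal(length(a$selected_idx), 5)  # round(0.25 * 20)
  expect_setequal(a$selected_idx, order(-s)[1:5])
  expect_equal(sum(a$weights), 1, tolerance = 1e-10)
  expect_true(all(a$weights >= 0))
  # convex-combination bound per coordinate
  sel_vals <- values[a$selected_idx, ]
  expect_true(all(a$delta >= apply(sel_vals, 2, min) - 1e-12))
  expect_true(all(a$delta <= apply(sel_vals, 2, max) + 1e-12))
  # duplicated key: stable tie-break selects the earlier row
  keys2 <- rbind(c(1, 0), c(2, 0), c(0, 1))
  a2 <- attend(c(1, 0), keys2, diag(3), attention_config(beta = 1 / 3))
  expect_equal(a2$selected_idx, 1L)
  expect_error(attend(q, keys[0, , drop = FALSE], values), "empty")
})

test_that("zero perturbation vectors make prediction a reconstruction", {
  sim <- small_sim()
  model <- small_vae()
  ctr <- subset_cells(sim$data, sim$data$condition == "control")
  queries <- subset_cells(ctr, 1:10)
  Zc <- encode(model, ctr)
  zeros <- matrix(0, n_cells(ctr), model$config$latent_dim)
  pred <- predict_response(model, Zc, zeros, queries)
  rec <- decode(model, encode(model, queries))
  expect_equal(as_dense(pred), as_dense(rec), tolerance = 1e-12)
  expect_identical(pred$cell_ids, queries$cell_ids)
  expect_identical(pred$cell_type, queries$cell_type)
  expect_true(all(pred$condition == "perturbed"))
})

test_that("identical query cells receive identical predictions", {
  sim <- small_sim()
  model <- small_vae()
  ctr <- subset_cells(sim$data, sim$data$condition == "control")
  ptb <- subset_cells(sim$data, sim$data$condition == "perturbed")
  Zc <- encode(model, ctr)
  Zp <- encode(model, ptb)
  pairs <- match_cells(sinkhorn(cost_matrix(Zc, Zp)), Z_ptb = Zp)
  vals <- perturbation_vectors(Zc, pairs)
  m <- as_dense(ctr)[c(1, 1, 2), , drop = FALSE]
  q <- expression_dataset(m, c("a", "b", "c"), ctr$gene_names)
  pred <- predict_response(model, Zc, vals, q)
  expect_identical(as_dense(pred)[1, ], as_dense(pred)[2, ])
})

test_that("a known uniform latent shift is recovered through the decoder", {
  sim <- small_sim()
  model <- small_vae()
  ctr <- subset_cells(sim$data, sim$data$condition == "control")
  ptb <- subset_cells(sim$data, sim$data$condition == "perturbed")
  Zc <- encode(model, ctr)
  # delta*: the population shift direction, a realistic latent displacement
  delta_star <- colMeans(encode(model, ptb)$Z) - colMeans(Zc$Z)
  vals <- matrix(delta_star, n_cells(ctr), length(delta_star), byrow = TRUE)
  pred <- predict_response(model, Zc, vals, ctr)
  realized <- colMeans(encode(model, pred)$Z) - colMeans(Zc$Z)
  rel_err <- sqrt(sum((realized - delta_star)^2) / sum(delta_star^2))
  expect_lt(rel_err, 0.1)
})

test_that("each query cluster receives its own perturbation vector", {
  sim <- small_sim()
  model <- small_vae()
  data <- sim$data
  ctr <- subset_cells(data, data$condition == "control")
  ptb <- subset_cells(data, data$condition == "perturbed")
  Zc <- encode(model, ctr)
  Zp <- encode(model, ptb)
  pairs <- match_cells(sinkhorn(cost_matrix(Zc, Zp)), Z_ptb = Zp)
  vals <- perturbation_vectors(Zc, pairs)
  pred <- predict_response(model, Zc, vals, ctr,
                           attention_config(beta = 0.05),
                           return_attention = TRUE)
  at <- attr(pred, "attention")
  deltas <- t(vapply(seq_along(at), function(i) {
    as.numeric(crossprod(unclass(vals)[at[[i]]$selected_idx, , drop = FALSE],
                         at[[i]]$weights))
  }, numeric(ncol(vals))))
  by_type <- split(seq_len(n_cells(ctr)), ctr$cell_type)
  d_a <- colMeans(deltas[by_type[[1]], , drop = FALSE])
  d_b <- colMeans(deltas[by_type[[2]], , drop = FALSE])
  expect_gt(sqrt(sum((d_a - d_b)^2)), 0)
  # and the per-query deltas are not all equal across clusters
  expect_gt(sd(deltas[, 1]), 0)
})
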
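test_that("1-D Wasserstein distance is exact on hand-checkable cases", {
  expect_equal(wasserstein_1d(0, 1), 1)
  expect_equal(wasserstein_1d(c(3, 1, 2), c(2, 3, 1)), 0)
  expect_equal(wasserstein_1d(c(0, 1), c(1, 2)), 1)  # order statistics pair up
  expect_equal(wasserstein_1d(c(0, 0, 1), c(1, 2)), 7 / 6)
  expect_error(wasserstein_1d(numeric(0), 1), "non-empty")
})

test_that("wasserstein_1d behaves as a pseudometric on random samples", {
  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1))
    z <- rnorm(sample(3:12, 1))
    dxy <- wasserstein_1d(x, y)
    expect_gte(dxy, 0)
    expect_equal(dxy, wasserstein_1d(y, x))
    expect_lte(dxy, wasserstein_1d(x, z) + wasserstein_1d(z, y) + 1e-12)
  }
})

test_that("distribution_distance averages per-gene distances", {
  sim <- tiny_sim()
  truth <- subset_cells(sim$data, sim$data$condition == "perturbed")
  expect_equal(distribution_distance(truth, truth), 0)
  # shifting one gene of k by +c moves the mean distance by c/k
  k <- n_genes(truth)
  shifted <- truth
  shifted$matrix[, 3] <- shifted$matrix[, 3] + 0.7
  expect_equal(distribution_distance(shifted, truth), 0.7 / k,
               tolerance = 1e-12)
  # matches a direct per-gene oracle on equal-sized random matrices
  set.seed(72)
  a <- expression_dataset(matrix(rexp(60), 10, 6), paste0("a", 1:10),
                          paste0("g", 1:6))
  b <- expression_dataset(matrix(rexp(60), 10, 6), paste0("b", 1:10),
                          paste0("g", 1:6))
  expect_equal(distribution_distance(a, b),
               w1_sorted_oracle(as_dense(a), as_dense(b)))
  # gene subset restriction and unknown-gene error
  expect_equal(distribution_distance(shifted, truth, genes = "g0003"), 0.7)
  expect_error(distribution_distance(a, b, genes = "nope"), "unknown gene")
})

test_that("expression_r2 equals the closed-form OLS oracle", {
  sim <- tiny_sim()
  truth <- subset_cells(sim$data, sim$data$condition == "perturbed")
  expect_equal(as.numeric(expression_r2(truth, truth, "mean")), 1)
  expect_equal(as.numeric(expression_r2(truth, truth, "variance")), 1)
  # constant predictor: no explanatory power, flagged
  flat <- truth
  flat$matrix <- matrix(1, n_cells(truth), n_genes(truth))
  r <- expression_r2(flat, truth, "mean")
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
  # 10-gene random example vs normal-equations oracle
  set.seed(73)
  p <- expression_dataset(matrix(runif(50), 5, 10), paste0("p", 1:5),
                          paste0("g", 1:10))
  t_ <- expression_dataset(matrix(runif(50), 5, 10), paste0("t", 1:5),
                           paste0("g", 1:10))
  expect_equal(as.numeric(expression_r2(p, t_, "mean")),
               ols_r2_oracle(colMeans(as_dense(p)), colMeans(as_dense(t_))))
  expect_equal(as.numeric(expression_r2(p, t_, "variance")),
               ols_r2_oracle(apply(as_dense(p), 2, var),
                             apply(as_dense(t_), 2, var)))
  # invariant to cell order
  perm <- sample(5)
  expect_equal(expression_r2(subset_cells(p, perm), t_, "mean"),
               expression_r2(p, t_, "mean"))
})

test_that("rank_degs orders by |z| with lexical tie-break", {
  d <- make_micro_example()
  a <- subset_cells(d, d$condition == "control")
  b <- subset_cells(d, d$condition == "control")
  # identical groups: z = 0 everywhere, ordering falls back to gene name
  degs <- rank_degs(a, b, k = 6)
  expect_equal(as.character(degs), paste0("g", 1:6))
  expect_true(all(attr(degs, "scores")$z == 0))
  expect_error(rank_degs(a, b, k = 7), "exceeds")
})

test_that("wilcoxon z matches exhaustive rank-sum enumeration at 3 vs 3", {
  set.seed(74)
  for (i in 1:10) {
    xa <- round(rnorm(3), 1)  # rounding induces occasional ties
    xb <- round(rnorm(3), 1)
    if (sd(rank(c(xa, xb))) == 0) next
    z_pkg <- wilcoxon_z(matrix(xa, 3, 1), matrix(xb, 3, 1))
    expect_equal(z_pkg, ranksum_enum_z(xa, xb), tolerance = 1e-12)
  }
})

test_that("a strongly shifted gene ranks first", {
  set.seed(75)
  n <- 200
  g <- 20
  base <- matrix(rnorm(n * g, mean = 5), n, g)
  shifted <- matrix(rnorm(n * g, mean = 5), n, g)
  shifted[, 7] <- shifted[, 7] + 10  # +10 sigma
  a <- expression_dataset(pmax(base, 0), paste0("a", 1:n), paste0("g", 1:g))
  b <- expression_dataset(pmax(shifted, 0), paste0("b", 1:n), paste0("g", 1:g))
  expect_equal(rank_degs(a, b, k = 1)[1], "g7")
  # invariant to gene order (up to the tie-break)
  perm <- sample(g)
  expect_equal(rank_degs(subset_genes(a, perm), subset_genes(b, perm),
                         k = 1)[1], "g7")
})

test_that("common_deg_count is the intersection size", {
  expect_equal(common_deg_count(paste0("g", 1:100), paste0("g", 1:100)), 100)
  expect_equal(common_deg_count(paste0("a", 1:10), paste0("b", 1:10)), 0)
  expect_equal(common_deg_count(paste0("g", 1:10), paste0("g", 6:15)), 5)
  expect_error(common_deg_count(letters[1:3], letters[1:4]), "same length")
})

test_that("evaluate_holdout is perfect on truth and internally consistent", {
  sim <- tiny_sim()
  d <- sim$data
  sp <- split_holdout(d, "type_A")
  perfect <- evaluate_holdout(sp$truth, sp$truth, sp$query, n_degs = 20)
  expect_equal(perfect$r2_mean, 1)
  expect_equal(perfect$r2_variance, 1)
  expect_equal(perfect$wasserstein_all_genes, 0)
  expect_equal(perfect$wasserstein_top_degs, 0)
  expect_equal(perfect$n_common_degs, 20)
  # the no-change baseline on a real shift is imperfect
  base <- evaluate_holdout(sp$query, sp$truth, sp$query, n_degs = 20)
  expect_lt(base$r2_mean, 1)
  expect_gt(base$wasserstein_top_degs, 0)
  # self-consistency with the per-gene table
  tab <- base$per_gene_table
  expect_equal(base$r2_mean, cor(tab$mean_pred, tab$mean_true)^2)
  expect_equal(base$r2_variance, cor(tab$var_pred, tab$var_true)^2)
  expect_setequal(tab$gene[tab$deg_rank_true <= 20], base$true_degs)
  expect_setequal(tab$gene[tab$deg_rank_pred <= 20], base$pred_degs)
  expect_equal(common_deg_count(base$pred_degs, base$true_degs),
               base$n_common_degs)
})
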
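test_that("csv parsing yields the written matrix, ids and annotations", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,gA,gB", "c1,1,0", "c2,2.5,3", "c3,0,4"), path)
  d <- read_dataset(path, format = "csv", require_condition = FALSE)
  expect_equal(dim(d$matrix), c(3L, 2L))
  expect_equal(d$cell_ids, c("c1", "c2", "c3"))
  expect_equal(d$gene_names, c("gA", "gB"))
  expect_equal(as_dense(d), matrix(c(1, 2.5, 0, 0, 3, 4), 3, 2))
  expect_null(d$condition)
})

test_that("csv and h5ad round trips preserve the dataset field by field", {
  d <- make_micro_example()
  for (fmt in c("csv", "h5ad")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_dataset(d, path, format = fmt)
    d2 <- read_dataset(path, format = fmt)
    expect_identical(as_dense(d2), as_dense(d), info = fmt)
    expect_identical(d2$cell_ids, d$cell_ids, info = fmt)
    expect_identical(d2$gene_names, d$gene_names, info = fmt)
    expect_identical(d2$condition, d$condition, info = fmt)
    expect_identical(d2$cell_type, d$cell_type, info = fmt)
  }
})

test_that("mtx triplet round trip keeps sparse zeros and annotations", {
  d <- make_micro_example()
  d$matrix[1, 1] <- 0  # ensure an omitted triplet position
  dir <- withr::local_tempdir()
  write_dataset(d, dir, format = "mtx")
  d2 <- read_dataset(dir, format = "mtx")
  expect_equal(as_dense(d2), as_dense(d))
  expect_equal(as_dense(d2)[1, 1], 0)
  expect_identical(d2$condition, d$condition)
})

test_that("condition labels are mapped and missing condition is an error", {
  path <- withr::local_tempfile(fileext = ".csv")
  d <- make_micro_example()
  write_dataset(d, path)
  obs_path <- paste0(tools::file_path_sans_ext(path), "_obs.csv")
  obs <- read.csv(obs_path)
  obs$condition <- ifelse(obs$condition == "control", "ctrl", "stimulated")
  write.csv(obs, obs_path, row.names = FALSE)
  d2 <- read_dataset(path, control_label = "ctrl",
                     perturbed_label = "stimulated")
  expect_identical(d2$condition, d$condition)
  expect_error(read_dataset(path, condition_key = "nope"), "no 'nope'")
})

test_that("validation rejects negative and non-finite entries, naming cells", {
  d <- make_micro_example()
  m <- as_dense(d)
  m[2, 1] <- -1
  expect_error(expression_dataset(m, d$cell_ids, d$gene_names), "mc02")
  m[2, 1] <- NaN
  expect_error(expression_dataset(m, d$cell_ids, d$gene_names), "mc02")
  expect_error(expression_dataset(as_dense(d), d$cell_ids[-1], d$gene_names),
               "cell_ids")
})

test_that("normalization scales cells to target_sum with optional log1p", {
  mk <- function(m) expression_dataset(m, paste0("c", seq_len(nrow(m))),
                                       paste0("g", seq_len(ncol(m))))
  # already at target
  n1 <- normalize_dataset(mk(rbind(c(2, 2))), target_sum = 4, log1p = FALSE)
  expect_equal(as_dense(n1), rbind(c(2, 2)))
  # rescaled, sum preserved at 4
  n2 <- normalize_dataset(mk(rbind(c(1, 3))), target_sum = 4, log1p = FALSE)
  expect_equal(sum(as_dense(n2)), 4)
  expect_equal(as_dense(n2), rbind(c(1, 3)))
  # hand arithmetic: (0, 4) -> (0, log 5)
  n3 <- normalize_dataset(mk(rbind(c(0, 4))), target_sum = 4, log1p = TRUE)
  expect_equal(as_dense(n3), rbind(c(0, log(5))))
  # all-zero cell kept as zeros with a warning
  expect_warning(n4 <- normalize_dataset(mk(rbind(c(0, 0), c(1, 1)))),
                 "zero total")
  expect_equal(as_dense(n4)[1, ], c(0, 0))
})

test_that("highly-variable-gene selection reduces genes and keeps alignment", {
  sim <- small_sim()
  n <- normalize_dataset(sim$data, n_hvg = 10, log1p = TRUE)
  expect_equal(n_genes(n), 10)
  expect_true(all(n$gene_names %in% sim$data$gene_names))
  # alignment: columns correspond to the named genes of the input
  j <- match(n$gene_names[1], sim$data$gene_names)
  raw <- as_dense(sim$data)
  libs <- rowSums(raw)
  expect_equal(as_dense(n)[, 1], log1p(raw[, j] * 1e4 / libs))
})

test_that("split_holdout partitions cells and errors on invalid targets", {
  d <- expression_dataset(
    matrix(runif(20 * 3), 20, 3), paste0("c", 1:20), paste0("g", 1:3),
    condition = rep(rep(c("control", "perturbed"), each = 5), 2),
    cell_type = rep(c("A", "B"), each = 10))
  sp <- split_holdout(d, "B")
  expect_equal(n_cells(sp$train), 15)
  expect_equal(n_cells(sp$query), 5)
  expect_equal(n_cells(sp$truth), 5)
  # train retains the target type's control cells
  expect_true(all(sp$query$cell_ids %in% sp$train$cell_ids))
  # partition: train + truth cover everything; train and truth disjoint
  expect_length(intersect(sp$train$cell_ids, sp$truth$cell_ids), 0)
  expect_setequal(c(sp$train$cell_ids, sp$truth$cell_ids), d$cell_ids)
  # a target with only control cells is an error
  d_ctrl <- subset_cells(d, !(d$cell_type == "B" & d$condition == "perturbed"))
  expect_error(split_holdout(d_ctrl, "B"), "no perturbed cells")
  expect_error(split_holdout(d, "Z"), "not present")
})

test_that("nested downsampling is monotone, seeded and exact at fraction 1", {
  sim <- small_sim()
  subs <- downsample_nested(sim$data, c(0.2, 0.5, 1.0), seed = 3)
  ids <- lapply(subs, `[[`, "cell_ids")
  expect_true(all(ids[[1]] %in% ids[[2]]))
  expect_true(all(ids[[2]] %in% ids[[3]]))
  expect_identical(ids[[3]], sim$data$cell_ids)
  # per-type-and-condition stratification: 20% of 80 = 16 per group
  tab <- table(subs[[1]]$cell_type, as.character(subs[[1]]$condition))
  expect_true(all(tab == 16))
  # determinism
  subs_again <- downsample_nested(sim$data, c(0.2, 0.5, 1.0), seed = 3)
  expect_identical(ids[[1]], subs_again[[1]]$cell_ids)
  expect_error(downsample_nested(sim$data, c(0, 0.5)), "fractions")
  expect_error(downsample_nested(sim$data, c(0.5, 0.2)), "ascending")
})

test_that("dropout-noise injection zeroes exactly the contracted count", {
  m <- matrix(0, 4, 5)
  m[1:10] <- seq(0.5, 5, by = 0.5)
  d <- expression_dataset(m, paste0("c", 1:4), paste0("g", 1:5))
  expect_identical(as_dense(inject_dropout_noise(d, 0, seed = 1)), m)
  half <- inject_dropout_noise(d, 0.5, seed = 1)
  expect_equal(sum(as_dense(half) != 0), 5)
  expect_true(all(as_dense(half) <= m))  # never increases an entry
  expect_equal(sum(as_dense(inject_dropout_noise(d, 1, seed = 1)) != 0), 0)
  # floor(0.25 * 10) = 2 entries zeroed
  q <- inject_dropout_noise(d, 0.25, seed = 7)
  expect_equal(sum(as_dense(q) != 0), 8)
  # determinism
  expect_identical(as_dense(inject_dropout_noise(d, 0.5, seed = 1)),
                   as_dense(half))
  expect_error(inject_dropout_noise(d, 1.5), "proportion")
})
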
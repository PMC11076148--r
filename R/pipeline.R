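#' Run configuration for hold-out experiments
#'
#' Bundles the per-stage configurations. All sub-seeds are derived
#' deterministically from the single global `seed`, so a run is a pure
#' function of `(data, config)`.
#'
#' @param vae a [vae_config()] (its own `seed` is overridden by the derived
#'   sub-seed).
#' @param attention an [attention_config()].
#' @param ot list of Sinkhorn options: `epsilon` (NULL = cost-adaptive
#'   default), `max_iter`, `tol`.
#' @param normalize list: `enabled` (apply [normalize_dataset()] first),
#'   `target_sum`, `log1p`, `n_hvg`. Disable for data that is already
#'   log-normalized (the preprocessed-input path).
#' @param n_degs DEG anchor-set size for evaluation.
#' @param seed global integer seed.
#' @param out_dir optional directory; when set, the prediction, report and
#'   manifest are written there.
#' @return a list of class `run_config`.
#' @export
run_config <- function(vae = vae_config(), attention = attention_config(),
                       ot = list(epsilon = NULL, max_iter = 5000, tol = 1e-8),
                       normalize = list(enabled = TRUE, target_sum = 1e4,
                                        log1p = TRUE, n_hvg = NULL),
                       n_degs = 100, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(vae, "vae_config"), inherits(attention, "attention_config"))
  structure(list(vae = vae, attention = attention, ot = ot,
                 normalize = normalize, n_degs = n_degs,
                 seed = .check_seed(seed), out_dir = out_dir),
            class = "run_config")
}

# Deterministic sub-seed derivation; stays within 32-bit integer range.
.sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 2654435 + 97 * k) %% 2147483647)
}

.report_metrics <- function(report) {
  c(r2_mean = report$r2_mean,
    r2_variance = report$r2_variance,
    wasserstein_all_genes = report$wasserstein_all_genes,
    wasserstein_top_degs = report$wasserstein_top_degs,
    n_common_degs = report$n_common_degs)
}

#' Run one hold-out experiment end to end
#'
#' Composition of all stages under the out-of-sample protocol: split off the
#' target type's perturbed cells as truth, train the VAE on the remaining
#' data only, Sinkhorn-match the training control and perturbed latents,
#' compute per-pair perturbation vectors, predict the query (target-type
#' control) cells by attention, and evaluate against the withheld truth.
#' The truth partition is never passed to the train/match/predict stages.
#'
#' @param data an [expression_dataset()] with `condition` and `cell_type`.
#' @param target_type the cell type whose perturbed cells are withheld.
#' @param config a [run_config()].
#' @return an object of class `holdout_run`: list with `prediction`
#'   (an [expression_dataset()]), `report` (an [evaluation_report]), the
#'   fitted `model`, the matching artifacts (`keys`, `values`, coupling
#'   diagnostics), the `split`, and a `manifest`.
#' @export
run_holdout_experiment <- function(data, target_type, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  if (isTRUE(config$normalize$enabled)) {
    data <- normalize_dataset(data,
                              target_sum = config$normalize$target_sum,
                              log1p = isTRUE(config$normalize$log1p),
                              n_hvg = config$normalize$n_hvg)
  }
  tick("normalize")
  split <- split_holdout(data, target_type)
  tick("split")

  vcfg <- config$vae
  vcfg$seed <- .sub_seed(config$seed, 1L)
  model <- .stage(train_vae(split$train, vcfg), "train_vae")
  tick("train_vae")

  is_ctr <- split$train$condition == "control"
  if (!any(is_ctr) || all(is_ctr)) {
    stop("[match] training partition must contain both conditions")
  }
  Zc <- encode(model, subset_cells(split$train, is_ctr))
  Zp <- encode(model, subset_cells(split$train, !is_ctr))
  tick("encode")
  coupling <- .stage(
    sinkhorn(cost_matrix(Zc, Zp),
             epsilon = config$ot$epsilon,
             max_iter = config$ot$max_iter %||% 5000,
             tol = config$ot$tol %||% 1e-8), "match")
  pairs <- match_cells(coupling, Z_ptb = Zp)
  values <- perturbation_vectors(Zc, pairs)
  tick("match")

  prediction <- .stage(
    predict_response(model, Zc, values, split$query, config$attention),
    "predict")
  tick("predict")
  report <- .stage(
    evaluate_holdout(prediction, split$truth, split$query,
                     n_degs = config$n_degs), "evaluate")
  tick("evaluate")

  manifest <- list(
    package = "perturbAttn",
    version = as.character(utils::packageVersion("perturbAttn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    target_type = target_type,
    seed = config$seed,
    derived_seeds = list(vae = vcfg$seed),
    config = .serializable(config),
    n_cells = list(train = n_cells(split$train), query = n_cells(split$query),
                   truth = n_cells(split$truth)),
    coupling = list(epsilon = coupling$epsilon, n_iter = coupling$n_iter,
                    marginal_error = coupling$marginal_error,
                    transport_cost = coupling$transport_cost),
    stage_seconds = as.list(timings))

  run <- structure(list(prediction = prediction, report = report,
                        model = model, keys = Zc, values = values,
                        coupling_diagnostics = manifest$coupling,
                        split = split, manifest = manifest),
                   class = "holdout_run")
  if (!is.null(config$out_dir)) {
    run$manifest$outputs <- .write_run_outputs(run, config$out_dir,
                                               target_type)
  }
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Annotate stage failures with the failing stage name.
.stage <- function(expr, stage) {
  tryCatch(expr, error = function(e) {
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

.serializable <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), .serializable)
  } else if (is.function(x)) {
    NULL
  } else x
}

.write_run_outputs <- function(run, out_dir, target_type) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- gsub("[^A-Za-z0-9_.-]", "_", target_type)
  pred_path <- file.path(out_dir, paste0("prediction_", stem, ".csv"))
  write_dataset(run$prediction, pred_path, format = "csv")
  report_path <- file.path(out_dir, paste0("report_", stem, ".json"))
  rep <- run$report
  rep$per_gene_table <- NULL
  jsonlite::write_json(unclass(rep), report_path, auto_unbox = TRUE,
                       digits = NA)
  per_gene_path <- file.path(out_dir, paste0("per_gene_", stem, ".tsv"))
  data.table::fwrite(run$report$per_gene_table, per_gene_path, sep = "\t")
  files <- c(prediction = pred_path, report = report_path,
             per_gene = per_gene_path)
  digests <- as.list(stats::setNames(tools::md5sum(files), names(files)))
  manifest_path <- file.path(out_dir, paste0("manifest_", stem, ".json"))
  m <- run$manifest
  m$outputs <- digests
  jsonlite::write_json(m, manifest_path, auto_unbox = TRUE, digits = NA)
  digests
}

#' @export
print.holdout_run <- function(x, ...) {
  cat("<holdout_run> target:", x$manifest$target_type, "\n")
  print(x$report)
  invisible(x)
}

#' Run every hold-out sub-experiment of a dataset
#'
#' One sub-experiment per cell type (or per requested type): hold out that
#' type's perturbed cells, retrain, predict, evaluate. Failures of
#' individual sub-experiments are recorded and the run continues.
#'
#' @param data an [expression_dataset()] with `condition` and `cell_type`.
#' @param config a [run_config()].
#' @param types optional subset of cell types; default all types present.
#' @param keep_runs keep the full `holdout_run` objects (models included);
#'   otherwise only reports are retained (default, lighter).
#' @return list with `reports` (named per type; a failed type holds the
#'   error message), `summary` (one row per succeeded type), and optionally
#'   `runs`.
#' @export
run_all_holdouts <- function(data, config = run_config(), types = NULL,
                             keep_runs = FALSE) {
  if (is.null(data$cell_type)) stop("run_all_holdouts requires cell_type")
  if (is.null(types)) types <- sort(unique(data$cell_type))
  reports <- list()
  runs <- list()
  rows <- list()
  for (t in types) {
    res <- tryCatch(run_holdout_experiment(data, t, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("sub-experiment for '", t, "' failed: ", conditionMessage(res))
      reports[[t]] <- conditionMessage(res)
      next
    }
    reports[[t]] <- res$report
    if (keep_runs) runs[[t]] <- res
    rows[[t]] <- data.frame(target_type = t,
                            t(.report_metrics(res$report)),
                            row.names = NULL)
  }
  out <- list(reports = reports,
              summary = if (length(rows)) do.call(rbind, rows) else
                data.frame())
  if (keep_runs) out$runs <- runs
  out
}

# Re-predict and re-evaluate an existing run at a different attention beta,
# reusing the trained model and the transport matching.
.repredict_beta <- function(run, beta, n_degs) {
  cfg <- attention_config(beta = beta)
  pred <- predict_response(run$model, run$keys, run$values, run$split$query,
                           cfg)
  evaluate_holdout(pred, run$split$truth, run$split$query, n_degs = n_degs)
}

#' Robustness protocols
#'
#' Three stress protocols over a grid of parameter values:
#' \describe{
#'   \item{`downsample`}{nested per-type downsampling at fractions 20% to
#'     100%; the whole hold-out suite is re-run on each subset.}
#'   \item{`noise`}{dropout-noise injection zeroing 10%–50% of the non-zero
#'     entries before the hold-out suite.}
#'   \item{`beta_sweep`}{attention proportion swept over
#'     0.001, 0.005, 0.01, 0.05, 0.1; the model and matching are trained
#'     once per target and only the attention/prediction stage is re-run.}
#' }
#'
#' @param data an [expression_dataset()] with `condition` and `cell_type`.
#' @param config a [run_config()].
#' @param mode one of `"downsample"`, `"noise"`, `"beta_sweep"`.
#' @param levels parameter grid; defaults to the protocol's standard grid.
#' @param types optional subset of target cell types.
#' @return a tidy long-format data frame with columns `mode`, `parameter`,
#'   `target_type`, `metric`, `value`.
#' @export
run_robustness_suite <- function(data, config = run_config(),
                                 mode = c("downsample", "noise", "beta_sweep"),
                                 levels = NULL, types = NULL) {
  mode <- match.arg(mode)
  if (is.null(types)) types <- sort(unique(data$cell_type))
  rows <- list()
  add_rows <- function(parameter, target_type, report) {
    m <- .report_metrics(report)
    rows[[length(rows) + 1]] <<- data.frame(
      mode = mode, parameter = parameter, target_type = target_type,
      metric = names(m), value = as.numeric(m), row.names = NULL)
  }
  if (mode == "downsample") {
    levels <- levels %||% c(0.2, 0.4, 0.6, 0.8, 1.0)
    subsets <- downsample_nested(data, fractions = levels,
                                 seed = .sub_seed(config$seed, 11L))
    for (i in seq_along(levels)) {
      res <- run_all_holdouts(subsets[[i]], config, types = types)
      for (t in names(res$reports)) {
        if (inherits(res$reports[[t]], "evaluation_report")) {
          add_rows(levels[i], t, res$reports[[t]])
        }
      }
    }
  } else if (mode == "noise") {
    levels <- levels %||% seq(0.1, 0.5, by = 0.1)
    for (i in seq_along(levels)) {
      noised <- inject_dropout_noise(data, levels[i],
                                     seed = .sub_seed(config$seed, 23L + i))
      res <- run_all_holdouts(noised, config, types = types)
      for (t in names(res$reports)) {
        if (inherits(res$reports[[t]], "evaluation_report")) {
          add_rows(levels[i], t, res$reports[[t]])
        }
      }
    }
  } else {  # beta_sweep
    levels <- levels %||% c(0.001, 0.005, 0.01, 0.05, 0.1)
    for (t in types) {
      run <- tryCatch(run_holdout_experiment(data, t, config),
                      error = function(e) e)
      if (inherits(run, "error")) {
        warning("sub-experiment for '", t, "' failed: ",
                conditionMessage(run))
        next
      }
      for (b in levels) {
        add_rows(b, t, .repredict_beta(run, b, config$n_degs))
      }
    }
  }
  do.call(rbind, rows)
}
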
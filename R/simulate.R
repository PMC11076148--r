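#' Simulation configuration
#'
#' Describes the synthetic world: several cell types with distinct expression
#' centroids, two conditions, and a perturbation that combines a shared
#' (all-types) shift with a type-specific shift concentrated on disjoint
#' marker genes. Defaults emulate a strongly, broadly responding stimulation
#' of closely related subtypes of one lineage (an IFN-beta-on-PBMC-like
#' setting) on a focused gene panel.
#'
#' @param n_types number of cell types.
#' @param cells_per_type_per_condition cells per (type, condition) group.
#' @param n_genes number of genes; must exceed
#'   `n_types * marker_genes_per_type`.
#' @param type_centroid_scale sd of the per-type, per-gene centroid
#'   deviation around the shared base profile (log scale).
#' @param shared_shift_scale sd of the shared per-gene perturbation shift
#'   (log scale), drawn once as `N(0, shared_shift_scale)`.
#' @param type_specific_shift_scale magnitude of the up-regulation added on
#'   each type's marker genes under perturbation.
#' @param marker_genes_per_type number of marker genes per type (disjoint
#'   across types).
#' @param noise_model `"lognormal"` (emits values directly on the
#'   log1p-normalized scale, truncated at zero) or `"negative_binomial"`
#'   (emits counts with `mu = expm1(log-scale value)`, to exercise the
#'   normalization path).
#' @param noise_sd per-gene biological + technical noise sd on the log scale.
#' @param nb_size negative-binomial size (inverse dispersion) for the count
#'   model.
#' @param dropout_rate Bernoulli probability of zeroing each entry
#'   (technical dropout), applied to both conditions alike.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the config.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_types = 3, cells_per_type_per_condition = 500,
                              n_genes = 200, type_centroid_scale = 0.4,
                              shared_shift_scale = 1.2,
                              type_specific_shift_scale = 1.0,
                              marker_genes_per_type = 10,
                              noise_model = c("lognormal",
                                              "negative_binomial"),
                              noise_sd = 0.4, nb_size = 5,
                              dropout_rate = 0.1, seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_types >= 1, cells_per_type_per_condition >= 1, n_genes >= 2,
            type_centroid_scale > 0, type_specific_shift_scale >= 0,
            marker_genes_per_type >= 0, noise_sd > 0, nb_size > 0,
            dropout_rate >= 0, dropout_rate < 1)
  if (n_genes <= marker_genes_per_type * n_types) {
    stop("n_genes must exceed marker_genes_per_type * n_types")
  }
  structure(list(n_types = as.integer(n_types),
                 cells_per_type_per_condition =
                   as.integer(cells_per_type_per_condition),
                 n_genes = as.integer(n_genes),
                 type_centroid_scale = type_centroid_scale,
                 shared_shift_scale = shared_shift_scale,
                 type_specific_shift_scale = type_specific_shift_scale,
                 marker_genes_per_type = as.integer(marker_genes_per_type),
                 noise_model = noise_model, noise_sd = noise_sd,
                 nb_size = nb_size, dropout_rate = dropout_rate,
                 seed = .check_seed(seed)),
            class = "simulation_config")
}

#' Simulate a perturbation dataset with known ground truth
#'
#' Control cells are drawn around their type centroid on the log-expression
#' scale; perturbed cells around `centroid + shared shift + type-specific
#' shift` (the latter non-zero only on that type's marker genes). Bernoulli
#' dropout zeroes entries at `dropout_rate`. Fully deterministic given the
#' config seed.
#'
#' @param config a [simulation_config()].
#' @return a list with `data` (an [expression_dataset()]) and `truth` (class
#'   `simulation_truth`): per-type total shift vectors (genes x types matrix
#'   `shift`), the `shared` shift, per-type `markers`, the `centroids`
#'   matrix, and the config.
#' @export
simulate_perturbation_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  G <- config$n_genes
  T_ <- config$n_types
  nc <- config$cells_per_type_per_condition
  genes <- sprintf("g%04d", seq_len(G))
  types <- paste0("type_", LETTERS[seq_len(T_)])

  base <- stats::runif(G, 1.5, 4.5)
  centroids <- pmax(base + matrix(stats::rnorm(G * T_,
                                               sd = config$type_centroid_scale),
                                  G, T_), 0.1)
  colnames(centroids) <- types
  rownames(centroids) <- genes

  shared <- stats::rnorm(G, sd = config$shared_shift_scale)
  markers <- list()
  pool <- seq_len(G)
  for (t in types) {
    pick <- if (config$marker_genes_per_type > 0) {
      sort(sample(pool, config$marker_genes_per_type))
    } else integer(0)
    pool <- setdiff(pool, pick)
    markers[[t]] <- genes[pick]
  }
  shift <- matrix(shared, G, T_, dimnames = list(genes, types))
  for (t in types) {
    shift[markers[[t]], t] <- shift[markers[[t]], t] +
      config$type_specific_shift_scale
  }

  n_total <- 2 * T_ * nc
  X <- matrix(0, n_total, G)
  cell_type <- character(n_total)
  condition <- character(n_total)
  row <- 0
  for (ti in seq_len(T_)) {
    for (cond in c("control", "perturbed")) {
      mu <- centroids[, ti] + if (cond == "perturbed") shift[, ti] else 0
      L <- matrix(mu, nc, G, byrow = TRUE) +
        matrix(stats::rnorm(nc * G, sd = config$noise_sd), nc, G)
      vals <- if (config$noise_model == "lognormal") {
        pmax(L, 0)
      } else {
        matrix(stats::rnbinom(nc * G, mu = expm1(pmax(L, 0)),
                              size = config$nb_size), nc, G)
      }
      idx <- row + seq_len(nc)
      X[idx, ] <- vals
      cell_type[idx] <- types[ti]
      condition[idx] <- cond
      row <- row + nc
    }
  }
  if (config$dropout_rate > 0) {
    X[matrix(stats::runif(length(X)) < config$dropout_rate,
             nrow(X), ncol(X))] <- 0
  }
  data <- expression_dataset(X, sprintf("cell%05d", seq_len(n_total)), genes,
                             condition = condition, cell_type = cell_type)
  truth <- structure(list(shift = shift, shared = stats::setNames(shared, genes),
                          markers = markers, centroids = centroids,
                          config = config), class = "simulation_truth")
  list(data = data, truth = truth)
}

#' A constant, hand-checkable micro dataset
#'
#' Twelve cells (2 types x 2 conditions x 3 cells), six genes, fixed numeric
#' literals. Gene `g5` is the designed marker: its perturbed values strictly
#' exceed every control value within each type, so it is the top
#' differentially expressed gene under the rank-sum test. Used by unit tests
#' for I/O, splitting and DEG ranking.
#'
#' @return an [expression_dataset()] (byte-identical on every call).
#' @export
make_micro_example <- function() {
  # rows: cells; columns: g1..g6 (g5 = perturbation marker)
  m <- matrix(c(
    # type_A control
    1.0, 2.0, 0.0, 3.0, 0.5, 1.5,
    1.2, 1.8, 0.1, 2.9, 0.7, 1.4,
    0.9, 2.1, 0.0, 3.1, 0.6, 1.6,
    # type_A perturbed
    1.1, 2.2, 0.0, 3.0, 2.5, 1.5,
    1.0, 1.9, 0.2, 2.8, 2.8, 1.3,
    1.3, 2.0, 0.0, 3.2, 2.6, 1.7,
    # type_B control
    3.0, 0.5, 1.0, 1.0, 0.4, 2.5,
    2.8, 0.6, 1.2, 0.9, 0.8, 2.4,
    3.1, 0.4, 0.9, 1.1, 0.3, 2.6,
    # type_B perturbed
    2.9, 0.5, 1.1, 1.0, 3.0, 2.5,
    3.2, 0.7, 1.0, 1.2, 3.2, 2.3,
    3.0, 0.6, 1.3, 0.8, 2.9, 2.7), nrow = 12, ncol = 6, byrow = TRUE)
  expression_dataset(
    m,
    cell_ids = sprintf("mc%02d", 1:12),
    gene_names = paste0("g", 1:6),
    condition = rep(rep(c("control", "perturbed"), each = 3), 2),
    cell_type = rep(c("type_A", "type_B"), each = 6))
}
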
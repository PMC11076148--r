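# perturbAttn

Attention-based prediction of single-cell gene-expression perturbation
responses for held-out cell types.

## The problem

Single-cell sequencing is destructive, so the same cell is never observed
both before and after a stimulus: control and perturbed populations are
unpaired samples. When an entire cell type is missing from the perturbed
data — a new patient, a new species, a hard-to-stimulate population — its
response must be predicted from how *other* types responded. Averaging
approaches assign every cell of a type the same perturbation vector and
miss the cell-level heterogeneity of real responses.

`perturbAttn` predicts a response for every individual query cell:

1. **Embed.** A variational autoencoder maps expression vectors to a latent
   space: `Z_ctr = f_enc(X_ctr)`, `Z_ptb = f_enc(X_ptb)`, trained on the
   loss `−E[log p(x|z)] + α·KL(q(z|x) ‖ N(0, I))` with `z = μ + εσ`.
2. **Match.** Entropic optimal transport with uniform marginals couples the
   unpaired populations: Sinkhorn scaling `u = a/(Kv)`, `v = b/(Kᵀu)`,
   `K = e^(−C/ε)` on the Euclidean cost `C`, giving
   `M = Diag(u) K Diag(v)`. Each control cell is matched to the perturbed
   cell with its row maximum, `p_i = argmax_j M_ij`, yielding per-pair
   perturbation vectors `δ_i = Z'_ptb,i − Z_ctr,i`.
3. **Attend.** For a query latent `z_t`, cosine similarities `s` against
   all training control latents are computed, the top `n_t = βn` selected,
   softmax-normalized into weights `p`, and the query's own vector is
   `δ_t = Σ_j p_j δ_j`. The prediction is `x_prd = f_dec(z_t + δ_t)`.

Cell-type labels are never used by the model — only for the evaluation
split. Evaluation is distributional: exact per-gene 1-D Wasserstein
distances, R² of per-gene means and variances, and overlap of top-100
Wilcoxon rank-sum DEG lists. The package also implements the robustness
protocols (nested downsampling 20–100%, dropout-noise injection 10–50%,
attention-proportion sweep β ∈ 0.001–0.1) and a seed-deterministic
synthetic generator with known ground-truth shift vectors.

## Worked example

Simulate a three-type world with a known perturbation, hold out one type's
perturbed cells, and predict them:

```r
library(perturbAttn)

sim <- simulate_perturbation_dataset(simulation_config(
  n_types = 3, cells_per_type_per_condition = 200, n_genes = 200, seed = 42))

cfg <- run_config(
  vae = vae_config(latent_dim = 12, hidden_dims = 64, epochs = 150,
                   learning_rate = 1.5e-3),
  normalize = list(enabled = FALSE),  # generator emits log-scale values
  seed = 7)

run <- run_holdout_experiment(sim$data, "type_B", cfg)
print(run$report)
#> <evaluation_report>
#>   Wasserstein (all genes):     0.62018
#>   Wasserstein (top 100 DEGs): 0.64514
#>   R2 mean:                     0.8867
#>   R2 variance:                 0.43003
#>   common DEGs (top 100):      78

shift_hat <- colMeans(as_dense(run$prediction)) -
  colMeans(as_dense(run$split$query))
cor(shift_hat, sim$truth$shift[, "type_B"])
#> [1] 0.902
```

Reading the numbers: the predicted perturbed population sits close to the
withheld truth per gene (mean Wasserstein 0.65 over the top-100 DEGs on the
log scale, versus 1.33 for the do-nothing baseline
`evaluate_holdout(query, truth, query)`), per-gene means are recovered with
R² ≈ 0.89, 78 of the 100 true differentially expressed genes are also found
in the prediction, and the predicted mean shift correlates with the
generator's true shift vector at r ≈ 0.90 — even though no perturbed
type_B cell was ever seen. The run takes a few seconds on one CPU.

`run_all_holdouts()` repeats this per type; `run_robustness_suite()` runs
the downsampling / noise / β-sweep protocols and returns a tidy metric
table. A thin command-line front end with `simulate`, `split`, `noise`,
`downsample`, `train`, `match`, `predict`, `holdout`, `robustness` and
`evaluate` subcommands lives at `inst/cli/perturbattn.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main end-to-end result from scratch: it simulates
the default synthetic world from the given seed, holds out one cell type's
perturbed cells, trains the VAE, transport-matches the unpaired
populations, predicts the held-out response by attention, evaluates the
prediction (shift-vector correlation, mean/variance R², Wasserstein
distances, DEG overlap — printed to stderr), and writes the JSON report to
`--out`.

`scripts/reproduce_external.R` documents the corresponding protocols on
the published external datasets (scGen-preprocessed PBMC/IFN-β and the
cross-species LPS macrophage set); it requires manually downloaded h5ad
files and is not part of the test suite.
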
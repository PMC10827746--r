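# scdvae

Disentangled variational autoencoders for multi-batch, multi-condition
single-cell RNA-seq count data.

A multi-sample scRNA-seq study is a grid of count matrices indexed by
technical batch and by donor-level covariates ("condition types": e.g.
treatment = ctrl/stim, severity = healthy/severe). `scdvae` fits a single
model that jointly

1. **removes batch effects while preserving condition effects** — the
   shared-bio factors `z_s` are a batch- and condition-free cell embedding;
2. **detects condition-associated key genes (CKGs)** — per-gene scores
   `s_i = ||w_i||_2` from the group-lasso-penalized input layer of each
   condition type's unshared encoder;
3. **predicts perturbation responses** — expression of given cells under
   any other observed condition combination and batch, via latent
   arithmetic on the unshared-bio factors `z_u`.

## Model

Counts follow a negative binomial,
`x_g ~ NB(mu_g, theta_g)` with `mu = library_size * softmax(decoder(z_s,
z_u, b))`, where `b` is the one-hot batch factor. Posteriors `Q(z_s | x, b)`
and `Q(z_u | x)` are diagonal Gaussians from small MLP encoders. The
training objective is

```
L = -E[log NB(x | z_s, z_u, b)]
    + 1e-5 * KL(Q(z_s) || N(0, I))
    + 1e-2 * KL(Q(z_u) || N(mu_c, sigma_c^2 I))   # mixture component of the cell's label c
    + 1    * mean_genes ||w_i||_2                 # group lasso on the gene-selection layer
    + 1e-4 * (MMD(z_s across batch x condition) + MMD(z_u across extended batches))
    + 1    * cross-entropy(linear classifier(z_u), labels)
```

optimized by alternating Adam steps (shared encoder + decoder, then
unshared encoders + classifiers + mixture prior + decoder) after a short
shared-only warm-up. Everything is implemented in base-R matrix algebra
with analytic backpropagation, verified against numerical gradients in the
test suite. See the methods vignette
(`vignettes/disentangled-nb-vae.Rmd`) for the full model, assumptions,
kernel calibration and numerical choices.

## Worked example

Simulate a ground-truthed benchmark (2 batches, treatment and severity
condition types, 3 cell types, 250 cells per count matrix, 500 genes,
treatment key genes 1–100), fit the model (a few minutes on one core), and
score all three tasks:

```r
library(scdvae)

truth <- simulate_mcd(sim_config(n_cells_per_matrix = 250, seed = 7))
fit <- scdvae(truth$ds, seed = 7)
fit
#> Disentangled NB-VAE fit (scdvae)
#>   genes: 500  batches: 2
#>   condition types: treatment, severity
#>   latent dims: shared 8 / unshared 2 per type
#>   epochs: 175 (hit max_epochs)
#>   final total loss: 1795.09

lat <- extract_latent(fit, truth$ds)
ari_score(truth$ds$conditions$treatment, lat$z_unshared$treatment, seed = 1)
#> [1] 0.98803
ari_score(truth$ds$cell_types, lat$z_shared, seed = 1)
#> [1] 1
asw_batch(lat$z_shared, truth$ds$batch, truth$ds$cell_types)
#> [1] 0.8965036

sc <- ckg_scores(fit)                    # or coef(fit)
auprc(sc$treatment, truth$ckg_sets[[1]])
#> [1] 0.6736302
round(head(sort(sc$treatment, decreasing = TRUE), 3), 4)
#> gene89 gene57 gene98
#> 0.4217 0.3773 0.3631

# predict ctrl/healthy cells of batch1 as stim cells in batch2
input <- subset_cells(truth$ds, truth$ds$conditions$treatment == "ctrl" &
                                truth$ds$conditions$severity == "healthy" &
                                truth$ds$batch == "batch1")
pred <- predict_perturbation(fit, input,
                             target_conditions = list(treatment = "stim"),
                             target_batch = "batch2")
dim(pred)
#> [1] 250 500
```

The treatment ARI near 1 means k-means on the 2-dimensional unshared block
recovers the condition labels almost exactly; the cell-type ARI of 1 and
batch ASW near 0.9 mean the shared embedding separates cell types while
mixing batches; the top-scoring genes all lie in the injected key-gene set
(treatment CKGs are genes 1–100 in this design); the prediction is a
denoised count matrix for the input cells under the counterfactual
condition and batch.

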
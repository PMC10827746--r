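# Small deterministic fixtures shared across test files. Heavier trained
# models used by the acceptance checks are built lazily and cached for the
# duration of the test run.

# A tiny hand-checkable dataset: 4 cells x 3 genes, 2 batches, 1 type.
tiny_ds <- function() {
  x <- matrix(c(1, 0, 2,
                0, 3, 1,
                4, 1, 0,
                2, 2, 2), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  mcd(x, batch = c("b1", "b1", "b2", "b2"),
      conditions = data.frame(treatment = c("ctrl", "stim", "ctrl", "stim")))
}

# Small simulated dataset with strong condition signal, for fast training
# smoke tests (2 condition types, 2 batches, 3 cell types).
small_sim <- function(seed = 5, eps = 8, cells = 30, genes = 60, m_diff = 6) {
  simulate_mcd(sim_config(n_cells_per_matrix = cells, n_genes = genes,
                          m_diff = m_diff, epsilon = eps, seed = seed))
}

# Monte-Carlo KL(q || p) between diagonal Gaussians, used as the
# independent oracle for the closed-form KL terms.
mc_kl <- function(m_q, lv_q, m_p, lv_p, n = 2e5, seed = 1) {
  set.seed(seed)
  d <- length(m_q)
  z <- matrix(stats::rnorm(n * d), n, d)
  zq <- sweep(z, 2, exp(lv_q / 2), "*")
  zq <- sweep(zq, 2, m_q, "+")
  log_q <- -0.5 * rowSums(sweep(sweep(zq, 2, m_q)^2, 2, exp(lv_q), "/") +
                            matrix(lv_q + log(2 * pi), n, d, byrow = TRUE))
  log_p <- -0.5 * rowSums(sweep(sweep(zq, 2, m_p)^2, 2, exp(lv_p), "/") +
                            matrix(lv_p + log(2 * pi), n, d, byrow = TRUE))
  diffs <- log_q - log_p
  list(est = mean(diffs), se = stats::sd(diffs) / sqrt(n))
}

# Cache of expensive trained models, built on first use within a run.
.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fit_cache)) {
    assign(key, builder(), envir = .fit_cache)
  }
  get(key, envir = .fit_cache)
}

# The benchmark-layout training used by the disentanglement / generalization
# acceptance checks: strong condition effect (epsilon 8, m_diff 100), two
# matrices removed from the 2x4 grid, 10% of the remaining cells held out
# for the generalization comparison. 250 cells per matrix keeps the suite
# interactive while leaving every group large enough for the latent
# structure to form.
acc_default <- function() {
  cached("acc_default", function() {
    truth <- simulate_mcd(sim_config(n_cells_per_matrix = 250, m_diff = 100,
                                     epsilon = 8, seed = 2026))
    split <- hold_out_matrices(truth, c("<ctrl,severe>@batch1",
                                       "<stim,healthy>@batch2"))
    ds_all <- split$train$ds
    set.seed(2026)
    test_idx <- sample(n_cells(ds_all), round(0.1 * n_cells(ds_all)))
    ds_train <- subset_cells(ds_all, -test_idx)
    ds_test <- subset_cells(ds_all, test_idx)
    fit <- scdvae(ds_train, seed = 2026, max_epochs = 170)
    list(truth = truth, ds_train = ds_train, ds_test = ds_test, fit = fit)
  })
}

# Out-of-sample prediction layout: the <ctrl, severe> matrix held out in
# BOTH batches, model trained on the remaining 6 matrices.
acc_prediction <- function() {
  cached("acc_prediction", function() {
    truth <- simulate_mcd(sim_config(n_cells_per_matrix = 250, m_diff = 100,
                                     epsilon = 8, seed = 3031))
    split <- hold_out_matrices(truth, c("<ctrl,severe>@batch1",
                                       "<ctrl,severe>@batch2"))
    fit <- scdvae(split$train$ds, seed = 3031, max_epochs = 140)
    list(truth = truth, split = split, fit = fit)
  })
}
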
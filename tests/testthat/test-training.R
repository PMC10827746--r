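test_that("training is reproducible and the loss decreases", {
  ds <- small_sim(seed = 7)$ds
  f1 <- scdvae(ds, hidden = 32, max_epochs = 8, seed = 42)
  f2 <- scdvae(ds, hidden = 32, max_epochs = 8, seed = 42)
  expect_identical(f1$state, f2$state)
  expect_identical(f1$log, f2$log)
  # end-of-training total strictly below the first epoch's
  expect_lt(utils::tail(f1$log$total, 1), f1$log$total[1])
})

test_that("alternating steps freeze the right parameter partitions", {
  ds <- small_sim(seed = 8, cells = 15, genes = 40, m_diff = 4)$ds
  set.seed(2)
  st <- new_model_state(n_genes(ds), n_batches(ds),
                        lapply(ds$conditions, levels), hidden = 16,
                        dropout = 0.2)
  bd <- scdvae:::.prepare_data(ds, ds$gene_ids, levels(ds$batch),
                               lapply(ds$conditions, levels),
                               stats::median(rowSums(ds$counts)))
  bd <- scdvae:::.subset_bd(bd, 1:32)
  w <- loss_weights()
  fw <- scdvae:::.forward_all(bd, st, sample = TRUE, train = TRUE)
  g1 <- scdvae:::.grads_step1(bd, st, fw, w, 5, "sample")$grads
  # step 1 produces gradients only for the shared encoder and decoder
  expect_named(g1, c("enc_s", "dec"))
  g2 <- scdvae:::.grads_step2(bd, st, fw, w, 5, "sample", "sample")$grads
  expect_named(g2, c("enc_u", "cls", "prior", "dec"))

  # applying step 1 through Adam leaves the unshared partition bit-identical
  opt <- scdvae:::.adam_init(list(enc_s = st$enc_s, dec = st$dec))
  upd <- scdvae:::.adam_step(list(enc_s = st$enc_s, dec = st$dec), g1, opt,
                             5e-4)
  st_after <- st
  st_after$enc_s <- upd$params$enc_s; st_after$dec <- upd$params$dec
  expect_identical(st_after$enc_u, st$enc_u)
  expect_identical(st_after$cls, st$cls)
  expect_identical(st_after$prior, st$prior)
  expect_false(identical(st_after$enc_s, st$enc_s))

  # with lambda_ce = lambda_gl = 0 the classifier gradient vanishes and the
  # gene-selection layer only sees the reconstruction path
  w0 <- loss_weights(lambda_ce = 0, lambda_gl = 0)
  g0 <- scdvae:::.grads_step2(bd, st, fw, w0, 5, "sample", "sample")$grads
  expect_equal(max(abs(g0$cls[[1]]$W)), 0)
  expect_equal(max(abs(g0$cls[[2]]$b)), 0)
})

test_that("a separable two-label fixture is classified almost perfectly", {
  # strong condition effect, single condition type
  cfg <- sim_config(n_cells_per_matrix = 40, n_genes = 60, n_batches = 2,
                    condition_types = list(treatment = c("ctrl", "stim")),
                    m_diff = 10, epsilon = 10, lib_meanlog = log(1200),
                    seed = 15)
  ds <- simulate_mcd(cfg)$ds
  fit <- scdvae(ds, hidden = 32, warmup_steps = 30, max_epochs = 100, seed = 3)
  lat <- extract_latent(fit, ds)
  logits <- classify_condition(fit$state, lat$z_unshared[[1]], 1)
  pred <- max.col(logits)
  truth <- as.integer(ds$conditions[[1]])
  expect_gt(mean(pred == truth), 0.95)
})

test_that("loss evaluation is deterministic and validates its inputs", {
  sim <- small_sim(seed = 9)
  fit <- scdvae(sim$ds, hidden = 32, max_epochs = 6, seed = 1)
  e1 <- evaluate_losses(fit, sim$ds)
  e2 <- evaluate_losses(fit, sim$ds)
  expect_identical(e1, e2)
  expect_s3_class(e1, "loss_breakdown")

  # unseen batch level is rejected
  bad <- sim$ds
  levels(bad$batch) <- c("bX", "bY")
  expect_error(evaluate_losses(fit, bad), "not in the encoding set")
  # unseen condition label is rejected
  bad2 <- sim$ds
  levels(bad2$conditions[[1]]) <- c("new1", "new2")
  expect_error(evaluate_losses(fit, bad2), "never seen in training")
})

test_that("fit refuses untrainable datasets", {
  x <- matrix(rpois(40, 3), 10, 4)
  one_label <- mcd(x, batch = rep(c("b1", "b2"), 5),
                   conditions = rep("only", 10))
  expect_error(scdvae(one_label), "fewer than 2 observed labels")

  with_zero <- mcd(rbind(x, 0), batch = rep("b1", 11),
                   conditions = rep(c("a", "b"), c(5, 6)))
  expect_error(scdvae(with_zero), "zero total counts")
})

test_that("analytic gradients match central differences on every parameter
           block", {
  ns <- asNamespace("scdvae")
  truth <- simulate_mcd(sim_config(n_cells_per_matrix = 3, n_genes = 8,
                                   m_diff = 2, epsilon = 4, n_cell_types = 2,
                                   seed = 5))
  ds <- truth$ds
  w <- loss_weights(lambda_kl1 = 0.3, lambda_kl2 = 0.5, lambda_mmd = 0,
                    lambda_ce = 0.7, lambda_gl = 0.4)
  set.seed(11)
  state <- new_model_state(n_genes(ds), n_batches(ds),
                           lapply(ds$conditions, levels),
                           d_shared = 3, d_unshared = 2, hidden = 6,
                           dropout = 0)
  bd <- ns$.prepare_data(ds, ds$gene_ids, levels(ds$batch),
                         lapply(ds$conditions, levels),
                         stats::median(rowSums(ds$counts)))
  bd <- ns$.subset_bd(bd, 1:10)
  G <- n_genes(ds)

  loss_s1 <- function(st) {
    set.seed(42)
    fw <- ns$.forward_all(bd, st, sample = TRUE, train = FALSE)
    recon <- mean(nb_log_likelihood(bd$counts, fw$dec$mu, fw$dec$theta))
    -recon + w$lambda_kl1 * mean(kl_standard_normal(fw$post_s))
  }
  loss_s2 <- function(st) {
    set.seed(42)
    fw <- ns$.forward_all(bd, st, sample = TRUE, train = FALSE)
    recon <- mean(nb_log_likelihood(bd$counts, fw$dec$mu, fw$dec$theta))
    kl_u <- 0; ce <- 0; gl <- 0
    for (k in 1:2) {
      kl_u <- kl_u + mean(kl_gmm_prior(fw$post_u[[k]], bd$label_codes[[k]],
                                       st$prior[[k]]))
      ce <- ce + cross_entropy_loss(bd$label_codes[[k]],
                                    classify_condition(st, fw$zu[[k]]$z, k))
      gl <- gl + group_lasso(st$enc_u[[k]]$l1$W, genes = "rows") / G
    }
    -recon + w$lambda_kl2 * kl_u + w$lambda_ce * ce + w$lambda_gl * gl
  }

  set.seed(42)
  fw <- ns$.forward_all(bd, state, sample = TRUE, train = FALSE)
  g1 <- ns$.grads_step1(bd, state, fw, w, 1, "sample")$grads
  set.seed(42)
  fw <- ns$.forward_all(bd, state, sample = TRUE, train = FALSE)
  g2 <- ns$.grads_step2(bd, state, fw, w, 1, "sample", "sample")$grads

  check <- function(lossfn, get, set, grad, nprobe = 4) {
    leaf <- get(state)
    set.seed(99)
    for (j in sample(length(leaf), min(nprobe, length(leaf)))) {
      h <- 1e-5
      num <- (lossfn(set(state, replace(leaf, j, leaf[j] + h))) -
                lossfn(set(state, replace(leaf, j, leaf[j] - h)))) / (2 * h)
      denom <- max(1e-4, abs(num) + abs(grad[j]))
      expect_lt(abs(num - grad[j]) / denom, 1e-4)
    }
  }
  reshape <- function(v, ref) if (is.matrix(ref)) matrix(v, nrow(ref)) else v

  # step 1: shared encoder and decoder paths
  check(loss_s1, function(s) s$enc_s$l1$W,
        function(s, v) { s$enc_s$l1$W <- reshape(v, s$enc_s$l1$W); s },
        g1$enc_s$l1$W)
  check(loss_s1, function(s) s$enc_s$logvar$W,
        function(s, v) { s$enc_s$logvar$W <- reshape(v, s$enc_s$logvar$W); s },
        g1$enc_s$logvar$W)
  check(loss_s1, function(s) s$dec$mean$W,
        function(s, v) { s$dec$mean$W <- reshape(v, s$dec$mean$W); s },
        g1$dec$mean$W)
  check(loss_s1, function(s) s$dec$theta_raw,
        function(s, v) { s$dec$theta_raw <- v; s }, g1$dec$theta_raw)
  check(loss_s1, function(s) s$dec$l1$W,
        function(s, v) { s$dec$l1$W <- reshape(v, s$dec$l1$W); s },
        g1$dec$l1$W)

  # step 2: unshared encoders, classifier, mixture prior, decoder
  check(loss_s2, function(s) s$enc_u[[1]]$l1$W,
        function(s, v) { s$enc_u[[1]]$l1$W <- reshape(v, s$enc_u[[1]]$l1$W); s },
        g2$enc_u[[1]]$l1$W)
  check(loss_s2, function(s) s$enc_u[[2]]$mean$W,
        function(s, v) { s$enc_u[[2]]$mean$W <- reshape(v, s$enc_u[[2]]$mean$W); s },
        g2$enc_u[[2]]$mean$W)
  check(loss_s2, function(s) s$cls[[1]]$W,
        function(s, v) { s$cls[[1]]$W <- reshape(v, s$cls[[1]]$W); s },
        g2$cls[[1]]$W)
  check(loss_s2, function(s) s$prior[[1]]$mu,
        function(s, v) { s$prior[[1]]$mu <- reshape(v, s$prior[[1]]$mu); s },
        g2$prior[[1]]$mu)
  check(loss_s2, function(s) s$prior[[2]]$logsig,
        function(s, v) { s$prior[[2]]$logsig <- v; s },
        g2$prior[[2]]$logsig)
  check(loss_s2, function(s) s$dec$l2$W,
        function(s, v) { s$dec$l2$W <- reshape(v, s$dec$l2$W); s },
        g2$dec$l2$W)
})

test_that("MMD point gradients match central differences", {
  ns <- asNamespace("scdvae")
  set.seed(8)
  a <- matrix(rnorm(12), 6, 2); b <- matrix(rnorm(10), 5, 2)
  bw <- c(0.7, 1.3)
  r <- ns$.mmd_with_grad(a, b, bandwidths = bw)
  expect_equal(r$value, mmd(a, b, bandwidths = bw), tolerance = 1e-12)
  for (j in sample(length(a), 4)) {
    h <- 1e-6
    num <- (mmd(replace(a, j, a[j] + h), b, bandwidths = bw) -
              mmd(replace(a, j, a[j] - h), b, bandwidths = bw)) / (2 * h)
    expect_equal(r$grad_a[j], num, tolerance = 1e-5)
  }
  for (j in sample(length(b), 4)) {
    h <- 1e-6
    num <- (mmd(a, replace(b, j, b[j] + h), bandwidths = bw) -
              mmd(a, replace(b, j, b[j] - h), bandwidths = bw)) / (2 * h)
    expect_equal(r$grad_b[j], num, tolerance = 1e-5)
  }
})
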
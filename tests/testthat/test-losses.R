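test_that("standard-normal KL closed form is exact and matches Monte Carlo", {
  expect_equal(kl_standard_normal(list(mean = c(0, 0), logvar = c(0, 0))), 0)
  expect_equal(kl_standard_normal(list(mean = c(1, 1), logvar = c(0, 0))), 1)

  set.seed(21)
  for (rep in 1:5) {
    m <- rnorm(3); lv <- rnorm(3, sd = 0.5)
    closed <- kl_standard_normal(list(mean = m, logvar = lv))
    mc <- mc_kl(m, lv, rep(0, 3), rep(0, 3), seed = rep)
    expect_lt(abs(closed - mc$est), 3 * mc$se)
  }
  # matrix form is per-row
  post <- list(mean = rbind(c(0, 0), c(1, 1)), logvar = matrix(0, 2, 2))
  expect_equal(kl_standard_normal(post), c(0, 1))
})

test_that("mixture-prior KL reduces to the labelled component", {
  prior <- list(mu = rbind(c(1, -1), c(0, 2)), logsig = c(log(1.5), 0))
  # posterior equal to its component -> 0
  post <- list(mean = rbind(c(1, -1)), logvar = matrix(2 * log(1.5), 1, 2))
  expect_equal(kl_gmm_prior(post, 1, prior), 0, tolerance = 1e-12)
  # mean shift delta along one axis: KL = delta^2 / (2 sigma^2)
  delta <- 0.8
  post2 <- list(mean = rbind(c(1 + delta, -1)),
                logvar = matrix(2 * log(1.5), 1, 2))
  expect_equal(kl_gmm_prior(post2, 1, prior), delta^2 / (2 * 1.5^2),
               tolerance = 1e-12)
  # random case against the Monte-Carlo oracle
  set.seed(31)
  for (rep in 1:5) {
    m <- rnorm(2); lv <- rnorm(2, sd = 0.4); c_idx <- sample(2, 1)
    closed <- kl_gmm_prior(list(mean = rbind(m), logvar = rbind(lv)),
                           c_idx, prior)
    mc <- mc_kl(m, lv, prior$mu[c_idx, ],
                rep(2 * prior$logsig[c_idx], 2), seed = 100 + rep)
    expect_lt(abs(closed - mc$est), 3 * mc$se)
  }
  expect_error(kl_gmm_prior(post, 5, prior), "unknown")
})

test_that("MMD is a symmetric kernel V-statistic", {
  set.seed(41)
  a <- matrix(rnorm(20), 10, 2)
  b <- matrix(rnorm(16), 8, 2)
  expect_equal(mmd(a, a), 0, tolerance = 1e-12)
  expect_equal(mmd(a, b), mmd(b, a), tolerance = 1e-12)
  expect_error(mmd(a[0, , drop = FALSE], b), "non-empty")
  expect_error(mmd(a, matrix(rnorm(9), 3, 3)), "dimensionality")

  # brute-force kernel double sum on 2-point samples, fixed bandwidths
  a2 <- rbind(c(0, 0), c(1, 1)); b2 <- rbind(c(2, 0), c(0, 2))
  bw <- c(0.9, 1.7)
  k <- function(x, y) sum(exp(-sum((x - y)^2) / (2 * bw^2)))
  brute <- (k(a2[1, ], a2[1, ]) + k(a2[1, ], a2[2, ]) + k(a2[2, ], a2[1, ]) +
              k(a2[2, ], a2[2, ])) / 4 +
    (k(b2[1, ], b2[1, ]) + k(b2[1, ], b2[2, ]) + k(b2[2, ], b2[1, ]) +
       k(b2[2, ], b2[2, ])) / 4 -
    2 * (k(a2[1, ], b2[1, ]) + k(a2[1, ], b2[2, ]) + k(a2[2, ], b2[1, ]) +
           k(a2[2, ], b2[2, ])) / 4
  expect_equal(mmd(a2, b2, bandwidths = bw), brute, tolerance = 1e-8)
})

test_that("MMD between same-distribution samples shrinks with n", {
  set.seed(51)
  vals <- sapply(c(50, 500, 2000), function(n) {
    mmd(matrix(rnorm(2 * n), n, 2), matrix(rnorm(2 * n), n, 2))
  })
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[3], 0.01)
})

test_that("grouped MMD picks the largest group as reference", {
  set.seed(61)
  z <- matrix(rnorm(40), 20, 2)
  g2 <- factor(rep(c("a", "b"), c(12, 8)))
  expect_equal(mmd_shared(z, g2),
               mmd(z[1:12, ], z[13:20, ]), tolerance = 1e-12)
  # three identical groups -> 0
  z3 <- rbind(z[1:5, ], z[1:5, ], z[1:5, ])
  expect_equal(mmd_shared(z3, factor(rep(1:3, each = 5))), 0,
               tolerance = 1e-12)
  expect_warning(v <- mmd_shared(z, factor(rep("only", 20))), "fewer than")
  expect_equal(v, 0)
  # explicit reference check: sum of mmd(largest, other)
  g3 <- factor(rep(c("a", "b", "c"), c(4, 10, 6)))
  manual <- mmd(z[5:14, ], z[1:4, ]) + mmd(z[5:14, ], z[15:20, ])
  expect_equal(mmd_shared(z, g3), manual, tolerance = 1e-12)
})

test_that("unshared MMD groups by label and extended batch", {
  set.seed(71)
  z <- matrix(rnorm(48), 24, 2)
  labels <- factor(rep(c("ctrl", "stim"), each = 12))
  batch <- factor(rep(rep(c("b1", "b2"), each = 6), 2))
  # K = 1, single batch -> 0
  expect_equal(mmd_unshared(z, labels, factor(rep("b1", 24))), 0)
  # per-label pairwise mmd, never across labels
  manual <- mmd(z[1:6, ], z[7:12, ]) + mmd(z[13:18, ], z[19:24, ])
  expect_equal(mmd_unshared(z, labels, batch), manual, tolerance = 1e-12)

  # K = 2: extended batches enumerate batch x other-type labels
  other <- factor(rep(c("h", "s"), 12))
  ext <- interaction(batch, other)
  val <- mmd_unshared(z, labels, ext)
  manual2 <- 0
  for (lab in c("ctrl", "stim")) {
    idx <- which(labels == lab)
    sub <- droplevels(ext[idx])
    sizes <- table(sub)
    ref <- names(sizes)[which.max(sizes)]
    for (o in setdiff(levels(sub), ref)) {
      manual2 <- manual2 + mmd(z[idx[sub == ref], , drop = FALSE],
                               z[idx[sub == o], , drop = FALSE])
    }
  }
  expect_equal(val, manual2, tolerance = 1e-12)
})

test_that("group lasso sums per-gene column norms", {
  expect_equal(group_lasso(diag(4)), 4)
  expect_equal(group_lasso(matrix(0, 3, 5)), 0)
  set.seed(81)
  W <- matrix(rnorm(15), 3, 5)
  expect_equal(group_lasso(W), sum(apply(W, 2, function(c) sqrt(sum(c^2)))),
               tolerance = 1e-12)
  expect_equal(group_lasso(t(W), genes = "rows"), group_lasso(W))
})

test_that("cross entropy matches manual softmax computation", {
  expect_equal(cross_entropy_loss(c(1, 2), matrix(0, 2, 4)), log(4))
  # very confident correct logits push the loss to 0
  confident <- rbind(c(50, 0, 0), c(0, 50, 0))
  expect_lt(cross_entropy_loss(c(1, 2), confident), 1e-15)
  # toy 2 x 3 case by hand
  logits <- rbind(c(1, 2, 0.5), c(-1, 0, 1))
  manual <- mean(c(-log(exp(2) / sum(exp(logits[1, ]))),
                   -log(exp(1) / sum(exp(logits[2, ])))))
  expect_equal(cross_entropy_loss(c(2, 3), logits), manual, tolerance = 1e-12)
  expect_error(cross_entropy_loss(c(1, 9), logits), "out of range")
})

test_that("total loss recombines its components exactly", {
  ds <- small_sim(seed = 12, cells = 10, genes = 30, m_diff = 3)$ds
  set.seed(5)
  st <- new_model_state(n_genes(ds), n_batches(ds),
                        lapply(ds$conditions, levels), hidden = 16,
                        dropout = 0)
  bd <- scdvae:::.prepare_data(ds, ds$gene_ids, levels(ds$batch),
                               lapply(ds$conditions, levels),
                               stats::median(rowSums(ds$counts)))
  w <- loss_weights()
  lb <- total_loss(bd, st, w, sample = FALSE, mmd_scale = 1)
  recombined <- -lb$reconstruction + w$lambda_kl1 * lb$kl_shared +
    w$lambda_kl2 * lb$kl_unshared + w$lambda_gl * lb$group_lasso +
    w$lambda_mmd * (lb$mmd_shared + lb$mmd_unshared) +
    w$lambda_ce * lb$cross_entropy
  expect_equal(lb$total, recombined, tolerance = 1e-6 * abs(lb$total))

  # all lambdas zero -> total is the negative reconstruction term
  w0 <- loss_weights(0, 0, 0, 0, 0)
  lb0 <- total_loss(bd, st, w0, sample = FALSE, mmd_scale = 1)
  expect_equal(lb0$total, -lb0$reconstruction, tolerance = 1e-12)

  # composition oracle: components equal independently invoked operations
  fw <- scdvae:::.forward_all(bd, st, sample = FALSE, train = FALSE)
  expect_equal(lb$reconstruction,
               mean(nb_log_likelihood(bd$counts, fw$dec$mu, fw$dec$theta)))
  expect_equal(lb$kl_shared, mean(kl_standard_normal(fw$post_s)))
  kl_u <- mean(kl_gmm_prior(fw$post_u[[1]], bd$label_codes[[1]], st$prior[[1]])) +
    mean(kl_gmm_prior(fw$post_u[[2]], bd$label_codes[[2]], st$prior[[2]]))
  expect_equal(lb$kl_unshared, kl_u)
  # the objective's group-lasso component is the per-gene mean column norm
  gl <- group_lasso(st$enc_u[[1]]$l1$W, genes = "rows") / n_genes(ds) +
    group_lasso(st$enc_u[[2]]$l1$W, genes = "rows") / n_genes(ds)
  expect_equal(lb$group_lasso, gl)
  ce <- cross_entropy_loss(bd$label_codes[[1]],
                           classify_condition(st, fw$post_u[[1]]$mean, 1)) +
    cross_entropy_loss(bd$label_codes[[2]],
                       classify_condition(st, fw$post_u[[2]]$mean, 2))
  expect_equal(lb$cross_entropy, ce)
  expect_equal(lb$mmd_shared, mmd_shared(fw$post_s$mean, bd$group))
  # signs: every penalty is non-negative; reconstruction loglik is <= 0
  expect_true(all(c(lb$kl_shared, lb$kl_unshared, lb$mmd_shared,
                    lb$mmd_unshared, lb$cross_entropy, lb$group_lasso) >= 0))
  expect_lt(lb$reconstruction, 0)
})
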
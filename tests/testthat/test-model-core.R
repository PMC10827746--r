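# Helper: a state with every weight and bias zeroed.
zero_state <- function(ds, d_s = 3, d_u = 2, hidden = 4) {
  set.seed(1)
  st <- new_model_state(n_genes(ds), n_batches(ds),
                        lapply(ds$conditions, levels),
                        d_shared = d_s, d_unshared = d_u, hidden = hidden,
                        dropout = 0)
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  st$enc_s <- zero(st$enc_s); st$enc_u <- zero(st$enc_u)
  st$dec <- zero(st$dec); st$cls <- zero(st$cls)
  st
}

prep <- function(ds) {
  scdvae:::.prepare_data(ds, ds$gene_ids, levels(ds$batch),
                         lapply(ds$conditions, levels),
                         stats::median(rowSums(ds$counts)))
}

test_that("encoders: zero weights give zero posteriors, batch factor matters", {
  ds <- tiny_ds()
  bd <- prep(ds)
  st0 <- zero_state(ds)
  post <- encode_shared(st0, bd$xin, bd$bmat)
  expect_equal(unname(post$mean), matrix(0, 4, 3))
  expect_equal(unname(post$logvar), matrix(0, 4, 3))
  postu <- encode_unshared(st0, bd$xin, 1)
  expect_equal(unname(postu$mean), matrix(0, 4, 2))

  # a random state distinguishes two cells identical except for batch
  set.seed(9)
  st <- new_model_state(3, 2, list(c("ctrl", "stim")), d_shared = 3,
                        d_unshared = 2, hidden = 8, dropout = 0)
  xin <- matrix(bd$xin[1, ], 2, 3, byrow = TRUE)
  bmat <- rbind(c(1, 0), c(0, 1))
  p2 <- encode_shared(st, xin, bmat)
  expect_gt(max(abs(p2$mean[1, ] - p2$mean[2, ])), 1e-8)

  # determinism with dropout off
  pa <- encode_shared(st, xin, bmat); pb <- encode_shared(st, xin, bmat)
  expect_identical(pa$mean, pb$mean)
  expect_error(encode_shared(st, xin[, 1:2, drop = FALSE], bmat), "mismatch")
  expect_error(encode_unshared(st, xin, 3), "invalid condition-type")
})

test_that("unshared encoder ignores dead gene columns only", {
  ds <- tiny_ds()
  bd <- prep(ds)
  set.seed(4)
  st <- new_model_state(3, 2, list(c("ctrl", "stim")), hidden = 8,
                        dropout = 0)
  st$enc_u[[1]]$l1$W[2, ] <- 0          # gene 2 carries no weight
  x1 <- bd$xin
  x2 <- x1; x2[, 2] <- x2[, 2] + 5
  expect_identical(encode_unshared(st, x1, 1)$mean,
                   encode_unshared(st, x2, 1)$mean)
  x3 <- x1; x3[, 1] <- x3[, 1] + 5      # live gene changes the posterior
  expect_gt(max(abs(encode_unshared(st, x3, 1)$mean -
                      encode_unshared(st, x1, 1)$mean)), 1e-8)
})

test_that("reparameterized sampling matches its posterior", {
  post <- list(mean = matrix(c(1, -2), 1), logvar = matrix(c(-60, -60), 1))
  expect_equal(sample_latent(post)$z, post$mean, tolerance = 1e-10)

  set.seed(3); s1 <- sample_latent(list(mean = matrix(0, 1, 2),
                                        logvar = matrix(0, 1, 2)))
  set.seed(3); s2 <- sample_latent(list(mean = matrix(0, 1, 2),
                                        logvar = matrix(0, 1, 2)))
  expect_identical(s1$z, s2$z)

  # 1e5 draws reproduce the posterior moments within 3 SE
  n <- 1e5
  post <- list(mean = matrix(0.7, n, 1), logvar = matrix(log(2.25), n, 1))
  set.seed(11)
  z <- sample_latent(post)$z
  expect_lt(abs(mean(z) - 0.7), 3 * 1.5 / sqrt(n))
  se_var <- 2.25 * sqrt(2 / (n - 1))
  expect_lt(abs(stats::var(as.vector(z)) - 2.25), 3 * se_var)
})

test_that("decoder obeys the softmax/library-size contract", {
  ds <- tiny_ds()
  st0 <- zero_state(ds)
  zs <- matrix(0.3, 4, 3); zu <- list(matrix(-0.2, 4, 2))
  bmat <- prep(ds)$bmat
  out <- decode(st0, zs, zu, bmat, library_size = c(3, 6, 9, 12))
  # all-equal mean head -> uniform signal 1/G
  expect_equal(unname(out$pi), matrix(1 / 3, 4, 3))
  expect_equal(unname(rowSums(out$mu)), c(3, 6, 9, 12))
  expect_true(all(out$theta > 0))

  set.seed(2)
  st <- new_model_state(3, 2, list(c("ctrl", "stim")), d_shared = 3,
                        hidden = 8, dropout = 0)
  o1 <- decode(st, zs, zu, bmat, library_size = rep(2, 4))
  o2 <- decode(st, zs, zu, bmat, library_size = rep(4, 4))
  expect_equal(o2$mu, 2 * o1$mu, tolerance = 1e-12)       # scaling contract
  expect_equal(unname(rowSums(o1$pi)), rep(1, 4))                 # normalization
  o3 <- decode(st, zs, zu, bmat, library_size = rep(2, 4))
  expect_identical(o1$mu, o3$mu)                           # reproducible
  zs_bad <- zs; zs_bad[1, 1] <- NaN
  expect_error(decode(st, zs_bad, zu, bmat, rep(2, 4)), "non-finite")
})

test_that("NB log-likelihood matches the closed-form pmf", {
  # x = 0, mu = 1, theta = 1: log(theta/(theta+mu))^theta = log(1/2)
  expect_equal(nb_log_likelihood(0, 1, 1), log(0.5), tolerance = 1e-12)
  # x = 2, mu = 1, theta = 1: Gamma(3)/(Gamma(1) 2!) (1/2)^1 (1/2)^2 = 1/8
  expect_equal(nb_log_likelihood(2, 1, 1), log(1 / 8), tolerance = 1e-12)

  # Poisson limit at huge dispersion
  for (x in 0:10) {
    expect_equal(nb_log_likelihood(x, 3, 1e6), stats::dpois(x, 3, log = TRUE),
                 tolerance = 1e-3)
  }

  # high-precision direct pmf on a grid, via log-gamma arithmetic
  direct <- function(x, mu, th) {
    lgamma(x + th) - lgamma(th) - lgamma(x + 1) +
      th * log(th / (th + mu)) + x * log(mu / (th + mu))
  }
  for (mu in c(0.1, 1, 10)) for (th in c(0.5, 2, 50)) for (x in c(0:5, 20)) {
    expect_equal(nb_log_likelihood(x, mu, th), direct(x, mu, th),
                 tolerance = 1e-8)
  }

  # matrix form sums over genes per cell
  x <- matrix(c(0, 2, 1, 3), 2, 2)
  mu <- matrix(c(1, 1, 2, 2), 2, 2)
  expect_equal(nb_log_likelihood(x, mu, c(1, 5)),
               c(sum(direct(c(0, 1), c(1, 2), c(1, 5))),
                 sum(direct(c(2, 3), c(1, 2), c(1, 5)))))
})

test_that("condition classifier is a plain affine map", {
  set.seed(6)
  st <- new_model_state(3, 2, list(c("a", "b", "c")), d_unshared = 2,
                        hidden = 4, dropout = 0)
  zu <- matrix(rnorm(4), 2, 2)
  logits <- classify_condition(st, zu, 1)
  manual <- zu %*% st$cls[[1]]$W + matrix(st$cls[[1]]$b, 2, 3, byrow = TRUE)
  expect_equal(logits, manual, tolerance = 1e-12)

  st$cls[[1]]$W[] <- 0; st$cls[[1]]$b[] <- 0
  p <- exp(classify_condition(st, zu, 1))
  expect_equal(unname(p / rowSums(p)), matrix(1 / 3, 2, 3))

  # logit margins scale linearly with the latent scale
  set.seed(7)
  st2 <- new_model_state(3, 2, list(c("a", "b", "c")), hidden = 4, dropout = 0)
  l1 <- classify_condition(st2, zu, 1)
  l2 <- classify_condition(st2, 2 * zu, 1)
  expect_equal(l2 - matrix(st2$cls[[1]]$b, 2, 3, byrow = TRUE),
               2 * (l1 - matrix(st2$cls[[1]]$b, 2, 3, byrow = TRUE)),
               tolerance = 1e-12)
})
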
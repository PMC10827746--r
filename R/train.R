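# Alternating two-step stochastic training.
#
# Each minibatch takes two Adam steps: step 1 updates the shared encoder and
# decoder on  L_s1 = -recon + lambda_kl1 * KL(z_s) + lambda_mmd * MMD(z_s)
# with the unshared encoders/classifiers frozen; step 2 freezes the shared
# encoder and updates the unshared encoders, classifiers, mixture-prior
# parameters and decoder on  L_s2 = -recon + lambda_kl2 * KL(z_u) +
# lambda_mmd * MMD(z_u) + lambda_ce * CE + lambda_gl * GL.  The decoder is
# updated in both steps; each step owns its own Adam moment state so moment
# statistics respect the freezing scheme.  All gradients are analytic and
# checked against numerical differentiation in the test suite.

# ---- data preparation ---------------------------------------------------

# Resolve a dataset against a training-time coordinate system (gene order,
# batch levels, condition levels) and precompute model inputs. Encoder
# input is log1p of library-size-stabilized counts, standardized per gene
# with the training-time location/scale so the encoder dynamics do not
# depend on sequencing depth.
.prepare_data <- function(ds, gene_ids, batch_levels, condition_levels,
                          lib_median, xin_center = NULL, xin_scale = NULL) {
  if (!identical(ds$gene_ids, gene_ids)) {
    missing <- setdiff(gene_ids, ds$gene_ids)
    if (length(missing)) {
      stop("dataset is missing ", length(missing), " training gene(s): ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) ", ..." else "")
    }
    ds$counts <- ds$counts[, gene_ids, drop = FALSE]
    ds$gene_ids <- gene_ids
  }
  K <- length(condition_levels)
  if (ncol(ds$conditions) != K) {
    stop("dataset has ", ncol(ds$conditions), " condition types; model was ",
         "trained with ", K)
  }
  libsize <- rowSums(ds$counts)
  xin <- log1p(ds$counts / libsize * lib_median)
  if (is.null(xin_center)) xin_center <- colMeans(xin)
  if (is.null(xin_scale)) xin_scale <- rep(1, ncol(xin))  # center-only
  xin <- sweep(sweep(xin, 2, xin_center), 2, xin_scale, "/")
  bmat <- batch_factor_matrix(ds, levels = batch_levels)
  labels <- vector("list", K); codes <- vector("list", K)
  for (k in seq_len(K)) {
    lv <- condition_levels[[k]]
    ck <- match(as.character(ds$conditions[[k]]), lv)
    if (anyNA(ck)) {
      stop("condition type '", names(ds$conditions)[k], "' has label(s) ",
           "never seen in training: ",
           paste(unique(as.character(ds$conditions[[k]])[is.na(ck)]),
                 collapse = ", "))
    }
    codes[[k]] <- ck
    labels[[k]] <- factor(lv[ck], levels = lv)
  }
  combo <- do.call(paste, c(lapply(labels, as.character), sep = "<>"))
  group <- factor(paste(as.character(ds$batch), combo, sep = "|"))
  ext_batch <- vector("list", K)
  for (k in seq_len(K)) {
    others <- if (K > 1) {
      do.call(paste, c(lapply(labels[-k], as.character), sep = "<>"))
    } else rep("", nrow(ds$counts))
    ext_batch[[k]] <- factor(paste(as.character(ds$batch), others, sep = "|"))
  }
  list(counts = ds$counts, xin = xin, bmat = bmat, libsize = libsize,
       labels = labels, label_codes = codes, group = group,
       ext_batch = ext_batch, xin_center = xin_center, xin_scale = xin_scale)
}

.subset_bd <- function(bd, idx) {
  list(counts = bd$counts[idx, , drop = FALSE],
       xin = bd$xin[idx, , drop = FALSE],
       bmat = bd$bmat[idx, , drop = FALSE],
       libsize = bd$libsize[idx],
       labels = lapply(bd$labels, `[`, idx),
       label_codes = lapply(bd$label_codes, `[`, idx),
       group = bd$group[idx],
       ext_batch = lapply(bd$ext_batch, `[`, idx))
}

# ---- backward passes ----------------------------------------------------

# Gradient of -mean(NB loglik) w.r.t. decoder parameters; returns decoder
# grads plus gradients w.r.t. z_s and each z_u (through the decoder input).
.backward_recon <- function(bd, state, fw) {
  n <- nrow(bd$counts)
  dc <- fw$dec$cache
  x <- bd$counts; mu <- fw$dec$mu
  if (state$dispersion == "gene") {
    th <- matrix(fw$dec$theta, n, ncol(x), byrow = TRUE)
  } else th <- fw$dec$theta
  ratio <- (x + th) / (mu + th)
  dmu <- -(x / mu - ratio) / n
  # softmax mean head: mu = pi * libsize
  S <- dmu * dc$library_size
  pi <- dc$pi
  dR <- pi * (S - rowSums(S * pi))
  g <- list(mean = list(W = crossprod(dc$h2d, dR), b = colSums(dR)))
  dH2d <- tcrossprod(dR, state$dec$mean$W)
  # dispersion: d loglik / d theta summed in log-gamma space
  if (state$dispersion == "gene") {
    thv <- fw$dec$theta
    dth_col <- -(colSums(digamma(x + th)) - n * digamma(thv) +
                   n * (log(thv) + 1) - colSums(log(th + mu)) -
                   colSums(ratio)) / n
    g$theta_raw <- dth_col * .sigmoid(state$dec$theta_raw)
  } else {
    dth <- -(digamma(x + th) - digamma(th) + log(th) + 1 - log(th + mu) -
               ratio) / n
    dpre <- dth * .sigmoid(dc$disp_raw)
    g$disp <- list(W = crossprod(dc$h2d, dpre), b = colSums(dpre))
    dH2d <- dH2d + tcrossprod(dpre, state$dec$disp$W)
    g$theta_raw <- state$dec$theta_raw * 0
  }
  dH2 <- if (is.null(dc$m2)) dH2d else dH2d * dc$m2
  dA2 <- dH2 * (dc$a2 > 0)
  g$l2 <- list(W = crossprod(dc$h1d, dA2), b = colSums(dA2))
  dH1d <- tcrossprod(dA2, state$dec$l2$W)
  dH1 <- if (is.null(dc$m1)) dH1d else dH1d * dc$m1
  dA1 <- dH1 * (dc$a1 > 0)
  g$l1 <- list(W = crossprod(dc$zin, dA1), b = colSums(dA1))
  dzin <- tcrossprod(dA1, state$dec$l1$W)
  ds_dim <- state$dims$d_shared; du <- state$dims$d_unshared
  dzs <- dzin[, seq_len(ds_dim), drop = FALSE]
  dzu <- vector("list", state$dims$K)
  for (k in seq_len(state$dims$K)) {
    off <- ds_dim + (k - 1) * du
    dzu[[k]] <- dzin[, off + seq_len(du), drop = FALSE]
  }
  list(dec = g, dzs = dzs, dzu = dzu)
}

# Backprop posterior-parameter gradients through the shared encoder.
.backward_enc_shared <- function(state, cache, dmu, dlv) {
  dlv_raw <- dlv * (abs(cache$lv_raw) < .LOGVAR_CLAMP)
  g <- list(mean = list(W = crossprod(cache$h2d, dmu), b = colSums(dmu)),
            logvar = list(W = crossprod(cache$h2d, dlv_raw),
                          b = colSums(dlv_raw)))
  dH2d <- tcrossprod(dmu, state$enc_s$mean$W) +
    tcrossprod(dlv_raw, state$enc_s$logvar$W)
  dH2 <- if (is.null(cache$m2)) dH2d else dH2d * cache$m2
  dA2 <- dH2 * (cache$a2 > 0)
  g$l2 <- list(W = crossprod(cache$h1d, dA2), b = colSums(dA2))
  dH1d <- tcrossprod(dA2, state$enc_s$l2$W)
  dH1 <- if (is.null(cache$m1)) dH1d else dH1d * cache$m1
  dA1 <- dH1 * (cache$a1 > 0)
  g$l1 <- list(W = crossprod(cache$xb, dA1), b = colSums(dA1))
  g
}

.backward_enc_unshared <- function(state, k, cache, dmu, dlv) {
  enc <- state$enc_u[[k]]
  dlv_raw <- dlv * (abs(cache$lv_raw) < .LOGVAR_CLAMP)
  g <- list(mean = list(W = crossprod(cache$h1d, dmu), b = colSums(dmu)),
            logvar = list(W = crossprod(cache$h1d, dlv_raw),
                          b = colSums(dlv_raw)))
  dH1d <- tcrossprod(dmu, enc$mean$W) + tcrossprod(dlv_raw, enc$logvar$W)
  dH1 <- if (is.null(cache$m1)) dH1d else dH1d * cache$m1
  dA1 <- dH1 * (cache$a1 > 0)
  g$l1 <- list(W = crossprod(cache$xin, dA1), b = colSums(dA1))
  g
}

# Step-1 gradients: shared encoder + decoder under L_s1.
.grads_step1 <- function(bd, state, fw, weights, min_group, mmd_on,
                         mmd_scale = 3e4, mmd_bandwidths = NULL) {
  n <- nrow(bd$counts)
  rec <- .backward_recon(bd, state, fw)
  dzs <- rec$dzs
  dmu_direct <- 0
  mmd_s <- 0
  if (weights$lambda_mmd > 0) {
    src <- if (mmd_on == "sample") fw$zs$z else fw$post_s$mean
    mg <- suppressWarnings(.mmd_grouped(src, bd$group, min_group,
                                        grad = TRUE,
                                        bandwidths = mmd_bandwidths))
    mmd_s <- mmd_scale * mg$value
    w_eff <- weights$lambda_mmd * mmd_scale
    if (mmd_on == "sample") dzs <- dzs + w_eff * mg$grad
    else dmu_direct <- w_eff * mg$grad
  }
  # reparameterization: z = m + exp(lv/2) eps
  dmu <- dzs + dmu_direct
  dlv <- dzs * fw$zs$eps * 0.5 * exp(fw$post_s$logvar / 2)
  # closed-form KL(N(m, s^2) || N(0, I)) gradients
  dmu <- dmu + weights$lambda_kl1 / n * fw$post_s$mean
  dlv <- dlv + weights$lambda_kl1 / n * 0.5 * (exp(fw$post_s$logvar) - 1)
  list(grads = list(enc_s = .backward_enc_shared(state, fw$post_s$cache,
                                                 dmu, dlv),
                    dec = rec$dec),
       mmd_shared = mmd_s)
}

# Step-2 gradients: unshared encoders, classifiers, prior, decoder under L_s2.
.grads_step2 <- function(bd, state, fw, weights, min_group, mmd_on,
                         classify_on, mmd_scale = 3e4,
                         mmd_bandwidths = NULL) {
  n <- nrow(bd$counts)
  rec <- .backward_recon(bd, state, fw)
  enc_u_g <- vector("list", state$dims$K)
  cls_g <- vector("list", state$dims$K)
  prior_g <- vector("list", state$dims$K)
  mmd_u_total <- 0; ce_total <- 0
  for (k in seq_len(state$dims$K)) {
    post <- fw$post_u[[k]]
    z <- fw$zu[[k]]$z
    dz <- rec$dzu[[k]]
    dmu_direct <- 0; dlv_direct <- 0
    if (weights$lambda_mmd > 0) {
      src <- if (mmd_on == "sample") z else post$mean
      mg <- .mmd_unshared_impl(src, bd$labels[[k]], bd$ext_batch[[k]],
                               min_group, grad = TRUE,
                               bandwidths = mmd_bandwidths)
      mmd_u_total <- mmd_u_total + mmd_scale * mg$value
      w_eff <- weights$lambda_mmd * mmd_scale
      if (mmd_on == "sample") dz <- dz + w_eff * mg$grad
      else dmu_direct <- dmu_direct + w_eff * mg$grad
    }
    # classifier cross entropy
    zin_cls <- if (classify_on == "sample") z else post$mean
    logits <- classify_condition(state, zin_cls, k)
    P <- .softmax_rows(logits)
    codes <- bd$label_codes[[k]]
    ce_total <- ce_total + cross_entropy_loss(codes, logits)
    Y <- matrix(0, n, ncol(P)); Y[cbind(seq_len(n), codes)] <- 1
    dlogits <- weights$lambda_ce * (P - Y) / n
    cls_g[[k]] <- list(W = crossprod(zin_cls, dlogits), b = colSums(dlogits))
    dcls <- tcrossprod(dlogits, state$cls[[k]]$W)
    if (classify_on == "sample") dz <- dz + dcls
    else dmu_direct <- dmu_direct + dcls
    # reparameterization
    dmu <- dz + dmu_direct
    dlv <- dz * fw$zu[[k]]$eps * 0.5 * exp(post$logvar / 2) + dlv_direct
    # KL to the label's mixture component
    pr <- state$prior[[k]]
    mu_c <- pr$mu[codes, , drop = FALSE]
    sig2 <- exp(2 * pr$logsig[codes])
    dmu <- dmu + weights$lambda_kl2 / n * (post$mean - mu_c) / sig2
    dlv <- dlv + weights$lambda_kl2 / n *
      (exp(post$logvar) / (2 * sig2) - 0.5)
    dmu_pr <- pr$mu * 0; dlogsig_pr <- pr$logsig * 0
    du <- ncol(post$mean)
    for (c in seq_len(nrow(pr$mu))) {
      idx <- which(codes == c)
      if (!length(idx)) next
      mc <- post$mean[idx, , drop = FALSE]
      lvc <- post$logvar[idx, , drop = FALSE]
      s2 <- exp(2 * pr$logsig[c])
      dmu_pr[c, ] <- -weights$lambda_kl2 / n *
        colSums((mc - matrix(pr$mu[c, ], length(idx), du, byrow = TRUE)) / s2)
      dev <- rowSums(exp(lvc)) +
        rowSums((mc - matrix(pr$mu[c, ], length(idx), du, byrow = TRUE))^2)
      dlogsig_pr[c] <- weights$lambda_kl2 / n * sum(du - dev / s2)
    }
    prior_g[[k]] <- list(mu = dmu_pr, logsig = dlogsig_pr)
    g <- .backward_enc_unshared(state, k, post$cache, dmu, dlv)
    # group-lasso subgradient on the gene-selection layer (rows = genes)
    if (weights$lambda_gl > 0) {
      W1 <- state$enc_u[[k]]$l1$W
      nrm <- sqrt(rowSums(W1^2))
      nz <- nrm > 1e-12
      sub <- W1 * 0
      sub[nz, ] <- W1[nz, , drop = FALSE] / nrm[nz]
      g$l1$W <- g$l1$W + weights$lambda_gl / nrow(W1) * sub
    }
    enc_u_g[[k]] <- g
  }
  list(grads = list(enc_u = enc_u_g, cls = cls_g, prior = prior_g,
                    dec = rec$dec),
       mmd_unshared = mmd_u_total, cross_entropy = ce_total)
}

# ---- the fitter ---------------------------------------------------------

#' Fit a disentangled variational autoencoder to multi-condition count data
#'
#' Trains the full model — shared encoder, one unshared encoder and linear
#' classifier per condition type, Gaussian-mixture prior, and a negative
#' binomial decoder — by alternating stochastic optimization with Adam.
#' Initialization, minibatch shuffling, dropout and reparameterization draws
#' are all determined by `seed`, so runs with the same seed and data produce
#' identical parameters.
#'
#' @param ds an [mcd()] dataset; every condition type must have at least two
#'   observed labels.
#' @param d_shared,d_unshared latent dimensions of the shared-bio and (per
#'   condition type) unshared-bio factors; defaults 8 and 2.
#' @param hidden hidden-layer width (default 128).
#' @param weights a [loss_weights()] object.
#' @param learning_rate Adam learning rate (default 5e-4).
#' @param minibatch minibatch size (default 64).
#' @param max_epochs hard stop; the default (`NULL`) budgets roughly 4400
#'   alternating optimizer steps after the warm-up (at least 100 and at most
#'   400 epochs). Training also stops early when the best epoch-mean total
#'   loss stops improving (see `convergence_window`).
#' @param convergence_window,convergence_tol convergence rule (defaults 10
#'   epochs, 1e-4 relative).
#' @param dropout dropout rate (default 0.2).
#' @param dispersion `"gene"` (default) or `"gene-cell"` NB dispersion.
#' @param seed integer RNG seed controlling everything stochastic.
#' @param warmup_steps optimizer steps of shared-only training (step 1
#'   alone) before the alternating scheme starts (default: 0.7 steps per
#'   training cell, capped at 1200); gives the
#'   shared factors a head start on the cell-level structure so the
#'   supervised unshared side does not absorb it, without handing the shared
#'   side so much of one that the decoder stops listening to the unshared
#'   factors. Counted in steps, not epochs, so the balance of the two phases
#'   does not depend on dataset size.
#' @param mmd_min_group minibatch groups smaller than this are skipped in the
#'   MMD terms (default 5; V-statistics on tiny groups are noise).
#' @param mmd_bandwidths fixed bandwidths of the Gaussian alignment kernel
#'   (default 0.5, 1, 2 — the natural unit scale of the latent space). Fixed
#'   bandwidths make the alignment pressure vanish once groups overlap; the
#'   adaptive median heuristic re-sharpens as the space contracts and can
#'   drive a runaway collapse of the latents.
#' @param mmd_kernel_scale amplitude of the Gaussian alignment kernel
#'   (default 3e4). The recommended `lambda_mmd = 1e-4` presumes a kernel
#'   normalization under which the alignment term balances the per-cell
#'   reconstruction likelihood; with the unit-amplitude RBF V-statistic the
#'   term would be inert. The amplitude is calibrated so that the documented
#'   behaviour of the recommended weight holds: alignment strong enough to
#'   remove condition and batch structure from the shared factors, not so
#'   strong that it over-corrects them (see the methods vignette).
#' @param classify_on,mmd_on compute the classifier / MMD terms on the
#'   posterior means (`"mean"`, default: lower-variance gradients, and the
#'   aligned quantity is exactly the embedding used downstream) or on the
#'   sampled latents (`"sample"`).
#' @param verbose print per-epoch loss totals.
#' @return An object of class `"scdvae"`; see [predict.scdvae()],
#'   [coef.scdvae()], [extract_latent()], [denoise()],
#'   [predict_perturbation()], [evaluate_losses()].
#' @examples
#' sim <- simulate_mcd(sim_config(n_cells_per_matrix = 40, n_genes = 60,
#'                                m_diff = 5, epsilon = 8, seed = 1))
#' fit <- scdvae(sim$ds, max_epochs = 2, seed = 1)
#' fit
#' @export
scdvae <- function(ds, d_shared = 8, d_unshared = 2, hidden = 128,
                   weights = loss_weights(), learning_rate = 5e-4,
                   minibatch = 64, max_epochs = NULL,
                   convergence_window = 30, convergence_tol = 1e-5,
                   dropout = 0.2, dispersion = c("gene", "gene-cell"),
                   seed = 1, warmup_steps = NULL, mmd_min_group = 5,
                   mmd_kernel_scale = 3e4,
                   mmd_bandwidths = c(0.5, 1, 2),
                   classify_on = c("mean", "sample"),
                   mmd_on = c("mean", "sample"), verbose = FALSE) {
  stopifnot(inherits(ds, "mcd"))
  dispersion <- match.arg(dispersion)
  classify_on <- match.arg(classify_on)
  mmd_on <- match.arg(mmd_on)
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (minibatch < 2) stop("minibatch size must be at least 2")
  .check_trainable(ds)

  cl <- match.call()
  n <- n_cells(ds)
  steps_per_epoch <- max(1, ceiling(n / minibatch))
  # data-size-aware schedule: the shared warm-up needs enough passes over
  # the data to imprint the cell-level structure but must not entrench the
  # decoder on the shared factors alone; the alternating phase needs a few
  # thousand optimizer steps for the supervised unshared side and degrades
  # (latent structure migrates between blocks) if run several-fold longer.
  if (is.null(warmup_steps)) {
    warmup_steps <- min(1200, ceiling(0.7 * n))
  }
  if (is.null(max_epochs)) {
    max_epochs <- min(400, max(100, ceiling((warmup_steps + 4400) /
                                              steps_per_epoch)))
  }
  cond_levels <- lapply(ds$conditions, levels)
  lib_median <- stats::median(rowSums(ds$counts))

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  state <- new_model_state(n_genes(ds), n_batches(ds), cond_levels,
                           d_shared = d_shared, d_unshared = d_unshared,
                           hidden = hidden, dropout = dropout,
                           dispersion = dispersion)
  bd_full <- .prepare_data(ds, ds$gene_ids, levels(ds$batch), cond_levels,
                           lib_median)
  xin_center <- bd_full$xin_center
  xin_scale <- bd_full$xin_scale

  part1 <- list(enc_s = state$enc_s, dec = state$dec)
  part2 <- list(enc_u = state$enc_u, cls = state$cls, prior = state$prior,
                dec = state$dec)
  opt1 <- .adam_init(part1)
  opt2 <- .adam_init(part2)

  log_rows <- vector("list", max_epochs)
  converged <- FALSE
  epoch <- 0
  step_count <- 0
  warmup_epochs <- ceiling(warmup_steps / max(1, ceiling(n / minibatch)))
  comp_names <- c("reconstruction", "kl_shared", "kl_unshared", "mmd_shared",
                  "mmd_unshared", "cross_entropy", "group_lasso", "total")
  while (epoch < max_epochs) {
    epoch <- epoch + 1
    ord <- sample.int(n)
    starts <- seq(1, n, by = minibatch)
    acc <- stats::setNames(numeric(length(comp_names)), comp_names)
    nb <- 0
    for (s in starts) {
      idx <- ord[s:min(s + minibatch - 1, n)]
      if (length(idx) < 2) next
      bd <- .subset_bd(bd_full, idx)
      ncell <- length(idx)
      step_count <- step_count + 1

      # -- step 1: shared encoder + decoder --------------------------------
      fw <- .forward_all(bd, state, sample = TRUE, train = TRUE)
      kl_s <- mean(kl_standard_normal(fw$post_s))
      g1 <- .grads_step1(bd, state, fw, weights, mmd_min_group, mmd_on,
                         mmd_kernel_scale, mmd_bandwidths)
      upd <- .adam_step(list(enc_s = state$enc_s, dec = state$dec),
                        g1$grads, opt1, learning_rate)
      opt1 <- upd$opt
      state$enc_s <- upd$params$enc_s
      state$dec <- upd$params$dec

      # -- step 2: unshared encoders, classifiers, prior, decoder ----------
      # (skipped during the shared warm-up phase, which lets the shared
      # factors bootstrap the cell-level structure before the supervised
      # unshared side starts competing for it)
      if (step_count <= warmup_steps) {
        acc <- acc + c(recon1 <- mean(nb_log_likelihood(bd$counts, fw$dec$mu,
                                                        fw$dec$theta)),
                       kl_s, 0, g1$mmd_shared, 0, 0, 0,
                       -recon1 + weights$lambda_kl1 * kl_s +
                         weights$lambda_mmd * g1$mmd_shared)
        nb <- nb + 1
        next
      }
      fw <- .forward_all(bd, state, sample = TRUE, train = TRUE)
      recon2 <- mean(nb_log_likelihood(bd$counts, fw$dec$mu, fw$dec$theta))
      kl_u <- 0; gl <- 0
      for (k in seq_len(state$dims$K)) {
        kl_u <- kl_u + mean(kl_gmm_prior(fw$post_u[[k]], bd$label_codes[[k]],
                                         state$prior[[k]]))
        gl <- gl + group_lasso(state$enc_u[[k]]$l1$W, genes = "rows") /
          nrow(state$enc_u[[k]]$l1$W)
      }
      g2 <- .grads_step2(bd, state, fw, weights, mmd_min_group, mmd_on,
                         classify_on, mmd_kernel_scale, mmd_bandwidths)
      upd <- .adam_step(list(enc_u = state$enc_u, cls = state$cls,
                             prior = state$prior, dec = state$dec),
                        g2$grads, opt2, learning_rate)
      opt2 <- upd$opt
      state$enc_u <- upd$params$enc_u
      state$cls <- upd$params$cls
      state$prior <- upd$params$prior
      state$dec <- upd$params$dec

      total <- -recon2 + weights$lambda_kl1 * kl_s +
        weights$lambda_kl2 * kl_u + weights$lambda_gl * gl +
        weights$lambda_mmd * (g1$mmd_shared + g2$mmd_unshared) +
        weights$lambda_ce * g2$cross_entropy
      if (!is.finite(total)) {
        stop("training diverged at epoch ", epoch,
             " (non-finite total loss); try a lower learning rate")
      }
      acc <- acc + c(recon2, kl_s, kl_u, g1$mmd_shared, g2$mmd_unshared,
                     g2$cross_entropy, gl, total)
      nb <- nb + 1
    }
    acc <- acc / nb
    log_rows[[epoch]] <- c(epoch = epoch, acc)
    if (verbose) {
      message(sprintf("epoch %3d  total %.4f  recon %.2f", epoch,
                      acc["total"], acc["reconstruction"]))
    }
    if (epoch > warmup_epochs + convergence_window) {
      # stop when the best epoch-mean total has not improved over the window
      totals <- vapply(log_rows[seq_len(epoch)], `[[`, numeric(1), "total")
      best_now <- min(totals[(warmup_epochs + 1):epoch])
      best_before <- min(totals[(warmup_epochs + 1):(epoch - convergence_window)])
      if (is.finite(best_before) &&
          (best_before - best_now) < convergence_tol * abs(best_before)) {
        converged <- TRUE
        break
      }
    }
  }
  log <- as.data.frame(do.call(rbind, log_rows[seq_len(epoch)]))

  object <- structure(
    list(state = state, weights = weights, gene_ids = ds$gene_ids,
         batch_levels = levels(ds$batch), condition_levels = cond_levels,
         condition_names = names(ds$conditions), lib_median = lib_median,
         xin_center = xin_center, xin_scale = xin_scale,
         log = log, converged = converged, epochs = epoch,
         config = list(d_shared = d_shared, d_unshared = d_unshared,
                       hidden = hidden, weights = unclass(weights),
                       learning_rate = learning_rate, minibatch = minibatch,
                       max_epochs = max_epochs,
                       convergence_window = convergence_window,
                       convergence_tol = convergence_tol,
                       warmup_steps = warmup_steps,
                       mmd_kernel_scale = mmd_kernel_scale,
                       mmd_bandwidths = mmd_bandwidths, dropout = dropout,
                       dispersion = dispersion, seed = seed,
                       mmd_min_group = mmd_min_group,
                       classify_on = classify_on, mmd_on = mmd_on),
         call = cl),
    class = "scdvae")

  # cache per-label mean unshared posterior means over the training cells,
  # so perturbation prediction needs no access to the training data
  lat <- extract_latent(object, ds)
  object$delta_means <- lapply(seq_along(cond_levels), function(k) {
    m <- t(vapply(cond_levels[[k]], function(lv) {
      colMeans(lat$z_unshared[[k]][bd_full$labels[[k]] == lv, , drop = FALSE])
    }, numeric(d_unshared)))
    rownames(m) <- cond_levels[[k]]
    m
  })
  names(object$delta_means) <- names(ds$conditions)
  object
}

#' Forward-only loss evaluation of a trained model
#'
#' Computes every component of the objective on a dataset with dropout
#' disabled and posterior means in place of sampled latents, so repeated
#' calls are bit-identical and no parameters change. Used for the in-sample
#' and out-of-sample generalization checks comparing training and test
#' losses.
#'
#' @param object a fitted [scdvae()] model.
#' @param ds an [mcd()] dataset over the training gene set whose batches and
#'   labels appeared in training.
#' @param weights loss weights (defaults to the training weights).
#' @return A `loss_breakdown` list.
#' @export
evaluate_losses <- function(object, ds, weights = object$weights) {
  stopifnot(inherits(object, "scdvae"))
  bd <- .prepare_data(ds, object$gene_ids, object$batch_levels,
                      object$condition_levels, object$lib_median,
                      object$xin_center, object$xin_scale)
  total_loss(bd, object$state, weights, sample = FALSE, train = FALSE,
             min_group = 1,
             mmd_scale = object$config$mmd_kernel_scale %||% 3e4,
             mmd_bandwidths = object$config$mmd_bandwidths)
}
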
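# Objective components. Each term is exposed on its own so it can be tested
# against an independent oracle (closed forms vs Monte Carlo, kernel double
# sums vs brute force) before entering the weighted objective.

#' Loss weights of the training objective
#'
#' Non-negative weights of the regularization terms. The defaults are the
#' recommended setting (kl shared 1e-5, kl unshared 1e-2, mmd 1e-4, cross
#' entropy 1, group lasso 1): the shared-KL weight is kept small to let cell
#' types separate, the unshared-KL weight ties z_u to its mixture prior, the
#' MMD weight aligns groups without over-correcting, and the classifier and
#' group-lasso terms carry unit weight.
#'
#' @param lambda_kl1 weight of the shared-factor KL term.
#' @param lambda_kl2 weight of the unshared-factor (mixture-prior) KL term.
#' @param lambda_mmd weight of the two MMD alignment terms.
#' @param lambda_ce weight of the condition classifier cross entropy.
#' @param lambda_gl weight of the group-lasso gene-selection penalty.
#' @return A named list of class `"loss_weights"`.
#' @export
loss_weights <- function(lambda_kl1 = 1e-5, lambda_kl2 = 1e-2,
                         lambda_mmd = 1e-4, lambda_ce = 1, lambda_gl = 1) {
  w <- list(lambda_kl1 = lambda_kl1, lambda_kl2 = lambda_kl2,
            lambda_mmd = lambda_mmd, lambda_ce = lambda_ce,
            lambda_gl = lambda_gl)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  structure(w, class = "loss_weights")
}

#' KL divergence from a diagonal Gaussian to the standard normal
#'
#' Closed form `0.5 * sum(exp(lv) + m^2 - 1 - lv)` per posterior, summed
#' over latent dimensions. This is the prior term of the shared-bio factors.
#'
#' @param posterior list with `mean` and `logvar`; vectors for one
#'   posterior, or matrices with one posterior per row.
#' @return Non-negative scalar, or a per-row vector for matrix input.
#' @export
kl_standard_normal <- function(posterior) {
  m <- posterior$mean; lv <- posterior$logvar
  if (is.matrix(m)) {
    0.5 * rowSums(exp(lv) + m^2 - 1 - lv)
  } else {
    0.5 * sum(exp(lv) + m^2 - 1 - lv)
  }
}

#' KL divergence to a Gaussian-mixture prior component
#'
#' Because every cell's condition label is known, the mixture-prior KL for
#' the unshared-bio factors reduces to the closed-form KL against the single
#' component `N(mu_c, sigma_c^2 I)` of the cell's label `c` (scalar
#' isotropic sigma_c).
#'
#' @param posterior list with `mean`/`logvar` (matrices, cells by d, or
#'   vectors).
#' @param labels integer label codes (one per cell) into the prior rows.
#' @param prior list with `mu` (labels by d matrix) and `logsig`
#'   (per-label log sigma_c).
#' @return Per-cell non-negative KL values.
#' @export
kl_gmm_prior <- function(posterior, labels, prior) {
  m <- posterior$mean; lv <- posterior$logvar
  if (!is.matrix(m)) { m <- matrix(m, 1); lv <- matrix(lv, 1) }
  labels <- as.integer(labels)
  if (any(labels < 1) || any(labels > nrow(prior$mu))) {
    stop("unknown condition label code in kl_gmm_prior")
  }
  mu_c <- prior$mu[labels, , drop = FALSE]
  logsig <- prior$logsig[labels]
  sig2 <- exp(2 * logsig)
  d <- ncol(m)
  d * logsig - 0.5 * rowSums(lv) +
    (rowSums(exp(lv)) + rowSums((m - mu_c)^2)) / (2 * sig2) - d / 2
}

# Multi-bandwidth Gaussian kernel bandwidths from the median pairwise
# distance of the pooled sample (the median heuristic); recomputed per call.
.mmd_bandwidths <- function(pooled) {
  d2 <- as.vector(stats::dist(pooled))
  med <- stats::median(d2)
  if (!is.finite(med) || med <= 0) med <- 1
  med * c(0.5, 1, 2)
}

.rbf_cross <- function(a, b, bw) {
  # sum over bandwidths of exp(-||a_i - b_j||^2 / (2 s^2))
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  out <- 0
  for (s in bw) out <- out + exp(-d2 / (2 * s^2))
  out
}

#' Maximum mean discrepancy between two samples
#'
#' Biased V-statistic form `mean(k_aa) + mean(k_bb) - 2 mean(k_ab)` under a
#' sum of Gaussian RBF kernels at bandwidths `{s/2, s, 2s}` where `s` is the
#' median pairwise distance of the pooled sample. Symmetric in its
#' arguments, non-negative, and exactly 0 when the samples coincide as
#' multisets.
#'
#' @param sample_a,sample_b numeric matrices with observations in rows and
#'   equal numbers of columns.
#' @param bandwidths optional kernel bandwidths overriding the median
#'   heuristic.
#' @return Non-negative scalar.
#' @export
mmd <- function(sample_a, sample_b, bandwidths = NULL) {
  if (!is.matrix(sample_a)) sample_a <- matrix(sample_a, ncol = 1)
  if (!is.matrix(sample_b)) sample_b <- matrix(sample_b, ncol = 1)
  if (nrow(sample_a) == 0 || nrow(sample_b) == 0) {
    stop("mmd requires two non-empty samples")
  }
  if (ncol(sample_a) != ncol(sample_b)) {
    stop("mmd samples must share dimensionality")
  }
  if (is.null(bandwidths)) bandwidths <- .mmd_bandwidths(rbind(sample_a, sample_b))
  kaa <- .rbf_cross(sample_a, sample_a, bandwidths)
  kbb <- .rbf_cross(sample_b, sample_b, bandwidths)
  kab <- .rbf_cross(sample_a, sample_b, bandwidths)
  max(mean(kaa) + mean(kbb) - 2 * mean(kab), 0)
}

# mmd value plus gradients w.r.t. the points of both samples (bandwidths
# treated as constants, as is standard for the median heuristic).
.mmd_with_grad <- function(a, b, bandwidths = NULL) {
  if (is.null(bandwidths)) bandwidths <- .mmd_bandwidths(rbind(a, b))
  na <- nrow(a); nb <- nrow(b)
  d2aa <- outer(rowSums(a^2), rowSums(a^2), "+") - 2 * tcrossprod(a)
  d2bb <- outer(rowSums(b^2), rowSums(b^2), "+") - 2 * tcrossprod(b)
  d2ab <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2aa[d2aa < 0] <- 0; d2bb[d2bb < 0] <- 0; d2ab[d2ab < 0] <- 0
  kaa <- 0; kbb <- 0; kab <- 0          # kernel values
  waa <- 0; wbb <- 0; wab <- 0          # kernel values / s^2 (grad weights)
  for (s in bandwidths) {
    eaa <- exp(-d2aa / (2 * s^2)); kaa <- kaa + eaa; waa <- waa + eaa / s^2
    ebb <- exp(-d2bb / (2 * s^2)); kbb <- kbb + ebb; wbb <- wbb + ebb / s^2
    eab <- exp(-d2ab / (2 * s^2)); kab <- kab + eab; wab <- wab + eab / s^2
  }
  value <- mean(kaa) + mean(kbb) - 2 * mean(kab)
  # d/da_i mean(kaa): -(2/na^2) sum_j waa_ij (a_i - a_j)
  ga <- -(2 / na^2) * (rowSums(waa) * a - waa %*% a) +
    (2 / (na * nb)) * (rowSums(wab) * a - wab %*% b)
  gb <- -(2 / nb^2) * (rowSums(wbb) * b - wbb %*% b) +
    (2 / (na * nb)) * (colSums(wab) * b - t(wab) %*% a)
  list(value = max(value, 0), grad_a = ga, grad_b = gb)
}

#' MMD alignment loss of the shared-bio factors
#'
#' Sums the MMD between a reference group and every other group, where
#' groups are the observed (batch, condition-combination) populations and
#' the reference is the group with the largest cell population (ties broken
#' by first group in categorical order). Driving this to zero makes the
#' shared-bio factors independent of batch and of every condition type.
#'
#' @param zs shared-bio factor matrix (cells by d).
#' @param groups factor assigning each cell to a (batch, condition
#'   combination) group.
#' @param min_group groups with fewer cells are skipped (V-statistics on
#'   tiny groups are noise-dominated); default 1 keeps everything.
#' @return Non-negative scalar; 0 with a warning when only one group exists.
#' @export
mmd_shared <- function(zs, groups, min_group = 1) {
  .mmd_grouped(zs, groups, min_group)$value
}

.mmd_grouped <- function(z, groups, min_group = 1, grad = FALSE,
                         warn = TRUE, bandwidths = NULL) {
  groups <- droplevels(as.factor(groups))
  sizes <- table(groups)
  keep <- names(sizes)[sizes >= min_group]
  if (length(keep) < 2) {
    if (warn && length(levels(groups)) < 2) {
      warning("fewer than two groups; MMD alignment term is 0")
    }
    return(list(value = 0, grad = if (grad) z * 0 else NULL))
  }
  ref <- keep[which.max(sizes[keep])]  # which.max: first max in order
  g <- if (grad) z * 0 else NULL
  value <- 0
  ref_idx <- which(groups == ref)
  for (other in setdiff(keep, ref)) {
    idx <- which(groups == other)
    if (grad) {
      r <- .mmd_with_grad(z[ref_idx, , drop = FALSE], z[idx, , drop = FALSE],
                          bandwidths = bandwidths)
      value <- value + r$value
      g[ref_idx, ] <- g[ref_idx, ] + r$grad_a
      g[idx, ] <- g[idx, ] + r$grad_b
    } else {
      value <- value + mmd(z[ref_idx, , drop = FALSE], z[idx, , drop = FALSE],
                           bandwidths = bandwidths)
    }
  }
  list(value = value, grad = g)
}

#' MMD alignment loss of the unshared-bio factors of one condition type
#'
#' For each label `c` of the condition type, cells carrying `c` are split
#' into "extended batches" — unique combinations of batch and the labels of
#' every other condition type — and the MMD between the largest such group
#' (the per-label reference) and each remaining group is summed. Factors are
#' never compared across different labels of the condition type itself,
#' whose separation is condition signal, not nuisance.
#'
#' @param zu unshared-bio factors of the condition type (cells by d).
#' @param labels factor of that type's per-cell condition labels.
#' @param extended_batch factor of per-cell batch-by-other-type-label
#'   combinations.
#' @param min_group see [mmd_shared()].
#' @return Non-negative scalar; a label observed in a single group
#'   contributes 0.
#' @export
mmd_unshared <- function(zu, labels, extended_batch, min_group = 1) {
  .mmd_unshared_impl(zu, labels, extended_batch, min_group)$value
}

.mmd_unshared_impl <- function(zu, labels, extended_batch, min_group = 1,
                               grad = FALSE, bandwidths = NULL) {
  labels <- as.factor(labels)
  value <- 0
  g <- if (grad) zu * 0 else NULL
  for (c in levels(labels)) {
    idx <- which(labels == c)
    if (!length(idx)) next
    sub <- .mmd_grouped(zu[idx, , drop = FALSE],
                        droplevels(factor(extended_batch[idx])),
                        min_group, grad = grad, warn = FALSE,
                        bandwidths = bandwidths)
    value <- value + sub$value
    if (grad && !is.null(sub$grad)) g[idx, ] <- g[idx, ] + sub$grad
  }
  list(value = value, grad = g)
}

#' Group-lasso penalty of a gene-selection weight matrix
#'
#' Sum over genes of the L2 norm of the weight group connecting that gene to
#' the first hidden layer of an unshared encoder: `sum_i ||w_i||_2` over the
#' `d` per-gene columns of `W`. Penalizing whole per-gene groups drives the
#' encoder to select few discriminative genes, whose surviving norms become
#' the key-gene scores.
#'
#' @param W weight matrix with one column per gene (the field's column
#'   convention; pass `genes = "rows"` for a rows-per-gene layout).
#' @param genes whether genes index the columns (default) or rows of `W`.
#' @return Non-negative scalar.
#' @export
group_lasso <- function(W, genes = c("columns", "rows")) {
  genes <- match.arg(genes)
  if (genes == "columns") sum(sqrt(colSums(W^2))) else sum(sqrt(rowSums(W^2)))
}

#' Multiclass cross-entropy loss
#'
#' Mean negative log-probability of the true labels under the softmax of the
#' logits.
#'
#' @param labels integer codes (1-based) or factor, one per row of `logits`.
#' @param logits numeric matrix, cells by classes.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(labels, logits) {
  labels <- if (is.numeric(labels)) as.integer(labels)
            else as.integer(as.factor(labels))
  if (any(labels < 1) || any(labels > ncol(logits))) {
    stop("label code out of range for ", ncol(logits), " classes")
  }
  lse <- apply(logits, 1, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
  mean(lse - logits[cbind(seq_along(labels), labels)])
}

#' Full objective on a set of cells
#'
#' Runs the model forward (posterior means plus reparameterized samples) on
#' `cells` and assembles every component of the training objective:
#' `total = -reconstruction + lambda_kl1 * kl_shared + lambda_kl2 *
#' kl_unshared + lambda_gl * group_lasso + lambda_mmd * (mmd_shared +
#' mmd_unshared) + lambda_ce * cross_entropy`, with the cross-entropy and
#' group-lasso terms summed over condition types. Mostly an internal; the
#' user-level entry point is [evaluate_losses()].
#'
#' @param batchdata prepared minibatch as built by the trainer (counts,
#'   stabilized input, batch factors, label codes, group factors).
#' @param state an `scdvae_state`.
#' @param weights a [loss_weights()] object.
#' @param sample logical: draw reparameterized latents (TRUE, training
#'   behaviour) or use posterior means (FALSE, deterministic evaluation).
#' @param train enable dropout.
#' @param min_group minibatch MMD group-size threshold.
#' @param mmd_scale amplitude of the alignment kernel: the MMD components
#'   enter the objective as `mmd_scale` times the unit-kernel V-statistic
#'   (see [scdvae()]).
#' @param mmd_bandwidths fixed kernel bandwidths for the alignment terms;
#'   `NULL` uses the per-call median heuristic.
#' @return A list of class `"loss_breakdown"` with every component and the
#'   weighted `total`.
#' @export
total_loss <- function(batchdata, state, weights = loss_weights(),
                       sample = TRUE, train = FALSE, min_group = 1,
                       mmd_scale = 3e4, mmd_bandwidths = NULL) {
  fw <- .forward_all(batchdata, state, sample = sample, train = train)
  .loss_from_forward(fw, batchdata, state, weights, min_group = min_group,
                     mmd_scale = mmd_scale, mmd_bandwidths = mmd_bandwidths)
}

# Forward pass over all pieces; used by total_loss and the trainer.
.forward_all <- function(bd, state, sample = TRUE, train = FALSE) {
  post_s <- encode_shared(state, bd$xin, bd$bmat, train = train)
  zs <- if (sample) sample_latent(post_s) else list(z = post_s$mean, eps = NULL)
  post_u <- vector("list", state$dims$K)
  zu <- vector("list", state$dims$K)
  for (k in seq_len(state$dims$K)) {
    post_u[[k]] <- encode_unshared(state, bd$xin, k, train = train)
    zu[[k]] <- if (sample) sample_latent(post_u[[k]])
               else list(z = post_u[[k]]$mean, eps = NULL)
  }
  dec <- decode(state, zs$z, lapply(zu, `[[`, "z"), bd$bmat, bd$libsize,
                train = train)
  list(post_s = post_s, zs = zs, post_u = post_u, zu = zu, dec = dec)
}

.loss_from_forward <- function(fw, bd, state, weights, min_group = 1,
                               mmd_scale = 3e4, mmd_bandwidths = NULL) {
  n <- nrow(bd$counts)
  recon <- mean(nb_log_likelihood(bd$counts, fw$dec$mu, fw$dec$theta))
  kl_s <- mean(kl_standard_normal(fw$post_s))
  kl_u <- 0; ce <- 0; gl <- 0; mmd_u <- 0
  for (k in seq_len(state$dims$K)) {
    kl_u <- kl_u + mean(kl_gmm_prior(fw$post_u[[k]], bd$label_codes[[k]],
                                     state$prior[[k]]))
    logits <- classify_condition(state, fw$zu[[k]]$z, k)
    ce <- ce + cross_entropy_loss(bd$label_codes[[k]], logits)
    gl <- gl + group_lasso(state$enc_u[[k]]$l1$W, genes = "rows") /
      nrow(state$enc_u[[k]]$l1$W)
    mmd_u <- mmd_u + mmd_scale *
      .mmd_unshared_impl(fw$zu[[k]]$z, bd$labels[[k]],
                         bd$ext_batch[[k]], min_group,
                         bandwidths = mmd_bandwidths)$value
  }
  mmd_s <- mmd_scale *
    suppressWarnings(.mmd_grouped(fw$zs$z, bd$group, min_group,
                                  bandwidths = mmd_bandwidths)$value)
  total <- -recon + weights$lambda_kl1 * kl_s + weights$lambda_kl2 * kl_u +
    weights$lambda_gl * gl + weights$lambda_mmd * (mmd_s + mmd_u) +
    weights$lambda_ce * ce
  structure(list(reconstruction = recon, kl_shared = kl_s, kl_unshared = kl_u,
                 mmd_shared = mmd_s, mmd_unshared = mmd_u,
                 cross_entropy = ce, group_lasso = gl, total = total,
                 n_cells = n),
            class = "loss_breakdown")
}

#' @method print loss_breakdown
#' @export
print.loss_breakdown <- function(x, ...) {
  cat("Loss breakdown over", x$n_cells, "cells\n")
  for (nm in c("reconstruction", "kl_shared", "kl_unshared", "mmd_shared",
               "mmd_unshared", "cross_entropy", "group_lasso", "total")) {
    cat(sprintf("  %-15s %12.6g\n", nm, x[[nm]]))
  }
  invisible(x)
}
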
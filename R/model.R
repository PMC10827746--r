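# Model state: encoder/decoder/classifier/prior parameterization.
#
# The shared encoder consumes log1p library-size-stabilized counts with the
# one-hot batch factor appended, and is a 3-layer fully connected network:
# two affine-ReLU-dropout blocks of 128 units, then separate affine heads
# for the posterior mean and log-variance of the shared-bio factors z_s.
# Each condition type has its own unshared encoder (one affine-ReLU-dropout
# block whose input-layer weight matrix is group-lasso-penalized and drives
# key-gene scoring, then mean/log-variance heads for z_u). The decoder maps
# [z_s, z_u^(1..K), b] through two 128-unit blocks to a softmax mean signal
# over genes (scaled by the cell's library size) and a positive per-gene NB
# dispersion. A linear classifier per condition type maps z_u to label
# logits, and a Gaussian-mixture prior holds a learnable (mu_c, sigma_c) per
# condition label.

.LOGVAR_CLAMP <- 10
.THETA_FLOOR <- 1e-4

#' Construct an untrained model state
#'
#' Builds all parameter tensors for the disentangled VAE with seed-controlled
#' fan-in-scaled random initialization. Mixture-prior means start from
#' N(0, I) and sigma_c from 1 (symmetric start, no label bias). Mostly an
#' internal building block of [scdvae()]; exposed for low-level testing and
#' experimentation.
#'
#' @param n_genes,n_batches input dimensions.
#' @param condition_levels list (one element per condition type) of label
#'   level vectors, in training order.
#' @param d_shared,d_unshared latent dimensions (defaults 8 and 2).
#' @param hidden hidden width of every block (default 128).
#' @param dropout dropout rate of every dropout layer (default 0.2).
#' @param dispersion `"gene"` for a gene-wise NB dispersion shared across
#'   cells (default), `"gene-cell"` for a per-cell dispersion head.
#' @return A list of parameter blocks with class `"scdvae_state"`.
#' @export
new_model_state <- function(n_genes, n_batches, condition_levels,
                            d_shared = 8, d_unshared = 2, hidden = 128,
                            dropout = 0.2, dispersion = c("gene", "gene-cell")) {
  dispersion <- match.arg(dispersion)
  K <- length(condition_levels)
  enc_s <- list(
    l1 = .init_layer(n_genes + n_batches, hidden),
    l2 = .init_layer(hidden, hidden),
    mean = .init_layer(hidden, d_shared, head = TRUE),
    logvar = .init_layer(hidden, d_shared, head = TRUE, bias = -4))
  enc_u <- lapply(seq_len(K), function(k) list(
    # small init for the gene-selection layer: informative genes grow under
    # the classification/reconstruction signal while the group lasso keeps
    # uninformative rows near zero, sharpening the key-gene score contrast
    l1 = .init_layer(n_genes, hidden, scale = 0.1),
    mean = .init_layer(hidden, d_unshared, head = TRUE),
    logvar = .init_layer(hidden, d_unshared, head = TRUE, bias = -4)))
  dec_in <- d_shared + K * d_unshared + n_batches
  dec <- list(
    l1 = .init_layer(dec_in, hidden),
    l2 = .init_layer(hidden, hidden),
    mean = .init_layer(hidden, n_genes, head = TRUE),
    theta_raw = numeric(n_genes))
  if (dispersion == "gene-cell") {
    dec$disp <- .init_layer(hidden, n_genes, head = TRUE)
  }
  cls <- lapply(condition_levels, function(lv)
    .init_layer(d_unshared, length(lv), head = TRUE))
  prior <- lapply(condition_levels, function(lv) list(
    mu = matrix(stats::rnorm(length(lv) * d_unshared), length(lv), d_unshared),
    logsig = numeric(length(lv))))
  structure(
    list(enc_s = enc_s, enc_u = enc_u, dec = dec, cls = cls, prior = prior,
         dims = list(n_genes = n_genes, n_batches = n_batches,
                     d_shared = d_shared, d_unshared = d_unshared,
                     hidden = hidden, K = K),
         condition_levels = condition_levels,
         dropout = dropout, dispersion = dispersion),
    class = "scdvae_state")
}

#' Shared-encoder forward pass
#'
#' Computes the diagonal-Gaussian posterior of the shared-bio factors z_s
#' given stabilized expression with the batch factor appended. Log-variances
#' are clamped to \[-10, 10\] for numerical stability. With `train = FALSE`
#' (dropout disabled) the output is a deterministic function of the inputs
#' and the state.
#'
#' @param state an `scdvae_state`.
#' @param xin stabilized expression matrix (cells by genes).
#' @param bmat one-hot batch factor matrix (cells by batches).
#' @param train enable dropout (draws masks from the current RNG).
#' @return list with `mean`, `logvar` (cells by d_shared) and `cache`.
#' @export
encode_shared <- function(state, xin, bmat, train = FALSE) {
  d <- state$dims
  if (ncol(xin) != d$n_genes || ncol(bmat) != d$n_batches) {
    stop("encoder input dimension mismatch: got ", ncol(xin), " genes + ",
         ncol(bmat), " batches, state expects ", d$n_genes, " + ", d$n_batches)
  }
  p <- if (train) state$dropout else 0
  xb <- cbind(xin, bmat)
  a1 <- .affine(xb, state$enc_s$l1); h1 <- .relu(a1)
  m1 <- .dropout_mask(nrow(h1), ncol(h1), p)
  h1d <- if (is.null(m1)) h1 else h1 * m1
  a2 <- .affine(h1d, state$enc_s$l2); h2 <- .relu(a2)
  m2 <- .dropout_mask(nrow(h2), ncol(h2), p)
  h2d <- if (is.null(m2)) h2 else h2 * m2
  mu <- .affine(h2d, state$enc_s$mean)
  lv_raw <- .affine(h2d, state$enc_s$logvar)
  lv <- .clamp(lv_raw, -.LOGVAR_CLAMP, .LOGVAR_CLAMP)
  list(mean = mu, logvar = lv,
       cache = list(xb = xb, a1 = a1, h1d = h1d, m1 = m1, a2 = a2,
                    h2d = h2d, m2 = m2, lv_raw = lv_raw))
}

#' Unshared-encoder forward pass
#'
#' Posterior of the unshared-bio factors z_u for condition type `k`. The
#' batch factor is deliberately excluded from the input: the first-layer
#' weight matrix doubles as the gene-selection layer whose per-gene column
#' norms are the key-gene scores, so its input must be genes only.
#'
#' @inheritParams encode_shared
#' @param k condition-type index.
#' @return list with `mean`, `logvar` (cells by d_unshared) and `cache`.
#' @export
encode_unshared <- function(state, xin, k, train = FALSE) {
  if (k < 1 || k > state$dims$K) stop("invalid condition-type index k = ", k)
  if (ncol(xin) != state$dims$n_genes) {
    stop("encoder input has ", ncol(xin), " genes, state expects ",
         state$dims$n_genes)
  }
  p <- if (train) state$dropout else 0
  enc <- state$enc_u[[k]]
  a1 <- .affine(xin, enc$l1); h1 <- .relu(a1)
  m1 <- .dropout_mask(nrow(h1), ncol(h1), p)
  h1d <- if (is.null(m1)) h1 else h1 * m1
  mu <- .affine(h1d, enc$mean)
  lv_raw <- .affine(h1d, enc$logvar)
  lv <- .clamp(lv_raw, -.LOGVAR_CLAMP, .LOGVAR_CLAMP)
  list(mean = mu, logvar = lv,
       cache = list(xin = xin, a1 = a1, h1d = h1d, m1 = m1, lv_raw = lv_raw))
}

#' Reparameterized sample from a diagonal-Gaussian posterior
#'
#' `sample = mean + exp(logvar / 2) * eps` with `eps` standard normal, drawn
#' from the current RNG stream (seed the RNG for reproducible draws), or
#' supplied explicitly.
#'
#' @param posterior list with `mean` and `logvar` matrices.
#' @param eps optional standard-normal draws of matching shape.
#' @return list with `z` and the `eps` used.
#' @export
sample_latent <- function(posterior, eps = NULL) {
  m <- posterior$mean
  if (is.null(eps)) eps <- matrix(stats::rnorm(length(m)), nrow(m), ncol(m))
  list(z = m + exp(posterior$logvar / 2) * eps, eps = eps)
}

#' Decoder forward pass
#'
#' Maps latent factors plus the batch factor to negative-binomial
#' parameters. The mean head is softmax-normalized over genes so the
#' per-cell mean signal sums to 1, then scaled by the cell's library size;
#' dispersion positivity comes from a softplus floored at 1e-4.
#'
#' @param state an `scdvae_state`.
#' @param zs shared-bio factors (cells by d_shared).
#' @param zu_list list of unshared-bio factor matrices, one per condition
#'   type.
#' @param bmat one-hot batch factor matrix.
#' @param library_size per-cell positive scale factors.
#' @param train enable dropout.
#' @return list with `mu` (cells by genes NB means), `theta` (positive
#'   dispersion: a gene vector, or a matrix for `"gene-cell"` dispersion),
#'   `pi` (normalized mean signal) and `cache`.
#' @export
decode <- function(state, zs, zu_list, bmat, library_size, train = FALSE) {
  d <- state$dims
  zin <- do.call(cbind, c(list(zs), zu_list, list(bmat)))
  if (!all(is.finite(zin))) stop("non-finite latent factors passed to decode")
  if (ncol(zin) != d$d_shared + d$K * d$d_unshared + d$n_batches) {
    stop("decoder input width ", ncol(zin), " does not match state (",
         d$d_shared + d$K * d$d_unshared + d$n_batches, ")")
  }
  p <- if (train) state$dropout else 0
  a1 <- .affine(zin, state$dec$l1); h1 <- .relu(a1)
  m1 <- .dropout_mask(nrow(h1), ncol(h1), p)
  h1d <- if (is.null(m1)) h1 else h1 * m1
  a2 <- .affine(h1d, state$dec$l2); h2 <- .relu(a2)
  m2 <- .dropout_mask(nrow(h2), ncol(h2), p)
  h2d <- if (is.null(m2)) h2 else h2 * m2
  r <- .affine(h2d, state$dec$mean)
  pi <- .softmax_rows(r)
  mu <- pi * library_size
  if (state$dispersion == "gene") {
    theta <- .softplus(state$dec$theta_raw) + .THETA_FLOOR
  } else {
    theta <- .softplus(.affine(h2d, state$dec$disp)) + .THETA_FLOOR
  }
  list(mu = mu, theta = theta, pi = pi,
       cache = list(zin = zin, a1 = a1, h1d = h1d, m1 = m1, a2 = a2,
                    h2d = h2d, m2 = m2, pi = pi,
                    library_size = library_size))
}

#' Negative binomial log-likelihood
#'
#' Total log-probability of counts under NB(mu, theta), where `theta` is the
#' dispersion (the distribution's `size`): large theta approaches Poisson,
#' small theta is overdispersed. Uses the standard normalized pmf including
#' the 1/Gamma(x + 1) term, evaluated in log-gamma space.
#'
#' @param x non-negative integer counts (vector or matrix).
#' @param mu positive NB means, same shape as `x` (or recyclable).
#' @param theta positive dispersion: scalar, per-gene vector (recycled along
#'   columns of a matrix `x`), or full matrix.
#' @return For matrix input, a per-cell vector of log-likelihoods summed
#'   over genes; for vector input, a single total.
#' @export
nb_log_likelihood <- function(x, mu, theta) {
  if (is.matrix(x)) {
    if (!is.matrix(theta)) theta <- matrix(theta, nrow(x), ncol(x), byrow = TRUE)
    ll <- stats::dnbinom(x, size = theta, mu = mu, log = TRUE)
    rowSums(ll)
  } else {
    sum(stats::dnbinom(x, size = theta, mu = mu, log = TRUE))
  }
}

#' Linear condition classifier
#'
#' Affine map (no hidden layer) from the unshared-bio factors of condition
#' type `k` to label logits, used with a cross-entropy loss to keep the
#' mixture-prior components of different condition labels from collapsing.
#'
#' @param state an `scdvae_state`.
#' @param zu unshared-bio factors (cells by d_unshared).
#' @param k condition-type index.
#' @return logits matrix (cells by number of labels of type `k`).
#' @export
classify_condition <- function(state, zu, k) {
  if (k < 1 || k > state$dims$K) stop("invalid condition-type index k = ", k)
  .affine(zu, state$cls[[k]])
}
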
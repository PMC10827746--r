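# Small dense-network primitives used by the encoder/decoder stacks.
# Everything is plain base-R matrix algebra; gradients are derived
# analytically in train.R and checked against numerical differentiation in
# the test suite.

.relu <- function(x) x * (x > 0)

.sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable log(1 + exp(x))
.softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Kaiming (fan-in) initialization for ReLU blocks; smaller Xavier-style
# scale for linear output heads. Draws come from the current RNG stream so
# construction is fully seed-determined.
.init_layer <- function(fan_in, fan_out, head = FALSE, scale = 1, bias = 0) {
  sd <- scale * if (head) sqrt(1 / fan_in) else sqrt(2 / fan_in)
  list(W = matrix(stats::rnorm(fan_in * fan_out, sd = sd), fan_in, fan_out),
       b = rep(bias, fan_out))
}

.affine <- function(x, layer) sweep(x %*% layer$W, 2, layer$b, "+")

# Inverted dropout: scales kept units by 1/(1-p) so eval-time forward needs
# no rescaling. Returns the mask so backward can reuse it.
.dropout_mask <- function(n, m, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(n * m) >= p) / (1 - p), n, m)
}

# row-wise softmax, max-shifted for stability
.softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

# ---- Adam over nested lists of parameter arrays -------------------------

.adam_init <- function(params) {
  rec <- function(p) if (is.list(p)) lapply(p, rec) else p * 0
  list(m = rec(params), v = rec(params), t = 0L)
}

# One Adam step: returns list(params, opt). `params` and `grads` share
# structure; grads may omit entries (treated as zero / untouched).
.adam_step <- function(params, grads, opt, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      # align gradient entries by name when both sides are named (gradient
      # builders order leaves differently), by position otherwise
      for (i in seq_along(p)) {
        nm <- names(p)[i]
        gk <- if (!is.null(nm) && nzchar(nm) && !is.null(names(g))) {
          g[[nm]]
        } else if (i <= length(g)) g[[i]] else NULL
        if (is.null(gk)) next
        r <- rec(p[[i]], gk, m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  r <- rec(params, grads, opt$m, opt$v)
  list(params = r$p, opt = list(m = r$m, v = r$v, t = opt$t))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
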
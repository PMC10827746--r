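# S3 methods for fitted models.

#' @method print scdvae
#' @export
print.scdvae <- function(x, ...) {
  cat("Disentangled NB-VAE fit (scdvae)\n")
  cat("  genes:", length(x$gene_ids), " batches:", length(x$batch_levels),
      "\n")
  cat("  condition types:", paste(x$condition_names, collapse = ", "), "\n")
  cat("  latent dims: shared", x$config$d_shared, "/ unshared",
      x$config$d_unshared, "per type\n")
  cat("  epochs:", x$epochs,
      if (x$converged) "(converged)" else "(hit max_epochs)", "\n")
  cat("  final total loss:", format(utils::tail(x$log$total, 1), digits = 6),
      "\n")
  invisible(x)
}

#' Summarize a fitted model
#'
#' @param object a fitted [scdvae()] model.
#' @param ... unused.
#' @return The object, invisibly, after printing the configuration, the
#'   final loss breakdown and the top key genes per condition type.
#' @method summary scdvae
#' @export
summary.scdvae <- function(object, ...) {
  print(object)
  last <- utils::tail(object$log, 1)
  cat("\nFinal epoch loss components:\n")
  for (nm in setdiff(names(last), "epoch")) {
    cat(sprintf("  %-15s %12.6g\n", nm, last[[nm]]))
  }
  sc <- ckg_scores(object)
  cat("\nTop condition-associated key genes:\n")
  for (k in seq_along(sc)) {
    top <- utils::head(sort(sc[[k]], decreasing = TRUE), 5)
    cat("  ", names(sc)[k], ": ",
        paste(names(top), collapse = ", "), "\n", sep = "")
  }
  invisible(object)
}

#' Key-gene score matrix of a fitted model
#'
#' The model's "coefficients": the group-lasso gene scores of each unshared
#' encoder's input layer, one column per condition type.
#'
#' @param object a fitted [scdvae()] model.
#' @param ... unused.
#' @return Numeric matrix, genes by condition types.
#' @export
coef.scdvae <- function(object, ...) {
  do.call(cbind, ckg_scores(object))
}

#' Predict from a fitted disentangled VAE
#'
#' @param object a fitted [scdvae()] model.
#' @param newdata an [mcd()] dataset over the training gene set.
#' @param type `"latent"` for posterior-mean factors ([extract_latent()]),
#'   `"denoise"` for the NB means under the cells' own condition and batch
#'   ([denoise()]), or `"perturb"` for counterfactual expression under
#'   `target_conditions`/`target_batch` ([predict_perturbation()]).
#' @param target_conditions,target_batch see [predict_perturbation()].
#' @param ... passed on to the task function.
#' @return See the task function for the chosen `type`.
#' @export
predict.scdvae <- function(object, newdata,
                           type = c("latent", "denoise", "perturb"),
                           target_conditions = NULL, target_batch = NULL,
                           ...) {
  type <- match.arg(type)
  switch(type,
         latent = extract_latent(object, newdata),
         denoise = denoise(object, newdata),
         perturb = predict_perturbation(object, newdata,
                                        target_conditions = target_conditions,
                                        target_batch = target_batch, ...))
}

#' Pearson residuals of observed counts against the denoised fit
#'
#' `(x - mu) / sqrt(mu + mu^2 / theta)` under the fitted NB parameters.
#'
#' @param object a fitted [scdvae()] model.
#' @param ds an [mcd()] dataset.
#' @param ... unused.
#' @return Matrix of residuals, cells by genes.
#' @export
residuals.scdvae <- function(object, ds, ...) {
  bd <- .prepare_data(ds, object$gene_ids, object$batch_levels,
                      object$condition_levels, object$lib_median,
                      object$xin_center, object$xin_scale)
  fw <- .forward_all(bd, object$state, sample = FALSE, train = FALSE)
  mu <- fw$dec$mu
  th <- if (is.matrix(fw$dec$theta)) fw$dec$theta else
    matrix(fw$dec$theta, nrow(mu), ncol(mu), byrow = TRUE)
  (bd$counts - mu) / sqrt(mu + mu^2 / th)
}

#' Training log-likelihood of a dataset under the fitted model
#'
#' @param object a fitted [scdvae()] model.
#' @param ds an [mcd()] dataset.
#' @param ... unused.
#' @return `logLik` object: total NB log-likelihood at the posterior means.
#' @export
logLik.scdvae <- function(object, ds, ...) {
  bd <- .prepare_data(ds, object$gene_ids, object$batch_levels,
                      object$condition_levels, object$lib_median,
                      object$xin_center, object$xin_scale)
  fw <- .forward_all(bd, object$state, sample = FALSE, train = FALSE)
  ll <- sum(nb_log_likelihood(bd$counts, fw$dec$mu, fw$dec$theta))
  structure(ll, df = NA_integer_, class = "logLik")
}

#' Plot the training curve
#'
#' @param x a fitted [scdvae()] model.
#' @param components which log columns to draw (default the weighted total).
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, the training log.
#' @export
plot.scdvae <- function(x, components = "total", ...) {
  graphics::matplot(x$log$epoch, x$log[, components, drop = FALSE],
                    type = "l", lty = 1, xlab = "epoch", ylab = "loss", ...)
  if (length(components) > 1) {
    graphics::legend("topright", legend = components, lty = 1,
                     col = seq_along(components), bty = "n")
  }
  invisible(x$log)
}

#' Simulate counts from the fitted generative model
#'
#' Draws NB counts at the denoised means of the given cells; the parametric
#' bootstrap counterpart of [denoise()].
#'
#' @param object a fitted [scdvae()] model.
#' @param nsim number of replicate draws.
#' @param seed RNG seed.
#' @param ds cells whose fitted means to sample around.
#' @param ... unused.
#' @return A list of `nsim` integer count matrices.
#' @export
simulate.scdvae <- function(object, nsim = 1, seed = NULL, ds, ...) {
  if (!is.null(seed)) set.seed(seed)
  bd <- .prepare_data(ds, object$gene_ids, object$batch_levels,
                      object$condition_levels, object$lib_median,
                      object$xin_center, object$xin_scale)
  fw <- .forward_all(bd, object$state, sample = FALSE, train = FALSE)
  mu <- fw$dec$mu
  th <- if (is.matrix(fw$dec$theta)) fw$dec$theta else
    matrix(fw$dec$theta, nrow(mu), ncol(mu), byrow = TRUE)
  lapply(seq_len(nsim), function(i) {
    out <- mu
    out[] <- stats::rnbinom(length(mu), size = th, mu = mu)
    out
  })
}
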
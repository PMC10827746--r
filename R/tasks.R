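# Headline capabilities of a trained model: latent extraction, key-gene
# scoring, denoising, and any-to-any perturbation prediction.

#' Extract per-cell latent factors (posterior means)
#'
#' Deterministic posterior means of the shared-bio factors and of each
#' condition type's unshared-bio factors, with dropout disabled. The
#' shared-bio factors are the batch- and condition-free cell embedding used
#' for clustering and cell-type identification.
#'
#' @param object a fitted [scdvae()] model.
#' @param ds an [mcd()] dataset over the training gene set.
#' @return list with `z_shared` (cells by d_shared) and `z_unshared` (list
#'   of cells-by-d_unshared matrices, one per condition type).
#' @export
extract_latent <- function(object, ds) {
  stopifnot(inherits(object, "scdvae"))
  bd <- .prepare_data(ds, object$gene_ids, object$batch_levels,
                      object$condition_levels, object$lib_median,
                      object$xin_center, object$xin_scale)
  post_s <- encode_shared(object$state, bd$xin, bd$bmat, train = FALSE)
  zu <- lapply(seq_len(object$state$dims$K), function(k) {
    encode_unshared(object$state, bd$xin, k, train = FALSE)$mean
  })
  names(zu) <- object$condition_names
  list(z_shared = post_s$mean, z_unshared = zu)
}

#' Condition-associated key gene scores
#'
#' Per-gene scores `s_i = ||w_i||_2`, the L2 norm of the weight group
#' connecting gene i to the first (group-lasso-penalized) layer of each
#' unshared encoder. A higher score marks a gene as more strongly driving
#' the condition effect of that type. Scores depend only on the first-layer
#' weights, so they are invariant to any change in deeper layers.
#'
#' @param object a fitted [scdvae()] model.
#' @return Named list (one element per condition type) of non-negative
#'   per-gene score vectors aligned to `object$gene_ids`.
#' @seealso [coef.scdvae()] which returns the same scores as a matrix;
#'   [write_ckg_ranking()] for the ranked TSV export.
#' @export
ckg_scores <- function(object) {
  stopifnot(inherits(object, "scdvae"))
  out <- lapply(object$state$enc_u, function(enc) {
    stats::setNames(sqrt(rowSums(enc$l1$W^2)), object$gene_ids)
  })
  names(out) <- object$condition_names
  out
}

#' Write a ranked key-gene table
#'
#' Exports one condition type's scores as a two-column TSV (gene_id, score)
#' sorted by decreasing score.
#'
#' @param object a fitted [scdvae()] model.
#' @param path output file.
#' @param type condition type name or index (default first).
#' @return Invisibly, the ranked data.frame.
#' @export
write_ckg_ranking <- function(object, path, type = 1) {
  s <- ckg_scores(object)[[type]]
  df <- data.frame(gene_id = names(s), score = as.numeric(s))
  df <- df[order(-df$score), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Denoised expression of observed cells
#'
#' Full forward pass with posterior means, each cell's own batch factor and
#' library size, and no parameter updates: returns the decoder's NB mean,
#' i.e. the model's estimate of the expression freed of sampling noise.
#' Per-cell output sums equal the observed library sizes (the mean head is
#' softmax-normalized over genes).
#'
#' @param object a fitted [scdvae()] model.
#' @param ds an [mcd()] dataset over the training gene set.
#' @return Positive matrix of denoised means, same shape as `ds$counts`.
#' @export
denoise <- function(object, ds) {
  stopifnot(inherits(object, "scdvae"))
  bd <- .prepare_data(ds, object$gene_ids, object$batch_levels,
                      object$condition_levels, object$lib_median,
                      object$xin_center, object$xin_scale)
  fw <- .forward_all(bd, object$state, sample = FALSE, train = FALSE)
  out <- fw$dec$mu
  dimnames(out) <- dimnames(bd$counts)
  out
}

#' Predict expression under another condition combination and batch
#'
#' Latent-arithmetic perturbation prediction: for every condition type whose
#' target label differs from the cells' current label, the shifting vector
#' `delta = mean z_u(target) - mean z_u(source)` (means of unshared
#' posterior means over training cells, cached in the fitted model) is added
#' to each cell's unshared-bio factors; the batch factor is replaced by the
#' target batch's one-hot; the shared-bio factors are kept unchanged — they
#' carry the cells' biological identity, which the prediction must preserve.
#' The decoder mean under the cell's own library size is returned as the
#' predicted (denoised) counts.
#'
#' Targets must have been observed in training, though the *combination*
#' requested may be novel: each condition type is shifted independently
#' under the additive latent-effect assumption.
#'
#' @param object a fitted [scdvae()] model.
#' @param ds input cells (an [mcd()] with their current batch and labels).
#' @param target_conditions named character vector or list: for each
#'   condition type to change, the target label. Types omitted (or `NA`)
#'   keep the cells' current labels.
#' @param target_batch target batch identifier; `NULL` keeps each cell's
#'   own batch.
#' @param sample_counts if `TRUE`, return NB integer draws at the predicted
#'   means instead of the continuous means (seed the RNG for
#'   reproducibility).
#' @return Positive matrix of predicted denoised counts (or integer draws).
#' @export
predict_perturbation <- function(object, ds, target_conditions = NULL,
                                 target_batch = NULL, sample_counts = FALSE) {
  stopifnot(inherits(object, "scdvae"))
  bd <- .prepare_data(ds, object$gene_ids, object$batch_levels,
                      object$condition_levels, object$lib_median,
                      object$xin_center, object$xin_scale)
  post_s <- encode_shared(object$state, bd$xin, bd$bmat, train = FALSE)
  zs <- post_s$mean
  K <- object$state$dims$K
  zu <- vector("list", K)
  for (k in seq_len(K)) {
    zu[[k]] <- encode_unshared(object$state, bd$xin, k, train = FALSE)$mean
    tgt <- NULL
    if (!is.null(target_conditions)) {
      nm <- object$condition_names[k]
      if (!is.null(names(target_conditions)) &&
          nm %in% names(target_conditions)) {
        tgt <- target_conditions[[nm]]
      } else if (is.null(names(target_conditions)) &&
                 length(target_conditions) >= k) {
        tgt <- target_conditions[[k]]
      }
    }
    if (is.null(tgt) || is.na(tgt)) next
    lv <- object$condition_levels[[k]]
    if (!tgt %in% lv) {
      stop("target label '", tgt, "' of condition type '",
           object$condition_names[k], "' was never seen in training")
    }
    means <- object$delta_means[[k]]
    delta <- matrix(means[tgt, ], nrow(zu[[k]]), ncol(zu[[k]]),
                    byrow = TRUE) -
      means[as.character(bd$labels[[k]]), , drop = FALSE]
    zu[[k]] <- zu[[k]] + delta
  }
  bmat <- bd$bmat
  if (!is.null(target_batch)) {
    j <- match(as.character(target_batch), object$batch_levels)
    if (is.na(j)) {
      stop("target batch '", target_batch, "' was never seen in training")
    }
    bmat <- matrix(0, nrow(bmat), ncol(bmat), dimnames = dimnames(bmat))
    bmat[, j] <- 1
  }
  dec <- decode(object$state, zs, zu, bmat, bd$libsize, train = FALSE)
  out <- dec$mu
  dimnames(out) <- dimnames(bd$counts)
  if (sample_counts) {
    th <- if (is.matrix(dec$theta)) dec$theta else
      matrix(dec$theta, nrow(out), ncol(out), byrow = TRUE)
    out[] <- stats::rnbinom(length(out), size = th, mu = out)
  }
  out
}

#' Latent shifting vector between two condition labels
#'
#' `delta = mean z_u(to) - mean z_u(from)` over training cells; exactly
#' antisymmetric, so a round trip A to B to A restores the factors.
#'
#' @param object a fitted [scdvae()] model.
#' @param type condition type name or index.
#' @param from,to condition labels.
#' @return Numeric vector of length d_unshared.
#' @export
latent_shift <- function(object, type, from, to) {
  means <- object$delta_means[[type]]
  if (is.null(means)) stop("unknown condition type: ", type)
  if (!from %in% rownames(means)) stop("unknown source label: ", from)
  if (!to %in% rownames(means)) stop("unknown target label: ", to)
  means[to, ] - means[from, ]
}

#' Save / load a fitted model
#'
#' Checkpoints the complete model — every parameter tensor, the categorical
#' level orders, latent dimensions, loss weights and the cached label means
#' — with a schema-version field, using R serialization.
#'
#' @param object a fitted [scdvae()] model.
#' @param path checkpoint file path.
#' @return `save_scdvae` invisibly returns `path`; `load_scdvae` returns the
#'   restored model.
#' @export
save_scdvae <- function(object, path) {
  stopifnot(inherits(object, "scdvae"))
  saveRDS(list(schema_version = 1L, model = object), path)
  invisible(path)
}

#' @rdname save_scdvae
#' @export
load_scdvae <- function(path) {
  x <- readRDS(path)
  if (is.null(x$schema_version)) stop("not an scdvae checkpoint: ", path)
  x$model
}
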
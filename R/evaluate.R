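# Evaluation metrics: disentanglement (ARI, batch ASW), key-gene ranking
# (AUPRC, early precision), prediction accuracy (centroid MSE / Pearson /
# R^2), the Wilcoxon rank-sum key-gene baseline, and the prediction
# scenario suite.

#' Adjusted Rand index of a latent embedding against reference labels
#'
#' Clusters the embedding with seeded k-means (k = number of reference
#' labels, 10 restarts) and returns the adjusted Rand index between the
#' clustering and the labels. 1 means the clustering recovers the labels
#' exactly; chance-level agreement scores near 0.
#'
#' @param true_labels reference labels (factor or vector).
#' @param embedding numeric matrix, one row per labelled observation.
#' @param k number of clusters; defaults to the number of distinct labels.
#' @param seed RNG seed for k-means.
#' @return ARI in (-1, 1].
#' @export
ari_score <- function(true_labels, embedding, k = NULL, seed = 0) {
  true_labels <- as.factor(true_labels)
  if (!is.matrix(embedding)) embedding <- as.matrix(embedding)
  if (nrow(embedding) != length(true_labels)) {
    stop("embedding rows (", nrow(embedding), ") must match label count (",
         length(true_labels), ")")
  }
  if (is.null(k)) k <- nlevels(droplevels(true_labels))
  if (k < 2) stop("k must be at least 2")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  cl <- stats::kmeans(embedding, centers = k, nstart = 10,
                      iter.max = 100)$cluster
  mclust::adjustedRandIndex(cl, true_labels)
}

#' Batch-mixing average silhouette width
#'
#' Measures how well cells of the same biological group (cell type or
#' condition) mix across batches in an embedding. Within each group the
#' silhouette width of every cell is computed with BATCH as the cluster
#' label and transformed to `1 - |s|`, so 1 means batches are
#' indistinguishable (perfect mixing) and 0 means batches form separated
#' clusters. Scores are averaged within each group, then across groups;
#' distances make the score invariant to rigid motions of the embedding.
#'
#' @param embedding numeric matrix, cells in rows.
#' @param batch_labels per-cell batch identifiers.
#' @param group_labels per-cell biological grouping (cell type or
#'   condition); a single group if omitted.
#' @return Score in \[0, 1\]; groups containing a single batch are skipped
#'   with a warning.
#' @export
asw_batch <- function(embedding, batch_labels, group_labels = NULL) {
  if (!is.matrix(embedding)) embedding <- as.matrix(embedding)
  if (is.null(group_labels)) group_labels <- rep("all", nrow(embedding))
  batch_labels <- as.factor(batch_labels)
  group_scores <- c()
  for (g in unique(group_labels)) {
    idx <- which(group_labels == g)
    b <- droplevels(batch_labels[idx])
    if (nlevels(b) < 2) {
      warning("group '", g, "' contains a single batch; skipped")
      next
    }
    sil <- cluster::silhouette(as.integer(b),
                               stats::dist(embedding[idx, , drop = FALSE]))
    group_scores <- c(group_scores, mean(1 - abs(sil[, "sil_width"])))
  }
  if (!length(group_scores)) stop("no group with at least two batches")
  mean(group_scores)
}

#' Area under the precision-recall curve of a gene ranking
#'
#' Step-wise interpolation over the distinct score thresholds, descending;
#' tied scores enter at the same threshold. Invariant under strictly
#' monotone transformations of the scores.
#'
#' @param scores per-gene scores, higher meaning more likely positive.
#' @param truth_set logical vector aligned to `scores`, or integer indices
#'   of the true positives.
#' @return AUPRC in \[0, 1\]; when every score is tied the curve is the
#'   prevalence line and the prevalence is returned with a warning.
#' @export
auprc <- function(scores, truth_set) {
  truth <- .as_truth_logical(truth_set, length(scores))
  if (!any(truth)) stop("truth set is empty")
  if (length(unique(scores)) == 1) {
    warning("all scores equal; AUPRC equals the prevalence")
    return(mean(truth))
  }
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(truth)
  area <- 0; prev_recall <- 0
  for (t in thresholds) {
    sel <- scores >= t
    tp <- sum(truth[sel])
    precision <- tp / sum(sel)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

.as_truth_logical <- function(truth_set, n) {
  if (is.logical(truth_set)) {
    if (length(truth_set) != n) stop("truth vector length mismatch")
    truth_set
  } else {
    truth <- rep(FALSE, n)
    truth[as.integer(truth_set)] <- TRUE
    truth
  }
}

#' Early precision of a gene ranking
#'
#' Precision among the top-k ranked genes with k the size of the truth set;
#' ties are broken by gene order (stable sort), which is documented rather
#' than randomized so results are reproducible.
#'
#' @inheritParams auprc
#' @return Early precision in \[0, 1\].
#' @export
early_precision <- function(scores, truth_set) {
  truth <- .as_truth_logical(truth_set, length(scores))
  k <- sum(truth)
  if (k == 0) stop("truth set is empty")
  top <- order(-scores)[seq_len(k)]   # order() is stable: ties by gene order
  mean(truth[top])
}

#' Centroid-level (or cell-level) prediction accuracy
#'
#' Both matrices are library-size normalized (each cell scaled to relative
#' expression) before comparison. For each cell type present in both
#' inputs, the centroid is the per-gene mean normalized expression, and
#' MSE, Pearson correlation and R-squared are computed between the
#' predicted and reference centroid vectors. With `cell_level = TRUE` (one
#' -to-one cell correspondence) the scores are computed per cell and
#' averaged.
#'
#' @param pred_counts,ref_counts matrices over a shared gene space.
#' @param pred_types,ref_types per-cell cell-type labels (ignored at cell
#'   level).
#' @param cell_level use the one-to-one per-cell variant.
#' @return data.frame with one row per cell type (or a single `all` row)
#'   and columns `mse`, `pearson`, `r2`; cell types present in only one
#'   input are skipped and recorded in the `skipped` attribute.
#' @export
centroid_metrics <- function(pred_counts, ref_counts, pred_types = NULL,
                             ref_types = NULL, cell_level = FALSE) {
  if (ncol(pred_counts) != ncol(ref_counts)) {
    stop("predicted and reference matrices must share the gene space")
  }
  norm <- function(m) m / rowSums(m)
  p <- norm(pred_counts); r <- norm(ref_counts)
  score <- function(a, b) {
    ss_res <- sum((a - b)^2)
    ss_tot <- sum((b - mean(b))^2)
    c(mse = mean((a - b)^2), pearson = stats::cor(a, b),
      r2 = 1 - ss_res / ss_tot)
  }
  if (cell_level) {
    if (nrow(p) != nrow(r)) {
      stop("cell_level scoring needs a one-to-one cell correspondence")
    }
    s <- t(vapply(seq_len(nrow(p)), function(i) score(p[i, ], r[i, ]),
                  numeric(3)))
    return(data.frame(cell_type = "all", mse = mean(s[, "mse"]),
                      pearson = mean(s[, "pearson"]), r2 = mean(s[, "r2"])))
  }
  if (is.null(pred_types) || is.null(ref_types)) {
    pred_types <- rep("all", nrow(p)); ref_types <- rep("all", nrow(r))
  }
  shared <- intersect(unique(as.character(pred_types)),
                      unique(as.character(ref_types)))
  skipped <- setdiff(union(unique(as.character(pred_types)),
                           unique(as.character(ref_types))), shared)
  if (!length(shared)) stop("no cell type present in both inputs")
  rows <- lapply(shared, function(ct) {
    pc <- colMeans(p[pred_types == ct, , drop = FALSE])
    rc <- colMeans(r[ref_types == ct, , drop = FALSE])
    s <- score(pc, rc)
    data.frame(cell_type = ct, mse = s["mse"], pearson = s["pearson"],
               r2 = s["r2"], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

#' Wilcoxon rank-sum key-gene baseline
#'
#' For every gene, a two-sided rank-sum test of expression between the
#' condition label groups of one condition type (with more than two labels,
#' the smallest p over label pairs), Benjamini-Hochberg corrected, then
#' transformed to scores `1 - p / max(p)` so the least significant gene
#' scores 0 and smaller p means a higher score.
#'
#' @param ds an [mcd()] dataset.
#' @param type condition type name or index (default 1).
#' @param normalize library-size normalize counts before testing (default
#'   TRUE).
#' @return Per-gene scores in \[0, 1\] aligned to `ds$gene_ids`.
#' @export
wilcoxon_ckg <- function(ds, type = 1, normalize = TRUE) {
  labels <- ds$conditions[[type]]
  lv <- levels(droplevels(labels))
  if (length(lv) < 2) stop("condition type needs at least 2 labels")
  x <- ds$counts
  if (normalize) x <- x / rowSums(x) * stats::median(rowSums(x))
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  pvals <- vapply(seq_len(ncol(x)), function(g) {
    col <- x[, g]
    if (length(unique(col)) == 1) return(1)  # constant gene
    min(vapply(pairs, function(pr) {
      stats::wilcox.test(col[labels == pr[1]], col[labels == pr[2]],
                         exact = FALSE)$p.value
    }, numeric(1)))
  }, numeric(1))
  pvals[is.na(pvals)] <- 1
  padj <- stats::p.adjust(pvals, method = "BH")
  stats::setNames(1 - padj / max(padj), ds$gene_ids)
}

#' Prediction scenario suite
#'
#' Runs every perturbation-prediction scenario toward one target (batch,
#' condition combination): each observed matrix with a different condition
#' combination serves as the input, is predicted into the target labels and
#' batch, and is scored against the gold standard with cell-type centroid
#' metrics. Scoring a denoising model's predictions against raw counts
#' would penalize the removal of technical noise, so the gold standard is
#' the model's denoised output on the target matrix's cells. An identity
#' baseline (the library-size-normalized input, unchanged) is scored
#' alongside each scenario. When cell-type labels are available the report
#' also carries disentanglement scores (ARI and batch ASW of the shared
#' factors, batch ASW and label ARI of each unshared block).
#'
#' @param object a fitted [scdvae()] model.
#' @param full_ds an [mcd()] containing all matrices including the target
#'   (typically the complete simulation truth), with cell types.
#' @param target list with `batch` (identifier) and `labels` (character
#'   vector of condition labels in condition-type order).
#' @param seed seed for the k-means inside ARI scoring.
#' @return data.frame report, one metric per row: `task`, `scenario`,
#'   `metric`, `value` plus scenario descriptors.
#' @export
run_scenario_suite <- function(object, full_ds, target, seed = 0) {
  stopifnot(inherits(object, "scdvae"))
  K <- n_condition_types(full_ds)
  if (length(target$labels) != K) {
    stop("target must name one label per condition type")
  }
  combo <- condition_combo(full_ds)
  target_combo <- paste(target$labels, collapse = "<>")
  gold_idx <- which(full_ds$batch == target$batch & combo == target_combo)
  if (!length(gold_idx)) stop("no cells in the target matrix")
  gold_ds <- subset_cells(full_ds, gold_idx)
  gold <- denoise(object, gold_ds)

  rows <- list()
  for (b in levels(full_ds$batch)) {
    for (cb in levels(combo)) {
      if (cb == target_combo) next
      idx <- which(full_ds$batch == b & combo == cb)
      if (!length(idx)) next
      input <- subset_cells(full_ds, idx)
      src_labels <- strsplit(cb, "<>", fixed = TRUE)[[1]]
      tc <- stats::setNames(as.list(target$labels), names(full_ds$conditions))
      pred <- predict_perturbation(object, input, target_conditions = tc,
                                   target_batch = target$batch)
      cm <- centroid_metrics(pred, gold, input$cell_types,
                             gold_ds$cell_types)
      cm_id <- centroid_metrics(input$counts, gold, input$cell_types,
                                gold_ds$cell_types)
      n_diff <- sum(src_labels != target$labels)
      scen <- paste0(if (b == target$batch) "within-batch" else "cross-batch",
                     " ", cb, " -> ", target_combo)
      for (m in c("mse", "pearson", "r2")) {
        rows[[length(rows) + 1]] <- data.frame(
          task = "prediction", scenario = scen, input_batch = b,
          input_combo = cb, cross_batch = b != target$batch,
          n_types_changed = n_diff, method = "model", metric = m,
          value = mean(cm[[m]]))
        rows[[length(rows) + 1]] <- data.frame(
          task = "prediction", scenario = scen, input_batch = b,
          input_combo = cb, cross_batch = b != target$batch,
          n_types_changed = n_diff, method = "identity", metric = m,
          value = mean(cm_id[[m]]))
      }
    }
  }
  report <- do.call(rbind, rows)

  if (!is.null(full_ds$cell_types)) {
    lat <- extract_latent(object, full_ds)
    dis <- list(
      c("shared", "ari_cell_type",
        ari_score(full_ds$cell_types, lat$z_shared, seed = seed)),
      c("shared", "asw_batch",
        asw_batch(lat$z_shared, full_ds$batch, full_ds$cell_types)))
    for (k in seq_len(K)) {
      nm <- names(full_ds$conditions)[k]
      dis[[length(dis) + 1]] <-
        c(paste0("unshared_", nm), "ari_condition",
          ari_score(full_ds$conditions[[k]], lat$z_unshared[[k]],
                    seed = seed))
      dis[[length(dis) + 1]] <-
        c(paste0("unshared_", nm), "asw_batch",
          asw_batch(lat$z_unshared[[k]], full_ds$batch,
                    full_ds$conditions[[k]]))
    }
    dis_df <- do.call(rbind, lapply(dis, function(r) data.frame(
      task = "disentanglement", scenario = r[1], input_batch = NA,
      input_combo = NA, cross_batch = NA, n_types_changed = NA,
      method = "model", metric = r[2], value = as.numeric(r[3]))))
    report <- rbind(report, dis_df)
  }
  rownames(report) <- NULL
  report
}

#' Write an evaluation report as tidy TSV
#'
#' @param report a data.frame from [run_scenario_suite()] or
#'   [centroid_metrics()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
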
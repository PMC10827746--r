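#' Multi-batch multi-condition single-cell dataset
#'
#' Bundles a cells-by-genes raw count matrix with per-cell batch identifiers,
#' one or more per-cell condition labels (one categorical per condition type,
#' e.g. treatment and disease severity), and optional cell-type labels used
#' only for evaluation. Counts must be non-negative integers: the negative
#' binomial likelihood the model fits is defined on counts, so fractional
#' entries are rejected rather than silently rounded.
#'
#' Batch and condition levels are recorded in first-appearance order and
#' persisted with any fitted model, so that label references at prediction
#' time are stable.
#'
#' @param counts numeric matrix or `Matrix` sparse matrix, cells in rows and
#'   genes in columns, raw (UMI-like) counts.
#' @param batch per-cell batch identifiers (character/factor/integer),
#'   length `nrow(counts)`.
#' @param conditions per-cell condition labels: a vector for a single
#'   condition type, or a data.frame/list with one column per condition type.
#'   Column names name the condition types.
#' @param cell_types optional per-cell cell-type labels, used by evaluation
#'   functions only; never visible to the model.
#' @param gene_ids gene identifiers; defaults to `colnames(counts)` or
#'   `gene1..geneG` when absent. Must be unique.
#' @return An object of class `"mcd"`: a list with elements `counts`
#'   (integer matrix), `gene_ids`, `batch` (factor), `conditions`
#'   (data.frame of factors, one column per condition type) and `cell_types`
#'   (factor or `NULL`).
#' @examples
#' x <- matrix(rpois(20, 3), nrow = 4)
#' ds <- mcd(x, batch = c("b1", "b1", "b2", "b2"),
#'           conditions = data.frame(treatment = c("ctrl", "stim", "ctrl", "stim")))
#' n_batches(ds)
#' @export
mcd <- function(counts, batch, conditions, cell_types = NULL, gene_ids = NULL) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  n <- nrow(counts)
  g <- ncol(counts)

  if (is.null(gene_ids)) gene_ids <- colnames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(g))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != g) {
    stop("length of gene_ids (", length(gene_ids),
         ") does not match number of count columns (", g, ")")
  }
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")

  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("counts must be non-negative; counts[", bad[1], ",", bad[2], "] = ",
         counts[bad[1], bad[2]])
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop("counts must be integers (raw counts); counts[", bad[1], ",",
         bad[2], "] = ", counts[bad[1], bad[2]],
         " -- refusing to round silently")
  }

  batch <- .first_appearance_factor(batch, n, "batch")

  if (is.data.frame(conditions) || is.list(conditions)) {
    conditions <- as.data.frame(conditions, stringsAsFactors = FALSE)
  } else {
    conditions <- data.frame(condition = conditions, stringsAsFactors = FALSE)
  }
  if (ncol(conditions) < 1) stop("at least one condition type is required")
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    names(conditions) <- paste0("condition", seq_len(ncol(conditions)))
  }
  conditions[] <- lapply(seq_along(conditions), function(k) {
    .first_appearance_factor(conditions[[k]], n, names(conditions)[k])
  })

  if (!is.null(cell_types)) {
    cell_types <- .first_appearance_factor(cell_types, n, "cell_types")
  }

  cn <- rownames(counts)
  if (is.null(cn)) cn <- paste0("cell", seq_len(n))
  dimnames(counts) <- list(cn, gene_ids)

  structure(
    list(counts = counts, gene_ids = gene_ids, batch = batch,
         conditions = conditions, cell_types = cell_types),
    class = "mcd")
}

# Factor with levels in first-appearance order; errors name the offending cell.
.first_appearance_factor <- function(x, n, what) {
  x <- as.character(x)
  if (length(x) != n) {
    stop(what, " has length ", length(x), " but there are ", n, " cells")
  }
  if (anyNA(x) || any(x == "")) {
    stop("cell ", which(is.na(x) | x == "")[1], " has a missing ", what, " label")
  }
  factor(x, levels = unique(x))
}

#' @method print mcd
#' @export
print.mcd <- function(x, ...) {
  cat("Multi-batch multi-condition dataset (mcd)\n")
  cat("  cells:", nrow(x$counts), " genes:", ncol(x$counts), "\n")
  cat("  batches (", nlevels(x$batch), "): ",
      paste(levels(x$batch), collapse = ", "), "\n", sep = "")
  for (k in seq_along(x$conditions)) {
    cat("  condition type '", names(x$conditions)[k], "' (",
        nlevels(x$conditions[[k]]), "): ",
        paste(levels(x$conditions[[k]]), collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$cell_types)) {
    cat("  cell types (", nlevels(x$cell_types), "): ",
        paste(levels(x$cell_types), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.mcd <- function(x) dim(x$counts)

#' Dataset accessors
#'
#' @param ds an [mcd()] dataset.
#' @return `n_cells`/`n_genes`/`n_batches` return integers;
#'   `n_condition_types` the number of condition types;
#'   `condition_combo` a factor of the per-cell combination of all condition
#'   labels (levels in first-appearance order).
#' @export
n_cells <- function(ds) nrow(ds$counts)

#' @rdname n_cells
#' @export
n_genes <- function(ds) ncol(ds$counts)

#' @rdname n_cells
#' @export
n_batches <- function(ds) nlevels(ds$batch)

#' @rdname n_cells
#' @export
n_condition_types <- function(ds) ncol(ds$conditions)

#' @rdname n_cells
#' @export
condition_combo <- function(ds) {
  key <- do.call(paste, c(lapply(ds$conditions, as.character), sep = "<>"))
  factor(key, levels = unique(key))
}

#' Subset cells of a dataset
#'
#' @param ds an [mcd()] dataset.
#' @param i cell indices (integer or logical).
#' @return An [mcd()] with the selected cells; factor levels are kept as in
#'   the parent dataset so group identities remain comparable.
#' @export
subset_cells <- function(ds, i) {
  out <- ds
  out$counts <- ds$counts[i, , drop = FALSE]
  out$batch <- ds$batch[i]
  out$conditions <- ds$conditions[i, , drop = FALSE]
  if (!is.null(ds$cell_types)) out$cell_types <- ds$cell_types[i]
  out
}

#' Filter genes by the number of cells expressing them
#'
#' Keeps genes with a nonzero count in at least `min_cells` cells, pooled
#' across all batches. The surviving genes keep their original order; cell
#' rows are untouched. This is the standard support filter applied to droplet
#' data before model fitting (e.g. dropping genes seen in fewer than 100
#' cells in a large tissue atlas).
#'
#' @param ds an [mcd()] dataset.
#' @param min_cells positive integer threshold.
#' @return The filtered [mcd()] dataset.
#' @export
filter_genes <- function(ds, min_cells) {
  if (!is.numeric(min_cells) || length(min_cells) != 1 || min_cells < 1) {
    stop("min_cells must be a positive integer")
  }
  support <- colSums(ds$counts > 0)
  keep <- support >= min_cells
  if (!any(keep)) {
    stop("filtering at min_cells = ", min_cells,
         " removes every gene; try a lower threshold (max support is ",
         max(support), " cells)")
  }
  out <- ds
  out$counts <- ds$counts[, keep, drop = FALSE]
  out$gene_ids <- ds$gene_ids[keep]
  out
}

#' One-hot batch factor matrix
#'
#' Maps each cell's batch identifier to a one-hot unit vector of length B
#' (the number of batches), with coordinate order following the recorded
#' batch-level order. These batch factors are appended to the shared
#' encoder's input and to the decoder's input; they are never learned.
#'
#' @param ds an [mcd()] dataset.
#' @param levels optional batch levels to encode against (defaults to the
#'   dataset's own); used at prediction time to encode new cells in a
#'   training-time coordinate system.
#' @return Binary matrix, cells by batches, each row summing to exactly 1.
#' @export
batch_factor_matrix <- function(ds, levels = NULL) {
  if (is.null(levels)) levels <- levels(ds$batch)
  codes <- match(as.character(ds$batch), levels)
  if (anyNA(codes)) {
    stop("batch level(s) not in the encoding set: ",
         paste(unique(as.character(ds$batch)[is.na(codes)]), collapse = ", "))
  }
  m <- matrix(0, nrow = n_cells(ds), ncol = length(levels),
              dimnames = list(rownames(ds$counts), levels))
  m[cbind(seq_len(nrow(m)), codes)] <- 1
  m
}

# Validate that a dataset is trainable: every condition type needs >= 2
# observed labels, and no cell may have a zero library size.
.check_trainable <- function(ds) {
  for (k in seq_along(ds$conditions)) {
    if (length(unique(ds$conditions[[k]])) < 2) {
      stop("condition type '", names(ds$conditions)[k],
           "' has fewer than 2 observed labels; it cannot be trained on")
    }
  }
  ls <- rowSums(ds$counts)
  if (any(ls == 0)) {
    stop("cell ", which(ls == 0)[1],
         " has zero total counts; remove empty cells before fitting")
  }
  if (nlevels(ds$batch) == 1 && nlevels(condition_combo(ds)) == 1) {
    warning("dataset has a single batch and a single condition combination; ",
            "the shared/unshared factorization is unidentifiable")
  }
  invisible(TRUE)
}
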
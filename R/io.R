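#' Read a multi-condition dataset from standard on-disk formats
#'
#' Supported formats:
#' \describe{
#'   \item{`csv`}{Dense counts as CSV/TSV with a header row of gene IDs and
#'     an index column of cell IDs (cells in rows); per-cell metadata in a
#'     separate CSV/TSV with one row per cell.}
#'   \item{`mtx`}{MatrixMarket coordinate triplets (1-based indices, cells in
#'     rows); gene IDs in a one-column sidecar next to the matrix file named
#'     `<stem>_genes.tsv`; per-cell metadata as for `csv`.}
#'   \item{`h5`}{An HDF5 single-cell container (h5ad dialect): counts in
#'     `/X` (dense, or a compressed-sparse group with `data`/`indices`/
#'     `indptr`), per-cell annotation columns under `/obs`, gene IDs under
#'     `/var/_index`. `metadata_path` is ignored.}
#' }
#' The metadata table must contain a batch column and at least one condition
#' column; sparse and dense encodings of the same data load to identical
#' datasets.
#'
#' @param count_path path to the count file.
#' @param metadata_path path to the per-cell metadata table (csv/mtx only).
#' @param format one of `"csv"`, `"mtx"`, `"h5"`.
#' @param batch_col name of the batch column in the metadata.
#' @param condition_cols names of the condition-type columns; default: every
#'   metadata column except the batch and cell-type columns.
#' @param cell_type_col optional name of a cell-type column.
#' @return An [mcd()] dataset.
#' @export
read_mcd <- function(count_path, metadata_path = NULL,
                     format = c("csv", "mtx", "h5"),
                     batch_col = "batch", condition_cols = NULL,
                     cell_type_col = NULL) {
  format <- match.arg(format)
  if (!file.exists(count_path)) stop("count file not found: ", count_path)

  if (format == "h5") {
    return(.read_mcd_h5(count_path, batch_col, condition_cols, cell_type_col))
  }

  if (is.null(metadata_path) || !file.exists(metadata_path)) {
    stop("metadata file not found: ", metadata_path)
  }
  meta <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(meta) == 1) {  # comma-separated fallback
    meta <- utils::read.table(metadata_path, header = TRUE, sep = ",",
                              stringsAsFactors = FALSE, check.names = FALSE)
  }

  if (format == "csv") {
    tab <- utils::read.csv(count_path, row.names = 1, check.names = FALSE)
    counts <- as.matrix(tab)
  } else {
    m <- Matrix::readMM(count_path)
    counts <- as.matrix(m)
    gene_file <- sub("\\.mtx$", "_genes.tsv", count_path)
    if (file.exists(gene_file)) {
      colnames(counts) <- readLines(gene_file)
    }
    cell_file <- sub("\\.mtx$", "_cells.tsv", count_path)
    if (file.exists(cell_file)) {
      rownames(counts) <- readLines(cell_file)
    }
  }

  if (nrow(counts) != nrow(meta)) {
    stop("dimension mismatch: counts have ", nrow(counts),
         " cells but metadata has ", nrow(meta), " rows")
  }
  .assemble_mcd(counts, meta, batch_col, condition_cols, cell_type_col)
}

.assemble_mcd <- function(counts, meta, batch_col, condition_cols,
                          cell_type_col) {
  if (!batch_col %in% names(meta)) {
    stop("metadata lacks batch column '", batch_col, "'")
  }
  if (is.null(condition_cols)) {
    condition_cols <- setdiff(names(meta),
                              c(batch_col, cell_type_col, "cell_id", "barcode"))
  }
  if (length(condition_cols) < 1) {
    stop("metadata must contain at least one condition column")
  }
  missing <- setdiff(condition_cols, names(meta))
  if (length(missing)) {
    stop("metadata lacks condition column(s): ", paste(missing, collapse = ", "))
  }
  ct <- if (!is.null(cell_type_col)) meta[[cell_type_col]] else NULL
  mcd(counts, batch = meta[[batch_col]],
      conditions = meta[condition_cols], cell_types = ct)
}

.read_mcd_h5 <- function(path, batch_col, condition_cols, cell_type_col) {
  contents <- rhdf5::h5ls(path)
  x_entry <- contents[contents$group == "/" & contents$name == "X", ]
  if (nrow(x_entry) == 0) stop("no /X matrix in ", path)
  if (x_entry$otype == "H5I_GROUP") {
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    shape <- tryCatch(
      as.integer(rhdf5::h5readAttributes(path, "X")$shape),
      error = function(e) NULL)
    if (is.null(shape)) shape <- c(length(indptr) - 1L, max(indices) + 1L)
    # CSR over (cells, genes): row i spans indptr[i]..indptr[i+1]-1
    counts <- matrix(0, nrow = shape[1], ncol = shape[2])
    rows <- rep.int(seq_len(shape[1]), diff(indptr))
    counts[cbind(rows, indices + 1L)] <- data
  } else {
    # 2-D HDF5 datasets written row-major over (cells, genes) read into R
    # column-major as (genes, cells); transpose back.
    counts <- t(rhdf5::h5read(path, "X"))
  }
  obs_names <- contents$name[contents$group == "/obs" &
                               contents$otype != "H5I_GROUP"]
  obs <- lapply(setdiff(obs_names, "_index"), function(nm) {
    as.character(rhdf5::h5read(path, paste0("obs/", nm)))
  })
  names(obs) <- setdiff(obs_names, "_index")
  # categorical columns encoded as groups with categories/codes
  obs_groups <- contents$name[contents$group == "/obs" &
                                contents$otype == "H5I_GROUP"]
  for (nm in obs_groups) {
    cats <- as.character(rhdf5::h5read(path, paste0("obs/", nm, "/categories")))
    codes <- as.integer(rhdf5::h5read(path, paste0("obs/", nm, "/codes")))
    obs[[nm]] <- cats[codes + 1L]
  }
  meta <- as.data.frame(obs, stringsAsFactors = FALSE, check.names = FALSE)
  if ("_index" %in% obs_names) {
    rownames(counts) <- as.character(rhdf5::h5read(path, "obs/_index"))
  }
  var_index <- tryCatch(as.character(rhdf5::h5read(path, "var/_index")),
                        error = function(e) NULL)
  if (!is.null(var_index)) colnames(counts) <- var_index
  if (nrow(counts) != nrow(meta)) {
    stop("dimension mismatch: counts have ", nrow(counts),
         " cells but /obs has ", nrow(meta), " rows")
  }
  .assemble_mcd(counts, meta, batch_col, condition_cols, cell_type_col)
}

#' Write a multi-condition dataset to disk
#'
#' Inverse of [read_mcd()]: writes counts plus per-cell metadata in the
#' requested format. Round-tripping through any supported format is lossless
#' for counts, batch, condition and cell-type labels.
#'
#' @param ds an [mcd()] dataset.
#' @param count_path output path for the counts (`.csv`, `.mtx` or `.h5`).
#' @param metadata_path output path for the metadata table (csv/mtx only).
#' @param format one of `"csv"`, `"mtx"`, `"h5"`.
#' @return Invisibly, `count_path`.
#' @export
write_mcd <- function(ds, count_path, metadata_path = NULL,
                      format = c("csv", "mtx", "h5")) {
  format <- match.arg(format)
  meta <- data.frame(batch = as.character(ds$batch),
                     lapply(ds$conditions, as.character),
                     stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(ds$cell_types)) meta$cell_type <- as.character(ds$cell_types)

  if (format == "h5") {
    if (file.exists(count_path)) file.remove(count_path)
    rhdf5::h5createFile(count_path)
    rhdf5::h5write(t(ds$counts), count_path, "X")
    rhdf5::h5createGroup(count_path, "obs")
    rhdf5::h5write(rownames(ds$counts), count_path, "obs/_index")
    for (nm in names(meta)) rhdf5::h5write(meta[[nm]], count_path,
                                           paste0("obs/", nm))
    rhdf5::h5createGroup(count_path, "var")
    rhdf5::h5write(ds$gene_ids, count_path, "var/_index")
    rhdf5::h5closeAll()
    return(invisible(count_path))
  }

  if (is.null(metadata_path)) stop("metadata_path is required for ", format)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (format == "csv") {
    utils::write.csv(as.data.frame(ds$counts), count_path, quote = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(ds$counts, sparse = TRUE), count_path)
    writeLines(ds$gene_ids, sub("\\.mtx$", "_genes.tsv", count_path))
    writeLines(rownames(ds$counts), sub("\\.mtx$", "_cells.tsv", count_path))
  }
  invisible(count_path)
}
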
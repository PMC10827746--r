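# Ground-truthed multi-batch multi-condition count simulator.
#
# A hierarchical NB generator provides the base data: a shared log-normal
# baseline expression program, per-cell-type log-normal effects on a random
# marker subset, per-batch multiplicative gene-wise log-normal distortion,
# log-normal library sizes, and NB sampling with gene-wise dispersion.
# Condition effects are then injected as uniform additive perturbations
# U(epsilon - 1, epsilon) on the designated key genes of every cell whose
# label is not the reference label of that condition type.

#' Simulation configuration
#'
#' Defaults describe the benchmark design: 2 batches, 2 condition types
#' (treatment ctrl/stim and severity healthy/severe, so 8 count matrices),
#' 500 cells per matrix, 500 genes, 3 cell types. Key genes default to
#' leading disjoint blocks: the first `m_diff` genes for condition type 1,
#' the next `m_diff` for type 2, and so on.
#'
#' @param n_cells_per_matrix cells per (batch, condition combination)
#'   matrix.
#' @param n_genes number of genes.
#' @param n_batches number of batches.
#' @param n_cell_types number of cell types.
#' @param condition_types named list of label vectors, one per condition
#'   type; the FIRST label of each type is the reference (no condition
#'   effect).
#' @param m_diff key genes per condition type (scalar or one per type).
#' @param epsilon perturbation strength per condition type (scalar or one
#'   per type); the additive shift is U(epsilon - 1, epsilon), so must be
#'   >= 1.
#' @param batch_strength sd of the log-normal per-batch gene-wise
#'   distortion.
#' @param type_strength sd of the log-normal cell-type marker effects.
#' @param marker_frac fraction of genes carrying each cell type's program.
#' @param lib_meanlog,lib_sdlog log-normal library-size parameters.
#' @param round round perturbed entries to integers (round-half-to-even,
#'   floored at 0); disable to keep the continuous injected values.
#' @param ckg_sets optional list of disjoint gene index vectors overriding
#'   the default leading blocks.
#' @param seed RNG seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_cells_per_matrix = 500, n_genes = 500,
                       n_batches = 2, n_cell_types = 3,
                       condition_types = list(
                         treatment = c("ctrl", "stim"),
                         severity = c("healthy", "severe")),
                       m_diff = 100, epsilon = 8,
                       batch_strength = 0.25, type_strength = 2,
                       marker_frac = 0.1,
                       lib_meanlog = log(20000), lib_sdlog = 0.35,
                       round = TRUE, ckg_sets = NULL, seed = 1) {
  K <- length(condition_types)
  m_diff <- rep(m_diff, length.out = K)
  epsilon <- rep(epsilon, length.out = K)
  if (any(epsilon < 1)) stop("epsilon must be >= 1")
  if (any(m_diff < 1)) stop("m_diff must be >= 1")
  if (is.null(ckg_sets)) {
    if (2 * sum(m_diff) > n_genes) {
      stop("2 * sum(m_diff) = ", 2 * sum(m_diff), " exceeds n_genes = ",
           n_genes)
    }
    off <- c(0, cumsum(m_diff))
    ckg_sets <- lapply(seq_len(K), function(k) (off[k] + 1):off[k + 1])
  }
  if (length(ckg_sets) != K) stop("one CKG set per condition type required")
  all_idx <- unlist(ckg_sets)
  if (anyDuplicated(all_idx)) {
    stop("CKG sets of different condition types must not overlap")
  }
  if (max(all_idx) > n_genes) stop("CKG index exceeds n_genes")
  structure(list(n_cells_per_matrix = n_cells_per_matrix, n_genes = n_genes,
                 n_batches = n_batches, n_cell_types = n_cell_types,
                 condition_types = condition_types, m_diff = m_diff,
                 epsilon = epsilon, batch_strength = batch_strength,
                 type_strength = type_strength, marker_frac = marker_frac,
                 lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog,
                 round = round, ckg_sets = ckg_sets, seed = seed),
            class = "sim_config")
}

#' Simulate the clean (condition-effect-free) base dataset
#'
#' Draws the hierarchical NB base data and assigns cells of every batch
#' evenly to the condition combinations (contiguous equal blocks after a
#' seeded within-batch shuffle). No condition effect is present yet; see
#' [add_condition_effect()].
#'
#' @param cfg a [sim_config()].
#' @return A list of class `"sim_truth"`: `ds` (an [mcd()] with cell types),
#'   `clean` (the untouched count matrix), `ckg_sets` and `config`.
#' @export
simulate_base <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_marker <- max(1, round(cfg$marker_frac * cfg$n_genes))
  if (n_marker > cfg$n_genes) stop("more marker genes than genes")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed)

  G <- cfg$n_genes
  combos <- expand.grid(lapply(cfg$condition_types, function(x) x),
                        stringsAsFactors = FALSE)
  n_combos <- nrow(combos)
  per_batch <- cfg$n_cells_per_matrix * n_combos
  n <- per_batch * cfg$n_batches

  base <- exp(stats::rnorm(G, 0, 1))
  type_fac <- matrix(1, cfg$n_cell_types, G)
  for (t in seq_len(cfg$n_cell_types)) {
    markers <- sample.int(G, n_marker)
    type_fac[t, markers] <- exp(stats::rnorm(n_marker, 0, cfg$type_strength))
  }
  batch_fac <- matrix(exp(stats::rnorm(cfg$n_batches * G, 0,
                                       cfg$batch_strength)),
                      cfg$n_batches, G)
  theta <- exp(stats::rnorm(G, log(4), 0.5))

  batch <- rep(seq_len(cfg$n_batches), each = per_batch)
  ctype <- sample.int(cfg$n_cell_types, n, replace = TRUE)
  libsize <- stats::rlnorm(n, cfg$lib_meanlog, cfg$lib_sdlog)

  prop <- matrix(base, n, G, byrow = TRUE) * type_fac[ctype, , drop = FALSE] *
    batch_fac[batch, , drop = FALSE]
  prop <- prop / rowSums(prop)
  mu <- prop * libsize
  counts <- matrix(stats::rnbinom(n * G, size = matrix(theta, n, G, byrow = TRUE),
                                  mu = mu), n, G)

  # evenly separate the cells of each batch into the condition combinations
  combo_id <- integer(n)
  for (b in seq_len(cfg$n_batches)) {
    idx <- sample(which(batch == b))
    combo_id[idx] <- rep(seq_len(n_combos), each = cfg$n_cells_per_matrix)
  }
  conditions <- combos[combo_id, , drop = FALSE]
  rownames(conditions) <- NULL

  dimnames(counts) <- list(paste0("cell", seq_len(n)),
                           paste0("gene", seq_len(G)))
  ds <- mcd(counts,
            batch = paste0("batch", batch),
            conditions = conditions,
            cell_types = paste0("type", ctype))
  structure(list(ds = ds, clean = counts, ckg_sets = cfg$ckg_sets,
                 config = cfg),
            class = "sim_truth")
}

#' Inject condition effects on the key genes
#'
#' For every condition type c, every cell whose label of type c is not the
#' reference (first) label receives an additive U(epsilon_c - 1, epsilon_c)
#' perturbation on each key gene of type c, rounded half-to-even to integer
#' counts (configurable). Reference-condition cells and non-key genes are
#' untouched, so the clean and perturbed matrices differ only on perturbed
#' cells x key-gene columns.
#'
#' @param truth a `"sim_truth"` from [simulate_base()].
#' @param cfg configuration (defaults to the truth's own).
#' @return The `"sim_truth"` with `ds$counts` replaced by the perturbed
#'   matrix (`clean` keeps the original).
#' @export
add_condition_effect <- function(truth, cfg = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  if (anyDuplicated(unlist(truth$ckg_sets))) {
    stop("CKG sets of different condition types must not overlap")
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed + 777L)
  x <- truth$clean
  for (k in seq_along(truth$ckg_sets)) {
    ref <- cfg$condition_types[[k]][1]
    hit <- which(as.character(truth$ds$conditions[[k]]) != ref)
    if (!length(hit)) next
    g <- truth$ckg_sets[[k]]
    shift <- matrix(stats::runif(length(hit) * length(g),
                                 cfg$epsilon[k] - 1, cfg$epsilon[k]),
                    length(hit), length(g))
    x[hit, g] <- x[hit, g] + shift
  }
  if (cfg$round) x <- pmax(round(x), 0)
  truth$ds$counts <- x
  dimnames(truth$ds$counts) <- dimnames(truth$clean)
  truth
}

#' Simulate a complete ground-truthed dataset
#'
#' [simulate_base()] followed by [add_condition_effect()].
#'
#' @param cfg a [sim_config()].
#' @return A `"sim_truth"`.
#' @examples
#' truth <- simulate_mcd(sim_config(n_cells_per_matrix = 30, n_genes = 50,
#'                                  m_diff = 5, seed = 1))
#' truth$ds
#' @export
simulate_mcd <- function(cfg = sim_config()) {
  add_condition_effect(simulate_base(cfg))
}

#' The 3 x 3 benchmark grid
#'
#' Generates one dataset per (m_diff, epsilon) combination of the benchmark
#' design — by default key-gene counts {20, 50, 100} crossed with
#' perturbation strengths {2, 4, 8} — each with every (batch, condition
#' combination) matrix present.
#'
#' @param base_cfg template [sim_config()]; its `m_diff`/`epsilon`/`seed`
#'   are overridden per grid cell.
#' @param m_diff,epsilon grid axes.
#' @param seed base seed; each grid cell derives its own deterministic
#'   sub-seed.
#' @return Named list of 9 `"sim_truth"` datasets (`m<m_diff>_e<epsilon>`).
#' @export
benchmark_grid <- function(base_cfg = sim_config(), m_diff = c(20, 50, 100),
                           epsilon = c(2, 4, 8), seed = base_cfg$seed) {
  out <- list()
  cell <- 0L
  for (m in m_diff) for (e in epsilon) {
    cell <- cell + 1L
    cfg <- base_cfg
    cfg$m_diff <- rep(m, length.out = length(cfg$condition_types))
    cfg$epsilon <- rep(e, length.out = length(cfg$condition_types))
    off <- c(0, cumsum(cfg$m_diff))
    cfg$ckg_sets <- lapply(seq_along(cfg$condition_types),
                           function(k) (off[k] + 1):off[k + 1])
    if (2 * sum(cfg$m_diff) > cfg$n_genes) {
      stop("grid cell m_diff = ", m, " infeasible for n_genes = ",
           cfg$n_genes)
    }
    cfg$seed <- seed * 100L + cell
    out[[paste0("m", m, "_e", e)]] <- simulate_mcd(cfg)
  }
  out
}

# Parse "<label1,label2>@batch" or "label1,label2@batch" holdout specs.
.parse_holdout <- function(spec, condition_names) {
  parts <- strsplit(gsub("[<>]", "", spec), "@", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop("holdout spec must look like '<label1,label2>@batch': ", spec)
  }
  labels <- strsplit(parts[1], ",", fixed = TRUE)[[1]]
  if (length(labels) != length(condition_names)) {
    stop("holdout spec '", spec, "' names ", length(labels),
         " labels but there are ", length(condition_names),
         " condition types")
  }
  list(batch = trimws(parts[2]), labels = trimws(labels))
}

#' Hold out whole count matrices
#'
#' Partitions the cells of a dataset by (batch, condition combination)
#' matrix membership, e.g. to reproduce out-of-sample layouts where one or
#' more matrices are removed before training and used as prediction gold
#' standards.
#'
#' @param x an [mcd()] or `"sim_truth"`.
#' @param spec character vector of matrices to hold out, each written
#'   `"<label1,label2>@batch"` with labels in condition-type order (angle
#'   brackets optional). Empty spec returns everything as training data.
#' @return list with `train` and `heldout`, each of the same class as `x`
#'   (`heldout` is `NULL` for an empty spec).
#' @export
hold_out_matrices <- function(x, spec = character()) {
  ds <- if (inherits(x, "sim_truth")) x$ds else x
  stopifnot(inherits(ds, "mcd"))
  if (!length(spec)) return(list(train = x, heldout = NULL))
  K <- n_condition_types(ds)
  hold <- rep(FALSE, n_cells(ds))
  for (s in spec) {
    p <- .parse_holdout(s, names(ds$conditions))
    if (!p$batch %in% levels(ds$batch)) {
      stop("holdout names unknown batch '", p$batch, "'")
    }
    sel <- ds$batch == p$batch
    for (k in seq_len(K)) sel <- sel & ds$conditions[[k]] == p$labels[k]
    if (!any(sel)) stop("no cells match holdout spec '", s, "'")
    hold <- hold | sel
  }
  for (k in seq_len(K)) {
    gone <- setdiff(unique(as.character(ds$conditions[[k]])),
                    unique(as.character(ds$conditions[[k]][!hold])))
    if (length(gone)) {
      stop("holding out these matrices removes every occurrence of label '",
           gone[1], "' of condition type '", names(ds$conditions)[k],
           "'; the label would be untrainable")
    }
  }
  take <- function(obj, idx) {
    if (inherits(obj, "sim_truth")) {
      obj$ds <- subset_cells(obj$ds, idx)
      obj$clean <- obj$clean[idx, , drop = FALSE]
      obj
    } else subset_cells(obj, idx)
  }
  list(train = take(x, which(!hold)), heldout = take(x, which(hold)))
}
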
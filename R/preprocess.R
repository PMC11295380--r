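# QC filtering, normalization, feature selection, PCA and SNN graph
# clustering of tumor cells.

#' Preprocessing configuration
#'
#' Defaults follow the standard single-cell workflow for this analysis:
#' cells with fewer than 500 detected genes or a mitochondrial fraction
#' above 15% are removed, samples with fewer than 20 surviving tumor cells
#' are excluded, 2000 highly variable genes feed a 20-component PCA, and
#' subclustering runs on a k=20 shared-nearest-neighbor graph.
#'
#' @param min_features minimum detected genes per cell.
#' @param max_mito_fraction maximum mitochondrial fraction per cell.
#' @param min_tumor_cells_per_sample samples below this surviving tumor-cell
#'   count are dropped entirely.
#' @param n_hvgs number of highly variable genes.
#' @param n_pcs number of principal components.
#' @param cluster_resolution modularity resolution for graph clustering.
#' @param snn_k neighbors for the SNN graph.
#' @param snn_prune Jaccard pruning threshold.
#' @param seed integer seed for graph clustering.
#' @return a validated `preprocess_config`.
#' @export
preprocess_config <- function(min_features = 500, max_mito_fraction = 0.15,
                              min_tumor_cells_per_sample = 20, n_hvgs = 2000,
                              n_pcs = 20, cluster_resolution = 1.0,
                              snn_k = 20, snn_prune = 1 / 15, seed = 1L) {
  cfg <- list(
    min_features = check_count(min_features, "min_features"),
    max_mito_fraction = check_fraction(max_mito_fraction, "max_mito_fraction",
                                       open_lo = TRUE, open_hi = TRUE),
    min_tumor_cells_per_sample =
      check_count(min_tumor_cells_per_sample, "min_tumor_cells_per_sample"),
    n_hvgs = check_count(n_hvgs, "n_hvgs"),
    n_pcs = check_count(n_pcs, "n_pcs"),
    cluster_resolution = check_positive(cluster_resolution, "cluster_resolution"),
    snn_k = check_count(snn_k, "snn_k", min = 2L),
    snn_prune = check_fraction(snn_prune, "snn_prune"),
    seed = check_count(seed, "seed", min = 0L)
  )
  class(cfg) <- "preprocess_config"
  cfg
}

#' Quality-control filtering of cells and samples
#'
#' Removes cells with fewer than `min_features` detected genes or a
#' mitochondrial fraction strictly above `max_mito_fraction`, then removes
#' entire samples whose surviving tumor-cell count falls below
#' `min_tumor_cells_per_sample`. Idempotent: filtering a filtered bundle is
#' a no-op.
#'
#' @param counts cells x genes count matrix.
#' @param meta per-cell metadata covering every row of `counts`; when it
#'   carries `n_features` / `mito_fraction` columns those are used, otherwise
#'   they are computed from `counts` (mitochondrial genes identified by the
#'   "MT-" symbol prefix).
#' @param cfg a [preprocess_config()].
#' @return list with filtered `counts`, `meta` and a `report` listing
#'   removals per rule.
#' @export
qc_filter <- function(counts, meta, cfg = preprocess_config()) {
  if (!all(rownames(counts) %in% meta$cell_id)) {
    stop("metadata does not cover all cells in the count matrix")
  }
  meta <- meta[match(rownames(counts), meta$cell_id), , drop = FALSE]
  n_features <- meta$n_features
  if (is.null(n_features)) n_features <- Matrix::rowSums(counts > 0)
  mito_fraction <- meta$mito_fraction
  if (is.null(mito_fraction)) {
    is_mito <- startsWith(colnames(counts), "MT-")
    tot <- Matrix::rowSums(counts)
    mito_fraction <- ifelse(tot > 0,
                            Matrix::rowSums(counts[, is_mito, drop = FALSE]) / tot, 0)
  }
  low_feat <- n_features < cfg$min_features
  high_mito <- mito_fraction > cfg$max_mito_fraction
  keep <- !(low_feat | high_mito)

  surviving <- meta[keep, , drop = FALSE]
  tumor_counts <- table(surviving$sample_id[surviving$cell_class == "tumor"])
  all_samples <- unique(surviving$sample_id)
  n_tumor <- stats::setNames(as.integer(tumor_counts[all_samples]), all_samples)
  n_tumor[is.na(n_tumor)] <- 0L
  small_samples <- all_samples[n_tumor < cfg$min_tumor_cells_per_sample]
  keep2 <- keep & !(meta$sample_id %in% small_samples)

  if (!any(keep2)) stop("no cells survive QC")
  report <- list(
    n_input = nrow(counts),
    removed_low_features = sum(low_feat),
    removed_high_mito = sum(high_mito & !low_feat),
    samples_removed = as.list(stats::setNames(as.integer(n_tumor[small_samples]),
                                              small_samples)),
    removed_small_samples = sum(keep & !keep2),
    n_output = sum(keep2)
  )
  list(counts = counts[keep2, , drop = FALSE],
       meta = meta[keep2, , drop = FALSE],
       report = report)
}

#' Log-normalize counts to counts-per-10k
#'
#' Each entry becomes `ln(1 + 1e4 * count / cell_total)`.
#'
#' @param counts cells x genes count matrix.
#' @return sparse cells x genes log-normalized expression matrix.
#' @export
normalize_log1p_cp10k <- function(counts) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0)) {
    bad <- rownames(counts)[which(totals == 0)]
    stop(sprintf("all-zero cell(s): %s", paste(utils::head(bad, 5), collapse = ", ")))
  }
  expr <- Matrix::Diagonal(x = 1e4 / totals) %*% counts
  expr@x <- log1p(expr@x)
  dimnames(expr) <- dimnames(counts)
  methods::as(methods::as(expr, "generalMatrix"), "CsparseMatrix")
}

#' Select highly variable genes
#'
#' Genes ranked by variance of log-normalized expression across cells
#' (sample variance); ties broken by gene order.
#'
#' @param expr cells x genes log-normalized matrix.
#' @param n_hvgs number of genes to return.
#' @return character vector of gene symbols, length `min(n_hvgs, n_genes)`.
#' @export
select_hvgs <- function(expr, n_hvgs = 2000) {
  n <- nrow(expr)
  if (n < 2) stop("need at least 2 cells to rank gene variance")
  mu <- Matrix::colMeans(expr)
  mu2 <- Matrix::colMeans(expr^2)
  v <- (mu2 - mu^2) * n / (n - 1)
  ord <- order(-v)  # stable: ties keep input gene order
  colnames(expr)[ord[seq_len(min(n_hvgs, ncol(expr)))]]
}

#' Exact PCA of the scaled HVG submatrix
#'
#' Centers and unit-scales each HVG across cells (constant genes become 0),
#' clips z-scores at +/-10 to bound outlier leverage, and computes exact
#' principal components via eigen-decomposition of the covariance matrix.
#'
#' @param expr cells x genes log-normalized matrix.
#' @param hvgs genes to use.
#' @param n_pcs components to keep.
#' @return list with `scores` (cells x n_pcs), `sdev` (component standard
#'   deviations) and `rotation`.
#' @export
pca_scores <- function(expr, hvgs, n_pcs = 20) {
  if (nrow(expr) < n_pcs) stop("fewer cells than requested principal components")
  z <- as_dense(expr[, hvgs, drop = FALSE])
  mu <- colMeans(z)
  sd <- apply(z, 2L, stats::sd)
  sd[sd == 0] <- Inf  # constant genes contribute nothing
  z <- scale(z, center = mu, scale = sd)
  z[z > 10] <- 10
  z[z < -10] <- -10
  cv <- crossprod(z) / (nrow(z) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  n_pcs <- min(n_pcs, ncol(z))
  rot <- eig$vectors[, seq_len(n_pcs), drop = FALSE]
  rownames(rot) <- colnames(z)
  scores <- z %*% rot
  rownames(scores) <- rownames(expr)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  list(scores = scores, sdev = sqrt(pmax(eig$values[seq_len(n_pcs)], 0)),
       rotation = rot)
}

# Blockwise k-nearest-neighbor search in PC space (squared Euclidean).
knn_indices <- function(scores, k, block = 1000L) {
  n <- nrow(scores)
  k <- min(k, n)
  sq <- rowSums(scores^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(scores[idx, , drop = FALSE], scores)
    for (j in seq_along(idx)) {
      d2[j, idx[j]] <- -Inf  # self is always the first neighbor
      out[idx[j], ] <- order(d2[j, ])[seq_len(k)]
    }
  }
  out
}

#' Shared-nearest-neighbor graph clustering
#'
#' Builds a k-nearest-neighbor graph in PC space, converts it to a
#' shared-nearest-neighbor graph with Jaccard edge weights (pruned below
#' `snn_prune`), and partitions it by modularity optimization (Louvain).
#' Deterministic for a fixed seed.
#'
#' @param scores cells x PCs matrix from [pca_scores()].
#' @param cfg a [preprocess_config()]; uses `snn_k`, `snn_prune`,
#'   `cluster_resolution` and `seed`.
#' @return integer cluster labels named by cell id (>= 1 cluster).
#' @export
cluster_snn <- function(scores, cfg = preprocess_config()) {
  n <- nrow(scores)
  k <- min(cfg$snn_k, n)
  nn <- knn_indices(scores, k)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)
  jac@x[jac@x < cfg$snn_prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
  set_substream(cfg$seed, "snn-cluster")
  comm <- igraph::cluster_louvain(g, resolution = cfg$cluster_resolution)
  labels <- as.integer(igraph::membership(comm))
  stats::setNames(labels, rownames(scores))
}
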
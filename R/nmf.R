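# Validation of the three-subtype classification by downsampled NMF
# clustering (k = 3, multiplicative updates on squared Frobenius error) and
# a best-matching resampling concordance statistic.

#' NMF validation configuration
#'
#' @param k number of factors (default 3).
#' @param cells_per_sample downsampling depth per sample (default 50).
#' @param n_repeats resampling repeats (default 10).
#' @param max_iter maximum multiplicative-update iterations.
#' @param tol relative loss-change stopping tolerance.
#' @param seed integer seed; repeat r uses `seed + r`.
#' @return a validated `nmf_config`.
#' @export
nmf_config <- function(k = 3, cells_per_sample = 50, n_repeats = 10,
                       max_iter = 500, tol = 1e-6, seed = 1L) {
  cfg <- list(
    k = check_count(k, "k", min = 2L),
    cells_per_sample = check_count(cells_per_sample, "cells_per_sample"),
    n_repeats = check_count(n_repeats, "n_repeats"),
    max_iter = check_count(max_iter, "max_iter"),
    tol = check_positive(tol, "tol"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$cells_per_sample < cfg$k) {
    stop("configuration error: 'cells_per_sample' must be >= k", call. = FALSE)
  }
  class(cfg) <- "nmf_config"
  cfg
}

#' Downsample tumor cells per sample
#'
#' Uniform sampling without replacement of `min(n_per_sample, sample size)`
#' tumor cells from each sample; deterministic for a fixed seed.
#'
#' @param meta per-cell metadata with `cell_id`, `sample_id`, `cell_class`.
#' @param n_per_sample cells to draw per sample.
#' @param seed integer seed.
#' @return character vector of cell ids.
#' @export
downsample_cells <- function(meta, n_per_sample = 50, seed = 1L) {
  if (is.null(meta) || nrow(meta) == 0) stop("empty metadata")
  tumor <- meta[meta$cell_class == "tumor", , drop = FALSE]
  if (nrow(tumor) == 0) stop("no tumor cells in metadata")
  set_substream(seed, "downsample")
  ids <- character(0)
  for (sid in sort(unique(tumor$sample_id))) {
    pool <- tumor$cell_id[tumor$sample_id == sid]
    take <- min(n_per_sample, length(pool))
    ids <- c(ids, pool[sample.int(length(pool), take)])
  }
  ids
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the squared Frobenius reconstruction error of `X ~ W H` with
#' Lee-Seung multiplicative updates; the loss trajectory is non-increasing.
#' Stops at `max_iter` or when the relative loss change drops below `tol`.
#' An all-zero matrix yields zero factors with loss 0.
#'
#' @param X non-negative matrix (rows = cells, columns = genes).
#' @param cfg an [nmf_config()].
#' @return list with `W` (cells x k), `H` (k x genes), `loss_trajectory`
#'   and `metagenes` (top 30 genes per factor by H loading).
#' @export
nmf_factorize <- function(X, cfg = nmf_config()) {
  X <- as_dense(X)
  if (any(X < 0)) stop("negative entry in NMF input matrix")
  n <- nrow(X); p <- ncol(X); k <- cfg$k
  if (all(X == 0)) {
    return(list(W = matrix(0, n, k, dimnames = list(rownames(X), NULL)),
                H = matrix(0, k, p, dimnames = list(NULL, colnames(X))),
                loss_trajectory = 0, metagenes = replicate(k, character(0), simplify = FALSE)))
  }
  set_substream(cfg$seed, "nmf-init")
  scale0 <- sqrt(mean(X) / k)
  W <- matrix(stats::runif(n * k, 0.1, 1) * scale0, n, k)
  H <- matrix(stats::runif(k * p, 0.1, 1) * scale0, k, p)
  eps <- .Machine$double.eps
  loss <- numeric(0)
  prev <- Inf
  for (it in seq_len(cfg$max_iter)) {
    H <- H * crossprod(W, X) / (crossprod(W) %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    cur <- sum((X - W %*% H)^2)
    loss <- c(loss, cur)
    if (is.finite(prev) && abs(prev - cur) / max(prev, eps) < cfg$tol) break
    prev <- cur
  }
  rownames(W) <- rownames(X)
  colnames(H) <- colnames(X)
  metagenes <- lapply(seq_len(k), function(f) {
    colnames(H)[order(-H[f, ])[seq_len(min(30, p))]]
  })
  list(W = W, H = H, loss_trajectory = loss, metagenes = metagenes)
}

#' Assign cells to factors by maximal loading
#'
#' Label = argmax over factors of the W row; ties resolve to the lowest
#' factor index with a warning; all-zero rows become "unassigned".
#'
#' @param result output of [nmf_factorize()].
#' @return character vector of labels ("factor1"... or "unassigned").
#' @export
assign_by_factor <- function(result) {
  W <- result$W
  labs <- character(nrow(W))
  n_ties <- 0L
  for (i in seq_len(nrow(W))) {
    row <- W[i, ]
    if (all(row == 0)) {
      labs[i] <- "unassigned"
      next
    }
    hit <- which(row == max(row))
    if (length(hit) > 1L) n_ties <- n_ties + 1L
    labs[i] <- paste0("factor", hit[1L])
  }
  if (n_ties > 0) warning(sprintf("%d tied W row(s) resolved to the lowest factor index", n_ties))
  stats::setNames(labs, rownames(W))
}

#' Best-matching concordance between two labelings
#'
#' The rate is the maximal fraction of agreeing cells over all one-to-one
#' matchings between the two class sets, found by exhaustive permutation
#' search (both labelings must have at most 6 classes). Cells labeled
#' "unassigned" (or NA) on either side are excluded from the denominator.
#'
#' @param labels_a,labels_b labelings; if both are named, aligned by name,
#'   otherwise by position.
#' @return agreement rate in `[0, 1]`.
#' @export
concordance <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    common <- intersect(names(labels_a), names(labels_b))
    if (!length(common)) stop("disjoint cell sets")
    labels_a <- labels_a[common]
    labels_b <- labels_b[common]
  } else if (length(labels_a) != length(labels_b)) {
    stop("labelings must cover the same cells")
  }
  ok <- !is.na(labels_a) & !is.na(labels_b) &
    labels_a != "unassigned" & labels_b != "unassigned"
  labels_a <- labels_a[ok]
  labels_b <- labels_b[ok]
  if (!length(labels_a)) stop("no assigned cells in common")
  tab <- table(labels_a, labels_b)
  ka <- nrow(tab); kb <- ncol(tab)
  if (ka > 6 || kb > 6) stop("concordance supports at most 6 classes per labeling")
  if (ka > kb) tab <- t(tab)
  perms <- permutations_of(ncol(tab))
  best <- 0
  for (r in seq_len(nrow(perms))) {
    agree <- sum(tab[cbind(seq_len(nrow(tab)), perms[r, seq_len(nrow(tab))])])
    if (agree > best) best <- agree
  }
  best / length(labels_a)
}

#' Resampling NMF concordance report
#'
#' For each repeat, downsamples tumor cells per sample, factorizes the
#' log-normalized expression over `features`, assigns cells to factors, and
#' computes the best-matching concordance with the subtype labels on the
#' downsampled cells. Repeat r uses seed `cfg$seed + r`.
#'
#' @param expr cells x genes log-normalized matrix.
#' @param meta per-cell metadata.
#' @param subtypes named per-cell subtype labels.
#' @param cfg an [nmf_config()].
#' @param features genes to factorize over (default: all genes of `expr`);
#'   conventionally the union of per-subtype top-50 markers and the HVGs.
#' @return list of class `concordance_report` with `per_repeat`, `median`,
#'   `min`, `max`.
#' @export
resample_concordance <- function(expr, meta, subtypes, cfg = nmf_config(),
                                 features = NULL) {
  if (is.null(features)) features <- colnames(expr)
  features <- intersect(features, colnames(expr))
  if (!length(features)) stop("no usable features for NMF")
  rates <- numeric(cfg$n_repeats)
  for (r in seq_len(cfg$n_repeats)) {
    ids <- downsample_cells(meta, cfg$cells_per_sample, seed = cfg$seed + r)
    X <- expr[ids, features, drop = FALSE]
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    res <- nmf_factorize(X, cfg_r)
    labs <- assign_by_factor(res)
    rates[r] <- concordance(labs, subtypes[ids])
  }
  structure(list(per_repeat = rates, median = stats::median(rates),
                 min = min(rates), max = max(rates)),
            class = "concordance_report")
}
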
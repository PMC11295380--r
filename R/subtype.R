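# Merge tumor-cell subclusters into the three subtypes via transcriptome
# similarity (Spearman correlation of mean profiles over the top-SD genes,
# average-linkage hierarchical clustering), name the groups by canonical
# markers, and rank subtype marker genes.

#' Mean expression profile per cluster
#'
#' @param expr cells x genes log-normalized matrix.
#' @param labels cluster labels, one per cell (named or positional).
#' @return list with `profile` (cluster x gene mean matrix) and `sizes`.
#' @export
mean_profiles <- function(expr, labels) {
  if (length(labels) != nrow(expr)) stop("every cell must be labeled")
  if (anyNA(labels)) stop("every cell must be labeled (NA found)")
  f <- factor(labels)
  if (any(table(f) == 0)) stop("empty cluster in labels")
  ind <- Matrix::fac2sparse(f)  # clusters x cells indicator
  sizes <- as.integer(Matrix::rowSums(ind))
  profile <- as_dense(ind %*% expr) / sizes
  rownames(profile) <- levels(f)
  list(profile = profile, sizes = stats::setNames(sizes, levels(f)))
}

#' Top genes by standard deviation across cluster profiles
#'
#' Genes ranked by the population standard deviation (ddof = 0) of their
#' cluster means; ties broken by gene order.
#'
#' @param profiles output of [mean_profiles()].
#' @param n number of genes.
#' @return character vector of exactly `n` gene symbols.
#' @export
top_sd_genes <- function(profiles, n = 50) {
  prof <- profiles$profile
  if (nrow(prof) < 2) stop("need at least 2 clusters")
  if (n > ncol(prof)) stop(sprintf("n = %d exceeds the %d available genes", n, ncol(prof)))
  mu <- colMeans(prof)
  sd_pop <- sqrt(colMeans(prof^2) - mu^2)
  colnames(prof)[order(-sd_pop)[seq_len(n)]]
}

#' Spearman similarity matrix between cluster profiles
#'
#' Each cluster's profile over `genes` is rank-transformed (average ranks on
#' ties) and Pearson correlation is taken on the ranks. A constant profile
#' has undefined correlation; it is recorded as 0 with a warning.
#'
#' @param profiles output of [mean_profiles()].
#' @param genes genes on which to correlate (>= 3).
#' @return symmetric cluster x cluster correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(profiles, genes) {
  if (length(genes) < 3) stop("need at least 3 genes")
  prof <- profiles$profile[, genes, drop = FALSE]
  ranks <- apply(prof, 1L, rank)  # genes x clusters, average ties
  constant <- apply(ranks, 2L, function(r) max(r) == min(r))
  if (any(constant)) {
    warning(sprintf("constant profile(s) %s: correlation recorded as 0",
                    paste(rownames(prof)[constant], collapse = ", ")))
  }
  cc <- suppressWarnings(stats::cor(ranks))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  dimnames(cc) <- list(rownames(prof), rownames(prof))
  cc
}

#' Merge subclusters into named subtypes by hierarchical clustering
#'
#' Agglomerative clustering (average linkage) on distance `1 - rho`, cut at
#' `k` groups. For `k = 3` the groups are named by marker evidence on the
#' cluster profiles: highest mean expression of ARG1/ALDOB names the metab
#' group, TOP2A/STMN1/MKI67 the prol group, S100A6/S100A11 the emt group.
#' If one group wins two names, an error instructs manual naming.
#'
#' @param sim Spearman similarity matrix from [spearman_matrix()].
#' @param profiles output of [mean_profiles()] (marker evidence for naming).
#' @param k number of groups (default 3).
#' @return list with `map` (subcluster -> subtype named character vector),
#'   `evidence` (group x program marker means, when k = 3) and `hclust`.
#' @export
hcluster_merge <- function(sim, profiles, k = 3) {
  if (nrow(sim) < k) stop("fewer clusters than requested groups")
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  grp <- stats::cutree(hc, k = k)
  if (k != 3) {
    map <- stats::setNames(paste0("group", grp), names(grp))
    return(list(map = map, evidence = NULL, hclust = hc))
  }
  prof <- profiles$profile
  marker_sets <- list(metab = METAB_MARKERS, prol = PROL_MARKERS, emt = EMT_MARKERS)
  evidence <- matrix(NA_real_, k, 3, dimnames = list(paste0("group", seq_len(k)),
                                                     names(marker_sets)))
  for (s in names(marker_sets)) {
    present <- intersect(marker_sets[[s]], colnames(prof))
    if (!length(present)) {
      stop(sprintf("no %s marker genes present; name the groups manually", s))
    }
    msc <- rowMeans(prof[, present, drop = FALSE])
    for (g in seq_len(k)) evidence[g, s] <- mean(msc[names(grp)[grp == g]])
  }
  winner <- apply(evidence, 2L, which.max)
  if (anyDuplicated(winner)) {
    stop("marker-naming collision: one group wins two subtype names; name the groups manually")
  }
  subtype_of_group <- character(k)
  subtype_of_group[winner] <- names(winner)
  map <- stats::setNames(subtype_of_group[grp], names(grp))
  list(map = map, evidence = evidence, hclust = hc)
}

#' Rank subtype marker genes by average log fold change
#'
#' For each subtype, `avg_logFC` is the mean log-expression in the subtype
#' minus the mean in all other cells; genes above `min_avg_logfc` are ranked
#' descending and the top `n_top` returned.
#'
#' @param expr cells x genes log-normalized matrix.
#' @param subtypes per-cell subtype labels (aligned to rows of `expr`).
#' @param min_avg_logfc inclusion threshold (strict).
#' @param n_top maximum markers per subtype.
#' @return named list of data.frames with `gene` and `avg_logfc`, ordered.
#' @export
rank_markers <- function(expr, subtypes, min_avg_logfc = 1.0, n_top = 50) {
  if (length(subtypes) != nrow(expr)) stop("labels must align to expression rows")
  levs <- unique(subtypes)
  if (length(levs) < 2) stop("need at least 2 subtypes")
  out <- list()
  for (s in levs) {
    inset <- subtypes == s
    if (sum(inset) < 2) stop(sprintf("subtype '%s' has fewer than 2 cells", s))
    mu_in <- Matrix::colMeans(expr[inset, , drop = FALSE])
    mu_out <- Matrix::colMeans(expr[!inset, , drop = FALSE])
    lfc <- mu_in - mu_out
    keep <- which(lfc > min_avg_logfc)
    keep <- keep[order(-lfc[keep])]
    keep <- utils::head(keep, n_top)
    out[[s]] <- data.frame(gene = colnames(expr)[keep],
                           avg_logfc = unname(lfc[keep]),
                           stringsAsFactors = FALSE)
  }
  out
}

#' Derive per-cell subtypes from expression and subcluster labels
#'
#' Convenience wrapper chaining [mean_profiles()], [top_sd_genes()],
#' [spearman_matrix()] and [hcluster_merge()], then projecting the
#' subcluster -> subtype map onto cells.
#'
#' @param expr cells x genes log-normalized matrix.
#' @param cluster_labels per-cell subcluster labels.
#' @param n_top_sd genes for the similarity profile (default 50).
#' @param k number of subtypes (default 3).
#' @return list with `cell_subtype` (named per-cell labels), `map`,
#'   `similarity`, `profiles`, `top_genes` and `evidence`.
#' @export
assign_subtypes <- function(expr, cluster_labels, n_top_sd = 50, k = 3) {
  profiles <- mean_profiles(expr, cluster_labels)
  genes <- top_sd_genes(profiles, n = min(n_top_sd, ncol(expr)))
  sim <- spearman_matrix(profiles, genes)
  merged <- hcluster_merge(sim, profiles, k = k)
  cell_subtype <- stats::setNames(unname(merged$map[as.character(cluster_labels)]),
                                  rownames(expr))
  list(cell_subtype = cell_subtype, map = merged$map, similarity = sim,
       profiles = profiles, top_genes = genes, evidence = merged$evidence)
}
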
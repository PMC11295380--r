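# Signature scoring of cells, spots and bulk samples: single-sample GSEA
# (rank-weighted ECDF difference) and mean z-score signatures, subtype
# assignment by score, and bulk-cohort Metab/EMT/Mixed classification.

#' Scoring configuration
#'
#' @param ssgsea_alpha rank-weight exponent of the ssGSEA running sum.
#' @param normalize_ssgsea divide scores by the analytic max - min achievable
#'   for the set size and gene count.
#' @param csc_markers cancer-stem-cell marker genes for the stemness score.
#' @return a validated `scoring_config`.
#' @export
scoring_config <- function(ssgsea_alpha = 0.25, normalize_ssgsea = TRUE,
                           csc_markers = CSC_MARKERS) {
  cfg <- list(
    ssgsea_alpha = check_positive(ssgsea_alpha, "ssgsea_alpha"),
    normalize_ssgsea = isTRUE(normalize_ssgsea),
    csc_markers = as.character(csc_markers)
  )
  if (!length(cfg$csc_markers)) {
    stop("configuration error: 'csc_markers' must be non-empty", call. = FALSE)
  }
  class(cfg) <- "scoring_config"
  cfg
}

#' Mean z-score signature
#'
#' Each set gene is z-scored across entities (genes with zero standard
#' deviation contribute 0), and the per-entity score is the average over the
#' set genes. Set genes absent from the matrix are dropped with a warning.
#'
#' @param expr entities x genes expression matrix.
#' @param gene_set character vector of gene symbols.
#' @return named numeric score per entity.
#' @export
mean_z_score <- function(expr, gene_set) {
  present <- intersect(gene_set, colnames(expr))
  if (!length(present)) stop("no gene of the set is present in the matrix")
  if (length(present) < length(unique(gene_set))) {
    warning(sprintf("%d set gene(s) absent from the matrix, dropped",
                    length(unique(gene_set)) - length(present)))
  }
  sub <- as_dense(expr[, present, drop = FALSE])
  mu <- colMeans(sub)
  sd <- apply(sub, 2L, stats::sd)
  sd[sd == 0 | is.na(sd)] <- Inf  # constant genes contribute 0
  z <- scale(sub, center = mu, scale = sd)
  stats::setNames(rowMeans(z), rownames(expr))
}

# Core ssGSEA running-sum statistic for one ranked indicator vector.
# `hits` is logical along the descending-expression ranking.
ssgsea_running_sum <- function(hits, alpha) {
  n <- length(hits)
  w <- ifelse(hits, seq_len(n)^alpha, 0)
  denom_in <- sum(w)
  if (denom_in == 0) return(0)
  ecdf_in <- cumsum(w) / denom_in
  n_out <- n - sum(hits)
  ecdf_out <- if (n_out > 0) cumsum(!hits) / n_out else rep(0, n)
  sum(ecdf_in - ecdf_out)
}

#' Single-sample GSEA score of one expression vector
#'
#' Genes are ranked by expression descending (ties keep input gene order);
#' the score is the sum over ranks of the difference between the
#' rank-weighted in-set ECDF (weight `rank^alpha`) and the unweighted
#' out-of-set ECDF. With `normalize_ssgsea`, the score is divided by the
#' difference between the maximal and minimal score achievable for that set
#' size and gene count, bounding it in `[-?, 1]`-style normalized units.
#'
#' @param x named expression vector for one entity.
#' @param gene_set character vector of gene symbols.
#' @param cfg a [scoring_config()].
#' @return a single numeric score.
#' @export
ssgsea_score <- function(x, gene_set, cfg = scoring_config()) {
  set <- intersect(gene_set, names(x))
  if (!length(set)) stop("empty intersection between gene set and expression vector")
  ord <- order(-x)  # stable for ties: input gene order
  hits <- names(x)[ord] %in% set
  score <- ssgsea_running_sum(hits, cfg$ssgsea_alpha)
  if (!cfg$normalize_ssgsea) return(score)
  n <- length(x); s <- length(set)
  top <- ssgsea_running_sum(c(rep(TRUE, s), rep(FALSE, n - s)), cfg$ssgsea_alpha)
  bot <- ssgsea_running_sum(c(rep(FALSE, n - s), rep(TRUE, s)), cfg$ssgsea_alpha)
  if (top == bot) return(0)
  score / (top - bot)
}

#' ssGSEA scores for a matrix of entities and a collection of sets
#'
#' @param expr entities x genes expression matrix.
#' @param sets named list of gene sets.
#' @param cfg a [scoring_config()].
#' @return entities x sets score matrix.
#' @export
ssgsea_matrix <- function(expr, sets, cfg = scoring_config()) {
  expr <- as_dense(expr)
  out <- matrix(NA_real_, nrow(expr), length(sets),
                dimnames = list(rownames(expr), names(sets)))
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, ]
    for (j in seq_along(sets)) out[i, j] <- ssgsea_score(x, sets[[j]], cfg)
  }
  out
}

#' Score entities against the three subtype signatures
#'
#' @param expr entities x genes expression matrix.
#' @param markers named list of three marker gene vectors (or data.frames
#'   from [rank_markers()] with a `gene` column).
#' @param cfg a [scoring_config()].
#' @param method "ssgsea" (default) or "meanz".
#' @return entities x subtypes score matrix.
#' @export
score_subtypes <- function(expr, markers, cfg = scoring_config(),
                           method = c("ssgsea", "meanz")) {
  method <- match.arg(method)
  sets <- lapply(markers, function(m) if (is.data.frame(m)) m$gene else m)
  if (method == "ssgsea") {
    ssgsea_matrix(expr, sets, cfg)
  } else {
    do.call(cbind, lapply(sets, function(s) mean_z_score(expr, s)))
  }
}

#' Assign each entity to the subtype with maximal score
#'
#' Exact score ties yield "unassigned".
#'
#' @param scores entities x subtypes score matrix.
#' @return named character labels.
#' @export
assign_subtype_by_score <- function(scores) {
  labs <- apply(scores, 1L, function(row) {
    hit <- which(row == max(row))
    if (length(hit) > 1L) "unassigned" else colnames(scores)[hit]
  })
  stats::setNames(labs, rownames(scores))
}

#' Classify bulk samples as Metab-HCC / EMT-HCC / Mixed-HCC
#'
#' Hierarchical clustering (average linkage, correlation distance) of the
#' samples on the combined metab + emt marker space, cut at three groups.
#' Groups are named by mean signature z-scores: the group highest on the
#' metab signature becomes Metab-HCC, highest on emt becomes EMT-HCC, the
#' remaining one Mixed-HCC.
#'
#' @param expr samples x genes expression matrix (>= 3 samples).
#' @param metab_genes,emt_genes marker gene vectors (typically top 50 each).
#' @return list with `assignment` (named per-sample labels), `groups` (raw
#'   cut), and `signature_means` (group x signature matrix).
#' @export
classify_bulk <- function(expr, metab_genes, emt_genes) {
  if (nrow(expr) < 3) stop("need at least 3 samples")
  genes <- intersect(unique(c(metab_genes, emt_genes)), colnames(expr))
  if (length(genes) < 2) stop("marker genes absent from the bulk matrix")
  sub <- as_dense(expr[, genes, drop = FALSE])
  if (all(apply(sub, 2L, function(v) max(v) == min(v)))) {
    stop("no separation: all samples identical on the marker space")
  }
  cc <- suppressWarnings(stats::cor(t(sub)))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  grp <- stats::cutree(hc, k = 3)
  metab_sc <- mean_z_score(expr, intersect(metab_genes, colnames(expr)))
  emt_sc <- mean_z_score(expr, intersect(emt_genes, colnames(expr)))
  sig <- cbind(metab = tapply(metab_sc, grp, mean), emt = tapply(emt_sc, grp, mean))
  g_metab <- which.max(sig[, "metab"])
  g_emt <- which.max(sig[, "emt"])
  if (g_metab == g_emt) stop("naming collision: one group wins both signatures")
  names_of_group <- rep("Mixed-HCC", 3)
  names_of_group[g_metab] <- "Metab-HCC"
  names_of_group[g_emt] <- "EMT-HCC"
  assignment <- stats::setNames(names_of_group[grp], rownames(expr))
  list(assignment = assignment, groups = grp, signature_means = sig)
}
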
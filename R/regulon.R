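# Regulon activity on pseudo-cells: recovery-curve AUC per regulon gene set
# and regulon specificity scores (1 - sqrt of Jensen-Shannon divergence
# between the activity distribution and a subtype indicator distribution).
# Regulons are inputs (GMT); no network inference is performed.

#' Regulon activity configuration
#'
#' @param pseudocell_size cells averaged into one pseudo-cell (default 20).
#' @param auc_top_fraction fraction of the ranking integrated by the
#'   recovery curve (default 0.05).
#' @param jsd_log_base logarithm base of the Jensen-Shannon divergence
#'   (base 2 bounds JSD in `[0, 1]`).
#' @param seed integer seed for the pseudo-cell grouping.
#' @return a validated `regulon_config`.
#' @export
regulon_config <- function(pseudocell_size = 20, auc_top_fraction = 0.05,
                           jsd_log_base = 2, seed = 1L) {
  cfg <- list(
    pseudocell_size = check_count(pseudocell_size, "pseudocell_size"),
    auc_top_fraction = check_fraction(auc_top_fraction, "auc_top_fraction",
                                      open_lo = TRUE),
    jsd_log_base = check_positive(jsd_log_base, "jsd_log_base"),
    seed = check_count(seed, "seed", min = 0L)
  )
  class(cfg) <- "regulon_config"
  cfg
}

#' Aggregate cells into fixed-size pseudo-cells per subtype
#'
#' Within each subtype the cells are randomly permuted (seeded) and chunked
#' into disjoint groups of exactly `pseudocell_size`; incomplete trailing
#' chunks are dropped and each pseudo-cell is the arithmetic mean expression
#' of its group. Subtypes with fewer cells than the chunk size contribute no
#' pseudo-cells (warning); if no subtype reaches the size, an error.
#'
#' @param expr cells x genes expression matrix.
#' @param labels per-cell subtype labels aligned to rows.
#' @param cfg a [regulon_config()].
#' @return list with `expr` (pseudo-cells x genes), `labels` (pseudo-cell
#'   subtype) and `members` (list of contributing cell indices).
#' @export
make_pseudocells <- function(expr, labels, cfg = regulon_config()) {
  if (length(labels) != nrow(expr)) stop("labels must align to expression rows")
  size <- cfg$pseudocell_size
  set_substream(cfg$seed, "pseudocells")
  out_rows <- list()
  out_labels <- character(0)
  members <- list()
  for (s in sort(unique(labels))) {
    idx <- which(labels == s)
    n_chunks <- length(idx) %/% size
    if (n_chunks == 0) {
      warning(sprintf("subtype '%s' has %d cells (< %d): no pseudo-cells",
                      s, length(idx), size))
      next
    }
    idx <- idx[sample.int(length(idx))]
    for (ch in seq_len(n_chunks)) {
      grp <- idx[((ch - 1) * size + 1):(ch * size)]
      out_rows[[length(out_rows) + 1L]] <- Matrix::colMeans(expr[grp, , drop = FALSE])
      out_labels <- c(out_labels, s)
      members[[length(members) + 1L]] <- grp
    }
  }
  if (!length(out_rows)) stop("no subtype reaches the pseudo-cell size")
  mat <- do.call(rbind, out_rows)
  rownames(mat) <- sprintf("pseudo%03d_%s", seq_along(out_labels), out_labels)
  colnames(mat) <- colnames(expr)
  names(members) <- rownames(mat)
  list(expr = mat, labels = stats::setNames(out_labels, rownames(mat)),
       members = members)
}

#' Recovery-curve AUC of a regulon in one expression profile
#'
#' Genes are ranked by expression descending (ties keep input gene order).
#' Over the top `ceiling(auc_top_fraction * n_genes)` positions the step
#' recovery curve (cumulative count of regulon genes) is integrated and
#' normalized by the maximal achievable area for that regulon size and
#' window, so the AUC lies in `[0, 1]`.
#'
#' @param x named expression vector.
#' @param regulon character vector of regulon gene symbols.
#' @param cfg a [regulon_config()].
#' @return AUC in `[0, 1]`.
#' @export
auc_recovery <- function(x, regulon, cfg = regulon_config()) {
  set <- intersect(regulon, names(x))
  if (!length(set)) stop("empty intersection between regulon and expression vector")
  n <- length(x)
  w <- ceiling(cfg$auc_top_fraction * n)
  ord <- order(-x)
  hits <- names(x)[ord][seq_len(w)] %in% set
  area <- sum(cumsum(hits))
  max_area <- sum(pmin(seq_len(w), length(set)))
  area / max_area
}

#' Regulon activity matrix over pseudo-cells
#'
#' @param expr pseudo-cells x genes expression matrix.
#' @param regulons named list of regulon gene sets.
#' @param cfg a [regulon_config()].
#' @return pseudo-cells x regulons AUC matrix.
#' @export
regulon_auc_matrix <- function(expr, regulons, cfg = regulon_config()) {
  expr <- as_dense(expr)
  out <- matrix(NA_real_, nrow(expr), length(regulons),
                dimnames = list(rownames(expr), names(regulons)))
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, ]
    for (j in seq_along(regulons)) out[i, j] <- auc_recovery(x, regulons[[j]], cfg)
  }
  out
}

# Jensen-Shannon divergence between two probability vectors, given log base.
jsd <- function(p, q, base = 2) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz], base = base))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Regulon specificity scores
#'
#' For regulon r and subtype s, the activity column is normalized to a
#' probability distribution P over pseudo-cells and compared with the
#' uniform indicator distribution Q of subtype s;
#' `RSS = 1 - sqrt(JSD(P, Q))` with the configured log base. An all-zero
#' activity column yields RSS 0 for every subtype, with a warning.
#'
#' @param activity pseudo-cells x regulons AUC matrix.
#' @param labels pseudo-cell subtype labels aligned to rows.
#' @param cfg a [regulon_config()].
#' @return regulons x subtypes RSS matrix, entries in `[0, 1]`.
#' @export
regulon_rss <- function(activity, labels, cfg = regulon_config()) {
  if (length(labels) != nrow(activity)) stop("labels must align to activity rows")
  if (anyNA(labels)) stop("unknown (NA) pseudo-cell label")
  subtypes <- sort(unique(labels))
  out <- matrix(NA_real_, ncol(activity), length(subtypes),
                dimnames = list(colnames(activity), subtypes))
  for (j in seq_len(ncol(activity))) {
    col <- activity[, j]
    if (sum(col) == 0) {
      warning(sprintf("all-zero activity column '%s': RSS recorded as 0",
                      colnames(activity)[j]))
      out[j, ] <- 0
      next
    }
    p <- col / sum(col)
    for (s in subtypes) {
      q <- as.numeric(labels == s)
      q <- q / sum(q)
      out[j, s] <- 1 - sqrt(jsd(p, q, base = cfg$jsd_log_base))
    }
  }
  out
}
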
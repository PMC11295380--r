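# Sample-level subtype composition, Metab-HCC / EMT-HCC cohort grouping,
# within- versus between-patient heterogeneity statistics, and the
# mutation-rate summary table.

#' Per-sample subtype composition
#'
#' Fraction of each subtype among the tumor cells of every sample. Samples
#' without tumor cells are excluded with a warning.
#'
#' @param subtypes named per-cell subtype labels (metab / prol / emt).
#' @param meta per-cell metadata with `cell_id`, `sample_id`, `patient_id`,
#'   `cell_class`.
#' @return object of class `composition_table`: list with `fractions`
#'   (samples x 3 matrix, rows summing to 1), `sample_id`, `patient_id`.
#' @export
composition_table <- function(subtypes, meta) {
  tumor <- meta[meta$cell_class == "tumor", , drop = FALSE]
  labs <- subtypes[tumor$cell_id]
  if (anyNA(labs)) stop("every tumor cell must carry a subtype label")
  samples <- unique(tumor$sample_id)
  keep <- samples[samples %in% tumor$sample_id]
  frac <- t(vapply(keep, function(sid) {
    l <- labs[tumor$sample_id == sid]
    vapply(SUBTYPES, function(s) mean(l == s), numeric(1))
  }, numeric(3)))
  colnames(frac) <- SUBTYPES
  rownames(frac) <- keep
  dropped <- setdiff(unique(meta$sample_id), keep)
  if (length(dropped)) {
    warning(sprintf("sample(s) without tumor cells excluded: %s",
                    paste(dropped, collapse = ", ")))
  }
  patient <- meta$patient_id[match(keep, meta$sample_id)]
  structure(list(fractions = frac, sample_id = keep,
                 patient_id = stats::setNames(patient, keep)),
            class = "composition_table")
}

#' Group samples into Metab-HCC and EMT-HCC
#'
#' Hierarchical clustering (average linkage, Euclidean distance on the
#' 3-vector compositions) cut at two groups; the group with the higher mean
#' emt fraction is named EMT-HCC.
#'
#' @param comp a [composition_table()].
#' @return list with `assignment` (named sample labels), `sizes` and
#'   `emt_hcc_proportion`.
#' @export
group_cohort <- function(comp) {
  frac <- comp$fractions
  if (nrow(frac) < 2) stop("need at least 2 samples")
  if (all(apply(frac, 2L, function(v) max(v) == min(v)))) {
    stop("no separation: identical compositions for all samples")
  }
  hc <- stats::hclust(stats::dist(frac), method = "average")
  grp <- stats::cutree(hc, k = 2)
  emt_means <- tapply(frac[, "emt"], grp, mean)
  if (emt_means[1] == emt_means[2]) {
    stop("naming collision: both groups have equal mean emt fraction")
  }
  emt_group <- as.integer(names(which.max(emt_means)))
  labels <- ifelse(grp == emt_group, "EMT-HCC", "Metab-HCC")
  structure(list(assignment = stats::setNames(labels, rownames(frac)),
                 sizes = table(labels),
                 emt_hcc_proportion = mean(labels == "EMT-HCC")),
            class = "cohort_grouping")
}

#' Exact or approximate two-sided Wilcoxon rank-sum test
#'
#' When the pooled size is at most `exact_max`, the two-sided p-value is
#' computed by exhaustive enumeration of all group assignments of the
#' pooled ranks (average ranks on ties; p = 2 * min(lower, upper) tail,
#' capped at 1). Larger inputs use the normal approximation with tie and
#' continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_max enumeration threshold on `length(x) + length(y)`.
#' @return list with `p_value`, `statistic` (rank sum of `x`) and `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 20L) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  if (n <= exact_max) {
    combos <- utils::combn(n, n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    p_low <- mean(w_all <= w_obs)
    p_high <- mean(w_all >= w_obs)
    p <- min(1, 2 * min(p_low, p_high))
    return(list(p_value = p, statistic = w_obs, method = "exact enumeration"))
  }
  p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  list(p_value = p, statistic = w_obs, method = "normal approximation")
}

#' Within- versus between-patient composition distances
#'
#' All pairwise Euclidean distances between sample composition vectors,
#' partitioned into within-patient and between-patient sets, with medians,
#' ranges and a two-sided rank-sum p-value.
#'
#' @param comp a [composition_table()]; needs at least one patient with two
#'   or more samples, and at least two patients.
#' @return list with `within`, `between`, medians, ranges, `p_value` and
#'   the test method used.
#' @export
distance_summary <- function(comp) {
  frac <- comp$fractions
  n <- nrow(frac)
  patient <- comp$patient_id[rownames(frac)]
  if (length(unique(patient)) < 2) stop("need at least 2 patients")
  d <- as.matrix(stats::dist(frac))
  within <- numeric(0); between <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (patient[i] == patient[j]) within <- c(within, d[i, j])
      else between <- c(between, d[i, j])
    }
  }
  if (!length(within)) stop("no within-patient sample pair")
  test <- rank_sum_test(within, between)
  list(within = within, between = between,
       median_within = stats::median(within),
       median_between = stats::median(between),
       range_within = range(within), range_between = range(between),
       p_value = test$p_value, method = test$method)
}

#' Mutation-rate percentages per subtype and gene
#'
#' Rate = 100 x mutant / total, rounded half-up to one decimal; raw counts
#' are retained alongside.
#'
#' @param mutations data.frame with `line_id`, `subtype` and logical
#'   per-gene flag columns (e.g. TP53, CTNNB1).
#' @return data.frame with `subtype`, `gene`, `n_mutant`, `n_total`,
#'   `rate_pct`.
#' @export
mutation_rate_table <- function(mutations) {
  genes <- setdiff(names(mutations), c("line_id", "subtype"))
  if (!length(genes)) stop("no mutation flag columns")
  subtypes <- unique(mutations$subtype)
  if (any(table(mutations$subtype) == 0) || !length(subtypes)) {
    stop("every subtype must have at least one line")
  }
  rows <- list()
  for (s in subtypes) {
    sub <- mutations[mutations$subtype == s, , drop = FALSE]
    for (g in genes) {
      flags <- sub[[g]]
      if (!is.logical(flags)) stop(sprintf("mutation flag column '%s' is not boolean", g))
      rows[[length(rows) + 1L]] <- data.frame(
        subtype = s, gene = g, n_mutant = sum(flags), n_total = length(flags),
        rate_pct = round_half_up(100 * sum(flags) / length(flags), 1L),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
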
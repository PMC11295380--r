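# Shared fixtures. Expensive cohort runs are memoized so several test files
# (and the acceptance checks) reuse one computation.

.fixtures <- new.env(parent = emptyenv())

# Small cohort for unit-scale checks: 8 samples x 150 cells.
small_cohort <- function(seed = 7) {
  key <- paste0("small", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_cohort(synth_config(
      n_patients = 4, samples_per_patient = 2, cells_per_sample = 150, seed = seed))
  }
  .fixtures[[key]]
}

# The full recovery run: 10 patients x 2 samples x 300 cells, program_log_fc
# 2, fixed seed — the cohort scale at which end-to-end recovery is assessed.
full_recovery_run <- function() {
  if (!is.null(.fixtures$full)) return(.fixtures$full)
  cohort <- generate_cohort(synth_config(seed = 1))
  pre_cfg <- preprocess_config(seed = 1)
  qc <- qc_filter(cohort$counts, cohort$meta, pre_cfg)
  expr <- normalize_log1p_cp10k(qc$counts)
  hvgs <- select_hvgs(expr, pre_cfg$n_hvgs)
  pca <- pca_scores(expr, hvgs, pre_cfg$n_pcs)
  clusters <- cluster_snn(pca$scores, pre_cfg)
  st <- assign_subtypes(expr, clusters)
  markers <- rank_markers(expr, st$cell_subtype)
  features <- union(unlist(lapply(markers, `[[`, "gene")), hvgs)
  report <- resample_concordance(expr, qc$meta, st$cell_subtype,
                                 nmf_config(seed = 1), features = features)
  comp <- composition_table(st$cell_subtype, qc$meta)
  grouping <- group_cohort(comp)
  dsum <- distance_summary(comp)
  .fixtures$full <- list(cohort = cohort, qc = qc, expr = expr, hvgs = hvgs,
                         clusters = clusters, st = st, markers = markers,
                         report = report, comp = comp, grouping = grouping,
                         dsum = dsum)
  .fixtures$full
}

# Deterministic dense expression fixture: entities x genes with names.
toy_expr <- function(n_entities, n_genes, seed = 11) {
  set.seed(seed)
  m <- matrix(stats::rexp(n_entities * n_genes), n_entities, n_genes,
              dimnames = list(sprintf("e%02d", seq_len(n_entities)),
                              sprintf("g%02d", seq_len(n_genes))))
  m
}
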
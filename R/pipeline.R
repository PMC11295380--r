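# End-to-end orchestration: simulate -> preprocess -> subtype ->
# nmf-validate -> score -> regulons -> composition, with a structured
# config, plain-file stage outputs and a JSON run manifest.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations. A global `seed`, when given,
#' propagates to every sub-config whose seed was not explicitly set.
#'
#' @param synth a [synth_config()].
#' @param preprocess a [preprocess_config()].
#' @param nmf an [nmf_config()].
#' @param scoring a [scoring_config()].
#' @param regulon a [regulon_config()].
#' @param seed optional global seed overriding all sub-config seeds.
#' @param log_level "info" or "quiet".
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(synth = synth_config(), preprocess = preprocess_config(),
                            nmf = nmf_config(), scoring = scoring_config(),
                            regulon = regulon_config(), seed = NULL,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (!is.null(seed)) {
    seed <- check_count(seed, "seed", min = 0L)
    synth$seed <- seed
    preprocess$seed <- substream_seed(seed, "preprocess")
    nmf$seed <- substream_seed(seed, "nmf")
    regulon$seed <- substream_seed(seed, "regulon")
  }
  structure(list(synth = synth, preprocess = preprocess, nmf = nmf,
                 scoring = scoring, regulon = regulon, seed = seed,
                 log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys `synth`, `preprocess`, `nmf`, `scoring`, `regulon` map to
#' the corresponding config constructors; unknown fields are rejected by the
#' constructors. A top-level `seed` propagates as in [pipeline_config()].
#'
#' @param path YAML (.yaml/.yml) or JSON file.
#' @return a `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  build <- function(ctor, args) if (is.null(args)) ctor() else do.call(ctor, args)
  pipeline_config(
    synth = build(synth_config, raw$synth),
    preprocess = build(preprocess_config, raw$preprocess),
    nmf = build(nmf_config, raw$nmf),
    scoring = build(scoring_config, raw$scoring),
    regulon = build(regulon_config, raw$regulon),
    seed = raw$seed,
    log_level = if (is.null(raw$log_level)) "info" else raw$log_level
  )
}

pipe_log <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "info")) message(sprintf(fmt, ...))
  invisible(NULL)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes all stages in order on a generated cohort and writes each
#' stage's artifacts as plain files under `out_dir`. Rerunning with the
#' same config reproduces every artifact bit-identically (the manifest's
#' timestamp aside).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @return the run manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("hccsubtype")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = config$seed, stages = list())
  stage <- function(name, seed, outputs) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(name = name, seed = seed, outputs = outputs)
  }
  run <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s (artifacts kept in %s)",
                   name, conditionMessage(e), out_dir), call. = FALSE)
    })
  }

  # -- simulate ----------------------------------------------------------
  pipe_log(config, "stage simulate: generating cohort")
  cohort <- run("simulate", generate_cohort(config$synth))
  sim_dir <- file.path(out_dir, "cohort")
  write_cohort(cohort, sim_dir)
  stage("simulate", config$synth$seed,
        file.path("cohort", c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                              "cells.tsv", "truth.json")))

  # -- preprocess --------------------------------------------------------
  pipe_log(config, "stage preprocess: QC, normalization, clustering")
  qc <- run("preprocess", qc_filter(cohort$counts, cohort$meta, config$preprocess))
  expr <- run("preprocess", normalize_log1p_cp10k(qc$counts))
  hvgs <- select_hvgs(expr, config$preprocess$n_hvgs)
  pca <- pca_scores(expr, hvgs, config$preprocess$n_pcs)
  clusters <- run("preprocess", cluster_snn(pca$scores, config$preprocess))
  write_report(qc$report, file.path(out_dir, "qc_report.json"))
  utils::write.table(data.frame(cell_id = names(clusters), subcluster = clusters),
                     file.path(out_dir, "subclusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stage("preprocess", config$preprocess$seed, c("qc_report.json", "subclusters.tsv"))

  # -- subtype -----------------------------------------------------------
  pipe_log(config, "stage subtype: similarity merge of %d subclusters",
           length(unique(clusters)))
  st <- run("subtype", assign_subtypes(expr, clusters))
  markers <- run("subtype", rank_markers(expr, st$cell_subtype))
  utils::write.table(data.frame(subcluster = names(st$map), subtype = st$map),
                     file.path(out_dir, "subtype_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(cell_id = names(st$cell_subtype),
                                subtype = st$cell_subtype),
                     file.path(out_dir, "cell_subtypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_report(as.data.frame(st$similarity), file.path(out_dir, "similarity.tsv"))
  for (s in names(markers)) {
    utils::write.table(markers[[s]], file.path(out_dir, sprintf("markers_%s.tsv", s)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stage("subtype", NULL, c("subtype_map.tsv", "cell_subtypes.tsv", "similarity.tsv",
                           sprintf("markers_%s.tsv", names(markers))))

  # -- nmf-validate ------------------------------------------------------
  pipe_log(config, "stage nmf-validate: %d resampling repeats", config$nmf$n_repeats)
  features <- union(unlist(lapply(markers, `[[`, "gene")), hvgs)
  report <- run("nmf-validate",
                resample_concordance(expr, qc$meta, st$cell_subtype, config$nmf,
                                     features = features))
  write_report(unclass(report), file.path(out_dir, "concordance_report.json"))
  stage("nmf-validate", config$nmf$seed, "concordance_report.json")

  # -- score -------------------------------------------------------------
  pipe_log(config, "stage score: subtype and stemness signatures")
  scores <- run("score", score_subtypes(expr, markers, config$scoring))
  csc <- run("score", mean_z_score(expr, config$scoring$csc_markers))
  score_tab <- data.frame(cell_id = rownames(scores), scores,
                          csc_score = csc[rownames(scores)],
                          score_label = assign_subtype_by_score(scores),
                          check.names = FALSE)
  utils::write.table(score_tab, file.path(out_dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stage("score", NULL, "scores.tsv")

  # -- regulons ----------------------------------------------------------
  pipe_log(config, "stage regulons: pseudo-cell AUC and RSS")
  regulon_path <- file.path(out_dir, "regulons.gmt")
  write_gmt(cohort$truth$program_genes, regulon_path)
  regulons <- read_gmt(regulon_path)
  pseudo <- run("regulons", make_pseudocells(expr, st$cell_subtype, config$regulon))
  auc <- run("regulons", regulon_auc_matrix(pseudo$expr, regulons, config$regulon))
  rss <- run("regulons", regulon_rss(auc, pseudo$labels, config$regulon))
  write_report(as.data.frame(auc), file.path(out_dir, "auc.tsv"))
  write_report(as.data.frame(rss), file.path(out_dir, "rss.tsv"))
  stage("regulons", config$regulon$seed, c("regulons.gmt", "auc.tsv", "rss.tsv"))

  # -- composition -------------------------------------------------------
  pipe_log(config, "stage composition: sample-level heterogeneity")
  comp <- run("composition", composition_table(st$cell_subtype, qc$meta))
  grouping <- run("composition", group_cohort(comp))
  dsum <- run("composition", distance_summary(comp))
  utils::write.table(data.frame(sample_id = rownames(comp$fractions),
                                patient_id = comp$patient_id[rownames(comp$fractions)],
                                comp$fractions,
                                group = grouping$assignment[rownames(comp$fractions)]),
                     file.path(out_dir, "composition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_report(dsum, file.path(out_dir, "distance_summary.json"))
  stage("composition", NULL, c("composition.tsv", "distance_summary.json"))

  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  pipe_log(config, "pipeline complete: %d stages, outputs in %s",
           manifest$n_stages, out_dir)
  invisible(manifest)
}
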
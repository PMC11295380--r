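# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: three
# latent expression programs (metabolism / proliferation / EMT), a roughly
# stable proliferative fraction per sample, patient-shared dominance of one
# terminal subtype over the other, negative-binomial counts with log-normal
# library sizes, designated mitochondrial genes, and a configurable share of
# deliberately low-quality cells to exercise QC thresholds.

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients number of patients.
#' @param samples_per_patient tumor samples per patient.
#' @param cells_per_sample tumor cells per sample.
#' @param n_genes total genes (programs + mitochondrial + background).
#' @param n_marker_genes_per_program genes per expression program (>= 10 so
#'   the literal marker symbols fit into their programs).
#' @param program_log_fc natural-log elevation of a program's genes in cells
#'   of that subtype.
#' @param prol_fraction_mean mean per-sample proliferative fraction.
#' @param prol_fraction_kappa beta concentration of the per-sample
#'   proliferative fraction around its mean (larger = more stable).
#' @param dominance_strength share of non-proliferative cells assigned to the
#'   patient's dominant terminal subtype, in (0.5, 1].
#' @param nb_dispersion negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param library_size_mean mean total counts per cell.
#' @param mito_gene_count number of designated mitochondrial genes.
#' @param lowq_cell_fraction fraction of cells generated to fail QC (fewer
#'   than 500 detected genes or mitochondrial fraction above 15%).
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return A validated `synth_config` object.
#' @export
synth_config <- function(n_patients = 10, samples_per_patient = 2,
                         cells_per_sample = 300, n_genes = 1000,
                         n_marker_genes_per_program = 50, program_log_fc = 2,
                         prol_fraction_mean = 0.2, prol_fraction_kappa = 2000,
                         dominance_strength = 0.85, nb_dispersion = 2,
                         library_size_mean = 5000, mito_gene_count = 10,
                         lowq_cell_fraction = 0.05, seed = 1L) {
  cfg <- list(
    n_patients = check_count(n_patients, "n_patients"),
    samples_per_patient = check_count(samples_per_patient, "samples_per_patient"),
    cells_per_sample = check_count(cells_per_sample, "cells_per_sample"),
    n_genes = check_count(n_genes, "n_genes"),
    n_marker_genes_per_program =
      check_count(n_marker_genes_per_program, "n_marker_genes_per_program", min = 10L),
    program_log_fc = {
      if (!is.numeric(program_log_fc) || program_log_fc < 0)
        stop("configuration error: 'program_log_fc' must be >= 0", call. = FALSE)
      as.numeric(program_log_fc)
    },
    prol_fraction_mean =
      check_fraction(prol_fraction_mean, "prol_fraction_mean", open_lo = TRUE, open_hi = TRUE),
    prol_fraction_kappa = check_positive(prol_fraction_kappa, "prol_fraction_kappa"),
    dominance_strength =
      check_fraction(dominance_strength, "dominance_strength", lo = 0.5, open_lo = TRUE),
    nb_dispersion = check_positive(nb_dispersion, "nb_dispersion"),
    library_size_mean = check_count(library_size_mean, "library_size_mean"),
    mito_gene_count = check_count(mito_gene_count, "mito_gene_count"),
    lowq_cell_fraction = check_fraction(lowq_cell_fraction, "lowq_cell_fraction"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (3L * cfg$n_marker_genes_per_program + cfg$mito_gene_count > cfg$n_genes) {
    stop("configuration error: 'n_genes' must cover 3 x n_marker_genes_per_program + mito_gene_count",
         call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

# The three program gene lists. Literal marker symbols are embedded so the
# signature operations (subtype naming, CSC score) run unmodified.
program_gene_lists <- function(m) {
  pad <- function(core, prefix) {
    c(core, sprintf("%s%03d", prefix, seq_len(m - length(core))))
  }
  list(metab = pad(c(METAB_MARKERS), "METSYN"),
       prol = pad(c(PROL_MARKERS), "PROSYN"),
       emt = pad(c(EMT_MARKERS, CSC_MARKERS), "EMTSYN"))
}

#' Generate a synthetic multi-patient tumor-cell cohort
#'
#' Draws a cohort of negative-binomial count profiles with three planted
#' expression programs and patient-level dominance structure, together with
#' per-cell metadata and the generating ground truth.
#'
#' Each sample draws its proliferative fraction from a beta distribution
#' around `prol_fraction_mean`; the remaining probability mass is split
#' `dominance_strength : (1 - dominance_strength)` between the patient's
#' dominant terminal subtype (metab or emt, shared by all samples of a
#' patient) and the other one. A `lowq_cell_fraction` share of cells is
#' generated to fail quality control, half by truncated library size (< 500
#' detected genes) and half by inflated mitochondrial fraction (> 15%).
#'
#' @param config a [synth_config()].
#' @return A list with `counts` (cells x genes sparse integer matrix),
#'   `meta` (per-cell metadata data.frame) and `truth` (cell subtypes,
#'   sample dominance, realized sample compositions, program gene lists,
#'   low-quality cell ids, and the config).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  cfg <- config
  m <- cfg$n_marker_genes_per_program
  programs <- program_gene_lists(m)
  mito_genes <- sprintf("MT-SYN%02d", seq_len(cfg$mito_gene_count))
  n_bg <- cfg$n_genes - 3L * m - cfg$mito_gene_count
  genes <- c(unlist(programs, use.names = FALSE), mito_genes,
             if (n_bg > 0) sprintf("GENE%04d", seq_len(n_bg)))

  set_substream(cfg$seed, "baseline")
  base_log <- stats::rnorm(cfg$n_genes, mean = 0, sd = 1)
  names(base_log) <- genes

  n_samples <- cfg$n_patients * cfg$samples_per_patient
  n_cells <- n_samples * cfg$cells_per_sample
  patient_ids <- sprintf("P%02d", seq_len(cfg$n_patients))
  sample_patient <- rep(patient_ids, each = cfg$samples_per_patient)
  sample_ids <- paste0(sample_patient, "S", rep(seq_len(cfg$samples_per_patient), cfg$n_patients))

  set_substream(cfg$seed, "composition")
  dominant <- sample(c("metab", "emt"), cfg$n_patients, replace = TRUE)
  names(dominant) <- patient_ids
  pf <- stats::rbeta(n_samples,
                     cfg$prol_fraction_mean * cfg$prol_fraction_kappa,
                     (1 - cfg$prol_fraction_mean) * cfg$prol_fraction_kappa)
  cell_subtype <- character(n_cells)
  cell_sample <- rep(sample_ids, each = cfg$cells_per_sample)
  for (j in seq_len(n_samples)) {
    dom <- dominant[sample_patient[j]]
    oth <- setdiff(c("metab", "emt"), dom)
    probs <- c(prol = pf[j])
    probs[dom] <- cfg$dominance_strength * (1 - pf[j])
    probs[oth] <- (1 - cfg$dominance_strength) * (1 - pf[j])
    idx <- which(cell_sample == sample_ids[j])
    cell_subtype[idx] <- sample(names(probs), length(idx), replace = TRUE, prob = probs)
  }

  set_substream(cfg$seed, "libsize")
  sdlog <- 0.3
  lib <- stats::rlnorm(n_cells, meanlog = log(cfg$library_size_mean) - sdlog^2 / 2, sdlog = sdlog)

  set_substream(cfg$seed, "mito")
  mito_frac <- stats::rbeta(n_cells, 2, 38)  # mean 5%, essentially always < 15%

  set_substream(cfg$seed, "lowq")
  n_low <- round(cfg$lowq_cell_fraction * n_cells)
  lowq_idx <- if (n_low > 0) sort(sample.int(n_cells, n_low)) else integer(0)
  lowq_mode <- rep(c("features", "mito"), length.out = n_low)
  feat_idx <- lowq_idx[lowq_mode == "features"]
  mito_idx <- lowq_idx[lowq_mode == "mito"]
  if (length(feat_idx)) lib[feat_idx] <- stats::runif(length(feat_idx), 100, 400)
  if (length(mito_idx)) mito_frac[mito_idx] <- stats::runif(length(mito_idx), 0.20, 0.50)

  set_substream(cfg$seed, "counts")
  is_mito <- genes %in% mito_genes
  q_mito <- exp(base_log[is_mito])
  q_mito <- q_mito / sum(q_mito)
  counts <- matrix(0L, n_cells, cfg$n_genes, dimnames = list(NULL, genes))
  for (s in SUBTYPES) {
    rel <- exp(base_log)
    rel[programs[[s]]] <- rel[programs[[s]]] * exp(cfg$program_log_fc)
    p_non <- rel[!is_mito] / sum(rel[!is_mito])
    cells <- which(cell_subtype == s)
    if (!length(cells)) next
    mu_non <- (lib[cells] * (1 - mito_frac[cells])) %o% p_non
    mu_mit <- (lib[cells] * mito_frac[cells]) %o% q_mito
    counts[cells, !is_mito] <- stats::rnbinom(length(mu_non), size = cfg$nb_dispersion, mu = mu_non)
    counts[cells, is_mito] <- stats::rnbinom(length(mu_mit), size = cfg$nb_dispersion, mu = mu_mit)
  }

  cell_ids <- sprintf("%s_C%04d", cell_sample,
                      unlist(lapply(seq_len(n_samples), function(j) seq_len(cfg$cells_per_sample))))
  rownames(counts) <- cell_ids
  totals <- rowSums(counts)
  meta <- data.frame(
    cell_id = cell_ids,
    sample_id = cell_sample,
    patient_id = rep(sample_patient, each = cfg$cells_per_sample),
    cell_class = "tumor",
    n_features = as.integer(rowSums(counts > 0)),
    mito_fraction = ifelse(totals > 0, rowSums(counts[, is_mito, drop = FALSE]) / totals, 0),
    stringsAsFactors = FALSE
  )

  comp <- t(vapply(sample_ids, function(sid) {
    labs <- cell_subtype[cell_sample == sid]
    vapply(SUBTYPES, function(s) mean(labs == s), numeric(1))
  }, numeric(3)))
  colnames(comp) <- SUBTYPES

  truth <- list(
    cell_subtype = stats::setNames(cell_subtype, cell_ids),
    sample_dominance = stats::setNames(dominant[sample_patient], sample_ids),
    sample_composition = comp,
    program_genes = programs,
    mito_genes = mito_genes,
    lowq_cells = cell_ids[lowq_idx],
    config_echo = cfg
  )
  list(counts = Matrix::Matrix(counts, sparse = TRUE), meta = meta, truth = truth)
}

#' Generate a synthetic bulk cell-line panel
#'
#' Emulates a panel of commercial liver-cancer cell lines whose bulk
#' log-expression is dominated by either the metabolism or the EMT program,
#' with simulated TP53/CTNNB1 mutation flags at configurable per-subtype
#' rates.
#'
#' @param config a [synth_config()]; supplies gene universe, program effect
#'   size and seed.
#' @param n_lines_per_subtype cell lines per subtype (metab and emt).
#' @param tp53_rate,ctnnb1_rate named mutation probabilities for
#'   `c(metab=, emt=)`. Defaults reproduce the reported cell-line rates
#'   (5/9 and 16/22 for TP53; 2/9 and 2/22 for CTNNB1).
#' @param noise_sd standard deviation of gaussian log-expression noise.
#' @return list with `expr` (lines x genes log-expression matrix) and
#'   `annotation` (line_id, subtype, TP53, CTNNB1).
#' @export
generate_cellline_panel <- function(config, n_lines_per_subtype,
                                    tp53_rate = c(metab = 5 / 9, emt = 16 / 22),
                                    ctnnb1_rate = c(metab = 2 / 9, emt = 2 / 22),
                                    noise_sd = 0.3) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  n_lines_per_subtype <- check_count(n_lines_per_subtype, "n_lines_per_subtype")
  cfg <- config
  m <- cfg$n_marker_genes_per_program
  programs <- program_gene_lists(m)
  mito_genes <- sprintf("MT-SYN%02d", seq_len(cfg$mito_gene_count))
  n_bg <- cfg$n_genes - 3L * m - cfg$mito_gene_count
  genes <- c(unlist(programs, use.names = FALSE), mito_genes,
             if (n_bg > 0) sprintf("GENE%04d", seq_len(n_bg)))
  set_substream(cfg$seed, "baseline")
  base_log <- stats::rnorm(cfg$n_genes, 0, 1)
  names(base_log) <- genes

  subtypes <- rep(c("metab", "emt"), each = n_lines_per_subtype)
  line_ids <- sprintf("LINE_%s_%02d", toupper(subtypes),
                      c(seq_len(n_lines_per_subtype), seq_len(n_lines_per_subtype)))
  set_substream(cfg$seed, "cellline-noise")
  expr <- matrix(stats::rnorm(length(line_ids) * cfg$n_genes, 0, noise_sd),
                 nrow = length(line_ids), ncol = cfg$n_genes,
                 dimnames = list(line_ids, genes))
  expr <- sweep(expr, 2L, -base_log)
  for (i in seq_along(line_ids)) {
    prog <- programs[[subtypes[i]]]
    expr[i, prog] <- expr[i, prog] + cfg$program_log_fc
  }
  expr <- pmax(expr, 0)

  set_substream(cfg$seed, "cellline-mutations")
  tp53 <- stats::rbinom(length(line_ids), 1, tp53_rate[subtypes]) == 1
  ctnnb1 <- stats::rbinom(length(line_ids), 1, ctnnb1_rate[subtypes]) == 1
  annotation <- data.frame(line_id = line_ids, subtype = subtypes,
                           TP53 = tp53, CTNNB1 = ctnnb1, stringsAsFactors = FALSE)
  list(expr = expr, annotation = annotation)
}

#' Generate pseudo-spots by summing 1-10 cells
#'
#' Emulates spatial-transcriptomics spots: each spot is the summed counts of
#' 1 to 10 cells drawn uniformly without replacement from a single sample of
#' the cohort, and the truth records the contributing subtype mixture.
#'
#' @param cohort output of [generate_cohort()].
#' @param n_spots number of spots to generate (> 0).
#' @param seed integer seed.
#' @return list with `counts` (spots x genes sparse matrix), `truth` (spot
#'   table with sample, cell count, subtype fractions) and `cells` (list of
#'   contributing cell ids per spot).
#' @export
generate_spots <- function(cohort, n_spots, seed = 1L) {
  if (is.null(cohort$counts) || nrow(cohort$counts) == 0)
    stop("cohort is empty")
  n_spots <- check_count(n_spots, "n_spots")
  set_substream(seed, "spots")
  samples <- unique(cohort$meta$sample_id)
  spot_ids <- sprintf("SPOT%04d", seq_len(n_spots))
  counts <- matrix(0, n_spots, ncol(cohort$counts),
                   dimnames = list(spot_ids, colnames(cohort$counts)))
  cells_per_spot <- vector("list", n_spots)
  names(cells_per_spot) <- spot_ids
  truth <- data.frame(spot_id = spot_ids, sample_id = NA_character_,
                      n_cells = NA_integer_, metab = 0, prol = 0, emt = 0,
                      stringsAsFactors = FALSE)
  subtype <- cohort$truth$cell_subtype
  for (i in seq_len(n_spots)) {
    sid <- samples[sample.int(length(samples), 1L)]
    pool <- cohort$meta$cell_id[cohort$meta$sample_id == sid]
    k <- sample.int(10L, 1L)
    chosen <- pool[sample.int(length(pool), min(k, length(pool)))]
    counts[i, ] <- Matrix::colSums(cohort$counts[chosen, , drop = FALSE])
    cells_per_spot[[i]] <- chosen
    truth$sample_id[i] <- sid
    truth$n_cells[i] <- length(chosen)
    for (s in SUBTYPES) truth[[s]][i] <- mean(subtype[chosen] == s)
  }
  list(counts = Matrix::Matrix(counts, sparse = TRUE), truth = truth,
       cells = cells_per_spot)
}

#' Write a cohort to disk as a Matrix Market bundle plus truth
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv`, `cells.tsv` and
#' `truth.json` into `dir`.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mtx_bundle(cohort$counts, cohort$meta, dir)
  truth <- cohort$truth
  truth$config_echo <- unclass(truth$config_echo)
  truth$sample_composition <- as.data.frame(truth$sample_composition)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
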
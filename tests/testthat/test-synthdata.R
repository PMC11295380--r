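# Synthetic cohort generator: determinism, planted structure, ground truth.

test_that("identical seeds give bit-identical cohorts", {
  cfg <- synth_config(n_patients = 2, samples_per_patient = 2,
                      cells_per_sample = 50, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$cell_subtype, b$truth$cell_subtype)
})

test_that("counts are non-negative integers and compositions sum to 1", {
  co <- small_cohort()
  expect_true(all(co$counts@x >= 0))
  expect_true(all(co$counts@x == round(co$counts@x)))
  expect_equal(unname(rowSums(co$truth$sample_composition)),
               rep(1, nrow(co$truth$sample_composition)), tolerance = 1e-9)
  progs <- co$truth$program_genes
  expect_length(intersect(progs$metab, progs$prol), 0)
  expect_length(intersect(progs$metab, progs$emt), 0)
  expect_length(intersect(progs$prol, progs$emt), 0)
})

test_that("literal marker symbols are present in the gene universe", {
  co <- small_cohort()
  genes <- colnames(co$counts)
  expect_true(all(c("ARG1", "ALDOB", "TOP2A", "STMN1", "MKI67", "S100A6",
                    "S100A11", "EPCAM", "CD24", "KRT19", "SOX9", "PROM1",
                    "CD44", "THY1", "CD47") %in% genes))
})

test_that("near-zero dispersion and strong programs make truth separable by argmax", {
  co <- generate_cohort(synth_config(n_patients = 2, samples_per_patient = 2,
                                     cells_per_sample = 100,
                                     nb_dispersion = 1e6, program_log_fc = 3,
                                     seed = 3))
  sums <- sapply(co$truth$program_genes,
                 function(g) Matrix::rowSums(co$counts[, g, drop = FALSE]))
  argmax <- colnames(sums)[max.col(sums, ties.method = "first")]
  nonlow <- setdiff(co$meta$cell_id, co$truth$lowq_cells)
  idx <- match(nonlow, co$meta$cell_id)
  expect_equal(mean(argmax[idx] == unname(co$truth$cell_subtype[nonlow])), 1)
})

test_that("per-sample prol fractions stay inside the central 99% binomial interval", {
  co <- generate_cohort(synth_config(prol_fraction_mean = 0.2,
                                     cells_per_sample = 500, seed = 1))
  obs <- tapply(co$truth$cell_subtype[co$meta$cell_id] == "prol",
                co$meta$sample_id, mean)
  lo <- qbinom(0.005, 500, 0.2) / 500
  hi <- qbinom(0.995, 500, 0.2) / 500
  expect_true(all(obs >= lo & obs <= hi))
})

test_that("low-quality cells violate a QC threshold; normal cells do not", {
  co <- small_cohort()
  meta <- co$meta
  low <- meta[meta$cell_id %in% co$truth$lowq_cells, ]
  expect_true(all(low$n_features < 500 | low$mito_fraction > 0.15))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(synth_config(prol_fraction_mean = 1.5), "prol_fraction_mean")
  expect_error(synth_config(dominance_strength = 0.3), "dominance_strength")
  expect_error(synth_config(n_genes = 50), "n_genes")
  expect_error(synth_config(n_marker_genes_per_program = 4),
               "n_marker_genes_per_program")
})

test_that("cell-line panel is separable and mutation rates match their binomial draw", {
  cfg <- synth_config(program_log_fc = 3, seed = 5)
  panel <- generate_cellline_panel(cfg, n_lines_per_subtype = 4)
  progs <- generate_cohort(
    synth_config(n_patients = 1, samples_per_patient = 1, cells_per_sample = 30,
                 seed = 5))$truth$program_genes
  res <- classify_bulk(panel$expr, progs$metab, progs$emt)
  ann <- panel$annotation
  named <- ifelse(ann$subtype == "metab", "Metab-HCC", "EMT-HCC")
  # the planted panel has no mixed lines; both planted groups must be pure
  expect_true(all(res$assignment[ann$line_id][named == "Metab-HCC"] != "EMT-HCC"))
  expect_true(all(res$assignment[ann$line_id][named == "EMT-HCC"] != "Metab-HCC"))

  big <- generate_cellline_panel(cfg, n_lines_per_subtype = 400,
                                 tp53_rate = c(metab = 16 / 22, emt = 16 / 22))
  rate <- mean(big$annotation$TP53)
  ci <- qbinom(c(0.005, 0.995), 800, 16 / 22) / 800
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])

  expect_error(generate_cellline_panel(cfg, n_lines_per_subtype = 0),
               "n_lines_per_subtype")
})

test_that("pseudo-spots sum the counts of their contributing cells", {
  co <- generate_cohort(synth_config(n_patients = 2, samples_per_patient = 1,
                                     cells_per_sample = 60, seed = 9))
  spots <- generate_spots(co, n_spots = 15, seed = 4)
  expect_true(all(spots$truth$n_cells >= 1 & spots$truth$n_cells <= 10))
  for (i in seq_len(nrow(spots$truth))) {
    cells <- spots$cells[[i]]
    expect_equal(as.numeric(spots$counts[i, ]),
                 unname(Matrix::colSums(co$counts[cells, , drop = FALSE])))
  }
  # subtype mix in truth matches the contributing cells
  one <- which(spots$truth$n_cells == 1)[1]
  if (!is.na(one)) {
    cell <- spots$cells[[one]]
    expect_equal(as.numeric(spots$counts[one, ]), as.numeric(co$counts[cell, ]))
    s <- unname(co$truth$cell_subtype[cell])
    expect_equal(spots$truth[[s]][one], 1)
  }
  expect_error(generate_spots(co, n_spots = 0), "n_spots")
})
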
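# Sample composition, cohort grouping, heterogeneity distances, exact
# rank-sum p-values and the mutation-rate table.

make_meta <- function(labels_per_sample, patients) {
  rows <- list()
  for (sid in names(labels_per_sample)) {
    labs <- labels_per_sample[[sid]]
    rows[[sid]] <- data.frame(
      cell_id = sprintf("%s_c%02d", sid, seq_along(labs)),
      sample_id = sid, patient_id = patients[[sid]],
      cell_class = "tumor", stringsAsFactors = FALSE)
    rows[[sid]]$subtype <- labs
  }
  meta <- do.call(rbind, rows)
  list(meta = meta[, 1:4],
       subtypes = setNames(meta$subtype, meta$cell_id))
}

test_that("composition fractions match direct counting", {
  fx <- make_meta(list(sA = rep("metab", 10),
                       sB = c(rep("metab", 2), rep("prol", 2), rep("emt", 6))),
                  list(sA = "p1", sB = "p1"))
  comp <- composition_table(fx$subtypes, fx$meta)
  expect_equal(unname(comp$fractions["sA", ]), c(1, 0, 0))
  expect_equal(unname(comp$fractions["sB", ]), c(0.2, 0.2, 0.6))
  expect_equal(unname(rowSums(comp$fractions)), c(1, 1))

  set.seed(17)
  labs <- sample(c("metab", "prol", "emt"), 40, replace = TRUE)
  fx2 <- make_meta(list(sC = labs), list(sC = "p2"))
  comp2 <- composition_table(fx2$subtypes, fx2$meta)
  expect_equal(unname(comp2$fractions["sC", "prol"]), mean(labs == "prol"))
})

test_that("cohort grouping separates planted dominance and names by emt fraction", {
  labels <- list()
  patients <- list()
  for (i in 1:6) {
    nm <- sprintf("m%d", i)
    labels[[nm]] <- c(rep("metab", 7), rep("prol", 2), "emt")
    patients[[nm]] <- sprintf("pm%d", i)
  }
  for (i in 1:4) {
    nm <- sprintf("e%d", i)
    labels[[nm]] <- c("metab", rep("prol", 2), rep("emt", 7))
    patients[[nm]] <- sprintf("pe%d", i)
  }
  fx <- make_meta(labels, patients)
  comp <- composition_table(fx$subtypes, fx$meta)
  g <- group_cohort(comp)
  expect_equal(unname(g$assignment[sprintf("m%d", 1:6)]), rep("Metab-HCC", 6))
  expect_equal(unname(g$assignment[sprintf("e%d", 1:4)]), rep("EMT-HCC", 4))
  expect_equal(g$emt_hcc_proportion, 0.4)

  # two samples, one per dominance
  two <- composition_table(fx$subtypes, fx$meta[fx$meta$sample_id %in% c("m1", "e1"), ])
  g2 <- group_cohort(two)
  expect_setequal(unname(g2$assignment), c("Metab-HCC", "EMT-HCC"))
  expect_equal(g2$emt_hcc_proportion, 0.5)
})

test_that("degenerate cohorts are rejected", {
  fx <- make_meta(list(s1 = rep("metab", 5), s2 = rep("metab", 5)),
                  list(s1 = "p1", s2 = "p2"))
  comp <- composition_table(fx$subtypes, fx$meta)
  expect_error(group_cohort(comp), "no separation")
})

test_that("exact rank-sum p-values match full enumeration", {
  # within = {1,2}, between = {3,4,5}: W = 3, the minimum of C(5,2)=10
  # assignments -> two-sided p = 2 * 1/10 = 0.2
  res <- rank_sum_test(c(1, 2), c(3, 4, 5))
  expect_equal(res$p_value, 0.2)
  expect_equal(res$method, "exact enumeration")
  expect_equal(res$p_value, wilcox.test(c(1, 2), c(3, 4, 5))$p.value)

  # property: equals an independent enumeration for random small inputs
  set.seed(18)
  for (rep in 1:5) {
    x <- runif(4)
    y <- runif(5)
    got <- rank_sum_test(x, y)$p_value
    r <- rank(c(x, y))
    combos <- combn(9, 4)
    w_all <- apply(combos, 2, function(ix) sum(r[ix]))
    w_obs <- sum(r[1:4])
    expected <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
    expect_equal(got, expected)
    expect_equal(got, wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("distance summary partitions pairs and handles closed forms", {
  fx <- make_meta(list(a1 = rep("metab", 10), a2 = rep("metab", 10),
                       b1 = rep("prol", 10)),
                  list(a1 = "pa", a2 = "pa", b1 = "pb"))
  comp <- composition_table(fx$subtypes, fx$meta)
  ds <- distance_summary(comp)
  expect_equal(ds$within, 0)                      # identical compositions
  expect_equal(ds$between, rep(sqrt(2), 2))       # (1,0,0) vs (0,1,0)
  expect_equal(ds$median_within, 0)
  expect_equal(ds$median_between, sqrt(2))
  expect_true(ds$p_value > 0 && ds$p_value <= 1)

  solo <- composition_table(fx$subtypes,
                            fx$meta[fx$meta$sample_id %in% c("a1", "b1"), ])
  expect_error(distance_summary(solo), "no within-patient")
})

test_that("mutation rates reproduce the printed worked example", {
  # counts as printed: EMT 16/22 TP53, 2/22 CTNNB1; Metab 5/9 TP53, 2/9 CTNNB1
  tab <- data.frame(
    line_id = sprintf("L%02d", 1:31),
    subtype = rep(c("emt", "metab"), c(22, 9)),
    TP53 = c(rep(TRUE, 16), rep(FALSE, 6), rep(TRUE, 5), rep(FALSE, 4)),
    CTNNB1 = c(rep(TRUE, 2), rep(FALSE, 20), rep(TRUE, 2), rep(FALSE, 7)),
    stringsAsFactors = FALSE)
  rates <- mutation_rate_table(tab)
  get <- function(s, g) rates$rate_pct[rates$subtype == s & rates$gene == g]
  expect_identical(get("emt", "TP53"), 72.7)
  expect_identical(get("metab", "TP53"), 55.6)
  expect_identical(get("metab", "CTNNB1"), 22.2)
  expect_identical(get("emt", "CTNNB1"), 9.1)
  expect_equal(rates$n_total[rates$subtype == "emt"][1], 22)

  # half-up rounding and the zero numerator
  zero <- data.frame(line_id = c("a", "b"), subtype = "s",
                     TP53 = c(FALSE, FALSE))
  expect_equal(mutation_rate_table(zero)$rate_pct, 0)
  third <- data.frame(line_id = letters[1:8], subtype = "s",
                      TP53 = rep(c(TRUE, FALSE), c(1, 7)))
  expect_equal(mutation_rate_table(third)$rate_pct, 12.5)
})

test_that("patient-shared dominance yields lower within- than between-patient distances", {
  co <- generate_cohort(synth_config(n_patients = 6, samples_per_patient = 3,
                                     cells_per_sample = 80, lowq_cell_fraction = 0,
                                     seed = 12))
  comp <- composition_table(co$truth$cell_subtype, co$meta)
  ds <- distance_summary(comp)
  expect_lt(ds$median_within, ds$median_between)
  expect_lt(ds$p_value, 0.05)
  g <- group_cohort(comp)
  truth_dom <- co$truth$sample_dominance[names(g$assignment)]
  agree <- mean((g$assignment == "EMT-HCC") == (truth_dom == "emt"))
  expect_gte(agree, 0.95)
})
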
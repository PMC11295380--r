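# Transcriptome-similarity merge: profiles, top-SD genes, Spearman matrix,
# hierarchical merge with marker naming, marker ranking.

test_that("cluster mean profiles match the grouping oracle", {
  expr <- toy_expr(10, 6)
  labels <- c(1, 1, 2, 2, 2, 3, 3, 3, 3, 1)
  prof <- mean_profiles(expr, labels)
  for (cl in unique(labels)) {
    expect_equal(prof$profile[as.character(cl), ],
                 colMeans(expr[labels == cl, , drop = FALSE]))
  }
  expect_equal(unname(prof$sizes), c(3L, 3L, 4L))

  # a cluster of identical cells has the cell itself as profile
  one <- rbind(expr[1, ], expr[1, ])
  rownames(one) <- c("a", "b")
  p1 <- mean_profiles(one, c("x", "x"))
  expect_equal(p1$profile["x", ], expr[1, ])
})

test_that("top-SD genes use population SD with stable tie-breaking", {
  prof <- list(profile = rbind(a = c(g1 = 0, g2 = 5, g3 = 1, g4 = 2),
                               b = c(g1 = 0, g2 = 0, g3 = 1, g4 = 4)),
               sizes = c(a = 2, b = 2))
  ranked <- top_sd_genes(prof, 4)
  # population SDs: g1 = 0, g2 = 2.5, g3 = 0, g4 = 1
  expect_equal(ranked, c("g2", "g4", "g1", "g3"))
  expect_equal(top_sd_genes(prof, 2), c("g2", "g4"))
  expect_error(top_sd_genes(prof, 5), "exceeds")

  # brute-force SD oracle on a random 20-gene fixture
  set.seed(21)
  pr <- matrix(rnorm(5 * 20), 5, 20,
               dimnames = list(paste0("cl", 1:5), paste0("g", sprintf("%02d", 1:20))))
  obj <- list(profile = pr, sizes = rep(2, 5))
  sd_pop <- apply(pr, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(top_sd_genes(obj, 20), colnames(pr)[order(-sd_pop)])
})

test_that("Spearman matrix matches rank-then-Pearson and handles constants", {
  prof <- list(profile = rbind(a = c(1, 2, 3, 4, 5),
                               b = c(2, 4, 6, 8, 10),
                               c = c(5, 4, 3, 2, 1),
                               d = c(7, 7, 7, 7, 7)))
  colnames(prof$profile) <- paste0("g", 1:5)
  expect_warning(s <- spearman_matrix(prof, paste0("g", 1:5)), "constant")
  expect_equal(s["a", "b"], 1)
  expect_equal(s["a", "c"], -1)
  expect_equal(s["a", "d"], 0)
  expect_equal(s, t(s))
  expect_equal(unname(diag(s)), rep(1, 4))

  # brute-force oracle with ties: average ranks then Pearson
  p2 <- list(profile = rbind(x = c(1, 1, 2, 5, 3), y = c(2, 3, 3, 1, 4)))
  colnames(p2$profile) <- paste0("g", 1:5)
  s2 <- spearman_matrix(p2, paste0("g", 1:5))
  oracle <- cor(rank(p2$profile["x", ]), rank(p2$profile["y", ]))
  expect_equal(s2["x", "y"], oracle)
  expect_equal(s2["x", "y"], cor(p2$profile["x", ], p2$profile["y", ],
                                 method = "spearman"))
})

test_that("Spearman similarity is invariant under monotone transforms", {
  set.seed(31)
  pr <- matrix(rexp(4 * 12), 4, 12,
               dimnames = list(paste0("cl", 1:4), paste0("g", 1:12)))
  a <- spearman_matrix(list(profile = pr), colnames(pr))
  b <- spearman_matrix(list(profile = exp(2 * pr + 1)), colnames(pr))
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("block-structured similarity merges into its blocks with marker naming", {
  cl <- paste0("c", 1:9)
  blocks <- rep(1:3, each = 3)
  sim <- matrix(0.1, 9, 9, dimnames = list(cl, cl))
  sim[outer(blocks, blocks, "==")] <- 0.9
  diag(sim) <- 1
  # profiles carrying the naming markers: block1 metab, block2 prol, block3 emt
  genes <- c("ARG1", "ALDOB", "TOP2A", "STMN1", "MKI67", "S100A6", "S100A11")
  prof <- matrix(0, 9, 7, dimnames = list(cl, genes))
  prof[blocks == 1, c("ARG1", "ALDOB")] <- 5
  prof[blocks == 2, c("TOP2A", "STMN1", "MKI67")] <- 5
  prof[blocks == 3, c("S100A6", "S100A11")] <- 5
  merged <- hcluster_merge(sim, list(profile = prof), k = 3)
  expect_equal(unname(merged$map[blocks == 1]), rep("metab", 3))
  expect_equal(unname(merged$map[blocks == 2]), rep("prol", 3))
  expect_equal(unname(merged$map[blocks == 3]), rep("emt", 3))

  # exhaustive check: the cut partition equals the planted blocks
  expect_equal(adjusted_rand_index(merged$map, blocks), 1)

  # k = 1 puts everything in one group
  one <- hcluster_merge(sim, list(profile = prof), k = 1)
  expect_equal(length(unique(one$map)), 1)
})

test_that("merge is invariant to cluster index permutation", {
  cl <- paste0("c", 1:6)
  blocks <- rep(1:3, each = 2)
  sim <- matrix(0.05, 6, 6, dimnames = list(cl, cl))
  sim[outer(blocks, blocks, "==")] <- 0.95
  diag(sim) <- 1
  genes <- c("ARG1", "ALDOB", "TOP2A", "STMN1", "MKI67", "S100A6", "S100A11")
  prof <- matrix(0, 6, 7, dimnames = list(cl, genes))
  prof[blocks == 1, 1:2] <- 3
  prof[blocks == 2, 3:5] <- 3
  prof[blocks == 3, 6:7] <- 3
  base <- hcluster_merge(sim, list(profile = prof), k = 3)$map
  perm <- c(5, 3, 1, 6, 2, 4)
  permuted <- hcluster_merge(sim[perm, perm],
                             list(profile = prof[perm, , drop = FALSE]), k = 3)$map
  expect_equal(permuted[names(base)], base)
})

test_that("marker-naming collisions are reported", {
  cl <- paste0("c", 1:3)
  sim <- diag(3); dimnames(sim) <- list(cl, cl)
  genes <- c("ARG1", "ALDOB", "TOP2A", "STMN1", "MKI67", "S100A6", "S100A11")
  prof <- matrix(0, 3, 7, dimnames = list(cl, genes))
  prof["c1", ] <- 5  # c1 wins every program
  expect_error(hcluster_merge(sim, list(profile = prof), k = 3),
               "manual")
})

test_that("marker ranking matches the per-gene mean-difference oracle", {
  set.seed(41)
  expr <- toy_expr(12, 30, seed = 41)
  subtypes <- rep(c("metab", "emt"), each = 6)
  expr[1:6, 1:3] <- expr[1:6, 1:3] + 4      # strong metab markers
  expr[7:12, 4] <- expr[7:12, 4] + 2        # one emt marker
  mk <- rank_markers(expr, subtypes, min_avg_logfc = 1, n_top = 50)
  lfc <- colMeans(expr[1:6, ]) - colMeans(expr[7:12, ])
  keep <- names(lfc)[lfc > 1]
  expect_equal(mk$metab$gene, keep[order(-lfc[keep])])
  expect_equal(mk$metab$avg_logfc, unname(sort(lfc[keep], decreasing = TRUE)))
  expect_true(all(mk$emt$avg_logfc > 1))

  # gene with identical means in and out is excluded
  flat <- cbind(expr, same = rep(3, 12))
  mk2 <- rank_markers(flat, subtypes)
  expect_false("same" %in% c(mk2$metab$gene, mk2$emt$gene))

  expect_error(rank_markers(expr[1:7, ], c(rep("a", 6), "b")), "fewer than 2")
})
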
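test_that("count matrices respect the level's feature identity", {
  ann <- make_ann(ann_row("c1", "m1", id = "r1"),
                  ann_row("c1", "m1", id = "r2"),
                  ann_row("c1", "m1", id = "r3"))
  m <- count_features(ann, "reads", "mirna")
  expect_identical(unname(m["c1", "m1"]), 3L)

  # one read in two categories increments both features, parent total once
  multi <- make_ann(ann_row("c1", "m1", fp = -1L, tp = 2L, id = "r1"))
  mc <- count_features(multi, "reads", "category")
  expect_identical(unname(mc["c1", "m1|FP_VARIANT"]), 1L)
  expect_identical(unname(mc["c1", "m1|TP_TEMPLATED"]), 1L)
  expect_identical(unname(count_features(multi, "reads", "mirna")["c1", "m1"]),
                   1L)

  # isomiR-level identity distinguishes annotation signatures
  iso <- make_ann(ann_row("c1", "m1", id = "r1"),
                  ann_row("c1", "m1", tp = 1L, id = "r2"),
                  ann_row("c1", "m1", tp = 1L, id = "r3"))
  mi <- count_features(iso, "reads", "isomir")
  expect_identical(ncol(mi), 2L)
  expect_identical(sort(as.integer(mi)), c(1L, 2L))

  expect_error(count_features(ann, "umis", "mirna"), "UMI")
})

test_that("miRNA-level counts match ground-truth aggregation", {
  ref <- tiny_ref()
  cfg <- simulation_config(n_cells = 4, reads_per_cell = 500,
                           pcr_duplication_mean = 1, umi_length = 0,
                           adapter = "", seed = 61)
  sim <- simulate_cells(ref, cfg)
  ann <- annotate_reads(sim$reads, ref)
  m <- count_features(ann, "reads", "mirna")
  truth_tab <- table(sim$truth$cell, sim$truth$mature)
  truth_tab <- truth_tab[, colSums(truth_tab) > 0, drop = FALSE]
  expect_identical(sort(colnames(m)), sort(colnames(truth_tab)))
  expect_true(all(m[rownames(truth_tab), colnames(truth_tab)] ==
                    as.integer(truth_tab)))
  # per-cell totals sum to the cell's miRNA-mapped reads
  expect_identical(unname(rowSums(m)[sort(unique(ann$cell_id))]),
                   as.numeric(table(ann$cell_id)))
})

test_that("the cell filter boundary sits exactly at the threshold", {
  m <- matrix(c(999L, 1000L, 1001L), nrow = 3,
              dimnames = list(c("a", "b", "c"), "m1"))
  out <- filter_cells(m, 1000)
  expect_identical(rownames(out), c("b", "c"))
  expect_warning(filter_cells(m, 5000), "below")

  set.seed(3)
  tot <- sample(500:1500, 50)
  m2 <- matrix(tot, ncol = 1, dimnames = list(sprintf("c%02d", 1:50), "m1"))
  expect_identical(nrow(filter_cells(m2, 1000)), sum(tot >= 1000))
})

test_that("length distributions keep the total-read denominator", {
  all22 <- make_ann(ann_row("c1", "m1", id = "r1", read_len = 22L),
                    ann_row("c1", "m1", id = "r2", read_len = 22L))
  expect_identical(length_distribution(all22, "all"), c(`22` = 1))
  expect_identical(length_distribution(all22, "canonical_only"), c(`22` = 1))

  mixed <- make_ann(ann_row("c1", "m1", id = "r1", read_len = 22L),
                    ann_row("c1", "m1", tp = 1L, id = "r2", read_len = 23L))
  expect_identical(length_distribution(mixed, "all"), c(`22` = 0.5, `23` = 0.5))
  expect_identical(length_distribution(mixed, "canonical_only"), c(`22` = 0.5))
})

test_that("positional profiles average per-cell proportions, not pooled reads", {
  # cell A: 1 of 5 reads at fp -1 (0.2); cell B: 2 of 5 at fp -1 (0.4)
  rows <- c(lapply(1:4, function(i) ann_row("A", "m1", id = paste0("a", i))),
            list(ann_row("A", "m1", fp = -1L, id = "a5")),
            lapply(1:3, function(i) ann_row("B", "m1", id = paste0("b", i))),
            lapply(4:5, function(i) ann_row("B", "m1", fp = -1L,
                                            id = paste0("b", i))))
  ann <- do.call(make_ann, rows)
  prof <- positional_profile(ann, "all", "cells")
  expect_equal(prof[["fp-1"]], 0.3)
  pooled <- positional_profile(ann, "all", "pooled")
  expect_equal(pooled[["fp-1"]], 0.3)  # equal depths: same value
  # unequal depths separate the two averaging orders
  rows2 <- c(list(ann_row("A", "m1", fp = -1L, id = "x1")),
             lapply(1:9, function(i) ann_row("B", "m1", id = paste0("y", i))),
             list(ann_row("B", "m1", fp = -1L, id = "y10")))
  ann2 <- do.call(make_ann, rows2)
  expect_equal(positional_profile(ann2, "all", "cells")[["fp-1"]], 0.55)
  expect_equal(positional_profile(ann2, "all", "pooled")[["fp-1"]], 2 / 11)
})

test_that("all-canonical input gives a degenerate profile", {
  rows <- lapply(1:20, function(i)
    ann_row(sprintf("c%d", (i %% 4) + 1), "m1", id = paste0("r", i)))
  ann <- do.call(make_ann, rows)
  prof <- positional_profile(ann, "all")
  expect_equal(prof[["fp0"]], 1)
  expect_equal(prof[["tp0"]], 1)
  expect_equal(prof$nta_A, 0)
  expect_equal(prof$nta_U, 0)
  cp <- category_proportions(ann)
  expect_true(all(cp[, "CANONICAL"] == 1))
  expect_true(all(cp[, colnames(cp) != "CANONICAL"] == 0))
})

test_that("category proportions handle multi-membership and bounds", {
  ann <- make_ann(ann_row("c1", "m1", fp = -1L, tail = "A", id = "r1"),
                  ann_row("c1", "m1", id = "r2"))
  cp <- category_proportions(ann)
  expect_equal(unname(cp["c1", "FP_VARIANT"]), 0.5)
  expect_equal(unname(cp["c1", "TP_NONTEMPLATED"]), 0.5)
  expect_equal(unname(cp["c1", "CANONICAL"]), 0.5)

  ten <- do.call(make_ann, c(
    lapply(1:4, function(i) ann_row("c1", "m1", id = paste0("a", i))),
    lapply(1:6, function(i) ann_row("c1", "m1", tp = 1L, id = paste0("b", i)))))
  cp10 <- category_proportions(ten)
  expect_equal(unname(cp10["c1", "CANONICAL"]), 0.4)
  expect_equal(unname(cp10["c1", "TP_TEMPLATED"]), 0.6)
})

test_that("profile and category proportions recover the simulated mixture", {
  ref <- tiny_ref()
  mix <- c(canonical = 0.5, fp_variant = 0.2, tp_templated = 0.2,
           nta = 0.1, substitution = 0)
  cfg <- simulation_config(n_cells = 6, reads_per_cell = 2000,
                           isomir_mixture = mix,
                           fp_offsets = c(`-1` = 1),
                           pcr_duplication_mean = 1, umi_length = 0,
                           adapter = "", seed = 67)
  sim <- simulate_cells(ref, cfg)
  ann <- annotate_reads(sim$reads, ref)
  prof <- positional_profile(ann, "all")
  expect_lt(abs(prof[["fp-1"]] - 0.2), 3 * sqrt(0.2 * 0.8 / 2000))
  expect_lt(abs(prof[["fp0"]] - 0.8), 3 * sqrt(0.8 * 0.2 / 2000))
  cp <- colMeans(category_proportions(ann))
  expect_lt(abs(cp[["CANONICAL"]] - 0.5), 3 * sqrt(0.5 * 0.5 / 2000))
  expect_lt(abs(cp[["TP_NONTEMPLATED"]] - 0.1), 3 * sqrt(0.1 * 0.9 / 2000))
})

test_that("Spearman clustering is symmetric with unit diagonal and exact for twins", {
  m <- matrix(c(10L, 20L, 30L,
                10L, 20L, 30L,
                30L, 20L, 10L), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("f1", "f2", "f3")))
  cl <- cell_similarity_clustering(m)
  expect_equal(unname(cl$rho["a", "b"]), 1)
  expect_true(isSymmetric(cl$rho))
  expect_true(all(diag(cl$rho) == 1))
  expect_error(cell_similarity_clustering(m[1, , drop = FALSE]), ">= 2")
  # zero-variance cell gets zero correlations with a warning
  m2 <- rbind(m, d = c(5L, 5L, 5L))
  expect_warning(cl2 <- cell_similarity_clustering(m2), "constant")
  expect_true(all(cl2$rho["d", c("a", "b", "c")] == 0))
})

test_that("cells from two abundance profiles separate on the 2-cut", {
  skip_if_not_installed("mclust")
  ref <- make_reference(10, seed = 71)
  mats <- ref$mature$mature
  half <- split(mats, rep(1:2, length.out = length(mats)))
  ab1 <- stats::setNames(rep(1 / length(half[[1]]), length(half[[1]])), half[[1]])
  ab2 <- stats::setNames(rep(1 / length(half[[2]]), length(half[[2]])), half[[2]])
  sims <- lapply(1:2, function(g) {
    cfg <- simulation_config(n_cells = 6, reads_per_cell = 500,
                             mirna_abundance = if (g == 1) ab1 else ab2,
                             pcr_duplication_mean = 1, umi_length = 0,
                             adapter = "", seed = 73 + g)
    s <- simulate_cells(ref, cfg)
    s$reads$cell <- paste0("g", g, "_", s$reads$cell)
    s
  })
  reads <- rbind(sims[[1]]$reads, sims[[2]]$reads)
  ann <- annotate_reads(reads, ref)
  m <- count_features(ann, "reads", "mirna")
  cl <- cell_similarity_clustering(m)
  cut <- stats::cutree(cl$hclust, k = 2)
  truth <- as.integer(grepl("^g1", rownames(m)))
  expect_equal(mclust::adjustedRandIndex(cut, truth), 1)
})

test_that("dedup shift report is zero for identical inputs and signed under bias", {
  cp <- matrix(c(0.4, 0.6), 1, 2, dimnames = list("c1", c("CANONICAL",
                                                          "TP_TEMPLATED")))
  rep0 <- dedup_shift_report(cp, cp)
  expect_true(all(rep0$delta == 0))
  expect_error(dedup_shift_report(cp, matrix(0, 1, 2,
    dimnames = list("zz", colnames(cp)))), "differ")

  # PCR bias toward canonical molecules: dedup lowers the canonical share
  ref <- tiny_ref()
  cfg <- simulation_config(n_cells = 4, reads_per_cell = 800,
                           pcr_duplication_mean = 4, pcr_canonical_bias = 3,
                           umi_length = 10, unique_umis = TRUE,
                           adapter = "", seed = 79)
  sim <- simulate_cells(ref, cfg)
  pr <- process_reads(sim$reads, umi_length = 10)
  ann <- annotate_reads(pr$reads, ref)
  pre <- category_proportions(ann)
  post <- category_proportions(dedup_umis(ann))
  shift <- dedup_shift_report(pre, post)
  expect_lt(shift$summary[["CANONICAL"]], 0)
  expect_true(all(shift$delta >= -1 & shift$delta <= 1))
})
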
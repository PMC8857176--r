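test_that("target aggregation applies the >= 2-source rule with minimum rank", {
  tt <- data.frame(
    mirna = c("m1", "m1", "m1", "m1"),
    gene = c("g1", "g2", "g2", "g3"),
    source = c("diana", "diana", "targetscan", "miranda"),
    rank = c(3L, 5L, 17L, 1L), stringsAsFactors = FALSE)
  agg <- aggregate_targets(tt)
  expect_identical(agg$gene, "g2")         # g1, g3: single source
  expect_identical(agg$score, 5)           # minimum across sources
  expect_identical(agg$n_sources, 2L)
  expect_warning(empty <- aggregate_targets(tt[0, ]), "empty")
  expect_identical(nrow(empty), 0L)

  set.seed(5)
  big <- data.frame(
    mirna = sample(paste0("m", 1:3), 300, TRUE),
    gene = sample(paste0("g", 1:40), 300, TRUE),
    source = sample(c("a", "b", "c", "d"), 300, TRUE),
    stringsAsFactors = FALSE)
  big <- big[!duplicated(big[, c("mirna", "gene", "source")]), ]
  big$rank <- sample.int(100, nrow(big), TRUE)
  agg2 <- aggregate_targets(big)
  # brute-force check
  for (m in unique(big$mirna)) {
    sub <- big[big$mirna == m, ]
    want <- names(which(vapply(split(sub$source, sub$gene),
                               function(s) length(unique(s)),
                               integer(1)) >= 2))
    expect_setequal(agg2$gene[agg2$mirna == m], want)
  }
})

test_that("category expression counts and normalises per cell", {
  rows <- c(lapply(1:6, function(i) ann_row("c1", "mX", id = paste0("x", i))),
            lapply(1:4, function(i) ann_row("c1", "mX", tail = "A",
                                            id = paste0("a", i))),
            lapply(1:10, function(i) ann_row("c1", "mY", id = paste0("y", i))))
  ann <- do.call(make_ann, rows)
  expect_identical(unname(category_expression(ann, "mX", "TOTAL", "raw")), 10)
  expect_identical(unname(category_expression(ann, "mX", "NTA_A", "raw")), 4)
  expect_identical(unname(category_expression(ann, "mX", "NTA_U", "raw")), 0)
  # cpm over the cell's total miRNA-mapped reads (20 here)
  expect_equal(unname(category_expression(ann, "mX", "TOTAL", "cpm_total")),
               10 / 20 * 1e6)
  expect_equal(unname(category_expression(ann, "mX", "NTA_A",
                                          "parent_relative")), 0.4)
  expect_error(category_expression(ann, "nope", "TOTAL"), "unknown")
})

test_that("correlation against genes hits the exact cases", {
  cells <- sprintf("c%d", 1:6)
  vec <- stats::setNames(c(1, 2, 3, 4, 5, 6), cells)
  mrna <- rbind(neg = 7 - vec, const = rep(3, 6),
                noise = c(2, 8, 1, 9, 4, 6))
  colnames(mrna) <- cells
  r <- correlate_expression(vec, mrna, "raw")
  expect_equal(unname(r["neg"]), -1)
  expect_true(is.na(r["const"]))
  expect_error(correlate_expression(vec[1:2], mrna), "shared")
})

test_that("planted negative coupling is recovered through the package path", {
  ref <- tiny_ref()
  cfg <- simulation_config(n_cells = 100, reads_per_cell = 1000,
                           pcr_duplication_mean = 1, umi_length = 0,
                           adapter = "", seed = 83)
  sim <- simulate_cells(ref, cfg)
  ann <- annotate_reads(sim$reads, ref)
  m <- names(sort(table(sim$truth$mature), decreasing = TRUE))[1]
  mr <- simulate_mrna_coupled(sim$truth, n_genes = 400,
                              n_targets_per_mirna = 50, effect_r = -0.5,
                              mirnas = m, seed = 89)
  vec <- category_expression(ann, m, "TOTAL", "cpm_total")
  r <- correlate_expression(vec, mr$mrna, "raw")
  expect_gt(mean(r[mr$target_map[[m]]]), -0.65)
  expect_lt(mean(r[mr$target_map[[m]]]), -0.35)
})

test_that("the KS test matches a brute-force ECDF sup-distance", {
  set.seed(11)
  x <- rnorm(40); y <- rnorm(60, 0.4)
  kt <- ks_target_test(x, y)
  expect_equal(kt$ks_statistic, oracle_ks_stat(x, y))
  ident <- ks_target_test(x, x)
  expect_equal(ident$ks_statistic, 0)
  expect_identical(ident$direction, "none")

  shifted <- ks_target_test(rnorm(200, -0.5), rnorm(200))
  expect_lt(shifted$p_value, 0.05)
  expect_identical(shifted$direction, "negative")

  small <- ks_target_test(rnorm(3), rnorm(100))
  expect_false(small$testable)
})

test_that("the full target analysis flags planted miRNAs and spares decoys", {
  ref <- tiny_ref()
  # uniform abundance: no miRNA dominates the per-cell totals, so the
  # decoy's CPM shares stay effectively independent of the planted miRNA
  ab <- stats::setNames(rep(1 / nrow(ref$mature), nrow(ref$mature)),
                        ref$mature$mature)
  cfg <- simulation_config(n_cells = 60, reads_per_cell = 1500,
                           mirna_abundance = ab,
                           pcr_duplication_mean = 1, umi_length = 0,
                           adapter = "", seed = 97)
  sim <- simulate_cells(ref, cfg)
  ann <- annotate_reads(sim$reads, ref)
  top <- names(sort(table(sim$truth$mature), decreasing = TRUE))
  planted <- top[1]; decoy <- top[2]
  mr <- simulate_mrna_coupled(sim$truth, n_genes = 800,
                              n_targets_per_mirna = 100, effect_r = -0.6,
                              mirnas = planted, seed = 101)
  # give the decoy a target list too, but with no planted coupling
  decoy_rows <- data.frame(mirna = decoy,
                           gene = rep(sample(setdiff(rownames(mr$mrna),
                                                     mr$target_map[[planted]]),
                                             100), each = 2),
                           source = rep(c("diana", "miranda"), 100),
                           rank = 1L, stringsAsFactors = FALSE)
  targets <- rbind(mr$targets, decoy_rows)
  res <- run_target_analysis(ann, mr$mrna, targets, top_k = 2,
                             min_noncanonical_share = 0)$results
  tot <- res[res$category == "TOTAL", ]
  expect_identical(tot$direction[tot$mirna == planted], "negative")
  expect_lt(tot$p_value[tot$mirna == planted], 0.05)
  expect_identical(tot$direction[tot$mirna == decoy], "none")
  # targets/non-targets partition the gene universe
  expect_identical(tot$n_target[tot$mirna == planted] +
                     tot$n_nontarget[tot$mirna == planted],
                   nrow(mr$mrna))
  # alpha = 1 assigns a direction to every testable category
  res1 <- run_target_analysis(ann, mr$mrna, targets, top_k = 2,
                              min_noncanonical_share = 0, alpha = 1)$results
  expect_true(all(res1$direction[res1$testable] != "none"))
})

test_that("ECDF tables are valid distribution samples", {
  ref <- tiny_ref()
  cfg <- simulation_config(n_cells = 30, reads_per_cell = 800,
                           pcr_duplication_mean = 1, umi_length = 0,
                           adapter = "", seed = 103)
  sim <- simulate_cells(ref, cfg)
  ann <- annotate_reads(sim$reads, ref)
  m <- names(sort(table(sim$truth$mature), decreasing = TRUE))[1]
  mr <- simulate_mrna_coupled(sim$truth, n_genes = 300,
                              n_targets_per_mirna = 40, effect_r = -0.5,
                              mirnas = m, seed = 107)
  out <- run_target_analysis(ann, mr$mrna, mr$targets, top_k = 1,
                             min_noncanonical_share = 0)
  ec <- out$ecdf
  expect_true(all(ec$r >= -1 & ec$r <= 1))
  for (cat in unique(ec$category)) {
    sub <- ec[ec$category == cat, ]
    F <- stats::ecdf(sub$r[sub$set == "target"])
    expect_equal(F(max(sub$r)), 1)   # reaches 1, non-decreasing by construction
  }
})
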
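KS_CATEGORIES <- c("TOTAL", "CANONICAL", "FP_VARIANT", "TP_TEMPLATED",
                   "NTA_A", "NTA_U", "SUBSTITUTION")

#' Aggregate predicted targets across prediction sources
#'
#' Keeps, per miRNA, the genes predicted by at least `min_sources` distinct
#' algorithms; each retained gene's aggregate score is its minimum
#' (strongest) rank across sources, reported for ordering but not used as a
#' cutoff.
#'
#' @param targets data.frame with columns mirna, gene, source, rank
#'   ((mirna, gene, source) unique; ranks positive).
#' @param min_sources minimum number of distinct predicting sources
#'   (default 2).
#' @return data.frame (mirna, gene, n_sources, score), sorted by miRNA then
#'   score.
#' @export
aggregate_targets <- function(targets, min_sources = 2L) {
  if (nrow(targets) == 0L) {
    warnf("empty target table")
    return(data.frame(mirna = character(0), gene = character(0),
                      n_sources = integer(0), score = integer(0)))
  }
  stopifnot(all(targets$rank > 0))
  key <- paste(targets$mirna, targets$gene, sep = "\r")
  nsrc <- tapply(targets$source, key, function(s) length(unique(s)))
  score <- tapply(targets$rank, key, min)
  keep <- names(nsrc)[nsrc >= min_sources]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(mirna = vapply(parts, `[`, character(1), 1L),
                    gene = vapply(parts, `[`, character(1), 2L),
                    n_sources = as.integer(nsrc[keep]),
                    score = as.numeric(score[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$mirna, out$score, out$gene), , drop = FALSE]
}

#' Per-cell expression of one miRNA's isomiR category
#'
#' Counts, per cell, the miRNA's reads belonging to the requested category
#' (TOTAL = all reads of the miRNA; NTA_A / NTA_U use the at-least-one
#' non-templated A / U rule) and normalises: `"cpm_total"` divides by the
#' cell's total miRNA-mapped reads (x 1e6), `"parent_relative"` divides by
#' the cell's reads of the same miRNA, `"raw"` leaves counts.
#'
#' @param ann annotation data.frame (cells already filtered).
#' @param mirna mature miRNA name.
#' @param category one of TOTAL, CANONICAL, FP_VARIANT, TP_TEMPLATED,
#'   NTA_A, NTA_U, SUBSTITUTION.
#' @param normalization `"cpm_total"`, `"parent_relative"` or `"raw"`.
#' @param cells optional cell universe (cells with no reads get 0).
#' @return Named numeric vector over cells.
#' @export
category_expression <- function(ann, mirna, category = "TOTAL",
                                normalization = c("cpm_total",
                                                  "parent_relative", "raw"),
                                cells = NULL) {
  normalization <- match.arg(normalization)
  category <- match.arg(category, KS_CATEGORIES)
  if (!mirna %in% ann$mature) stopf("unknown miRNA: %s", mirna)
  if (is.null(cells)) cells <- sort(unique(ann$cell_id))
  f <- factor(ann$cell_id, levels = cells)
  total_mirna_reads <- as.numeric(table(f))
  mine <- ann$mature == mirna
  in_cat <- switch(category,
    TOTAL = mine,
    NTA_A = mine & grepl("A", ann$nta_tail, fixed = TRUE),
    NTA_U = mine & grepl("T", ann$nta_tail, fixed = TRUE),
    mine & category_flags(ann)[, category])
  cnt <- as.numeric(table(f[in_cat]))
  parent <- as.numeric(table(f[mine]))
  denom <- switch(normalization,
                  cpm_total = total_mirna_reads / 1e6,
                  parent_relative = parent,
                  raw = rep(1, length(cells)))
  out <- ifelse(denom > 0, cnt / denom, 0)
  stats::setNames(out, cells)
}

#' Pearson correlation of a per-cell vector against every gene
#'
#' Correlates the category-expression vector with each gene of the mRNA
#' matrix over the shared cells. mRNA values are normalised per cell to
#' counts-per-million and log1p-transformed by default; `"raw"` skips both.
#' Zero-variance genes (or a zero-variance category vector) yield NA and
#' are excluded from downstream ECDFs.
#'
#' @param category_vec named per-cell numeric vector.
#' @param mrna genes x cells numeric matrix.
#' @param normalization `"log1p_cpm"` or `"raw"`.
#' @return Named numeric vector: Pearson r per gene (NA = undefined).
#' @export
correlate_expression <- function(category_vec, mrna,
                                 normalization = c("log1p_cpm", "raw")) {
  normalization <- match.arg(normalization)
  shared <- intersect(names(category_vec), colnames(mrna))
  if (length(shared) < 3L)
    stopf("need >= 3 shared cells, got %d", length(shared))
  x <- category_vec[shared]
  m <- mrna[, shared, drop = FALSE]
  if (normalization == "log1p_cpm") {
    cs <- colSums(m)
    cs[cs == 0] <- 1
    m <- log1p(sweep(m, 2, cs, "/") * 1e6)
  }
  r <- suppressWarnings(stats::cor(x, t(m))[1, ])
  stats::setNames(r, rownames(mrna))
}

#' Two-sample KS test of target vs non-target correlation distributions
#'
#' Two-sided two-sample Kolmogorov-Smirnov test on the Pearson-correlation
#' vectors of predicted targets and non-targets. When p < alpha a direction
#' is assigned by the median difference: `negative` if the target
#' correlations' median is below the non-targets' (the repression
#' signature), else `positive`; otherwise `none`. Vectors shorter than 5
#' are flagged untestable.
#'
#' @param target_r,nontarget_r numeric vectors of per-gene Pearson r (NAs
#'   dropped).
#' @param alpha significance level (default 0.05).
#' @return list: n_target, n_nontarget, ks_statistic, p_value, direction,
#'   testable.
#' @export
ks_target_test <- function(target_r, nontarget_r, alpha = 0.05) {
  target_r <- target_r[!is.na(target_r)]
  nontarget_r <- nontarget_r[!is.na(nontarget_r)]
  if (length(target_r) < 5L || length(nontarget_r) < 5L) {
    return(list(n_target = length(target_r), n_nontarget = length(nontarget_r),
                ks_statistic = NA_real_, p_value = NA_real_,
                direction = "none", testable = FALSE))
  }
  kt <- suppressWarnings(stats::ks.test(target_r, nontarget_r,
                                        alternative = "two.sided"))
  direction <- "none"
  if (kt$p.value < alpha) {
    direction <- if (stats::median(target_r) < stats::median(nontarget_r))
      "negative" else "positive"
  }
  list(n_target = length(target_r), n_nontarget = length(nontarget_r),
       ks_statistic = unname(kt$statistic), p_value = kt$p.value,
       direction = direction, testable = TRUE)
}

#' Full target-correlation analysis for the top expressed miRNAs
#'
#' Selects the `top_k` most highly expressed miRNAs whose non-canonical
#' read share is at least `min_noncanonical_share`; for each, correlates
#' the TOTAL and per-category expression vectors with every gene and runs
#' the target vs non-target KS test. Non-targets are all genes of the
#' matrix not in the miRNA's aggregated (>= `min_sources`-algorithm)
#' target set. Categories with fewer than `min_category_reads` reads over
#' all cells are skipped as untestable.
#'
#' @param ann annotation data.frame (cells already filtered).
#' @param mrna genes x cells matrix.
#' @param targets target table (mirna, gene, source, rank).
#' @param top_k number of miRNAs to analyse (default 6).
#' @param min_noncanonical_share exclusion floor on the non-canonical read
#'   share (default 0.10).
#' @param min_category_reads minimum total reads for a category to be
#'   tested (default 10).
#' @param alpha KS significance level.
#' @param normalization passed to [category_expression()].
#' @param mrna_normalization passed to [correlate_expression()].
#' @param min_sources passed to [aggregate_targets()].
#' @return list with `results` (data.frame: mirna, category,
#'   category_read_share, n_target, n_nontarget, ks_statistic, p_value,
#'   p_bh, direction, testable) and `ecdf` (long data.frame: mirna,
#'   category, set, r) for plotting.
#' @export
run_target_analysis <- function(ann, mrna, targets, top_k = 6L,
                                min_noncanonical_share = 0.10,
                                min_category_reads = 10L,
                                alpha = 0.05,
                                normalization = "cpm_total",
                                mrna_normalization = "log1p_cpm",
                                min_sources = 2L) {
  cells <- sort(intersect(unique(ann$cell_id), colnames(mrna)))
  ann <- ann[ann$cell_id %in% cells, , drop = FALSE]
  agg <- aggregate_targets(targets, min_sources)
  expr <- sort(table(ann$mature), decreasing = TRUE)
  flags <- category_flags(ann)
  noncanon_share <- vapply(names(expr), function(m) {
    mine <- ann$mature == m
    sum(!flags[mine, "CANONICAL"]) / sum(mine)
  }, numeric(1))
  chosen <- names(expr)[noncanon_share >= min_noncanonical_share]
  chosen <- utils::head(chosen, top_k)
  if (!length(chosen)) {
    warnf("no miRNA passes the expression/isomiR-share selection")
    return(list(results = data.frame(), ecdf = data.frame()))
  }
  res <- list(); ecdf_rows <- list()
  for (m in chosen) {
    tg <- intersect(agg$gene[agg$mirna == m], rownames(mrna))
    ntg <- setdiff(rownames(mrna), tg)
    mine <- ann$mature == m
    n_mine <- sum(mine)
    for (cat in KS_CATEGORIES) {
      n_cat <- switch(cat,
        TOTAL = n_mine,
        NTA_A = sum(mine & grepl("A", ann$nta_tail, fixed = TRUE)),
        NTA_U = sum(mine & grepl("T", ann$nta_tail, fixed = TRUE)),
        sum(mine & flags[, cat]))
      share <- if (n_mine > 0) n_cat / n_mine else 0
      if (n_cat < min_category_reads) {
        res[[paste(m, cat)]] <- data.frame(
          mirna = m, category = cat, category_read_share = share,
          n_target = 0L, n_nontarget = 0L, ks_statistic = NA_real_,
          p_value = NA_real_, direction = "none", testable = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      vec <- category_expression(ann, m, cat, normalization, cells)
      r <- correlate_expression(vec, mrna, mrna_normalization)
      kt <- ks_target_test(r[tg], r[ntg], alpha)
      res[[paste(m, cat)]] <- data.frame(
        mirna = m, category = cat, category_read_share = share,
        n_target = kt$n_target, n_nontarget = kt$n_nontarget,
        ks_statistic = kt$ks_statistic, p_value = kt$p_value,
        direction = kt$direction, testable = kt$testable,
        stringsAsFactors = FALSE)
      rt <- r[tg]; rn <- r[ntg]
      ecdf_rows[[paste(m, cat)]] <- rbind(
        data.frame(mirna = m, category = cat, set = "target",
                   r = unname(rt[!is.na(rt)]), stringsAsFactors = FALSE),
        data.frame(mirna = m, category = cat, set = "nontarget",
                   r = unname(rn[!is.na(rn)]), stringsAsFactors = FALSE))
    }
  }
  results <- do.call(rbind, c(res, make.row.names = FALSE))
  results$p_bh <- NA_real_
  testable <- results$testable & !is.na(results$p_value)
  results$p_bh[testable] <- stats::p.adjust(results$p_value[testable], "BH")
  list(results = results, ecdf = do.call(rbind, c(ecdf_rows,
                                                  make.row.names = FALSE)))
}
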
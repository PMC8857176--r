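#' Build a cells x features count matrix from annotations
#'
#' Feature identity depends on `level`: `mirna` counts reads per mature
#' miRNA; `isomir` per distinct annotation signature (mature, 5'/3'
#' offsets, tail, substitution); `category` per (mature, category) pair --
#' in category mode one read increments every category it belongs to while
#' the parent miRNA total (the `mirna`-level matrix) is incremented once.
#'
#' @param ann annotation data.frame from [annotate_reads()] (post-dedup
#'   when `mode = "umis"`).
#' @param mode `"reads"` or `"umis"`; recorded as metadata on the matrix.
#' @param level `"mirna"`, `"isomir"` or `"category"`.
#' @return Integer matrix cells x features with `attr(, "mode")`.
#' @export
count_features <- function(ann, mode = c("reads", "umis"),
                           level = c("mirna", "isomir", "category")) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  if (mode == "umis" && any(!nzchar(ann$umi)))
    stopf("umis counting mode requires UMI-bearing annotations")
  cells <- sort(unique(ann$cell_id))
  feat <- switch(level,
    mirna = ann$mature,
    isomir = paste(ann$mature, ann$fp_offset, ann$tp_offset, ann$nta_tail,
                   ifelse(is.na(ann$sub_pos), "",
                          paste0(ann$sub_pos, ann$sub_ref, ">", ann$sub_read)),
                   sep = "|"),
    category = NULL)
  if (level == "category") {
    flags <- category_flags(ann)
    idx <- which(flags, arr.ind = TRUE)
    feat <- paste(ann$mature[idx[, 1]], colnames(flags)[idx[, 2]], sep = "|")
    cell <- ann$cell_id[idx[, 1]]
  } else {
    cell <- ann$cell_id
  }
  tab <- table(factor(cell, levels = cells), feat)
  m <- matrix(as.integer(tab), nrow = length(cells),
              dimnames = list(cells, colnames(tab)))
  attr(m, "mode") <- mode
  m
}

#' Drop cells with too few miRNA-mapped reads
#'
#' Cells whose total count is below `min_mirna_reads` are excluded (the
#' threshold applies to pre-deduplication read totals).
#'
#' @param m cells x features count matrix (reads mode).
#' @param min_mirna_reads minimum total (default 1000; cells with fewer are
#'   dropped, so a cell at exactly the threshold is retained).
#' @return The filtered matrix.
#' @export
filter_cells <- function(m, min_mirna_reads = 1000L) {
  keep <- rowSums(m) >= min_mirna_reads
  if (!any(keep)) warnf("all cells fall below %d miRNA reads", min_mirna_reads)
  out <- m[keep, , drop = FALSE]
  attr(out, "mode") <- attr(m, "mode")
  out
}

#' Read-length distribution of miRNA-mapped reads
#'
#' Proportion of miRNA-mapped reads at each observed length. With
#' `scope = "canonical_only"` the numerator is restricted to CANONICAL
#' reads while the denominator remains all miRNA-mapped reads, so the
#' canonical curve is directly comparable to (and bounded by) the total
#' curve.
#'
#' @param ann annotation data.frame.
#' @param scope `"all"` or `"canonical_only"`.
#' @return Named numeric vector: proportion per read length.
#' @export
length_distribution <- function(ann, scope = c("all", "canonical_only")) {
  scope <- match.arg(scope)
  if (nrow(ann) == 0L) return(stats::setNames(numeric(0), character(0)))
  total <- nrow(ann)
  len <- ann$read_len
  if (scope == "canonical_only")
    len <- len[category_flags(ann)[, "CANONICAL"]]
  tab <- table(len)
  stats::setNames(as.numeric(tab) / total, names(tab))
}

per_cell_profile <- function(ann_rows, flags_rows) {
  n <- nrow(ann_rows)
  fp <- vapply(-3:3, function(k) sum(ann_rows$fp_offset == k) / n, numeric(1))
  tp <- vapply(-3:3, function(k) sum(ann_rows$tp_offset == k) / n, numeric(1))
  names(fp) <- names(tp) <- as.character(-3:3)
  c(stats::setNames(fp, paste0("fp", names(fp))),
    stats::setNames(tp, paste0("tp", names(tp))),
    nta_A = sum(grepl("A", ann_rows$nta_tail, fixed = TRUE)) / n,
    nta_U = sum(grepl("T", ann_rows$nta_tail, fixed = TRUE)) / n)
}

#' Positional profile: 5'/3' offset mass and A/U addition proportions
#'
#' For each cell (optionally within each mature miRNA) the proportion of
#' miRNA-mapped reads starting at each 5' offset in -3..+3, ending at each
#' 3' templated offset in -3..+3, and carrying at least one non-templated
#' A or U. Proportions are computed per cell first and then averaged
#' unweighted across cells (`average = "cells"`); `average = "pooled"`
#' pools reads across cells instead.
#'
#' @param ann annotation data.frame.
#' @param group_by `"all"` (one aggregate profile) or `"mature"` (one
#'   profile per mature miRNA).
#' @param average `"cells"` (cell-averaged, the default) or `"pooled"`.
#' @param min_group_reads for `group_by = "mature"`: a mature must have at
#'   least this many reads summed over the group to be profiled.
#' @return data.frame: one row per group with columns `group`, `n_cells`,
#'   fp-3..fp3, tp-3..tp3, nta_A, nta_U.
#' @export
positional_profile <- function(ann, group_by = c("all", "mature"),
                               average = c("cells", "pooled"),
                               min_group_reads = 50L) {
  group_by <- match.arg(group_by)
  average <- match.arg(average)
  groups <- if (group_by == "all") list(all = seq_len(nrow(ann)))
            else split(seq_len(nrow(ann)), ann$mature)
  out <- list()
  for (g in names(groups)) {
    rows <- groups[[g]]
    if (group_by == "mature" && length(rows) < min_group_reads) next
    if (length(rows) == 0L) { warnf("group %s has no miRNA reads", g); next }
    sub <- ann[rows, , drop = FALSE]
    if (average == "pooled") {
      prof <- per_cell_profile(sub, NULL)
      ncell <- length(unique(sub$cell_id))
    } else {
      by_cell <- split(seq_len(nrow(sub)), sub$cell_id)
      mat <- t(vapply(by_cell,
                      function(i) per_cell_profile(sub[i, , drop = FALSE], NULL),
                      numeric(16)))
      prof <- colMeans(mat)
      ncell <- length(by_cell)
    }
    out[[g]] <- data.frame(group = g, n_cells = ncell, t(prof),
                           check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    warnf("no group had miRNA reads")
    return(data.frame())
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res
}

#' Per-cell isomiR category proportions
#'
#' Fraction of each cell's miRNA-mapped reads whose annotation includes
#' each of the five categories. Because one read may carry several
#' alterations, the five fractions need not sum to 1.
#'
#' @param ann annotation data.frame.
#' @return Numeric matrix cells x 5 categories.
#' @export
category_proportions <- function(ann) {
  flags <- category_flags(ann)
  cells <- sort(unique(ann$cell_id))
  out <- matrix(0, length(cells), ncol(flags),
                dimnames = list(cells, colnames(flags)))
  f <- factor(ann$cell_id, levels = cells)
  tot <- as.integer(table(f))
  for (k in colnames(flags)) {
    out[, k] <- as.integer(rowsum(as.integer(flags[, k]), f)) / tot
  }
  out
}

#' Spearman cell-cell similarity and hierarchical clustering
#'
#' Normalises each cell's miRNA counts to counts-per-million, computes the
#' Spearman correlation between all cell pairs, and clusters cells with
#' average-linkage hierarchical clustering on distance 1 - rho.
#'
#' @param m cells x miRNA count matrix (at least 2 cells).
#' @param normalization `"cpm"` or `"none"` (rank-based Spearman makes the
#'   within-cell scale immaterial; CPM is kept for the exported matrices).
#' @return list with `rho` (cells x cells), `hclust` and `order` (leaf
#'   order).
#' @export
cell_similarity_clustering <- function(m, normalization = c("cpm", "none")) {
  normalization <- match.arg(normalization)
  if (nrow(m) < 2L) stopf("need >= 2 cells to cluster")
  x <- m
  if (normalization == "cpm") x <- m / rowSums(m) * 1e6
  rho <- suppressWarnings(stats::cor(t(x), method = "spearman"))
  if (anyNA(rho)) {
    warnf("constant-expression cell(s); their correlations set to 0")
    rho[is.na(rho)] <- 0
    diag(rho) <- 1
  }
  hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
  list(rho = rho, hclust = hc, order = rownames(m)[hc$order])
}

#' Per-category proportion shift after UMI deduplication
#'
#' @param pre,post cells x categories proportion matrices (same cells) from
#'   [category_proportions()] before and after deduplication.
#' @return list with `delta` (per-cell post - pre) and `summary` (mean
#'   delta per category).
#' @export
dedup_shift_report <- function(pre, post) {
  if (!setequal(rownames(pre), rownames(post)))
    stopf("cell sets differ between pre and post matrices")
  post <- post[rownames(pre), colnames(pre), drop = FALSE]
  delta <- post - pre
  list(delta = delta, summary = colMeans(delta))
}
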
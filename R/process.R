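#' Read one FASTQ file of small-RNA reads
#'
#' @param path FASTQ path (uncompressed or gzipped).
#' @param cell cell id to attach; defaults to the filename without
#'   extension.
#' @return data.frame with columns id, cell, sequence, quality.
#' @export
read_fastq <- function(path, cell = NULL) {
  if (is.null(cell)) cell <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  data.frame(id = sub("\\s.*$", "", names(seqs)),
             cell = cell,
             sequence = as.character(seqs),
             quality = as.character(S4Vectors::mcols(seqs)$qualities),
             stringsAsFactors = FALSE)
}

#' Move a fixed-length 5' UMI prefix off each read
#'
#' The first `umi_length` bases of every read become its `umi` field and are
#' removed from the sequence (done before adapter trimming, matching the
#' processing order for UMI-tagged small-RNA protocols). Reads shorter than
#' the UMI are discarded and counted.
#'
#' @param reads data.frame with columns id, cell, sequence.
#' @param umi_length UMI length (0 = identity, empty `umi`).
#' @return The reads with `umi` populated; dropped-read count in
#'   `attr(, "umi_dropped")` (a per-cell table).
#' @export
extract_umi <- function(reads, umi_length = 8L) {
  stopifnot(umi_length >= 0)
  umi_length <- as.integer(umi_length)
  if (umi_length == 0L) {
    reads$umi <- ""
    attr(reads, "umi_dropped") <- table(character(0))
    return(reads)
  }
  short <- nchar(reads$sequence) <= umi_length
  if (any(short))
    warnf("%d read(s) shorter than the UMI were discarded", sum(short))
  dropped <- table(reads$cell[short])
  reads <- reads[!short, , drop = FALSE]
  reads$umi <- substr(reads$sequence, 1L, umi_length)
  reads$sequence <- substr(reads$sequence, umi_length + 1L,
                           nchar(reads$sequence))
  if ("quality" %in% names(reads))
    reads$quality <- substr(reads$quality, umi_length + 1L,
                            nchar(reads$quality))
  attr(reads, "umi_dropped") <- dropped
  reads
}

# Best 3'-end adapter alignment for a single sequence. Considers every
# start offset: a full internal occurrence or a read-suffix overlap with an
# adapter prefix. Valid if overlap >= min_overlap and mismatches <=
# floor(max_error_rate * overlap). Best = most matching bases, ties by
# longer overlap then leftmost. Returns the 0-based cut position or -1.
adapter_cut_pos <- function(seq, adapter, min_overlap, max_error_rate) {
  sr <- charToRaw(seq); ar <- charToRaw(adapter)
  L <- length(sr); al <- length(ar)
  best <- c(score = -1L, ov = -1L, pos = -1L)
  if (L == 0L) return(-1L)
  for (p in 0:(L - 1L)) {
    ov <- min(al, L - p)
    if (ov < min_overlap) break  # offsets only get shorter from here
    err <- sum(sr[(p + 1L):(p + ov)] != ar[seq_len(ov)])
    if (err > floor(max_error_rate * ov)) next
    score <- ov - err
    if (score > best["score"] ||
        (score == best["score"] && ov > best["ov"])) {
      best <- c(score = score, ov = ov, pos = p)
    }
  }
  as.integer(unname(best["pos"]))
}

#' Trim the 3' adapter off reads
#'
#' Removes the best-scoring adapter occurrence (internal match or 3'-end
#' overlap with an adapter prefix) and everything 3' of it, with a minimum
#' overlap of `min_overlap` nt and at most `floor(max_error_rate * overlap)`
#' mismatches (substitutions only). Reads without a valid occurrence are
#' left unchanged. Ties go to the alignment with most matching bases, then
#' the longest, then the leftmost.
#'
#' @param reads data.frame with a `sequence` column.
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum aligned length (default 1).
#' @param max_error_rate maximum mismatch fraction (default 0.1).
#' @return The reads with trimmed sequences; number trimmed per cell in
#'   `attr(, "adapter_trimmed")`.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 1L,
                         max_error_rate = 0.1) {
  if (!nzchar(adapter)) stopf("adapter must be non-empty")
  useq <- unique(reads$sequence)
  cut <- vapply(useq, adapter_cut_pos, integer(1), adapter = adapter,
                min_overlap = min_overlap, max_error_rate = max_error_rate,
                USE.NAMES = FALSE)
  m <- match(reads$sequence, useq)
  pos <- cut[m]
  trimmed <- pos >= 0
  reads$sequence[trimmed] <- substr(reads$sequence[trimmed], 1L, pos[trimmed])
  if ("quality" %in% names(reads))
    reads$quality[trimmed] <- substr(reads$quality[trimmed], 1L, pos[trimmed])
  attr(reads, "adapter_trimmed") <- table(reads$cell[trimmed])
  reads
}

#' Drop reads below the minimum length
#'
#' @param reads data.frame with a `sequence` column.
#' @param min_len minimum surviving length (default 15 nt; shorter reads
#'   are excluded).
#' @return Surviving reads, order preserved; per-cell drop counts in
#'   `attr(, "length_dropped")`.
#' @export
length_filter <- function(reads, min_len = 15L) {
  stopifnot(min_len >= 1)
  short <- nchar(reads$sequence) < min_len
  out <- reads[!short, , drop = FALSE]
  attr(out, "length_dropped") <- table(reads$cell[short])
  out
}

#' Run the fixed preprocessing pipeline: UMI -> adapter -> length
#'
#' The stage order is fixed (UMI extraction before adapter removal before
#' the length filter) and not configurable, because each stage's contract
#' assumes its predecessors ran.
#'
#' @param reads data.frame with columns id, cell, sequence.
#' @param umi_length 5' UMI length (0 = none).
#' @param adapter 3' adapter ("" = skip trimming).
#' @param min_overlap,max_error_rate adapter-matching tolerances.
#' @param min_len minimum read length after trimming.
#' @return list with `reads` (processed) and `stats` (per-cell data.frame:
#'   input, umi_dropped, adapter_trimmed, length_dropped, survivors).
#' @export
process_reads <- function(reads, umi_length = 0L, adapter = "",
                          min_overlap = 1L, max_error_rate = 0.1,
                          min_len = 15L) {
  cells <- sort(unique(reads$cell))
  input <- table(factor(reads$cell, levels = cells))
  r <- extract_umi(reads, umi_length)
  umi_dropped <- attr(r, "umi_dropped")
  if (nzchar(adapter)) {
    r <- trim_adapter(r, adapter, min_overlap, max_error_rate)
    adapter_trimmed <- attr(r, "adapter_trimmed")
  } else {
    adapter_trimmed <- table(character(0))
  }
  r <- length_filter(r, min_len)
  length_dropped <- attr(r, "length_dropped")
  survivors <- table(factor(r$cell, levels = cells))
  pick <- function(tab) {
    v <- rep(0L, length(cells)); names(v) <- cells
    v[names(tab)[names(tab) %in% cells]] <- as.integer(tab[names(tab) %in% cells])
    v
  }
  stats <- data.frame(cell = cells,
                      input = as.integer(input),
                      umi_dropped = pick(umi_dropped),
                      adapter_trimmed = pick(adapter_trimmed),
                      length_dropped = pick(length_dropped),
                      survivors = as.integer(survivors),
                      row.names = NULL, stringsAsFactors = FALSE)
  list(reads = r, stats = stats)
}

# Cluster the UMIs of one alignment group. counts: named integer vector of
# UMI frequencies. Returns a named integer vector mapping each UMI to a
# cluster index.
cluster_umis <- function(counts, method = c("exact", "directional")) {
  method <- match.arg(method)
  umis <- names(sort(counts, decreasing = TRUE))
  # deterministic order: frequency desc, then lexicographic
  umis <- umis[order(-counts[umis], umis)]
  assign <- stats::setNames(seq_along(umis), umis)
  if (method == "exact" || length(umis) < 2L) return(assign)
  for (i in seq_along(umis)[-1L]) {
    for (j in seq_len(i - 1L)) {
      if (assign[umis[j]] != j) next  # only merge into cluster roots
      if (hamming(umis[i], umis[j]) == 1L &&
          counts[umis[j]] >= 2L * counts[umis[i]] - 1L) {
        assign[umis[i]] <- assign[umis[j]]
        break
      }
    }
  }
  assign
}

#' Deduplicate annotated reads by UMI within precursor-alignment groups
#'
#' Reads are grouped by (cell, precursor, alignment start on the
#' precursor); within each group UMIs are clustered -- exact-match collapse
#' by default, or the "directional" adjacency rule (merge UMIs at Hamming
#' distance 1 when the larger count >= 2 x smaller - 1) -- and one
#' representative read is kept per UMI cluster: the most frequent sequence
#' in the cluster, ties broken by the lexicographically smallest sequence,
#' then smallest read id.
#'
#' @param ann annotation data.frame from [annotate_reads()] whose reads all
#'   carry a non-empty `umi`.
#' @param method `"exact"` or `"directional"`.
#' @return The deduplicated annotation data.frame (one row per molecule).
#' @export
dedup_umis <- function(ann, method = c("exact", "directional")) {
  method <- match.arg(method)
  if (nrow(ann) == 0L) return(ann)
  if (any(!nzchar(ann$umi)))
    stopf("read(s) with empty UMI in UMI mode: %s",
          paste(utils::head(ann$read_id[!nzchar(ann$umi)], 3), collapse = ", "))
  grp <- paste(ann$cell_id, ann$precursor, ann$aln_start, sep = "\r")
  keep <- logical(nrow(ann))
  for (g in split(seq_len(nrow(ann)), grp)) {
    counts <- table(ann$umi[g])
    cl <- cluster_umis(stats::setNames(as.integer(counts), names(counts)),
                       method)
    cl_of_read <- cl[ann$umi[g]]
    for (cid in unique(cl_of_read)) {
      rows <- g[cl_of_read == cid]
      seqs <- ann$sequence[rows]
      tab <- table(seqs)
      best_seq <- names(tab)[order(-as.integer(tab), names(tab))][1L]
      cand <- rows[seqs == best_seq]
      keep[cand[order(ann$read_id[cand])[1L]]] <- TRUE
    }
  }
  out <- ann[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
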
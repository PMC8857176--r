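ISOMIR_CATEGORIES <- c("CANONICAL", "FP_VARIANT", "TP_TEMPLATED",
                       "TP_NONTEMPLATED", "SUBSTITUTION")

#' Alignment tolerance parameters
#'
#' Bounds of the tolerance model: at most `max_sub` internal substitutions,
#' 5'/3' templated offsets within +/- `max_trim` nt, and a non-templated 3'
#' tail of at most `max_add` nt (the `-sub 1 -trim 3 -add 3` regime of
#' small-RNA isomiR aligners).
#'
#' @param max_sub maximum internal substitutions per read.
#' @param max_trim maximum absolute 5' and 3' templated offset.
#' @param max_add maximum non-templated 3' tail length.
#' @return An `AlignmentParams` object.
#' @export
alignment_params <- function(max_sub = 1L, max_trim = 3L, max_add = 3L) {
  stopifnot(max_sub >= 0, max_trim >= 0, max_add >= 0)
  structure(list(max_sub = as.integer(max_sub), max_trim = as.integer(max_trim),
                 max_add = as.integer(max_add)),
            class = "AlignmentParams")
}

#' Assign isomiR categories from an annotation's alterations
#'
#' A read may belong to several categories at once: CANONICAL iff it has no
#' alteration at all; FP_VARIANT iff the 5' offset is non-zero; TP_TEMPLATED
#' iff the 3' templated offset is non-zero; TP_NONTEMPLATED iff a
#' non-templated tail is present; SUBSTITUTION iff an internal substitution
#' is present.
#'
#' @param fp_offset,tp_offset signed templated offsets.
#' @param nta_tail non-templated tail ("" if none).
#' @param n_sub number of internal substitutions.
#' @return Character vector of categories (never empty).
#' @export
classify <- function(fp_offset, tp_offset, nta_tail, n_sub) {
  cats <- character(0)
  if (fp_offset == 0 && tp_offset == 0 && nta_tail == "" && n_sub == 0)
    cats <- "CANONICAL"
  if (fp_offset != 0) cats <- c(cats, "FP_VARIANT")
  if (tp_offset != 0) cats <- c(cats, "TP_TEMPLATED")
  if (nta_tail != "") cats <- c(cats, "TP_NONTEMPLATED")
  if (n_sub > 0) cats <- c(cats, "SUBSTITUTION")
  cats
}

#' A/U composition of a non-templated tail
#'
#' Uses the at-least-one rule: `has_A` iff the tail contains one or more
#' non-templated adenines, `has_U` iff one or more uridines (T in DNA
#' space). Both can be true for mixed tails.
#'
#' @param nta_tail tail string in DNA space ("" = no tail).
#' @return Named logical vector `c(has_A =, has_U =)`.
#' @export
tail_composition <- function(nta_tail) {
  c(has_A = grepl("A", nta_tail, fixed = TRUE),
    has_U = grepl("T", nta_tail, fixed = TRUE))
}

# Precompute per-arm raw byte vectors for fast alignment.
build_arm_index <- function(ref) {
  pre_raw <- lapply(ref$precursors, charToRaw)
  arms <- ref$mature
  ord <- order(arms$precursor, arms$mature)  # lexicographic tie-break order
  arms <- arms[ord, , drop = FALSE]
  list(pre_raw = pre_raw, arms = arms,
       plen = nchar(ref$precursors))
}

# Enumerate all valid decompositions of one read sequence against the arm
# index; returns a data.frame of candidates (possibly empty).
enumerate_candidates <- function(seq_raw, idx, params) {
  L <- length(seq_raw)
  arms <- idx$arms
  out <- vector("list", 32L); nout <- 0L
  for (a in seq_len(nrow(arms))) {
    pre <- idx$pre_raw[[arms$precursor[a]]]
    plen <- length(pre)
    start <- arms$start[a]; end <- arms$end[a]
    for (fp in (-params$max_trim):(params$max_trim)) {
      s <- start - fp
      if (s < 0L) next
      maxcmp <- min(L, plen - s)
      if (maxcmp < 1L) next
      mism <- which(seq_raw[seq_len(maxcmp)] != pre[(s + 1L):(s + maxcmp)]) - 1L
      for (tp in (-params$max_trim):(params$max_trim)) {
        tlen <- end + tp - s           # templated segment length
        if (tlen < 1L || tlen > maxcmp) next
        tail_len <- L - tlen
        if (tail_len < 0L || tail_len > params$max_add) next
        m <- mism[mism < tlen]
        # substitutions may not sit on the read's terminal bases
        if (length(m) > params$max_sub) next
        if (length(m) && (any(m == 0L) || any(m == L - 1L))) next
        if (tail_len > 0L) {
          # maximal templating: first tail base must not match the next
          # precursor base (when one exists)
          if (s + tlen < plen && seq_raw[tlen + 1L] == pre[s + tlen + 1L]) next
        }
        nout <- nout + 1L
        if (nout > length(out)) out <- c(out, vector("list", length(out)))
        out[[nout]] <- list(
          mature = arms$mature[a], precursor = arms$precursor[a],
          fp_offset = fp, tp_offset = tp,
          tail = if (tail_len > 0L) rawToChar(seq_raw[(tlen + 1L):L]) else "",
          n_sub = length(m),
          sub_pos = if (length(m)) m[1L] else NA_integer_,
          sub_ref = if (length(m)) rawToChar(pre[s + m[1L] + 1L]) else NA_character_,
          sub_read = if (length(m)) rawToChar(seq_raw[m[1L] + 1L]) else NA_character_,
          aln_start = s)
      }
    }
  }
  if (nout == 0L) return(NULL)
  cand <- do.call(rbind, lapply(out[seq_len(nout)], as.data.frame,
                                stringsAsFactors = FALSE))
  cand
}

# Order candidates by the declared parsimony scoring:
# fewest substitutions -> shortest tail -> smallest |fp|+|tp| ->
# smallest |fp| -> lexicographically smallest (precursor, mature).
rank_candidates <- function(cand) {
  ord <- order(cand$n_sub, nchar(cand$tail),
               abs(cand$fp_offset) + abs(cand$tp_offset),
               abs(cand$fp_offset), cand$precursor, cand$mature)
  cand[ord, , drop = FALSE]
}

#' Align one read to the reference under the isomiR tolerance model
#'
#' Enumerates, for every mature arm, every decomposition of the read into a
#' templated precursor segment (5'/3' offsets within +/- `max_trim`, at most
#' `max_sub` internal substitutions) plus a non-templated 3' tail of at most
#' `max_add` nt, requiring maximal templating (a 3' base matching the next
#' precursor base is always consumed as templated). Returns the single best
#' candidate under the parsimony scoring order, or NULL if no decomposition
#' exists. Multi-precursor ties at the best score are assigned to the
#' lexicographically first arm and flagged `ambiguous`.
#'
#' @param read DNA sequence (>= 15 nt, alphabet ACGT; any N gives a no-hit).
#' @param ref a `ReferenceSet`.
#' @param params an `AlignmentParams` object.
#' @return One-row data.frame (mature, precursor, fp_offset, tp_offset,
#'   nta_tail, n_sub, sub_pos, sub_ref, sub_read, aln_start, ambiguous,
#'   categories), or NULL for no-hit.
#' @export
align_read <- function(read, ref, params = alignment_params()) {
  if (length(ref$precursors) == 0L) stopf("empty reference")
  if (grepl("[^ACGT]", read)) return(NULL)
  idx <- build_arm_index(ref)
  align_one(charToRaw(read), idx, params)
}

align_one <- function(seq_raw, idx, params) {
  cand <- enumerate_candidates(seq_raw, idx, params)
  if (is.null(cand)) return(NULL)
  cand <- rank_candidates(cand)
  best <- cand[1L, , drop = FALSE]
  key <- c(best$n_sub, nchar(best$tail),
           abs(best$fp_offset) + abs(best$tp_offset), abs(best$fp_offset))
  ties <- cand$n_sub == key[1] & nchar(cand$tail) == key[2] &
    abs(cand$fp_offset) + abs(cand$tp_offset) == key[3] &
    abs(cand$fp_offset) == key[4]
  best$ambiguous <- length(unique(cand$precursor[ties])) > 1L
  best$categories <- paste(classify(best$fp_offset, best$tp_offset, best$tail,
                                    best$n_sub), collapse = ";")
  names(best)[names(best) == "tail"] <- "nta_tail"
  best
}

#' Annotate a set of processed reads against the reference
#'
#' Vectorised driver for [align_read()]: identical sequences are aligned
#' once and the result joined back, so PCR-duplicated libraries annotate in
#' time proportional to the number of distinct sequences.
#'
#' @param reads data.frame with columns `id`, `cell`, `sequence` (and
#'   optionally `umi`).
#' @param ref a `ReferenceSet`.
#' @param params an `AlignmentParams`.
#' @return An annotation data.frame (class `isomir_annotation`): one row per
#'   aligned read with columns read_id, cell_id, mature, precursor,
#'   fp_offset, tp_offset, nta_tail, n_sub, sub_pos, sub_ref, sub_read,
#'   aln_start, ambiguous, categories, read_len, umi. Reads that fail to
#'   align are dropped; per-cell no-hit counts are in `attr(, "nohit")`.
#' @export
annotate_reads <- function(reads, ref, params = alignment_params()) {
  stopifnot(all(c("id", "cell", "sequence") %in% names(reads)))
  if (length(ref$precursors) == 0L) stopf("empty reference")
  idx <- build_arm_index(ref)
  useq <- unique(reads$sequence)
  hits <- vector("list", length(useq))
  ok <- !grepl("[^ACGT]", useq)
  for (i in which(ok)) {
    hits[[i]] <- align_one(charToRaw(useq[i]), idx, params)
  }
  hit_rows <- !vapply(hits, is.null, logical(1))
  lut <- do.call(rbind, hits[hit_rows])
  if (is.null(lut)) {
    ann <- empty_annotation()
    attr(ann, "nohit") <- table(reads$cell)
    return(ann)
  }
  lut$sequence <- useq[hit_rows]
  m <- match(reads$sequence, lut$sequence)
  keep <- !is.na(m)
  ann <- lut[m[keep], , drop = FALSE]
  ann$read_id <- reads$id[keep]
  ann$cell_id <- reads$cell[keep]
  ann$read_len <- nchar(reads$sequence[keep])
  ann$umi <- if ("umi" %in% names(reads)) reads$umi[keep] else ""
  ann$sequence <- reads$sequence[keep]
  rownames(ann) <- NULL
  cols <- c("read_id", "cell_id", "mature", "precursor", "fp_offset",
            "tp_offset", "nta_tail", "n_sub", "sub_pos", "sub_ref",
            "sub_read", "aln_start", "ambiguous", "categories", "read_len",
            "umi", "sequence")
  ann <- ann[, cols]
  class(ann) <- c("isomir_annotation", "data.frame")
  attr(ann, "nohit") <- table(reads$cell[!keep])
  attr(ann, "params") <- params
  ann
}

empty_annotation <- function() {
  ann <- data.frame(read_id = character(0), cell_id = character(0),
                    mature = character(0), precursor = character(0),
                    fp_offset = integer(0), tp_offset = integer(0),
                    nta_tail = character(0), n_sub = integer(0),
                    sub_pos = integer(0), sub_ref = character(0),
                    sub_read = character(0), aln_start = integer(0),
                    ambiguous = logical(0), categories = character(0),
                    read_len = integer(0), umi = character(0),
                    sequence = character(0), stringsAsFactors = FALSE)
  class(ann) <- c("isomir_annotation", "data.frame")
  ann
}

# Logical category membership matrix (reads x 5), from the semicolon field.
category_flags <- function(ann) {
  out <- matrix(FALSE, nrow(ann), length(ISOMIR_CATEGORIES),
                dimnames = list(NULL, ISOMIR_CATEGORIES))
  if (nrow(ann) == 0L) return(out)
  cats <- strsplit(ann$categories, ";", fixed = TRUE)
  for (k in ISOMIR_CATEGORIES) {
    out[, k] <- vapply(cats, function(x) k %in% x, logical(1))
  }
  out
}

#' Write / read an annotation table as TSV
#'
#' The on-disk layout is a miRTop-flavoured flat table: one row per read
#' with offsets, tail, substitution detail and the semicolon-joined
#' category set; it round-trips losslessly through these two functions.
#'
#' @param ann annotation data.frame from [annotate_reads()].
#' @param path TSV path.
#' @return `write_annotation` the path, invisibly; `read_annotation` the
#'   annotation data.frame.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c(nta_tail = "character",
                                          umi = "character"),
                           stringsAsFactors = FALSE)
  ann$nta_tail[is.na(ann$nta_tail)] <- ""
  ann$umi[is.na(ann$umi)] <- ""
  class(ann) <- c("isomir_annotation", "data.frame")
  ann
}
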
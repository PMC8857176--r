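# Independent brute-force oracles used to check the package's optimised
# implementations. These are written string-first (substr / strsplit) and
# enumerate every decomposition exhaustively; they share only the declared
# contracts with the implementation, not its code paths.

# --- annotation oracle -------------------------------------------------------

# Exhaustively enumerate every (arm, fp_offset, tp_offset, tail)
# decomposition of `read` and return the best under the declared parsimony
# order, or NULL. Coordinates 0-based half-open as in the package.
oracle_align <- function(read, ref, max_sub = 1, max_trim = 3, max_add = 3) {
  rc <- strsplit(read, "")[[1]]
  L <- length(rc)
  cands <- list()
  for (a in seq_len(nrow(ref$mature))) {
    arm <- ref$mature[a, ]
    pre <- ref$precursors[[arm$precursor]]
    pc <- strsplit(pre, "")[[1]]
    for (fp in -max_trim:max_trim) {
      for (tp in -max_trim:max_trim) {
        s <- arm$start - fp
        e <- arm$end + tp
        tlen <- e - s
        if (s < 0 || e > length(pc) || tlen < 1) next
        tail_len <- L - tlen
        if (tail_len < 0 || tail_len > max_add) next
        templ <- pc[(s + 1):e]
        mism <- which(rc[1:tlen] != templ)     # 1-based read positions
        if (length(mism) > max_sub) next
        if (length(mism) && (any(mism == 1) || any(mism == L))) next
        tail <- if (tail_len > 0) paste(rc[(tlen + 1):L], collapse = "") else ""
        if (tail_len > 0 && e < length(pc) && rc[tlen + 1] == pc[e + 1]) next
        cands[[length(cands) + 1]] <- data.frame(
          mature = arm$mature, precursor = arm$precursor,
          fp_offset = fp, tp_offset = tp, nta_tail = tail,
          n_sub = length(mism), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cands)) return(NULL)
  cand <- do.call(rbind, cands)
  ord <- order(cand$n_sub, nchar(cand$nta_tail),
               abs(cand$fp_offset) + abs(cand$tp_offset),
               abs(cand$fp_offset), cand$precursor, cand$mature)
  cand[ord[1], , drop = FALSE]
}

# --- adapter-trimming oracle -------------------------------------------------

# Enumerate every alignment offset of the adapter against the read, score by
# matching bases (ties: longer overlap, then leftmost), and return the
# trimmed read.
oracle_trim <- function(seq, adapter, min_overlap = 1, max_error_rate = 0.1) {
  sc <- strsplit(seq, "")[[1]]
  ac <- strsplit(adapter, "")[[1]]
  L <- length(sc)
  best <- NULL
  for (p in 0:(L - 1)) {
    ov <- min(length(ac), L - p)
    if (ov < min_overlap) next
    err <- sum(sc[(p + 1):(p + ov)] != ac[1:ov])
    if (err > floor(max_error_rate * ov)) next
    sc_score <- ov - err
    if (is.null(best) || sc_score > best$score ||
        (sc_score == best$score && ov > best$ov)) {
      best <- list(score = sc_score, ov = ov, pos = p)
    }
  }
  if (is.null(best)) seq else substr(seq, 1, best$pos)
}

# --- two-sample ECDF sup-distance oracle -------------------------------------

oracle_ks_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

# --- shared fixtures ---------------------------------------------------------

# Small fixed reference used across test files.
tiny_ref <- function(seed = 42) make_reference(6, seed = seed)

# A hand-built two-arm reference where every coordinate is known exactly.
handmade_ref <- function() {
  pre <- paste0("ACGTA",                    # 5' flank (positions 0-4)
                "TGAGGTAGTAGGTTGTATAGTT",   # 5p arm  (positions 5-26)
                "CGGGC",                    # loop
                "CTATACAACCTACTACCTCAGG",   # 3p arm  (positions 32-53)
                "TACGT")                    # 3' flank
  reference_set(
    c(`pre-let-7` = pre),
    data.frame(mature = c("let-7-5p", "let-7-3p"),
               precursor = "pre-let-7",
               start = c(5L, 32L), end = c(27L, 54L),
               stringsAsFactors = FALSE))
}

# Minimal annotation row constructor for profile-level unit tests.
ann_row <- function(cell, mature, fp = 0L, tp = 0L, tail = "", n_sub = 0L,
                    read_len = 22L, id = NULL, precursor = "p1",
                    aln_start = 10L, umi = "", sequence = "ACGT") {
  cats <- paste(classify(fp, tp, tail, n_sub), collapse = ";")
  data.frame(read_id = id %||% paste0(cell, "_", sample.int(1e9, 1)),
             cell_id = cell, mature = mature, precursor = precursor,
             fp_offset = fp, tp_offset = tp, nta_tail = tail, n_sub = n_sub,
             sub_pos = NA_integer_, sub_ref = NA_character_,
             sub_read = NA_character_, aln_start = aln_start,
             ambiguous = FALSE, categories = cats, read_len = read_len,
             umi = umi, sequence = sequence, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_ann <- function(...) {
  ann <- do.call(rbind, list(...))
  class(ann) <- c("isomir_annotation", "data.frame")
  ann
}
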
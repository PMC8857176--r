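#' Reference set of precursor miRNAs with mature-arm coordinates
#'
#' A `ReferenceSet` bundles precursor hairpin sequences with the coordinates
#' of their annotated mature arms, mirroring the structure of a miRBase-style
#' precursor/mature annotation. Coordinates are 0-based half-open on the
#' precursor's 5'->3' strand; GFF3 I/O converts to/from 1-based inclusive.
#'
#' @param precursors named character vector of precursor DNA sequences
#'   (alphabet ACGT; U is converted to T at I/O boundaries).
#' @param mature data.frame with columns `mature`, `precursor`, `start`,
#'   `end` (0-based half-open interval on the precursor).
#' @return An object of class `ReferenceSet`.
#' @export
reference_set <- function(precursors, mature) {
  stopifnot(is.character(precursors), !is.null(names(precursors)))
  mature <- as.data.frame(mature, stringsAsFactors = FALSE)
  stopifnot(all(c("mature", "precursor", "start", "end") %in% names(mature)))
  mature$start <- as.integer(mature$start)
  mature$end <- as.integer(mature$end)
  ref <- structure(list(precursors = precursors, mature = mature),
                   class = "ReferenceSet")
  validate_reference(ref)
  ref
}

validate_reference <- function(ref) {
  if (anyDuplicated(names(ref$precursors)))
    stopf("duplicated precursor names")
  if (anyDuplicated(ref$mature$mature))
    stopf("duplicated mature miRNA names")
  bad <- !ref$mature$precursor %in% names(ref$precursors)
  if (any(bad))
    stopf("mature arm(s) reference unknown precursor: %s",
          paste(ref$mature$mature[bad], collapse = ", "))
  plen <- nchar(ref$precursors)[match(ref$mature$precursor, names(ref$precursors))]
  with(ref$mature, {
    if (any(start < 0 | end > plen | start >= end))
      stopf("mature interval outside its precursor")
  })
  mlen <- ref$mature$end - ref$mature$start
  if (any(mlen < 18 | mlen > 26))
    stopf("mature length outside [18, 26]")
  if (any(nchar(ref$precursors) < 50 | nchar(ref$precursors) > 120))
    stopf("precursor length outside [50, 120]")
  if (any(grepl("[^ACGT]", ref$precursors)))
    stopf("precursor sequences must be over {A,C,G,T}")
  invisible(ref)
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat(sprintf("ReferenceSet: %d precursors, %d mature arms\n",
              length(x$precursors), nrow(x$mature)))
  invisible(x)
}

#' Extract the mature (canonical) sequence of each annotated arm
#'
#' @param ref a `ReferenceSet`.
#' @return Named character vector of mature sequences.
#' @export
mature_sequences <- function(ref) {
  pre <- ref$precursors[ref$mature$precursor]
  out <- substr(pre, ref$mature$start + 1L, ref$mature$end)
  names(out) <- ref$mature$mature
  out
}

#' Generate a random miRNA precursor reference with known structure
#'
#' Creates `n_precursors` random hairpin-scale precursor sequences, each with
#' one or two annotated mature arms (5p/3p). The first precursor always
#' carries both arms so that arm-assignment tie-breaking is exercised. Arms
#' are placed with >= 4 nt of flanking precursor sequence on each side so
#' that the full +/-3 nt offset tolerance of the aligner, plus one extra
#' templated base, is always available.
#'
#' @param n_precursors number of precursors (>= 1).
#' @param seed integer seed; output is deterministic given the seed.
#' @return A `ReferenceSet`.
#' @export
make_reference <- function(n_precursors, seed = 1L) {
  if (length(n_precursors) != 1L || !is.finite(n_precursors) || n_precursors < 1)
    stopf("n_precursors must be a positive count")
  n_precursors <- as.integer(n_precursors)
  with_seed(seed, {
    plen <- sample(70:110, n_precursors, replace = TRUE)
    pre <- random_dna(n_precursors, plen)
    names(pre) <- sprintf("pre-mir-%03d", seq_len(n_precursors))
    rows <- vector("list", n_precursors)
    for (i in seq_len(n_precursors)) {
      both <- i == 1L || runif(1) < 0.3
      arms <- if (both) c("5p", "3p") else sample(c("5p", "3p"), 1)
      r <- list()
      for (arm in arms) {
        mlen <- sample(20:24, 1)
        if (arm == "5p") {
          start <- sample(4:8, 1)
        } else {
          start <- plen[i] - 4L - mlen - sample(0:4, 1)
        }
        r[[arm]] <- data.frame(
          mature = sprintf("mir-%03d-%s", i, arm),
          precursor = names(pre)[i],
          start = as.integer(start), end = as.integer(start + mlen),
          stringsAsFactors = FALSE)
      }
      rows[[i]] <- do.call(rbind, r)
    }
    reference_set(pre, do.call(rbind, rows))
  })
}

#' Write a ReferenceSet as FASTA + GFF3
#'
#' The FASTA holds precursor sequences; the GFF3 has one `miRNA` feature per
#' mature arm (seqid = precursor, 1-based inclusive coordinates,
#' `Name=<mature>` attribute).
#'
#' @param ref a `ReferenceSet`.
#' @param fasta,gff3 output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference <- function(ref, fasta, gff3) {
  seqs <- Biostrings::DNAStringSet(ref$precursors)
  Biostrings::writeXStringSet(seqs, fasta)
  gr <- GenomicRanges::GRanges(
    seqnames = ref$mature$precursor,
    ranges = IRanges::IRanges(start = ref$mature$start + 1L, end = ref$mature$end),
    strand = "+")
  S4Vectors::mcols(gr)$source <- "isomirsc"
  S4Vectors::mcols(gr)$type <- "miRNA"
  S4Vectors::mcols(gr)$Name <- ref$mature$mature
  S4Vectors::mcols(gr)$ID <- ref$mature$mature
  rtracklayer::export(gr, gff3, format = "gff3")
  invisible(c(fasta = fasta, gff3 = gff3))
}

#' Read a ReferenceSet from FASTA + GFF3
#'
#' Converts GFF3 1-based inclusive coordinates to the internal 0-based
#' half-open convention and maps U to T.
#'
#' @param fasta path to the precursor FASTA.
#' @param gff3 path to the mature-arm GFF3 (`type = miRNA`, attribute
#'   `Name=<mature>`).
#' @return A `ReferenceSet`.
#' @export
read_reference <- function(fasta, gff3) {
  if (!file.exists(fasta)) stopf("reference FASTA not found: %s", fasta)
  if (!file.exists(gff3)) stopf("mature GFF3 not found: %s", gff3)
  # read as plain strings so RNA-alphabet (U) references are accepted, then
  # map into DNA space
  seqs <- Biostrings::readBStringSet(fasta)
  pre <- chartr("Uu", "Tt", toupper(as.character(seqs)))
  names(pre) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff3, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("miRNA", "mature", "miRNA_primary_transcript") &
             as.character(gr$type) != "miRNA_primary_transcript"]
  nm <- gr$Name %||% gr$ID
  if (is.null(nm)) stopf("GFF3 records lack Name/ID attributes")
  seqid <- as.character(GenomicRanges::seqnames(gr))
  missing <- setdiff(seqid, names(pre))
  if (length(missing))
    stopf("GFF3 seqid(s) absent from FASTA: %s", paste(unique(missing), collapse = ", "))
  mature <- data.frame(
    mature = as.character(nm),
    precursor = seqid,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  plen <- nchar(pre)[match(mature$precursor, names(pre))]
  oob <- mature$start < 0 | mature$end > plen
  if (any(oob))
    stopf("mature interval out of precursor bounds for: %s",
          paste(mature$mature[oob], collapse = ", "))
  reference_set(pre, mature)
}
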
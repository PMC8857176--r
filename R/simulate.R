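ISOMIR_MIXTURE_CLASSES <- c("canonical", "fp_variant", "tp_templated", "nta",
                            "substitution")

#' Configuration for the single-cell small-RNA read simulator
#'
#' All distributional knobs of the generator live here; a fixed `seed`
#' determines every random draw end-to-end, so identical configs give
#' byte-identical FASTQ/TSV output.
#'
#' @param n_cells number of cells.
#' @param reads_per_cell number of cDNA molecules drawn per cell (pre-PCR);
#'   the expected read count per cell is `reads_per_cell *
#'   pcr_duplication_mean`.
#' @param mirna_abundance named probability vector over mature miRNA names
#'   (must sum to 1). See [skewed_abundance()] for a generator emulating the
#'   few-species-dominate shape of real small-RNA libraries.
#' @param isomir_mixture named weight vector over the five molecule classes
#'   `canonical`, `fp_variant`, `tp_templated`, `nta`, `substitution`
#'   (sums to 1). Each molecule is drawn from exactly one class.
#' @param fp_offsets named probability vector over 5' offsets for
#'   `fp_variant` molecules; names in `-3..-1` (negative = 5' shortening,
#'   the dominant mode observed in real cells).
#' @param tp_offsets named probability vector over 3' templated offsets for
#'   `tp_templated` molecules; names in `-3..3` excluding 0.
#' @param nta_tail_lengths named probability vector over tail lengths 1..3
#'   for `nta` molecules.
#' @param nta_a_fraction probability that each non-templated tail base is A
#'   (otherwise U, written T in DNA space).
#' @param pcr_duplication_mean expected PCR copies per molecule (>= 1);
#'   copies are 1 + Poisson(mean - 1).
#' @param pcr_canonical_bias multiplier applied to the Poisson rate of
#'   canonical molecules only; > 1 makes PCR preferentially duplicate
#'   canonical molecules.
#' @param umi_length UMI length in nt (0 = no UMIs). UMIs are emitted as a
#'   5' prefix of the read.
#' @param unique_umis if TRUE, UMIs are drawn without replacement within
#'   each cell (an idealised collision-free tag assignment).
#' @param adapter 3' adapter sequence appended to every read ("" = none).
#' @param seed master seed for all randomness.
#' @return A `SimulationConfig` object.
#' @export
simulation_config <- function(n_cells = 50L,
                              reads_per_cell = 5000L,
                              mirna_abundance = NULL,
                              isomir_mixture = c(canonical = 0.40,
                                                 fp_variant = 0.10,
                                                 tp_templated = 0.30,
                                                 nta = 0.15,
                                                 substitution = 0.05),
                              fp_offsets = c(`-1` = 0.6, `-2` = 0.3, `-3` = 0.1),
                              tp_offsets = c(`-3` = 0.05, `-2` = 0.15, `-1` = 0.30,
                                             `1` = 0.30, `2` = 0.15, `3` = 0.05),
                              nta_tail_lengths = c(`1` = 0.7, `2` = 0.2, `3` = 0.1),
                              nta_a_fraction = 0.6,
                              pcr_duplication_mean = 5,
                              pcr_canonical_bias = 1,
                              umi_length = 8L,
                              unique_umis = FALSE,
                              adapter = "TGGAATTCTCGGGTGCCAAGG",
                              seed = 1L) {
  chk_prob <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-9) stopf("%s must sum to 1", what)
    if (any(p < 0)) stopf("%s must be non-negative", what)
  }
  if (n_cells < 1 || reads_per_cell < 1) stopf("counts must be positive")
  if (pcr_duplication_mean < 1) stopf("pcr_duplication_mean must be >= 1")
  if (umi_length < 0 || umi_length > 13) stopf("umi_length must be in 0..13")
  if (!setequal(names(isomir_mixture), ISOMIR_MIXTURE_CLASSES))
    stopf("isomir_mixture must be named over: %s",
          paste(ISOMIR_MIXTURE_CLASSES, collapse = ", "))
  chk_prob(isomir_mixture, "isomir_mixture")
  chk_prob(fp_offsets, "fp_offsets")
  chk_prob(tp_offsets, "tp_offsets")
  chk_prob(nta_tail_lengths, "nta_tail_lengths")
  fo <- as.integer(names(fp_offsets))
  if (any(is.na(fo)) || any(fo < -3 | fo > 3 | fo == 0))
    stopf("fp_offsets names must be in -3..3, excluding 0")
  to <- as.integer(names(tp_offsets))
  if (any(is.na(to)) || any(to < -3 | to > 3 | to == 0))
    stopf("tp_offsets names must be in -3..3, excluding 0")
  if (!is.null(mirna_abundance)) chk_prob(mirna_abundance, "mirna_abundance")
  if (nchar(adapter) > 0 && grepl("[^ACGT]", adapter))
    stopf("adapter must be over {A,C,G,T}")
  structure(list(
    n_cells = as.integer(n_cells), reads_per_cell = as.integer(reads_per_cell),
    mirna_abundance = mirna_abundance,
    isomir_mixture = isomir_mixture[ISOMIR_MIXTURE_CLASSES],
    fp_offsets = fp_offsets, tp_offsets = tp_offsets,
    nta_tail_lengths = nta_tail_lengths, nta_a_fraction = nta_a_fraction,
    pcr_duplication_mean = pcr_duplication_mean,
    pcr_canonical_bias = pcr_canonical_bias,
    umi_length = as.integer(umi_length), unique_umis = isTRUE(unique_umis),
    adapter = adapter, seed = as.integer(seed)),
    class = "SimulationConfig")
}

#' Skewed miRNA abundance vector
#'
#' Draws a Dirichlet-like probability vector (normalised gamma variates with
#' a small shape) so that a handful of miRNA species dominate the library,
#' as observed in real small-RNA data.
#'
#' @param mature_names mature miRNA names to assign mass to.
#' @param shape gamma shape; smaller = more skew.
#' @param seed integer seed.
#' @return Named probability vector.
#' @export
skewed_abundance <- function(mature_names, shape = 0.3, seed = 1L) {
  with_seed(seed, {
    w <- rgamma(length(mature_names), shape = shape) + 1e-8
    p <- w / sum(w)
    names(p) <- mature_names
    p
  })
}

#' Simulate single-cell small-RNA reads with full ground truth
#'
#' Each molecule is drawn as (miRNA ~ abundance, class ~ mixture, then the
#' class-specific offset/tail/substitution draw); its read is the modified
#' mature sequence plus any non-templated tail, prefixed by the UMI and
#' suffixed by the 3' adapter; PCR emits 1 + Poisson(mean - 1) identical
#' copies. The first base of a non-templated tail is re-drawn whenever it
#' equals the next templated precursor base, so tails are genuinely
#' non-templated. Every draw is recorded in the ground-truth table.
#'
#' @param ref a `ReferenceSet`.
#' @param cfg a `SimulationConfig`. If `cfg$mirna_abundance` is NULL a
#'   skewed abundance over all mature arms of `ref` is drawn from the seed.
#' @return A `SimulatedCells` object: list with `reads` (data.frame: id,
#'   cell, sequence), `truth` (one row per molecule: cell, molecule, mature,
#'   precursor, class, fp_offset, tp_offset, nta_tail, sub_pos (0-based
#'   within read), sub_ref, sub_base, umi, n_copies, insert), and `config`.
#' @export
simulate_cells <- function(ref, cfg) {
  stopifnot(inherits(ref, "ReferenceSet"), inherits(cfg, "SimulationConfig"))
  ab <- cfg$mirna_abundance
  if (is.null(ab))
    ab <- skewed_abundance(ref$mature$mature, seed = derive_seed(cfg$seed, "abundance"))
  unknown <- setdiff(names(ab), ref$mature$mature)
  if (length(unknown))
    stopf("mirna_abundance names unknown in reference: %s",
          paste(unknown, collapse = ", "))
  midx <- match(names(ab), ref$mature$mature)
  truth_all <- vector("list", cfg$n_cells)
  reads_all <- vector("list", cfg$n_cells)
  with_seed(derive_seed(cfg$seed, "simulate_cells"), {
    for (ci in seq_len(cfg$n_cells)) {
      cell <- sprintf("cell%03d", ci)
      n <- cfg$reads_per_cell
      pick <- sample(length(ab), n, replace = TRUE, prob = ab)
      arm <- ref$mature[midx[pick], , drop = FALSE]
      pre <- ref$precursors[arm$precursor]
      cls <- sample(ISOMIR_MIXTURE_CLASSES, n, replace = TRUE,
                    prob = cfg$isomir_mixture)
      fp <- integer(n); tp <- integer(n)
      i_fp <- cls == "fp_variant"
      fp[i_fp] <- as.integer(names(cfg$fp_offsets))[
        sample.int(length(cfg$fp_offsets), sum(i_fp), replace = TRUE,
                   prob = cfg$fp_offsets)]
      i_tp <- cls == "tp_templated"
      tp[i_tp] <- as.integer(names(cfg$tp_offsets))[
        sample.int(length(cfg$tp_offsets), sum(i_tp), replace = TRUE,
                   prob = cfg$tp_offsets)]
      s <- arm$start - fp
      e <- arm$end + tp
      body <- substr(pre, s + 1L, e)

      # planted internal substitutions (positions exclude both terminal bases)
      sub_pos <- rep(NA_integer_, n); sub_ref <- rep(NA_character_, n)
      sub_base <- rep(NA_character_, n)
      i_sub <- which(cls == "substitution")
      if (length(i_sub)) {
        L <- nchar(body[i_sub])
        pos <- 1L + floor(runif(length(i_sub)) * (L - 2L))  # 0-based 1..L-2
        refb <- substr(body[i_sub], pos + 1L, pos + 1L)
        alt <- vapply(refb, function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1), USE.NAMES = FALSE)
        substr(body[i_sub], pos + 1L, pos + 1L) <- alt
        sub_pos[i_sub] <- as.integer(pos); sub_ref[i_sub] <- refb
        sub_base[i_sub] <- alt
      }

      # non-templated A/U tails; first base must differ from next templated base
      tail <- rep("", n)
      i_nta <- which(cls == "nta")
      if (length(i_nta)) {
        tl <- as.integer(names(cfg$nta_tail_lengths))[
          sample.int(length(cfg$nta_tail_lengths), length(i_nta), replace = TRUE,
                     prob = cfg$nta_tail_lengths)]
        tail[i_nta] <- vapply(tl, function(k)
          paste(ifelse(runif(k) < cfg$nta_a_fraction, "A", "T"), collapse = ""),
          character(1))
        nxt <- substr(pre[i_nta], e[i_nta] + 1L, e[i_nta] + 1L)
        clash <- substr(tail[i_nta], 1L, 1L) == nxt & nxt %in% c("A", "T")
        if (any(clash)) {
          flip <- ifelse(nxt[clash] == "A", "T", "A")
          tail[i_nta] <- replace(tail[i_nta], clash,
                                 `substr<-`(tail[i_nta][clash], 1L, 1L, flip))
        }
      }
      insert <- paste0(body, tail)

      lambda <- (cfg$pcr_duplication_mean - 1) *
        ifelse(cls == "canonical", cfg$pcr_canonical_bias, 1)
      k <- 1L + rpois(n, lambda)

      umi <- rep("", n)
      if (cfg$umi_length > 0L) {
        if (cfg$unique_umis) {
          space <- 4^cfg$umi_length
          if (space < n) stopf("UMI space too small for unique UMIs")
          umi <- int_to_dna(sample.int(space, n) - 1, cfg$umi_length)
        } else {
          umi <- random_dna(n, cfg$umi_length)
        }
      }

      truth_all[[ci]] <- data.frame(
        cell = cell, molecule = sprintf("%s_m%05d", cell, seq_len(n)),
        mature = arm$mature, precursor = arm$precursor, class = cls,
        fp_offset = fp, tp_offset = tp, nta_tail = tail,
        sub_pos = sub_pos, sub_ref = sub_ref, sub_base = sub_base,
        umi = umi, n_copies = k, insert = insert, stringsAsFactors = FALSE)

      mol_of_read <- rep.int(seq_len(n), k)
      copy_no <- sequence(k)
      reads_all[[ci]] <- data.frame(
        id = sprintf("%s_m%05d_c%d", cell, mol_of_read, copy_no),
        cell = cell,
        sequence = paste0(umi[mol_of_read], insert[mol_of_read], cfg$adapter),
        stringsAsFactors = FALSE)
    }
  })
  structure(list(reads = do.call(rbind, reads_all),
                 truth = do.call(rbind, truth_all),
                 config = cfg),
            class = "SimulatedCells")
}

#' @export
print.SimulatedCells <- function(x, ...) {
  cat(sprintf("SimulatedCells: %d cells, %d molecules, %d reads\n",
              length(unique(x$truth$cell)), nrow(x$truth), nrow(x$reads)))
  invisible(x)
}

#' Write simulated reads as one FASTQ per cell
#'
#' Phred+33 with constant quality 'I' (Q40); filename = `<cell>.fastq`.
#'
#' @param sim a `SimulatedCells` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_fastq <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cell in unique(sim$reads$cell)) {
    r <- sim$reads[sim$reads$cell == cell, ]
    path <- file.path(dir, paste0(cell, ".fastq"))
    lines <- character(4L * nrow(r))
    lines[seq(1, length(lines), 4)] <- paste0("@", r$id)
    lines[seq(2, length(lines), 4)] <- r$sequence
    lines[seq(3, length(lines), 4)] <- "+"
    lines[seq(4, length(lines), 4)] <- strrep("I", nchar(r$sequence))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' True per-cell category proportions from the ground-truth table
#'
#' Category flags are recomputed from the recorded molecular alterations
#' (not from the sampled class label), so multi-membership semantics match
#' the annotator: CANONICAL iff no alteration, FP_VARIANT iff a 5' offset,
#' TP_TEMPLATED iff a 3' templated offset, TP_NONTEMPLATED iff a tail,
#' SUBSTITUTION iff a planted substitution.
#'
#' @param truth the `truth` data.frame of a `SimulatedCells` object.
#' @param weight `"molecules"` (one per molecule) or `"reads"` (weight by
#'   PCR copy number).
#' @return Matrix cells x 5 categories of proportions.
#' @export
truth_category_proportions <- function(truth, weight = c("molecules", "reads")) {
  weight <- match.arg(weight)
  w <- if (weight == "reads") truth$n_copies else rep(1L, nrow(truth))
  flags <- cbind(
    CANONICAL = truth$fp_offset == 0 & truth$tp_offset == 0 &
      truth$nta_tail == "" & is.na(truth$sub_pos),
    FP_VARIANT = truth$fp_offset != 0,
    TP_TEMPLATED = truth$tp_offset != 0,
    TP_NONTEMPLATED = truth$nta_tail != "",
    SUBSTITUTION = !is.na(truth$sub_pos))
  cells <- sort(unique(truth$cell))
  out <- matrix(0, length(cells), ncol(flags),
                dimnames = list(cells, colnames(flags)))
  tot <- tapply(w, truth$cell, sum)
  for (k in colnames(flags)) {
    s <- tapply(w * flags[, k], truth$cell, sum)
    out[names(s), k] <- s / tot[names(s)]
  }
  out
}

#' Simulate an mRNA expression matrix coupled to simulated miRNA totals
#'
#' For each chosen miRNA, `n_targets_per_mirna` genes are planted whose
#' per-cell expression has population Pearson correlation `effect_r` with
#' the miRNA's per-cell molecule total: target values are
#' `mu + s * (r * z + sqrt(1 - r^2) * eps)` with `z` the standardised miRNA
#' total, `eps ~ N(0,1)`, `mu = 100` and `s = noise_sd`; non-target genes
#' are independent noise on the same scale. Values are floored at zero
#' (rare at the default scale). A target table is emitted naming 2-3
#' pseudo-algorithm sources per planted target (so the >= 2-source filter
#' retains them) plus single-source decoy rows that the filter must drop.
#'
#' @param truth ground-truth table from [simulate_cells()].
#' @param n_genes total genes in the matrix.
#' @param n_targets_per_mirna planted targets per miRNA.
#' @param effect_r planted population Pearson correlation, in (-1, 1).
#' @param noise_sd expression scale of the noise/signal components.
#' @param mirnas mature names to plant targets for (default: all in truth).
#' @param seed integer seed.
#' @return List with `mrna` (genes x cells matrix), `targets` (data.frame
#'   mirna, gene, source, rank) and `target_map` (named list of planted
#'   target genes per miRNA).
#' @export
simulate_mrna_coupled <- function(truth, n_genes, n_targets_per_mirna,
                                  effect_r = -0.5, noise_sd = 20,
                                  mirnas = NULL, seed = 1L) {
  if (abs(effect_r) >= 1) stopf("effect_r must be in (-1, 1)")
  if (noise_sd <= 0) stopf("noise_sd must be positive")
  if (is.null(mirnas)) mirnas <- sort(unique(truth$mature))
  if (n_targets_per_mirna * length(mirnas) >= n_genes)
    stopf("n_targets_per_mirna * n_mirnas must be < n_genes")
  cells <- sort(unique(truth$cell))
  counts <- table(factor(truth$cell, levels = cells),
                  factor(truth$mature, levels = mirnas))
  genes <- sprintf("gene%05d", seq_len(n_genes))
  sources <- c("diana", "miranda", "pictar", "targetscan", "mirdb")
  with_seed(seed, {
    mrna <- matrix(100 + noise_sd * rnorm(n_genes * length(cells)),
                   nrow = n_genes, dimnames = list(genes, cells))
    target_map <- list()
    rows <- list()
    gi <- 1L
    for (m in mirnas) {
      tg <- genes[gi:(gi + n_targets_per_mirna - 1L)]
      gi <- gi + n_targets_per_mirna
      x <- as.numeric(counts[, m])
      z <- if (sd(x) > 0) (x - mean(x)) / sd(x) else {
        warnf("miRNA %s has constant totals; planted correlation degenerate", m)
        rep(0, length(x))
      }
      eps <- matrix(rnorm(length(tg) * length(cells)), nrow = length(tg))
      mrna[tg, ] <- 100 + noise_sd *
        (effect_r * matrix(z, length(tg), length(cells), byrow = TRUE) +
           sqrt(1 - effect_r^2) * eps)
      target_map[[m]] <- tg
      nsrc <- sample(2:3, length(tg), replace = TRUE)
      rows[[m]] <- data.frame(
        mirna = m,
        gene = rep(tg, nsrc),
        source = unlist(lapply(nsrc, function(k) sample(sources, k))),
        rank = sample.int(500, sum(nsrc), replace = TRUE),
        stringsAsFactors = FALSE)
      # single-source decoys drawn from the non-target pool
      decoy <- sample(setdiff(genes, unlist(target_map)), min(5L, n_genes))
      rows[[paste0(m, "_decoy")]] <- data.frame(
        mirna = m, gene = decoy, source = sample(sources, 1L),
        rank = sample.int(500, length(decoy), replace = TRUE),
        stringsAsFactors = FALSE)
    }
    mrna[mrna < 0] <- 0
    list(mrna = mrna, targets = do.call(rbind, c(rows, make.row.names = FALSE)),
         target_map = target_map, effect_r = effect_r)
  })
}
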
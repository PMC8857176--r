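#' Pipeline configuration
#'
#' Collects every stage parameter and input path for [run_pipeline()]. Can
#' be built directly or loaded from YAML with [read_pipeline_config()].
#'
#' @param reads_dir directory of per-cell FASTQ files (filename = cell id).
#' @param reference_fasta,mature_gff3 precursor reference paths.
#' @param targets_tsv,mrna_tsv optional target-table / mRNA-matrix paths
#'   (both required for the target-correlation stage to run).
#' @param output_dir output directory.
#' @param umi_length,adapter,min_overlap,max_error_rate,min_len
#'   preprocessing parameters (see [process_reads()]).
#' @param max_sub,max_trim,max_add alignment tolerances.
#' @param min_cell_reads cell filter threshold (pre-dedup miRNA reads).
#' @param dedup_method `"exact"` or `"directional"` UMI clustering.
#' @param alpha,top_k,min_noncanonical_share target-analysis parameters.
#' @param normalization,mrna_normalization normalisation modes for the
#'   target-analysis stage.
#' @param seed master seed echoed into the manifest.
#' @return A `PipelineConfig` object.
#' @export
pipeline_config <- function(reads_dir, reference_fasta, mature_gff3,
                            output_dir,
                            targets_tsv = NULL, mrna_tsv = NULL,
                            umi_length = 0L, adapter = "",
                            min_overlap = 1L, max_error_rate = 0.1,
                            min_len = 15L,
                            max_sub = 1L, max_trim = 3L, max_add = 3L,
                            min_cell_reads = 1000L,
                            dedup_method = "exact",
                            alpha = 0.05, top_k = 6L,
                            min_noncanonical_share = 0.10,
                            normalization = "cpm_total",
                            mrna_normalization = "log1p_cpm",
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Load / save a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @param cfg a `PipelineConfig`.
#' @return The config / the path.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

#' Run the full isomiR pipeline on a directory of per-cell FASTQ files
#'
#' Stages, in order: read + preprocess every cell's FASTQ (UMI extraction,
#' adapter trimming, length filter), annotate against the precursor
#' reference, count and filter cells, profile (length distribution,
#' positional profile, category proportions), cluster cells, UMI-dedup
#' (when UMIs are present) with a pre/post category-shift report, and --
#' when a target table and mRNA matrix are provided -- the target
#' correlation KS analysis. All tables are written under
#' `cfg$output_dir`, together with the verbatim config and a manifest
#' (parameter echo + md5 of every output), so identical config + seed
#' reruns are byte-identical.
#'
#' @param cfg a `PipelineConfig`.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  for (p in c(cfg$reads_dir, cfg$reference_fasta, cfg$mature_gff3,
              cfg$targets_tsv, cfg$mrna_tsv)) {
    if (!is.null(p) && !file.exists(p)) stopf("input path missing: %s", p)
  }
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_pipeline_config(cfg, file.path(out, "config.yaml"))

  ref <- read_reference(cfg$reference_fasta, cfg$mature_gff3)
  fq <- sort(list.files(cfg$reads_dir, pattern = "\\.(fastq|fq)(\\.gz)?$",
                        full.names = TRUE))
  if (!length(fq)) stopf("no FASTQ files in %s", cfg$reads_dir)
  reads <- do.call(rbind, lapply(fq, read_fastq))

  proc <- process_reads(reads, cfg$umi_length, cfg$adapter, cfg$min_overlap,
                        cfg$max_error_rate, cfg$min_len)
  utils::write.table(proc$stats, file.path(out, "drop_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  params <- alignment_params(cfg$max_sub, cfg$max_trim, cfg$max_add)
  ann <- annotate_reads(proc$reads, ref, params)
  write_annotation(ann, file.path(out, "annotations.tsv"))

  counts <- count_features(ann, "reads", "mirna")
  counts_f <- filter_cells(counts, cfg$min_cell_reads)
  write_count_matrix(counts_f, file.path(out, "counts_mirna.tsv"))
  keep_cells <- rownames(counts_f)
  ann_f <- ann[ann$cell_id %in% keep_cells, , drop = FALSE]

  lens <- data.frame(
    length = as.integer(names(length_distribution(ann_f, "all"))),
    all = as.numeric(length_distribution(ann_f, "all")))
  canon <- length_distribution(ann_f, "canonical_only")
  lens$canonical_only <- as.numeric(canon[match(as.character(lens$length),
                                                names(canon))])
  lens$canonical_only[is.na(lens$canonical_only)] <- 0
  utils::write.table(lens, file.path(out, "length_distribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  prof <- positional_profile(ann_f, "all")
  utils::write.table(prof, file.path(out, "positional_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prof_m <- positional_profile(ann_f, "mature")
  utils::write.table(prof_m, file.path(out, "positional_profile_by_mirna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  catprop <- category_proportions(ann_f)
  write_count_matrix(catprop, file.path(out, "category_proportions.tsv"))

  clust <- NULL
  if (nrow(counts_f) >= 2L) {
    clust <- cell_similarity_clustering(counts_f)
    write_count_matrix(clust$rho, file.path(out, "cell_spearman.tsv"))
    writeLines(clust$order, file.path(out, "cell_order.txt"))
  }

  dedup <- NULL; shift <- NULL
  if (cfg$umi_length > 0L) {
    dedup <- dedup_umis(ann_f, cfg$dedup_method)
    write_annotation(dedup, file.path(out, "annotations_dedup.tsv"))
    counts_d <- count_features(dedup, "umis", "mirna")
    write_count_matrix(counts_d, file.path(out, "counts_mirna_dedup.tsv"))
    shift <- dedup_shift_report(catprop, category_proportions(dedup))
    utils::write.table(
      data.frame(category = names(shift$summary),
                 mean_delta = as.numeric(shift$summary)),
      file.path(out, "dedup_shift.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  ks <- NULL
  if (!is.null(cfg$targets_tsv) && !is.null(cfg$mrna_tsv)) {
    targets <- read_target_table(cfg$targets_tsv)
    mrna <- read_mrna_matrix(cfg$mrna_tsv)
    ks <- run_target_analysis(ann_f, mrna, targets, top_k = cfg$top_k,
                              min_noncanonical_share = cfg$min_noncanonical_share,
                              alpha = cfg$alpha,
                              normalization = cfg$normalization,
                              mrna_normalization = cfg$mrna_normalization)
    utils::write.table(ks$results, file.path(out, "ks_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ks$ecdf, file.path(out, "ecdf_long.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  files <- sort(setdiff(list.files(out), "manifest.json"))
  manifest <- list(
    package = "isomirsc",
    version = as.character(utils::packageVersion("isomirsc")),
    seed = cfg$seed,
    parameters = unclass(cfg)[!vapply(cfg, is.null, logical(1))],
    outputs = as.list(tools::md5sum(file.path(out, files))))
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(reads = proc$reads, stats = proc$stats, annotations = ann,
                 counts = counts_f, category_proportions = catprop,
                 clustering = clust, dedup = dedup, dedup_shift = shift,
                 ks = ks, manifest = manifest))
}

#' Simulate a dataset and run the full pipeline on it (demo mode)
#'
#' Generates a reference, reads and a coupled mRNA matrix under `dir`,
#' writes them in their interchange formats, then runs [run_pipeline()] on
#' the files. One command exercises every stage end-to-end.
#'
#' @param dir working directory for inputs and outputs.
#' @param n_precursors,n_cells,reads_per_cell simulation scale.
#' @param seed master seed.
#' @return The [run_pipeline()] result, invisibly.
#' @export
run_demo <- function(dir = tempfile("isomirsc_demo"), n_precursors = 15L,
                     n_cells = 12L, reads_per_cell = 2000L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(n_precursors, seed = derive_seed(seed, "reference"))
  write_reference(ref, file.path(dir, "precursors.fa"),
                  file.path(dir, "mature.gff3"))
  cfg <- simulation_config(n_cells = n_cells, reads_per_cell = reads_per_cell,
                           pcr_duplication_mean = 2,
                           seed = derive_seed(seed, "reads"))
  sim <- simulate_cells(ref, cfg)
  write_fastq(sim, file.path(dir, "fastq"))
  mr <- simulate_mrna_coupled(sim$truth, n_genes = 400,
                              n_targets_per_mirna = 8, effect_r = -0.5,
                              mirnas = utils::head(names(sort(table(sim$truth$mature),
                                                              decreasing = TRUE)), 6),
                              seed = derive_seed(seed, "mrna"))
  write_mrna_matrix(mr$mrna, file.path(dir, "mrna.tsv"))
  write_target_table(mr$targets, file.path(dir, "targets.tsv"))
  pcfg <- pipeline_config(
    reads_dir = file.path(dir, "fastq"),
    reference_fasta = file.path(dir, "precursors.fa"),
    mature_gff3 = file.path(dir, "mature.gff3"),
    output_dir = file.path(dir, "out"),
    targets_tsv = file.path(dir, "targets.tsv"),
    mrna_tsv = file.path(dir, "mrna.tsv"),
    umi_length = cfg$umi_length, adapter = cfg$adapter,
    min_cell_reads = 1000L, seed = seed)
  run_pipeline(pcfg)
}
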
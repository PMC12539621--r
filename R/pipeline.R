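## End-to-end orchestration: simulate -> extract -> map -> analyze,
## with TSV/JSON reports and mutually consistent counters.

#' Build and validate a pipeline configuration
#'
#' Unknown keys are rejected. Either enable the simulate stage (which
#' writes references and reads into `out_dir`) or provide
#' `chromosome_fasta`/`plasmid_fasta`/`reads_fastq` paths.
#'
#' @param out_dir output directory.
#' @param simulate logical: run the simulator first?
#' @param sim a [sim_config()] (used when `simulate = TRUE`).
#' @param model a [crispr_array_model()].
#' @param chromosome_fasta,plasmid_fasta,reads_fastq input paths (used
#'   when `simulate = FALSE`).
#' @param max_edit_fraction repeat/anchor matching tolerance.
#' @param max_edits mapping edit-distance cap.
#' @param pam_offset,pam_width PAM window definition.
#' @param bin_width_chromosome,bin_width_plasmid hotspot bin widths (bp).
#' @param n_perm permutations for the duplication trend test.
#' @param plasmid_copy_number copy number used for molar-excess
#'   normalisation.
#' @param seed seed for the analysis-stage RNG (permutation test).
#' @return object of class `PipelineConfig`.
#' @export
pipeline_config <- function(out_dir,
                            simulate = TRUE,
                            sim = sim_config(),
                            model = crispr_array_model(),
                            chromosome_fasta = NULL,
                            plasmid_fasta = NULL,
                            reads_fastq = NULL,
                            max_edit_fraction = 0.2,
                            max_edits = 2L,
                            pam_offset = -2L,
                            pam_width = 3L,
                            bin_width_chromosome = 10000L,
                            bin_width_plasmid = 50L,
                            n_perm = 10000L,
                            plasmid_copy_number = 40,
                            seed = 1L) {
  if (missing(out_dir) || !is.character(out_dir)) {
    stop("pipeline_config(): out_dir is required")
  }
  if (!simulate &&
      (is.null(chromosome_fasta) || is.null(plasmid_fasta) ||
       is.null(reads_fastq))) {
    stop("pipeline_config(): chromosome_fasta, plasmid_fasta and ",
         "reads_fastq are required when simulate = FALSE")
  }
  stopifnot(inherits(sim, "SimulationConfig"),
            inherits(model, "CrisprArrayModel"),
            max_edit_fraction > 0, max_edit_fraction < 1,
            max_edits >= 0, bin_width_chromosome > 0, bin_width_plasmid > 0,
            n_perm >= 0, plasmid_copy_number > 0)
  structure(list(out_dir = out_dir, simulate = simulate, sim = sim,
                 model = model,
                 chromosome_fasta = chromosome_fasta,
                 plasmid_fasta = plasmid_fasta,
                 reads_fastq = reads_fastq,
                 max_edit_fraction = max_edit_fraction,
                 max_edits = as.integer(max_edits),
                 pam_offset = as.integer(pam_offset),
                 pam_width = as.integer(pam_width),
                 bin_width_chromosome = as.integer(bin_width_chromosome),
                 bin_width_plasmid = as.integer(bin_width_plasmid),
                 n_perm = as.integer(n_perm),
                 plasmid_copy_number = plasmid_copy_number,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages: (optional) simulate, extract (repeat-anchored spacer parsing
#' and exact-duplicate collapse), map (protospacer assignment + PAM),
#' analyze (bin maps, bias summary, PAM matrix, frame annotation and the
#' duplication trend). All outputs land in `config$out_dir`:
#' spacers.tsv, tally.tsv, hits.tsv, bins_chromosome.tsv,
#' bins_plasmid.tsv, pam_matrix.tsv, bias_summary.json,
#' frame_annotations.tsv, duplication_bins.tsv, run_summary.json (plus the
#' simulator outputs when simulating). Deterministic given config + seed.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages (default TRUE).
#' @return `RunSummary` list, invisibly.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()

  ## ---- stage: input ----
  if (config$simulate) {
    say("stage simulate: seed ", config$sim$seed)
    sim <- simulate_run(config$sim, config$model, out_dir = config$out_dir)
    refs <- sim$refgen$refs
    model <- sim$refgen$model
    reads <- sim$reads
  } else {
    refs <- load_references(config$chromosome_fasta, config$plasmid_fasta,
                            plasmid_copy_number = config$plasmid_copy_number)
    model <- config$model
    reads <- read_fastq(config$reads_fastq)
  }
  refs$plasmid_copy_number <- config$plasmid_copy_number
  timings$input <- proc.time()[["elapsed"]] - t0

  if (nrow(reads) == 0) {
    stop(structure(class = c("spacertrace_no_reads", "error", "condition"),
                   list(message = "no reads in input", call = NULL)))
  }

  ## ---- stage: extract ----
  t1 <- proc.time()[["elapsed"]]
  say("stage extract: ", nrow(reads), " reads")
  parsed <- parse_reads(reads, model, config$max_edit_fraction)
  tal <- collapse_duplicates(parsed$spacers$spacer)
  write_tsv(parsed$spacers, file.path(config$out_dir, "spacers.tsv"))
  write_tsv(tal$tally, file.path(config$out_dir, "tally.tsv"))
  timings$extract <- proc.time()[["elapsed"]] - t1
  if (nrow(tal$tally) == 0) {
    stop(structure(class = c("spacertrace_no_spacers", "error", "condition"),
                   list(message = "no spacers extracted", call = NULL)))
  }

  ## ---- stage: map (unique spacers once; all-spacer stats by weights) ----
  t2 <- proc.time()[["elapsed"]]
  say("stage map: ", nrow(tal$tally), " unique spacers")
  hits <- map_spacers(tal$tally$spacer, refs, config$max_edits,
                      config$pam_offset, config$pam_width)
  hits$duplication_count <- tal$tally$duplication_count
  mapped <- hits$source %in% c("chromosome", "plasmid")
  bed <- data.frame(source_name = hits$source,
                    start = hits$start,
                    end = ifelse(mapped, hits$start + nchar(hits$spacer),
                                 NA_integer_),
                    spacer = hits$spacer,
                    edit_distance = hits$edit_distance,
                    strand = hits$strand,
                    pam = hits$pam,
                    category = hits$source,
                    stringsAsFactors = FALSE)
  write_tsv(bed, file.path(config$out_dir, "hits.tsv"))
  timings$map <- proc.time()[["elapsed"]] - t2

  ## ---- stage: analyze ----
  t3 <- proc.time()[["elapsed"]]
  counts_unique <- classify_sources(hits)
  counts_all <- classify_sources(hits, weights = hits$duplication_count)
  bias <- if (counts_all[["chromosome"]] + counts_all[["plasmid"]] > 0) {
    bias_summary(counts_all[["chromosome"]], counts_all[["plasmid"]], refs)
  } else NULL

  chrom_hits <- hits[hits$source == "chromosome", ]
  plas_hits <- hits[hits$source == "plasmid", ]
  bins_chrom <- bin_hits(chrom_hits$start, config$bin_width_chromosome,
                         nchar(refs$chromosome))
  bins_plas <- bin_hits(plas_hits$start, config$bin_width_plasmid,
                        nchar(refs$plasmid))
  write_tsv(bins_chrom, file.path(config$out_dir, "bins_chromosome.tsv"))
  write_tsv(bins_plas, file.path(config$out_dir, "bins_plasmid.tsv"))

  pams <- hits$pam[mapped & nchar(hits$pam) == config$pam_width]
  pam_mat <- if (length(pams) > 0) build_pam_matrix(pams) else NULL
  if (!is.null(pam_mat)) {
    pm <- as.data.frame(pam_mat$counts)
    names(pm) <- paste0("pos", seq_len(ncol(pm)) + config$pam_offset - 1L)
    pm <- rbind(pm, as.list(round(pam_mat$information, 6)))
    pm <- cbind(row = c(rownames(pam_mat$counts), "information"), pm)
    write_tsv(pm, file.path(config$out_dir, "pam_matrix.tsv"))
  }

  ann <- annotate_frames(tal$tally$spacer, model)
  fa <- merge(tal$tally, ann, by = "spacer", sort = FALSE)
  write_tsv(fa[, c("spacer", "duplication_count", "has_inframe_atg",
                   "has_inframe_stop")],
            file.path(config$out_dir, "frame_annotations.tsv"))
  dupres <- atg_fraction_by_duplication(tal$tally, ann,
                                        n_perm = config$n_perm,
                                        seed = config$seed)
  write_tsv(dupres$bins, file.path(config$out_dir, "duplication_bins.tsv"))

  if (!is.null(bias)) {
    bj <- unclass(bias)
    bj$bias_index <- if (is.infinite(bj$bias_index)) "Inf" else bj$bias_index
    bj$dedup_rule <- "ratios use all spacers; maps and PAM matrices use unique spacers"
    jsonlite::write_json(bj, file.path(config$out_dir, "bias_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  timings$analyze <- proc.time()[["elapsed"]] - t3

  summary <- list(
    schema = "spacertrace/run_summary/v1",
    version = as.character(utils::packageVersion("spacertrace")),
    counters = c(parsed$counters,
                 list(unique_spacers = nrow(tal$tally),
                      mapped_chromosome = as.integer(counts_unique[["chromosome"]]),
                      mapped_plasmid = as.integer(counts_unique[["plasmid"]]),
                      ambiguous = as.integer(counts_unique[["ambiguous"]]),
                      unmapped = as.integer(counts_unique[["unmapped"]]),
                      all_spacer_counts = as.list(counts_all))),
    bias = bias,
    pam_consensus = if (!is.null(pam_mat)) pam_mat$consensus else NULL,
    duplication_trend = list(trend = dupres$trend, p_value = dupres$p_value,
                             n_perm = dupres$n_perm),
    analytic_constants = list(
      k = config$model$atg_window %/% 3L,
      atg_baseline_percent = 100 * p_inframe_atg_no_stop(config$model$atg_window %/% 3L),
      detection_limit_percent = 100 * p_no_inframe_stop(config$model$atg_window %/% 3L)),
    thresholds = list(max_edit_fraction = config$max_edit_fraction,
                      max_edits = config$max_edits,
                      pam_offset = config$pam_offset,
                      pam_width = config$pam_width),
    timings = timings)
  js <- summary
  if (!is.null(js$bias)) {
    js$bias <- unclass(js$bias)
    if (is.infinite(js$bias$bias_index)) js$bias$bias_index <- "Inf"
  }
  jsonlite::write_json(js, file.path(config$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  class(summary) <- "RunSummary"
  invisible(summary)
}
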
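# end-to-end pipeline driver with config, logging and explicit seeds

#' Read and validate a run configuration
#'
#' YAML with per-stage sections; all referenced paths are resolved at
#' validation time and seeds are mandatory for the simulation stage.
#'
#' ```yaml
#' reference: {fasta: ref.fasta, annotations: domains.tsv}
#' workdir: out
#' mutagenesis: {n_alleles: 500, mean_mutations: 1.5, gc_to_at_fraction: 0.9, seed: 11}
#' reads: {n_reads: 50000, read_length: 100, fragment_min: 200, fragment_max: 500,
#'         error_coupling: true, seed: 12}
#' caller: {min_quality: 38, top_n: 100}
#' screen_label: screen_A
#' ```
#'
#' @param path path to the YAML config, or an equivalent named list.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) .config_error("config file not found: %s", path)
    yaml::read_yaml(path)
  }
  if (is.null(cfg$reference$fasta)) .config_error("config lacks reference$fasta")
  if (!file.exists(cfg$reference$fasta)) {
    .config_error("reference FASTA not found: %s", cfg$reference$fasta)
  }
  if (!is.null(cfg$reference$annotations) && !file.exists(cfg$reference$annotations)) {
    .config_error("annotation file not found: %s", cfg$reference$annotations)
  }
  if (is.null(cfg$workdir)) .config_error("config lacks workdir")
  mut <- cfg$mutagenesis %||% list()
  rds <- cfg$reads %||% list()
  if (!is.null(cfg$mutagenesis) || !is.null(cfg$reads)) {
    if (is.null(mut$seed) || is.null(rds$seed)) {
      .config_error("seeds are mandatory for the simulate stage (mutagenesis$seed, reads$seed)")
    }
  }
  cal <- cfg$caller %||% list()
  cfg$mutagenesis_config <- mutagenesis_config(
    mean_mutations = mut$mean_mutations %||% 1.5,
    gc_to_at_fraction = mut$gc_to_at_fraction %||% 0.9,
    seed = mut$seed)
  cfg$n_alleles <- as.integer(mut$n_alleles %||% 500L)
  cfg$abundance_model <- mut$abundance_model %||% "lognormal"
  if (!is.null(cfg$reads)) {
    cfg$read_sim_config <- read_sim_config(
      n_reads = rds$n_reads %||% 50000L,
      read_length = rds$read_length %||% 100L,
      fragment_min = rds$fragment_min %||% 200L,
      fragment_max = rds$fragment_max %||% 500L,
      quality_model = rds$quality_model %||%
        list(type = "discrete", q = c(22, 27, 32, 37, 40),
             p = c(0.03, 0.05, 0.12, 0.20, 0.60)),
      error_coupling = rds$error_coupling %||% TRUE,
      seed = rds$seed)
  }
  cfg$caller_config <- caller_config(
    min_quality = cal$min_quality %||% 38L,
    top_n = cal$top_n %||% 100L,
    include_synonymous = cal$include_synonymous %||% FALSE,
    include_stops = cal$include_stops %||% TRUE)
  cfg$seed_align <- cfg$align$seed %||% NULL
  cfg$screen_label <- cfg$screen_label %||% "screen"
  structure(cfg, class = c("run_config", "list"))
}

.log_stage <- function(workdir, stage, ...) {
  msg <- sprintf("%s\t%s\tpoolscreen %s\t%s",
                 format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                 as.character(packageVersion("poolscreen")),
                 paste(..., collapse = "\t"))
  cat(msg, "\n", sep = "", file = file.path(workdir, "pipeline.log"), append = TRUE)
  message(msg)
}

.file_md5 <- function(path) unname(tools::md5sum(path))

#' Run the pooled-screen pipeline
#'
#' Chains the pipeline stages (`simulate` -> `align` -> `call` ->
#' `landscape`) from one configuration, writing each stage's declared outputs
#' plus a log (`pipeline.log`: timestamp, package version, seeds, input
#' checksums) into the work directory. Every output is reproducible
#' byte-for-byte from config + seeds.
#'
#' @param config path to a YAML run configuration, a named list, or a
#'   `run_config`.
#' @param stages subset of `c("simulate", "align", "call", "landscape")`;
#'   later stages consume the declared outputs of earlier ones, which must
#'   exist in `workdir` if their stage is skipped.
#' @return (invisibly) list with the per-stage result objects and output
#'   paths.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "align", "call", "landscape")) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$workdir, showWarnings = FALSE, recursive = TRUE)
  loaded <- read_reference(cfg$reference$fasta, cfg$reference$annotations)
  ref <- loaded$ref
  ann <- loaded$annotations
  paths <- list(fastq = file.path(cfg$workdir, "reads.fastq"),
                truth = file.path(cfg$workdir, "truth.tsv"),
                mismatches = file.path(cfg$workdir, "mismatches.tsv"),
                sam = file.path(cfg$workdir, "alignments.sam"),
                calls = file.path(cfg$workdir, "calls.tsv"),
                tally = file.path(cfg$workdir, "domain_tally.tsv"),
                report = file.path(cfg$workdir, "landscape_report.txt"))
  out <- list(config = cfg, paths = paths, ref = ref, annotations = ann)

  if ("simulate" %in% stages) {
    if (is.null(cfg$read_sim_config)) .config_error("simulate stage requires a 'reads' config section")
    pool <- mutagenize(ref, cfg$mutagenesis_config, cfg$n_alleles,
                       abundance_model = cfg$abundance_model)
    sim <- simulate_reads(ref, pool, cfg$read_sim_config,
                          fastq_out = paths$fastq, truth_out = paths$truth)
    out$pool <- pool
    out$sim <- sim
    .log_stage(cfg$workdir, "simulate",
               sprintf("seed_mut=%s seed_reads=%s n_alleles=%d n_reads=%d",
                       cfg$mutagenesis_config$seed, cfg$read_sim_config$seed,
                       cfg$n_alleles, cfg$read_sim_config$n_reads),
               sprintf("fastq_md5=%s", .file_md5(paths$fastq)))
  }
  if ("align" %in% stages) {
    if (!file.exists(paths$fastq)) .data_error("align stage input missing: %s", paths$fastq)
    index <- build_index(ref, k = cfg$align$k %||% 31L)
    aln <- align_batch(index, paths$fastq, mismatch_out = paths$mismatches,
                       sam_out = paths$sam)
    out$alignment <- aln
    .log_stage(cfg$workdir, "align",
               sprintf("k=%d fastq_md5=%s", index$k, .file_md5(paths$fastq)),
               sprintf("unique=%d ambiguous=%d unmapped=%d too_many=%d",
                       aln$summary$n_unique, aln$summary$n_ambiguous,
                       aln$summary$n_unmapped, aln$summary$n_too_many_mismatches))
  }
  if ("call" %in% stages) {
    if (!file.exists(paths$mismatches)) .data_error("call stage input missing: %s", paths$mismatches)
    obs <- read_mismatches(paths$mismatches)
    calls <- call_and_rank(ref, obs, cfg$caller_config)
    write_calls(calls, paths$calls)
    out$calls <- calls
    .log_stage(cfg$workdir, "call",
               sprintf("min_quality=%d top_n=%d mismatches_md5=%s",
                       cfg$caller_config$min_quality, cfg$caller_config$top_n,
                       .file_md5(paths$mismatches)),
               sprintf("reported=%d threshold_reads=%s", nrow(calls),
                       as.character(attr(calls, "threshold_reads"))))
  }
  if ("landscape" %in% stages) {
    if (is.null(out$calls)) {
      if (!file.exists(paths$calls)) .data_error("landscape stage input missing: %s", paths$calls)
      out$calls <- read_calls(paths$calls)
    }
    audit <- spectrum_audit(out$calls)
    out$audit <- audit
    rpt <- c(sprintf("screen: %s", cfg$screen_label),
             sprintf("calls reported: %d", nrow(out$calls)),
             sprintf("read cutoff at rank %d: %s",
                     nrow(out$calls), as.character(attr(out$calls, "threshold_reads"))),
             sprintf("GC->AT fraction among calls: %s",
                     if (is.na(audit$fraction_gc_to_at)) "undefined (no calls)"
                     else sprintf("%.3f", audit$fraction_gc_to_at)))
    if (!is.null(ann)) {
      tly <- domain_tally(out$calls, ann)
      tly_roll <- domain_tally(out$calls, ann, rollup = TRUE)
      out$tally <- tly
      write.table(data.frame(domain = names(tly), deepest = as.integer(tly),
                             rollup = as.integer(tly_roll[match(names(tly), names(tly_roll))])),
                  paths$tally, sep = "\t", quote = FALSE, row.names = FALSE)
      rpt <- c(rpt, "", "per-domain counts (deepest containment):",
               sprintf("  %-20s %d", names(tly), as.integer(tly)))
    }
    writeLines(rpt, paths$report)
    .log_stage(cfg$workdir, "landscape",
               sprintf("calls_md5=%s", .file_md5(paths$calls)))
  }
  invisible(out)
}
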
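## Stage orchestration. Every stage reads/writes plain TSV under a single
## output directory, writes atomically (temp file + rename), appends a
## manifest entry with a content hash, and is byte-reproducible given the
## same config and seed.

#' Pipeline configuration
#'
#' @param out_dir directory for all stage outputs.
#' @param sim named list of [simulation_config()] overrides.
#' @param priors named list of [hse_priors()] overrides.
#' @param cores named list: `min_score`, `min_len` for CORE delimitation.
#' @param additivity named list: `min_cpm`, `min_samples`, `alpha_fdr`.
#' @param fates named list: `min_dna`, `min_rna`.
#' @param reads_dir optional directory of per-sample read FASTAs for the
#'   read-level path of the `assign` stage; when absent, `assign` uses the
#'   simulated count-level path.
#' @param seed integer seed used by stochastic stages.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "polyfate_out", sim = list(),
                            priors = list(), cores = list(),
                            additivity = list(), fates = list(),
                            reads_dir = NULL, seed = 42L) {
  for (nm in names(sim))
    if (!nm %in% names(formals(simulation_config)))
      stop_named("unknown sim config key: %s", nm)
  for (nm in names(priors))
    if (!nm %in% names(formals(hse_priors)))
      stop_named("unknown priors config key: %s", nm)
  chk <- function(block, allowed, label)
    for (nm in names(block))
      if (!nm %in% allowed) stop_named("unknown %s config key: %s",
                                       label, nm)
  chk(cores, c("min_score", "min_len"), "cores")
  chk(additivity, c("min_cpm", "min_samples", "alpha_fdr"), "additivity")
  chk(fates, c("min_dna", "min_rna"), "fates")
  structure(list(out_dir = out_dir, sim = sim, priors = priors,
                 cores = cores, additivity = additivity, fates = fates,
                 reads_dir = reads_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys mirror [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_named("reading YAML configs requires the yaml package")
  do.call(pipeline_config, yaml::read_yaml(path))
}

pf_path <- function(config, name) file.path(config$out_dir, name)

## atomic TSV write + manifest entry
stage_write <- function(x, config, name, stage) {
  path <- pf_path(config, name)
  tmp <- tempfile(tmpdir = config$out_dir, fileext = ".tmp")
  write_tsv(x, tmp)
  file.rename(tmp, path)
  manifest <- pf_path(config, "manifest.tsv")
  entry <- data.frame(stage = stage, file = name,
                      md5 = unname(tools::md5sum(path)),
                      n_rows = nrow(x))
  write.table(entry, manifest, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = !file.exists(manifest),
              append = file.exists(manifest))
  path
}

stage_read <- function(config, name, producer) {
  path <- pf_path(config, name)
  if (!file.exists(path))
    stop_named("missing input '%s'; run stage '%s' first", path, producer)
  read_tsv(path)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic transcriptomes, counts and truth),
#' `cores` (RBH orthologs and CORE BED files from the FASTAs), `assign`
#' (per-CORE assignment counts; read-level via [toy_map()] when
#' `reads_dir` is set, count-level pass-through otherwise), `bias`
#' (diploid mapping-bias verdicts), `hse` (per-lineage HSE calls and
#' report), `additivity` (filter, transform, fit, classify), `fates`
#' (DNA/RNA fate calls and table), `converge` (cross-lineage convergence),
#' `report` (percentage tables). Outputs are TSV files under
#' `config$out_dir`; each write is atomic and appends a manifest entry
#' with an md5 content hash.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return invisibly, the paths written.
#' @export
run_stage <- function(stage, config, seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  if (is.null(seed)) seed <- config$seed
  t0 <- proc.time()[["elapsed"]]
  paths <- switch(
    stage,
    simulate = stage_simulate(config, seed),
    cores = stage_cores(config),
    assign = stage_assign(config),
    bias = stage_bias(config),
    hse = stage_hse(config),
    additivity = stage_additivity(config),
    fates = stage_fates(config),
    converge = stage_converge(config),
    report = stage_report(config),
    stop_named("unknown stage '%s'", stage))
  message(sprintf("[%s] done in %.1fs: %s", stage,
                  proc.time()[["elapsed"]] - t0,
                  paste(basename(paths), collapse = ", ")))
  invisible(paths)
}

#' Run a sequence of pipeline stages
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stages, in order.
#' @param seed optional integer seed.
#' @return invisibly, all paths written.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "assign", "bias", "hse",
                                    "additivity", "fates", "converge"),
                         seed = NULL) {
  invisible(unlist(lapply(stages, run_stage, config = config,
                          seed = seed)))
}

stage_simulate <- function(config, seed) {
  cfg <- do.call(simulation_config, config$sim)
  sim <- simulate_counts(cfg, seed = seed)
  tx <- generate_parent_transcriptomes(cfg, seed = seed)
  write_fasta(tx$seqs_A, pf_path(config, "parent_A.fasta"))
  write_fasta(tx$seqs_B, pf_path(config, "parent_B.fasta"))
  resolved <- data.frame(key = names(unlist(cfg)),
                         value = as.character(unlist(cfg)))
  c(stage_write(sim$rna_counts, config, "rna_counts.tsv", "simulate"),
    stage_write(sim$dna_counts, config, "dna_counts.tsv", "simulate"),
    stage_write(sim$samples, config, "samples.tsv", "simulate"),
    stage_write(sim$truth$loci, config, "truth_loci.tsv", "simulate"),
    stage_write(sim$truth$lineage_q, config, "truth_lineage_q.tsv",
                "simulate"),
    stage_write(sim$truth$fates, config, "truth_fates.tsv", "simulate"),
    stage_write(resolved, config, "config_resolved.tsv", "simulate"),
    pf_path(config, "parent_A.fasta"), pf_path(config, "parent_B.fasta"))
}

stage_cores <- function(config) {
  fa <- pf_path(config, "parent_A.fasta")
  fb <- pf_path(config, "parent_B.fasta")
  if (!file.exists(fa) || !file.exists(fb))
    stop_named("missing input '%s'; run stage 'simulate' first (or place parental FASTAs there)", fa)
  args <- modifyList(list(min_score = 80, min_len = 100), config$cores)
  sa <- read_fasta(fa); sb <- read_fasta(fb)
  pairs <- reciprocal_best_hits(sa, sb, min_score = args$min_score,
                                min_len = args$min_len)
  cores <- delimit_cores(pairs, sa, sb, min_score = args$min_score,
                         min_len = args$min_len)
  write_core_bed(cores, pf_path(config, "cores_A.bed"),
                 pf_path(config, "cores_B.bed"))
  c(stage_write(pairs, config, "orthologs.tsv", "cores"),
    stage_write(as.data.frame(cores), config, "cores.tsv", "cores"),
    pf_path(config, "cores_A.bed"), pf_path(config, "cores_B.bed"))
}

stage_assign <- function(config) {
  if (!is.null(config$reads_dir)) {
    cores <- stage_read(config, "cores.tsv", "cores")
    sa <- read_fasta(pf_path(config, "parent_A.fasta"))
    sb <- read_fasta(pf_path(config, "parent_B.fasta"))
    files <- list.files(config$reads_dir, pattern = "\\.fasta$",
                        full.names = TRUE)
    if (length(files) == 0)
      stop_named("missing input '%s/*.fasta'; provide per-sample reads or unset reads_dir",
                 config$reads_dir)
    counts <- do.call(rbind, lapply(files, function(f) {
      reads <- read_fasta(f)
      count_assignments(toy_map(reads, sa), toy_map(reads, sb), cores,
                        sample_id = sub("\\.fasta$", "",
                                        basename(f)))$counts
    }))
    stage_write(counts, config, "counts.tsv", "assign")
  } else {
    counts <- stage_read(config, "rna_counts.tsv", "simulate")
    stage_write(counts, config, "counts.tsv", "assign")
  }
}

pf_samples <- function(config) stage_read(config, "samples.tsv",
                                          "simulate")

stage_bias <- function(config) {
  counts <- stage_read(config, "counts.tsv", "assign")
  samples <- pf_samples(config)
  dip <- samples[samples$group %in% c("parent_A", "parent_B"), ]
  species <- setNames(ifelse(dip$group == "parent_A", "A", "B"),
                      dip$sample_id)
  pri <- do.call(hse_priors, config$priors)
  bias <- flag_biased_cores(counts[counts$sample_id %in%
                                     dip$sample_id, ],
                            species, pri)
  stage_write(as.data.frame(bias), config, "bias_verdicts.tsv", "bias")
}

stage_hse <- function(config) {
  counts <- stage_read(config, "counts.tsv", "assign")
  samples <- pf_samples(config)
  bias <- stage_read(config, "bias_verdicts.tsv", "bias")
  poly <- samples[!samples$group %in% c("parent_A", "parent_B"), ]
  pri <- do.call(hse_priors, config$priors)
  calls <- call_hse(counts[counts$sample_id %in% poly$sample_id, ],
                    bias, setNames(poly$lineage, poly$sample_id), pri)
  c(stage_write(as.data.frame(calls), config, "hse_calls.tsv", "hse"),
    stage_write(hse_report(calls), config, "hse_report.tsv", "hse"))
}

stage_additivity <- function(config) {
  counts <- stage_read(config, "counts.tsv", "assign")
  samples <- pf_samples(config)
  args <- modifyList(list(min_cpm = 10, min_samples = NULL,
                          alpha_fdr = 0.05), config$additivity)
  m <- build_expression_matrix(counts)
  flt <- filter_low_expression(m, min_cpm = args$min_cpm,
                               min_samples = args$min_samples)
  di <- data.frame(sample_id = samples$sample_id, group = samples$group)
  dm <- design_matrix(di, colnames(flt$counts))
  v <- transform_and_weight(flt$counts, dm$design)
  fit <- fit_contrasts(v, di)
  cls <- classify_additivity(fit, alpha_fdr = args$alpha_fdr)
  c(stage_write(cls$results, config, "additivity_results.tsv",
                "additivity"),
    stage_write(cls$table, config, "additivity_table.tsv", "additivity"))
}

stage_fates <- function(config) {
  counts <- stage_read(config, "counts.tsv", "assign")
  dna <- stage_read(config, "dna_counts.tsv", "simulate")
  samples <- pf_samples(config)
  bias <- stage_read(config, "bias_verdicts.tsv", "bias")
  args <- modifyList(list(min_dna = 1L, min_rna = 1L), config$fates)
  poly <- samples[!samples$group %in% c("parent_A", "parent_B"), ]
  fates <- call_fates(counts[counts$sample_id %in% poly$sample_id, ],
                      dna, setNames(poly$lineage, poly$sample_id),
                      bias_verdicts = bias, min_dna = args$min_dna,
                      min_rna = args$min_rna)
  c(stage_write(as.data.frame(fates), config, "fate_calls.tsv", "fates"),
    stage_write(fate_table(fates), config, "fate_table.tsv", "fates"))
}

stage_converge <- function(config) {
  fates <- stage_read(config, "fate_calls.tsv", "fates")
  class(fates) <- c("fate_calls", "data.frame")
  stage_write(convergence_summary(fates), config, "convergence.tsv",
              "converge")
}

stage_report <- function(config) {
  tab <- stage_read(config, "additivity_counts.tsv", "additivity")
  stage_write(additivity_percentages(tab), config,
              "report_additivity.tsv", "report")
}
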
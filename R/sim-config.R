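#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' emulate the sampling design the pipeline is meant for: four independently
#' formed allotetraploid lineages with three biological replicates each,
#' five diploid individuals of parent A and three of parent B, ortholog
#' pairs with low SNP divergence, and realistic RNA-seq count noise.
#'
#' @param n_loci number of ortholog pairs (COREs) to simulate.
#' @param contig_len_range integer length-2 vector; range of the homologous
#'   core length in bp (a contig is core plus two flanks).
#' @param snp_rate per-base substitution probability between the two
#'   parental orthologs, in \[0,1\].
#' @param flank_len bp of non-homologous random sequence appended to each
#'   contig end (independently per parent).
#' @param read_len read length in bp.
#' @param seq_error_rate per-base sequencing error probability.
#' @param n_lineages number of independently formed polyploid lineages.
#' @param n_reps biological replicates per polyploid lineage.
#' @param n_diploid_A,n_diploid_B diploid sample counts for parents A and B.
#' @param lib_size_mean expected reads per sample.
#' @param dispersion negative-binomial dispersion phi; counts have variance
#'   mu + phi * mu^2.
#' @param frac_hse fraction of (locus, lineage) combinations with true
#'   homoeolog proportion different from 0.5.
#' @param q_alt true biased homoeolog proportion for HSE loci (direction
#'   toward either parent is drawn at random).
#' @param frac_bias fraction of COREs with mapping bias.
#' @param delta mapping-bias ratio: the odds multiplier toward parent A for
#'   a biased CORE. Realised per read as misassignment of diagnostic reads
#'   from the disfavoured parent with probability (delta - 1)/(delta + 1)
#'   for delta >= 1 (symmetrically for delta < 1), so that a balanced
#'   diploid mixture has assignment odds exactly delta.
#' @param frac_nonadditive fraction of loci whose polyploid log2 mean
#'   deviates from the mid-parent log2 mean by `beta_na`.
#' @param beta_na non-additivity effect size in log2 units.
#' @param frac_parents_diff fraction of loci where the two parents differ
#'   in expression by `parent_lfc` log2 units.
#' @param parent_lfc parental differential-expression effect in log2 units.
#' @param frac_lost per-homoeolog probability of ancestral loss (shared by
#'   all lineages: loss is planted before the lineage split).
#' @param frac_silenced per-homoeolog, per-lineage probability of silencing
#'   (drawn independently in each lineage).
#' @param dna_depth_mean expected DNA-capture reads per retained homoeolog
#'   per lineage.
#' @param seed integer RNG seed used by generator operations unless they
#'   are given their own.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- simulation_config(n_loci = 50, seed = 1)
#' cfg$n_lineages
#' @export
simulation_config <- function(n_loci = 2000,
                              contig_len_range = c(400L, 800L),
                              snp_rate = 0.02,
                              flank_len = 100L,
                              read_len = 100L,
                              seq_error_rate = 0.005,
                              n_lineages = 4L,
                              n_reps = 3L,
                              n_diploid_A = 5L,
                              n_diploid_B = 3L,
                              lib_size_mean = 1e6,
                              dispersion = 0.05,
                              frac_hse = 0.3,
                              q_alt = 0.8,
                              frac_bias = 0.1,
                              delta = 1.5,
                              frac_nonadditive = 0.3,
                              beta_na = 1,
                              frac_parents_diff = 0.22,
                              parent_lfc = 1.5,
                              frac_lost = 0.03,
                              frac_silenced = 0.03,
                              dna_depth_mean = 50,
                              seed = 42L) {
  cfg <- list(n_loci = as.integer(n_loci),
              contig_len_range = as.integer(contig_len_range),
              snp_rate = snp_rate, flank_len = as.integer(flank_len),
              read_len = as.integer(read_len),
              seq_error_rate = seq_error_rate,
              n_lineages = as.integer(n_lineages),
              n_reps = as.integer(n_reps),
              n_diploid_A = as.integer(n_diploid_A),
              n_diploid_B = as.integer(n_diploid_B),
              lib_size_mean = lib_size_mean, dispersion = dispersion,
              frac_hse = frac_hse, q_alt = q_alt,
              frac_bias = frac_bias, delta = delta,
              frac_nonadditive = frac_nonadditive, beta_na = beta_na,
              frac_parents_diff = frac_parents_diff,
              parent_lfc = parent_lfc,
              frac_lost = frac_lost, frac_silenced = frac_silenced,
              dna_depth_mean = dna_depth_mean, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fr <- c("snp_rate", "seq_error_rate", "frac_hse", "frac_bias",
          "frac_nonadditive", "frac_parents_diff", "frac_lost",
          "frac_silenced")
  for (f in fr) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_named("field '%s' must be a single value in [0, 1]", f)
  }
  if (cfg$frac_lost + cfg$frac_silenced > 1)
    stop_named("frac_lost + frac_silenced must not exceed 1")
  if (cfg$n_loci < 1L) stop_named("field 'n_loci' must be >= 1")
  if (length(cfg$contig_len_range) != 2L ||
      any(cfg$contig_len_range < 1L) || diff(cfg$contig_len_range) < 0)
    stop_named("field 'contig_len_range' must be an increasing positive pair")
  if (cfg$q_alt <= 0 || cfg$q_alt >= 1)
    stop_named("field 'q_alt' must lie strictly in (0, 1)")
  if (cfg$delta <= 0) stop_named("field 'delta' must be positive")
  if (cfg$dispersion < 0) stop_named("field 'dispersion' must be >= 0")
  for (f in c("n_lineages", "n_reps", "n_diploid_A", "n_diploid_B",
              "read_len", "flank_len"))
    if (cfg[[f]] < 0L || (f %in% c("n_lineages", "n_reps", "read_len") &&
                          cfg[[f]] < 1L))
      stop_named("field '%s' is out of range", f)
  # A contig must hold at least one read outside pure flank: core >= read_len.
  if (cfg$contig_len_range[1] < cfg$read_len)
    stop_named(paste0("field 'contig_len_range': contigs would be shorter ",
                      "than 2*flank_len + read_len (core length %d < ",
                      "read_len %d)"),
               cfg$contig_len_range[1], cfg$read_len)
  if (cfg$frac_hse > 0 &&
      cfg$snp_rate * mean(cfg$contig_len_range) < 1)
    warning("expected diagnostic SNPs per locus < 1; HSE loci may be ",
            "undetectable at this snp_rate", call. = FALSE)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic allopolyploid design:\n")
  cat(sprintf("  %d ortholog pairs, core length %d-%d bp, SNP rate %.3g\n",
              x$n_loci, x$contig_len_range[1], x$contig_len_range[2],
              x$snp_rate))
  cat(sprintf("  samples: %d + %d diploids, %d lineages x %d reps\n",
              x$n_diploid_A, x$n_diploid_B, x$n_lineages, x$n_reps))
  cat(sprintf("  HSE %g @ q=%g | bias %g @ delta=%g | non-additive %g @ %g log2\n",
              x$frac_hse, x$q_alt, x$frac_bias, x$delta,
              x$frac_nonadditive, x$beta_na))
  cat(sprintf("  lost %g (ancestral) | silenced %g (per lineage)\n",
              x$frac_lost, x$frac_silenced))
  invisible(x)
}

#' Read a simulation configuration from a key-value file
#'
#' The file is TSV/whitespace `key value` lines (or `key: value`) mirroring
#' [simulation_config()] argument names; unknown keys are rejected.
#'
#' @param path file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(sub(":", " ", lines, fixed = TRUE), "[[:space:]]+")
  keys <- vapply(kv, `[`, "", 1L)
  known <- names(formals(simulation_config))
  bad <- setdiff(keys, known)
  if (length(bad)) stop_named("unknown config key(s): %s",
                              paste(bad, collapse = ", "))
  vals <- lapply(kv, function(x) as.numeric(x[-1L]))
  names(vals) <- keys
  do.call(simulation_config, vals)
}
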
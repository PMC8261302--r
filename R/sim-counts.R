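## Count-level simulation. Statistical modules (bias flagging, HSE calling,
## additivity, fates) are tested on counts directly; sequence-level fixtures
## for CORE/mapping modules come from generate_parent_transcriptomes() and
## simulate_reads(). Keeping the two paths separate decouples alignment
## fidelity from inference testing.

## Probability a diagnostic read is assigned to parent A, given the
## probability qA that it originates from A. Bias is per-read misassignment
## of reads from the disfavoured parent with probability
## (delta - 1)/(delta + 1) (delta >= 1; symmetric below 1), so a balanced
## mixture has assignment odds exactly delta.
assign_prob <- function(qA, biased, delta) {
  if (delta >= 1) {
    eps_b2a <- (delta - 1) / (delta + 1); eps_a2b <- 0
  } else {
    inv <- 1 / delta
    eps_a2b <- (inv - 1) / (inv + 1); eps_b2a <- 0
  }
  ifelse(biased, qA * (1 - eps_a2b) + (1 - qA) * eps_b2a, qA)
}

rcounts <- function(n, mu, dispersion) {
  if (dispersion > 0) rnbinom(n, size = 1 / dispersion, mu = mu)
  else rpois(n, mu)
}

#' Simulate per-CORE assignment counts with a known truth table
#'
#' Generates RNA diagnostic/shared counts for all diploid and polyploid
#' samples and DNA-capture counts per homoeolog per lineage, together with
#' the complete ground truth. Per locus, total expression is
#' negative-binomial (variance `mu + phi mu^2`) around a library-size-scaled
#' locus mean; the polyploid log2 mean is the mid-parent log2 mean, plus
#' `beta_na` for non-additive loci; a fraction `1 - (1 - snp_rate)^read_len`
#' of reads is diagnostic and is split between the parents by a binomial
#' whose success probability composes the true homoeolog proportion with the
#' mapping-bias misassignment for biased COREs. Loss is ancestral (shared by
#' all lineages); silencing is drawn independently per lineage. Lost
#' homoeologs emit zero DNA and zero RNA; silenced homoeologs emit DNA but
#' zero RNA.
#'
#' @param config a [simulation_config()].
#' @param seed optional integer seed overriding `config$seed`.
#' @return an object of class `sim_counts`: a list with
#'   \describe{
#'     \item{rna_counts}{data frame `core_id, sample_id, n_A, n_B,
#'       n_shared` for every CORE and RNA sample;}
#'     \item{dna_counts}{data frame `core_id, lineage, parent, dna_count`;}
#'     \item{samples}{data frame `sample_id, group, lineage, rep`, where
#'       `group` is `parent_A`, `parent_B` or the lineage ID;}
#'     \item{truth}{list of `loci` (per-locus states: `biased`,
#'       `parents_state`, `additivity_state`, locus means), `lineage_q`
#'       (per locus x lineage: `true_q`, `hse`, `q_eff`) and `fates`
#'       (per locus x parent x lineage: `fate` in expressed / silenced /
#'       lost);}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_counts(simulation_config(n_loci = 20, lib_size_mean = 1e4))
#' head(sim$rna_counts)
#' @export
simulate_counts <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(if (is.null(seed)) config$seed else seed, {
    n <- config$n_loci
    core_id <- sprintf("locus%04d", seq_len(n))

    ## per-locus states
    biased <- runif(n) < config$frac_bias
    parents_diff <- runif(n) < config$frac_parents_diff
    s_par <- sample(c(-1, 1), n, replace = TRUE)
    nonadd <- runif(n) < config$frac_nonadditive
    s_na <- sample(c(-1, 1), n, replace = TRUE)

    ## locus base expression (log2-normal spread, realistic dynamic range)
    z <- rnorm(n, 0, 1.2)
    wA <- 2^z
    wB <- wA * 2^(ifelse(parents_diff, s_par * config$parent_lfc, 0))
    denom <- (sum(wA) + sum(wB)) / 2
    mA <- config$lib_size_mean * wA / denom
    mB <- config$lib_size_mean * wB / denom
    mP <- 2^((log2(mA) + log2(mB)) / 2 +
               ifelse(nonadd, s_na * config$beta_na, 0))

    ## homoeolog fates: ancestral loss, per-lineage silencing
    lost <- matrix(runif(2 * n) < config$frac_lost, n, 2,
                   dimnames = list(NULL, c("A", "B")))
    p_sil <- if (config$frac_lost < 1)
      config$frac_silenced / (1 - config$frac_lost) else 0
    lineages <- sprintf("P%d", seq_len(config$n_lineages))
    sil <- array(FALSE, c(n, 2, config$n_lineages))
    for (l in seq_len(config$n_lineages))
      sil[, , l] <- !lost & matrix(runif(2 * n) < p_sil, n, 2)

    ## true homoeolog proportion per locus x lineage
    qmat <- matrix(0.5, n, config$n_lineages)
    hse <- matrix(runif(n * config$n_lineages) < config$frac_hse,
                  n, config$n_lineages)
    dir_a <- matrix(sample(c(TRUE, FALSE), n * config$n_lineages,
                           replace = TRUE), n, config$n_lineages)
    qmat[hse] <- ifelse(dir_a[hse], config$q_alt, 1 - config$q_alt)

    ## samples
    samples <- rbind(
      data.frame(sample_id = sprintf("dipA_%d", seq_len(config$n_diploid_A)),
                 group = "parent_A", lineage = NA_character_,
                 rep = seq_len(config$n_diploid_A)),
      data.frame(sample_id = sprintf("dipB_%d", seq_len(config$n_diploid_B)),
                 group = "parent_B", lineage = NA_character_,
                 rep = seq_len(config$n_diploid_B)),
      do.call(rbind, lapply(seq_len(config$n_lineages), function(l)
        data.frame(sample_id = sprintf("%s_r%d", lineages[l],
                                       seq_len(config$n_reps)),
                   group = lineages[l], lineage = lineages[l],
                   rep = seq_len(config$n_reps)))))

    d_frac <- 1 - (1 - config$snp_rate)^config$read_len
    p_dipA <- assign_prob(rep(1, n), biased, config$delta)
    p_dipB <- assign_prob(rep(0, n), biased, config$delta)

    rna <- vector("list", nrow(samples))
    for (s in seq_len(nrow(samples))) {
      grp <- samples$group[s]
      if (grp == "parent_A") { mu <- mA; p <- p_dipA }
      else if (grp == "parent_B") { mu <- mB; p <- p_dipB }
      else {
        l <- match(grp, lineages)
        actA <- !(lost[, "A"] | sil[, 1, l])
        actB <- !(lost[, "B"] | sil[, 2, l])
        act <- qmat[, l] * actA + (1 - qmat[, l]) * actB
        q_eff <- ifelse(act > 0, qmat[, l] * actA / act, 0.5)
        mu <- mP * act
        p <- assign_prob(q_eff, biased, config$delta)
      }
      tot <- rcounts(n, mu, config$dispersion)
      diag <- rbinom(n, tot, d_frac)
      n_A <- rbinom(n, diag, p)
      rna[[s]] <- data.frame(core_id = core_id,
                             sample_id = samples$sample_id[s],
                             n_A = n_A, n_B = diag - n_A,
                             n_shared = tot - diag)
    }
    rna <- do.call(rbind, rna)
    rownames(rna) <- NULL

    ## DNA capture: per lineage x homoeolog; zero iff lost
    dna <- do.call(rbind, lapply(seq_len(config$n_lineages), function(l) {
      do.call(rbind, lapply(1:2, function(pidx) {
        present <- !lost[, pidx]
        data.frame(core_id = core_id, lineage = lineages[l],
                   parent = c("A", "B")[pidx],
                   dna_count = ifelse(present,
                                      rcounts(n, config$dna_depth_mean,
                                              config$dispersion) +
                                        as.integer(present), 0L))
      }))
    }))
    ## +1 above guarantees silenced/expressed homoeologs emit >= 1 DNA read
    rownames(dna) <- NULL

    q_eff_mat <- matrix(NA_real_, n, config$n_lineages)
    fate <- vector("list", 2 * config$n_lineages)
    k <- 0
    for (l in seq_len(config$n_lineages)) {
      actA <- !(lost[, "A"] | sil[, 1, l])
      actB <- !(lost[, "B"] | sil[, 2, l])
      act <- qmat[, l] * actA + (1 - qmat[, l]) * actB
      q_eff_mat[, l] <- ifelse(act > 0, qmat[, l] * actA / act, NA_real_)
      for (pidx in 1:2) {
        st <- ifelse(lost[, pidx], "lost",
                     ifelse(sil[, pidx, l], "silenced", "expressed"))
        k <- k + 1
        fate[[k]] <- data.frame(core_id = core_id, lineage = lineages[l],
                                parent = c("A", "B")[pidx], fate = st)
      }
    }
    fates <- do.call(rbind, fate)
    rownames(fates) <- NULL

    truth <- list(
      loci = data.frame(core_id = core_id, biased = biased,
                        parents_state = ifelse(parents_diff, "different",
                                               "same"),
                        additivity_state = ifelse(nonadd, "nonadditive",
                                                  "additive"),
                        mean_A = mA, mean_B = mB, mean_poly = mP),
      lineage_q = do.call(rbind, lapply(seq_len(config$n_lineages),
        function(l) data.frame(core_id = core_id, lineage = lineages[l],
                               true_q = qmat[, l], hse = hse[, l],
                               q_eff = q_eff_mat[, l]))),
      fates = fates)
    rownames(truth$lineage_q) <- NULL

    structure(list(rna_counts = rna, dna_counts = dna, samples = samples,
                   truth = truth, config = config),
              class = "sim_counts")
  })
}

#' @export
print.sim_counts <- function(x, ...) {
  cat(sprintf("Simulated assignment counts: %d COREs x %d samples (%d lineages)\n",
              x$config$n_loci, nrow(x$samples), x$config$n_lineages))
  cat(sprintf("  truth: %d HSE locus-lineage pairs, %d biased COREs, %d lost, %d silenced homoeolog states\n",
              sum(x$truth$lineage_q$hse), sum(x$truth$loci$biased),
              sum(x$truth$fates$fate == "lost"),
              sum(x$truth$fates$fate == "silenced")))
  invisible(x)
}
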
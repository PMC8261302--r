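#' Prior set for the homoeolog-proportion posterior
#'
#' The homoeolog proportion q (fraction of diagnostic expression from the
#' parent-A homoeolog) gets a Beta(c*pi0, c*(1-pi0)) prior for each prior
#' mean pi0. A CORE is only called when the credible interval excludes 0.5
#' under *every* prior, which makes the rule robust to the prior and
#' conservative for the type-I error.
#'
#' @param prior_means prior means pi0, each strictly in (0, 1).
#' @param concentration prior concentration c > 0 (total pseudo-counts).
#' @param ci_level equal-tailed credible-interval level in (0, 1).
#' @param min_total minimum diagnostic reads (n_A + n_B) for a call.
#' @return an object of class `hse_priors`.
#' @export
hse_priors <- function(prior_means = c(0.4, 0.5, 0.6), concentration = 2,
                       ci_level = 0.95, min_total = 10L) {
  stopifnot(all(prior_means > 0 & prior_means < 1), concentration > 0,
            ci_level > 0, ci_level < 1, min_total >= 0)
  structure(list(prior_means = prior_means, concentration = concentration,
                 ci_level = ci_level, min_total = as.integer(min_total)),
            class = "hse_priors")
}

## Vectorized conjugate posterior (delta = 1): Beta(c*pi0 + nA, c*(1-pi0) + nB).
post_closed <- function(n_A, n_B, prior_mean, concentration, ci_level) {
  a <- concentration * prior_mean + n_A
  b <- concentration * (1 - prior_mean) + n_B
  al <- (1 - ci_level) / 2
  data.frame(prior_mean = prior_mean, mean = a / (a + b),
             lo = qbeta(al, a, b), hi = qbeta(1 - al, a, b))
}

#' Posterior summary of the homoeolog proportion
#'
#' Independent Poisson counts with Gamma rates, conditioned on the
#' diagnostic total, reduce to a Binomial likelihood in the proportion q
#' with a Beta prior. With `delta = 1` the posterior is the conjugate
#' Beta(c*pi0 + n_A, c*(1-pi0) + n_B), computed in closed form. With
#' `delta != 1` the assignment odds toward parent A are multiplied by
#' `delta` — the likelihood is Binomial(n_A + n_B, q*delta/(q*delta+1-q))
#' — and the posterior is evaluated on a uniform grid over \[0,1\] and
#' normalized, with equal-tailed quantiles by cumulative interpolation.
#'
#' @param n_A,n_B diagnostic read counts for parents A and B.
#' @param prior_mean prior mean pi0 in (0, 1).
#' @param concentration prior concentration c.
#' @param ci_level credible-interval level.
#' @param delta mapping-bias odds multiplier toward parent A (1 = none).
#' @param method `"auto"` (closed form when `delta == 1`, grid otherwise),
#'   or force `"closed"` / `"grid"`.
#' @param grid_points number of grid points for the grid posterior.
#' @return one-row data frame of class `posterior_summary`: `prior_mean`,
#'   `mean`, `lo`, `hi`, `n_A`, `n_B`, `delta`.
#' @examples
#' posterior_q(3, 1)          # Beta(4, 2): mean 2/3
#' posterior_q(0, 0)          # returns the prior
#' @export
posterior_q <- function(n_A, n_B, prior_mean = 0.5, concentration = 2,
                        ci_level = 0.95, delta = 1,
                        method = c("auto", "closed", "grid"),
                        grid_points = 4001L) {
  stopifnot(n_A >= 0, n_B >= 0, delta > 0,
            prior_mean > 0, prior_mean < 1)
  method <- match.arg(method)
  if (method == "auto") method <- if (delta == 1) "closed" else "grid"
  if (method == "closed") {
    if (delta != 1)
      stop_named("closed-form posterior requires delta = 1")
    s <- post_closed(n_A, n_B, prior_mean, concentration, ci_level)
  } else {
    q <- seq(0, 1, length.out = grid_points)
    lp <- dbeta(q, concentration * prior_mean,
                concentration * (1 - prior_mean), log = TRUE)
    p <- q * delta / (q * delta + 1 - q)
    n <- n_A + n_B
    if (n > 0) {
      ll <- n_A * log(p) + n_B * log1p(-p)
      ll[!is.finite(ll)] <- -Inf
      lp <- lp + ll
    }
    lp[!is.finite(lp)] <- -Inf               # clamp infinite prior endpoints
    w <- exp(lp - max(lp))
    ## trapezoid weights for integration on the uniform grid
    tw <- rep(1, grid_points); tw[c(1, grid_points)] <- 0.5
    dens <- w * tw
    dens <- dens / sum(dens)
    cdf <- cumsum(dens)
    al <- (1 - ci_level) / 2
    keep <- !duplicated(cdf)
    s <- data.frame(prior_mean = prior_mean,
                    mean = sum(q * dens),
                    lo = approx(cdf[keep], q[keep], xout = al,
                                rule = 2)$y,
                    hi = approx(cdf[keep], q[keep], xout = 1 - al,
                                rule = 2)$y)
  }
  out <- cbind(s, n_A = n_A, n_B = n_B, delta = delta)
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Three-prior HSE decision rule
#'
#' `toward_A` iff the credible interval lies entirely above 0.5 for every
#' prior; `toward_B` iff entirely below for every prior; `none` otherwise.
#' `insufficient_data` when the diagnostic total is below `min_total`.
#' Mixed-sign exclusions (possible only at tiny counts) give `none` with a
#' warning.
#'
#' @param summaries data frame with one row per prior mean (`lo`, `hi`,
#'   `n_A`, `n_B` columns), e.g. stacked [posterior_q()] rows.
#' @param min_total minimum diagnostic total for a call.
#' @return a single verdict string.
#' @export
decide_hse <- function(summaries, min_total = 10L) {
  stopifnot(nrow(summaries) >= 1,
            !anyDuplicated(summaries$prior_mean))
  if (summaries$n_A[1] + summaries$n_B[1] < min_total)
    return("insufficient_data")
  above <- summaries$lo > 0.5
  below <- summaries$hi < 0.5
  if (any(above) && any(below)) {
    warning("credible intervals exclude 0.5 on opposite sides across ",
            "priors; verdict 'none'", call. = FALSE)
    return("none")
  }
  if (all(above)) return("toward_A")
  if (all(below)) return("toward_B")
  "none"
}

## Vectorized three-prior decision over n cores: returns verdict vector and
## per-prior summaries as a wide data.frame.
decide_hse_vec <- function(n_A, n_B, priors) {
  n <- length(n_A)
  all_above <- rep(TRUE, n); all_below <- rep(TRUE, n)
  any_above <- rep(FALSE, n); any_below <- rep(FALSE, n)
  wide <- data.frame(row.names = seq_len(n))
  for (p0 in priors$prior_means) {
    s <- post_closed(n_A, n_B, p0, priors$concentration, priors$ci_level)
    tag <- sub("^0\\.", "", format(p0))
    wide[[paste0("mean_", tag)]] <- s$mean
    wide[[paste0("lo_", tag)]] <- s$lo
    wide[[paste0("hi_", tag)]] <- s$hi
    all_above <- all_above & s$lo > 0.5
    all_below <- all_below & s$hi < 0.5
    any_above <- any_above | s$lo > 0.5
    any_below <- any_below | s$hi < 0.5
  }
  verdict <- rep("none", n)
  verdict[all_above] <- "toward_A"
  verdict[all_below] <- "toward_B"
  mixed <- any_above & any_below
  if (any(mixed)) {
    warning(sum(mixed), " CORE(s) with opposite-side exclusions across ",
            "priors; verdict 'none'", call. = FALSE)
    verdict[mixed] <- "none"
  }
  verdict[n_A + n_B < priors$min_total] <- "insufficient_data"
  list(verdict = verdict, summaries = wide)
}

#' Flag COREs with systematic mapping bias from diploid data
#'
#' Under no mapping bias, a library-size-equalized 50/50 in-silico mixture
#' of reads from the two diploid species has expected parent-A assignment
#' proportion exactly 0.5. Per CORE, the diagnostic counts of each
#' species' pooled samples are scaled to equal totals, summed into a
#' mixture, and the three-prior rule ([decide_hse()]-style, `delta = 1`)
#' is applied: the CORE is biased iff the mixture proportion is credibly
#' different from 0.5 under every prior. `delta_hat` is the smoothed
#' mixture assignment odds `(n_A + 0.5)/(n_B + 0.5)`, which estimates the
#' bias odds multiplier (1 = unbiased).
#'
#' @param diploid_counts data frame `core_id, sample_id, n_A, n_B` (extra
#'   columns ignored) for the diploid samples only.
#' @param sample_species named character vector or data frame
#'   (`sample_id`, `species`) mapping each diploid sample to `"A"` or
#'   `"B"`.
#' @param priors an [hse_priors()].
#' @return data frame of class `bias_verdicts`: `core_id`, `biased`,
#'   `verdict`, `delta_hat`, `n_mix_A`, `n_mix_B`, `low_power`, plus
#'   per-prior `mean_*`, `lo_*`, `hi_*` columns. COREs where a species has
#'   zero diagnostic reads get `verdict = "insufficient_data"`,
#'   `biased = FALSE`, `low_power = TRUE`.
#' @export
flag_biased_cores <- function(diploid_counts, sample_species,
                              priors = hse_priors()) {
  if (is.data.frame(sample_species))
    sample_species <- setNames(sample_species$species,
                               sample_species$sample_id)
  sp <- sample_species[diploid_counts$sample_id]
  if (anyNA(sp)) stop_named("diploid sample(s) missing a species label")
  if (!all(sp %in% c("A", "B")))
    stop_named("species labels must be 'A' or 'B'")
  cores <- sort(unique(diploid_counts$core_id))
  agg <- function(species, col) {
    x <- diploid_counts[sp == species, , drop = FALSE]
    v <- tapply(x[[col]], factor(x$core_id, levels = cores), sum,
                default = 0)
    as.numeric(v)
  }
  aA <- agg("A", "n_A"); aB <- agg("A", "n_B")
  bA <- agg("B", "n_A"); bB <- agg("B", "n_B")
  totA <- aA + aB; totB <- bA + bB
  target <- pmin(totA, totB)
  sc <- function(x, tot) ifelse(tot > 0, round(x * target / tot), 0)
  n_mix_A <- sc(aA, totA) + sc(bA, totB)
  n_mix_B <- sc(aB, totA) + sc(bB, totB)
  dec <- decide_hse_vec(n_mix_A, n_mix_B, priors)
  verdict <- dec$verdict
  low_power <- totA == 0 | totB == 0
  verdict[low_power] <- "insufficient_data"
  out <- data.frame(core_id = cores, biased = verdict %in%
                      c("toward_A", "toward_B"),
                    verdict = verdict,
                    delta_hat = (n_mix_A + 0.5) / (n_mix_B + 0.5),
                    n_mix_A = n_mix_A, n_mix_B = n_mix_B,
                    low_power = low_power)
  out <- cbind(out, dec$summaries)
  rownames(out) <- NULL
  class(out) <- c("bias_verdicts", "data.frame")
  out
}

#' Call homoeolog-specific expression per CORE per polyploid lineage
#'
#' Replicate diagnostic counts are summed within each lineage; COREs
#' flagged as mapping-biased from diploid data are excluded
#' (`excluded_biased`); the remainder get the three-prior posterior rule
#' with `delta = 1`.
#'
#' @param polyploid_counts data frame `core_id, sample_id, n_A, n_B` for
#'   polyploid samples.
#' @param bias_verdicts output of [flag_biased_cores()] over the same CORE
#'   set (may be `NULL` to skip bias filtering).
#' @param sample_lineage named character vector or data frame
#'   (`sample_id`, `lineage`) mapping each polyploid sample to its
#'   lineage.
#' @param priors an [hse_priors()].
#' @return data frame of class `hse_calls`: `core_id`, `lineage`,
#'   `verdict` (`toward_A`, `toward_B`, `none`, `excluded_biased`,
#'   `insufficient_data`), `n_A`, `n_B`, plus per-prior summary columns.
#' @export
call_hse <- function(polyploid_counts, bias_verdicts, sample_lineage,
                     priors = hse_priors()) {
  if (is.data.frame(sample_lineage))
    sample_lineage <- setNames(sample_lineage$lineage,
                               sample_lineage$sample_id)
  lin <- sample_lineage[polyploid_counts$sample_id]
  if (anyNA(lin)) stop_named("polyploid sample(s) missing a lineage label")
  lineages <- sort(unique(lin))
  if (length(lineages) == 0) stop_named("no polyploid samples given")
  biased_ids <- if (is.null(bias_verdicts)) character(0) else
    bias_verdicts$core_id[bias_verdicts$biased]
  out <- vector("list", length(lineages))
  for (k in seq_along(lineages)) {
    x <- polyploid_counts[lin == lineages[k], , drop = FALSE]
    cores <- sort(unique(x$core_id))
    f <- factor(x$core_id, levels = cores)
    n_A <- as.numeric(tapply(x$n_A, f, sum, default = 0))
    n_B <- as.numeric(tapply(x$n_B, f, sum, default = 0))
    dec <- decide_hse_vec(n_A, n_B, priors)
    verdict <- dec$verdict
    verdict[cores %in% biased_ids] <- "excluded_biased"
    res <- data.frame(core_id = cores, lineage = lineages[k],
                      verdict = verdict, n_A = n_A, n_B = n_B)
    res <- cbind(res, dec$summaries)
    res[res$verdict == "excluded_biased",
        names(dec$summaries)] <- NA_real_
    out[[k]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("hse_calls", "data.frame")
  out
}

#' Tabulate HSE calls per lineage, optionally stratified by parental state
#'
#' Produces the per-lineage tally of loci with expression biased toward
#' each parent or neither, in strata `parents_same`, `parents_different`
#' and `ignoring_parents` when a parental-difference classification is
#' supplied. Excluded (biased) and insufficient-data COREs are not
#' tallied.
#'
#' @param calls an `hse_calls` data frame from [call_hse()].
#' @param parents_state optional data frame (`core_id`, `parents_state`
#'   with values `"same"` / `"different"`), e.g. from
#'   [classify_additivity()] results.
#' @return data frame: `stratum`, `lineage`, `toward_A`, `toward_B`,
#'   `none`.
#' @export
hse_report <- function(calls, parents_state = NULL) {
  tally <- function(x, stratum) {
    x <- x[x$verdict %in% c("toward_A", "toward_B", "none"), ,
           drop = FALSE]
    t <- table(x$lineage, factor(x$verdict,
                                 levels = c("toward_A", "toward_B",
                                            "none")))
    data.frame(stratum = stratum, lineage = rownames(t),
               toward_A = as.integer(t[, "toward_A"]),
               toward_B = as.integer(t[, "toward_B"]),
               none = as.integer(t[, "none"]))
  }
  out <- tally(calls, "ignoring_parents")
  if (!is.null(parents_state)) {
    st <- setNames(parents_state$parents_state, parents_state$core_id)
    cs <- st[calls$core_id]
    out <- rbind(tally(calls[!is.na(cs) & cs == "same", ], "parents_same"),
                 tally(calls[!is.na(cs) & cs == "different", ],
                       "parents_different"),
                 out)
  }
  rownames(out) <- NULL
  out
}

#' @export
print.hse_calls <- function(x, ...) {
  cat("HSE calls:", length(unique(x$core_id)), "COREs x",
      length(unique(x$lineage)), "lineages\n")
  print(table(x$lineage, x$verdict))
  invisible(x)
}

#' @export
summary.hse_calls <- function(object, ...) hse_report(object)
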
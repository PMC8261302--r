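#' Filter lowly expressed loci from a count matrix
#'
#' A locus is retained iff its raw count reaches `min_cpm` counts-per-
#' million, evaluated against the *average* library size, in at least
#' `min_samples` samples. With the study design of 20 samples the default
#' `min_samples` is 11; otherwise it defaults to `ceiling(0.55 * n)`.
#'
#' @param counts integer matrix, loci x samples.
#' @param min_cpm CPM threshold.
#' @param min_samples minimum number of samples at or above the threshold.
#' @return list: `counts` (filtered matrix), `n_kept`, `n_dropped`,
#'   `count_threshold` (the raw-count equivalent of `min_cpm`),
#'   `min_samples`.
#' @export
filter_low_expression <- function(counts, min_cpm = 10,
                                  min_samples = NULL) {
  stopifnot(is.matrix(counts))
  n <- ncol(counts)
  if (is.null(min_samples))
    min_samples <- if (n == 20L) 11L else ceiling(0.55 * n)
  if (min_samples > n)
    stop_named("min_samples (%d) exceeds the number of samples (%d)",
               min_samples, n)
  thr <- min_cpm * mean(colSums(counts)) / 1e6
  keep <- rowSums(counts >= thr) >= min_samples
  list(counts = counts[keep, , drop = FALSE],
       n_kept = sum(keep), n_dropped = sum(!keep),
       count_threshold = thr, min_samples = as.integer(min_samples))
}

#' Log2-CPM transform with mean-variance precision weights
#'
#' Computes `log2((count + 0.5)/(lib + 1) * 1e6)` and per-observation
#' precision weights from a locally weighted regression of the residual
#' standard deviation against mean log count (the voom procedure from the
#' limma package). With fewer than 10 loci the trend cannot be estimated:
#' weights fall back to 1 with a warning.
#'
#' @param counts filtered count matrix, loci x samples.
#' @param design design matrix (e.g. from [design_matrix()]); defaults to
#'   an intercept-only design.
#' @param span loess span of the mean-variance trend.
#' @return a limma `EList` with components `E` (log2-CPM) and `weights`.
#' @export
transform_and_weight <- function(counts, design = NULL, span = 0.5) {
  stopifnot(is.matrix(counts))
  if (nrow(counts) < 10) {
    warning("fewer than 10 loci: precision weights set to 1",
            call. = FALSE)
    lib <- colSums(counts)
    E <- log2(t((t(counts) + 0.5) / (lib + 1)) * 1e6)
    return(methods::new("EList",
                        list(E = E,
                             weights = matrix(1, nrow(E), ncol(E)))))
  }
  limma::voom(counts, design = design, span = span)
}

#' Build the group design matrix and default contrasts
#'
#' @param design_info data frame with `sample_id` and `group` (values
#'   `parent_A`, `parent_B` and one label per polyploid lineage), covering
#'   every matrix column.
#' @param samples character vector of sample IDs in matrix column order.
#' @return list: `design` (0/1 group-means design matrix), `contrasts`
#'   (matrix with one column `parents` = parent_A - parent_B and one
#'   `midparent_<lineage>` column = lineage - (parent_A + parent_B)/2 per
#'   lineage), `lineages`.
#' @export
design_matrix <- function(design_info, samples) {
  grp <- setNames(design_info$group, design_info$sample_id)[samples]
  if (anyNA(grp))
    stop_named("design does not cover sample(s): %s",
               paste(samples[is.na(grp)], collapse = ", "))
  groups <- unique(grp)
  if (!all(c("parent_A", "parent_B") %in% groups))
    stop_named("design must contain groups 'parent_A' and 'parent_B'")
  f <- factor(grp, levels = c("parent_A", "parent_B",
                              sort(setdiff(groups,
                                           c("parent_A", "parent_B")))))
  design <- stats::model.matrix(~ 0 + f)
  colnames(design) <- levels(f)
  rownames(design) <- samples
  lineages <- setdiff(levels(f), c("parent_A", "parent_B"))
  cm <- matrix(0, ncol(design), 1 + length(lineages),
               dimnames = list(colnames(design),
                               c("parents",
                                 if (length(lineages))
                                   paste0("midparent_", lineages))))
  cm["parent_A", "parents"] <- 1; cm["parent_B", "parents"] <- -1
  for (l in lineages) {
    cm[l, paste0("midparent_", l)] <- 1
    cm["parent_A", paste0("midparent_", l)] <- -0.5
    cm["parent_B", paste0("midparent_", l)] <- -0.5
  }
  list(design = design, contrasts = cm, lineages = lineages)
}

#' Fit weighted group means and moderated contrast tests per locus
#'
#' Weighted least-squares group means per locus; residual variances are
#' shrunk toward a common prior by empirical Bayes (limma's `eBayes`) and
#' contrast t-statistics use the moderated variance on `d0 + d` degrees of
#' freedom. With `moderated = FALSE`, or when only one locus is supplied
#' (no variance distribution to shrink toward, i.e. d0 = 0), ordinary
#' t-tests are returned.
#'
#' @param elist an `EList` from [transform_and_weight()] (or a plain
#'   log-expression matrix).
#' @param design_info data frame `sample_id`, `group` (see
#'   [design_matrix()]).
#' @param moderated use empirical-Bayes variance moderation.
#' @return object of class `pf_fit`: list with `group_means` (loci x
#'   groups, log2 scale), `coefficients` (contrast estimates),
#'   `t`, `p.value`, `df.total`, `contrasts`, `lineages`, `design_info`.
#' @export
fit_contrasts <- function(elist, design_info, moderated = TRUE) {
  E <- if (methods::is(elist, "EList")) elist$E else as.matrix(elist)
  samples <- colnames(E)
  dm <- design_matrix(design_info, samples)
  ## every group entering a contrast needs >= 2 samples for a variance
  nper <- colSums(dm$design)
  used <- rownames(dm$contrasts)[rowSums(dm$contrasts != 0) > 0]
  short <- used[nper[used] < 2]
  if (length(short))
    stop_named("group(s) with fewer than 2 samples in a contrast: %s",
               paste(short, collapse = ", "))
  fit <- limma::lmFit(elist, dm$design)
  cf <- limma::contrasts.fit(fit, dm$contrasts)
  if (moderated && nrow(E) > 1) {
    eb <- limma::eBayes(cf)
    tt <- eb$t; pp <- eb$p.value; dft <- eb$df.total
  } else {
    tt <- cf$coefficients / (cf$stdev.unscaled * cf$sigma)
    dft <- cf$df.residual
    pp <- 2 * pt(-abs(tt), dft)
  }
  structure(list(group_means = fit$coefficients,
                 coefficients = cf$coefficients, t = tt, p.value = pp,
                 df.total = dft, contrasts = dm$contrasts,
                 lineages = dm$lineages, design_info = design_info),
            class = "pf_fit")
}

#' @export
print.pf_fit <- function(x, ...) {
  cat(sprintf("Weighted linear fit: %d loci, groups [%s]\n",
              nrow(x$group_means),
              paste(colnames(x$group_means), collapse = ", ")))
  cat("Contrasts:", paste(colnames(x$contrasts), collapse = ", "), "\n")
  invisible(x)
}

#' Classify parental difference and mid-parent additivity
#'
#' Applies Benjamini-Hochberg FDR control within each contrast family
#' separately (one family for the parental contrast across loci; one
#' family per lineage for the mid-parent contrast). A locus is
#' `parents_state = "different"` iff the adjusted parental p-value is
#' below `alpha_fdr`; `additivity_state = "not_additive"` iff the
#' adjusted mid-parent p-value is below `alpha_fdr`. `power_flag` marks
#' loci where the parents differ and the lineage mean lies strictly
#' between the two parental means, where the mid-parent test has limited
#' power.
#'
#' @param fit a `pf_fit` from [fit_contrasts()].
#' @param alpha_fdr FDR threshold.
#' @param scale test the mid-parent contrast on the log2 scale (default,
#'   matching the linear-model pipeline) or on the linear scale via the
#'   same contrast on unlogged fitted means with a delta-method variance.
#' @return object of class `additivity_result`: list with `results` (data
#'   frame, one row per locus x lineage: `locus`, `lineage`,
#'   `parents_state`, `padj_parents`, `estimate`, `padj_additivity`,
#'   `additivity_state`, `power_flag`) and `table` (the per-lineage 2x2
#'   report with percentages, see [additivity_percentages()]).
#' @export
classify_additivity <- function(fit, alpha_fdr = 0.05,
                                scale = c("log", "linear")) {
  stopifnot(inherits(fit, "pf_fit"))
  scale <- match.arg(scale)
  loci <- rownames(fit$group_means)
  padj_par <- p.adjust(fit$p.value[, "parents"], method = "BH")
  parents_state <- ifelse(padj_par < alpha_fdr, "different", "same")
  mA <- fit$group_means[, "parent_A"]
  mB <- fit$group_means[, "parent_B"]
  out <- vector("list", length(fit$lineages))
  for (k in seq_along(fit$lineages)) {
    l <- fit$lineages[k]
    cn <- paste0("midparent_", l)
    if (scale == "log") {
      est <- fit$coefficients[, cn]
      p <- fit$p.value[, cn]
    } else {
      ## same contrast on unlogged fitted means; delta-method variance
      mP <- fit$group_means[, l]
      est <- 2^mP - 0.5 * (2^mA + 2^mB)
      se_log <- abs(fit$coefficients[, cn] / fit$t[, cn])
      grad <- log(2) * sqrt((2^mP)^2 + 0.25 * (2^mA)^2 + 0.25 * (2^mB)^2) /
        sqrt(1 + 0.25 + 0.25)
      tstat <- est / (se_log * grad)
      dft <- if (is.matrix(fit$df.total)) fit$df.total[, cn] else
        fit$df.total
      p <- 2 * pt(-abs(tstat), dft)
    }
    padj <- p.adjust(p, method = "BH")
    mP <- fit$group_means[, l]
    out[[k]] <- data.frame(
      locus = loci, lineage = l, parents_state = parents_state,
      padj_parents = padj_par, estimate = est, padj_additivity = padj,
      additivity_state = ifelse(padj < alpha_fdr, "not_additive",
                                "consistent_with_additive"),
      power_flag = parents_state == "different" &
        mP > pmin(mA, mB) & mP < pmax(mA, mB))
  }
  results <- do.call(rbind, out)
  rownames(results) <- NULL
  counts <- as.data.frame(table(lineage = results$lineage,
                                parents_state = results$parents_state,
                                additivity_state = results$additivity_state),
                          responseName = "count")
  structure(list(results = results,
                 table = additivity_percentages(counts),
                 alpha_fdr = alpha_fdr, scale = scale),
            class = "additivity_result")
}

#' Percentages for a per-lineage additivity classification table
#'
#' Adds the percentage of each cell relative to its lineage total, rounded
#' half away from zero to one decimal — the arithmetic used for published
#' classification tables.
#'
#' @param counts data frame with columns `lineage`, `parents_state`
#'   (`same` / `different`), `additivity_state` (`not_additive` /
#'   `consistent_with_additive`) and `count`.
#' @return the same data frame, ordered, with a `pct` column.
#' @examples
#' counts <- data.frame(
#'   lineage = "L1",
#'   parents_state = c("same", "same", "different", "different"),
#'   additivity_state = rep(c("not_additive", "consistent_with_additive"), 2),
#'   count = c(2762, 1516, 787, 391))
#' additivity_percentages(counts)$pct  # 50.6 27.8 14.4 7.2
#' @export
additivity_percentages <- function(counts) {
  stopifnot(all(c("lineage", "parents_state", "additivity_state",
                  "count") %in% names(counts)))
  counts$count <- as.numeric(counts$count)
  tot <- tapply(counts$count, counts$lineage, sum)
  counts$pct <- round_half_away(100 * counts$count /
                                  as.numeric(tot[as.character(counts$lineage)]),
                                1)
  ord <- order(counts$lineage,
               match(counts$parents_state, c("same", "different")),
               match(counts$additivity_state,
                     c("not_additive", "consistent_with_additive")))
  counts <- counts[ord, c("lineage", "parents_state", "additivity_state",
                          "count", "pct")]
  rownames(counts) <- NULL
  counts
}

#' @export
print.additivity_result <- function(x, ...) {
  cat(sprintf("Mid-parent additivity classification (FDR %.2g, %s scale)\n",
              x$alpha_fdr, x$scale))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
summary.additivity_result <- function(object, ...) object$table
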
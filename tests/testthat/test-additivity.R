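## 20-sample layout matching the study design: 5 + 3 diploids, 4 lineages
## x 3 reps.
sim_design <- function(sim) data.frame(sample_id = sim$samples$sample_id,
                                       group = sim$samples$group)

test_that("low-expression filtering applies the CPM-in-enough-samples rule", {
  m <- matrix(0L, 3, 20,
              dimnames = list(c("hi", "border", "zero"), paste0("s", 1:20)))
  m["hi", ] <- 50L
  m["border", 1:10] <- 50L         # threshold reached in only 10 samples
  lib_target <- 1e6
  scale <- lib_target * 20 / sum(m)
  m <- round(m * scale)            # mean library size 1e6
  storage.mode(m) <- "integer"
  flt <- filter_low_expression(m, min_cpm = 10, min_samples = 11)
  expect_equal(rownames(flt$counts), "hi")
  expect_equal(flt$n_dropped, 2)
  expect_equal(flt$count_threshold, 10 * mean(colSums(m)) / 1e6)
  expect_error(filter_low_expression(m, min_samples = 25), "min_samples")
  ## default min_samples: 11 at 20 samples, ceiling(0.55 n) otherwise
  expect_equal(filter_low_expression(m)$min_samples, 11L)
  expect_equal(filter_low_expression(m[, 1:10, drop = FALSE])$min_samples,
               6L)
})

test_that("log2-CPM matches closed-form arithmetic and few-locus input falls back to unit weights", {
  m <- matrix(c(9L, 9L), 1, 2, dimnames = list("L1", c("s1", "s2")))
  lib <- 1e6 - 9
  m2 <- rbind(m, matrix(as.integer(lib), 1, 2,
                        dimnames = list("filler", NULL)))
  expect_warning(v <- transform_and_weight(m2), "weights")
  ## oracle: log2((9 + 0.5)/(1e6 + 1) * 1e6)
  expect_equal(v$E["L1", "s1"], log2(9.5 / (1e6 + 1) * 1e6),
               tolerance = 1e-9)
  expect_equal(abs(v$E["L1", "s1"] - 3.248) < 1e-3, TRUE)
  expect_true(all(v$weights == 1))
})

test_that("precision weights increase with mean when variance falls with mean", {
  set.seed(97)
  n <- 500; ns <- 12
  mu <- 2^seq(3, 12, length.out = n)
  ## dispersion falling with mean: strong mean-variance trend
  counts <- sapply(seq_len(ns), function(s)
    rnbinom(n, mu = mu, size = 0.5 + mu / 50))
  dimnames(counts) <- list(sprintf("g%03d", 1:n), sprintf("s%02d", 1:ns))
  v <- transform_and_weight(counts)
  w <- rowMeans(v$weights)
  expect_gt(cor(w, log2(mu), method = "spearman"), 0.8)
})

test_that("contrast fits recover exact mid-parent structure and the ordinary t-test", {
  ## zero-noise: polyploid = mid-parent exactly, on the log scale
  di <- data.frame(sample_id = c("a1", "a2", "b1", "b2", "p1", "p2"),
                   group = c("parent_A", "parent_A", "parent_B",
                             "parent_B", "P1", "P1"))
  E <- rbind(g1 = c(4, 4, 8, 8, 6, 6), g2 = c(5, 5, 5, 5, 5, 5))
  colnames(E) <- di$sample_id
  fit <- fit_contrasts(E, di, moderated = FALSE)
  expect_equal(unname(fit$coefficients[, "midparent_P1"]), c(0, 0))
  expect_equal(unname(fit$coefficients["g1", "parents"]), -4)

  ## single locus, equal weights: matches the textbook contrast t-test
  set.seed(103)
  y <- c(rnorm(2, 5), rnorm(2, 7), rnorm(2, 6.5))
  E1 <- matrix(y, 1, dimnames = list("g1", di$sample_id))
  f1 <- fit_contrasts(E1, di, moderated = FALSE)
  gm <- tapply(y, di$group, mean)
  s2 <- sum((y - gm[di$group])^2) / 3          # pooled, 3 df
  L <- gm[["P1"]] - 0.5 * gm[["parent_A"]] - 0.5 * gm[["parent_B"]]
  se <- sqrt(s2 * (1 / 2 + 0.25 * (1 / 2 + 1 / 2)))
  expect_equal(unname(f1$coefficients[, "midparent_P1"]), unname(L),
               tolerance = 1e-9)
  expect_equal(unname(f1$t[, "midparent_P1"]), unname(L / se),
               tolerance = 1e-9)
  expect_equal(unname(f1$p.value[, "midparent_P1"]),
               2 * pt(-abs(L / se), 3), tolerance = 1e-9)

  expect_error(fit_contrasts(E, data.frame(
    sample_id = di$sample_id,
    group = c("parent_A", "parent_A", "parent_B", "parent_B", "P1",
              "P2")), moderated = FALSE), "fewer than 2")
})

test_that("raw p-values are uniform under the null", {
  cfg <- simulation_config(n_loci = 2000, lib_size_mean = 4e5,
                           frac_parents_diff = 0, frac_nonadditive = 0,
                           frac_hse = 0, frac_lost = 0, frac_silenced = 0,
                           seed = 107)
  sim <- simulate_counts(cfg)
  m <- filter_low_expression(build_expression_matrix(sim$rna_counts))$counts
  di <- sim_design(sim)
  v <- transform_and_weight(m, design_matrix(di, colnames(m))$design)
  fit <- fit_contrasts(v, di, moderated = FALSE)
  frac <- mean(fit$p.value[, "parents"] < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(m))
  expect_lt(abs(frac - 0.05), 3 * se + 0.01)
})

test_that("published-style percentage arithmetic is reproduced exactly", {
  cells <- data.frame(
    lineage = rep(c("Cast_2", "Cast_10", "Cast_13", "Cast_31"), each = 4),
    parents_state = rep(c("same", "same", "different", "different"), 4),
    additivity_state = rep(c("not_additive", "consistent_with_additive"),
                           8),
    count = c(2762, 1516, 787, 391,
              2612, 1666, 757, 421,
              2515, 1763, 710, 468,
              2466, 1812, 744, 434))
  got <- additivity_percentages(cells)
  want <- c(Cast_2 = list(c(50.6, 27.8, 14.4, 7.2)),
            Cast_10 = list(c(47.9, 30.5, 13.9, 7.7)),
            Cast_13 = list(c(46.1, 32.3, 13.0, 8.6)),
            Cast_31 = list(c(45.2, 33.2, 13.6, 8.0)))
  for (l in names(want))
    expect_equal(got$pct[got$lineage == l], want[[l]])
  ## rounded percentages sum to ~100 per lineage
  sums <- tapply(got$pct, got$lineage, sum)
  expect_true(all(abs(sums - 100) <= 0.2))
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_away(0.15, 1), 0.2)
  expect_equal(round_half_away(-0.15, 1), -0.2)
  expect_equal(round_half_away(7.25, 1), 7.3)
})

test_that("BH adjustment within families matches a brute-force implementation", {
  set.seed(109)
  for (n in c(7, 100, 1000)) {
    p <- runif(n)^2
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("classification controls the null and detects planted non-additivity", {
  cfg <- simulation_config(n_loci = 900, lib_size_mean = 4e5,
                           frac_nonadditive = 0.4, beta_na = 1,
                           frac_hse = 0, frac_lost = 0, frac_silenced = 0,
                           seed = 113)
  sim <- simulate_counts(cfg)
  m <- filter_low_expression(build_expression_matrix(sim$rna_counts))$counts
  di <- sim_design(sim)
  v <- transform_and_weight(m, design_matrix(di, colnames(m))$design)
  cls <- classify_additivity(fit_contrasts(v, di))
  r <- merge(cls$results, sim$truth$loci, by.x = "locus",
             by.y = "core_id")
  sens <- with(r[r$additivity_state.y == "nonadditive", ],
               mean(additivity_state.x == "not_additive"))
  expect_gte(sens, 0.8)
  fpr <- with(r[r$additivity_state.y == "additive", ],
              mean(additivity_state.x == "not_additive"))
  expect_lte(fpr, 0.05 + 3 * sqrt(0.05 * 0.95 / sum(
    r$additivity_state.y == "additive")))
  ## the four cells partition the tested loci
  tab <- cls$table
  expect_equal(sum(tab$count[tab$lineage == "P1"]),
               length(unique(cls$results$locus)))
  ## power flag only where parents differ and the lineage mean is between
  pf <- cls$results[cls$results$power_flag, ]
  expect_true(all(pf$parents_state == "different"))
})

test_that("the additivity contrast is invariant to relabeling the parents", {
  cfg <- simulation_config(n_loci = 60, lib_size_mean = 1e5, seed = 127)
  sim <- simulate_counts(cfg)
  m <- filter_low_expression(build_expression_matrix(sim$rna_counts),
                             min_samples = 10)$counts
  di <- sim_design(sim)
  sw <- di
  sw$group[sw$group == "parent_A"] <- "tmp"
  sw$group[sw$group == "parent_B"] <- "parent_A"
  sw$group[sw$group == "tmp"] <- "parent_B"
  v <- transform_and_weight(m, design_matrix(di, colnames(m))$design)
  f1 <- fit_contrasts(v, di)
  f2 <- fit_contrasts(v, sw)
  expect_equal(f1$coefficients[, "midparent_P1"],
               f2$coefficients[, "midparent_P1"], tolerance = 1e-9)
  expect_equal(abs(f1$coefficients[, "parents"]),
               abs(f2$coefficients[, "parents"]), tolerance = 1e-9)
})
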
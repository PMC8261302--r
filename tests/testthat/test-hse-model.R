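test_that("the conjugate posterior matches closed-form Beta arithmetic", {
  ## flat case: prior returned untouched
  s0 <- posterior_q(0, 0, prior_mean = 0.5, concentration = 2)
  expect_equal(s0$mean, 0.5)
  expect_equal(s0$lo, qbeta(0.025, 1, 1))
  expect_equal(s0$hi, qbeta(0.975, 1, 1))

  s <- posterior_q(3, 1, prior_mean = 0.5, concentration = 2)
  expect_equal(s$mean, 4 / 6, tolerance = 1e-12)
  expect_equal(s$lo, qbeta(0.025, 4, 2))

  ## strong signal excludes 0.5 under every prior
  for (p0 in c(0.4, 0.5, 0.6)) {
    si <- posterior_q(90, 10, prior_mean = p0)
    expect_gt(si$lo, 0.5)
  }
  expect_error(posterior_q(5, 5, delta = 1.2, method = "closed"),
               "delta")
})

test_that("the grid posterior reproduces the conjugate posterior within 1e-3", {
  for (nA in c(1, 5, 40, 250, 2000, 10000)) {
    for (nB in c(2, 30, 900, 10000)) {
      for (p0 in c(0.4, 0.5, 0.6)) {
        g <- posterior_q(nA, nB, p0, method = "grid")
        cf <- posterior_q(nA, nB, p0, method = "closed")
        expect_lt(abs(g$mean - cf$mean), 1e-3)
        expect_lt(abs(g$lo - cf$lo), 1e-3)
        expect_lt(abs(g$hi - cf$hi), 1e-3)
      }
    }
  }
})

test_that("the posterior is symmetric and monotone in the count split", {
  set.seed(71)
  for (rep in 1:20) {
    nA <- rpois(1, 50); nB <- rpois(1, 50); p0 <- runif(1, 0.3, 0.7)
    a <- posterior_q(nA, nB, p0)
    b <- posterior_q(nB, nA, 1 - p0)
    expect_equal(a$mean, 1 - b$mean, tolerance = 1e-12)
    expect_equal(a$lo, 1 - b$hi, tolerance = 1e-12)
  }
  ## grid route mirrors too (within grid tolerance)
  g1 <- posterior_q(30, 10, 0.4, method = "grid")
  g2 <- posterior_q(10, 30, 0.6, method = "grid")
  expect_lt(abs(g1$mean - (1 - g2$mean)), 1e-3)
  ## monotone in n_A at fixed total
  means <- vapply(0:60, function(k) posterior_q(k, 60 - k)$mean, 1)
  expect_true(all(diff(means) > 0))
  ## bias-aware likelihood shifts the posterior toward parent B when
  ## assignment odds favoured A
  gb <- posterior_q(60, 40, 0.5, delta = 1.5)
  g0 <- posterior_q(60, 40, 0.5, delta = 1)
  expect_lt(gb$mean, g0$mean)
})

test_that("the three-prior decision rule applies as specified", {
  mk <- function(lo, hi, nA = 50, nB = 50)
    data.frame(prior_mean = c(0.4, 0.5, 0.6), lo = lo, hi = hi,
               n_A = nA, n_B = nB)
  expect_equal(decide_hse(mk(c(0.52, 0.51, 0.53), c(0.70, 0.69, 0.71))),
               "toward_A")
  expect_equal(decide_hse(mk(c(0.52, 0.49, 0.53), c(0.70, 0.69, 0.71))),
               "none")
  expect_equal(decide_hse(mk(c(0.30, 0.29, 0.31), c(0.45, 0.44, 0.46))),
               "toward_B")
  expect_equal(decide_hse(mk(c(0.52, 0.51, 0.53), c(0.70, 0.69, 0.71),
                             nA = 4, nB = 3)),
               "insufficient_data")
  expect_warning(v <- decide_hse(mk(c(0.52, 0.2, 0.53),
                                    c(0.70, 0.45, 0.71))),
                 "opposite")
  expect_equal(v, "none")
})

test_that("the three-prior rule is never less conservative than the central prior alone", {
  set.seed(73)
  priors <- hse_priors()
  for (rep in 1:200) {
    n <- rpois(1, 80) + 10
    nA <- rbinom(1, n, runif(1, 0.2, 0.8)); nB <- n - nA
    all3 <- decide_hse(do.call(rbind, lapply(c(0.4, 0.5, 0.6), function(p)
      posterior_q(nA, nB, p))))
    central <- decide_hse(posterior_q(nA, nB, 0.5))
    if (all3 %in% c("toward_A", "toward_B"))
      expect_equal(central, all3)
  }
})

test_that("mapping-bias flagging detects planted bias and spares clean COREs", {
  ## planted single-CORE example: A-origin (100, 0), B-origin (60, 40)
  counts <- data.frame(core_id = "c1",
                       sample_id = c("a1", "b1"),
                       n_A = c(100L, 60L), n_B = c(0L, 40L),
                       n_shared = 0L)
  species <- c(a1 = "A", b1 = "B")
  bv <- flag_biased_cores(counts, species)
  expect_true(bv$biased)
  ## oracle: Beta(c*pi0 + 160, c*(1-pi0) + 40) quantiles exclude 0.5
  for (p0 in c(0.4, 0.5, 0.6))
    expect_gt(qbeta(0.025, 2 * p0 + 160, 2 * (1 - p0) + 40), 0.5)
  expect_equal(bv$n_mix_A, 160); expect_equal(bv$n_mix_B, 40)

  ## symmetric mis-assignment: unbiased at large counts
  sym <- data.frame(core_id = "c1", sample_id = c("a1", "b1"),
                    n_A = c(900L, 100L), n_B = c(100L, 900L),
                    n_shared = 0L)
  expect_false(flag_biased_cores(sym, species)$biased)

  ## a species with zero diagnostic reads: retained but low power
  zero <- data.frame(core_id = "c1", sample_id = c("a1", "b1"),
                     n_A = c(500L, 0L), n_B = c(0L, 0L), n_shared = 0L)
  bz <- flag_biased_cores(zero, species)
  expect_equal(bz$verdict, "insufficient_data")
  expect_false(bz$biased)
  expect_true(bz$low_power)
})

test_that("bias flagging hits the planted sensitivity/specificity on simulated COREs", {
  cfg <- simulation_config(n_loci = 500, lib_size_mean = 5e5,
                           frac_bias = 0.1, delta = 1.5, frac_hse = 0,
                           seed = 79)
  sim <- simulate_counts(cfg)
  parts <- sim_parts(sim)
  bv <- flag_biased_cores(parts$dip_counts, parts$species)
  truth <- sim$truth$loci$biased[match(bv$core_id,
                                       sim$truth$loci$core_id)]
  expect_gte(mean(bv$biased[truth]), 0.8)
  expect_lte(mean(bv$biased[!truth]), 0.05)
  ## delta_hat estimates the planted odds multiplier
  expect_equal(median(bv$delta_hat[truth]), 1.5, tolerance = 0.1)
  expect_equal(median(bv$delta_hat[!truth]), 1.0, tolerance = 0.05)
})

test_that("HSE calling is sensitive, directionally accurate, and excludes biased COREs", {
  cfg <- simulation_config(n_loci = 600, lib_size_mean = 4e5,
                           frac_hse = 0.3, q_alt = 0.8, frac_lost = 0,
                           frac_silenced = 0, seed = 83)
  sim <- simulate_counts(cfg)
  parts <- sim_parts(sim)
  bv <- flag_biased_cores(parts$dip_counts, parts$species)
  calls <- call_hse(parts$poly_counts, bv, parts$lineage)
  ## excluded COREs never appear in toward/none tallies
  rep_tab <- hse_report(calls)
  excl <- unique(calls$core_id[calls$verdict == "excluded_biased"])
  tallied <- calls[calls$verdict %in% c("toward_A", "toward_B", "none"), ]
  expect_length(intersect(excl, tallied$core_id), 0)
  expect_equal(sum(rep_tab[rep_tab$lineage == "P1", c("toward_A",
                                                      "toward_B",
                                                      "none")]),
               sum(tallied$lineage == "P1"))
  ## truth-table comparison on tested COREs
  m <- merge(as.data.frame(tallied), sim$truth$lineage_q,
             by = c("core_id", "lineage"))
  called <- m$verdict != "none"
  expect_gte(mean(called[m$hse]), 0.9)
  hit <- m[m$hse & called, ]
  expect_gte(mean((hit$verdict == "toward_A") == (hit$true_q > 0.5)),
             0.99)
  ## on balanced loci each direction is called at most 5% of the time
  bal <- m[!m$hse, ]
  expect_lte(mean(bal$verdict == "toward_A"), 0.05)
  expect_lte(mean(bal$verdict == "toward_B"), 0.05)
})

test_that("lineages without replicates are rejected and labels validated", {
  counts <- data.frame(core_id = "c1", sample_id = "p1",
                       n_A = 5L, n_B = 5L, n_shared = 0L)
  expect_error(call_hse(counts, NULL, c(other = "P1")), "lineage")
  expect_error(flag_biased_cores(counts, c(p1 = "X")), "species")
})
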
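make_ref <- function(...) Biostrings::DNAStringSet(c(...))

test_that("the toy mapper places, rejects and discards reads as specified", {
  set.seed(41)
  ref <- make_ref(c1 = rand_dna(400), c2 = rand_dna(400))
  exact <- substr(as.character(ref[["c1"]]), 101, 200)
  four_mm <- mutate_dna(exact, sample(100, 4))
  reads <- Biostrings::DNAStringSet(c(hit = exact, miss = four_mm))
  m <- toy_map(reads, ref)
  expect_true(m$mapped[1] && !m$multi[1])
  expect_equal(m$contig[1], "c1")
  expect_equal(m$pos[1], 100L)
  expect_equal(m$mismatches[1], 0L)
  expect_false(m$mapped[2])

  ## reverse-complement placement
  rc <- Biostrings::reverseComplement(Biostrings::DNAStringSet(exact))
  names(rc) <- "rcread"
  mr <- toy_map(rc, ref)
  expect_true(mr$mapped[1])
  expect_equal(mr$strand[1], "-")
  expect_equal(mr$pos[1], 100L)

  ## two identical planted loci: discarded as multimapper
  dup <- make_ref(d1 = paste0(rand_dna(50), exact, rand_dna(50)),
                  d2 = paste0(rand_dna(50), exact, rand_dna(50)))
  md <- toy_map(Biostrings::DNAStringSet(c(r = exact)), dup)
  expect_true(md$mapped[1] && md$multi[1])
  expect_true(is.na(md$pos[1]))

  expect_error(toy_map(reads, Biostrings::DNAStringSet()), "empty")
})

test_that("read classification is total and matches a truth-table oracle", {
  ## enumerate all (state_A, state_B) x mismatch relations
  states <- c("unmapped", "unique", "multi")
  grid <- expand.grid(sA = states, sB = states,
                      rel = c("lt", "eq", "gt"),
                      stringsAsFactors = FALSE)
  mmA <- c(lt = 1L, eq = 2L, gt = 3L); mmB <- 2L
  oracle <- function(sA, sB, rel) {
    ## independent restatement of the rule
    if (sA == "unique" && sB == "unique")
      return(switch(rel, lt = "better_A", eq = "shared", gt = "better_B"))
    if (sA == "unique") return("better_A")
    if (sB == "unique") return("better_B")
    "unusable"
  }
  got <- classify_read(grid$sA != "unmapped", grid$sA == "multi",
                       ifelse(grid$sA == "unmapped", NA, mmA[grid$rel]),
                       grid$sB != "unmapped", grid$sB == "multi",
                       ifelse(grid$sB == "unmapped", NA, mmB))
  want <- mapply(oracle, grid$sA, grid$sB, grid$rel)
  expect_equal(got, unname(want))
  expect_true(all(got %in% c("better_A", "better_B", "shared",
                             "unusable")))
})

test_that("assignment counts match per-read origin bookkeeping on error-free reads", {
  cfg <- simulation_config(n_loci = 6, contig_len_range = c(250, 350),
                           snp_rate = 0.03, flank_len = 60, seed = 43)
  tx <- generate_parent_transcriptomes(cfg)
  rbh <- reciprocal_best_hits(tx$seqs_A, tx$seqs_B)
  cores <- delimit_cores(rbh, tx$seqs_A, tx$seqs_B)
  reads <- simulate_reads(tx$seqs_A, 250, read_len = 100, error_rate = 0,
                          seed = 3)
  aA <- toy_map(reads, tx$seqs_A); aB <- toy_map(reads, tx$seqs_B)
  res <- count_assignments(aA, aB, cores, sample_id = "dipA_1")

  ## oracle: per-read origin bookkeeping from simulator read IDs
  info <- parse_read_ids(names(reads))
  core_of <- setNames(seq_len(nrow(cores)), cores$contig_A)
  exp_A <- exp_shared <- setNames(integer(nrow(cores)), cores$core_id)
  snps <- tx$snps
  loci <- tx$loci
  for (k in seq_len(nrow(info))) {
    ci <- core_of[info$contig[k]]
    if (is.na(ci)) next
    s <- info$start[k]; e <- s + 100
    if (s < cores$start_A[ci] || e > cores$end_A[ci]) next
    locus <- loci$locus[match(info$contig[k], loci$contig_A)]
    covered <- sum(snps$locus == locus & snps$pos_A >= s &
                     snps$pos_A < e)
    ## a read over >= 1 SNP maps better to A; otherwise equally well
    id <- cores$core_id[ci]
    if (covered >= 1) exp_A[id] <- exp_A[id] + 1L
    else exp_shared[id] <- exp_shared[id] + 1L
  }
  expect_equal(res$counts$n_A, unname(exp_A[res$counts$core_id]))
  expect_equal(res$counts$n_shared,
               unname(exp_shared[res$counts$core_id]))
  expect_true(all(res$counts$n_B == 0))
  ## conservation: verdicts over contained reads sum to the totals
  expect_equal(sum(res$counts$n_A + res$counts$n_B + res$counts$n_shared),
               nrow(info) - unname(res$qc["n_outside_core"]) -
                 unname(res$qc["n_unusable"]))
})

test_that("boundary-straddling reads and unknown contigs are excluded", {
  set.seed(47)
  A <- make_ref(ca = rand_dna(300))
  cores <- data.frame(core_id = "c1", contig_A = "ca", contig_B = "cb",
                      start_A = 100L, end_A = 200L,
                      start_B = 100L, end_B = 200L)
  mk <- function(contig, pos, mapped = TRUE) {
    data.frame(read_id = "r1", mapped = mapped, multi = FALSE,
               contig = contig, pos = pos, strand = "+",
               mismatches = 0L, read_len = 50L)
  }
  inside <- count_assignments(mk("ca", 120L), mk("cb", NA, mapped = FALSE),
                              cores)
  expect_equal(inside$counts$n_A, 1L)
  straddle <- count_assignments(mk("ca", 180L),
                                mk("cb", NA, mapped = FALSE), cores)
  expect_equal(sum(straddle$counts[, 3:5]), 0L)
  expect_equal(unname(straddle$qc["n_outside_core"]), 1L)
  expect_message(
    unk <- count_assignments(mk("weird", 10L),
                             mk("cb", NA, mapped = FALSE), cores,
                             known_contigs = c("ca", "cb")),
    "unknown")
  expect_equal(unname(unk$qc["n_unknown_contig"]), 1L)
  ## CORE with zero overlapping reads reports (0,0,0)
  expect_equal(unlist(inside$counts[1, 3:5], use.names = FALSE) >= 0,
               c(TRUE, TRUE, TRUE))
})

test_that("with zero divergence no diploid read is parent-diagnostic", {
  cfg <- simulation_config(n_loci = 4, contig_len_range = c(200, 250),
                           snp_rate = 0, flank_len = 0, frac_hse = 0,
                           seed = 53)
  tx <- generate_parent_transcriptomes(cfg)
  cores <- delimit_cores(data.frame(contig_A = names(tx$seqs_A),
                                    contig_B = names(tx$seqs_B)),
                         tx$seqs_A, tx$seqs_B)
  reads <- simulate_reads(tx$seqs_A, 120, read_len = 80, error_rate = 0,
                          seed = 5)
  res <- count_assignments(toy_map(reads, tx$seqs_A),
                           toy_map(reads, tx$seqs_B), cores)
  expect_equal(sum(res$counts$n_A), 0L)
  expect_equal(sum(res$counts$n_B), 0L)
})

test_that("the expression matrix aggregates totals with stable labels", {
  counts <- data.frame(core_id = c("c1", "c1"), sample_id = c("s1", "s2"),
                       n_A = c(3L, 0L), n_B = c(2L, 0L),
                       n_shared = c(5L, 0L))
  m <- build_expression_matrix(counts)
  expect_equal(m["c1", "s1"], 10L)
  expect_equal(m["c1", "s2"], 0L)
  expect_error(build_expression_matrix(rbind(counts, counts[1, ])),
               "duplicate")
  ## simulator oracle: column means track the negative-binomial truth
  cfg <- simulation_config(n_loci = 400, lib_size_mean = 2e5,
                           frac_lost = 0, frac_silenced = 0,
                           frac_bias = 0, seed = 59)
  sim <- simulate_counts(cfg)
  mm <- build_expression_matrix(sim$rna_counts)
  muA <- sim$truth$loci$mean_A[match(rownames(mm),
                                     sim$truth$loci$core_id)]
  obs <- rowMeans(mm[, sim$samples$sample_id[sim$samples$group ==
                                               "parent_A"]])
  se <- sd(obs - muA) / sqrt(length(obs))
  expect_lt(abs(mean(obs - muA)), 3 * se + 1e-9)
})

test_that("SAM round-trip preserves alignments and missing NM tags error", {
  set.seed(61)
  ref <- make_ref(c1 = rand_dna(300))
  reads <- simulate_reads(ref, 40, read_len = 60, error_rate = 0.01,
                          seed = 7)
  aln <- toy_map(reads, ref)
  skip_if_not_installed("Rsamtools")
  f <- tempfile(fileext = ".sam")
  write_alignments_sam(aln, ref, f)
  back <- read_alignments_sam(f)
  back <- back[match(aln$read_id, back$read_id), ]
  expect_equal(back$mapped, aln$mapped & !aln$multi)
  keep <- back$mapped
  expect_equal(back$pos[keep], aln$pos[keep])
  expect_equal(back$mismatches[keep], aln$mismatches[keep])
  expect_equal(back$strand[keep], aln$strand[keep])

  bad <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:c1\tLN:300",
               "readX\t0\tc1\t10\t60\t5M\t*\t0\t0\tACGTA\t*"), bad)
  expect_error(read_alignments_sam(bad), "readX")
})
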
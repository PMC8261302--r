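#' Generate a pair of parental transcriptomes with known orthology
#'
#' For each locus a homologous core sequence is drawn, mutated at
#' `snp_rate` per base to obtain the second parent's ortholog, and flanked
#' on each side by independent random (non-homologous) sequence of
#' `flank_len` bp. The planted homologous interval and every SNP position
#' are recorded in the returned truth tables, so CORE delimitation and
#' read assignment can be checked against ground truth.
#'
#' @param config a [simulation_config()].
#' @param seed optional integer seed overriding `config$seed`.
#' @return a list with components
#'   \describe{
#'     \item{seqs_A, seqs_B}{`DNAStringSet` of parental contigs with IDs
#'       `locus<i>_A` / `locus<i>_B`;}
#'     \item{loci}{data frame with one row per locus: `locus`, `contig_A`,
#'       `contig_B`, `core_len`, `core_start`, `core_end` (0-based
#'       half-open; identical on both contigs by construction), `n_snp`;}
#'     \item{snps}{data frame of SNPs: `locus`, `core_pos` (0-based within
#'       the core), `pos_A`, `pos_B` (0-based contig coordinates),
#'       `base_A`, `base_B`.}
#'   }
#' @examples
#' tx <- generate_parent_transcriptomes(simulation_config(n_loci = 5), seed = 1)
#' tx$loci
#' @export
generate_parent_transcriptomes <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(if (is.null(seed)) config$seed else seed, {
    n <- config$n_loci
    bases <- c("A", "C", "G", "T")
    ## sample.int avoids the sample(x:x) scalar pitfall
    core_len <- config$contig_len_range[1] +
      sample.int(diff(config$contig_len_range) + 1L, n,
                 replace = TRUE) - 1L
    seq_A <- character(n); seq_B <- character(n)
    snp_list <- vector("list", n)
    for (i in seq_len(n)) {
      core <- sample(bases, core_len[i], replace = TRUE)
      core_b <- core
      if (config$snp_rate > 0) {
        mut <- which(runif(core_len[i]) < config$snp_rate)
        for (j in mut) core_b[j] <- sample(setdiff(bases, core[j]), 1L)
      } else mut <- integer(0)
      fl <- function() if (config$flank_len > 0)
        sample(bases, config$flank_len, replace = TRUE) else character(0)
      seq_A[i] <- paste(c(fl(), core, fl()), collapse = "")
      seq_B[i] <- paste(c(fl(), core_b, fl()), collapse = "")
      snp_list[[i]] <- if (length(mut))
        data.frame(locus = i, core_pos = mut - 1L,
                   pos_A = config$flank_len + mut - 1L,
                   pos_B = config$flank_len + mut - 1L,
                   base_A = core[mut], base_B = core_b[mut])
      else NULL
    }
    ids_A <- sprintf("locus%04d_A", seq_len(n))
    ids_B <- sprintf("locus%04d_B", seq_len(n))
    loci <- data.frame(locus = seq_len(n), contig_A = ids_A, contig_B = ids_B,
                       core_len = core_len,
                       core_start = config$flank_len,
                       core_end = config$flank_len + core_len,
                       n_snp = vapply(snp_list,
                                      function(x) if (is.null(x)) 0L else nrow(x),
                                      0L))
    snps <- do.call(rbind, snp_list)
    if (is.null(snps))
      snps <- data.frame(locus = integer(0), core_pos = integer(0),
                         pos_A = integer(0), pos_B = integer(0),
                         base_A = character(0), base_B = character(0))
    list(seqs_A = Biostrings::DNAStringSet(setNames(seq_A, ids_A)),
         seqs_B = Biostrings::DNAStringSet(setNames(seq_B, ids_B)),
         loci = loci, snps = snps)
  })
}

#' Simulate fixed-length reads from a set of contigs
#'
#' Reads are drawn uniformly over all valid start positions of the given
#' contigs (so longer contigs yield proportionally more reads), on a random
#' strand, with independent per-base substitution errors. Read IDs encode
#' the origin — `read<k>|<contig>|<start0>|<strand>` — so downstream
#' assignment can be checked read by read.
#'
#' @param seqs a `DNAStringSet` of origin contigs.
#' @param n_reads number of reads to draw.
#' @param read_len read length (bp).
#' @param error_rate per-base substitution error probability.
#' @param seed optional integer seed.
#' @return a `DNAStringSet` of reads; origin metadata is recoverable with
#'   [parse_read_ids()].
#' @export
simulate_reads <- function(seqs, n_reads, read_len = 100L,
                           error_rate = 0.005, seed = NULL) {
  stopifnot(inherits(seqs, "DNAStringSet"), n_reads >= 1)
  widths <- Biostrings::width(seqs)
  if (read_len > min(widths))
    stop_named("read_len (%d) exceeds the shortest contig (%d bp)",
               as.integer(read_len), min(widths))
  with_seed(seed, {
    nstart <- widths - read_len + 1L
    idx <- sample.int(length(seqs), n_reads, replace = TRUE,
                      prob = nstart / sum(nstart))
    start <- vapply(idx, function(i) sample.int(nstart[i], 1L), 1L)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    reads <- Biostrings::subseq(seqs[idx], start = start,
                                width = read_len)
    reads <- as.character(reads)
    if (error_rate > 0) {
      bases <- c("A", "C", "G", "T")
      n_err <- rbinom(n_reads, read_len, error_rate)
      for (k in which(n_err > 0)) {
        pos <- sample.int(read_len, n_err[k])
        chars <- strsplit(reads[k], "")[[1]]
        for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
        reads[k] <- paste(chars, collapse = "")
      }
    }
    reads <- Biostrings::DNAStringSet(reads)
    rc <- strand == "-"
    if (any(rc)) reads[rc] <- Biostrings::reverseComplement(reads[rc])
    names(reads) <- sprintf("read%06d|%s|%d|%s", seq_len(n_reads),
                            names(seqs)[idx], start - 1L, strand)
    reads
  })
}

#' Recover read origin from simulated read IDs
#'
#' @param ids character vector of IDs produced by [simulate_reads()].
#' @return data frame with `read_id`, `contig`, `start` (0-based),
#'   `strand`.
#' @export
parse_read_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  data.frame(read_id = ids,
             contig = vapply(parts, `[`, "", 2L),
             start = as.integer(vapply(parts, `[`, "", 3L)),
             strand = vapply(parts, `[`, "", 4L))
}

#' Write sequences to FASTA
#'
#' @param seqs a `DNAStringSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file as a DNAStringSet
#'
#' @param path FASTA file.
#' @return `DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)
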
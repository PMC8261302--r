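#' Reciprocal-best-hit ortholog pairs between two assemblies
#'
#' Identifies putative ortholog pairs: `(a, b)` is reported iff `b` is the
#' highest-scoring local-alignment hit of `a` in assembly B and vice versa,
#' with best score at least `min_score` over an aligned length of at least
#' `min_len`. Ties are broken by the lexicographically smallest partner ID,
#' so the output is deterministic. An exact-k-mer seeding step (shared
#' k-mer count) restricts the all-vs-all alignment to plausible candidate
#' pairs, as seeded aligners do; sequences shorter than `kmer` are aligned
#' against everything.
#'
#' @param seqs_A,seqs_B named `DNAStringSet`s (unique IDs required).
#' @param scoring an [alignment_scoring()] list.
#' @param min_score minimum best local alignment score.
#' @param min_len minimum aligned length (bp on the query).
#' @param kmer seed k-mer length.
#' @param min_shared_kmers minimum shared-k-mer count for a candidate pair.
#' @return data frame with one row per ortholog pair: `contig_A`,
#'   `contig_B`, `score`, `identity`, sorted by `contig_A`.
#' @export
reciprocal_best_hits <- function(seqs_A, seqs_B,
                                 scoring = alignment_scoring(),
                                 min_score = 80, min_len = 100,
                                 kmer = 11L, min_shared_kmers = 2L) {
  stopifnot(length(seqs_A) > 0, length(seqs_B) > 0)
  if (anyDuplicated(names(seqs_A)) || anyDuplicated(names(seqs_B)) ||
      is.null(names(seqs_A)) || is.null(names(seqs_B)))
    stop_named("sequence IDs must be present and unique in both assemblies")

  cand <- candidate_pairs(seqs_A, seqs_B, kmer, min_shared_kmers)
  if (nrow(cand) == 0)
    return(data.frame(contig_A = character(0), contig_B = character(0),
                      score = numeric(0), identity = numeric(0)))

  ## score every candidate pair once (SW score is symmetric in the pair)
  res <- vector("list", length(unique(cand$a)))
  k <- 0
  for (ai in unique(cand$a)) {
    bs <- cand$b[cand$a == ai]
    hit <- align_local(as.character(seqs_A[[ai]]), seqs_B[bs], scoring)
    k <- k + 1
    res[[k]] <- data.frame(a = ai, b = bs, score = hit$score,
                           alen = hit$q_end - hit$q_start,
                           identity = hit$identity)
  }
  res <- do.call(rbind, res)
  res <- res[res$score >= min_score & res$alen >= min_len, , drop = FALSE]
  if (nrow(res) == 0)
    return(data.frame(contig_A = character(0), contig_B = character(0),
                      score = numeric(0), identity = numeric(0)))

  ids_A <- names(seqs_A); ids_B <- names(seqs_B)
  best_of <- function(group_idx, partner_ids) {
    ## index of the row with max score, ties to lexicographically
    ## smallest partner ID
    vapply(split(seq_len(nrow(res)), group_idx), function(rows) {
      sc <- res$score[rows]
      top <- rows[sc == max(sc)]
      top[order(partner_ids[top])][1L]
    }, 1L)
  }
  best_a <- best_of(res$a, ids_B[res$b])   # per A contig: its best B hit
  best_b <- best_of(res$b, ids_A[res$a])   # per B contig: its best A hit
  mutual <- intersect(best_a, best_b)
  out <- data.frame(contig_A = ids_A[res$a[mutual]],
                    contig_B = ids_B[res$b[mutual]],
                    score = res$score[mutual],
                    identity = res$identity[mutual])
  out[order(out$contig_A), , drop = FALSE]
}

## Shared-k-mer candidate pairs (indices into seqs_A / seqs_B).
candidate_pairs <- function(seqs_A, seqs_B, kmer, min_shared) {
  kmers_of <- function(s) {
    if (nchar(s) < kmer) return(character(0))
    unique(substring(s, 1:(nchar(s) - kmer + 1),
                     kmer:nchar(s)))
  }
  sa <- as.character(seqs_A); sb <- as.character(seqs_B)
  kb <- lapply(sb, kmers_of)
  index <- split(rep(seq_along(sb), lengths(kb)), unlist(kb))
  out <- vector("list", length(sa))
  for (i in seq_along(sa)) {
    ka <- kmers_of(sa[i])
    if (length(ka) == 0) {               # too short to seed: try all
      out[[i]] <- data.frame(a = i, b = seq_along(sb))
      next
    }
    hits <- unlist(index[intersect(ka, names(index))], use.names = FALSE)
    if (length(hits) == 0) next
    tab <- tabulate(hits, nbins = length(sb))
    bs <- which(tab >= min_shared)
    if (length(bs)) out[[i]] <- data.frame(a = i, b = bs)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) return(data.frame(a = integer(0), b = integer(0)))
  do.call(rbind, out)
}

#' Delimit common orthologous regions (COREs)
#'
#' For each ortholog pair the CORE is the query/subject interval of the
#' single highest-scoring local alignment between the two contigs (no HSP
#' chaining). Pairs whose best alignment falls below `min_score` or
#' `min_len` are dropped with a message. GC content is computed on each
#' CORE subsequence.
#'
#' @param pairs data frame with columns `contig_A`, `contig_B` (e.g. from
#'   [reciprocal_best_hits()]).
#' @param seqs_A,seqs_B named `DNAStringSet`s holding the contigs.
#' @param scoring an [alignment_scoring()] list.
#' @param min_score,min_len thresholds for a qualifying alignment.
#' @return data frame of class `core_set`: `core_id`, `contig_A`,
#'   `contig_B`, `start_A`, `end_A`, `start_B`, `end_B` (0-based
#'   half-open), `len_A`, `len_B`, `gc_A`, `gc_B`, `score`, `identity`.
#' @export
delimit_cores <- function(pairs, seqs_A, seqs_B,
                          scoring = alignment_scoring(),
                          min_score = 80, min_len = 100) {
  stopifnot(all(c("contig_A", "contig_B") %in% names(pairs)))
  n <- nrow(pairs)
  rows <- vector("list", n)
  dropped <- character(0)
  for (i in seq_len(n)) {
    a <- pairs$contig_A[i]; b <- pairs$contig_B[i]
    hit <- align_local(as.character(seqs_A[[a]]), seqs_B[b], scoring)
    if (hit$score < min_score || (hit$q_end - hit$q_start) < min_len) {
      dropped <- c(dropped, sprintf("%s/%s (score %.0f, len %d)",
                                    a, b, hit$score,
                                    hit$q_end - hit$q_start))
      next
    }
    sub_a <- Biostrings::subseq(seqs_A[a], hit$q_start + 1L, hit$q_end)
    sub_b <- Biostrings::subseq(seqs_B[b], hit$s_start + 1L, hit$s_end)
    rows[[i]] <- data.frame(
      core_id = NA_character_, contig_A = a, contig_B = b,
      start_A = hit$q_start, end_A = hit$q_end,
      start_B = hit$s_start, end_B = hit$s_end,
      len_A = hit$q_end - hit$q_start, len_B = hit$s_end - hit$s_start,
      gc_A = gc_fraction(sub_a), gc_B = gc_fraction(sub_b),
      score = hit$score, identity = hit$identity)
  }
  if (length(dropped))
    message("dropped ", length(dropped), " pair(s) with no qualifying ",
            "alignment: ", paste(head(dropped, 5), collapse = "; "),
            if (length(dropped) > 5) " ..." else "")
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(core_id = character(0), contig_A = character(0),
                      contig_B = character(0), start_A = integer(0),
                      end_A = integer(0), start_B = integer(0),
                      end_B = integer(0), len_A = integer(0),
                      len_B = integer(0), gc_A = numeric(0),
                      gc_B = numeric(0), score = numeric(0),
                      identity = numeric(0))
  else out$core_id <- sprintf("core%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("core_set", "data.frame")
  out
}

#' Check CORE similarity between the two parents
#'
#' Reports per-CORE absolute length and GC-content differences between the
#' two sides and how many exceed the given thresholds. COREs are never
#' removed; this is a reporting/QC step.
#'
#' @param cores a `core_set` from [delimit_cores()].
#' @param max_len_diff flag threshold for `|len_A - len_B|` (bp).
#' @param max_gc_diff flag threshold for `|gc_A - gc_B|`.
#' @return list with `per_core` (data frame: `core_id`, `len_diff`,
#'   `gc_diff`, `len_flag`, `gc_flag`), `n_len_flagged`, `n_gc_flagged`.
#' @export
validate_cores <- function(cores, max_len_diff = 16, max_gc_diff = 0.02) {
  stopifnot(nrow(cores) > 0)
  per <- data.frame(core_id = cores$core_id,
                    len_diff = abs(cores$len_A - cores$len_B),
                    gc_diff = abs(cores$gc_A - cores$gc_B))
  per$len_flag <- per$len_diff > max_len_diff
  per$gc_flag <- per$gc_diff > max_gc_diff
  list(per_core = per, n_len_flagged = sum(per$len_flag),
       n_gc_flagged = sum(per$gc_flag))
}

#' Write COREs as BED6 (one file per parent)
#'
#' Standard BED: 0-based half-open coordinates, `name` = core_id, `score`
#' = alignment score capped at 1000, strand `+`.
#'
#' @param cores a `core_set`.
#' @param path_A,path_B output BED paths for the parent-A and parent-B
#'   coordinate systems.
#' @return invisibly, `c(path_A, path_B)`.
#' @export
write_core_bed <- function(cores, path_A, path_B) {
  bed <- function(contig, start, end) {
    data.frame(chrom = contig, start = start, end = end,
               name = cores$core_id,
               score = pmin(1000L, as.integer(round(cores$score))),
               strand = "+")
  }
  write.table(bed(cores$contig_A, cores$start_A, cores$end_A), path_A,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(bed(cores$contig_B, cores$start_B, cores$end_B), path_B,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(path_A, path_B))
}

#' Read a BED6 file of CORE intervals
#'
#' @param path BED file written by [write_core_bed()] (or any BED6).
#' @return data frame: `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_core_bed <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  names(bed) <- c("chrom", "start", "end", "name", "score",
                  "strand")[seq_len(ncol(bed))]
  bed
}
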
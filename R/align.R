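## Local alignment wrapper. The engine is Smith-Waterman local alignment
## with blastn-like affine-gap scoring; defaults: match +1, mismatch -3,
## gap open -5, gap extend -2.

#' Default alignment scoring scheme
#'
#' @param match match reward (positive).
#' @param mismatch mismatch penalty (negative).
#' @param gap_open gap-opening penalty (negative).
#' @param gap_extend gap-extension penalty (negative).
#' @return a named list used by [local_align()], [reciprocal_best_hits()]
#'   and [delimit_cores()].
#' @export
alignment_scoring <- function(match = 1, mismatch = -3, gap_open = -5,
                              gap_extend = -2) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0)
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

subst_matrix <- function(scoring) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- scoring$match
  m["N", ] <- scoring$mismatch; m[, "N"] <- scoring$mismatch
  m
}

## One-vs-many local alignment; returns a data.frame of intervals
## (0-based half-open), scores and identities.
align_local <- function(pattern, subjects, scoring) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = rep(Biostrings::DNAStringSet(pattern), length(subjects)),
    subject = subjects, type = "local",
    substitutionMatrix = subst_matrix(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  pr <- Biostrings::pattern(aln); sr <- Biostrings::subject(aln)
  data.frame(
    score = Biostrings::score(aln),
    q_start = Biostrings::start(pr) - 1L, q_end = Biostrings::end(pr),
    s_start = Biostrings::start(sr) - 1L, s_end = Biostrings::end(sr),
    identity = Biostrings::nmatch(aln) /
      pmax(1L, Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) +
             Biostrings::nindel(aln)@insertion[, "WidthSum"] +
             Biostrings::nindel(aln)@deletion[, "WidthSum"]))
}

#' Best local alignment between two sequences
#'
#' @param a,b DNA sequences (character or `DNAString`-compatible).
#' @param scoring an [alignment_scoring()] list.
#' @return one-row data frame: `score`, `q_start`, `q_end`, `s_start`,
#'   `s_end` (0-based half-open intervals on `a` and `b`), `identity`
#'   (fraction of aligned columns that match).
#' @examples
#' local_align("ACGTACGT", "TTACGTACGTTT")
#' @export
local_align <- function(a, b, scoring = alignment_scoring()) {
  align_local(as.character(a), Biostrings::DNAStringSet(as.character(b)),
              scoring)
}
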
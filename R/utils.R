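## Small shared helpers.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published tables in this field are
#' almost always rounded half away from zero, so percentage reports use this
#' rule.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_away(0.15, 1)  # 0.2, where round(0.15, 1) gives 0.1
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a data frame as TSV
#'
#' All inter-stage tables are plain TSV for diffability.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

## GC fraction of a character or DNAStringSet sequence interval.
gc_fraction <- function(seq) {
  if (!inherits(seq, "DNAStringSet")) seq <- Biostrings::DNAStringSet(seq)
  f <- Biostrings::alphabetFrequency(seq, baseOnly = TRUE)
  tot <- rowSums(f[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- rowSums(f[, c("C", "G"), drop = FALSE])
  ifelse(tot == 0, NA_real_, gc / tot)
}

## Deterministic seed handling: set.seed(seed) when non-NULL.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
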
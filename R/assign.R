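#' Map reads to a reference with a minimal ungapped mapper
#'
#' A deliberately simple end-to-end (ungapped) mapper for synthetic
#' fixtures: each read is placed at the position minimizing its mismatch
#' count over all contigs and both strands. A read is reported mapped iff
#' its best placement has at most `max_mismatch` mismatches, and is
#' discarded as a multimapper iff two or more placements tie at the best
#' mismatch count across the whole reference. Real alignments from a
#' production mapper are accepted through [read_alignments_sam()].
#'
#' @param reads named `DNAStringSet` of equal-length reads.
#' @param reference named `DNAStringSet` of contigs.
#' @param max_mismatch maximum mismatches for a valid placement.
#' @return data frame with one row per read: `read_id`, `mapped`, `multi`,
#'   `contig`, `pos` (0-based start), `strand`, `mismatches`, `read_len`.
#'   Multimapped reads have `mapped = TRUE`, `multi = TRUE` and carry no
#'   usable position (`contig`/`pos` are `NA`).
#' @export
toy_map <- function(reads, reference, max_mismatch = 3L) {
  if (length(reference) == 0) stop_named("empty reference")
  stopifnot(inherits(reads, "DNAStringSet"),
            inherits(reference, "DNAStringSet"))
  n <- length(reads)
  out <- data.frame(read_id = names(reads), mapped = FALSE, multi = FALSE,
                    contig = NA_character_, pos = NA_integer_,
                    strand = NA_character_, mismatches = NA_integer_,
                    read_len = Biostrings::width(reads))
  ref_chars <- names(reference)
  for (i in seq_len(n)) {
    best_mm <- max_mismatch + 1L
    hits <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") reads[[i]] else
        Biostrings::reverseComplement(reads[[i]])
      m <- Biostrings::vmatchPattern(pat, reference,
                                     max.mismatch = max_mismatch)
      for (j in seq_along(reference)) {
        st <- Biostrings::startIndex(m)[[j]]
        if (is.null(st) || length(st) == 0) next
        st <- st[st >= 1 & st + length(pat) - 1L <=
                   Biostrings::width(reference)[j]]
        if (length(st) == 0) next
        mm <- vapply(st, function(s)
          Biostrings::neditStartingAt(pat, reference[[j]], starting.at = s,
                                      with.indels = FALSE), 1L)
        keep <- mm <= max_mismatch
        if (any(keep))
          hits[[length(hits) + 1L]] <-
            data.frame(contig = ref_chars[j], pos = st[keep] - 1L,
                       strand = strand, mm = mm[keep])
      }
    }
    if (length(hits) == 0) next
    hits <- do.call(rbind, hits)
    best_mm <- min(hits$mm)
    ties <- hits[hits$mm == best_mm, , drop = FALSE]
    out$mapped[i] <- TRUE
    out$mismatches[i] <- best_mm
    if (nrow(ties) > 1L) {
      out$multi[i] <- TRUE
    } else {
      out$contig[i] <- ties$contig[1]
      out$pos[i] <- ties$pos[1]
      out$strand[i] <- ties$strand[1]
    }
  }
  out
}

#' Classify a read from its alignments against both parental references
#'
#' Vectorized total classification. A side is *usable* when the read maps
#' uniquely there. With both sides usable the verdict follows the mismatch
#' comparison (`better_A` / `better_B` / `shared` on a tie); with exactly
#' one usable side the verdict defers to that side (a read unique on one
#' reference and unmapped or multimapping on the other is diagnostic for
#' the mapped side); with neither side usable the read is `unusable`.
#'
#' @param mapped_A,multi_A,mm_A logical, logical, integer vectors for the
#'   parent-A alignment (mismatch count may be `NA` when unmapped).
#' @param mapped_B,multi_B,mm_B same for parent B.
#' @return character vector in `better_A`, `better_B`, `shared`,
#'   `unusable`.
#' @examples
#' classify_read(TRUE, FALSE, 1L, TRUE, FALSE, 3L)  # "better_A"
#' @export
classify_read <- function(mapped_A, multi_A, mm_A,
                          mapped_B, multi_B, mm_B) {
  usable_A <- mapped_A & !multi_A
  usable_B <- mapped_B & !multi_B
  out <- rep("unusable", length(usable_A))
  both <- usable_A & usable_B
  out[both & mm_A < mm_B] <- "better_A"
  out[both & mm_A > mm_B] <- "better_B"
  out[both & mm_A == mm_B] <- "shared"
  out[usable_A & !usable_B] <- "better_A"
  out[usable_B & !usable_A] <- "better_B"
  out
}

#' Count parent-diagnostic and shared reads per CORE
#'
#' Joins the per-read alignments against the two parental references,
#' classifies every read with [classify_read()], and counts reads per CORE.
#' A read contributes iff on every reference where it mapped uniquely its
#' full alignment interval is contained in the CORE interval of that
#' contig, and the COREs agree across sides. Reads straddling a CORE
#' boundary, or mapped outside any CORE on a side they use, are excluded.
#'
#' @param alignments_A,alignments_B data frames in the layout of
#'   [toy_map()] for the same reads against parents A and B.
#' @param cores a `core_set` from [delimit_cores()] (or an equivalent data
#'   frame with `core_id`, `contig_A/B`, `start_A/B`, `end_A/B`).
#' @param sample_id label recorded in the output.
#' @param known_contigs optional character vector of valid contig IDs;
#'   alignments referencing other contigs are skipped and tallied.
#' @return list with `counts` (data frame `core_id, sample_id, n_A, n_B,
#'   n_shared`, one row per CORE including zero-count COREs) and `qc`
#'   (named tallies: reads seen, unusable, outside any CORE, unknown
#'   contig).
#' @export
count_assignments <- function(alignments_A, alignments_B, cores,
                              sample_id = "sample", known_contigs = NULL) {
  a <- alignments_A; b <- alignments_B
  stopifnot(identical(sort(a$read_id), sort(b$read_id)))
  b <- b[match(a$read_id, b$read_id), , drop = FALSE]

  qc <- c(n_reads = nrow(a), n_unknown_contig = 0L, n_unusable = 0L,
          n_outside_core = 0L)
  if (!is.null(known_contigs)) {
    bad <- (!is.na(a$contig) & !(a$contig %in% known_contigs)) |
      (!is.na(b$contig) & !(b$contig %in% known_contigs))
    if (any(bad)) {
      message(sum(bad), " alignment(s) reference unknown contigs; skipped")
      qc["n_unknown_contig"] <- sum(bad)
      a <- a[!bad, , drop = FALSE]; b <- b[!bad, , drop = FALSE]
    }
  }
  verdict <- classify_read(a$mapped, a$multi, a$mismatches,
                           b$mapped, b$multi, b$mismatches)
  qc["n_unusable"] <- sum(verdict == "unusable")

  ## CORE containing a read interval on a given side ("" when none)
  core_on <- function(aln, contig_col, start_col, end_col) {
    idx <- match(aln$contig, cores[[contig_col]])
    ok <- !is.na(idx) & !is.na(aln$pos) &
      aln$pos >= cores[[start_col]][idx] &
      (aln$pos + aln$read_len) <= cores[[end_col]][idx]
    ifelse(ok, cores$core_id[idx], NA_character_)
  }
  core_A <- core_on(a, "contig_A", "start_A", "end_A")
  core_B <- core_on(b, "contig_B", "start_B", "end_B")

  use_A <- a$mapped & !a$multi
  use_B <- b$mapped & !b$multi
  ok <- verdict != "unusable" &
    (!use_A | !is.na(core_A)) & (!use_B | !is.na(core_B)) &
    (!(use_A & use_B) | core_A == core_B)
  ok[is.na(ok)] <- FALSE
  core <- ifelse(use_A, core_A, core_B)
  qc["n_outside_core"] <- sum(verdict != "unusable" & !ok)

  counts <- data.frame(core_id = cores$core_id, sample_id = sample_id,
                       n_A = 0L, n_B = 0L, n_shared = 0L)
  if (any(ok)) {
    tab <- table(factor(core[ok], levels = cores$core_id),
                 factor(verdict[ok],
                        levels = c("better_A", "better_B", "shared")))
    counts$n_A <- as.integer(tab[, "better_A"])
    counts$n_B <- as.integer(tab[, "better_B"])
    counts$n_shared <- as.integer(tab[, "shared"])
  }
  list(counts = counts, qc = qc)
}

#' Build the homoeolog-agnostic expression matrix
#'
#' @param assignment_counts data frame `core_id, sample_id, n_A, n_B,
#'   n_shared` covering all samples (e.g. `rna_counts` from
#'   [simulate_counts()], or stacked [count_assignments()] outputs).
#' @return integer matrix of total counts (`n_A + n_B + n_shared`), COREs
#'   in rows and samples in columns, both sorted.
#' @export
build_expression_matrix <- function(assignment_counts) {
  ac <- assignment_counts
  if (anyDuplicated(ac[c("core_id", "sample_id")]))
    stop_named("duplicate (core_id, sample_id) records in counts")
  loci <- sort(unique(ac$core_id)); samp <- sort(unique(ac$sample_id))
  m <- matrix(0L, length(loci), length(samp),
              dimnames = list(loci, samp))
  m[cbind(match(ac$core_id, loci), match(ac$sample_id, samp))] <-
    as.integer(ac$n_A + ac$n_B + ac$n_shared)
  m
}

#' Read alignments from a SAM/BAM file
#'
#' Accepts production alignments in the standard format. Every mapped
#' record must carry an `NM` tag (edit distance); records lacking it stop
#' with an error naming the read. Secondary alignments (flag 0x100) mark a
#' read as multimapping.
#'
#' @param path SAM or BAM file (SAM is converted on the fly; requires the
#'   Rsamtools package).
#' @return data frame in the layout of [toy_map()].
#' @export
read_alignments_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop_named("reading SAM/BAM requires the Rsamtools package")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "qwidth"),
                               tag = "NM")
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !bitwAnd(rec$flag, 4L)
  secondary <- bitwAnd(rec$flag, 256L) > 0
  nm <- rec$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(rec$qname))
  rec$tag$NM <- nm
  if (any(mapped & !secondary & is.na(nm))) {
    bad <- rec$qname[mapped & !secondary & is.na(nm)][1]
    stop_named("SAM record for read '%s' lacks the required NM tag", bad)
  }
  multi_ids <- unique(rec$qname[secondary])
  prim <- !secondary
  data.frame(read_id = rec$qname[prim],
             mapped = mapped[prim],
             multi = rec$qname[prim] %in% multi_ids,
             contig = ifelse(mapped[prim],
                             as.character(rec$rname[prim]), NA),
             pos = ifelse(mapped[prim], rec$pos[prim] - 1L, NA),
             strand = ifelse(mapped[prim],
                             ifelse(bitwAnd(rec$flag[prim], 16L) > 0,
                                    "-", "+"), NA),
             mismatches = ifelse(mapped[prim], rec$tag$NM[prim], NA),
             read_len = rec$qwidth[prim])
}

#' Write alignments as a minimal SAM file
#'
#' Intended for small text fixtures: emits a valid header and one primary
#' record per read with an `NM` tag (ungapped CIGAR).
#'
#' @param alignments data frame in the layout of [toy_map()].
#' @param reference named `DNAStringSet` used for `@SQ` header lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(alignments, reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                     Biostrings::width(reference)), con)
  a <- alignments
  seq_placeholder <- vapply(a$read_len, function(w)
    paste(rep("N", w), collapse = ""), "")
  mapped <- a$mapped & !a$multi & !is.na(a$pos)
  flag <- ifelse(mapped, ifelse(!is.na(a$strand) & a$strand == "-",
                                16L, 0L), 4L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
                   a$read_id, flag,
                   ifelse(mapped, a$contig, "*"),
                   ifelse(mapped, a$pos + 1L, 0L),
                   ifelse(mapped, 60L, 0L),
                   ifelse(mapped, sprintf("%dM", a$read_len), "*"),
                   seq_placeholder,
                   ifelse(mapped, sprintf("\tNM:i:%d", a$mismatches), ""))
  writeLines(lines, con)
  invisible(path)
}
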
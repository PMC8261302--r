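#' Classify homoeolog fate from DNA and RNA evidence
#'
#' A homoeolog with DNA-capture reads and RNA reads is present and
#' *expressed*; DNA without RNA is putatively *silenced*; neither is
#' putative *loss*; RNA without DNA likely reflects a *failed* capture or
#' mismapped reads. Vectorized; thresholds default to a single read, the
#' most literal reading of "mapped reads", and are exposed for robustness
#' analysis. Fates should be assessed on the unbiased CORE set.
#'
#' @param dna_count,rna_count non-negative read counts per homoeolog.
#' @param min_dna,min_rna presence thresholds (reads).
#' @return character vector in `expressed`, `silenced`, `lost`, `failed`.
#' @examples
#' classify_fate(c(3, 5, 0, 0), c(12, 0, 0, 7))
#' @export
classify_fate <- function(dna_count, rna_count, min_dna = 1L,
                          min_rna = 1L) {
  if (any(dna_count < 0) || any(rna_count < 0))
    stop_named("negative counts are not valid")
  dna <- dna_count >= min_dna
  rna <- rna_count >= min_rna
  ifelse(dna & rna, "expressed",
         ifelse(dna & !rna, "silenced",
                ifelse(!dna & rna, "failed", "lost")))
}

#' Per-lineage homoeolog fate calls
#'
#' Pools polyploid RNA diagnostic counts per lineage (the parent-A
#' homoeolog's RNA evidence is `n_A`, parent-B's is `n_B`), joins the
#' DNA-capture counts, restricts to unbiased COREs when bias verdicts are
#' given, and classifies every homoeolog with [classify_fate()].
#'
#' @param polyploid_counts data frame `core_id, sample_id, n_A, n_B`.
#' @param dna_counts data frame `core_id, lineage, parent, dna_count`.
#' @param sample_lineage named vector or data frame (`sample_id`,
#'   `lineage`) for the polyploid samples.
#' @param bias_verdicts optional [flag_biased_cores()] output; biased
#'   COREs are dropped.
#' @param min_dna,min_rna presence thresholds.
#' @return data frame of class `fate_calls`: `core_id`, `lineage`,
#'   `parent`, `dna_count`, `rna_count`, `fate`.
#' @export
call_fates <- function(polyploid_counts, dna_counts, sample_lineage,
                       bias_verdicts = NULL, min_dna = 1L, min_rna = 1L) {
  if (is.data.frame(sample_lineage))
    sample_lineage <- setNames(sample_lineage$lineage,
                               sample_lineage$sample_id)
  lin <- sample_lineage[polyploid_counts$sample_id]
  if (anyNA(lin)) stop_named("polyploid sample(s) missing a lineage label")
  if (!is.null(bias_verdicts)) {
    keep <- !(dna_counts$core_id %in%
                bias_verdicts$core_id[bias_verdicts$biased])
    dna_counts <- dna_counts[keep, , drop = FALSE]
  }
  key <- interaction(polyploid_counts$core_id, lin, drop = FALSE)
  rna_A <- tapply(polyploid_counts$n_A, key, sum)
  rna_B <- tapply(polyploid_counts$n_B, key, sum)
  dkey <- paste(dna_counts$core_id, dna_counts$lineage, sep = ".")
  rna <- ifelse(dna_counts$parent == "A",
                rna_A[dkey], rna_B[dkey])
  rna[is.na(rna)] <- 0
  out <- data.frame(core_id = dna_counts$core_id,
                    lineage = dna_counts$lineage,
                    parent = dna_counts$parent,
                    dna_count = dna_counts$dna_count,
                    rna_count = as.numeric(rna))
  out$fate <- classify_fate(out$dna_count, out$rna_count, min_dna,
                            min_rna)
  rownames(out) <- NULL
  class(out) <- c("fate_calls", "data.frame")
  out
}

#' Tabulate fates per lineage and parent of origin
#'
#' @param fates a `fate_calls` data frame.
#' @return data frame: `lineage`, `parent`, `expressed`, `silenced`,
#'   `lost`, `failed` (counts).
#' @export
fate_table <- function(fates) {
  t <- table(interaction(fates$lineage, fates$parent, sep = "/"),
             factor(fates$fate,
                    levels = c("expressed", "silenced", "lost", "failed")))
  key <- do.call(rbind, strsplit(rownames(t), "/", fixed = TRUE))
  out <- data.frame(lineage = key[, 1], parent = key[, 2],
                    expressed = as.integer(t[, "expressed"]),
                    silenced = as.integer(t[, "silenced"]),
                    lost = as.integer(t[, "lost"]),
                    failed = as.integer(t[, "failed"]))
  out[order(out$parent, out$lineage), ]
}

#' @export
print.fate_calls <- function(x, ...) {
  cat("Homoeolog fate calls:", nrow(x), "homoeolog x lineage records\n")
  print(fate_table(x), row.names = FALSE)
  invisible(x)
}

#' Exclusive set intersections (UpSet semantics)
#'
#' For every non-empty combination of the named sets, counts the elements
#' belonging to *exactly* that combination (the bar heights of an UpSet
#' plot), ordered by decreasing count then lexicographic combination
#' label.
#'
#' @param sets named list (>= 2) of vectors of element IDs.
#' @return list of class `intersection_report`: `exclusive` (data frame
#'   `combination` — set names joined by `&` — and `count`), `set_totals`,
#'   `union_size`, `all_way` (size of the intersection of all sets).
#' @examples
#' exclusive_intersections(list(x = c("a", "b", "c"), y = c("b", "c"),
#'                              z = c("b", "c", "d")))
#' @export
exclusive_intersections <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)),
            all(nzchar(names(sets))))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL,
                                                               names(sets)))
  pattern <- apply(member, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  tab <- table(pattern)
  excl <- data.frame(combination = names(tab),
                     count = as.integer(tab))
  excl <- excl[order(-excl$count, excl$combination), , drop = FALSE]
  rownames(excl) <- NULL
  structure(list(exclusive = excl,
                 set_totals = vapply(sets, function(s)
                   length(unique(s)), 1L),
                 union_size = length(universe),
                 all_way = sum(rowSums(member) == length(sets))),
            class = "intersection_report")
}

#' @export
print.intersection_report <- function(x, ...) {
  cat(sprintf("Exclusive intersections over %d sets (union %d, all-way %d)\n",
              length(x$set_totals), x$union_size, x$all_way))
  print(head(x$exclusive, 12), row.names = FALSE)
  invisible(x)
}

#' Convergence of homoeolog fates across independent lineages
#'
#' For each fate state and parent of origin, compares the per-lineage sets
#' of homoeologs in that state: per-lineage totals, the size of the
#' all-lineage intersection, the union, and two overlap fractions —
#' intersection/union and intersection/min(set sizes) — since either
#' denominator is defensible for "percent shared".
#'
#' @param fates a `fate_calls` data frame covering >= 2 lineages over a
#'   common CORE universe.
#' @return data frame: `fate`, `parent`, `n_lineages`, per-lineage
#'   minimum/maximum set size, `intersection`, `union`,
#'   `frac_of_union`, `frac_of_min`.
#' @export
convergence_summary <- function(fates) {
  lineages <- unique(fates$lineage)
  if (length(lineages) < 2)
    stop_named("need fate calls for at least 2 lineages")
  universes <- lapply(lineages, function(l)
    unique(fates$core_id[fates$lineage == l]))
  common <- Reduce(intersect, universes)
  if (length(common) == 0)
    stop_named("lineages have disjoint CORE universes")
  rows <- list()
  for (p in unique(fates$parent)) {
    for (st in c("expressed", "silenced", "lost", "failed")) {
      sets <- lapply(lineages, function(l)
        fates$core_id[fates$lineage == l & fates$parent == p &
                        fates$fate == st])
      sizes <- lengths(sets)
      inter <- length(Reduce(intersect, sets))
      uni <- length(unique(unlist(sets)))
      rows[[length(rows) + 1L]] <- data.frame(
        fate = st, parent = p, n_lineages = length(lineages),
        min_size = min(sizes), max_size = max(sizes),
        intersection = inter, union = uni,
        frac_of_union = if (uni > 0) inter / uni else NA_real_,
        frac_of_min = if (min(sizes) > 0) inter / min(sizes) else
          NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Degree and clustering summary of an undirected simple graph
#'
#' @param n_nodes total node count (isolated nodes allowed and counted).
#' @param edge_list two-column matrix or data frame of node IDs
#'   (integers in `1:n_nodes` or character labels); self-loops and
#'   duplicate edges are rejected.
#' @return list of class `network_summary`: `n_nodes`, `n_edges`,
#'   `avg_degree` (2E/N, also reported rounded to two decimals as
#'   `avg_degree_2dp`), `avg_clustering` (mean local clustering
#'   coefficient, 0 for degree < 2 nodes).
#' @examples
#' network_summary(787, cbind(1:185, 186 + 1:185))$avg_degree_2dp  # 0.47
#' @export
network_summary <- function(n_nodes, edge_list) {
  el <- as.matrix(edge_list)
  if (nrow(el) > 0) {
    if (any(el[, 1] == el[, 2]))
      stop_named("self-loops are not allowed")
    key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    if (anyDuplicated(key)) stop_named("duplicate edges are not allowed")
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  if (is.numeric(el)) {
    g <- igraph::make_graph(t(el), n = n_nodes, directed = FALSE)
  } else {
    verts <- unique(c(as.character(el)))
    extra <- n_nodes - length(verts)
    if (extra < 0) stop_named("n_nodes smaller than the labelled nodes")
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (extra > 0) g <- igraph::add_vertices(g, extra)
  }
  lc <- igraph::transitivity(g, type = "local", isolates = "zero")
  avg_deg <- 2 * nrow(el) / n_nodes
  structure(list(n_nodes = as.integer(n_nodes), n_edges = nrow(el),
                 avg_degree = avg_deg,
                 avg_degree_2dp = round_half_away(avg_deg, 2),
                 avg_clustering = mean(lc)),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("Network: %d nodes, %d edges; average degree %.2f; average local clustering %.3f\n",
              x$n_nodes, x$n_edges, x$avg_degree_2dp, x$avg_clustering))
  invisible(x)
}

#' Read an edge list from a two-column TSV
#'
#' @param path TSV with two columns of node IDs (no header).
#' @return two-column character matrix.
#' @export
read_edge_list <- function(path) {
  el <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  as.matrix(el[, 1:2])
}
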
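## Independent oracles used to cross-check the implementation. These are
## deliberately naive (quadratic/cubic, enumerative) and share no code with
## the package internals.

## Full affine-gap Smith-Waterman with traceback; gap of length L costs
## open + extend * L, matching the package's scoring convention.
sw_oracle <- function(a, b, match = 1, mismatch = -3, gap_open = 5,
                      gap_extend = 2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)      # best ending in a match/mismatch
  X <- matrix(-Inf, n + 1, m + 1)   # gap in b (consume a)
  Y <- matrix(-Inf, n + 1, m + 1)   # gap in a (consume b)
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], X[i - 1, j - 1],
                                Y[i - 1, j - 1]))
      if (M[i, j] > best) { best <- M[i, j]; bi <- i; bj <- j }
    }
  }
  ## traceback from (bi, bj) through M until a zero cell
  i <- bi; j <- bj; state <- "M"
  while (i > 1 && j > 1) {
    if (state == "M") {
      if (M[i, j] == 0) break
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      prev <- M[i, j] - s
      state <- if (isTRUE(all.equal(prev, M[i - 1, j - 1]))) "M"
      else if (isTRUE(all.equal(prev, X[i - 1, j - 1]))) "X" else "Y"
      i <- i - 1; j <- j - 1
    } else if (state == "X") {
      state <- if (isTRUE(all.equal(X[i, j],
                                    M[i - 1, j] - gap_open - gap_extend)))
        "M" else "X"
      i <- i - 1
    } else {
      state <- if (isTRUE(all.equal(Y[i, j],
                                    M[i, j - 1] - gap_open - gap_extend)))
        "M" else "Y"
      j <- j - 1
    }
  }
  list(score = best, q_start = i - 1, q_end = bi - 1,
       s_start = j - 1, s_end = bj - 1)   # 0-based half-open
}

## Brute-force Benjamini-Hochberg adjusted p-values.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- prev
  }
  adj
}

## Brute-force exclusive intersection counts by membership pattern.
exclusive_oracle <- function(sets) {
  universe <- unique(unlist(sets))
  pat <- vapply(universe, function(e)
    paste(names(sets)[vapply(sets, function(s) e %in% s, TRUE)],
          collapse = "&"), "")
  as.list(table(pat))
}

## Brute-force average local clustering coefficient (triangle counting).
clustering_oracle <- function(n_nodes, edges) {
  adj <- matrix(FALSE, n_nodes, n_nodes)
  adj[edges] <- TRUE; adj[edges[, 2:1]] <- TRUE
  lc <- numeric(n_nodes)
  for (v in seq_len(n_nodes)) {
    nb <- which(adj[v, ])
    k <- length(nb)
    if (k < 2) { lc[v] <- 0; next }
    tri <- 0
    for (x in seq_along(nb)) for (y in seq_len(x - 1))
      if (adj[nb[x], nb[y]]) tri <- tri + 1
    lc[v] <- 2 * tri / (k * (k - 1))
  }
  mean(lc)
}

## Random DNA string.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

## Mutate a DNA string at given 1-based positions (to a different base).
mutate_dna <- function(s, pos) {
  ch <- strsplit(s, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

## Count character mismatches between equal-length strings.
str_mismatches <- function(x, y) {
  mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
         x, y, USE.NAMES = FALSE)
}

## Split a sim into diploid/polyploid count subsets with label maps.
sim_parts <- function(sim) {
  s <- sim$samples
  dip <- s[s$group %in% c("parent_A", "parent_B"), ]
  poly <- s[!s$group %in% c("parent_A", "parent_B"), ]
  list(dip_counts = sim$rna_counts[sim$rna_counts$sample_id %in%
                                     dip$sample_id, ],
       poly_counts = sim$rna_counts[sim$rna_counts$sample_id %in%
                                      poly$sample_id, ],
       species = setNames(ifelse(dip$group == "parent_A", "A", "B"),
                          dip$sample_id),
       lineage = setNames(poly$lineage, poly$sample_id))
}
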
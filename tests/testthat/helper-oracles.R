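# Independent brute-force oracles and small fixture builders. The bond
# table here is written down from the pairing rules directly (G-C 3, A-U 2,
# G-U 1, A-C 1) and shares no code with the package implementation.

oracle_bonds <- function(b1, b2) {
  key <- paste(sort(c(b1, b2)), collapse = "")
  switch(key, "CG" = 3L, "AU" = 2L, "GU" = 1L, "AC" = 1L, 0L)
}

# per-duplex bond total by an explicit position loop, miRNA reversed
oracle_duplex_bonds <- function(mirna, window) {
  m <- rev(strsplit(mirna, "")[[1]])
  w <- strsplit(window, "")[[1]]
  stopifnot(length(m) == length(w))
  total <- 0L
  paired <- 0L
  for (i in seq_along(w)) {
    b <- oracle_bonds(w[i], m[i])
    total <- total + b
    paired <- paired + (b > 0L)
  }
  list(bonds = total, paired = paired)
}

oracle_max_bonds <- function(mirna) {
  ch <- strsplit(mirna, "")[[1]]
  sum(ifelse(ch %in% c("G", "C"), 3L, 2L))
}

# score every window, filter by ratio threshold; returns start positions
oracle_scan_starts <- function(mirna, tx, threshold, mode = "bonds") {
  m <- nchar(mirna)
  L <- nchar(tx)
  if (L < m) return(integer(0))
  keep <- integer(0)
  for (s in seq_len(L - m + 1)) {
    d <- oracle_duplex_bonds(mirna, substr(tx, s, s + m - 1))
    ratio <- if (mode == "bonds") {
      100 * d$bonds / oracle_max_bonds(mirna)
    } else {
      100 * d$paired / m
    }
    if (ratio >= threshold) keep <- c(keep, s)
  }
  keep
}

# connected components of the interval overlap graph via igraph
oracle_cluster_membership <- function(start, len) {
  n <- length(start)
  end <- start + len - 1L
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    start[i] <= end[j] & start[j] <= end[i]
  })
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# minimal sites tibble for interval-level tests
make_sites <- function(start, length, gene = "G", mirna_id = NULL,
                       region = "5UTR", dG = -120, ratio_pct = 92) {
  tibble::tibble(
    mirna_id = mirna_id %||% sprintf("m%02d", seq_along(start)),
    gene = gene, start = as.integer(start), length = as.integer(length),
    dG = dG, ratio_pct = ratio_pct, region = region
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a 22-nt miRNA plus a window pairing at exactly `paired` positions
# (unpaired positions mutated to zero-bond bases, away from the ends)
window_with_paired <- function(mirna, paired) {
  L <- nchar(mirna)
  w <- strsplit(reverse_complement(mirna), "")[[1]]
  opp <- rev(strsplit(mirna, "")[[1]])
  kill <- seq(3, length.out = L - paired)
  nonpair <- c(A = "G", C = "U", G = "A", U = "C")
  for (i in kill) {
    cand <- nonpair[[opp[i]]]
    if (cand == w[i]) cand <- switch(opp[i], A = "A", C = "C", G = "G",
                                     U = "U")
    w[i] <- cand
  }
  paste(w, collapse = "")
}
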
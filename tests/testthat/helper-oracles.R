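# Independent oracles used to cross-check the implementation. These are
# deliberately naive re-derivations (full pairwise distance matrices,
# Floyd-Warshall shortest paths) that share no code with the package
# internals.

# Naive Hamming distance matrix via character comparison.
oracle_hamming_matrix <- function(bcs) {
  n <- length(bcs)
  ch <- strsplit(bcs, "")
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(ch[[i]] != ch[[j]])
    }
  }
  d
}

# Greedy centroid absorption recomputed from the full distance matrix.
oracle_collapse <- function(counts, max_dist = 1) {
  ord <- order(-as.numeric(counts), names(counts))
  bcs <- names(counts)[ord]
  cts <- as.numeric(counts)[ord]
  d <- oracle_hamming_matrix(bcs)
  taken <- logical(length(bcs))
  res <- numeric(0)
  for (i in seq_along(bcs)) {
    if (taken[i]) next
    members <- which(!taken & d[i, ] <= max_dist)
    taken[members] <- TRUE
    res[bcs[i]] <- sum(cts[members])
  }
  res <- res[order(-res, names(res))]
  stats::setNames(as.integer(res), names(res))
}

# All-pairs shortest paths by Floyd-Warshall on an adjacency matrix.
oracle_shortest_paths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d
}

# Random symmetric similarity matrix with unit diagonal.
random_similarity <- function(n) {
  s <- matrix(stats::runif(n * n), n, n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(paste0("mc", seq_len(n)), paste0("mc", seq_len(n)))
  s
}

# Adjacency matrix of a MetacellGraph, indexed like its node order.
graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  adj <- matrix(0L, n, n, dimnames = list(graph$nodes, graph$nodes))
  for (r in seq_len(nrow(graph$edges))) {
    a <- graph$edges[r, 1]
    b <- graph$edges[r, 2]
    adj[a, b] <- 1L
    adj[b, a] <- 1L
  }
  adj
}

# Assemble a read from a flank pair and an insert.
make_read <- function(insert, pair = 1, flanks = amplicon_flanks()) {
  paste0(flanks$flank5[pair], insert, flanks$flank3[pair])
}

qual_string <- function(len, phred = 37) {
  strrep(intToUtf8(phred + 33), len)
}
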
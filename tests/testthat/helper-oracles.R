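# Test oracles used across files.

# Build the tree encoded by a Prufer sequence (nodes 1..n, n = length + 2).
# Enumerating all n^(n-2) sequences enumerates all labeled spanning trees,
# giving a brute-force MST oracle for small n.
prufer_tree <- function(seq, n) {
  degree <- rep(1L, n)
  for (v in seq) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (i in seq_along(seq)) {
    leaf <- which(degree == 1L)[1L]
    edges[i, ] <- c(leaf, seq[i])
    degree[leaf] <- degree[leaf] - 1L
    degree[seq[i]] <- degree[seq[i]] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

# Minimum total spanning-tree length by exhaustive Prufer enumeration (n <= 8).
brute_force_mst_length <- function(D) {
  n <- nrow(D)
  stopifnot(n <= 8L)
  if (n == 2L) return(D[1L, 2L])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (i in seq_len(nrow(seqs))) {
    e <- prufer_tree(seqs[i, ], n)
    best <- min(best, sum(D[e]))
  }
  best
}

tree_total_length <- function(edges) sum(edges[, "length"])

# Two well-separated Gaussian blobs in 2-D.
two_blobs <- function(n_per, gap = 10, sd = 1, seed = 1) {
  set.seed(seed)
  rbind(cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
        cbind(rnorm(n_per, gap, sd), rnorm(n_per, gap, sd)))
}

tiny_panel <- function() {
  panel(channel_def("A", "M1", "phenotype"),
        channel_def("B", "M2", "phenotype"),
        channel_def("C", "M3", "biosynthesis"))
}

barcode_channel_defs_for_test <- function(m = 6L) {
  do.call(rbind, lapply(seq_len(m), function(i)
    channel_def(paste0("bc", i), paste0("Pd", 101 + i), "barcode")))
}

tiny_table <- function(values, transformed = FALSE, labels = NULL) {
  event_table(values, tiny_panel()[seq_len(ncol(values)), , drop = FALSE],
              labels = labels, transformed = transformed)
}
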
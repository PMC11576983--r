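# Shared fixtures, all generated in code.

# A small labeled pair of graph datasets for loop-level tests.
tiny_pair <- function(n = 40L, seed = 5L, shift = "edge_density", mag = 0.5) {
  make_graph_shift_pair(shift_spec(
    n_per_domain = n, shift_kind = shift, shift_magnitude = mag,
    base_edge_prob = 0.2, seed = seed))
}

# A couple of hand-built graphs with a uniform 3-dim feature space.
toy_graphs <- function() {
  g1 <- graph(matrix(c(1, 0, 0,
                       0, 1, 0,
                       0, 0, 1), 3, 3, byrow = TRUE),
              rbind(c(1, 2), c(2, 3)), label = 0L)
  g2 <- graph(matrix(c(1, 0, 0,
                       0, 1, 0,
                       0, 0, 1,
                       1, 1, 0), 4, 3, byrow = TRUE),
              rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)), label = 1L)
  list(g1, g2)
}

# Dense oracle for D^{-1/2}(A + I)D^{-1/2}, optionally edge-weighted.
dense_norm_adj <- function(n, edges, w = NULL) {
  A <- matrix(0, n, n)
  if (nrow(edges) > 0L) {
    if (is.null(w)) w <- rep(1, nrow(edges))
    for (i in seq_len(nrow(edges))) {
      A[edges[i, 1L], edges[i, 2L]] <- A[edges[i, 1L], edges[i, 2L]] + w[i]
      A[edges[i, 2L], edges[i, 1L]] <- A[edges[i, 2L], edges[i, 1L]] + w[i]
    }
  }
  A <- A + diag(n)
  d <- rowSums(A)
  diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d))
}

# A random small graph as (n, edges) with every edge kept once.
random_small_graph <- function(n, p = 0.4) {
  pairs <- t(utils::combn(n, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  list(n = n, edges = pairs[keep, , drop = FALSE])
}

# Single-node graphs whose feature IS a point in R^d: lets the adaptation
# machinery run on plain vector data (readout of one node = its embedding).
points_as_graphs <- function(X, labels = NULL) {
  lapply(seq_len(nrow(X)), function(i) {
    graph(matrix(X[i, ], 1L), NULL,
          label = if (is.null(labels)) NULL else labels[i])
  })
}
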
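# Seeded synthetic benchmarks with a known invariant mechanism.
#
# Graph task: the class of every graph is decided solely by a planted motif
# (a distinct wiring on `motif_size` nodes: a ring plus `class` chords), and
# the Erdos-Renyi background is the nuisance that carries the domain shift
# (denser background, rewired background, or shifted nuisance features).
# Node task: two stochastic-block-model networks with identical block
# structure; the target's features and/or densities are perturbed.

#' Specification of a paired source/target benchmark
#'
#' @param task `"graph"` or `"node"`.
#' @param n_per_domain graphs per domain (graph task) or nodes per network.
#' @param n_classes number of classes (graph task: at most the number of
#'   distinct chord sets on the motif, `choose(motif_size, 2) - motif_size + 1`).
#' @param motif_size nodes of the planted motif (graph task, default 6).
#' @param shift_kind `"none"`, `"edge_density"`, `"structure_noise"` or
#'   `"feature_shift"`.
#' @param shift_magnitude non-negative shift size: edge-density multiplies
#'   the background edge probability by `1 + magnitude`; structure-noise
#'   rewires each background edge with probability `magnitude`;
#'   feature-shift adds `magnitude` to the nuisance feature block.
#' @param base_edge_prob background edge probability (default 0.20).
#' @param feature_dim nuisance feature dimension (graph task: one-hot
#'   categories, default 8).
#' @param seed integer seed; the pair is fully determined by the spec.
#' @export
shift_spec <- function(task = c("graph", "node"), n_per_domain = 300L,
                       n_classes = 2L, motif_size = 6L,
                       shift_kind = c("none", "edge_density", "structure_noise",
                                      "feature_shift"),
                       shift_magnitude = 0.5, base_edge_prob = 0.20,
                       feature_dim = 8L, seed = 1L) {
  task <- match.arg(task); shift_kind <- match.arg(shift_kind)
  stopifnot(shift_magnitude >= 0, n_classes >= 2L)
  if (shift_kind == "none") shift_magnitude <- 0
  list(task = task, n_per_domain = as.integer(n_per_domain),
       n_classes = as.integer(n_classes), motif_size = as.integer(motif_size),
       shift_kind = shift_kind, shift_magnitude = shift_magnitude,
       base_edge_prob = base_edge_prob, feature_dim = as.integer(feature_dim),
       seed = as.integer(seed))
}

# Motif wiring for class `cl` of `n_classes` (0-based): a ring on m nodes
# plus an evenly graded number of chords, so class 0 is the bare ring and
# the top class the complete graph K_m. Distinct classes differ strongly in
# local degree structure and wiring density inside the motif block — a
# signal a message-passing encoder can register.
.motif_edges <- function(m, cl, n_classes) {
  stopifnot(m >= 4L)
  ring <- cbind(seq_len(m), c(seq_len(m)[-1L], 1L))
  ring <- cbind(pmin(ring[, 1L], ring[, 2L]), pmax(ring[, 1L], ring[, 2L]))
  all_pairs <- t(utils::combn(m, 2L))
  key <- function(e) paste(e[, 1L], e[, 2L])
  chords <- all_pairs[!(key(all_pairs) %in% key(ring)), , drop = FALSE]
  n_chords <- if (n_classes == 1L) 0L else {
    as.integer(round(cl / (n_classes - 1L) * nrow(chords)))
  }
  if (cl >= 1L && n_chords == 0L) n_chords <- cl  # force distinct wirings
  if (n_chords > nrow(chords)) stop("shift_spec: too many classes for this motif size")
  rbind(ring, chords[seq_len(n_chords), , drop = FALSE])
}

# One benchmark graph; returns the graph plus the planted motif edge rows.
.make_motif_graph <- function(cl, spec, p_bg, rewire, feat_shift, seed) {
  set.seed(seed)
  n <- sample(10:20, 1L)
  m <- spec$motif_size
  if (m > n) stop("shift_spec: motif_size exceeds the minimum graph size")
  # background ER on all n nodes, excluding pairs inside the motif block
  pairs <- t(utils::combn(n, 2L))
  inside <- pairs[, 2L] <= m  # both endpoints in the motif block (1..m)
  keep <- stats::runif(nrow(pairs)) < p_bg & !inside
  bg <- pairs[keep, , drop = FALSE]
  if (rewire > 0 && nrow(bg) > 0L) {
    for (i in seq_len(nrow(bg))) {
      if (stats::runif(1L) < rewire) {
        repeat {
          cand <- sort(sample.int(n, 2L))
          if (cand[2L] > m) break  # keep the motif block untouched
        }
        bg[i, ] <- cand
      }
    }
    bg <- unique(bg)
  }
  motif <- .motif_edges(m, cl, spec$n_classes)
  edges <- rbind(motif, bg)
  # drop background duplicates of motif edges
  key <- paste(edges[, 1L], edges[, 2L])
  edges <- edges[!duplicated(key), , drop = FALSE]
  n_motif <- nrow(motif)
  # nuisance one-hot category per node: features carry no class signal, the
  # planted structure alone decides the label
  cats <- sample.int(spec$feature_dim, n, replace = TRUE)
  X <- matrix(0, n, spec$feature_dim)
  X[cbind(seq_len(n), cats)] <- 1
  if (feat_shift != 0) {
    half <- seq.int(spec$feature_dim %/% 2 + 1L, spec$feature_dim)
    X[, half] <- X[, half] + feat_shift
  }
  list(graph = graph(X, edges, label = cl), motif_rows = seq_len(n_motif))
}

.domain_graphs <- function(spec, domain_seed, p_bg, rewire, feat_shift) {
  npc <- spec$n_per_domain %/% spec$n_classes
  labels <- rep(0:(spec$n_classes - 1L), each = npc)
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    out[[i]] <- .make_motif_graph(labels[i], spec, p_bg, rewire, feat_shift,
                                  derive_seed(domain_seed, i))
  }
  out
}

#' Generate a paired graph-classification benchmark with known shift
#'
#' The source is labeled; the target's labels are hidden (kept in
#' `hidden_labels` for evaluation only). Per-graph planted-motif edge rows
#' are attached as the `motif_truth` attribute of each dataset.
#'
#' @param spec a [shift_spec()] with `task = "graph"`.
#' @return list with `source` and `target` [domain_dataset()]s.
#' @export
make_graph_shift_pair <- function(spec) {
  stopifnot(spec$task == "graph")
  p_src <- spec$base_edge_prob
  p_tgt <- p_src; rewire <- 0; fshift <- 0
  if (spec$shift_kind == "edge_density") p_tgt <- p_src * (1 + spec$shift_magnitude)
  if (spec$shift_kind == "structure_noise") rewire <- spec$shift_magnitude
  if (spec$shift_kind == "feature_shift") fshift <- spec$shift_magnitude
  src <- .domain_graphs(spec, derive_seed(spec$seed, 1001L), p_src, 0, 0)
  tgt <- .domain_graphs(spec, derive_seed(spec$seed, 2002L), p_tgt, rewire, fshift)
  source <- domain_dataset(lapply(src, `[[`, "graph"), "source", TRUE)
  target <- domain_dataset(lapply(tgt, `[[`, "graph"), "target", FALSE)
  attr(source, "motif_truth") <- lapply(src, `[[`, "motif_rows")
  attr(target, "motif_truth") <- lapply(tgt, `[[`, "motif_rows")
  source$spec <- spec; target$spec <- spec
  list(source = source, target = target)
}

#' Planted-motif edge rows per graph
#'
#' @param dataset a dataset produced by [make_graph_shift_pair()].
#' @return list of integer vectors: the rows of each graph's edge matrix
#'   that belong to the planted motif.
#' @export
motif_edge_ground_truth <- function(dataset) {
  truth <- attr(dataset, "motif_truth")
  if (is.null(truth)) stop("motif_edge_ground_truth: dataset lacks generation metadata")
  truth
}

#' Generate a paired node-classification benchmark
#'
#' Two stochastic-block-model networks whose blocks are the classes;
#' class-conditional Gaussian features. The target's feature means are
#' shifted by `shift_magnitude` (feature shift) or its block densities
#' perturbed (edge-density / structure-noise shifts).
#'
#' @param spec a [shift_spec()] with `task = "node"`.
#' @param p_in,p_out within/between block edge probabilities.
#' @param class_sep distance between consecutive class feature means.
#' @return list with `source` and `target` [domain_dataset()]s (each one
#'   network whose nodes carry labels; target labels hidden).
#' @export
make_node_shift_pair <- function(spec, p_in = 0.10, p_out = 0.02,
                                 class_sep = 2) {
  stopifnot(spec$task == "node")
  if (spec$n_classes > spec$n_per_domain) {
    stop("make_node_shift_pair: more classes than nodes")
  }
  gen <- function(dom_seed, p_in_d, p_out_d, mean_shift) {
    set.seed(dom_seed)
    n <- spec$n_per_domain
    sizes <- rep(n %/% spec$n_classes, spec$n_classes)
    sizes[seq_len(n - sum(sizes))] <- sizes[seq_len(n - sum(sizes))] + 1L
    blocks <- rep(0:(spec$n_classes - 1L), sizes)
    pairs <- t(utils::combn(n, 2L))
    same <- blocks[pairs[, 1L]] == blocks[pairs[, 2L]]
    p <- ifelse(same, p_in_d, p_out_d)
    edges <- pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
    mu <- matrix(0, spec$n_classes, spec$feature_dim)
    for (cl in seq_len(spec$n_classes)) {
      mu[cl, ((cl - 1L) %% spec$feature_dim) + 1L] <- class_sep
    }
    X <- mu[blocks + 1L, , drop = FALSE] +
      matrix(stats::rnorm(n * spec$feature_dim), n) + mean_shift
    graph(X, edges, node_labels = blocks)
  }
  din <- p_in; dout <- p_out; mshift <- 0
  if (spec$shift_kind == "edge_density") {
    din <- p_in * (1 + spec$shift_magnitude)
    dout <- p_out * (1 + spec$shift_magnitude)
  }
  if (spec$shift_kind == "structure_noise") {
    dout <- p_out + (p_in - p_out) * spec$shift_magnitude  # blur the blocks
  }
  if (spec$shift_kind == "feature_shift") mshift <- spec$shift_magnitude
  src <- gen(derive_seed(spec$seed, 3003L), p_in, p_out, 0)
  tgt <- gen(derive_seed(spec$seed, 4004L), din, dout, mshift)
  hidden <- tgt$node_labels
  tgt$node_labels <- NULL
  source <- domain_dataset(list(src), "source", TRUE)
  target <- domain_dataset(list(tgt), "target", FALSE, hidden_labels = hidden)
  source$spec <- spec; target$spec <- spec
  list(source = source, target = target)
}
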
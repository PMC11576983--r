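# Graph containers, TUDataset flat-file IO, batching, normalized adjacency.

#' Construct an attributed graph
#'
#' A graph is a list with a numeric feature matrix (one row per node), an
#' integer edge matrix with one row per undirected edge (each edge stored
#' once, 1-based node indices), an optional graph-level class label and
#' optional per-node labels for node-level tasks.
#'
#' @param node_features numeric matrix, `n_nodes x d`.
#' @param edges integer matrix with two columns, or NULL/empty for an
#'   edgeless graph. Duplicate undirected edges and self loops are rejected.
#' @param label optional integer class label (0-based classes).
#' @param node_labels optional integer vector of length `n_nodes`.
#' @return an object of class `da_graph`.
#' @export
graph <- function(node_features, edges = NULL, label = NULL, node_labels = NULL) {
  node_features <- as.matrix(node_features)
  n <- nrow(node_features)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
  }
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > n)) {
      stop("graph: edge references a node outside [1, n_nodes]")
    }
    if (any(edges[, 1L] == edges[, 2L])) stop("graph: self loops are not allowed")
    key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(key)) stop("graph: duplicate undirected edge")
  }
  if (!is.null(node_labels) && length(node_labels) != n) {
    stop("graph: node_labels length must equal n_nodes")
  }
  structure(list(node_features = node_features, edges = edges,
                 label = if (is.null(label)) NULL else as.integer(label),
                 node_labels = if (is.null(node_labels)) NULL else as.integer(node_labels)),
            class = "da_graph")
}

#' Construct a domain-tagged dataset of graphs
#'
#' @param graphs list of [graph()] objects.
#' @param domain `"source"` or `"target"`.
#' @param labels_visible whether labels may be consumed by training losses.
#'   When `FALSE` the labels carried by the graphs (if any) are moved to
#'   `hidden_labels` and stripped from the graphs, so no training code can
#'   reach them.
#' @param hidden_labels optional integer vector of held-out labels
#'   (synthetic evaluation only).
#' @return an object of class `domain_dataset`.
#' @export
domain_dataset <- function(graphs, domain = c("source", "target"),
                           labels_visible = TRUE, hidden_labels = NULL) {
  domain <- match.arg(domain)
  stopifnot(is.list(graphs), length(graphs) > 0L)
  if (labels_visible) {
    has <- vapply(graphs, function(g) !is.null(g$label) || !is.null(g$node_labels),
                  logical(1L))
    if (!all(has)) stop("domain_dataset: labels_visible=TRUE requires every graph labeled")
  } else {
    lifted <- vapply(graphs, function(g) if (is.null(g$label)) NA_integer_ else g$label,
                     integer(1L))
    if (is.null(hidden_labels) && !all(is.na(lifted))) hidden_labels <- lifted
    graphs <- lapply(graphs, function(g) { g$label <- NULL; g })
  }
  structure(list(graphs = graphs, domain = domain,
                 labels_visible = labels_visible, hidden_labels = hidden_labels),
            class = "domain_dataset")
}

#' @export
length.domain_dataset <- function(x) length(x$graphs)

#' Read a graph collection in TUDataset flat-file format
#'
#' Expects `<DS>_A.txt` (comma-separated directed edge pairs, 1-based) and
#' `<DS>_graph_indicator.txt`; `<DS>_graph_labels.txt`,
#' `<DS>_node_labels.txt` and `<DS>_node_attributes.txt` are optional.
#' Discrete node labels are one-hot encoded; when attributes are also
#' present, features are the concatenation of the one-hot labels and the
#' attributes. Duplicate directed pairs collapse to one undirected edge.
#' Graph labels are remapped to contiguous 0-based classes.
#'
#' @param directory path containing the flat files; the dataset name is
#'   inferred from the `*_graph_indicator.txt` file.
#' @param domain,labels_visible passed to [domain_dataset()].
#' @return a [domain_dataset()].
#' @export
read_tudataset <- function(directory, domain = "source", labels_visible = TRUE) {
  ind_file <- list.files(directory, pattern = "_graph_indicator\\.txt$",
                         full.names = TRUE)
  if (length(ind_file) != 1L) {
    stop("read_tudataset: need exactly one *_graph_indicator.txt in ", directory)
  }
  prefix <- sub("_graph_indicator\\.txt$", "", ind_file)
  a_file <- paste0(prefix, "_A.txt")
  if (!file.exists(a_file)) stop("read_tudataset: missing ", basename(a_file))

  indicator <- as.integer(readLines(ind_file))
  n_graphs <- max(indicator)
  n_nodes_tot <- length(indicator)

  am <- utils::read.table(a_file, sep = ",", strip.white = TRUE,
                          col.names = c("u", "v"))
  if (nrow(am) > 0L && (max(am) > n_nodes_tot || min(am) < 1L)) {
    stop("read_tudataset: edge references node outside the indicator range")
  }
  if (nrow(am) > 0L && any(indicator[am$u] != indicator[am$v])) {
    stop("read_tudataset: edge crosses graph boundaries per the indicator")
  }

  lab_file <- paste0(prefix, "_graph_labels.txt")
  glabels <- if (file.exists(lab_file)) as.integer(readLines(lab_file)) else NULL
  if (!is.null(glabels)) {
    glabels <- match(glabels, sort(unique(glabels))) - 1L
  }

  nl_file <- paste0(prefix, "_node_labels.txt")
  na_file <- paste0(prefix, "_node_attributes.txt")
  nlab <- if (file.exists(nl_file)) as.integer(readLines(nl_file)) else NULL
  nattr <- if (file.exists(na_file)) {
    as.matrix(utils::read.table(na_file, sep = ",", strip.white = TRUE))
  } else NULL

  feats <- NULL
  if (!is.null(nlab)) {
    lev <- sort(unique(nlab))
    onehot <- matrix(0, n_nodes_tot, length(lev))
    onehot[cbind(seq_len(n_nodes_tot), match(nlab, lev))] <- 1
    feats <- onehot
  }
  if (!is.null(nattr)) {
    feats <- if (is.null(feats)) nattr else cbind(feats, nattr)
  }
  if (is.null(feats)) feats <- matrix(1, n_nodes_tot, 1L)  # constant feature

  offsets <- c(0L, cumsum(tabulate(indicator, nbins = n_graphs)))
  graphs <- vector("list", n_graphs)
  eg <- if (nrow(am) > 0L) indicator[am$u] else integer(0)
  for (gi in seq_len(n_graphs)) {
    rows <- which(indicator == gi)
    sel <- which(eg == gi)
    if (length(sel) > 0L) {
      u <- am$u[sel] - offsets[gi]
      v <- am$v[sel] - offsets[gi]
      und <- unique(cbind(pmin(u, v), pmax(u, v)))
      und <- und[und[, 1L] != und[, 2L], , drop = FALSE]
    } else {
      und <- matrix(integer(0), ncol = 2L)
    }
    graphs[[gi]] <- graph(feats[rows, , drop = FALSE], und,
                          label = if (is.null(glabels)) NULL else glabels[gi])
  }
  domain_dataset(graphs, domain = domain, labels_visible = labels_visible)
}

#' Write a domain dataset in TUDataset flat-file format
#'
#' Emits `DS_A.txt` (both directions of every undirected edge, 1-based,
#' comma separated), `DS_graph_indicator.txt`, `DS_graph_labels.txt` (if
#' labels are present or hidden labels exist) and `DS_node_attributes.txt`.
#' Output is byte-stable for a fixed dataset.
#'
#' @param dataset a [domain_dataset()].
#' @param directory output directory (created if needed).
#' @param name dataset prefix, default `"DS"`.
#' @export
write_tudataset <- function(dataset, directory, name = "DS") {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  gs <- dataset$graphs
  sizes <- vapply(gs, function(g) nrow(g$node_features), integer(1L))
  offsets <- c(0L, cumsum(sizes))
  indicator <- rep(seq_along(gs), sizes)

  edges <- do.call(rbind, lapply(seq_along(gs), function(i) {
    e <- gs[[i]]$edges
    if (nrow(e) == 0L) return(NULL)
    e <- e + offsets[i]
    rbind(e, e[, 2:1, drop = FALSE])
  }))
  pfx <- file.path(directory, name)
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2L)
  ord <- order(edges[, 1L], edges[, 2L])
  writeLines(sprintf("%d, %d", edges[ord, 1L], edges[ord, 2L]),
             paste0(pfx, "_A.txt"))
  writeLines(as.character(indicator), paste0(pfx, "_graph_indicator.txt"))

  labels <- if (dataset$labels_visible) {
    vapply(gs, function(g) g$label, integer(1L))
  } else dataset$hidden_labels
  if (!is.null(labels) && !any(is.na(labels))) {
    writeLines(as.character(labels), paste0(pfx, "_graph_labels.txt"))
  }
  feats <- do.call(rbind, lapply(gs, function(g) g$node_features))
  writeLines(apply(feats, 1L, function(r) paste(sprintf("%.17g", r), collapse = ", ")),
             paste0(pfx, "_node_attributes.txt"))
  invisible(pfx)
}

#' Read a single network from edge-list plus feature and label tables
#'
#' @param edge_file whitespace- or comma-separated `u v` pairs, one per line.
#' @param feature_file table `id f1 f2 ...`, one row per node; isolated
#'   nodes listed here are retained.
#' @param label_file table `id class`.
#' @return a [graph()] with `node_labels` populated.
#' @export
read_network <- function(edge_file, feature_file, label_file) {
  ft <- utils::read.table(feature_file)
  ids <- as.integer(ft[, 1L])
  feats <- as.matrix(ft[, -1L, drop = FALSE])
  lt <- utils::read.table(label_file)
  if (!all(as.integer(lt[, 1L]) %in% ids)) {
    stop("read_network: label for unknown node id")
  }
  labels <- rep(NA_integer_, length(ids))
  labels[match(as.integer(lt[, 1L]), ids)] <- as.integer(lt[, 2L])

  etxt <- readLines(edge_file)
  etxt <- etxt[nzchar(trimws(etxt))]
  em <- if (length(etxt) > 0L) {
    do.call(rbind, lapply(strsplit(gsub(",", " ", etxt), "\\s+"), function(p) {
      p <- p[nzchar(p)]
      as.integer(p[1:2])
    }))
  } else matrix(integer(0), ncol = 2L)
  if (nrow(em) > 0L) {
    if (!all(em %in% ids)) stop("read_network: edge references unknown node id")
    u <- match(em[, 1L], ids); v <- match(em[, 2L], ids)
    und <- unique(cbind(pmin(u, v), pmax(u, v)))
    und <- und[und[, 1L] != und[, 2L], , drop = FALSE]
  } else und <- matrix(integer(0), ncol = 2L)
  graph(feats, und, node_labels = labels)
}

#' Stack graphs into one disconnected block batch
#'
#' @param graphs list of [graph()] objects with a uniform feature dimension.
#' @return a `graph_batch`: stacked `X`, offset-shifted edge endpoints
#'   `eu`/`ev`, per-node owner `graph_index`, per-graph `labels` (NA where
#'   absent) and `sizes`.
#' @export
batch_graphs <- function(graphs) {
  stopifnot(length(graphs) > 0L)
  dims <- vapply(graphs, function(g) ncol(g$node_features), integer(1L))
  if (length(unique(dims)) != 1L) stop("batch_graphs: mixed feature dimensions")
  sizes <- vapply(graphs, function(g) nrow(g$node_features), integer(1L))
  offsets <- c(0L, cumsum(sizes))
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  eu <- integer(0); ev <- integer(0)
  for (i in seq_along(graphs)) {
    e <- graphs[[i]]$edges
    if (nrow(e) > 0L) {
      eu <- c(eu, e[, 1L] + offsets[i])
      ev <- c(ev, e[, 2L] + offsets[i])
    }
  }
  labels <- vapply(graphs, function(g) if (is.null(g$label)) NA_integer_ else g$label,
                   integer(1L))
  node_labels <- unlist(lapply(graphs, function(g) {
    if (is.null(g$node_labels)) rep(NA_integer_, nrow(g$node_features)) else g$node_labels
  }))
  structure(list(X = X, eu = eu, ev = ev,
                 graph_index = rep(seq_along(graphs), sizes),
                 n_nodes = nrow(X), n_graphs = length(graphs),
                 sizes = sizes, labels = labels, node_labels = node_labels),
            class = "graph_batch")
}

#' Recover the individual graphs from a batch
#'
#' @param batch a `graph_batch`.
#' @return list of [graph()] objects identical to the batched input.
#' @export
unbatch_graphs <- function(batch) {
  offsets <- c(0L, cumsum(batch$sizes))
  lapply(seq_len(batch$n_graphs), function(i) {
    rows <- (offsets[i] + 1L):offsets[i + 1L]
    sel <- batch$eu > offsets[i] & batch$eu <= offsets[i + 1L]
    e <- cbind(batch$eu[sel] - offsets[i], batch$ev[sel] - offsets[i])
    nl <- batch$node_labels[rows]
    graph(batch$X[rows, , drop = FALSE], e,
          label = if (is.na(batch$labels[i])) NULL else batch$labels[i],
          node_labels = if (all(is.na(nl))) NULL else nl)
  })
}

# Select a subset of graphs from a batch by index (duplicates allowed),
# without materializing the individual graphs.
.subset_batch <- function(batch, idx) {
  offsets <- c(0L, cumsum(batch$sizes))
  rows <- integer(0); eu <- integer(0); ev <- integer(0)
  gi <- integer(0); pos <- 0L
  for (k in seq_along(idx)) {
    i <- idx[k]
    r <- (offsets[i] + 1L):offsets[i + 1L]
    sel <- which(batch$eu > offsets[i] & batch$eu <= offsets[i + 1L])
    eu <- c(eu, batch$eu[sel] - offsets[i] + pos)
    ev <- c(ev, batch$ev[sel] - offsets[i] + pos)
    rows <- c(rows, r)
    gi <- c(gi, rep(k, batch$sizes[i]))
    pos <- pos + batch$sizes[i]
  }
  structure(list(X = batch$X[rows, , drop = FALSE], eu = eu, ev = ev,
                 graph_index = gi, n_nodes = length(rows),
                 n_graphs = length(idx), sizes = batch$sizes[idx],
                 labels = batch$labels[idx],
                 node_labels = batch$node_labels[rows]),
            class = "graph_batch")
}

#' Symmetrically normalized adjacency with self loops
#'
#' Computes `D^{-1/2} (A + I) D^{-1/2}` where each undirected edge
#' contributes its weight (1, or the supplied retention weight) in both
#' directions, the self-loop weight is always 1 and the degrees are taken
#' from the weighted `A + I`.
#'
#' @param x a [graph()] or `graph_batch`.
#' @param edge_weights optional numeric vector in `[0, 1]`, one weight per
#'   stored undirected edge.
#' @return a sparse symmetric `dgCMatrix`.
#' @export
normalized_adjacency <- function(x, edge_weights = NULL) {
  if (inherits(x, "da_graph")) {
    n <- nrow(x$node_features); eu <- x$edges[, 1L]; ev <- x$edges[, 2L]
  } else {
    n <- x$n_nodes; eu <- x$eu; ev <- x$ev
  }
  E <- length(eu)
  w <- if (is.null(edge_weights)) rep(1, E) else {
    stopifnot(length(edge_weights) == E)
    as.numeric(edge_weights)
  }
  d <- rep(1, n)
  if (E > 0L) {
    agg <- rowsum(matrix(c(w, w), ncol = 1L), group = c(eu, ev))
    ids <- as.integer(rownames(agg))
    d[ids] <- d[ids] + agg[, 1L]
  }
  i <- c(eu, ev, seq_len(n))
  j <- c(ev, eu, seq_len(n))
  vals <- c(w, w, rep(1, n)) / sqrt(d[i] * d[j])
  Matrix::sparseMatrix(i = i, j = j, x = vals, dims = c(n, n))
}
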
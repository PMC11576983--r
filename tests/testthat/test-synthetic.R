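# The seeded benchmark generators.

test_that("the graph pair is seed-deterministic, balanced and label-hidden", {
  spec <- shift_spec(n_per_domain = 60, shift_kind = "edge_density",
                     shift_magnitude = 0.5, seed = 21)
  p1 <- make_graph_shift_pair(spec)
  p2 <- make_graph_shift_pair(spec)
  expect_identical(p1$source$graphs, p2$source$graphs)
  expect_identical(p1$target$hidden_labels, p2$target$hidden_labels)
  expect_equal(as.vector(table(vapply(p1$source$graphs, function(g) g$label,
                                      integer(1L)))), c(30, 30))
  expect_equal(as.vector(table(p1$target$hidden_labels)), c(30, 30))
  expect_true(p1$source$labels_visible)
  expect_false(p1$target$labels_visible)
})

test_that("edge-density shift raises background edge counts by the stated factor", {
  spec <- shift_spec(n_per_domain = 300, shift_kind = "edge_density",
                     shift_magnitude = 0.5, seed = 22)
  pair <- make_graph_shift_pair(spec)
  bg_count <- function(ds) {
    truth <- motif_edge_ground_truth(ds)
    mean(vapply(seq_along(ds$graphs), function(i) {
      nrow(ds$graphs[[i]]$edges) - length(truth[[i]])
    }, numeric(1L)))
  }
  ratio <- bg_count(pair$target) / bg_count(pair$source)
  expect_gte(ratio, 1.4); expect_lte(ratio, 1.6)
})

test_that("motif ground truth enumerates exactly the planted wiring", {
  # motif_size 4, 2 classes: class 0 is the 4-ring, class 1 fully wired
  # (ring + both chords = choose(4, 2) = 6 edges)
  spec <- shift_spec(n_per_domain = 20, motif_size = 4L, seed = 23)
  pair <- make_graph_shift_pair(spec)
  truth <- motif_edge_ground_truth(pair$source)
  labs <- vapply(pair$source$graphs, function(g) g$label, integer(1L))
  for (i in seq_along(labs)) {
    rows <- truth[[i]]
    expect_equal(length(rows), if (labs[i] == 0L) 4L else 6L)
    motif_edges <- pair$source$graphs[[i]]$edges[rows, , drop = FALSE]
    expect_true(all(motif_edges <= 4L))  # endpoints in the motif block
  }
  plain <- domain_dataset(pair$source$graphs, "source", TRUE)
  expect_error(motif_edge_ground_truth(plain), "metadata")
})

test_that("distinct classes get distinct motif wirings, ring through complete", {
  for (k in 2:4) {
    wirings <- lapply(0:(k - 1), function(cl) gdadapt:::.motif_edges(6L, cl, k))
    sigs <- vapply(wirings, function(w) paste(w[, 1], w[, 2], collapse = ";"),
                   character(1L))
    expect_equal(length(unique(sigs)), k)
    expect_equal(nrow(wirings[[1]]), 6L)            # bare ring
    expect_equal(nrow(wirings[[k]]), choose(6, 2))  # complete graph
    for (w in wirings) expect_false(anyDuplicated(paste(w[, 1], w[, 2])) > 0)
  }
})

test_that("node pair produces block-structured networks with the stated feature shift", {
  spec <- shift_spec(task = "node", n_per_domain = 500, n_classes = 2L,
                     shift_kind = "feature_shift", shift_magnitude = 2,
                     feature_dim = 4L, seed = 24)
  pair <- make_node_shift_pair(spec)
  src <- pair$source$graphs[[1]]
  expect_equal(length(src$node_labels), 500L)
  expect_equal(as.vector(table(src$node_labels)), c(250, 250))
  hid <- pair$target$hidden_labels
  expect_equal(length(hid), 500L)
  tgt <- pair$target$graphs[[1]]
  # per-class target means exceed source means by 2.0 within sampling error
  for (cl in 0:1) {
    dmean <- colMeans(tgt$node_features[hid == cl, , drop = FALSE]) -
      colMeans(src$node_features[src$node_labels == cl, , drop = FALSE])
    expect_true(all(abs(dmean - 2) < 0.2))
  }
  # zero magnitude: same generating parameters, so moments agree closely
  s0 <- shift_spec(task = "node", n_per_domain = 400, n_classes = 2L,
                   shift_kind = "none", seed = 25)
  p0 <- make_node_shift_pair(s0)
  m_s <- mean(p0$source$graphs[[1]]$node_features)
  m_t <- mean(p0$target$graphs[[1]]$node_features)
  expect_lt(abs(m_s - m_t), 0.15)
  expect_error(make_node_shift_pair(
    shift_spec(task = "node", n_per_domain = 2, n_classes = 3L, seed = 1)),
    "classes")
})

test_that("a stats-based domain probe separates shifted pairs but not identical ones", {
  graph_stats <- function(g) {
    n <- nrow(g$node_features); e <- nrow(g$edges)
    deg <- tabulate(c(g$edges[, 1], g$edges[, 2]), nbins = n)
    c(n = n, e = e, dens = e / choose(n, 2), dmean = mean(deg),
      dsd = stats::sd(deg), dmax = max(deg), dmin = min(deg),
      d2 = mean(deg^2))
  }
  probe <- function(pair) {
    X <- rbind(t(vapply(pair$source$graphs, graph_stats, numeric(8L))),
               t(vapply(pair$target$graphs, graph_stats, numeric(8L))))
    y <- rep(0:1, times = c(length(pair$source$graphs),
                            length(pair$target$graphs)))
    set.seed(1)
    tr <- sample(length(y), length(y) / 2)
    df <- data.frame(y = y, X)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df[tr, ],
                                       family = stats::binomial))
    pr <- suppressWarnings(stats::predict(fit, df[-tr, ], type = "response"))
    mean((pr > 0.5) == df$y[-tr])
  }
  none <- make_graph_shift_pair(shift_spec(n_per_domain = 300,
                                           shift_kind = "none", seed = 26))
  expect_lte(probe(none), 0.58)
  dens <- make_graph_shift_pair(shift_spec(n_per_domain = 300,
                                           shift_kind = "edge_density",
                                           shift_magnitude = 0.5, seed = 26))
  expect_gte(probe(dens), 0.75)
})

test_that("structure-noise and feature shifts perturb only what they claim", {
  sn <- make_graph_shift_pair(shift_spec(n_per_domain = 40,
                                         shift_kind = "structure_noise",
                                         shift_magnitude = 0.4, seed = 27))
  # rewiring preserves features
  fs_src <- do.call(rbind, lapply(sn$source$graphs, function(g) g$node_features))
  expect_true(all(fs_src %in% c(0, 1)))
  fshift <- make_graph_shift_pair(shift_spec(n_per_domain = 40,
                                             shift_kind = "feature_shift",
                                             shift_magnitude = 1.5, seed = 27))
  ft <- do.call(rbind, lapply(fshift$target$graphs, function(g) g$node_features))
  expect_gt(max(ft), 1)  # shifted nuisance block
  fs <- do.call(rbind, lapply(fshift$source$graphs, function(g) g$node_features))
  expect_lte(max(fs), 1)
})
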
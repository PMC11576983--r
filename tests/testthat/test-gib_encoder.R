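# The stochastic invariant-subgraph encoder.

test_that("edge keep probabilities are sigmoid scores on symmetric endpoint pairs", {
  set.seed(1)
  z <- matrix(rnorm(12), 4, 3)
  edges <- rbind(c(1, 2), c(3, 4))
  zero <- list(W = matrix(0, 3, 1), b = matrix(0, 1, 1))
  expect_equal(edge_keep_probability(z, edges, zero), c(0.5, 0.5))
  sc <- list(W = matrix(rnorm(3), 3, 1), b = matrix(0.2, 1, 1))
  a <- edge_keep_probability(z, edges, sc)
  expect_true(all(a > 0 & a < 1))
  # orientation invariance
  expect_equal(a, edge_keep_probability(z, edges[, 2:1], sc))
  # raising the bias strictly raises every probability
  sc2 <- sc; sc2$b <- sc$b + 1
  expect_true(all(edge_keep_probability(z, edges, sc2) > a))
})

test_that("structure sampling honors degenerate probabilities, seeds and statistics", {
  expect_equal(sample_structure(rep(1, 5), "hard", seed = 2), rep(1, 5))
  expect_equal(sample_structure(rep(0, 5), "hard", seed = 2), rep(0, 5))
  expect_equal(sample_structure(rep(1, 5), "relaxed", 0.5, seed = 2), rep(1, 5),
               tolerance = 1e-9)
  expect_identical(sample_structure(rep(0.3, 10), "hard", seed = 7),
                   sample_structure(rep(0.3, 10), "hard", seed = 7))
  expect_error(sample_structure(0.5, "relaxed", temperature = 0), "temperature")
  # 3-sigma binomial intervals at 10,000 draws
  for (a in c(0.2, 0.5, 0.8)) {
    m <- sample_structure(rep(a, 10000), "hard", seed = 11)
    s3 <- 3 * sqrt(a * (1 - a) / 10000)
    expect_gt(mean(m), a - s3)
    expect_lt(mean(m), a + s3)
  }
})

test_that("the relaxed sampler approaches hard draws as temperature shrinks", {
  m <- sample_structure(rep(0.5, 1000), "relaxed", temperature = 0.01, seed = 3)
  expect_lt(mean(abs(m - round(m))), 0.05)
})

test_that("the relaxed sampler has finite positive sensitivity to alpha", {
  eps <- 1e-5
  for (a in seq(0.05, 0.95, by = 0.15)) {
    up <- sample_structure(rep(a + eps, 200), "relaxed", 1, seed = 9)
    dn <- sample_structure(rep(a - eps, 200), "relaxed", 1, seed = 9)
    g <- (up - dn) / (2 * eps)
    expect_true(all(is.finite(g)))
    expect_true(all(g > 0))
  }
})

test_that("gcn_layer handles self-loops, masks and matches the dense oracle", {
  g1 <- graph(matrix(c(2, -3), 1, 2), NULL)
  out <- gcn_layer(matrix(c(2, -3), 1, 2), g1, NULL, diag(2))
  expect_equal(out, matrix(c(2, 0), 1, 2), ignore_attr = TRUE)
  expect_error(gcn_layer(matrix(1, 1, 3), g1, NULL, diag(2)), "mismatch")

  set.seed(20)
  rg <- random_small_graph(8)
  g <- graph(matrix(rnorm(8 * 3), 8, 3), rg$edges)
  W <- matrix(rnorm(9), 3, 3)
  z <- g$node_features
  # mask of zeros equals the edgeless (self-loop only) propagation
  ml0 <- gcn_layer(z, g, rep(0, nrow(rg$edges)), W)
  g0 <- graph(g$node_features, NULL)
  expect_equal(ml0, gcn_layer(z, g0, NULL, W), tolerance = 1e-12)
  # dense brute force
  w <- stats::runif(nrow(rg$edges))
  got <- gcn_layer(z, g, w, W)
  want <- pmax(dense_norm_adj(8, rg$edges, w) %*% z %*% W, 0)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("encode_graphs is seed-deterministic with per-layer outputs", {
  pair <- tiny_pair(n = 10, seed = 2)
  b <- batch_graphs(pair$source$graphs[1:5])
  cfg <- encoder_config(ncol(b$X), hidden_dim = 8L, n_layers = 2L)
  p <- init_encoder_params(cfg, 4L)
  e1 <- encode_graphs(b, p, cfg, seed = 6, mode = "relaxed")
  e2 <- encode_graphs(b, p, cfg, seed = 6, mode = "relaxed")
  expect_identical(e1, e2)
  expect_length(e1$node_embeddings, 2L)
  expect_length(e1$edge_alpha, 2L)
  expect_equal(nrow(e1$graph_embeddings), 5L)
  eh <- encode_graphs(b, p, cfg, seed = 6, mode = "hard")
  expect_true(all(eh$edge_mask[[1]] %in% c(0, 1)))
  expect_true(all(e1$edge_alpha[[1]] > 0 & e1$edge_alpha[[1]] < 1))
})

test_that("with every edge kept the encoder is exactly a plain GCN", {
  pair <- tiny_pair(n = 10, seed = 8)
  b <- batch_graphs(pair$source$graphs[1:6])
  cfg <- encoder_config(ncol(b$X), hidden_dim = 8L)
  p <- init_encoder_params(cfg, 3L)
  eo <- encode_graphs(b, p, cfg, seed = 1, mode = "off")
  # dense two-layer oracle
  S <- dense_norm_adj(b$n_nodes, cbind(b$eu, b$ev))
  Z <- b$X
  for (l in 1:2) {
    Z <- pmax(sweep(S %*% Z %*% p[[paste0("W", l)]], 2,
                    p[[paste0("b", l)]][1, ], "+"), 0)
  }
  expect_lt(max(abs(eo$node_embeddings[[2]] - Z)), 1e-6)
  zg <- rowsum(Z, b$graph_index) / as.vector(table(b$graph_index)) *
    cfg$readout_scale
  expect_lt(max(abs(eo$graph_embeddings - zg)), 1e-6)
})

test_that("readout and encoder are invariant to within-graph node permutation", {
  set.seed(13)
  Z <- matrix(rnorm(14), 7, 2)
  gi <- c(1, 1, 1, 2, 2, 2, 2)
  r <- readout_mean(Z, gi)
  expect_equal(r[1, ], colMeans(Z[1:3, ]))
  expect_equal(r[2, ], colMeans(Z[4:7, ]))
  # single-node graph returns its own embedding
  expect_equal(readout_mean(matrix(c(3, 4), 1), 1L), matrix(c(3, 4), 1))
  # permute nodes of one graph; encode in deterministic mode
  pair <- tiny_pair(n = 6, seed = 4)
  g <- pair$source$graphs[[1]]
  n <- nrow(g$node_features)
  perm <- sample(n)
  inv <- order(perm)
  gp <- graph(g$node_features[perm, , drop = FALSE],
              cbind(inv[g$edges[, 1]], inv[g$edges[, 2]]), label = g$label)
  cfg <- encoder_config(ncol(g$node_features), hidden_dim = 8L)
  p <- init_encoder_params(cfg, 5L)
  e1 <- encode_graphs(batch_graphs(list(g)), p, cfg, mode = "off")
  e2 <- encode_graphs(batch_graphs(list(gp)), p, cfg, mode = "off")
  expect_lt(max(abs(e1$graph_embeddings - e2$graph_embeddings)), 1e-6)
})

test_that("the variational bound is the Gaussian KL in closed form", {
  expect_equal(vib_upper_bound(matrix(0, 3, 2), matrix(0, 3, 2)), 0)
  expect_equal(vib_upper_bound(matrix(1, 1, 1), matrix(0, 1, 1)), 0.5)
  set.seed(2)
  for (i in 1:20) {
    mu <- matrix(rnorm(8), 2, 4); lv <- matrix(rnorm(8, sd = 0.5), 2, 4)
    manual <- mean(vapply(1:2, function(r) {
      0.5 * sum(mu[r, ]^2 + exp(lv[r, ]) - lv[r, ] - 1)
    }, numeric(1L)))
    expect_equal(vib_upper_bound(mu, lv), manual, tolerance = 1e-12)
    expect_gte(vib_upper_bound(mu, lv), 0)
  }
})
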
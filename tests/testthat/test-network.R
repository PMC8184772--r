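test_that("edges appear exactly when Bonferroni-adjusted p < 0.05", {
  set.seed(91)
  X <- matrix(rnorm(16 * 12), 16)
  colnames(X) <- paste0("S", 1:12, "|m|response")
  X[, 2] <- X[, 1] + rnorm(16, sd = 0.01)   # one near-duplicate pair
  net <- build_network(X)
  expect_true(net$adjacency[1, 2])
  # brute-force recomputation of the whole edge criterion
  m_pairs <- choose(ncol(X), 2)
  for (i in 1:11) for (j in (i + 1):12) {
    ref <- spearman_rho_p(X[, i], X[, j])
    expect_equal(net$p[i, j], ref$p_two_sided, tolerance = 1e-12)
    expect_equal(net$adjacency[i, j],
                 ref$p_two_sided * m_pairs < 0.05)
  }
  expect_true(isSymmetric(net$adjacency))
  expect_false(any(diag(net$adjacency)))

  # identical feature columns are a guaranteed edge
  X2 <- cbind(X[, 1:3], dup = X[, 1])
  colnames(X2) <- paste0("S", 1:4, "|m|response")
  net2 <- build_network(X2)
  expect_equal(net2$rho[1, 4], 1)
  expect_true(net2$adjacency[1, 4])

  # duplicating every row leaves rho unchanged (rank invariance)
  net3 <- build_network(rbind(X, X))
  expect_equal(net3$rho, net$rho, tolerance = 1e-12)
})

test_that("the exact small-n edge p-values match the permutation oracle", {
  set.seed(92)
  X <- matrix(rnorm(6 * 5), 6)
  colnames(X) <- paste0("S", 1:5, "|m|response")
  net <- build_network(X)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(net$p[i, j], oracle_spearman_p(X[, i], X[, j]),
                 tolerance = 1e-12)
  }
})

test_that("independent features rarely produce Bonferroni edges", {
  n_edges <- vapply(1:30, function(s) {
    set.seed(900 + s)
    X <- matrix(rnorm(16 * 50), 16)
    colnames(X) <- paste0("S", 1:50, "|m|response")
    sum(build_network(X)$adjacency) / 2
  }, 0)
  expect_gte(mean(n_edges == 0), 0.9)
})

test_that("constant features are excluded with a warning", {
  X <- matrix(rnorm(16 * 4), 16)
  X[, 3] <- 2
  colnames(X) <- paste0("S", 1:4, "|m|response")
  expect_warning(net <- build_network(X), "constant")
  expect_length(net$nodes, 3)
  expect_equal(net$dropped, "S3|m|response")
})

test_that("community detection partitions nodes and honors structure", {
  # two disjoint near-clique blocks -> exactly two communities
  set.seed(93)
  base <- matrix(rnorm(16 * 2), 16)
  X <- cbind(base[, 1] + matrix(rnorm(16 * 5, sd = 0.05), 16),
             base[, 2] + matrix(rnorm(16 * 5, sd = 0.05), 16))
  colnames(X) <- c(paste0("A", 1:5, "|m1|response"),
                   paste0("B", 1:5, "|m2|response"))
  net <- build_network(X)
  labels <- detect_communities(net, seed = 2)
  expect_length(labels, 10)
  expect_equal(length(unique(labels)), 2)
  expect_equal(length(unique(labels[1:5])), 1)
  expect_equal(length(unique(labels[6:10])), 1)
  # determinism
  expect_identical(labels, detect_communities(net, seed = 2))

  # edgeless graph -> all singletons
  set.seed(94)
  X0 <- matrix(rnorm(16 * 6), 16)
  colnames(X0) <- paste0("S", 1:6, "|m|response")
  net0 <- build_network(X0)
  if (sum(net0$adjacency) == 0) {
    expect_equal(length(unique(detect_communities(net0))), 6)
  }
})

test_that("communities are annotated by their modal marker", {
  labels <- c("s1|CD25|r" = 1, "s2|CD25|r" = 1, "s3|CD25|r" = 1,
              "s1|pSTAT5|r" = 2, "s2|pSTAT5|r" = 2, "s3|CD69|r" = 2,
              "s4|CD69|r" = 3, "s5|pP38|r" = 3)
  ann <- annotate_communities(labels)
  expect_equal(ann$attribute[ann$community == 1], "CD25")
  expect_false(ann$tie[ann$community == 1])
  expect_equal(ann$attribute[ann$community == 2], "pSTAT5")
  # 1-1 tie resolves alphabetically and is flagged
  expect_equal(ann$attribute[ann$community == 3], "CD69")
  expect_true(ann$tie[ann$community == 3])
})

test_that("layouts are deterministic, finite, and distance-faithful", {
  set.seed(95)
  X <- matrix(rnorm(16 * 20), 16)
  X[, 2] <- X[, 1] + rnorm(16, sd = 0.05)   # nodes 1,2 near-duplicates
  colnames(X) <- paste0("S", 1:20, "|m|response")
  net <- build_network(X)
  xy1 <- layout_2d(net, seed = 4)
  xy2 <- layout_2d(net, seed = 4)
  expect_identical(xy1, xy2)
  expect_true(all(is.finite(xy1)))
  expect_equal(dim(xy1), c(20, 2))

  # correlated pair closer than an independent node, across seeds
  hits <- vapply(1:10, function(s) {
    xy <- layout_2d(net, seed = s)
    d12 <- sqrt(sum((xy[1, ] - xy[2, ])^2))
    d13 <- sqrt(sum((xy[1, ] - xy[3, ])^2))
    d12 < d13
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("network exports produce GraphML plus edge and node tables", {
  set.seed(96)
  X <- matrix(rnorm(16 * 6), 16)
  X[, 2] <- X[, 1] + rnorm(16, sd = 0.01)
  colnames(X) <- paste0("S", 1:6, "|m|response")
  net <- build_network(X)
  labels <- detect_communities(net)
  xy <- layout_2d(net, seed = 1)
  stem <- file.path(withr::local_tempdir(), "net")
  files <- export_network(net, stem, labels, xy)
  expect_true(all(file.exists(files)))
  edges <- read.delim(paste0(stem, "_edges.tsv"))
  expect_equal(nrow(edges), choose(6, 2))
  expect_equal(sum(edges$significant), sum(net$adjacency) / 2)
  g <- igraph::read_graph(paste0(stem, ".graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), 6)
})
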
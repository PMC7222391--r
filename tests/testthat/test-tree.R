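# Kruskal maximum-weight spanning trees and the tree topology metrics.

test_that("Kruskal matches exhaustive enumeration on small graphs", {
  for (seed in 1:30) {
    n <- sample(3:6, 1)
    v <- rand_sym_matrix(n, seed = seed)
    tree <- max_spanning_tree(v)
    expect_equal(sum(tree$edges$weight), brute_max_tree_weight(v),
                 tolerance = 1e-12)
  }
})

test_that("Kruskal agrees with an independent MST library", {
  for (seed in 31:40) {
    v <- rand_sym_matrix(12, seed = seed)
    tree <- max_spanning_tree(v)
    g <- igraph::graph_from_adjacency_matrix(v, mode = "undirected",
                                             weighted = TRUE)
    ref <- igraph::mst(g, weights = -igraph::E(g)$weight)
    expect_equal(sum(tree$edges$weight), sum(igraph::E(ref)$weight),
                 tolerance = 1e-12)
  }
})

test_that("trees have N-1 edges, are deterministic under ties, and reject bad input", {
  v <- rand_sym_matrix(32, seed = 1)
  tree <- max_spanning_tree(v)
  expect_length(tree$nodes, 32L)
  expect_equal(nrow(tree$edges), 31L)
  # two-node case: the single edge
  v2 <- matrix(c(0, 0.7, 0.7, 0), 2)
  t2 <- max_spanning_tree(v2)
  expect_equal(t2$edges$weight, 0.7)
  # all-equal weights (ties everywhere): still a tree, reproducibly
  tie <- matrix(1, 6, 6); diag(tie) <- 0
  ta <- max_spanning_tree(tie); tb <- max_spanning_tree(tie)
  expect_identical(ta$edges, tb$edges)
  expect_equal(nrow(ta$edges), 5L)
  asym <- matrix(c(0, 1, 0.5, 0), 2, 2)
  expect_error(max_spanning_tree(asym), "symmetric")
})

test_that("star-tree metrics take their closed-form values", {
  st <- star_tree(32)
  m_hop <- tree_metrics(st, mpli = 0.1, distance = "hop")
  expect_equal(m_hop$leaf_fraction, 1)        # all 31 non-centre nodes
  expect_equal(m_hop$degree_max, 1)           # 31 / 31
  expect_equal(m_hop$bc_max, 1)               # centre carries every path
  expect_equal(m_hop$tree_hierarchy, 0.5)     # 31 / (2 * 31 * 1)
  expect_equal(m_hop$diameter, 2 / 31)        # leaf-centre-leaf
  # leaves score zero betweenness
  bc <- node_betweenness(st)
  expect_equal(unname(bc[-1]), rep(0, 31))
  expect_equal(unname(bc[1]), 1)
})

test_that("path-tree metrics match hand derivations", {
  pt <- path_tree(8)
  m <- tree_metrics(pt, mpli = 0.1, distance = "hop")
  expect_equal(m$diameter * m$n_edges, 7)     # 7 steps end to end
  expect_equal(m$leaf_fraction, 2 / 7)        # the two ends
  expect_equal(m$degree_max, 2 / 7)
  # weighted convention on a uniform path: D = (N-1)(1-w)/M = 1-w
  w <- 0.62
  mw <- tree_metrics(path_tree(32, weight = w), distance = "weighted")
  expect_equal(mw$diameter, 1 - w)
})

test_that("betweenness matches brute-force path enumeration and igraph", {
  for (seed in 1:10) {
    tr <- random_tree(7, seed = seed)
    bc <- node_betweenness(tr)
    expect_equal(bc, brute_betweenness(tr), tolerance = 1e-12)
    g <- igraph::graph_from_data_frame(tr$edges[, 1:2], directed = FALSE,
                                       vertices = data.frame(name = tr$nodes))
    ref <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
    expect_equal(unname(bc[tr$nodes]), unname(ref[tr$nodes]),
                 tolerance = 1e-12)
  }
})

test_that("degree sum, leaf count and the line-vs-star ordering hold", {
  for (seed in 11:25) {
    n <- sample(5:20, 1)
    tr <- random_tree(n, seed = seed)
    deg <- node_degrees(tr)
    expect_equal(sum(deg), 2 * (n - 1))
    expect_gte(sum(deg == 1), 2)
  }
  # hop diameter and leaf fraction move oppositely from line to star
  line <- tree_metrics(path_tree(16), distance = "hop")
  star <- tree_metrics(star_tree(16), distance = "hop")
  expect_gt(line$diameter, star$diameter)
  expect_lt(line$leaf_fraction, star$leaf_fraction)
  expect_gt(line$eccentricity, star$eccentricity)
})

test_that("metrics are invariant under node relabeling", {
  tr <- random_tree(9, seed = 77)
  # same topology under relabelled nodes and shuffled edge order
  relabel <- stats::setNames(sample(tr$nodes), tr$nodes)
  shuf <- data.frame(node_a = unname(relabel[tr$edges$node_a]),
                     node_b = unname(relabel[tr$edges$node_b]),
                     weight = tr$edges$weight)
  shuf <- shuf[sample(nrow(shuf)), ]
  tr2 <- spanning_tree(unname(relabel[tr$nodes]), shuf)
  m1 <- unlist(tree_metrics(tr, mpli = 0)[tree_metric_names()])
  m2 <- unlist(tree_metrics(tr2, mpli = 0)[tree_metric_names()])
  expect_equal(m1, m2)
})

test_that("spanning_tree validates structure", {
  labs <- c("a", "b", "c", "d")
  expect_error(spanning_tree(labs, data.frame(node_a = c("a", "b"),
                                              node_b = c("b", "c"),
                                              weight = 1)), "exactly 3")
  expect_error(spanning_tree(labs, data.frame(node_a = c("a", "b", "a"),
                                              node_b = c("b", "a", "c"),
                                              weight = 1)), "cycle")
  # tree hierarchy undefined only for degenerate 2-node trees
  t2 <- spanning_tree(c("a", "b"), data.frame(node_a = "a", node_b = "b",
                                              weight = 0.4))
  m <- tree_metrics(t2)
  expect_true(is.na(m$tree_hierarchy))
})
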
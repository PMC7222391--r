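# Maximum-weight spanning trees (Kruskal) and tree topology metrics.

#' Construct a spanning tree object
#'
#' @param nodes character vector of node labels (length N).
#' @param edges data frame with columns `node_a`, `node_b` (labels) and
#'   `weight`; must contain exactly N - 1 edges forming a connected,
#'   acyclic graph.
#' @return a `spanning_tree` object.
#' @export
spanning_tree <- function(nodes, edges) {
  stopifnot(is.character(nodes), length(nodes) >= 2L,
            all(c("node_a", "node_b", "weight") %in% names(edges)))
  n <- length(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node labels")
  if (nrow(edges) != n - 1L)
    stop("a spanning tree on ", n, " nodes needs exactly ", n - 1L,
         " edges, got ", nrow(edges))
  ia <- match(edges$node_a, nodes); ib <- match(edges$node_b, nodes)
  if (anyNA(ia) || anyNA(ib)) stop("edge endpoints not in node set")
  # connectivity check via union-find (acyclicity follows from edge count)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in seq_len(nrow(edges))) {
    ra <- find(ia[e]); rb <- find(ib[e])
    if (ra == rb) stop("edges contain a cycle")
    parent[ra] <- rb
  }
  structure(list(nodes = nodes, edges = edges), class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("<spanning_tree> %d nodes, %d edges, total weight %.4g\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

# Kruskal's algorithm on an explicit edge list, maximising total weight.
# Edges are ranked by descending weight with a deterministic lexicographic
# (i, j) tie-break, and an edge is accepted iff it joins two components.
kruskal_select <- function(i, j, w, n) {
  ord <- order(-w, i, j)
  parent <- seq_len(n)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) { nxt <- parent[x]; parent[x] <<- root; x <- nxt }
    root
  }
  chosen <- integer(0)
  for (e in ord) {
    ri <- find(i[e]); rj <- find(j[e])
    if (ri != rj) {
      parent[ri] <- rj
      chosen <- c(chosen, e)
      if (length(chosen) == n - 1L) break
    }
  }
  if (length(chosen) < n - 1L) stop("graph is disconnected; no spanning tree")
  sort(chosen)
}

#' Maximum-weight spanning tree of a connectivity matrix
#'
#' Kruskal's algorithm over all edges ranked from highest to lowest PLI:
#' starting from disconnected nodes, each edge is added iff it joins two
#' components, until all nodes are connected without forming a closed
#' loop. The result is the strongest backbone of the weighted network —
#' the spanning tree maximising total PLI (equivalently, the minimum
#' spanning tree in the distance sense). For a 32-channel matrix the tree
#' has 32 nodes and 31 edges. Ties in weight are broken by lexicographic
#' node-index order, so the tree is deterministic.
#'
#' @param m a `connectivity_matrix` or symmetric numeric matrix (N >= 2).
#' @return a [spanning_tree()] with PLI edge weights.
#' @export
max_spanning_tree <- function(m) {
  cm <- if (inherits(m, "connectivity_matrix")) m else NULL
  v <- as_conn_values(m)
  if (!is.matrix(v) || nrow(v) != ncol(v)) stop("input must be square")
  if (nrow(v) < 2L) stop("need at least 2 nodes")
  if (!isSymmetric(unname(v), tol = 1e-9)) stop("matrix must be symmetric")
  n <- nrow(v)
  labels <- rownames(v) %||% default_channel_names(n)
  idx <- which(upper.tri(v), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]; w <- v[idx]
  sel <- kruskal_select(i, j, w, n)
  tree <- spanning_tree(labels, data.frame(node_a = labels[i[sel]],
                                           node_b = labels[j[sel]],
                                           weight = w[sel],
                                           stringsAsFactors = FALSE))
  if (!is.null(cm)) {
    attr(tree, "band") <- cm$band
    attr(tree, "subject_id") <- cm$subject_id
    attr(tree, "condition") <- cm$condition
  }
  tree
}

tree_edge_indices <- function(tree) {
  cbind(match(tree$edges$node_a, tree$nodes),
        match(tree$edges$node_b, tree$nodes))
}

#' Node degrees of a spanning tree
#' @param tree a [spanning_tree()].
#' @return named integer vector of raw degrees.
#' @export
node_degrees <- function(tree) {
  tab <- table(factor(c(tree$edges$node_a, tree$edges$node_b),
                      levels = tree$nodes))
  stats::setNames(as.integer(tab), tree$nodes)
}

#' Normalized betweenness centrality of every tree node
#'
#' Fraction of all shortest paths passing through each node, normalised by
#' `1 / ((n - 1) (n - 2))` over ordered pairs of distinct endpoints. In a
#' tree the path between any two nodes is unique, so the count reduces to
#' the number of endpoint pairs separated by removing the node: with
#' component sizes `c_k` after removal, ordered pairs through the node =
#' `(n - 1)^2 - sum(c_k^2)`. The centre of a star scores 1; leaves score 0.
#'
#' @param tree a [spanning_tree()].
#' @return named numeric vector of BC values in `[0, 1]`.
#' @export
node_betweenness <- function(tree) {
  n <- length(tree$nodes)
  eidx <- tree_edge_indices(tree)
  adj <- vector("list", n)
  for (e in seq_len(nrow(eidx))) {
    a <- eidx[e, 1L]; b <- eidx[e, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  bc <- numeric(n)
  if (n > 2L) {
    for (v in seq_len(n)) {
      # sizes of the components of the tree with v removed: one BFS per
      # neighbour, never crossing v
      sizes <- vapply(adj[[v]], function(start) {
        seen <- logical(n); seen[v] <- TRUE; seen[start] <- TRUE
        queue <- start; count <- 1L
        while (length(queue) > 0L) {
          x <- queue[[1L]]; queue <- queue[-1L]
          for (y in adj[[x]]) if (!seen[y]) {
            seen[y] <- TRUE; count <- count + 1L; queue <- c(queue, y)
          }
        }
        count
      }, integer(1))
      bc[v] <- ((n - 1)^2 - sum(sizes^2)) / ((n - 1) * (n - 2))
    }
  }
  stats::setNames(bc, tree$nodes)
}

tree_igraph <- function(tree) {
  igraph::graph_from_data_frame(tree$edges[, c("node_a", "node_b")],
                                directed = FALSE,
                                vertices = data.frame(name = tree$nodes))
}

#' Tree topology metrics
#'
#' The descriptive statistics of a spanning tree with N nodes and
#' M = N - 1 edges:
#'
#' * `mpli` — mean PLI of the source network (passed in, not derived from
#'   the tree);
#' * `degree_max` — max node degree / M;
#' * `bc_max` — maximum normalized betweenness ([node_betweenness()]);
#' * `leaf_fraction` — L / M, L = number of degree-1 nodes;
#' * `diameter` — largest inter-node distance / M;
#' * `eccentricity` — mean over nodes of the largest distance from that
#'   node, / M;
#' * `tree_hierarchy` — L / (2 M bc_max), the trade-off between
#'   integration (many leaves) and central-node overload; 0.5 for a star.
#'
#' Distances use the configured convention: `"weighted"` (default) sums
#' per-edge lengths `1 - weight`, so strong (high-PLI) edges are short;
#' `"hop"` counts edges. Both are normalised by M.
#'
#' @param tree a [spanning_tree()].
#' @param mpli mean PLI of the underlying network (see [mean_pli()]).
#' @param distance `"weighted"` or `"hop"`.
#' @return a `tree_metrics` object (named list, incl.
#'   `distance_convention`).
#' @export
tree_metrics <- function(tree, mpli = NA_real_,
                         distance = c("weighted", "hop")) {
  stopifnot(inherits(tree, "spanning_tree"))
  distance <- match.arg(distance)
  n <- length(tree$nodes)
  m <- nrow(tree$edges)
  deg <- node_degrees(tree)
  leaves <- sum(deg == 1L)
  bc <- node_betweenness(tree)
  bc_max <- max(bc)
  g <- tree_igraph(tree)
  wts <- if (distance == "weighted") 1 - tree$edges$weight else NA
  dmat <- igraph::distances(g, weights = wts)
  diam <- max(dmat)
  ecc <- apply(dmat, 1L, max)
  structure(list(
    mpli = mpli,
    degree_max = max(deg) / m,
    bc_max = bc_max,
    leaf_fraction = leaves / m,
    diameter = diam / m,
    eccentricity = mean(ecc) / m,
    tree_hierarchy = if (bc_max > 0) leaves / (2 * m * bc_max) else NA_real_,
    n_nodes = n, n_edges = m, n_leaves = leaves,
    distance_convention = distance
  ), class = "tree_metrics")
}

#' @export
print.tree_metrics <- function(x, ...) {
  cat(sprintf(
    "<tree_metrics> N=%d M=%d (%s distances)\n  MPLI=%.4g degree_max=%.3f bc_max=%.3f leaf_fraction=%.3f\n  diameter=%.4g eccentricity=%.4g tree_hierarchy=%.3f\n",
    x$n_nodes, x$n_edges, x$distance_convention, x$mpli, x$degree_max,
    x$bc_max, x$leaf_fraction, x$diameter, x$eccentricity,
    x$tree_hierarchy))
  invisible(x)
}

#' Names of the metrics a tree analysis produces
#' @return character vector of metric column names.
#' @export
tree_metric_names <- function() {
  c("mpli", "degree_max", "bc_max", "leaf_fraction", "diameter",
    "eccentricity", "tree_hierarchy")
}
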
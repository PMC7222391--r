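# Cross-subject aggregation: overlap graphs, average spanning trees, hubs.

#' Overlap graph of subject spanning trees
#'
#' For one condition and band, the spanning trees of all subjects are
#' overlaid on the shared node set; each edge's integer weight is the
#' number of subjects whose tree contains it.
#'
#' @param trees list of [spanning_tree()] objects on the same node set.
#' @return an `overlap_graph`: list with `nodes`, `edges` (data frame
#'   `node_a`, `node_b`, `count`) and `n_subjects`.
#' @export
overlap_graph <- function(trees) {
  stopifnot(is.list(trees), length(trees) >= 1L,
            all(vapply(trees, inherits, logical(1), "spanning_tree")))
  nodes <- trees[[1L]]$nodes
  for (t in trees)
    if (!identical(sort(t$nodes), sort(nodes)))
      stop("trees do not share a node set")
  n <- length(nodes)
  counts <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (t in trees) {
    ia <- match(t$edges$node_a, nodes); ib <- match(t$edges$node_b, nodes)
    i <- pmin(ia, ib); j <- pmax(ia, ib)
    for (e in seq_along(i)) counts[i[e], j[e]] <- counts[i[e], j[e]] + 1L
  }
  idx <- which(upper.tri(counts) & counts > 0L, arr.ind = TRUE)
  edges <- data.frame(node_a = nodes[idx[, 1L]], node_b = nodes[idx[, 2L]],
                      count = counts[idx], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 n_subjects = length(trees)),
            class = "overlap_graph")
}

#' @export
print.overlap_graph <- function(x, ...) {
  cat(sprintf("<overlap_graph> %d nodes, %d distinct edges from %d subject trees\n",
              length(x$nodes), nrow(x$edges), x$n_subjects))
  invisible(x)
}

#' Average spanning tree of a condition
#'
#' The maximum-weight spanning tree of the overlap graph, where weights
#' are subject counts: the tree built from the most-shared edges, a
#' group-representative backbone. Uses the same Kruskal construction and
#' tie-break as [max_spanning_tree()].
#'
#' @param overlap an [overlap_graph()].
#' @return a [spanning_tree()] whose edge weights are subject counts.
#' @export
average_mst <- function(overlap) {
  stopifnot(inherits(overlap, "overlap_graph"))
  nodes <- overlap$nodes
  n <- length(nodes)
  i <- match(overlap$edges$node_a, nodes)
  j <- match(overlap$edges$node_b, nodes)
  sel <- tryCatch(kruskal_select(i, j, overlap$edges$count, n),
                  error = function(e) stop("overlap graph is disconnected"))
  spanning_tree(nodes, data.frame(node_a = overlap$edges$node_a[sel],
                                  node_b = overlap$edges$node_b[sel],
                                  weight = overlap$edges$count[sel],
                                  stringsAsFactors = FALSE))
}

#' Hub table of an average spanning tree
#'
#' Nodes whose raw tree degree reaches `min_degree` (default 3, the
#' convention for calling a node a hub of an average tree), ranked by
#' degree (descending) then channel name. The `class` column separates
#' strong hubs (degree >= 4) from degree-3 hubs, mirroring the two-tier
#' display convention for hub nodes.
#'
#' @param avg_tree a [spanning_tree()].
#' @param min_degree minimum raw degree to list (default 3).
#' @return data frame with columns `channel`, `degree`, `class`.
#' @export
hub_table <- function(avg_tree, min_degree = 3L) {
  stopifnot(inherits(avg_tree, "spanning_tree"), min_degree >= 1L)
  deg <- node_degrees(avg_tree)
  keep <- deg >= min_degree
  out <- data.frame(channel = names(deg)[keep],
                    degree = unname(deg[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$channel), , drop = FALSE]
  out$class <- ifelse(out$degree >= 4L, "strong", "minor")
  rownames(out) <- NULL
  out
}
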
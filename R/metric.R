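#' All-pairs graph metric of a brain network
#'
#' Computes the ground distances used by the Wasserstein-1 computation.
#' The default `"hop"` metric counts the number of edges on the shortest path
#' between two nodes, treating every positive-weight edge as length 1 — the
#' intrinsic graph metric on the vertex set. The `"weighted"` alternative uses
#' edge length `1/w`, so strongly connected region pairs are metrically close;
#' any intrinsic metric is admissible for the curvature definition.
#'
#' Node pairs in different connected components have distance `Inf`; this is
#' flagged, not fatal, because curvature is computed per component.
#'
#' @param network A [brain_network()].
#' @param metric One of `"hop"` or `"weighted"`.
#' @return An object of class `graph_metric`: list with `distances` (square
#'   matrix, node ids as dimnames), `metric`, and `connected` (logical).
#' @export
graph_metric <- function(network, metric = c("hop", "weighted")) {
  stopifnot(inherits(network, "brain_network"))
  metric <- match.arg(metric)
  g <- igraph::graph_from_adjacency_matrix(network$weights,
                                           mode = "undirected",
                                           weighted = TRUE)
  ew <- if (metric == "hop") NA else 1 / igraph::E(g)$weight
  d <- igraph::distances(g, weights = ew)
  dimnames(d) <- list(network$nodes$id, network$nodes$id)
  structure(
    list(distances = d, metric = metric, connected = all(is.finite(d))),
    class = "graph_metric"
  )
}

#' @export
print.graph_metric <- function(x, ...) {
  cat("<graph_metric> ", nrow(x$distances), " nodes, metric = ", x$metric,
      if (!x$connected) ", disconnected" else "", "\n", sep = "")
  invisible(x)
}
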
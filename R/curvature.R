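#' Ollivier-Ricci curvature of one edge
#'
#' For adjacent nodes `x`, `y` the edge curvature is
#' \deqn{k(x, y) = 1 - W_1(\mu_x, \mu_y) / d(x, y),}
#' the Wasserstein-1 distance between the one-step random-walk measures at the
#' endpoints, normalized by the ground distance between them. Under the hop
#' metric adjacent nodes have `d = 1`. Positive curvature means the endpoint
#' neighborhoods are on average closer than the endpoints themselves —
#' well-connected, feedback-rich, robust; negative curvature marks
#' bridge-like, fragile connections. Always `k <= 1`, and under the hop
#' metric `k >= -2` for adjacent nodes.
#'
#' @param network A [brain_network()].
#' @param x,y Node ids or indices joined by a positive-weight edge.
#' @param metric Optional precomputed [graph_metric()]; computed on the fly
#'   (with `metric_kind`) when omitted.
#' @param metric_kind Ground metric to use when `metric` is missing.
#' @return The curvature, a scalar.
#' @examples
#' w <- matrix(1, 3, 3); diag(w) <- 0   # triangle
#' meta <- data.frame(id = letters[1:3], name = letters[1:3],
#'                    hemisphere = "left")
#' net <- brain_network(w, meta)
#' edge_curvature(net, "a", "b")        # 1/2
#' @export
edge_curvature <- function(network, x, y, metric = NULL,
                           metric_kind = c("hop", "weighted")) {
  stopifnot(inherits(network, "brain_network"))
  xi <- resolve_node(network, x)
  yi <- resolve_node(network, y)
  if (network$weights[xi, yi] <= 0) {
    stop("nodes '", network$nodes$id[xi], "' and '", network$nodes$id[yi],
         "' are not joined by a positive-weight edge", call. = FALSE)
  }
  if (is.null(metric)) {
    metric <- graph_metric(network, match.arg(metric_kind))
  }
  mu <- node_measure(network, xi)
  nu <- node_measure(network, yi)
  w1 <- wasserstein1(mu, nu, metric)$cost
  1 - w1 / metric$distances[xi, yi]
}

#' Ollivier-Ricci curvature of every edge and node of a network
#'
#' Computes the edge curvature `k(x, y)` for every positive-weight edge and
#' the scalar curvature at every non-isolated node,
#' \deqn{\hat S(x) = \sum_y \mu_x(y)\, k(x, y),}
#' the random-walk-weighted average of the curvatures of the incident edges
#' (the discrete contraction of Ricci curvature). Scalar curvature always
#' lies between the minimum and maximum incident edge curvature.
#'
#' @param network A [brain_network()].
#' @param metric_kind Ground metric: `"hop"` (shortest path counting edges;
#'   the default) or `"weighted"` (edge length `1/w`).
#' @return An object of class `ricci_curvature`: list with
#'   * `edges` — tibble `node_a`, `node_b`, `weight`, `curvature`, one row per
#'     edge, `node_a` before `node_b` in node order;
#'   * `nodes` — tibble `node`, `hemisphere`, `weighted_degree`,
#'     `scalar_curvature` (`NA` for isolated nodes), one row per node;
#'   * `metric_kind`.
#' @examples
#' w <- matrix(1, 4, 4); diag(w) <- 0   # K4
#' meta <- data.frame(id = letters[1:4], name = letters[1:4],
#'                    hemisphere = "left")
#' ricci_curvature(brain_network(w, meta))
#' @export
ricci_curvature <- function(network, metric_kind = c("hop", "weighted")) {
  stopifnot(inherits(network, "brain_network"))
  metric_kind <- match.arg(metric_kind)
  metric <- graph_metric(network, metric_kind)
  nn <- n_nodes(network)
  ids <- network$nodes$id
  w <- network$weights

  degrees <- rowSums(w)
  measures <- vector("list", nn)
  for (i in seq_len(nn)) {
    if (degrees[i] > 0) measures[[i]] <- node_measure(network, i)
  }

  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  ne <- nrow(idx)
  kvals <- numeric(ne)
  K <- matrix(NA_real_, nn, nn)
  for (e in seq_len(ne)) {
    i <- idx[e, 1]
    j <- idx[e, 2]
    w1 <- tryCatch(
      wasserstein1(measures[[i]], measures[[j]], metric)$cost,
      error = function(err) {
        stop("edge ", ids[i], "--", ids[j], ": ", conditionMessage(err),
             call. = FALSE)
      }
    )
    kvals[e] <- 1 - w1 / metric$distances[i, j]
    K[i, j] <- K[j, i] <- kvals[e]
  }

  scalar <- rep(NA_real_, nn)
  for (i in seq_len(nn)) {
    mu <- measures[[i]]
    if (!is.null(mu)) {
      scalar[i] <- sum(mu$masses * K[i, mu$support])
    }
  }

  structure(
    list(
      edges = tibble::tibble(node_a = ids[idx[, 1]], node_b = ids[idx[, 2]],
                             weight = w[idx], curvature = kvals),
      nodes = tibble::tibble(node = ids, hemisphere = network$nodes$hemisphere,
                             weighted_degree = unname(degrees),
                             scalar_curvature = scalar),
      metric_kind = metric_kind
    ),
    class = "ricci_curvature"
  )
}

#' @export
print.ricci_curvature <- function(x, ...) {
  cat("<ricci_curvature> metric = ", x$metric_kind, "\n", sep = "")
  cat(nrow(x$edges), " edges, mean k = ",
      format(mean(x$edges$curvature), digits = 4), "\n", sep = "")
  cat(sum(!is.na(x$nodes$scalar_curvature)), " nodes with scalar curvature\n",
      sep = "")
  invisible(x)
}

#' @rdname ricci_curvature
#' @param x A `ricci_curvature` object.
#' @param type Which table to return: `"edges"` or `"nodes"`.
#' @param ... Unused.
#' @method tidy ricci_curvature
#' @export
tidy.ricci_curvature <- function(x, type = c("edges", "nodes"), ...) {
  type <- match.arg(type)
  x[[type]]
}

#' @rdname ricci_curvature
#' @method glance ricci_curvature
#' @export
glance.ricci_curvature <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    mean_edge_curvature = mean(x$edges$curvature),
    sd_edge_curvature = stats::sd(x$edges$curvature),
    frac_positive = mean(x$edges$curvature > 0),
    mean_scalar_curvature = mean(x$nodes$scalar_curvature, na.rm = TRUE),
    metric_kind = x$metric_kind
  )
}

#' Plot the curvature distribution of a network
#'
#' Histograms of edge curvature and node scalar curvature, side by side.
#'
#' @param object A [ricci_curvature()] result.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ricci_curvature
#' @export
autoplot.ricci_curvature <- function(object, bins = 30, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(value = object$edges$curvature, what = "edge curvature"),
    tibble::tibble(value = object$nodes$scalar_curvature,
                   what = "scalar curvature")
  )
  df <- df[!is.na(df$value), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", color = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$what), scales = "free") +
    ggplot2::labs(x = "Ollivier-Ricci curvature", y = "count") +
    ggplot2::theme_minimal()
}

#' Write curvature tables to tab-delimited files
#'
#' @param result A [ricci_curvature()] result.
#' @param edges_path,nodes_path Output paths; either may be `NULL` to skip.
#' @return `result`, invisibly.
#' @export
write_curvature <- function(result, edges_path = NULL, nodes_path = NULL) {
  stopifnot(inherits(result, "ricci_curvature"))
  if (!is.null(edges_path)) {
    readr::write_tsv(result$edges, edges_path, progress = FALSE)
  }
  if (!is.null(nodes_path)) {
    readr::write_tsv(result$nodes, nodes_path, progress = FALSE)
  }
  invisible(result)
}
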
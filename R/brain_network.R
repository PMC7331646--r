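#' Construct a weighted brain network
#'
#' A `brain_network` holds a symmetric, non-negative weighted adjacency matrix
#' over a set of labeled, hemisphere-tagged nodes (parcellated gray-matter
#' regions). Edge weights are dimensionless connectivity strengths, typically
#' streamline volumes normalized by whole-brain white-matter volume.
#'
#' Self-loops (non-zero diagonal entries) are dropped with a warning: the
#' one-step random-walk measure underlying the curvature computation is defined
#' over the neighbors of a node, so intra-region weight carries no meaning
#' here. Small numerical asymmetry (within `symmetry_tol`) is repaired by
#' averaging the matrix with its transpose; larger asymmetry is an error,
#' since tractography-derived matrices are symmetric by construction and a
#' substantial violation signals a corrupted input.
#'
#' @param weights Square numeric matrix of non-negative edge weights.
#' @param nodes Data frame with one row per matrix row and columns `id`
#'   (unique region identifier), `name` (region label) and `hemisphere`
#'   (one of `"left"`, `"right"`, `"none"`; the brainstem is `"none"`).
#' @param symmetry_tol Maximum tolerated absolute asymmetry before the input
#'   is rejected.
#'
#' @return An object of class `brain_network`: a list with elements `weights`
#'   (the validated matrix, dimnames set to node ids) and `nodes` (a tibble).
#' @examples
#' w <- matrix(c(0, 3, 3, 0), 2, 2)
#' meta <- data.frame(id = c("A", "B"), name = c("A", "B"),
#'                    hemisphere = c("left", "left"))
#' net <- brain_network(w, meta)
#' network_edges(net)
#' @export
brain_network <- function(weights, nodes, symmetry_tol = 1e-8) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("`weights` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(weights) != ncol(weights)) {
    stop("`weights` must be square, got ", nrow(weights), " x ", ncol(weights),
         call. = FALSE)
  }
  nodes <- tibble::as_tibble(nodes)
  required <- c("id", "name", "hemisphere")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0) {
    stop("`nodes` is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  nodes$id <- as.character(nodes$id)
  nodes$name <- as.character(nodes$name)
  nodes$hemisphere <- as.character(nodes$hemisphere)
  if (nrow(nodes) != nrow(weights)) {
    stop("node metadata has ", nrow(nodes), " rows but the matrix has ",
         nrow(weights), " rows", call. = FALSE)
  }
  if (anyDuplicated(nodes$id)) {
    stop("node ids must be unique", call. = FALSE)
  }
  bad_hemi <- setdiff(unique(nodes$hemisphere), c("left", "right", "none"))
  if (length(bad_hemi) > 0 || anyNA(nodes$hemisphere)) {
    stop("hemisphere labels must be 'left', 'right' or 'none'; found: ",
         paste(bad_hemi, collapse = ", "), call. = FALSE)
  }
  if (anyNA(weights) || any(!is.finite(weights))) {
    bad <- which(!is.finite(weights), arr.ind = TRUE)[1, ]
    stop("non-finite weight at matrix cell (", bad[1], ", ", bad[2], ")",
         call. = FALSE)
  }
  if (any(weights < 0)) {
    bad <- which(weights < 0, arr.ind = TRUE)[1, ]
    stop("negative weight ", weights[bad[1], bad[2]], " at matrix cell (",
         bad[1], ", ", bad[2], ")", call. = FALSE)
  }
  asym <- max(abs(weights - t(weights)))
  if (asym > symmetry_tol) {
    stop("weight matrix is asymmetric (max |w - t(w)| = ",
         format(asym), ", tolerance ", format(symmetry_tol), ")",
         call. = FALSE)
  }
  if (asym > 0) {
    weights <- (weights + t(weights)) / 2
  }
  if (any(diag(weights) != 0)) {
    warning("dropping ", sum(diag(weights) != 0),
            " self-loop(s): diagonal entries set to zero", call. = FALSE)
    diag(weights) <- 0
  }
  dimnames(weights) <- list(nodes$id, nodes$id)
  structure(list(weights = weights, nodes = nodes), class = "brain_network")
}

#' @export
print.brain_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("<brain_network> ", nrow(x$nodes), " nodes, ", ne, " edges\n", sep = "")
  tab <- table(x$nodes$hemisphere)
  cat("  hemispheres: ",
      paste(names(tab), unname(tab), sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Number of nodes in a brain network
#' @param network A [brain_network()].
#' @return Integer node count.
#' @export
n_nodes <- function(network) {
  stopifnot(inherits(network, "brain_network"))
  nrow(network$nodes)
}

#' Edge table of a brain network
#'
#' Lists every positive-weight edge exactly once, with `node_a` preceding
#' `node_b` in node order — a deterministic unordered-pair key used throughout
#' the package for joining curvature results across timepoints.
#'
#' @param network A [brain_network()].
#' @return A tibble with columns `node_a`, `node_b`, `weight`, ordered by
#'   node index of `node_a` then `node_b`.
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "brain_network"))
  w <- network$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tibble::tibble(
    node_a = network$nodes$id[idx[, 1]],
    node_b = network$nodes$id[idx[, 2]],
    weight = w[idx]
  )
}

#' Read a brain network from a matrix file and a node-metadata file
#'
#' The adjacency matrix is a plain-text square numeric matrix without header,
#' whitespace- or comma-delimited. Node metadata is a tab-delimited table with
#' header columns `id`, `name`, `hemisphere`.
#'
#' @param matrix_path Path to the adjacency matrix file.
#' @param metadata_path Path to the node metadata file.
#' @inheritParams brain_network
#' @return A [brain_network()].
#' @export
read_network <- function(matrix_path, metadata_path, symmetry_tol = 1e-8) {
  if (!file.exists(matrix_path)) {
    stop("matrix file not found: ", matrix_path, call. = FALSE)
  }
  if (!file.exists(metadata_path)) {
    stop("metadata file not found: ", metadata_path, call. = FALSE)
  }
  first <- readLines(matrix_path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  mat <- tryCatch(
    as.matrix(utils::read.table(matrix_path, header = FALSE, sep = sep,
                                colClasses = "numeric")),
    error = function(e) {
      stop("failed to parse matrix file '", matrix_path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  dimnames(mat) <- NULL
  meta <- read_node_metadata(metadata_path)
  brain_network(mat, meta, symmetry_tol = symmetry_tol)
}

#' Read a node-metadata table
#' @param path Path to a tab-delimited file with columns `id`, `name`,
#'   `hemisphere`.
#' @return A tibble.
#' @export
read_node_metadata <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Write a brain network to a matrix file and a node-metadata file
#'
#' Weights are written with 17 significant digits so that a write/read
#' round-trip reproduces the matrix bit-exactly.
#'
#' @param network A [brain_network()].
#' @param matrix_path Output path for the adjacency matrix.
#' @param metadata_path Output path for node metadata; omit to skip.
#' @return `network`, invisibly.
#' @export
write_network <- function(network, matrix_path, metadata_path = NULL) {
  stopifnot(inherits(network, "brain_network"))
  lines <- apply(network$weights, 1, function(row) {
    paste(sprintf("%.17g", row), collapse = " ")
  })
  writeLines(lines, matrix_path)
  if (!is.null(metadata_path)) {
    readr::write_tsv(network$nodes, metadata_path, progress = FALSE)
  }
  invisible(network)
}

#' Rescale edge weights by a total-volume denominator
#'
#' Divides every edge weight by `total_volume`, the standard normalization of
#' streamline edge volumes by whole-brain white-matter volume. The zero
#' pattern of the matrix is unchanged.
#'
#' @param network A [brain_network()].
#' @param total_volume Positive scalar divisor.
#' @return A [brain_network()] with rescaled weights.
#' @export
normalize_edge_weights <- function(network, total_volume) {
  stopifnot(inherits(network, "brain_network"))
  if (!is.numeric(total_volume) || length(total_volume) != 1 ||
      !is.finite(total_volume) || total_volume <= 0) {
    stop("`total_volume` must be a positive finite scalar", call. = FALSE)
  }
  network$weights <- network$weights / total_volume
  network
}

#' Remove cross-hemisphere edges
#'
#' Sets to zero the weight of every edge whose endpoints lie in opposite
#' hemispheres (`left`/`right`), the preprocessing applied before curvature
#' analysis when inter-hemispheric streamlines are unreliable at the imaging
#' resolution. Edges touching a node with hemisphere `"none"` (the brainstem)
#' are kept by default; set `keep_brainstem = FALSE` to remove them as well.
#' Intra-hemisphere edges are never altered, and the operation is idempotent.
#'
#' @param network A [brain_network()].
#' @param keep_brainstem Keep edges incident to hemisphere-`none` nodes?
#' @return A [brain_network()] with the filtered weight matrix.
#' @export
remove_cross_hemisphere_edges <- function(network, keep_brainstem = TRUE) {
  stopifnot(inherits(network, "brain_network"))
  h <- network$nodes$hemisphere
  left <- h == "left"
  right <- h == "right"
  none <- h == "none"
  drop <- outer(left, right) | outer(right, left)
  if (!keep_brainstem) {
    drop <- drop | outer(none, !none) | outer(!none, none) | outer(none, none)
  }
  network$weights[drop] <- 0
  diag(network$weights) <- 0
  network
}
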
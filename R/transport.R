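#' One-step random-walk measure at a node
#'
#' The probability measure `mu_x` places mass `w_xy / d_x` on every neighbor
#' `y` of `x`, where `d_x = sum_z w_xz` is the weighted degree. The walk is
#' non-lazy: no mass remains at `x` itself. (Much published curvature software
#' defaults to a lazy walk with idleness 1/2; results differ, so the
#' convention is stated here explicitly.)
#'
#' @param network A [brain_network()].
#' @param x Node id (character) or index of the base node.
#' @return An object of class `node_measure`: list with `base_node` (index),
#'   `support` (neighbor indices), `masses` (positive, summing to 1) and
#'   `weighted_degree`.
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 2; w[1, 3] <- w[3, 1] <- 6
#' meta <- data.frame(id = c("x", "y", "z"), name = c("x", "y", "z"),
#'                    hemisphere = "left")
#' node_measure(brain_network(w, meta), "x")
#' @export
node_measure <- function(network, x) {
  stopifnot(inherits(network, "brain_network"))
  xi <- resolve_node(network, x)
  w <- network$weights[xi, ]
  support <- which(w > 0)
  deg <- sum(w[support])
  if (length(support) == 0 || deg <= 0) {
    stop("node '", network$nodes$id[xi],
         "' is isolated: its random-walk measure is undefined", call. = FALSE)
  }
  structure(
    list(base_node = xi, support = unname(support),
         masses = unname(w[support] / deg), weighted_degree = deg),
    class = "node_measure"
  )
}

resolve_node <- function(network, x) {
  if (is.character(x)) {
    xi <- match(x, network$nodes$id)
    if (is.na(xi)) stop("unknown node id '", x, "'", call. = FALSE)
    return(xi)
  }
  xi <- as.integer(x)
  if (is.na(xi) || xi < 1 || xi > nrow(network$nodes)) {
    stop("node index out of range: ", x, call. = FALSE)
  }
  xi
}

#' Wasserstein-1 distance between two node measures
#'
#' Solves the transportation linear program
#' \deqn{W_1(\mu, \nu) = \min_\pi \sum_{i,j} \pi_{ij}\, d(i, j)}
#' over couplings \eqn{\pi} with row marginals \eqn{\mu} and column marginals
#' \eqn{\nu}, where the ground distances `d` come from [graph_metric()]. The
#' program is restricted to the two supports (the neighbor sets); ground
#' distances are computed on the full graph. The optimal cost is unique even
#' when the optimal plan is not, so downstream code relies only on the cost.
#'
#' @param mu,nu [node_measure()] objects from the same network.
#' @param metric A [graph_metric()] for that network.
#' @param tol Optimality tolerance of the solver.
#' @return An object of class `transport_plan`: list with `cost`, `plan`
#'   (matrix, rows = support of `mu`, columns = support of `nu`), and the two
#'   supports.
#' @export
wasserstein1 <- function(mu, nu, metric, tol = 1e-9) {
  stopifnot(inherits(mu, "node_measure"), inherits(nu, "node_measure"),
            inherits(metric, "graph_metric"))
  d <- metric$distances[mu$support, nu$support, drop = FALSE]
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1, ]
    stop("no path between nodes ",
         rownames(metric$distances)[mu$support[bad[1]]], " and ",
         colnames(metric$distances)[nu$support[bad[2]]],
         ": supports lie in different components", call. = FALSE)
  }
  sol <- transport_simplex(mu$masses, nu$masses, d, tol = tol)
  structure(
    list(cost = sol$cost, plan = sol$plan,
         support_mu = mu$support, support_nu = nu$support),
    class = "transport_plan"
  )
}

#' @export
print.transport_plan <- function(x, ...) {
  cat("<transport_plan> ", nrow(x$plan), " x ", ncol(x$plan),
      ", cost = ", format(x$cost), "\n", sep = "")
  invisible(x)
}

#' Solve a balanced transportation problem by the transportation simplex
#'
#' Minimizes `sum(plan * cost)` subject to `rowSums(plan) = a`,
#' `colSums(plan) = b`, `plan >= 0`, with `sum(a) == sum(b)`. Uses a
#' northwest-corner initial basis and u-v (MODI) pivoting on the basis
#' spanning tree. Intended for the small dense problems arising from
#' neighbor-support couplings; exposed so the solver can be exercised
#' directly against independent implementations.
#'
#' @param a,b Non-negative marginals with equal sums.
#' @param cost Cost matrix, `length(a)` rows by `length(b)` columns.
#' @param tol Optimality tolerance on reduced costs.
#' @param max_iter Pivot limit; exceeding it is an error, not a silent
#'   approximation.
#' @param engine `"compiled"` (default) or `"reference"`, a plain-R
#'   implementation of the identical algorithm kept for cross-checking.
#' @return List with `cost` (optimal value) and `plan` (an optimal basic
#'   solution).
#' @export
transport_simplex <- function(a, b, cost, tol = 1e-9, max_iter = NULL,
                              engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  m <- length(a)
  n <- length(b)
  cost <- matrix(as.numeric(cost), m, n)
  if (any(a < 0) || any(b < 0)) stop("marginals must be non-negative", call. = FALSE)
  if (abs(sum(a) - sum(b)) > 1e-9 * max(1, sum(a))) {
    stop("unbalanced problem: sum(a) != sum(b)", call. = FALSE)
  }
  if (m == 1L || n == 1L) {
    plan <- if (m == 1L) matrix(b, 1L, n) else matrix(a, m, 1L)
    return(list(cost = sum(plan * cost), plan = plan))
  }
  if (is.null(max_iter)) max_iter <- 200L * (m + n)
  if (engine == "compiled") {
    sol <- cpp_transport_simplex(as.numeric(a), as.numeric(b), cost,
                                 tol, as.integer(max_iter))
    return(list(cost = sol$cost, plan = sol$plan))
  }

  ## northwest-corner start: always m + n - 1 basis cells forming a tree
  X <- matrix(0, m, n)
  basis <- matrix(FALSE, m, n)
  arem <- a
  brem <- b
  i <- 1L
  j <- 1L
  repeat {
    t <- min(arem[i], brem[j])
    X[i, j] <- t
    basis[i, j] <- TRUE
    arem[i] <- arem[i] - t
    brem[j] <- brem[j] - t
    if (i == m && j == n) break
    if (arem[i] <= brem[j] && i < m) i <- i + 1L else j <- j + 1L
  }

  scale <- max(1, max(abs(cost)))
  for (iter in seq_len(max_iter)) {
    duals <- transport_duals(basis, cost)
    red <- cost - outer(duals$u, duals$v, "+")
    red[basis] <- 0
    enter <- arr_which_min(red)
    if (red[enter[1], enter[2]] >= -tol * scale) {
      X[X < 0] <- 0
      return(list(cost = sum(X * cost), plan = X))
    }
    cyc <- basis_cycle(basis, enter[1], enter[2])
    minus <- cyc[seq(2, nrow(cyc), by = 2), , drop = FALSE]
    theta_idx <- which.min(X[minus])
    theta <- X[minus][theta_idx]
    sgn <- rep(c(1, -1), length.out = nrow(cyc))
    X[cyc] <- X[cyc] + sgn * theta
    leave <- minus[theta_idx, ]
    basis[leave[1], leave[2]] <- FALSE
    basis[enter[1], enter[2]] <- TRUE
    X[leave[1], leave[2]] <- 0
  }
  stop("transportation simplex did not converge within ", max_iter,
       " pivots", call. = FALSE)
}

## Solve u_i + v_j = cost_ij over the basis spanning tree (u_1 = 0).
transport_duals <- function(basis, cost) {
  m <- nrow(basis)
  n <- ncol(basis)
  cells <- which(basis, arr.ind = TRUE)
  u <- rep(NA_real_, m)
  v <- rep(NA_real_, n)
  u[1] <- 0
  remaining <- nrow(cells)
  repeat {
    progressed <- FALSE
    keep <- rep(TRUE, nrow(cells))
    for (k in seq_len(nrow(cells))) {
      ci <- cells[k, 1]
      cj <- cells[k, 2]
      if (!is.na(u[ci]) && is.na(v[cj])) {
        v[cj] <- cost[ci, cj] - u[ci]
        keep[k] <- FALSE
        progressed <- TRUE
      } else if (is.na(u[ci]) && !is.na(v[cj])) {
        u[ci] <- cost[ci, cj] - v[cj]
        keep[k] <- FALSE
        progressed <- TRUE
      } else if (!is.na(u[ci]) && !is.na(v[cj])) {
        keep[k] <- FALSE
      }
    }
    cells <- cells[keep, , drop = FALSE]
    if (!anyNA(u) && !anyNA(v)) break
    if (!progressed) {
      stop("degenerate basis: not a spanning tree", call. = FALSE)
    }
  }
  list(u = u, v = v)
}

## Unique alternating cycle created by adding cell (ei, ej) to the basis
## tree. Returns the cycle cells in order starting with the entering cell;
## odd positions (2nd, 4th, ...) are the "minus" cells.
basis_cycle <- function(basis, ei, ej) {
  m <- nrow(basis)
  n <- ncol(basis)
  ## bipartite tree: vertices 1..m are rows, m+1..m+n are columns
  nv <- m + n
  adj <- vector("list", nv)
  cells <- which(basis, arr.ind = TRUE)
  for (k in seq_len(nrow(cells))) {
    r <- cells[k, 1]
    c <- m + cells[k, 2]
    adj[[r]] <- c(adj[[r]], c)
    adj[[c]] <- c(adj[[c]], r)
  }
  ## BFS path from row ei to column m + ej
  target <- m + ej
  parent <- rep(NA_integer_, nv)
  parent[ei] <- ei
  queue <- ei
  while (length(queue) > 0) {
    vtx <- queue[1]
    queue <- queue[-1]
    if (vtx == target) break
    for (nb in adj[[vtx]]) {
      if (is.na(parent[nb])) {
        parent[nb] <- vtx
        queue <- c(queue, nb)
      }
    }
  }
  if (is.na(parent[target])) {
    stop("basis tree disconnected; cannot form pivot cycle", call. = FALSE)
  }
  path <- target
  while (path[1] != ei) path <- c(parent[path[1]], path)
  ## consecutive path vertices are basis cells; prepend the entering cell
  cyc <- matrix(c(ei, ej), 1, 2)
  for (k in seq_len(length(path) - 1)) {
    v1 <- path[k]
    v2 <- path[k + 1]
    cell <- if (v1 <= m) c(v1, v2 - m) else c(v2, v1 - m)
    cyc <- rbind(cyc, cell)
  }
  unname(cyc)
}

arr_which_min <- function(x) {
  k <- which.min(x)
  m <- nrow(x)
  c((k - 1L) %% m + 1L, (k - 1L) %/% m + 1L)
}
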
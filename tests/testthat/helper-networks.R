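# Builders and independent oracles shared across the test files.

make_net <- function(w, hemi = rep("left", nrow(w)), ids = NULL) {
  n <- nrow(w)
  if (is.null(ids)) ids <- sprintf("n%02d", seq_len(n))
  brain_network(w, data.frame(id = ids, name = ids, hemisphere = hemi))
}

make_kn <- function(n, weight = 1) {
  w <- matrix(weight, n, n)
  diag(w) <- 0
  make_net(w)
}

make_path <- function(n, weight = 1) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- weight
  make_net(w)
}

# Random connected weighted graph; weights log-normal.
random_connected_net <- function(n, density = 0.5, meanlog = 0, sdlog = 1) {
  repeat {
    w <- matrix(0, n, n)
    up <- which(upper.tri(w))
    on <- up[stats::runif(length(up)) < density]
    if (length(on) < n - 1) next
    w[on] <- stats::rlnorm(length(on), meanlog, sdlog)
    w <- w + t(w)
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
    if (igraph::is_connected(g)) return(make_net(w))
  }
}

# Independent breadth-first-search all-pairs hop distances (no igraph).
oracle_bfs_distances <- function(net) {
  w <- net$weights
  n <- nrow(w)
  adj <- lapply(seq_len(n), function(i) which(w[i, ] > 0))
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(d[s, nxt])]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# Independent W1 via boot::simplex on the full transportation LP
# (one redundant marginal constraint dropped).
oracle_w1_lp <- function(a, b, cost) {
  m <- length(a)
  n <- length(b)
  if (m == 1) return(sum(b * cost))
  if (n == 1) return(sum(a * cost))
  A3 <- matrix(0, m + n - 1, m * n)
  for (i in seq_len(m)) A3[i, (seq_len(n) - 1) * m + i] <- 1
  for (j in seq_len(n - 1)) A3[m + j, (j - 1) * m + seq_len(m)] <- 1
  sol <- boot::simplex(a = as.vector(cost), A3 = A3, b3 = c(a, b[-n]),
                       maxi = FALSE)
  sol$value
}

# Exhaustive vertex enumeration of the transportation polytope: every basic
# solution corresponds to m+n-1 cells whose marginal system is uniquely
# solvable; feasible vertices are scored directly. Only for tiny supports.
oracle_w1_vertices <- function(a, b, cost) {
  m <- length(a)
  n <- length(b)
  stopifnot(m <= 4, n <= 4)
  cells <- expand.grid(i = seq_len(m), j = seq_len(n))
  k <- m + n - 1
  best <- Inf
  for (pick in utils::combn(nrow(cells), k, simplify = FALSE)) {
    E <- matrix(0, m + n, k)
    for (c_idx in seq_along(pick)) {
      E[cells$i[pick[c_idx]], c_idx] <- 1
      E[m + cells$j[pick[c_idx]], c_idx] <- 1
    }
    Ered <- E[-(m + n), , drop = FALSE]
    if (qr(Ered)$rank < k) next
    x <- tryCatch(solve(Ered, c(a, b)[-(m + n)]), error = function(e) NULL)
    if (is.null(x) || any(x < -1e-9)) next
    if (max(abs(E %*% x - c(a, b))) > 1e-9) next
    val <- sum(x * cost[cbind(cells$i[pick], cells$j[pick])])
    best <- min(best, val)
  }
  best
}

# Independent edge curvature: BFS hop distances + boot::simplex W1.
oracle_edge_curvature <- function(net, xi, yi) {
  w <- net$weights
  d <- oracle_bfs_distances(net)
  sup_x <- which(w[xi, ] > 0)
  sup_y <- which(w[yi, ] > 0)
  a <- unname(w[xi, sup_x] / sum(w[xi, sup_x]))
  b <- unname(w[yi, sup_y] / sum(w[yi, sup_y]))
  unname(1 - oracle_w1_lp(a, b, d[sup_x, sup_y, drop = FALSE]) / d[xi, yi])
}

# Hand-rolled Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in rev(seq_len(m))) {
    val <- min(prev, p[ord[k]] * m / k)
    q[ord[k]] <- val
    prev <- val
  }
  q
}
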
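// Transportation simplex (northwest-corner start, u-v pivoting) for the
// small dense couplings arising from neighbor-support Wasserstein-1
// problems. Mirrors the reference R implementation exactly; only cost is
// contractually unique.
#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Solve u_i + v_j = c_ij over the basis spanning tree, u_0 = 0.
static bool solve_duals(int m, int n,
                        const std::vector<char>& basis,
                        const NumericMatrix& cost,
                        std::vector<double>& u, std::vector<double>& v) {
  // bipartite adjacency: vertex 0..m-1 rows, m..m+n-1 cols
  std::vector<std::vector<int>> adj(m + n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      if (basis[i + m * j]) {
        adj[i].push_back(m + j);
        adj[m + j].push_back(i);
      }
  std::vector<char> seen(m + n, 0);
  std::queue<int> q;
  u.assign(m, 0.0);
  v.assign(n, 0.0);
  seen[0] = 1;
  q.push(0);
  int visited = 0;
  while (!q.empty()) {
    int x = q.front(); q.pop();
    ++visited;
    for (int y : adj[x]) {
      if (seen[y]) continue;
      seen[y] = 1;
      if (x < m) v[y - m] = cost(x, y - m) - u[x];
      else       u[y]     = cost(y, x - m) - v[x - m];
      q.push(y);
    }
  }
  return visited == m + n;
}

// Path between row ei and column ej through the basis tree; returns the
// cycle cells (entering cell first, then path edges in order).
static bool pivot_cycle(int m, int n,
                        const std::vector<char>& basis,
                        int ei, int ej,
                        std::vector<std::pair<int,int>>& cycle) {
  std::vector<std::vector<int>> adj(m + n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      if (basis[i + m * j]) {
        adj[i].push_back(m + j);
        adj[m + j].push_back(i);
      }
  int target = m + ej;
  std::vector<int> parent(m + n, -1);
  parent[ei] = ei;
  std::queue<int> q;
  q.push(ei);
  while (!q.empty()) {
    int x = q.front(); q.pop();
    if (x == target) break;
    for (int y : adj[x])
      if (parent[y] < 0) { parent[y] = x; q.push(y); }
  }
  if (parent[target] < 0) return false;
  std::vector<int> path;
  for (int x = target; x != ei; x = parent[x]) path.push_back(x);
  path.push_back(ei);
  // path runs ei ... target after reversal
  cycle.clear();
  cycle.emplace_back(ei, ej);
  for (int k = (int)path.size() - 1; k > 0; --k) {
    int a = path[k], b = path[k - 1];
    if (a < m) cycle.emplace_back(a, b - m);
    else       cycle.emplace_back(b, a - m);
  }
  return true;
}

// [[Rcpp::export]]
List cpp_transport_simplex(NumericVector a, NumericVector b,
                           NumericMatrix cost, double tol, int max_iter) {
  const int m = a.size(), n = b.size();
  NumericMatrix X(m, n);
  std::vector<char> basis(m * n, 0);

  // northwest-corner start: m + n - 1 basis cells forming a spanning tree
  {
    std::vector<double> arem(a.begin(), a.end()), brem(b.begin(), b.end());
    int i = 0, j = 0;
    while (true) {
      double t = std::min(arem[i], brem[j]);
      X(i, j) = t;
      basis[i + m * j] = 1;
      arem[i] -= t;
      brem[j] -= t;
      if (i == m - 1 && j == n - 1) break;
      if (arem[i] <= brem[j] && i < m - 1) ++i; else ++j;
    }
  }

  double scale = 1.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      scale = std::max(scale, std::abs(cost(i, j)));

  std::vector<double> u, v;
  std::vector<std::pair<int,int>> cycle;
  for (int iter = 0; iter < max_iter; ++iter) {
    if (!solve_duals(m, n, basis, cost, u, v))
      stop("degenerate basis: not a spanning tree");
    // most negative reduced cost among non-basis cells
    double best = -tol * scale;
    int ei = -1, ej = -1;
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < m; ++i)
        if (!basis[i + m * j]) {
          double red = cost(i, j) - u[i] - v[j];
          if (red < best) { best = red; ei = i; ej = j; }
        }
    if (ei < 0) {  // optimal
      double total = 0.0;
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < m; ++i) {
          if (X(i, j) < 0) X(i, j) = 0;
          total += X(i, j) * cost(i, j);
        }
      return List::create(_["cost"] = total, _["plan"] = X,
                          _["iterations"] = iter);
    }
    if (!pivot_cycle(m, n, basis, ei, ej, cycle))
      stop("basis tree disconnected; cannot form pivot cycle");
    // minus cells are the odd positions; theta = min allocation there
    double theta = R_PosInf;
    int li = -1, lj = -1;
    for (size_t k = 1; k < cycle.size(); k += 2) {
      double x = X(cycle[k].first, cycle[k].second);
      if (x < theta) { theta = x; li = cycle[k].first; lj = cycle[k].second; }
    }
    for (size_t k = 0; k < cycle.size(); ++k) {
      double s = (k % 2 == 0) ? 1.0 : -1.0;
      X(cycle[k].first, cycle[k].second) += s * theta;
    }
    basis[li + m * lj] = 0;
    basis[ei + m * ej] = 1;
    X(li, lj) = 0;
  }
  stop("transportation simplex did not converge within %d pivots", max_iter);
}
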
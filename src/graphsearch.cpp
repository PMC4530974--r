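#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
#include <limits>

using namespace Rcpp;

// Shared conventions for both engines:
//  - the M x N gradient grid is augmented with one virtual column of value 1
//    on each side; source = top cell of the left virtual column, sink = top
//    cell of the right virtual column;
//  - arc weight between 8-neighbours a, b: 2 - (g_a + g_b) + wmin (> 0),
//    plus an infinitesimal penalty wmin*1e-3 per row of vertical travel so
//    that ties among equal-gradient paths resolve to the geometrically
//    straightest one (otherwise a uniform region admits arbitrary
//    equal-weight zigzags and the reported path shape is an accident of
//    heap order);
//  - the reported boundary gives, for every real column, the row at which
//    the optimal path first enters that column (0-based here; the R wrapper
//    converts to 1-based).

static inline double cell(const NumericMatrix& g, int r, int c) {
  // augmented grid lookup: c == 0 or c == N+1 are the virtual columns
  if (c == 0 || c == g.ncol() + 1) return 1.0;
  return g(r, c - 1);
}

static IntegerVector first_entry_rows(const std::vector<std::pair<int,int> >& path,
                                      int ncols_real) {
  IntegerVector rows(ncols_real, NA_INTEGER);
  for (size_t k = 0; k < path.size(); ++k) {
    int c = path[k].second;
    if (c >= 1 && c <= ncols_real && rows[c - 1] == NA_INTEGER)
      rows[c - 1] = path[k].first;
  }
  return rows;
}

// [[Rcpp::export]]
List cpp_dijkstra_path(NumericMatrix g, double wmin) {
  const int M = g.nrow(), N = g.ncol();
  const int NC = N + 2;                       // augmented columns
  for (int i = 0; i < M * N; ++i)
    if (!R_finite(g[i])) stop("gradient grid contains non-finite values");

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist((size_t)M * NC, INF);
  std::vector<int> prev((size_t)M * NC, -1);
  std::vector<char> done((size_t)M * NC, 0);

  // min-heap ordered by (distance, row, column): at equal tentative distance
  // the smaller row index is settled first, making ties deterministic
  typedef std::tuple<double,int,int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  const int start = 0;                        // (r=0, c=0), id = c*M + r
  const int target = (NC - 1) * M;            // (r=0, c=NC-1)
  dist[start] = 0.0;
  pq.push(Node(0.0, 0, 0));

  const int dr[8] = { 0, -1, 1, -1, 1, 0, -1, 1 };
  const int dc[8] = { 1,  1, 1,  0, 0, -1, -1, -1 };

  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double d = std::get<0>(top);
    int r = std::get<1>(top), c = std::get<2>(top);
    int u = c * M + r;
    if (done[u]) continue;
    done[u] = 1;
    if (u == target) break;
    double gu = cell(g, r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= M || cc < 0 || cc >= NC) continue;
      int v = cc * M + rr;
      if (done[v]) continue;
      double w = 2.0 - (gu + cell(g, rr, cc)) + wmin;
      if (rr != r) w += wmin * 1e-3;
      double nd = d + w;
      if (nd < dist[v]) {
        dist[v] = nd;
        prev[v] = u;
        pq.push(Node(nd, rr, cc));
      }
    }
  }

  if (!R_finite(dist[target])) stop("no path found (internal error)");

  std::vector<std::pair<int,int> > path;
  for (int u = target; u != -1; u = prev[u])
    path.push_back(std::make_pair(u % M, u / M));
  std::reverse(path.begin(), path.end());

  return List::create(_["rows"] = first_entry_rows(path, N),
                      _["total_weight"] = dist[target],
                      _["n_settled"] = (int)path.size());
}

// ---- exhaustive oracle ------------------------------------------------------

struct BFState {
  const NumericMatrix* g;
  double wmin;
  int M, NC, N;
  std::vector<char> visited;
  std::vector<std::pair<int,int> > cur, best_path;
  double best;
};

static void bf_dfs(BFState& S, int r, int c, double w) {
  // lower bound on the remaining cost: one arc per remaining column advance,
  // each at least wmin; prunes only provably suboptimal prefixes
  double lb = (S.NC - 1 - c) * S.wmin;
  if (w + lb >= S.best) return;
  if (r == 0 && c == S.NC - 1) {
    S.best = w;
    S.best_path = S.cur;
    return;
  }
  static const int dr[8] = { 0, -1, 1, -1, 1, 0, -1, 1 };
  static const int dc[8] = { 1,  1, 1,  0, 0, -1, -1, -1 };
  double gu = cell(*S.g, r, c);
  for (int k = 0; k < 8; ++k) {
    int rr = r + dr[k], cc = c + dc[k];
    if (rr < 0 || rr >= S.M || cc < 0 || cc >= S.NC) continue;
    size_t v = (size_t)cc * S.M + rr;
    if (S.visited[v]) continue;
    double arc = 2.0 - (gu + cell(*S.g, rr, cc)) + S.wmin;
    if (rr != r) arc += S.wmin * 1e-3;
    S.visited[v] = 1;
    S.cur.push_back(std::make_pair(rr, cc));
    bf_dfs(S, rr, cc, w + arc);
    S.cur.pop_back();
    S.visited[v] = 0;
  }
}

// [[Rcpp::export]]
List cpp_brute_force_path(NumericMatrix g, double wmin) {
  const int M = g.nrow(), N = g.ncol();
  if (M > 8 || N > 8)
    stop("brute-force search refused for grids larger than 8x8");
  for (int i = 0; i < M * N; ++i)
    if (!R_finite(g[i])) stop("gradient grid contains non-finite values");

  BFState S;
  S.g = &g; S.wmin = wmin; S.M = M; S.N = N; S.NC = N + 2;
  S.visited.assign((size_t)M * S.NC, 0);
  S.best = std::numeric_limits<double>::infinity();
  S.visited[0] = 1;
  S.cur.push_back(std::make_pair(0, 0));
  bf_dfs(S, 0, 0, 0.0);

  return List::create(_["rows"] = first_entry_rows(S.best_path, N),
                      _["total_weight"] = S.best);
}
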
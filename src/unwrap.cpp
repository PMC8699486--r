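// Reliability-sorting 2D phase unwrapper (Herraez-style, non-continuous path).
// Pixels are merged into groups along edges sorted by reliability; each merge
// adds the integer number of 2*pi cycles that makes the two groups congruent
// across the edge.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <functional>
#include <vector>
using namespace Rcpp;

static inline double wrap_pi(double x) {
  const double TWO_PI = 2.0 * M_PI;
  return x - TWO_PI * std::floor(x / TWO_PI + 0.5);
}

// [[Rcpp::export]]
NumericMatrix unwrap_reliability_cpp(NumericMatrix ph) {
  const int nr = ph.nrow(), nc = ph.ncol();
  const int n = nr * nc;
  const double TWO_PI = 2.0 * M_PI;
  if (nr < 2 || nc < 2) return clone(ph);

  // second-difference reliability; borders get a poor (large) score
  std::vector<double> D(n);
  const double BAD = 1e9;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int id = i + nr * j;
      if (i == 0 || i == nr - 1 || j == 0 || j == nc - 1) {
        D[id] = BAD;
        continue;
      }
      double c = ph(i, j);
      double H = wrap_pi(ph(i, j - 1) - c) - wrap_pi(c - ph(i, j + 1));
      double V = wrap_pi(ph(i - 1, j) - c) - wrap_pi(c - ph(i + 1, j));
      double D1 = wrap_pi(ph(i - 1, j - 1) - c) - wrap_pi(c - ph(i + 1, j + 1));
      double D2 = wrap_pi(ph(i - 1, j + 1) - c) - wrap_pi(c - ph(i + 1, j - 1));
      D[id] = std::sqrt(H * H + V * V + D1 * D1 + D2 * D2);
    }
  }

  // edges: horizontal (p, p+nr) and vertical (p, p+1); lower D-sum = more
  // reliable, processed first
  struct Edge { double d; int p, q; };
  std::vector<Edge> edges;
  edges.reserve(2 * n);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int id = i + nr * j;
      if (j + 1 < nc) edges.push_back({D[id] + D[id + nr], id, id + nr});
      if (i + 1 < nr) edges.push_back({D[id] + D[id + 1], id, id + 1});
    }
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge& a, const Edge& b) { return a.d < b.d; });

  // union-find with per-pixel cycle counts and member chains
  std::vector<int> parent(n), sz(n, 1), nxt(n, -1), last(n), m(n, 0);
  for (int i = 0; i < n; ++i) { parent[i] = i; last[i] = i; }
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  const double* phd = ph.begin();
  for (const Edge& e : edges) {
    int rp = find(e.p), rq = find(e.q);
    if (rp == rq) continue;
    double up = phd[e.p] + TWO_PI * m[e.p];
    double uq = phd[e.q] + TWO_PI * m[e.q];
    int delta = (int)std::lround((up - uq) / TWO_PI);
    if (sz[rq] <= sz[rp]) {
      // shift q's group by +delta, attach to p's
      if (delta != 0) for (int k = rq; k != -1; k = nxt[k]) m[k] += delta;
      parent[rq] = rp;
      nxt[last[rp]] = rq; last[rp] = last[rq];
      sz[rp] += sz[rq];
    } else {
      if (delta != 0) for (int k = rp; k != -1; k = nxt[k]) m[k] -= delta;
      parent[rp] = rq;
      nxt[last[rq]] = rp; last[rq] = last[rp];
      sz[rq] += sz[rp];
    }
  }

  NumericMatrix out(nr, nc);
  for (int id = 0; id < n; ++id) out[id] = phd[id] + TWO_PI * m[id];
  return out;
}
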
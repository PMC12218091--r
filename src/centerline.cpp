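#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Separable Gaussian blur with replicate boundary handling.
// Used by the synthetic renderer; kernel truncated at 3.5 sigma.
// [[Rcpp::export]]
NumericMatrix blur_gaussian(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int rad = (int)std::ceil(3.5 * sigma);
  std::vector<double> k(2 * rad + 1);
  double sum = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    sum += k[i + rad];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= sum;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = r + i;
        if (rr < 0) rr = 0;
        if (rr >= nr) rr = nr - 1;
        acc += k[i + rad] * img(rr, c);
      }
      tmp(r, c) = acc;
    }
  }
  // along columns (horizontal)
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = c + i;
        if (cc < 0) cc = 0;
        if (cc >= nc) cc = nc - 1;
        acc += k[i + rad] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  }
  return out;
}

static inline int px(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c);
}

// Zhang-Suen binary thinning. Input/output: 0/1 integer matrix.
// [[Rcpp::export]]
IntegerMatrix thin_mask(IntegerMatrix mask) {
  IntegerMatrix m = clone(mask);
  int nr = m.nrow(), nc = m.ncol();
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!m(r, c)) continue;
          int p2 = px(m, r - 1, c), p3 = px(m, r - 1, c + 1), p4 = px(m, r, c + 1),
              p5 = px(m, r + 1, c + 1), p6 = px(m, r + 1, c), p7 = px(m, r + 1, c - 1),
              p8 = px(m, r, c - 1), p9 = px(m, r - 1, c - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int a = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) + (p4 == 0 && p5 == 1) +
                  (p5 == 0 && p6 == 1) + (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (a != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i) m(kill[i].first, kill[i].second) = 0;
    }
  }
  return m;
}

// Count of 8-neighbours for every on-pixel (0 elsewhere).
// [[Rcpp::export]]
IntegerMatrix neighbour_counts(IntegerMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!m(r, c)) continue;
      int b = 0;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc)
          if (dr || dc) b += px(m, r + dr, c + dc);
      out(r, c) = b;
    }
  return out;
}

// BFS from a start pixel over the 8-connected skeleton; returns the path
// (1-based row, col) from start to the farthest reachable pixel, by
// backtracking BFS parents. Diagonal steps cost sqrt(2) so the farthest
// pixel is farthest along the curve, not in hops.
// [[Rcpp::export]]
IntegerMatrix skeleton_path(IntegerMatrix skel, int start_r, int start_c) {
  int nr = skel.nrow(), nc = skel.ncol();
  int n = nr * nc;
  std::vector<double> dist(n, -1.0);
  std::vector<int> parent(n, -1);
  int s = (start_r - 1) + (start_c - 1) * nr;
  if (start_r < 1 || start_c < 1 || start_r > nr || start_c > nc ||
      !skel(start_r - 1, start_c - 1))
    stop("skeleton_path: start pixel is not on the skeleton");
  // Dijkstra-lite with two-weight edges via simple priority queue
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > q;
  dist[s] = 0.0;
  q.push(std::make_pair(0.0, s));
  int far = s;
  while (!q.empty()) {
    QE top = q.top(); q.pop();
    int u = top.second;
    if (top.first > dist[u] + 1e-9) continue;
    if (dist[u] > dist[far]) far = u;
    int r = u % nr, c = u / nr;
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        if (!dr && !dc) continue;
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
        if (!skel(rr, cc)) continue;
        int v = rr + cc * nr;
        double w = (dr && dc) ? 1.4142135623730951 : 1.0;
        if (dist[v] < 0 || dist[u] + w < dist[v] - 1e-9) {
          dist[v] = dist[u] + w;
          parent[v] = u;
          q.push(std::make_pair(dist[v], v));
        }
      }
  }
  std::vector<int> chain;
  for (int u = far; u >= 0; u = parent[u]) chain.push_back(u);
  std::reverse(chain.begin(), chain.end());
  IntegerMatrix out(chain.size(), 2);
  for (size_t i = 0; i < chain.size(); ++i) {
    out(i, 0) = chain[i] % nr + 1;
    out(i, 1) = chain[i] / nr + 1;
  }
  return out;
}
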
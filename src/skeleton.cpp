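#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-neighbourhood in Zhang-Suen order: P2..P9 clockwise from north.
// Matrices are row-major indexed (i = row, j = col); outside pixels read as 0.
static inline int px(const IntegerMatrix &m, int i, int j) {
  if (i < 0 || j < 0 || i >= m.nrow() || j >= m.ncol()) return 0;
  return m(i, j);
}

static inline void ring(const IntegerMatrix &m, int i, int j, int p[8]) {
  p[0] = px(m, i - 1, j);     // N
  p[1] = px(m, i - 1, j + 1); // NE
  p[2] = px(m, i, j + 1);     // E
  p[3] = px(m, i + 1, j + 1); // SE
  p[4] = px(m, i + 1, j);     // S
  p[5] = px(m, i + 1, j - 1); // SW
  p[6] = px(m, i, j - 1);     // W
  p[7] = px(m, i - 1, j - 1); // NW
}

static inline int transitions(const int p[8]) {
  int a = 0;
  for (int k = 0; k < 8; ++k) a += (p[k] == 0 && p[(k + 1) % 8] == 1);
  return a;
}

// Yokoi connectivity number for 8-connectivity: the number of foreground
// components 8-adjacent to the centre pixel. The centre is a simple point
// (deletable without changing topology) iff this equals 1.
static inline int yokoi8(const int p[8]) {
  // ring order here: p[0]=N p[1]=NE p[2]=E p[3]=SE p[4]=S p[5]=SW p[6]=W p[7]=NW
  int q[8];
  for (int k = 0; k < 8; ++k) q[k] = 1 - p[k];
  int c = 0;
  for (int k = 0; k < 8; k += 2)
    c += q[k] - q[k] * q[(k + 1) % 8] * q[(k + 2) % 8];
  return c;
}

// [[Rcpp::export]]
IntegerMatrix thin_zhangsuen(IntegerMatrix mask, int max_iter = 1000) {
  IntegerMatrix m = clone(mask);
  int nr = m.nrow(), nc = m.ncol();
  std::vector<std::pair<int, int> > del;
  del.reserve(1024);
  for (int it = 0; it < max_iter; ++it) {
    bool changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (int i = 0; i < nr; ++i) {
        for (int j = 0; j < nc; ++j) {
          if (!m(i, j)) continue;
          int p[8];
          ring(m, i, j, p);
          int b = p[0] + p[1] + p[2] + p[3] + p[4] + p[5] + p[6] + p[7];
          if (b < 2 || b > 6) continue;
          if (transitions(p) != 1) continue;
          // p[0]=N(P2), p[2]=E(P4), p[4]=S(P6), p[6]=W(P8)
          if (sub == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          del.push_back(std::make_pair(i, j));
        }
      }
      for (size_t k = 0; k < del.size(); ++k) m(del[k].first, del[k].second) = 0;
      if (!del.empty()) changed = true;
    }
    if (!changed) break;
  }
  // Sequential cleanup of redundant staircase pixels: delete simple points
  // (Yokoi 8-connectivity number 1) that are not endpoints. Immediate update
  // keeps the result 8-connected and minimally thin.
  for (int pass = 0; pass < 8; ++pass) {
    bool changed = false;
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) {
        if (!m(i, j)) continue;
        int p[8];
        ring(m, i, j, p);
        int b = p[0] + p[1] + p[2] + p[3] + p[4] + p[5] + p[6] + p[7];
        if (b >= 2 && b <= 6 && yokoi8(p) == 1) {
          m(i, j) = 0;
          changed = true;
        }
      }
    }
    if (!changed) break;
  }
  return m;
}

// Count of foreground 8-neighbours for every pixel.
// [[Rcpp::export]]
IntegerMatrix neighbor_count8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      int p[8];
      ring(mask, i, j, p);
      out(i, j) = p[0] + p[1] + p[2] + p[3] + p[4] + p[5] + p[6] + p[7];
    }
  return out;
}

// 8-connected component labelling; labels contiguous 1..n in raster-scan
// order of first encounter (deterministic).
// [[Rcpp::export]]
IntegerMatrix label_components8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(4096);
  int next = 0;
  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int ni = ci + di[k], nj = cj + dj[k];
          if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
          if (mask(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Order the pixels of a simple 8-connected path (degree <= 2 everywhere).
// Returns 1-based positions along the path for each input pixel, starting
// from an endpoint (or from the first pixel for a closed loop).
// [[Rcpp::export]]
IntegerVector order_path(IntegerVector rows, IntegerVector cols) {
  int n = rows.size();
  IntegerVector ord(n, NA_INTEGER);
  if (n == 0) return ord;
  // adjacency by brute force; path segments are short
  std::vector<std::vector<int> > adj(n);
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      int dr = rows[a] - rows[b], dc = cols[a] - cols[b];
      if (dr >= -1 && dr <= 1 && dc >= -1 && dc <= 1)
        { adj[a].push_back(b); adj[b].push_back(a); }
    }
  int start = 0;
  for (int a = 0; a < n; ++a) if (adj[a].size() <= 1) { start = a; break; }
  std::vector<bool> seen(n, false);
  int cur = start, pos = 1;
  while (cur >= 0) {
    ord[cur] = pos++;
    seen[cur] = true;
    int nxt = -1;
    for (size_t k = 0; k < adj[cur].size(); ++k)
      if (!seen[adj[cur][k]]) { nxt = adj[cur][k]; break; }
    cur = nxt;
  }
  return ord;
}
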
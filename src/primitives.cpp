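#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Euclidean distance transform (Felzenszwalb & Huttenlocher), separable,
// anisotropic-capable. Input: logical target mask; output: distance in the
// units of `spacing` from every voxel to the nearest TRUE voxel.
// Arrays are column-major with dim = (n1, n2, n3) = (z, y, x).
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double> &f, double s) {
  // squared distance transform on a line with grid step s; +Inf entries
  // (no source anywhere on the line yet) contribute no parabola
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  std::vector<double> d(n, INF);
  const double s2 = s * s;
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double sq = (double)q;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double sec;
    while (true) {
      double sv = (double)v[k];
      sec = ((f[q] + s2 * sq * sq) - (f[v[k]] + s2 * sv * sv)) / (2.0 * s2 * (sq - sv));
      if (sec <= z[k]) {
        --k;
        if (k < 0) break;
      } else break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : sec;
    z[k + 1] = INF;
  }
  if (k < 0) return; // whole line has no source
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    double dq = (double)(q - v[k]) * s;
    d[q] = dq * dq + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  const double INF = std::numeric_limits<double>::infinity();
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> line;
  // axis 1 (stride 1)
  line.resize(n1);
  for (int x = 0; x < n3; ++x)
    for (int y = 0; y < n2; ++y) {
      R_xlen_t base = (R_xlen_t)n1 * (y + (R_xlen_t)n2 * x);
      for (int i = 0; i < n1; ++i) line[i] = out[base + i];
      dt1d(line, spacing[0]);
      for (int i = 0; i < n1; ++i) out[base + i] = line[i];
    }
  // axis 2 (stride n1)
  line.resize(n2);
  for (int x = 0; x < n3; ++x)
    for (int zi = 0; zi < n1; ++zi) {
      R_xlen_t base = zi + (R_xlen_t)n1 * n2 * x;
      for (int i = 0; i < n2; ++i) line[i] = out[base + (R_xlen_t)n1 * i];
      dt1d(line, spacing[1]);
      for (int i = 0; i < n2; ++i) out[base + (R_xlen_t)n1 * i] = line[i];
    }
  // axis 3 (stride n1*n2)
  line.resize(n3);
  for (int y = 0; y < n2; ++y)
    for (int zi = 0; zi < n1; ++zi) {
      R_xlen_t base = zi + (R_xlen_t)n1 * y;
      for (int i = 0; i < n3; ++i) line[i] = out[base + (R_xlen_t)n1 * n2 * i];
      dt1d(line, spacing[2]);
      for (int i = 0; i < n3; ++i) out[base + (R_xlen_t)n1 * n2 * i] = line[i];
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling, 6- or 26-connectivity, BFS.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n, 0);
  std::vector<int> d1, d2, d3;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        d1.push_back(a); d2.push_back(b); d3.push_back(c);
      }
  const int nd = (int)d1.size();
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int z = (int)(cur % n1);
      int y = (int)((cur / n1) % n2);
      int x = (int)(cur / ((R_xlen_t)n1 * n2));
      for (int k = 0; k < nd; ++k) {
        int zz = z + d1[k], yy = y + d2[k], xx = x + d3[k];
        if (zz < 0 || zz >= n1 || yy < 0 || yy >= n2 || xx < 0 || xx >= n3) continue;
        R_xlen_t idx = zz + (R_xlen_t)n1 * (yy + (R_xlen_t)n2 * xx);
        if (mask[idx] && lab[idx] == 0) { lab[idx] = next; stack.push_back(idx); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Topological thinning to a 1-voxel curve skeleton: distance-ordered
// homotopic thinning. A voxel is deletable when it is a (26,6) simple point
// (one 26-connected object component in N26; one 6-connected background
// component in N18 that is 6-adjacent to the center) and not a curve
// endpoint (<= 1 object neighbor). Voxels are peeled in increasing order of
// distance to the background so the result is centered.
// ---------------------------------------------------------------------------

static inline int off_index(int a, int b, int c) { // a,b,c in {-1,0,1}
  return (a + 1) + 3 * (b + 1) + 9 * (c + 1);
}

static bool is_simple(const bool nb[27]) {
  // nb: 3x3x3 object occupancy, center nb[13] ignored.
  // --- object: 26-connected components among object voxels in N26 ---
  bool obj[27];
  for (int i = 0; i < 27; ++i) obj[i] = nb[i];
  obj[13] = false;
  int ncomp = 0;
  bool seen[27] = {false};
  int stack[27], top;
  for (int s = 0; s < 27; ++s) {
    if (!obj[s] || seen[s]) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    top = 0; stack[top++] = s; seen[s] = true;
    while (top > 0) {
      int cur = stack[--top];
      int ca = cur % 3 - 1, cb = (cur / 3) % 3 - 1, cc = cur / 9 - 1;
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            int na = ca + a, nbb = cb + b, nc = cc + c;
            if (na < -1 || na > 1 || nbb < -1 || nbb > 1 || nc < -1 || nc > 1) continue;
            int id = off_index(na, nbb, nc);
            if (id == 13 || id == cur) continue;
            if (obj[id] && !seen[id]) { seen[id] = true; stack[top++] = id; }
          }
    }
  }
  if (ncomp != 1) return false;

  // --- background: 6-connected components in N18 touching a face neighbor ---
  // N18 = offsets with max-norm 1 and manhattan <= 2, excluding center.
  bool bg[27];
  for (int i = 0; i < 27; ++i) {
    int a = i % 3 - 1, b = (i / 3) % 3 - 1, c = i / 9 - 1;
    int manh = std::abs(a) + std::abs(b) + std::abs(c);
    bg[i] = (manh >= 1 && manh <= 2) && !nb[i];
  }
  int nbg = 0;
  bool seen2[27] = {false};
  for (int s = 0; s < 27; ++s) {
    if (!bg[s]) continue;
    int a = s % 3 - 1, b = (s / 3) % 3 - 1, c = s / 9 - 1;
    if (std::abs(a) + std::abs(b) + std::abs(c) != 1) continue; // start only from face neighbors
    if (seen2[s]) continue;
    ++nbg;
    if (nbg > 1) return false;
    top = 0; stack[top++] = s; seen2[s] = true;
    while (top > 0) {
      int cur = stack[--top];
      int ca = cur % 3 - 1, cb = (cur / 3) % 3 - 1, cc = cur / 9 - 1;
      const int fd[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int na = ca + fd[k][0], nbb = cb + fd[k][1], nc = cc + fd[k][2];
        if (na < -1 || na > 1 || nbb < -1 || nbb > 1 || nc < -1 || nc > 1) continue;
        int id = off_index(na, nbb, nc);
        if (id == 13) continue;
        if (bg[id] && !seen2[id]) { seen2[id] = true; stack[top++] = id; }
      }
    }
  }
  return nbg == 1;
}

// For each 26-connected component, find the two voxels that are farthest
// apart along the component (double BFS); protecting these "cap anchors"
// during thinning prevents the skeleton from retreating off the tube ends.
// Returns 0-based linear indices.

// [[Rcpp::export]]
IntegerVector cap_anchors_cpp(LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<int> dist(n, -1);
  std::vector<char> seen(n, 0);
  std::vector<R_xlen_t> queue;
  std::vector<int> anchors;
  int d1[26], d2[26], d3[26];
  int nd = 0;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        d1[nd] = a; d2[nd] = b; d3[nd] = c; ++nd;
      }
  auto bfs = [&](R_xlen_t start) -> R_xlen_t {
    std::fill(dist.begin(), dist.end(), -1);
    std::queue<R_xlen_t> q;
    q.push(start); dist[start] = 0;
    R_xlen_t far = start; int fard = 0;
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int z = (int)(cur % n1);
      int y = (int)((cur / n1) % n2);
      int x = (int)(cur / ((R_xlen_t)n1 * n2));
      for (int k = 0; k < nd; ++k) {
        int zz = z + d1[k], yy = y + d2[k], xx = x + d3[k];
        if (zz < 0 || zz >= n1 || yy < 0 || yy >= n2 || xx < 0 || xx >= n3) continue;
        R_xlen_t idx = zz + (R_xlen_t)n1 * (yy + (R_xlen_t)n2 * xx);
        if (mask[idx] && dist[idx] < 0) {
          dist[idx] = dist[cur] + 1;
          if (dist[idx] > fard) { fard = dist[idx]; far = idx; }
          q.push(idx);
        }
      }
    }
    return far;
  };
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || seen[s]) continue;
    R_xlen_t a1 = bfs(s);
    // mark component as seen using the dist field from this BFS
    for (R_xlen_t i = 0; i < n; ++i) if (dist[i] >= 0) seen[i] = 1;
    R_xlen_t a2 = bfs(a1);
    anchors.push_back((int)a1);
    anchors.push_back((int)a2);
  }
  return wrap(anchors);
}

// [[Rcpp::export]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dim,
                         IntegerVector anchors = IntegerVector::create()) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<char> m(n);
  for (R_xlen_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;
  std::vector<char> keep(n, 0);
  for (int i = 0; i < anchors.size(); ++i) keep[anchors[i]] = 1;

  NumericVector sp = NumericVector::create(1.0, 1.0, 1.0);
  LogicalVector inv(n);
  for (R_xlen_t i = 0; i < n; ++i) inv[i] = !m[i];
  NumericVector dist = edt3d_cpp(inv, dim, sp); // distance of object voxels to background

  std::vector<R_xlen_t> order;
  order.reserve(n / 8);
  for (R_xlen_t i = 0; i < n; ++i) if (m[i]) order.push_back(i);
  std::stable_sort(order.begin(), order.end(),
                   [&dist](R_xlen_t a, R_xlen_t b) { return dist[a] < dist[b]; });

  auto occ = [&](int z, int y, int x) -> bool {
    if (z < 0 || z >= n1 || y < 0 || y >= n2 || x < 0 || x >= n3) return false;
    return m[z + (R_xlen_t)n1 * (y + (R_xlen_t)n2 * x)] != 0;
  };

  bool changed = true;
  bool nb[27];
  while (changed) {
    changed = false;
    for (size_t oi = 0; oi < order.size(); ++oi) {
      R_xlen_t idx = order[oi];
      if (!m[idx] || keep[idx]) continue;
      int z = (int)(idx % n1);
      int y = (int)((idx / n1) % n2);
      int x = (int)(idx / ((R_xlen_t)n1 * n2));
      int nnb = 0;
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            bool o = occ(z + a, y + b, x + c);
            nb[off_index(a, b, c)] = o;
            if (o && !(a == 0 && b == 0 && c == 0)) ++nnb;
          }
      if (nnb <= 1) continue;       // curve endpoint: keep
      if (nnb == 26) continue;      // interior voxel: not deletable yet
      nb[13] = true;
      if (is_simple(nb)) {
        m[idx] = 0;
        changed = true;
      }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// 2D grayscale min/max filter over a disk (used for rolling-ball style
// background flattening before mask creation).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix disk_filter2d_cpp(NumericMatrix img, double radius, bool maximum) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dr, dc;
  int r = (int)std::floor(radius);
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b)
      if ((double)a * a + (double)b * b <= radius * radius) { dr.push_back(a); dc.push_back(b); }
  const int nd = (int)dr.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double v = maximum ? -std::numeric_limits<double>::infinity()
                         :  std::numeric_limits<double>::infinity();
      for (int k = 0; k < nd; ++k) {
        int ii = i + dr[k], jj = j + dc[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        double w = img(ii, jj);
        v = maximum ? std::max(v, w) : std::min(v, w);
      }
      out(i, j) = v;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Separable 1D convolution along an axis with replicate padding (Gaussian
// smoothing of large volumes) and binary dilation/erosion by an explicit
// voxel-offset structuring element (fast path for small radii).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector arr, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const int kr = ((int)kernel.size() - 1) / 2;
  NumericVector out(n);
  int len, nline;
  R_xlen_t stride;
  if (axis == 1) { len = n1; stride = 1; nline = n2 * n3; }
  else if (axis == 2) { len = n2; stride = n1; nline = n1 * n3; }
  else { len = n3; stride = (R_xlen_t)n1 * n2; nline = n1 * n2; }
  std::vector<double> line(len);
  for (int li = 0; li < nline; ++li) {
    R_xlen_t base;
    if (axis == 1) base = (R_xlen_t)li * n1;
    else if (axis == 2) {
      int z = li % n1, x = li / n1;
      base = z + (R_xlen_t)n1 * n2 * x;
    } else base = li;
    for (int i = 0; i < len; ++i) line[i] = arr[base + stride * i];
    for (int i = 0; i < len; ++i) {
      double acc = 0;
      for (int k = -kr; k <= kr; ++k) {
        int j = i + k;
        if (j < 0) j = 0; else if (j >= len) j = len - 1;
        acc += kernel[k + kr] * line[j];
      }
      out[base + stride * i] = acc;
    }
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector morph3d_cpp(LogicalVector mask, IntegerVector dim,
                          IntegerMatrix offsets, bool dilate) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const int nd = offsets.nrow();
  LogicalVector out(n);
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    int z = (int)(idx % n1);
    int y = (int)((idx / n1) % n2);
    int x = (int)(idx / ((R_xlen_t)n1 * n2));
    bool acc = !dilate;
    for (int k = 0; k < nd; ++k) {
      int zz = z + offsets(k, 0), yy = y + offsets(k, 1), xx = x + offsets(k, 2);
      bool v;
      if (zz < 0 || zz >= n1 || yy < 0 || yy >= n2 || xx < 0 || xx >= n3)
        v = false; // outside the volume counts as background
      else
        v = mask[zz + (R_xlen_t)n1 * (yy + (R_xlen_t)n2 * xx)];
      if (dilate) { if (v) { acc = true; break; } }
      else { if (!v) { acc = false; break; } }
    }
    out[idx] = acc;
  }
  return out;
}
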
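#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Grid indexing: matrices are column-major R matrices, pixel (r, c) with
// r in 1..H (row 1 = top of the image), c in 1..W. Linear index = (c-1)*H + (r-1).

// 4-connected components of a logical mask. Labels 1..k in raster-scan
// order of each component's first pixel; 0 elsewhere.
// [[Rcpp::export]]
IntegerMatrix cpp_label4(const LogicalMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(c * H + r);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % H, cc = idx / H;
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(c2 * H + r2);
          }
        }
      }
    }
  }
  return lab;
}

// 4-connected BFS distance (in steps) from each true pixel of `mask` to the
// nearest false pixel or image border. Used to pick the most interior seed.
// [[Rcpp::export]]
IntegerMatrix cpp_dist_to_zero(const LogicalMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix dist(H, W);
  std::queue<int> q;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) { dist(r, c) = 0; q.push(c * H + r); continue; }
      bool border = (r == 0 || r == H - 1 || c == 0 || c == W - 1);
      if (border) { dist(r, c) = 1; q.push(c * H + r); }
      else dist(r, c) = -1;
    }
  }
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int r = idx % H, c = idx / H;
    for (int k = 0; k < 4; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
      if (dist(r2, c2) == -1) {
        dist(r2, c2) = dist(r, c) + 1;
        q.push(c2 * H + r2);
      }
    }
  }
  return dist;
}

// Multi-source first-arrival (Dijkstra on the 8-connected pixel grid).
// speed: positive propagation speed per pixel; NA = outside the wing
// silhouette (never entered). Edge cost between adjacent pixels a,b is
// steplen * (1/speed_a + 1/speed_b) / 2, steplen in {1, sqrt(2)}.
// seeds: 1-based (row, col) pairs, label i+1 for seed i.
// Returns labels (0 where unreached) and arrival times (Inf unreached).
// [[Rcpp::export]]
List cpp_first_arrival(const NumericMatrix& speed,
                       const IntegerVector& seed_row,
                       const IntegerVector& seed_col) {
  int H = speed.nrow(), W = speed.ncol();
  int n = H * W;
  std::vector<double> arr(n, std::numeric_limits<double>::infinity());
  std::vector<int> lab(n, 0);
  std::vector<bool> done(n, false);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int i = 0; i < seed_row.size(); ++i) {
    int r = seed_row[i] - 1, c = seed_col[i] - 1;
    if (r < 0 || r >= H || c < 0 || c >= W)
      stop("seed %d outside the image", i + 1);
    if (NumericMatrix::is_na(speed(r, c)))
      stop("seed %d lies outside the wing silhouette", i + 1);
    int idx = c * H + r;
    arr[idx] = 0.0;
    lab[idx] = i + 1;
    pq.push(QE(0.0, idx));
  }
  // 16-neighbourhood (axis, diagonal and knight moves) keeps the grid
  // metric within ~3% of Euclidean, so fronts meet close to true midlines
  const int dr[16] = {-1, 1, 0, 0, -1, -1, 1, 1,
                      -2, -2, -1, -1, 1, 1, 2, 2};
  const int dc[16] = {0, 0, -1, 1, -1, 1, -1, 1,
                      -1, 1, -2, 2, -2, 2, -1, 1};
  const double SQ2 = std::sqrt(2.0), SQ5 = std::sqrt(5.0);
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int idx = top.second;
    if (done[idx]) continue;
    done[idx] = true;
    int r = idx % H, c = idx / H;
    double inv_here = 1.0 / speed(r, c);
    for (int k = 0; k < 16; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
      if (NumericMatrix::is_na(speed(r2, c2))) continue;
      int idx2 = c2 * H + r2;
      if (done[idx2]) continue;
      double steplen, w;
      if (k < 4) steplen = 1.0;
      else if (k < 8) steplen = SQ2;
      else steplen = SQ5;
      if (k < 8) {
        w = steplen * 0.5 * (inv_here + 1.0 / speed(r2, c2));
      } else {
        // knight move: pass through the two cells nearest the chord so a
        // slow vein cannot be jumped over
        int rm1 = r + dr[k] / 2, cm1 = c + dc[k] / 2;
        int rm2 = r2 - dr[k] / 2, cm2 = c2 - dc[k] / 2;
        if (NumericMatrix::is_na(speed(rm1, cm1)) ||
            NumericMatrix::is_na(speed(rm2, cm2))) continue;
        double invm = 0.5 * (1.0 / speed(rm1, cm1) + 1.0 / speed(rm2, cm2));
        w = steplen * (0.25 * (inv_here + 1.0 / speed(r2, c2)) + 0.5 * invm);
      }
      double cand = top.first + w;
      if (cand < arr[idx2]) {
        arr[idx2] = cand;
        lab[idx2] = lab[idx];
        pq.push(QE(cand, idx2));
      }
    }
  }
  NumericMatrix arrival(H, W);
  IntegerMatrix labels(H, W);
  for (int i = 0; i < n; ++i) {
    arrival[i] = arr[i];
    labels[i] = lab[i];
  }
  return List::create(_["labels"] = labels, _["arrival"] = arrival);
}

// Trace the outer boundary of each positive label on the pixel-corner
// lattice. Corners are (i, j), i in 0..H (down from the top edge),
// j in 0..W. The ring is walked with the region on the LEFT of the travel
// direction; diagonal pinches are split (consistent with 4-connectivity).
// Returns a list: for label k a (m x 2) matrix of (i, j) corner coordinates,
// one ring per label, not closed (first vertex not repeated).
// [[Rcpp::export]]
List cpp_trace_rings(const IntegerMatrix& labels, int nlab) {
  int H = labels.nrow(), W = labels.ncol();
  List out(nlab);
  // helper lambda: label at pixel (r, c), 0 outside
  #define LAB(r, c) (((r) < 0 || (r) >= H || (c) < 0 || (c) >= W) ? 0 : labels((r), (c)))
  for (int k = 1; k <= nlab; ++k) {
    // find topmost-leftmost pixel of label k (scan columns outer, rows inner
    // -> first in column-major order; any deterministic start works)
    int sr = -1, sc = -1;
    for (int c = 0; c < W && sr < 0; ++c)
      for (int r = 0; r < H; ++r)
        if (labels(r, c) == k) { sr = r; sc = c; break; }
    if (sr < 0) { out[k - 1] = R_NilValue; continue; }
    // Start on the left edge of pixel (sr, sc), walking DOWN (region on left
    // means: travelling down the edge x=sc, pixels to the left in travel
    // direction are at column sc). Directions: 0=up,1=right,2=down,3=left
    // in (i, j) corner space where i grows downward.
    // Travel direction d moves corner by: up (i-1), right (j+1), down (i+1),
    // left (j-1). Pixel on the LEFT of travel:
    //  up:    pixel (i-1, j-1)   (left of upward travel)
    //  right: pixel (i-1, j)
    //  down:  pixel (i,   j)
    //  left:  pixel (i,   j-1)
    // We walk so label-k is on the left.
    int i0 = sr, j0 = sc;      // top-left corner of start pixel
    int ci = i0, cj = j0, d = 2; // moving down along the pixel's left edge
    std::vector<int> ri, rj;
    int guard = 4 * (H + 2) * (W + 2) * 4;
    do {
      ri.push_back(ci); rj.push_back(cj);
      // advance one step
      if (d == 0) --ci; else if (d == 1) ++cj; else if (d == 2) ++ci; else --cj;
      // choose next direction: prefer turning left, then straight, then
      // right, then back; a turn is taken when the pixel on the left of the
      // candidate direction is label k and the pixel on its right is not.
      int nd = -1;
      for (int t = 0; t < 4; ++t) {
        int cand = (d + 3 + t) % 4; // left turn first (d-1), then d, d+1, d+2
        int lr, lc, rr, rc;
        if (cand == 0)      { lr = ci - 1; lc = cj - 1; rr = ci - 1; rc = cj; }
        else if (cand == 1) { lr = ci - 1; lc = cj;     rr = ci;     rc = cj; }
        else if (cand == 2) { lr = ci;     lc = cj;     rr = ci;     rc = cj - 1; }
        else                { lr = ci;     lc = cj - 1; rr = ci - 1; rc = cj - 1; }
        if (LAB(lr, lc) == k && LAB(rr, rc) != k) { nd = cand; break; }
      }
      if (nd < 0) stop("boundary tracing failed for label %d", k);
      d = nd;
      if (--guard <= 0) stop("boundary tracing did not terminate for label %d", k);
    } while (!(ci == i0 && cj == j0 && d == 2));
    int m = (int)ri.size();
    IntegerMatrix ring(m, 2);
    for (int t = 0; t < m; ++t) { ring(t, 0) = ri[t]; ring(t, 1) = rj[t]; }
    out[k - 1] = ring;
  }
  #undef LAB
  return out;
}

// Exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher):
// for every pixel, squared distance to the nearest FALSE pixel of `mask`.
// Pixels beyond the image border are NOT counted as false.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(const LogicalMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  const double INF = 1e18;
  NumericMatrix D(H, W);
  // 1-D pass along rows (within each column): distance to nearest false
  for (int c = 0; c < W; ++c) {
    double d = INF;
    for (int r = 0; r < H; ++r) {
      d = mask(r, c) ? (d >= INF ? INF : d + 1.0) : 0.0;
      D(r, c) = d;
    }
    d = INF;
    for (int r = H - 1; r >= 0; --r) {
      d = mask(r, c) ? (d >= INF ? INF : d + 1.0) : 0.0;
      if (d < D(r, c)) D(r, c) = d;
    }
    for (int r = 0; r < H; ++r)
      D(r, c) = D(r, c) >= INF ? INF : D(r, c) * D(r, c);
  }
  // lower envelope of parabolas along each row (finite columns only)
  std::vector<int> v(W), cols(W);
  std::vector<double> z(W + 1), f(W), d(W);
  for (int r = 0; r < H; ++r) {
    int m = 0;
    for (int c = 0; c < W; ++c)
      if (D(r, c) < INF) { cols[m] = c; f[m] = D(r, c); ++m; }
    if (m == 0) continue;   // row stays INF
    int k = 0;
    v[0] = 0; z[0] = -INF; z[1] = INF;
    for (int qi = 1; qi < m; ++qi) {
      double q = cols[qi];
      double s;
      while (true) {
        double p = cols[v[k]];
        s = ((f[qi] + q * q) - (f[v[k]] + p * p)) / (2.0 * q - 2.0 * p);
        if (s <= z[k] && k > 0) { --k; continue; }
        break;
      }
      ++k; v[k] = qi; z[k] = s; z[k + 1] = INF;
    }
    k = 0;
    for (int c = 0; c < W; ++c) {
      while (z[k + 1] < c) ++k;
      double p = cols[v[k]];
      d[c] = (c - p) * (c - p) + f[v[k]];
    }
    for (int c = 0; c < W; ++c) D(r, c) = d[c];
  }
  return D;
}

// Scanline fill of a simple polygon given in pixel coordinates (x right,
// y DOWN, matching row index). Sets inside pixels (centre test, even-odd
// rule) to `value` in img (modified copy returned).
// [[Rcpp::export]]
NumericMatrix cpp_fill_polygon(NumericMatrix img,
                               const NumericVector& px,
                               const NumericVector& py,
                               double value) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out = clone(img);
  int n = px.size();
  std::vector<double> xs;
  for (int r = 0; r < H; ++r) {
    double ycen = r + 0.5;
    xs.clear();
    for (int i = 0; i < n; ++i) {
      int j = (i + 1) % n;
      double y1 = py[i], y2 = py[j];
      if ((y1 <= ycen && y2 > ycen) || (y2 <= ycen && y1 > ycen)) {
        double t = (ycen - y1) / (y2 - y1);
        xs.push_back(px[i] + t * (px[j] - px[i]));
      }
    }
    std::sort(xs.begin(), xs.end());
    for (size_t s = 0; s + 1 < xs.size(); s += 2) {
      int c0 = (int)std::ceil(xs[s] - 0.5);
      int c1 = (int)std::floor(xs[s + 1] - 0.5);
      if (c0 < 0) c0 = 0;
      if (c1 >= W) c1 = W - 1;
      for (int c = c0; c <= c1; ++c) out(r, c) = value;
    }
  }
  return out;
}

// Draw thick segments (veins): pixels whose centre lies within width/2 of
// any segment get `value`. Coordinates in pixel space (x right, y down).
// [[Rcpp::export]]
NumericMatrix cpp_draw_segments(NumericMatrix img,
                                const NumericMatrix& seg, // x1,y1,x2,y2 rows
                                double width, double value) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out = clone(img);
  double hw = width / 2.0;
  for (int s = 0; s < seg.nrow(); ++s) {
    double x1 = seg(s, 0), y1 = seg(s, 1), x2 = seg(s, 2), y2 = seg(s, 3);
    int c0 = (int)std::floor(std::min(x1, x2) - hw - 1);
    int c1 = (int)std::ceil(std::max(x1, x2) + hw + 1);
    int r0 = (int)std::floor(std::min(y1, y2) - hw - 1);
    int r1 = (int)std::ceil(std::max(y1, y2) + hw + 1);
    if (c0 < 0) c0 = 0;
    if (r0 < 0) r0 = 0;
    if (c1 >= W) c1 = W - 1;
    if (r1 >= H) r1 = H - 1;
    double dx = x2 - x1, dy = y2 - y1;
    double len2 = dx * dx + dy * dy;
    for (int r = r0; r <= r1; ++r) {
      for (int c = c0; c <= c1; ++c) {
        double pxx = c + 0.5, pyy = r + 0.5;
        double t = len2 > 0 ? ((pxx - x1) * dx + (pyy - y1) * dy) / len2 : 0.0;
        if (t < 0) t = 0;
        if (t > 1) t = 1;
        double ddx = pxx - (x1 + t * dx), ddy = pyy - (y1 + t * dy);
        if (ddx * ddx + ddy * ddy <= hw * hw) out(r, c) = value;
      }
    }
  }
  return out;
}

// Exact maximum-modularity partition by enumeration of all set partitions
// (restricted-growth strings), for small weighted graphs (N <= 12).
// W: symmetric nonnegative weight matrix, zero diagonal.
// Returns 0-based community labels (first-appearance order) and Q.
// [[Rcpp::export]]
List cpp_exact_modularity(const NumericMatrix& Wm) {
  int n = Wm.nrow();
  if (n < 2) stop("need at least 2 nodes");
  if (n > 12) stop("exact enumeration limited to 12 nodes");
  std::vector<double> deg(n, 0.0);
  double two_m = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) { deg[i] += Wm(i, j); two_m += Wm(i, j); }
  if (two_m <= 0) stop("graph has no edges");
  // B_ij = W_ij - k_i k_j / (2m); Q = sum_{same community} B_ij / (2m)
  std::vector<double> B(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      B[i * n + j] = Wm(i, j) - deg[i] * deg[j] / two_m;
  std::vector<int> a(n, 0), best(n, 0);
  double bestQ = -std::numeric_limits<double>::infinity();
  // iterate restricted growth strings: a[0] = 0; a[i] <= max(a[0..i-1]) + 1
  std::vector<int> mx(n, 0); // mx[i] = max of a[0..i]
  int i = n - 1;
  while (true) {
    // evaluate current string
    double Q = 0.0;
    for (int p = 0; p < n; ++p)
      for (int q = 0; q < n; ++q)
        if (a[p] == a[q]) Q += B[p * n + q];
    Q /= two_m;
    if (Q > bestQ + 1e-15) { bestQ = Q; best = a; }
    // next restricted growth string
    i = n - 1;
    while (i > 0 && a[i] == mx[i - 1] + 1) --i;
    if (i == 0) break;
    a[i] += 1;
    mx[i] = std::max(mx[i - 1], a[i]);
    for (int j = i + 1; j < n; ++j) { a[j] = 0; mx[j] = mx[i]; }
  }
  return List::create(_["labels"] = IntegerVector(best.begin(), best.end()),
                      _["Q"] = bestQ);
}
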
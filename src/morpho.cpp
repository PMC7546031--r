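// Low-level 3D raster primitives. Arrays are column-major with dim (nz, ny, nx),
// matching R: linear index = z + nz*(y + ny*x), 0-based here.
#include <Rcpp.h>
#include <queue>
#include <deque>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

struct NbOffset { int dz, dy, dx; double w; };

static std::vector<NbOffset> neighborhood(int connectivity, double sz, double sy, double sx) {
  std::vector<NbOffset> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && m != 1) continue;
        double w = std::sqrt(dz * sz * dz * sz + dy * sy * dy * sy + dx * sx * dx * sx);
        nb.push_back({dz, dy, dx, w});
      }
  return nb;
}

// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<NbOffset> nb = neighborhood(connectivity, 1, 1, 1);
  std::vector<int> stack;
  int cur = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++cur;
    lab[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int x = v / (nz * ny), r = v % (nz * ny), y = r / nz, z = r % nz;
      for (size_t k = 0; k < nb.size(); ++k) {
        int zz = z + nb[k].dz, yy = y + nb[k].dy, xx = x + nb[k].dx;
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        int u = lin(zz, yy, xx, nz, ny);
        if (mask[u] && lab[u] == 0) { lab[u] = cur; stack.push_back(u); }
      }
    }
  }
  return lab;
}

// Multi-source Dijkstra over the foreground voxel graph (26-connectivity),
// edge weights = physical distance between voxel centers.
// sources: 0-based linear indices. Returns dist (Inf where unreachable) and
// pred (0-based linear index of predecessor, -1 at sources / unreachable).
// [[Rcpp::export(name = ".geodesic_paths")]]
List geodesic_paths(LogicalVector mask, IntegerVector dims, NumericVector spacing,
                    IntegerVector sources) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  NumericVector dist(n, R_PosInf);
  IntegerVector pred(n, -1);
  std::vector<NbOffset> nb = neighborhood(26, spacing[0], spacing[1], spacing[2]);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int k = 0; k < sources.size(); ++k) {
    int s = sources[k];
    if (s < 0 || s >= n || !mask[s]) continue;
    dist[s] = 0.0;
    pq.push(QE(0.0, s));
  }
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d = top.first; int v = top.second;
    if (d > dist[v]) continue;
    int x = v / (nz * ny), r = v % (nz * ny), y = r / nz, z = r % nz;
    for (size_t k = 0; k < nb.size(); ++k) {
      int zz = z + nb[k].dz, yy = y + nb[k].dy, xx = x + nb[k].dx;
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      int u = lin(zz, yy, xx, nz, ny);
      if (!mask[u]) continue;
      double nd = d + nb[k].w;
      if (nd < dist[u]) { dist[u] = nd; pred[u] = v; pq.push(QE(nd, u)); }
    }
  }
  return List::create(_["dist"] = dist, _["pred"] = pred);
}

// ---- marching tetrahedra ------------------------------------------------

static inline void interp_pt(const double *p, const double *q, double vp, double vq,
                             double level, double *out) {
  double t = (level - vp) / (vq - vp);
  for (int k = 0; k < 3; ++k) out[k] = p[k] + t * (q[k] - p[k]);
}

static void add_tri(const double *a, const double *b, const double *c,
                    const double *away_from, bool toward,
                    double &area, double &vol6) {
  // orient so normal points away from `away_from` (toward==false) or toward it
  double u[3], v[3], nrm[3], cen[3], dref[3];
  for (int k = 0; k < 3; ++k) {
    u[k] = b[k] - a[k];
    v[k] = c[k] - a[k];
    cen[k] = (a[k] + b[k] + c[k]) / 3.0;
    dref[k] = cen[k] - away_from[k];
  }
  nrm[0] = u[1] * v[2] - u[2] * v[1];
  nrm[1] = u[2] * v[0] - u[0] * v[2];
  nrm[2] = u[0] * v[1] - u[1] * v[0];
  double dp = nrm[0] * dref[0] + nrm[1] * dref[1] + nrm[2] * dref[2];
  bool flip = toward ? (dp > 0) : (dp < 0);
  const double *bb = b, *cc = c;
  if (flip) { bb = c; cc = b; } // flipping affects only the sign, not the area
  double nlen = std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1] + nrm[2] * nrm[2]);
  area += 0.5 * nlen;
  // signed volume contribution (divergence theorem, origin at 0)
  double s =
    a[0] * (bb[1] * cc[2] - bb[2] * cc[1]) -
    a[1] * (bb[0] * cc[2] - bb[2] * cc[0]) +
    a[2] * (bb[0] * cc[1] - bb[1] * cc[0]);
  vol6 += s;
}

static void do_tet(const double pts[4][3], const double val[4], double level,
                   double &area, double &vol6) {
  bool in[4];
  int nin = 0;
  for (int i = 0; i < 4; ++i) { in[i] = val[i] >= level; if (in[i]) ++nin; }
  if (nin == 0 || nin == 4) return;
  int ii[4], oo[4], ni = 0, no = 0;
  for (int i = 0; i < 4; ++i) { if (in[i]) ii[ni++] = i; else oo[no++] = i; }
  double P[4][3];
  if (nin == 1) {
    int A = ii[0];
    for (int j = 0; j < 3; ++j) interp_pt(pts[A], pts[oo[j]], val[A], val[oo[j]], level, P[j]);
    add_tri(P[0], P[1], P[2], pts[A], false, area, vol6);
  } else if (nin == 3) {
    int D = oo[0];
    for (int j = 0; j < 3; ++j) interp_pt(pts[D], pts[ii[j]], val[D], val[ii[j]], level, P[j]);
    add_tri(P[0], P[1], P[2], pts[D], true, area, vol6);
  } else { // nin == 2: quad ordered AC, AD, BD, BC lies on the four tet faces
    int A = ii[0], B = ii[1], C = oo[0], D = oo[1];
    interp_pt(pts[A], pts[C], val[A], val[C], level, P[0]);
    interp_pt(pts[A], pts[D], val[A], val[D], level, P[1]);
    interp_pt(pts[B], pts[D], val[B], val[D], level, P[2]);
    interp_pt(pts[B], pts[C], val[B], val[C], level, P[3]);
    double mid[3];
    for (int k = 0; k < 3; ++k) mid[k] = 0.5 * (pts[A][k] + pts[B][k]);
    add_tri(P[0], P[1], P[2], mid, false, area, vol6);
    add_tri(P[0], P[2], P[3], mid, false, area, vol6);
  }
}

// Marching tetrahedra over an isotropic scalar field; returns c(area, volume)
// of the `level` isosurface in physical units. The surface is closed provided
// all border values are below `level` (callers pad with zeros).
// [[Rcpp::export(name = ".march_tets")]]
NumericVector march_tets(NumericVector field, IntegerVector dims, double spacing,
                         double level) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  // 8 cube corners, local (z,y,x) offsets; 6 tetrahedra share diagonal 0-6
  static const int corner[8][3] = {
    {0,0,0},{0,0,1},{0,1,1},{0,1,0},{1,0,0},{1,0,1},{1,1,1},{1,1,0}};
  static const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};
  double area = 0.0, vol6 = 0.0;
  double cpts[8][3], cval[8];
  for (int x = 0; x + 1 < nx; ++x)
    for (int y = 0; y + 1 < ny; ++y)
      for (int z = 0; z + 1 < nz; ++z) {
        bool any_in = false, all_in = true;
        for (int c = 0; c < 8; ++c) {
          int zz = z + corner[c][0], yy = y + corner[c][1], xx = x + corner[c][2];
          cval[c] = field[lin(zz, yy, xx, nz, ny)];
          cpts[c][0] = zz * spacing; cpts[c][1] = yy * spacing; cpts[c][2] = xx * spacing;
          if (cval[c] >= level) any_in = true; else all_in = false;
        }
        if (!any_in) continue;
        if (all_in) continue; // interior cube: no surface; volume handled below
        for (int t = 0; t < 6; ++t) {
          double tp[4][3], tv[4];
          for (int i = 0; i < 4; ++i) {
            int c = tets[t][i];
            for (int k = 0; k < 3; ++k) tp[i][k] = cpts[c][k];
            tv[i] = cval[c];
          }
          do_tet(tp, tv, level, area, vol6);
        }
      }
  // vol6/6 is the enclosed volume by the divergence theorem over the closed,
  // outward-oriented surface (origin-independent for closed surfaces).
  NumericVector out = NumericVector::create(area, vol6 / 6.0);
  return out;
}

// ---- 2D rank filters (disc neighborhood, clamped borders) ---------------

static std::vector<std::pair<int,int> > disc_offsets(int radius) {
  std::vector<std::pair<int,int> > off;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      if (dy * dy + dx * dx <= radius * radius) off.push_back(std::make_pair(dy, dx));
  return off;
}

// [[Rcpp::export(name = ".median_filter_2d")]]
NumericMatrix median_filter_2d(NumericMatrix img, int radius) {
  if (radius <= 0) return clone(img);
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<std::pair<int,int> > off = disc_offsets(radius);
  std::vector<double> buf(off.size());
  const int mid = (int)(off.size() - 1) / 2;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      for (size_t k = 0; k < off.size(); ++k) {
        int ii = std::min(std::max(i + off[k].first, 0), nr - 1);
        int jj = std::min(std::max(j + off[k].second, 0), nc - 1);
        buf[k] = img(ii, jj);
      }
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(i, j) = buf[mid];
    }
  return out;
}

// sliding-window min/max over truncated windows [i-r, i+r] (monotonic deque)
static void rank_line(const double *in, double *out, int n, int stride,
                      int r, bool maximum) {
  std::deque<int> dq;
  int right = -1;
  for (int i = 0; i < n; ++i) {
    while (right < std::min(i + r, n - 1)) {
      ++right;
      double v = in[right * stride];
      while (!dq.empty()) {
        double b = in[dq.back() * stride];
        if (maximum ? (b <= v) : (b >= v)) dq.pop_back(); else break;
      }
      dq.push_back(right);
    }
    while (!dq.empty() && dq.front() < i - r) dq.pop_front();
    out[i * stride] = in[dq.front() * stride];
  }
}

// Separable grayscale min/max filter with a (2r+1)^2 square window.
// [[Rcpp::export(name = ".rank_filter_2d")]]
NumericMatrix rank_filter_2d(NumericMatrix img, int radius, bool maximum) {
  if (radius <= 0) return clone(img);
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    rank_line(&img(0, j), &tmp(0, j), nr, 1, radius, maximum);
  for (int i = 0; i < nr; ++i)
    rank_line(&tmp(i, 0), &out(i, 0), nc, nr, radius, maximum);
  return out;
}
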
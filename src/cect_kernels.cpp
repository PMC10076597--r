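#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Volumes are R arrays with dim = (ny, nx, nz), column-major:
// linear index i = y + ny * (x + nx * z), zero-based here.

static inline int lin(int y, int x, int z, int ny, int nx) {
  return y + ny * (x + nx * z);
}

static void neighbor_offsets(int conn, std::vector<std::array<int,3> > &off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        int a = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (a == 0) continue;
        if (conn == 6 && a != 1) continue;
        off.push_back({dy, dx, dz});
      }
}

// Connected-component labeling of a binary volume (BFS, deterministic:
// components numbered by first voxel in scan order).
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  int n = ny * nx * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3> > off;
  neighbor_offsets(connectivity, off);
  std::vector<int> queue;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    queue.clear();
    queue.push_back(i);
    while (!queue.empty()) {
      int cur = queue.back(); queue.pop_back();
      int z = cur / (ny * nx), rem = cur % (ny * nx);
      int x = rem / ny, y = rem % ny;
      for (size_t k = 0; k < off.size(); ++k) {
        int yy = y + off[k][0], xx = x + off[k][1], zz = z + off[k][2];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        int j = lin(yy, xx, zz, ny, nx);
        if (mask[j] && !lab[j]) { lab[j] = next; queue.push_back(j); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Fill internal cavities: background is flooded from the volume border with
// 6-connectivity; unreachable background becomes foreground.
// [[Rcpp::export]]
IntegerVector cpp_fill_holes(IntegerVector mask, IntegerVector dim) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  int n = ny * nx * nz;
  std::vector<char> outside(n, 0);
  std::vector<std::array<int,3> > off;
  neighbor_offsets(6, off);
  std::vector<int> queue;
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        if (y > 0 && y < ny - 1 && x > 0 && x < nx - 1 && z > 0 && z < nz - 1)
          continue;
        int i = lin(y, x, z, ny, nx);
        if (!mask[i] && !outside[i]) { outside[i] = 1; queue.push_back(i); }
      }
  while (!queue.empty()) {
    int cur = queue.back(); queue.pop_back();
    int z = cur / (ny * nx), rem = cur % (ny * nx);
    int x = rem / ny, y = rem % ny;
    for (size_t k = 0; k < off.size(); ++k) {
      int yy = y + off[k][0], xx = x + off[k][1], zz = z + off[k][2];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
        continue;
      int j = lin(yy, xx, zz, ny, nx);
      if (!mask[j] && !outside[j]) { outside[j] = 1; queue.push_back(j); }
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (mask[i] || !outside[i]) ? 1 : 0;
  out.attr("dim") = dim;
  return out;
}

// One-dimensional squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> zpt(n + 1);
  int k = 0;
  v[0] = 0; zpt[0] = -1e20; zpt[1] = 1e20;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zpt[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; zpt[k] = s; zpt[k + 1] = 1e20;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zpt[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (voxel units) from each foreground voxel to the
// nearest background voxel center. Background voxels get 0. The volume
// boundary is treated as background (distance to just outside the lattice).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dim,
                         bool border_background = true) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  int n = ny * nx * nz;
  NumericVector d(n);
  const double INF = 1e20;
  for (int i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;
  std::vector<double> f(std::max(std::max(ny, nx), nz)),
                      g(std::max(std::max(ny, nx), nz));
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = d[lin(y, x, z, ny, nx)];
      dt1d(f, g, ny);
      for (int y = 0; y < ny; ++y) {
        double v = g[y];
        if (border_background) {
          double b = std::min((double)(y + 1), (double)(ny - y));
          v = std::min(v, b * b);
        }
        d[lin(y, x, z, ny, nx)] = v;
      }
    }
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = d[lin(y, x, z, ny, nx)];
      dt1d(f, g, nx);
      for (int x = 0; x < nx; ++x) {
        double v = g[x];
        if (border_background) {
          double b = std::min((double)(x + 1), (double)(nx - x));
          v = std::min(v, b * b);
        }
        d[lin(y, x, z, ny, nx)] = v;
      }
    }
  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = d[lin(y, x, z, ny, nx)];
      dt1d(f, g, nz);
      for (int z = 0; z < nz; ++z) {
        double v = g[z];
        if (border_background) {
          double b = std::min((double)(z + 1), (double)(nz - z));
          v = std::min(v, b * b);
        }
        d[lin(y, x, z, ny, nx)] = v;
      }
    }
  d.attr("dim") = dim;
  return d;
}

// Local thickness by inscribed-sphere painting. For each foreground voxel c
// with EDT radius r_c, all voxels strictly inside the sphere |p-c| < r_c are
// covered by an inscribed sphere spanning 2*ceil(r_c) - 1 voxels across
// (2*r_c - 1 when r_c is integral). Thickness(p) = max span over covering
// spheres, in voxel units.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(IntegerVector mask, IntegerVector dim) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  int n = ny * nx * nz;
  NumericVector edt2 = cpp_edt_sq(mask, dim, true);
  NumericVector th(n, 0.0);
  std::vector<int> idx;
  idx.reserve(n / 8);
  for (int i = 0; i < n; ++i) if (mask[i]) idx.push_back(i);
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (edt2[a] != edt2[b]) return edt2[a] > edt2[b];
    return a < b;
  });
  for (size_t q = 0; q < idx.size(); ++q) {
    int c = idx[q];
    double r2 = edt2[c];
    double r = std::sqrt(r2);
    double rceil = std::ceil(r - 1e-9);
    double span = 2.0 * rceil - 1.0;
    int z = c / (ny * nx), rem = c % (ny * nx);
    int x = rem / ny, y = rem % ny;
    int R = (int)std::ceil(r);
    for (int dz = -R; dz <= R; ++dz) {
      int zz = z + dz; if (zz < 0 || zz >= nz) continue;
      for (int dx = -R; dx <= R; ++dx) {
        int xx = x + dx; if (xx < 0 || xx >= nx) continue;
        for (int dy = -R; dy <= R; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          double dd = dy * (double)dy + dx * (double)dx + dz * (double)dz;
          if (dd >= r2) continue; // strict: |p-c| < r
          int j = lin(yy, xx, zz, ny, nx);
          if (mask[j] && th[j] < span) th[j] = span;
        }
      }
    }
  }
  th.attr("dim") = dim;
  return th;
}

// Marker-based watershed inside a mask: priority flood from markers, lower
// priority values flooded first; FIFO order breaks ties deterministically.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector markers,
                            IntegerVector mask, IntegerVector dim,
                            int connectivity) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  int n = ny * nx * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3> > off;
  neighbor_offsets(connectivity, off);
  typedef std::tuple<double, long, int> Node; // (priority, order, index)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  long order = 0;
  for (int i = 0; i < n; ++i) {
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      pq.push(Node(priority[i], order++, i));
    }
  }
  while (!pq.empty()) {
    int cur = std::get<2>(pq.top());
    pq.pop();
    int z = cur / (ny * nx), rem = cur % (ny * nx);
    int x = rem / ny, y = rem % ny;
    for (size_t k = 0; k < off.size(); ++k) {
      int yy = y + off[k][0], xx = x + off[k][1], zz = z + off[k][2];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
        continue;
      int j = lin(yy, xx, zz, ny, nx);
      if (mask[j] && !lab[j]) {
        lab[j] = lab[cur];
        pq.push(Node(priority[j], order++, j));
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Regional maxima of a map within a mask, with a minimum separation radius
// (Euclidean, voxels). Plateau ties broken toward the lowest linear index.
// Returns marker labels numbered in scan order.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector map, IntegerVector mask,
                               IntegerVector dim, double radius) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  int n = ny * nx * nz;
  IntegerVector out(n, 0);
  int R = std::max(1, (int)std::ceil(radius));
  double r2 = radius * radius + 1e-9;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int z = i / (ny * nx), rem = i % (ny * nx);
    int x = rem / ny, y = rem % ny;
    bool is_max = true;
    for (int dz = -R; dz <= R && is_max; ++dz) {
      int zz = z + dz; if (zz < 0 || zz >= nz) continue;
      for (int dx = -R; dx <= R && is_max; ++dx) {
        int xx = x + dx; if (xx < 0 || xx >= nx) continue;
        for (int dy = -R; dy <= R; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          double dd = dy * (double)dy + dx * (double)dx + dz * (double)dz;
          if (dd > r2 || dd == 0) continue;
          int j = lin(yy, xx, zz, ny, nx);
          if (!mask[j]) continue;
          if (map[j] > map[i] || (map[j] == map[i] && j < i)) {
            is_max = false; break;
          }
        }
      }
    }
    if (is_max) out[i] = ++next;
  }
  out.attr("dim") = dim;
  return out;
}

// Separable Gaussian smoothing with mirror boundary; deriv_axis in {-1,0,1,2}
// applies a normalized first-derivative-of-Gaussian kernel along that axis
// (0 = y, 1 = x, 2 = z) instead of the plain Gaussian.
static void make_kernels(double sigma, std::vector<double> &g,
                         std::vector<double> &dg, int &rad) {
  rad = std::max(1, (int)std::ceil(3.0 * sigma));
  g.assign(2 * rad + 1, 0.0);
  dg.assign(2 * rad + 1, 0.0);
  double s = 0.0;
  for (int k = -rad; k <= rad; ++k) {
    double w = std::exp(-0.5 * k * k / (sigma * sigma));
    g[k + rad] = w;
    s += w;
  }
  for (int k = -rad; k <= rad; ++k) g[k + rad] /= s;
  // derivative kernel, normalized so the response to a unit ramp is 1
  double sd = 0.0;
  for (int k = -rad; k <= rad; ++k) {
    dg[k + rad] = -(double)k * g[k + rad];
    sd += dg[k + rad] * (double)(-k); // = sum k^2 g[k]
  }
  if (sd != 0.0) for (size_t k = 0; k < dg.size(); ++k) dg[k] /= sd;
}

static inline int mirror(int i, int n) {
  // reflect about edges (no repeated edge sample beyond simple mirroring)
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static void conv_axis(std::vector<double> &v, int ny, int nx, int nz,
                      int axis, const std::vector<double> &ker, int rad) {
  int len = (axis == 0) ? ny : (axis == 1) ? nx : nz;
  std::vector<double> line(len), out(len);
  int n1 = (axis == 0) ? nx : ny;
  int n2 = (axis == 2) ? nx : nz;
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      for (int t = 0; t < len; ++t) {
        int y, x, z;
        if (axis == 0)      { y = t; x = a; z = b; }
        else if (axis == 1) { y = a; x = t; z = b; }
        else                { y = a; x = b; z = t; }
        line[t] = v[lin(y, x, z, ny, nx)];
      }
      for (int t = 0; t < len; ++t) {
        double s = 0.0;
        for (int k = -rad; k <= rad; ++k)
          s += ker[k + rad] * line[mirror(t + k, len)];
        out[t] = s;
      }
      for (int t = 0; t < len; ++t) {
        int y, x, z;
        if (axis == 0)      { y = t; x = a; z = b; }
        else if (axis == 1) { y = a; x = t; z = b; }
        else                { y = a; x = b; z = t; }
        v[lin(y, x, z, ny, nx)] = out[t];
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dim,
                               double sigma, int deriv_axis = -1) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  int n = ny * nx * nz;
  std::vector<double> v(vol.begin(), vol.end());
  std::vector<double> g, dg;
  int rad;
  make_kernels(sigma, g, dg, rad);
  for (int axis = 0; axis < 3; ++axis) {
    // convolution flips the kernel; dg is odd, so flip its sign for a
    // correlation-style derivative (response +1 on an increasing ramp)
    if (axis == deriv_axis) {
      std::vector<double> dflip(dg.rbegin(), dg.rend());
      conv_axis(v, ny, nx, nz, axis, dflip, rad);
    } else {
      conv_axis(v, ny, nx, nz, axis, g, rad);
    }
  }
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}
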
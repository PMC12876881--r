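// Low-level 3D grid kernels shared by the segmentation, radiomics and fusion
// stages. All arrays are R arrays with dim = (nz, ny, nx), column-major, so a
// 0-based voxel (z, y, x) sits at linear index z + nz * (y + ny * x).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + (R_xlen_t)ny * x);
}

// 26-connected component labelling of a logical foreground.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector fg, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!fg[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v / ((R_xlen_t)nz * ny));
      int rem = (int)(v - (R_xlen_t)x * nz * ny);
      int y = rem / nz, z = rem % nz;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            R_xlen_t w = lin(zz, yy, xx, nz, ny);
            if (fg[w] && lab[w] == 0) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
    }
  }
  return lab;
}

// One-dimensional squared-distance transform (lower envelope of parabolas),
// with anisotropic sample spacing w (distance between neighbours).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double w) {
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  const double w2 = w * w;
  int k = 0;
  v[0] = 0;
  zb[0] = -INFINITY;
  zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s > zb[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// Squared Euclidean distance (um^2) from each foreground voxel to the nearest
// background voxel, under anisotropic spacing (dz, dy, dx).
// [[Rcpp::export]]
NumericVector cpp_sqedt(LogicalVector fg, IntegerVector dims,
                        NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double BIG = 1e30;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = fg[i] ? BIG : 0.0;

  std::vector<double> f, g;
  // along z
  f.resize(nz); g.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = d[lin(z, y, x, nz, ny)];
      dt1d(f, g, nz, spacing[0]);
      for (int z = 0; z < nz; ++z) d[lin(z, y, x, nz, ny)] = g[z];
    }
  // along y
  f.resize(ny); g.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = d[lin(z, y, x, nz, ny)];
      dt1d(f, g, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) d[lin(z, y, x, nz, ny)] = g[y];
    }
  // along x
  f.resize(nx); g.resize(nx);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = d[lin(z, y, x, nz, ny)];
      dt1d(f, g, nx, spacing[2]);
      for (int x = 0; x < nx; ++x) d[lin(z, y, x, nz, ny)] = g[x];
    }
  return d;
}

// Seeded watershed by priority flooding: voxels with higher priority are
// claimed first; ties broken by linear index for determinism. 26-connected.
// [[Rcpp::export]]
IntegerVector cpp_watershed26(NumericVector priority, IntegerVector markers,
                              LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  typedef std::pair<double, R_xlen_t> Node; // (priority, -index) max-heap
  std::priority_queue<std::pair<double, R_xlen_t> > pq;
  for (R_xlen_t i = 0; i < n; ++i)
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      pq.push(Node(priority[i], -(i + 1)));
    }
  while (!pq.empty()) {
    R_xlen_t v = -pq.top().second - 1;
    pq.pop();
    int x = (int)(v / ((R_xlen_t)nz * ny));
    int rem = (int)(v - (R_xlen_t)x * nz * ny);
    int y = rem / nz, z = rem % nz;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dz && !dy && !dx) continue;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          R_xlen_t w = lin(zz, yy, xx, nz, ny);
          if (mask[w] && lab[w] == 0) {
            lab[w] = lab[v];
            pq.push(Node(priority[w], -(w + 1)));
          }
        }
  }
  return lab;
}

// 3x3x3 rank filter: type 0 = min, 1 = max, 2 = median. Borders use the
// available neighbours only.
// [[Rcpp::export]]
NumericVector cpp_rank3(NumericVector vol, IntegerVector dims, int type) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector out((R_xlen_t)nz * ny * nx);
  std::vector<double> buf;
  buf.reserve(27);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        buf.clear();
        for (int dz = -1; dz <= 1; ++dz) {
          int zz = z + dz;
          if (zz < 0 || zz >= nz) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              int xx = x + dx;
              if (xx < 0 || xx >= nx) continue;
              buf.push_back(vol[lin(zz, yy, xx, nz, ny)]);
            }
          }
        }
        double r;
        if (type == 0)
          r = *std::min_element(buf.begin(), buf.end());
        else if (type == 1)
          r = *std::max_element(buf.begin(), buf.end());
        else {
          size_t m = buf.size() / 2;
          std::nth_element(buf.begin(), buf.begin() + m, buf.end());
          r = buf[m];
          if (buf.size() % 2 == 0) {
            double lo = *std::max_element(buf.begin(), buf.begin() + m);
            r = 0.5 * (r + lo);
          }
        }
        out[lin(z, y, x, nz, ny)] = r;
      }
  return out;
}

// Separable Gaussian blur with replicate borders; sigma per axis in voxels.
static void blur_axis(std::vector<double>& a, int nz, int ny, int nx,
                      double sigma, int axis) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += kern[i + r];
  }
  for (double& k : kern) k /= s;
  int len = axis == 0 ? nz : (axis == 1 ? ny : nx);
  std::vector<double> line(len), outl(len);
  int n1 = axis == 0 ? ny : nz, n2 = axis == 2 ? ny : nx;
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1) {
      for (int t = 0; t < len; ++t) {
        int z, y, x;
        if (axis == 0) { z = t; y = i1; x = i2; }
        else if (axis == 1) { z = i1; y = t; x = i2; }
        else { z = i1; y = i2; x = t; }
        line[t] = a[lin(z, y, x, nz, ny)];
      }
      for (int t = 0; t < len; ++t) {
        double acc = 0;
        for (int i = -r; i <= r; ++i) {
          int u = t + i;
          if (u < 0) u = 0;
          if (u >= len) u = len - 1;
          acc += kern[i + r] * line[u];
        }
        outl[t] = acc;
      }
      for (int t = 0; t < len; ++t) {
        int z, y, x;
        if (axis == 0) { z = t; y = i1; x = i2; }
        else if (axis == 1) { z = i1; y = t; x = i2; }
        else { z = i1; y = i2; x = t; }
        a[lin(z, y, x, nz, ny)] = outl[t];
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector dims,
                         NumericVector sigma) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<double> a(vol.begin(), vol.end());
  blur_axis(a, nz, ny, nx, sigma[0], 0);
  blur_axis(a, nz, ny, nx, sigma[1], 1);
  blur_axis(a, nz, ny, nx, sigma[2], 2);
  return NumericVector(a.begin(), a.end());
}

// Strict-or-equal local maxima over the 26-neighbourhood, restricted to mask.
// [[Rcpp::export]]
LogicalVector cpp_localmax26(NumericVector v, LogicalVector mask,
                             IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector out(n, FALSE);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = lin(z, y, x, nz, ny);
        if (!mask[i] || v[i] <= 0) continue;
        bool ok = true;
        for (int dz = -1; dz <= 1 && ok; ++dz)
          for (int dy = -1; dy <= 1 && ok; ++dy)
            for (int dx = -1; dx <= 1 && ok; ++dx) {
              if (!dz && !dy && !dx) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
                  xx >= nx)
                continue;
              if (v[lin(zz, yy, xx, nz, ny)] > v[i]) ok = false;
            }
        out[i] = ok;
      }
  return out;
}

// Symmetric grey-level co-occurrence counts per offset. `levels` holds
// 1..ng inside the ROI and 0 outside; pairs need both ends inside.
// [[Rcpp::export]]
List cpp_glcm_counts(IntegerVector levels, IntegerVector dims,
                     IntegerMatrix offsets, int ng) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int nd = offsets.nrow();
  List out(nd);
  for (int d = 0; d < nd; ++d) {
    NumericMatrix m(ng, ng);
    const int dz = offsets(d, 0), dy = offsets(d, 1), dx = offsets(d, 2);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          int l1 = levels[lin(z, y, x, nz, ny)];
          if (l1 == 0) continue;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          int l2 = levels[lin(zz, yy, xx, nz, ny)];
          if (l2 == 0) continue;
          m(l1 - 1, l2 - 1) += 1;
          m(l2 - 1, l1 - 1) += 1;
        }
    out[d] = m;
  }
  return out;
}

// Grey-level run-length counts per direction: maximal runs of equal level
// along lines in the direction; runs break at the ROI boundary.
// [[Rcpp::export]]
List cpp_glrlm_counts(IntegerVector levels, IntegerVector dims,
                      IntegerMatrix offsets, int ng) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int nd = offsets.nrow();
  const int maxlen = nz + ny + nx;
  List out(nd);
  for (int d = 0; d < nd; ++d) {
    NumericMatrix m(ng, maxlen);
    const int dz = offsets(d, 0), dy = offsets(d, 1), dx = offsets(d, 2);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          int l1 = levels[lin(z, y, x, nz, ny)];
          if (l1 == 0) continue;
          // run start: predecessor out of grid, outside ROI, or other level
          int pz = z - dz, py = y - dy, px = x - dx;
          if (pz >= 0 && pz < nz && py >= 0 && py < ny && px >= 0 && px < nx &&
              levels[lin(pz, py, px, nz, ny)] == l1)
            continue;
          int len = 1;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          while (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 &&
                 xx < nx && levels[lin(zz, yy, xx, nz, ny)] == l1) {
            ++len;
            zz += dz; yy += dy; xx += dx;
          }
          if (len > maxlen) len = maxlen;
          m(l1 - 1, len - 1) += 1;
        }
    out[d] = m;
  }
  return out;
}
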
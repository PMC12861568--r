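#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline void neighbour_offsets(const int *dim, int conn,
                                     std::vector<int> &dx,
                                     std::vector<int> &dy,
                                     std::vector<int> &dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int k = -1; k <= 1; ++k)
    for (int j = -1; j <= 1; ++j)
      for (int i = -1; i <= 1; ++i) {
        if (i == 0 && j == 0 && k == 0) continue;
        if (conn == 6 && std::abs(i) + std::abs(j) + std::abs(k) != 1) continue;
        dx.push_back(i); dy.push_back(j); dz.push_back(k);
      }
  (void)dim;
}

// Connected-component labelling of a 3D logical mask (6- or 26-connectivity).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  int dim[3] = {nx, ny, nz};
  std::vector<int> dx, dy, dz;
  neighbour_offsets(dim, connectivity, dx, dy, dz);
  const int ndir = (int)dx.size();
  IntegerVector lab(mask.size());
  lab.attr("dim") = mask.attr("dim");
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < mask.size(); ++start) {
    if (!mask[start] || lab[start]) continue;
    lab[start] = ++next;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back(); stack.pop_back();
      int x = idx % nx, y = (idx / nx) % ny, z = idx / ((R_xlen_t)nx * ny);
      for (int n = 0; n < ndir; ++n) {
        int xx = x + dx[n], yy = y + dy[n], zz = z + dz[n];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t nb = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[nb] && !lab[nb]) { lab[nb] = next; stack.push_back(nb); }
      }
    }
  }
  return lab;
}

struct QVox {
  double prio;
  unsigned long order;
  R_xlen_t idx;
};
struct QVoxCmp {
  bool operator()(const QVox &a, const QVox &b) const {
    if (a.prio != b.prio) return a.prio > b.prio;  // min-heap on priority
    return a.order > b.order;                      // FIFO tie-break
  }
};

// Seeded watershed by priority flooding (Meyer). Floods from the seed
// labels in increasing order of `prio` (pass negated intensity to flood
// bright objects first); voxels outside `mask` are never assigned.
// 6-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_watershed3d(NumericVector prio, IntegerVector seeds,
                              LogicalVector mask) {
  IntegerVector d = prio.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  int dim[3] = {nx, ny, nz};
  std::vector<int> dx, dy, dz;
  neighbour_offsets(dim, 6, dx, dy, dz);
  IntegerVector lab = clone(seeds);
  lab.attr("dim") = prio.attr("dim");
  std::priority_queue<QVox, std::vector<QVox>, QVoxCmp> pq;
  unsigned long order = 0;
  for (R_xlen_t i = 0; i < seeds.size(); ++i)
    if (seeds[i] > 0 && mask[i]) pq.push({prio[i], order++, i});
  while (!pq.empty()) {
    QVox q = pq.top(); pq.pop();
    int x = q.idx % nx, y = (q.idx / nx) % ny, z = q.idx / ((R_xlen_t)nx * ny);
    int l = lab[q.idx];
    for (int n = 0; n < 6; ++n) {
      int xx = x + dx[n], yy = y + dy[n], zz = z + dz[n];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t nb = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (!mask[nb] || lab[nb]) continue;
      lab[nb] = l;
      pq.push({prio[nb], order++, nb});
    }
  }
  return lab;
}

// Grayscale reconstruction by dilation (Vincent's hybrid algorithm):
// largest image <= mask whose regional maxima are limited by `marker`.
// 6-connectivity.
// [[Rcpp::export]]
NumericVector cpp_reconstruct_dilation(NumericVector marker,
                                       NumericVector mask) {
  IntegerVector d = marker.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  NumericVector rec = clone(marker);
  rec.attr("dim") = marker.attr("dim");
  const R_xlen_t n = rec.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (rec[i] > mask[i]) rec[i] = mask[i];
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  // forward raster pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = x * sx + y * sy + z * sz;
        double m = rec[i];
        if (x > 0 && rec[i - sx] > m) m = rec[i - sx];
        if (y > 0 && rec[i - sy] > m) m = rec[i - sy];
        if (z > 0 && rec[i - sz] > m) m = rec[i - sz];
        rec[i] = std::min(m, mask[i]);
      }
  // backward raster pass, queueing boundary voxels
  std::queue<R_xlen_t> fifo;
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        R_xlen_t i = x * sx + y * sy + z * sz;
        double m = rec[i];
        if (x < nx - 1 && rec[i + sx] > m) m = rec[i + sx];
        if (y < ny - 1 && rec[i + sy] > m) m = rec[i + sy];
        if (z < nz - 1 && rec[i + sz] > m) m = rec[i + sz];
        rec[i] = std::min(m, mask[i]);
        bool push = false;
        if (x < nx - 1 && rec[i + sx] < rec[i] && rec[i + sx] < mask[i + sx]) push = true;
        if (y < ny - 1 && rec[i + sy] < rec[i] && rec[i + sy] < mask[i + sy]) push = true;
        if (z < nz - 1 && rec[i + sz] < rec[i] && rec[i + sz] < mask[i + sz]) push = true;
        if (push) fifo.push(i);
      }
  const R_xlen_t step[6] = {sx, -sx, sy, -sy, sz, -sz};
  while (!fifo.empty()) {
    R_xlen_t i = fifo.front(); fifo.pop();
    int x = i % nx, y = (i / nx) % ny, z = i / sz;
    int cx[6] = {x + 1, x - 1, x, x, x, x};
    int cy[6] = {y, y, y + 1, y - 1, y, y};
    int cz[6] = {z, z, z, z, z + 1, z - 1};
    for (int k = 0; k < 6; ++k) {
      if (cx[k] < 0 || cx[k] >= nx || cy[k] < 0 || cy[k] >= ny ||
          cz[k] < 0 || cz[k] >= nz) continue;
      R_xlen_t nb = i + step[k];
      if (rec[nb] < rec[i] && rec[nb] < mask[nb]) {
        rec[nb] = std::min(rec[i], mask[nb]);
        fifo.push(nb);
      }
    }
  }
  return rec;
}

// Regional maxima (plateau-aware, 26-connectivity): TRUE on every voxel of
// a connected equal-valued plateau none of whose neighbours is greater.
// [[Rcpp::export]]
LogicalVector cpp_regional_maxima(NumericVector f) {
  IntegerVector d = f.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  int dim[3] = {nx, ny, nz};
  std::vector<int> dx, dy, dz;
  neighbour_offsets(dim, 26, dx, dy, dz);
  LogicalVector out(f.size());
  out.attr("dim") = f.attr("dim");
  std::vector<char> visited(f.size(), 0);
  std::vector<R_xlen_t> plateau, stack;
  for (R_xlen_t start = 0; start < f.size(); ++start) {
    if (visited[start]) continue;
    const double v = f[start];
    plateau.clear(); stack.clear();
    stack.push_back(start);
    visited[start] = 1;
    bool is_max = true;
    while (!stack.empty()) {
      R_xlen_t i = stack.back(); stack.pop_back();
      plateau.push_back(i);
      int x = i % nx, y = (i / nx) % ny, z = i / ((R_xlen_t)nx * ny);
      for (size_t n = 0; n < dx.size(); ++n) {
        int xx = x + dx[n], yy = y + dy[n], zz = z + dz[n];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t nb = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (f[nb] > v) is_max = false;
        else if (f[nb] == v && !visited[nb]) {
          visited[nb] = 1;
          stack.push_back(nb);
        }
      }
    }
    if (is_max)
      for (size_t k = 0; k < plateau.size(); ++k) out[plateau[k]] = TRUE;
  }
  return out;
}

// Separable 3D Gaussian smoothing, reflective boundaries.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, double sigma) {
  IntegerVector d = vol.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  if (sigma <= 0) return clone(vol);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &w : k) w /= s;
  NumericVector a = clone(vol), b(vol.size());
  b.attr("dim") = vol.attr("dim");
  const R_xlen_t str[3] = {1, nx, (R_xlen_t)nx * ny};
  const int len[3] = {nx, ny, nz};
  double *pa = a.begin(), *pb = b.begin();
  for (int axis = 0; axis < 3; ++axis) {
    const R_xlen_t st = str[axis];
    const int n = len[axis];
    const R_xlen_t total = (R_xlen_t)nx * ny * nz;
    for (R_xlen_t base = 0; base < total; ++base) {
      // process only positions whose coordinate along `axis` is 0
      R_xlen_t coord = (base / st) % n;
      if (coord != 0) continue;
      for (int i = 0; i < n; ++i) {
        double acc = 0;
        for (int j = -r; j <= r; ++j) {
          int idx = i + j;
          if (idx < 0) idx = -idx;                 // reflect
          if (idx > n - 1) idx = 2 * (n - 1) - idx;
          acc += k[j + r] * pa[base + (R_xlen_t)idx * st];
        }
        pb[base + (R_xlen_t)i * st] = acc;
      }
    }
    std::swap(pa, pb);
  }
  if (pa == a.begin()) return a;
  return b;
}
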
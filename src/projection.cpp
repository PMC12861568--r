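#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parallel-beam forward projection of a 3D volume about the vertical (z)
// axis. Volume dim (nx, ny, nz); beam along +y at angle 0; detector axes
// (u = x, v = z). Rotation centre is the voxel-centre midpoint (n-1)/2 so
// that the 180-degree projection is the exact mirror of the 0-degree one.
// Bilinear in-plane interpolation; samples outside the grid contribute 0.
// [[Rcpp::export]]
NumericMatrix cpp_project(NumericVector vol, double theta) {
  IntegerVector d = vol.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double ct = std::cos(theta), st = std::sin(theta);
  NumericMatrix out(nx, nz);
  const double *v = vol.begin();
  for (int u = 0; u < nx; ++u) {
    const double du = u - cx;
    for (int t = 0; t < ny; ++t) {
      const double dt = t - cy;
      const double x = cx + du * ct - dt * st;
      const double y = cy + du * st + dt * ct;
      if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1) continue;
      int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
      if (x0 == nx - 1) x0--;
      if (y0 == ny - 1) y0--;
      const double fx = x - x0, fy = y - y0;
      const double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy),
                   w01 = (1 - fx) * fy,       w11 = fx * fy;
      const R_xlen_t b00 = x0 + (R_xlen_t)nx * y0;
      for (int z = 0; z < nz; ++z) {
        const double *p = v + b00 + (R_xlen_t)nx * ny * z;
        out(u, z) += w00 * p[0] + w10 * p[1] + w01 * p[nx] + w11 * p[nx + 1];
      }
    }
  }
  return out;
}

// Back projection of filtered sinograms. sino dim (nu, n_angles, nz);
// returns volume (nu, nu, nz). Linear interpolation on the detector,
// consistent with cpp_project's rotation convention and centre.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector sino, NumericVector angles,
                              int nx, int ny) {
  IntegerVector d = sino.attr("dim");
  const int nu = d[0], na = d[1], nz = d[2];
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1), cu = 0.5 * (nu - 1);
  NumericVector out(Dimension(nx, ny, nz));
  std::vector<double> ct(na), st(na);
  for (int a = 0; a < na; ++a) { ct[a] = std::cos(angles[a]); st[a] = std::sin(angles[a]); }
  const double *s = sino.begin();
  double *o = out.begin();
  for (int z = 0; z < nz; ++z) {
    const double *sz = s + (R_xlen_t)nu * na * z;
    double *oz = o + (R_xlen_t)nx * ny * z;
    for (int y = 0; y < ny; ++y) {
      const double dy = y - cy;
      for (int x = 0; x < nx; ++x) {
        const double dx = x - cx;
        double acc = 0.0;
        for (int a = 0; a < na; ++a) {
          const double u = cu + dx * ct[a] + dy * st[a];
          if (u < 0 || u > nu - 1) continue;
          int u0 = (int)std::floor(u);
          if (u0 == nu - 1) u0--;
          const double fu = u - u0;
          const double *col = sz + (R_xlen_t)nu * a;
          acc += (1 - fu) * col[u0] + fu * col[u0 + 1];
        }
        oz[x + (R_xlen_t)nx * y] = acc;
      }
    }
  }
  return out;
}
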
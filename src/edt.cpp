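#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Anisotropy-aware squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher lower-envelope, applied per axis).
// mask != 0 is foreground; returns distance in physical units (spacing per
// axis) from each foreground voxel to the nearest background voxel center.

static void dt1d(std::vector<double>& f, std::vector<double>& d, double s2,
                 std::vector<int>& v, std::vector<double>& z) {
  int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double sq = f[q] + s2 * q * q;
    while (true) {
      int p = v[k];
      double sp = f[p] + s2 * p * p;
      double inter = (sq - sp) / (2.0 * s2 * (q - p));
      if (inter <= z[k]) { --k; }
      else {
        ++k; v[k] = q; z[k] = inter; z[k + 1] = INF;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = s2 * (q - p) * (q - p) + f[p];
  }
}

// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(IntegerVector mask, NumericVector spacing) {
  IntegerVector dim = mask.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(mask.size());
  out.attr("dim") = dim;
  // large finite stand-in for "no background seen yet" keeps the
  // lower-envelope intersections finite
  const double BIG = 1e18;
  for (long i = 0; i < mask.size(); ++i) out[i] = mask[i] ? BIG : 0.0;
  (void)INF;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // z axis
  double s2 = spacing[0] * spacing[0];
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      long b = (long)y * nz + (long)x * nz * ny;
      f.assign(nz, 0);
      for (int z0 = 0; z0 < nz; ++z0) f[z0] = out[b + z0];
      dt1d(f, d, s2, v, z);
      for (int z0 = 0; z0 < nz; ++z0) out[b + z0] = d[z0];
    }
  // y axis
  s2 = spacing[1] * spacing[1];
  for (int x = 0; x < nx; ++x)
    for (int z0 = 0; z0 < nz; ++z0) {
      long b = z0 + (long)x * nz * ny;
      f.assign(ny, 0);
      for (int y = 0; y < ny; ++y) f[y] = out[b + (long)y * nz];
      dt1d(f, d, s2, v, z);
      for (int y = 0; y < ny; ++y) out[b + (long)y * nz] = d[y];
    }
  // x axis
  s2 = spacing[2] * spacing[2];
  for (int y = 0; y < ny; ++y)
    for (int z0 = 0; z0 < nz; ++z0) {
      long b = z0 + (long)y * nz;
      f.assign(nx, 0);
      for (int x = 0; x < nx; ++x) f[x] = out[b + (long)x * nz * ny];
      dt1d(f, d, s2, v, z);
      for (int x = 0; x < nx; ++x) out[b + (long)x * nz * ny] = d[x];
    }
  for (long i = 0; i < out.size(); ++i) out[i] = std::sqrt(out[i]);
  return out;
}
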
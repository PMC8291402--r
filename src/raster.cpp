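#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Rasterize a set of polyline capsules (sphere-swept segments with linearly
// tapered radii) into a binary volume. Points are world μm (columns x,y,z);
// voxel (z,y,x) 1-based in R has center ((i-0.5)*spacing) per axis.
// starts: 1-based start row of each polyline; a polyline runs to the row
// before the next start (last runs to n).
// Each densely sampled centerline point also marks its containing voxel so
// sub-voxel-radius capillaries stay connected.
// [[Rcpp::export(name = ".rasterize_capsules")]]
IntegerVector rasterize_capsules(IntegerVector dim, NumericVector spacing,
                                 NumericMatrix P, NumericVector R,
                                 IntegerVector starts) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  IntegerVector mask((long)nz * ny * nx);
  mask.attr("dim") = dim;
  int nseg = starts.size();
  double step = 0.4 * std::min(sz, std::min(sy, sx));

  auto mark_point = [&](double x, double y, double z) {
    int ix = (int)std::floor(x / sx), iy = (int)std::floor(y / sy),
        iz = (int)std::floor(z / sz);
    if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz)
      mask[iz + (long)iy * nz + (long)ix * nz * ny] = 1;
  };

  for (int s = 0; s < nseg; ++s) {
    int a = starts[s] - 1;
    int b = (s + 1 < nseg) ? starts[s + 1] - 1 : P.nrow();
    for (int i = a; i + 1 < b; ++i) {
      double x0 = P(i, 0), y0 = P(i, 1), z0 = P(i, 2);
      double x1 = P(i + 1, 0), y1 = P(i + 1, 1), z1 = P(i + 1, 2);
      double r0 = R[i], r1 = R[i + 1];
      double rmax = std::max(r0, r1);
      // capsule bounding box in voxel indices
      int xlo = std::max(0, (int)std::floor((std::min(x0, x1) - rmax) / sx) - 1);
      int xhi = std::min(nx - 1, (int)std::ceil((std::max(x0, x1) + rmax) / sx) + 1);
      int ylo = std::max(0, (int)std::floor((std::min(y0, y1) - rmax) / sy) - 1);
      int yhi = std::min(ny - 1, (int)std::ceil((std::max(y0, y1) + rmax) / sy) + 1);
      int zlo = std::max(0, (int)std::floor((std::min(z0, z1) - rmax) / sz) - 1);
      int zhi = std::min(nz - 1, (int)std::ceil((std::max(z0, z1) + rmax) / sz) + 1);
      double dx = x1 - x0, dy = y1 - y0, dz = z1 - z0;
      double len2 = dx * dx + dy * dy + dz * dz;
      for (int ix = xlo; ix <= xhi; ++ix) {
        double cx = (ix + 0.5) * sx;
        for (int iy = ylo; iy <= yhi; ++iy) {
          double cy = (iy + 0.5) * sy;
          for (int iz = zlo; iz <= zhi; ++iz) {
            double cz = (iz + 0.5) * sz;
            double t = 0;
            if (len2 > 0) {
              t = ((cx - x0) * dx + (cy - y0) * dy + (cz - z0) * dz) / len2;
              t = std::max(0.0, std::min(1.0, t));
            }
            double px = x0 + t * dx - cx, py = y0 + t * dy - cy,
                   pz = z0 + t * dz - cz;
            double r = r0 + t * (r1 - r0);
            if (px * px + py * py + pz * pz <= r * r)
              mask[iz + (long)iy * nz + (long)ix * nz * ny] = 1;
          }
        }
      }
      // dense centerline walk for sub-voxel radii
      double len = std::sqrt(len2);
      int nstep = std::max(1, (int)std::ceil(len / step));
      for (int k = 0; k <= nstep; ++k) {
        double t = (double)k / nstep;
        mark_point(x0 + t * dx, y0 + t * dy, z0 + t * dz);
      }
    }
  }
  return mask;
}
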
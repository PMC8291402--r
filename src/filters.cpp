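#include <Rcpp.h>
#include <deque>
#include <cmath>
using namespace Rcpp;

// Volumes are numeric 3D arrays in (z, y, x) index order, column-major,
// i.e. linear index = z + y*nz + x*nz*ny (0-based).

static inline int reflect_idx(int p, int n) {
  // symmetric reflection including the edge sample: -1 -> 0, n -> n-1
  while (p < 0 || p >= n) {
    if (p < 0) p = -p - 1;
    if (p >= n) p = 2 * n - 1 - p;
  }
  return p;
}

struct AxisIter {
  int len, stride;
  long nlines;
  int d0, d1, d2;       // dims
  int a;                // axis: 0=z, 1=y, 2=x
  AxisIter(IntegerVector dim, int axis) {
    d0 = dim[0]; d1 = dim[1]; d2 = dim[2];
    a = axis;
    int s0 = 1, s1 = d0, s2 = d0 * d1;
    int d[3] = {d0, d1, d2}, s[3] = {s0, s1, s2};
    len = d[axis]; stride = s[axis];
    nlines = (long)d0 * d1 * d2 / len;
  }
  // base linear index of line number l (0..nlines-1)
  long base(long l) const {
    int db[2], sb[2], k = 0;
    int d[3] = {d0, d1, d2}, s[3] = {1, d0, d0 * d1};
    for (int i = 0; i < 3; ++i) if (i != a) { db[k] = d[i]; sb[k] = s[i]; ++k; }
    long i0 = l % db[0], i1 = l / db[0];
    return i0 * sb[0] + i1 * sb[1];
  }
};

// type: 0 = min, 1 = max, 2 = mean; window k odd, reflective padding
// [[Rcpp::export(name = ".box_filter_axis")]]
NumericVector box_filter_axis(NumericVector v, int axis, int k, int type) {
  IntegerVector dim = v.attr("dim");
  AxisIter ax(dim, axis);
  NumericVector out(v.size());
  out.attr("dim") = dim;
  int h = k / 2, L = ax.len;
  std::vector<double> line(L + 2 * h), res(L);
  for (long l = 0; l < ax.nlines; ++l) {
    long b = ax.base(l);
    for (int i = -h; i < L + h; ++i)
      line[i + h] = v[b + (long)reflect_idx(i, L) * ax.stride];
    if (type == 2) {
      double s = 0;
      for (int i = 0; i < k; ++i) s += line[i];
      res[0] = s / k;
      for (int i = 1; i < L; ++i) { s += line[i + k - 1] - line[i - 1]; res[i] = s / k; }
    } else {
      // monotonic deque of indices into padded line
      std::deque<int> dq;
      for (int i = 0; i < L + 2 * h; ++i) {
        while (!dq.empty() && ((type == 0) ? line[dq.back()] >= line[i]
                                           : line[dq.back()] <= line[i]))
          dq.pop_back();
        dq.push_back(i);
        int lo = i - k + 1;
        while (dq.front() < lo) dq.pop_front();
        if (i >= k - 1) res[i - k + 1] = line[dq.front()];
      }
    }
    for (int i = 0; i < L; ++i) out[b + (long)i * ax.stride] = res[i];
  }
  return out;
}

// [[Rcpp::export(name = ".conv_axis")]]
NumericVector conv_axis(NumericVector v, int axis, NumericVector kernel) {
  IntegerVector dim = v.attr("dim");
  AxisIter ax(dim, axis);
  NumericVector out(v.size());
  out.attr("dim") = dim;
  int k = kernel.size(), h = k / 2, L = ax.len;
  for (long l = 0; l < ax.nlines; ++l) {
    long b = ax.base(l);
    for (int i = 0; i < L; ++i) {
      double s = 0;
      for (int j = 0; j < k; ++j)
        s += kernel[j] * v[b + (long)reflect_idx(i + j - h, L) * ax.stride];
      out[b + (long)i * ax.stride] = s;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".bilateral3")]]
NumericVector bilateral3(NumericVector v, double sigma_spatial, double sigma_range) {
  IntegerVector dim = v.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(v.size());
  out.attr("dim") = dim;
  double ws[27];
  int off[27][3], n = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        off[n][0] = dz; off[n][1] = dy; off[n][2] = dx;
        double d2 = dx * dx + dy * dy + dz * dz;
        ws[n] = std::exp(-d2 / (2 * sigma_spatial * sigma_spatial));
        ++n;
      }
  double inv2sr2 = 1.0 / (2 * sigma_range * sigma_range);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double c = v[z + (long)y * nz + (long)x * nz * ny];
        double num = 0, den = 0;
        for (int i = 0; i < 27; ++i) {
          int zz = reflect_idx(z + off[i][0], nz);
          int yy = reflect_idx(y + off[i][1], ny);
          int xx = reflect_idx(x + off[i][2], nx);
          double u = v[zz + (long)yy * nz + (long)xx * nz * ny];
          double w = ws[i] * std::exp(-(u - c) * (u - c) * inv2sr2);
          num += w * u; den += w;
        }
        out[z + (long)y * nz + (long)x * nz * ny] = num / den;
      }
  return out;
}

// trilinear resize to new dims (voxel-center aligned)
// [[Rcpp::export(name = ".resize3d")]]
NumericVector resize3d(NumericVector v, IntegerVector newdim) {
  IntegerVector dim = v.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int mz = newdim[0], my = newdim[1], mx = newdim[2];
  NumericVector out((long)mz * my * mx);
  out.attr("dim") = newdim;
  for (int x = 0; x < mx; ++x) {
    double fx = ((x + 0.5) * nx) / mx - 0.5;
    int x0 = std::max(0, std::min(nx - 1, (int)std::floor(fx)));
    int x1 = std::min(nx - 1, x0 + 1);
    double tx = std::min(1.0, std::max(0.0, fx - x0));
    for (int y = 0; y < my; ++y) {
      double fy = ((y + 0.5) * ny) / my - 0.5;
      int y0 = std::max(0, std::min(ny - 1, (int)std::floor(fy)));
      int y1 = std::min(ny - 1, y0 + 1);
      double ty = std::min(1.0, std::max(0.0, fy - y0));
      for (int z = 0; z < mz; ++z) {
        double fz = ((z + 0.5) * nz) / mz - 0.5;
        int z0 = std::max(0, std::min(nz - 1, (int)std::floor(fz)));
        int z1 = std::min(nz - 1, z0 + 1);
        double tz = std::min(1.0, std::max(0.0, fz - z0));
        #define V(Z, Y, X) v[(Z) + (long)(Y) * nz + (long)(X) * nz * ny]
        double c00 = V(z0, y0, x0) * (1 - tz) + V(z1, y0, x0) * tz;
        double c10 = V(z0, y1, x0) * (1 - tz) + V(z1, y1, x0) * tz;
        double c01 = V(z0, y0, x1) * (1 - tz) + V(z1, y0, x1) * tz;
        double c11 = V(z0, y1, x1) * (1 - tz) + V(z1, y1, x1) * tz;
        #undef V
        double c0 = c00 * (1 - ty) + c10 * ty;
        double c1 = c01 * (1 - ty) + c11 * ty;
        out[z + (long)y * mz + (long)x * mz * my] = c0 * (1 - tx) + c1 * tx;
      }
    }
  }
  return out;
}

// block-mean downsample by integer factors per axis (partial edge blocks kept)
// [[Rcpp::export(name = ".block_mean")]]
NumericVector block_mean(NumericVector v, IntegerVector factor) {
  IntegerVector dim = v.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int fz = factor[0], fy = factor[1], fx = factor[2];
  int mz = (nz + fz - 1) / fz, my = (ny + fy - 1) / fy, mx = (nx + fx - 1) / fx;
  NumericVector out((long)mz * my * mx);
  out.attr("dim") = IntegerVector::create(mz, my, mx);
  for (int x = 0; x < mx; ++x)
    for (int y = 0; y < my; ++y)
      for (int z = 0; z < mz; ++z) {
        double s = 0; long n = 0;
        for (int xx = x * fx; xx < std::min(nx, (x + 1) * fx); ++xx)
          for (int yy = y * fy; yy < std::min(ny, (y + 1) * fy); ++yy)
            for (int zz = z * fz; zz < std::min(nz, (z + 1) * fz); ++zz) {
              s += v[zz + (long)yy * nz + (long)xx * nz * ny]; ++n;
            }
        out[z + (long)y * mz + (long)x * mz * my] = s / n;
      }
  return out;
}
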
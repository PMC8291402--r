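#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Iso-surface of a scalar field sampled at voxel centers, by marching
// tetrahedra on the Freudenthal (Kuhn) 6-tetrahedron cube decomposition.
// The decomposition is identical in every cube, so shared faces carry the
// same diagonal and the surface is watertight. Triangles are oriented so
// normals point from the inside (value > iso) toward the outside.

// corner code bits: 1 = +x, 2 = +y, 4 = +z
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

// [[Rcpp::export(name = ".march_tets")]]
List march_tets(NumericVector field, NumericVector spacing, double iso) {
  IntegerVector dim = field.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  long ntot = (long)nz * ny * nx;

  std::unordered_map<long long, int> edge_vert;
  std::vector<double> VX, VY, VZ;
  std::vector<int> T0, T1, T2;

  auto node_val = [&](long gid) { return field[gid]; };
  auto node_pos = [&](long gid, double* p) {
    int z = (int)(gid % nz), y = (int)((gid / nz) % ny),
        x = (int)(gid / ((long)nz * ny));
    p[0] = (x + 0.5) * sx; p[1] = (y + 0.5) * sy; p[2] = (z + 0.5) * sz;
  };
  auto edge_vertex = [&](long ga, long gb) -> int {
    long long key = (ga < gb) ? (long long)ga * ntot + gb
                              : (long long)gb * ntot + ga;
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double va = node_val(ga), vb = node_val(gb);
    double t = (iso - va) / (vb - va);
    t = std::max(0.0, std::min(1.0, t));
    double pa[3], pb[3];
    node_pos(ga, pa); node_pos(gb, pb);
    int id = (int)VX.size();
    VX.push_back(pa[0] + t * (pb[0] - pa[0]));
    VY.push_back(pa[1] + t * (pb[1] - pa[1]));
    VZ.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_vert[key] = id;
    return id;
  };
  auto emit = [&](int q0, int q1, int q2,
                  const double* cin, const double* cout) {
    double ax = VX[q1] - VX[q0], ay = VY[q1] - VY[q0], az = VZ[q1] - VZ[q0];
    double bx = VX[q2] - VX[q0], by = VY[q2] - VY[q0], bz = VZ[q2] - VZ[q0];
    double nxv = ay * bz - az * by, nyv = az * bx - ax * bz,
           nzv = ax * by - ay * bx;
    double dx = cout[0] - cin[0], dy = cout[1] - cin[1], dz = cout[2] - cin[2];
    if (nxv * dx + nyv * dy + nzv * dz < 0) std::swap(q1, q2);
    T0.push_back(q0); T1.push_back(q1); T2.push_back(q2);
  };

  long corner_gid[8];
  for (int x = 0; x + 1 < nx; ++x)
    for (int y = 0; y + 1 < ny; ++y)
      for (int z = 0; z + 1 < nz; ++z) {
        for (int c = 0; c < 8; ++c) {
          int cx = x + (c & 1), cy = y + ((c >> 1) & 1), cz = z + ((c >> 2) & 1);
          corner_gid[c] = cz + (long)cy * nz + (long)cx * nz * ny;
        }
        for (int t = 0; t < 6; ++t) {
          long g[4];
          bool in[4];
          int nin = 0;
          for (int k = 0; k < 4; ++k) {
            g[k] = corner_gid[TETS[t][k]];
            in[k] = node_val(g[k]) > iso;
            if (in[k]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0}, p[3];
          int ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            node_pos(g[k], p);
            if (in[k]) { cin[0] += p[0]; cin[1] += p[1]; cin[2] += p[2]; ++ni; }
            else { cout[0] += p[0]; cout[1] += p[1]; cout[2] += p[2]; ++no; }
          }
          for (int k = 0; k < 3; ++k) { cin[k] /= ni; cout[k] /= no; }
          int ii[4], oo[4];
          ni = no = 0;
          for (int k = 0; k < 4; ++k) (in[k] ? ii[ni++] : oo[no++]) = k;
          if (nin == 1) {
            int a = ii[0];
            emit(edge_vertex(g[a], g[oo[0]]), edge_vertex(g[a], g[oo[1]]),
                 edge_vertex(g[a], g[oo[2]]), cin, cout);
          } else if (nin == 3) {
            int a = oo[0];
            emit(edge_vertex(g[a], g[ii[0]]), edge_vertex(g[a], g[ii[1]]),
                 edge_vertex(g[a], g[ii[2]]), cin, cout);
          } else {  // nin == 2
            int a = ii[0], b = ii[1], c = oo[0], d = oo[1];
            int v1 = edge_vertex(g[a], g[c]), v2 = edge_vertex(g[a], g[d]);
            int v3 = edge_vertex(g[b], g[d]), v4 = edge_vertex(g[b], g[c]);
            emit(v1, v2, v3, cin, cout);
            emit(v1, v3, v4, cin, cout);
          }
        }
      }

  int nV = (int)VX.size(), nT = (int)T0.size();
  NumericMatrix V(nV, 3);
  IntegerMatrix F(nT, 3);
  for (int i = 0; i < nV; ++i) { V(i, 0) = VX[i]; V(i, 1) = VY[i]; V(i, 2) = VZ[i]; }
  for (int i = 0; i < nT; ++i) {
    F(i, 0) = T0[i] + 1; F(i, 1) = T1[i] + 1; F(i, 2) = T2[i] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = F);
}

// Per-vertex ray casting against the mesh itself (Möller–Trumbore), with a
// uniform-grid acceleration structure. dirs are unit ray directions; rays
// start at each vertex; triangles incident to the vertex are excluded, as
// are hits closer than eps. Returns hit distance or NA (no hit <= max_ray).
// [[Rcpp::export(name = ".ray_self_distance")]]
NumericVector ray_self_distance(NumericMatrix V, IntegerMatrix F,
                                NumericMatrix dirs, double eps,
                                double max_ray) {
  int nV = V.nrow(), nT = F.nrow();
  // uniform grid over mesh bbox
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
  for (int i = 0; i < nV; ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], V(i, k)); hi[k] = std::max(hi[k], V(i, k));
    }
  int ncell = std::max(1, (int)std::floor(std::cbrt((double)nT / 4.0)));
  ncell = std::min(ncell, 64);
  double cs[3];
  for (int k = 0; k < 3; ++k)
    cs[k] = std::max(1e-9, (hi[k] - lo[k]) / ncell);
  auto cell_of = [&](double x, double y, double z, int* c) {
    double p[3] = {x, y, z};
    for (int k = 0; k < 3; ++k) {
      int i = (int)std::floor((p[k] - lo[k]) / cs[k]);
      c[k] = std::max(0, std::min(ncell - 1, i));
    }
  };
  std::vector<std::vector<int>> cells((long)ncell * ncell * ncell);
  for (int t = 0; t < nT; ++t) {
    int cmin[3], cmax[3];
    double bmin[3] = {R_PosInf, R_PosInf, R_PosInf},
           bmax[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int j = 0; j < 3; ++j) {
      int vi = F(t, j) - 1;
      for (int k = 0; k < 3; ++k) {
        bmin[k] = std::min(bmin[k], V(vi, k));
        bmax[k] = std::max(bmax[k], V(vi, k));
      }
    }
    cell_of(bmin[0], bmin[1], bmin[2], cmin);
    cell_of(bmax[0], bmax[1], bmax[2], cmax);
    for (int cx = cmin[0]; cx <= cmax[0]; ++cx)
      for (int cy = cmin[1]; cy <= cmax[1]; ++cy)
        for (int cz = cmin[2]; cz <= cmax[2]; ++cz)
          cells[cx + (long)cy * ncell + (long)cz * ncell * ncell].push_back(t);
  }

  NumericVector out(nV, NA_REAL);
  std::vector<int> last_seen(nT, -1);
  for (int v = 0; v < nV; ++v) {
    double ox = V(v, 0), oy = V(v, 1), oz = V(v, 2);
    double dx = dirs(v, 0), dy = dirs(v, 1), dz = dirs(v, 2);
    double best = max_ray;
    bool hit = false;
    // DDA walk through grid cells along the ray
    double t_travel = 0;
    while (t_travel <= best) {
      double px = ox + dx * t_travel, py = oy + dy * t_travel,
             pz = oz + dz * t_travel;
      if (t_travel > 0 &&
          (px < lo[0] - 1e-9 || px > hi[0] + 1e-9 || py < lo[1] - 1e-9 ||
           py > hi[1] + 1e-9 || pz < lo[2] - 1e-9 || pz > hi[2] + 1e-9))
        break;
      int c[3];
      cell_of(px, py, pz, c);
      const std::vector<int>& lst =
          cells[c[0] + (long)c[1] * ncell + (long)c[2] * ncell * ncell];
      for (int t : lst) {
        if (last_seen[t] == v) continue;
        last_seen[t] = v;
        int a = F(t, 0) - 1, b = F(t, 1) - 1, cc = F(t, 2) - 1;
        if (a == v || b == v || cc == v) continue;
        double e1x = V(b, 0) - V(a, 0), e1y = V(b, 1) - V(a, 1),
               e1z = V(b, 2) - V(a, 2);
        double e2x = V(cc, 0) - V(a, 0), e2y = V(cc, 1) - V(a, 1),
               e2z = V(cc, 2) - V(a, 2);
        double hx = dy * e2z - dz * e2y, hy = dz * e2x - dx * e2z,
               hz = dx * e2y - dy * e2x;
        double det = e1x * hx + e1y * hy + e1z * hz;
        if (std::fabs(det) < 1e-12) continue;
        double inv = 1.0 / det;
        double sx_ = ox - V(a, 0), sy_ = oy - V(a, 1), sz_ = oz - V(a, 2);
        double u = (sx_ * hx + sy_ * hy + sz_ * hz) * inv;
        if (u < -1e-9 || u > 1 + 1e-9) continue;
        double qx = sy_ * e1z - sz_ * e1y, qy = sz_ * e1x - sx_ * e1z,
               qz = sx_ * e1y - sy_ * e1x;
        double w = (dx * qx + dy * qy + dz * qz) * inv;
        if (w < -1e-9 || u + w > 1 + 1e-9) continue;
        double tt = (e2x * qx + e2y * qy + e2z * qz) * inv;
        if (tt >= eps && tt < best) { best = tt; hit = true; }
      }
      // step to next cell boundary
      double step = std::min(cs[0], std::min(cs[1], cs[2])) * 0.5;
      t_travel += step;
    }
    if (hit) out[v] = best;
  }
  return out;
}
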
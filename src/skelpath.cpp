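#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Centerline skeletonization by distance-penalized geodesic path tracing
// (TEASAR-family). Per connected component: start from the voxel of
// maximal EDT, repeatedly find the object voxel farthest (unweighted
// geodesic distance) from the current skeleton among voxels not yet
// covered, and trace it back to the skeleton along a path that minimizes
// a cost strongly penalizing distance from the medial axis
// (1 + K * (1 - EDT/EDTmax)^4 per voxel). Each accepted path paints the
// voxels within paint_scale * EDT + 2 of its points as covered. Unlike
// topological thinning, this yields full-length, centered centerlines on
// tubes of any voxel parity; anastomotic loops are broken into trees.

struct HeapItem {
  double d; int v;
  bool operator<(const HeapItem& o) const { return d > o.d; }
};

// [[Rcpp::export(name = ".skeleton_paths")]]
IntegerVector skeleton_paths(IntegerVector mask, NumericVector edt,
                             double paint_scale = 1.3,
                             double paint_add = 2.0,
                             double penalty = 100.0,
                             double stop_dist = 3.0) {
  IntegerVector dim = mask.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long N = (long)nz * ny * nx;
  const double INF = std::numeric_limits<double>::infinity();

  // compact indexing of object voxels
  std::vector<int> cid(N, -1);
  std::vector<long> vox;
  for (long i = 0; i < N; ++i)
    if (mask[i]) { cid[i] = (int)vox.size(); vox.push_back(i); }
  int n = (int)vox.size();
  if (n == 0) {
    IntegerVector out(N); out.attr("dim") = dim; return out;
  }

  // 26-neighborhood with step lengths
  int noff[26]; double nlen[26]; int ndz[26], ndy[26], ndx[26];
  int nn = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (!dx && !dy && !dz) continue;
        noff[nn] = dz + dy * nz + dx * nz * ny;
        nlen[nn] = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
        ndz[nn] = dz; ndy[nn] = dy; ndx[nn] = dx;
        ++nn;
      }
  auto coords = [&](long li, int& z, int& y, int& x) {
    z = (int)(li % nz); y = (int)((li / nz) % ny); x = (int)(li / ((long)nz * ny));
  };
  auto neighbors_of = [&](int v, std::vector<int>& out) {
    out.clear();
    int z, y, x; coords(vox[v], z, y, x);
    for (int k = 0; k < 26; ++k) {
      int zz = z + ndz[k], yy = y + ndy[k], xx = x + ndx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int u = cid[vox[v] + noff[k]];
      if (u >= 0) out.push_back(k * (n + 1) + u);  // pack (k, u)
    }
  };

  // connected components over object voxels
  std::vector<int> comp(n, -1);
  std::vector<std::vector<int>> comps;
  {
    std::vector<int> stack, nb;
    for (int s = 0; s < n; ++s) {
      if (comp[s] >= 0) continue;
      int c = (int)comps.size();
      comps.push_back(std::vector<int>());
      stack.assign(1, s); comp[s] = c;
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        comps[c].push_back(v);
        neighbors_of(v, nb);
        for (int pk : nb) {
          int u = pk % (n + 1);
          if (comp[u] < 0) { comp[u] = c; stack.push_back(u); }
        }
      }
    }
  }

  std::vector<char> skel(n, 0), covered(n, 0);
  std::vector<double> dist(n, INF);
  std::vector<int> pred(n, -1);
  std::vector<int> nb;

  auto paint = [&](int p) {
    int z, y, x; coords(vox[p], z, y, x);
    double r = paint_scale * edt[vox[p]] + paint_add;
    int ri = (int)std::ceil(r);
    double r2 = r * r;
    for (int dx = -ri; dx <= ri; ++dx)
      for (int dy = -ri; dy <= ri; ++dy)
        for (int dz = -ri; dz <= ri; ++dz) {
          if (dx * dx + dy * dy + dz * dz > r2) continue;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          int u = cid[zz + (long)yy * nz + (long)xx * nz * ny];
          if (u >= 0) covered[u] = 1;
        }
  };

  for (size_t c = 0; c < comps.size(); ++c) {
    std::vector<int>& cv = comps[c];
    double emax = 0;
    int root = cv[0];
    for (int v : cv) if (edt[vox[v]] > emax) { emax = edt[vox[v]]; root = v; }
    if (emax <= 0) emax = 1;
    auto weight = [&](int v) {
      double f = 1.0 - edt[vox[v]] / emax;
      return 1.0 + penalty * f * f * f * f;
    };

    // full penalized dijkstra (used once per component, for the main path)
    auto dijkstra_pen_full = [&](int source) {
      for (int v : cv) { dist[v] = INF; pred[v] = -1; }
      std::priority_queue<HeapItem> pq;
      dist[source] = 0; pq.push({0.0, source});
      while (!pq.empty()) {
        HeapItem it = pq.top(); pq.pop();
        if (it.d > dist[it.v]) continue;
        neighbors_of(it.v, nb);
        for (int pk : nb) {
          int k = pk / (n + 1), u = pk % (n + 1);
          double w = nlen[k] * 0.5 * (weight(it.v) + weight(u));
          if (it.d + w < dist[u]) {
            dist[u] = it.d + w; pred[u] = it.v;
            pq.push({dist[u], u});
          }
        }
      }
    };
    // persistent unweighted distance-to-skeleton, updated incrementally by
    // relaxing outward from newly added skeleton voxels only
    std::vector<double>& dist_u = dist;   // reuse the shared buffer
    std::vector<int> pred_u(n, -1);
    auto relax_from = [&](const std::vector<int>& fresh) {
      std::priority_queue<HeapItem> pq;
      for (int s : fresh) {
        if (dist_u[s] > 0) { dist_u[s] = 0; }
        pq.push({0.0, s});
      }
      while (!pq.empty()) {
        HeapItem it = pq.top(); pq.pop();
        if (it.d > dist_u[it.v]) continue;
        neighbors_of(it.v, nb);
        for (int pk : nb) {
          int k = pk / (n + 1), u = pk % (n + 1);
          if (it.d + nlen[k] < dist_u[u]) {
            dist_u[u] = it.d + nlen[k];
            pq.push({dist_u[u], u});
          }
        }
      }
    };
    // penalized dijkstra from a target, stopping at the first skeleton
    // voxel settled; local arrays are restored afterwards
    std::vector<double> dloc(n, INF);
    std::vector<int> ploc(n, -1), touched;
    auto route_to_skeleton = [&](int target) -> int {
      touched.clear();
      std::priority_queue<HeapItem> pq;
      dloc[target] = 0; touched.push_back(target);
      pq.push({0.0, target});
      int hit = -1;
      while (!pq.empty()) {
        HeapItem it = pq.top(); pq.pop();
        if (it.d > dloc[it.v]) continue;
        if (skel[it.v]) { hit = it.v; break; }
        neighbors_of(it.v, nb);
        for (int pk : nb) {
          int k = pk / (n + 1), u = pk % (n + 1);
          double w = nlen[k] * 0.5 * (weight(it.v) + weight(u));
          if (it.d + w < dloc[u]) {
            if (dloc[u] == INF) touched.push_back(u);
            dloc[u] = it.d + w; ploc[u] = it.v;
            pq.push({dloc[u], u});
          }
        }
      }
      return hit;
    };

    // first path: farthest voxel from the deepest point, traced back
    std::vector<int> skel_c, fresh;
    {
      dijkstra_pen_full(root);
      int far = root; double dmax = -1;
      for (int v : cv)
        if (dist[v] < INF && dist[v] > dmax) { dmax = dist[v]; far = v; }
      for (int v = far; v != -1; v = pred[v]) {
        if (!skel[v]) { skel[v] = 1; skel_c.push_back(v); paint(v); }
      }
    }
    for (int v : cv) dist_u[v] = INF;
    relax_from(skel_c);
    // subsequent branches until everything is covered
    for (int guard = 0; guard < 100000; ++guard) {
      // a target must stand clear of the skeleton by more than the local
      // vessel radius, so junction-bulge corners and surface roughness do
      // not spawn stub branches
      int far = -1; double dmax = 0;
      for (int v : cv) {
        if (covered[v] || dist_u[v] == INF) continue;
        double thr = std::max(stop_dist, 1.5 * edt[vox[v]]);
        if (dist_u[v] > thr && dist_u[v] > dmax) { dmax = dist_u[v]; far = v; }
      }
      if (far < 0) break;
      int hit = route_to_skeleton(far);
      fresh.clear();
      if (hit >= 0) {
        for (int v = hit; v != -1; v = ploc[v]) {
          if (!skel[v]) {
            skel[v] = 1; skel_c.push_back(v); fresh.push_back(v); paint(v);
          }
        }
      }
      for (int v : touched) { dloc[v] = INF; ploc[v] = -1; }
      covered[far] = 1;
      if (!fresh.empty()) relax_from(fresh);
    }
  }

  IntegerVector out(N);
  out.attr("dim") = dim;
  for (int v = 0; v < n; ++v) if (skel[v]) out[vox[v]] = 1;
  return out;
}
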
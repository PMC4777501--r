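// Compiled kernels: kd-tree nearest neighbour, 26-connectivity labelling,
// cell-boundary surface extraction and Taubin mesh smoothing.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- kd-tree

namespace {

// Balanced implicit kd-tree with points copied into tree order (median of
// each range at the middle slot) for cache-friendly queries.
struct KdTree {
  int n;
  std::vector<double> px, py, pz; // tree-ordered coordinates
  std::vector<int> orig;          // tree slot -> original index

  KdTree(const double *pts, int n_) : n(n_), px(n_), py(n_), pz(n_), orig(n_) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    build(pts, idx, 0, n, 0);
    for (int s = 0; s < n; ++s) {
      int i = orig[s];
      px[s] = pts[i];
      py[s] = pts[i + (size_t)n];
      pz[s] = pts[i + 2 * (size_t)n];
    }
  }

  void build(const double *pts, std::vector<int> &idx, int lo, int hi, int depth) {
    if (hi - lo <= 0) return;
    if (hi - lo == 1) { orig[lo] = idx[lo]; return; }
    int ax = depth % 3;
    int mid = (lo + hi) / 2;
    const double *col = pts + (size_t)ax * n;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [col](int a, int b) { return col[a] < col[b]; });
    orig[mid] = idx[mid];
    build(pts, idx, lo, mid, depth + 1);
    build(pts, idx, mid + 1, hi, depth + 1);
  }

  inline double coord(int s, int ax) const {
    return ax == 0 ? px[s] : (ax == 1 ? py[s] : pz[s]);
  }

  void query(double qx, double qy, double qz, int lo, int hi, int depth,
             int &best, double &bestd) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    double dx = px[mid] - qx, dy = py[mid] - qy, dz = pz[mid] - qz;
    double d = dx * dx + dy * dy + dz * dz;
    if (d < bestd) { bestd = d; best = mid; }
    if (hi - lo == 1) return;
    int ax = depth % 3;
    double diff = (ax == 0 ? qx : (ax == 1 ? qy : qz)) - coord(mid, ax);
    if (diff < 0) {
      query(qx, qy, qz, lo, mid, depth + 1, best, bestd);
      if (diff * diff < bestd) query(qx, qy, qz, mid + 1, hi, depth + 1, best, bestd);
    } else {
      query(qx, qy, qz, mid + 1, hi, depth + 1, best, bestd);
      if (diff * diff < bestd) query(qx, qy, qz, lo, mid, depth + 1, best, bestd);
    }
  }

  // squared distance from query to original point index i (via slot s)
  inline double dist2_slot(int s, double qx, double qy, double qz) const {
    double dx = px[s] - qx, dy = py[s] - qy, dz = pz[s] - qz;
    return dx * dx + dy * dy + dz * dz;
  }
};

} // namespace

// Nearest neighbour in `target` (n x 3) for each row of `query` (m x 3).
// Returns 1-based indices and Euclidean distances. `warm` may give a
// 1-based candidate target index per query (e.g. the previous ICP
// iteration's correspondence) used to initialize the search radius.
// [[Rcpp::export]]
List cpp_nn(NumericMatrix target, NumericMatrix query,
            Nullable<IntegerVector> warm = R_NilValue) {
  int n = target.nrow(), m = query.nrow();
  if (n < 1) stop("empty target point set");
  KdTree tree(REAL(target), n);
  // map original index -> tree slot for warm starts
  std::vector<int> slot_of;
  IntegerVector warmv;
  bool has_warm = warm.isNotNull();
  if (has_warm) {
    warmv = warm.get();
    if (warmv.size() != m) stop("warm-start index length mismatch");
    slot_of.assign(n, 0);
    for (int s = 0; s < n; ++s) slot_of[tree.orig[s]] = s;
  }
  IntegerVector out_idx(m);
  NumericVector out_dist(m);
  const double *q = REAL(query);
  for (int i = 0; i < m; ++i) {
    double qx = q[i], qy = q[i + (size_t)m], qz = q[i + 2 * (size_t)m];
    int best = -1;
    double bestd = R_PosInf;
    if (has_warm) {
      int s = slot_of[warmv[i] - 1];
      best = s;
      bestd = tree.dist2_slot(s, qx, qy, qz);
    }
    tree.query(qx, qy, qz, 0, n, 0, best, bestd);
    out_idx[i] = tree.orig[best] + 1;
    out_dist[i] = std::sqrt(bestd);
  }
  return List::create(_["index"] = out_idx, _["distance"] = out_dist);
}

// ------------------------------------------------- connected components

// 26-connectivity labelling of a binary 3-D array (flattened, column-major,
// dims = c(nx, ny, nz)). Returns integer labels, 0 for background; labels
// are ordered by decreasing component voxel count (1 = largest).
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  if ((size_t)mask.size() != nvox) stop("mask size does not match dims");
  IntegerVector labels(mask.size(), 0);
  std::vector<size_t> stack;
  int next = 0;
  std::vector<size_t> counts;
  for (size_t s = 0; s < nvox; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next;
    size_t cnt = 0;
    stack.push_back(s);
    labels[s] = next;
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      ++cnt;
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((size_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
            size_t w = (size_t)X + (size_t)nx * (Y + (size_t)ny * Z);
            if (mask[w] && labels[w] == 0) { labels[w] = next; stack.push_back(w); }
          }
    }
    counts.push_back(cnt);
  }
  // relabel by decreasing size
  std::vector<int> order(next);
  for (int i = 0; i < next; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&counts](int a, int b) { return counts[a] > counts[b]; });
  std::vector<int> remap(next + 1, 0);
  for (int r = 0; r < next; ++r) remap[order[r] + 1] = r + 1;
  for (R_xlen_t i = 0; i < labels.size(); ++i)
    if (labels[i]) labels[i] = remap[labels[i]];
  return labels;
}

// --------------------------------------------- cell-boundary surface

// Extract the boundary surface of a binary voxel mask as a triangle mesh.
// Voxel (i,j,k) (0-based) is the cell [i-0.5,i+0.5]x...; vertices are cell
// corners in index units, faces wind outward. Returns vertices (index
// coordinates) and 1-based faces.
// [[Rcpp::export]]
List cpp_cuberille(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  if ((size_t)mask.size() != nvox) stop("mask size does not match dims");
  auto inside = [&](int x, int y, int z) -> bool {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return false;
    return mask[(size_t)x + (size_t)nx * (y + (size_t)ny * z)];
  };
  // corner lattice key -> vertex id
  std::unordered_map<long long, int> vid;
  std::vector<double> vx, vy, vz;
  std::vector<int> f1, f2, f3;
  long long CX = (long long)nx + 2, CY = (long long)ny + 2;
  auto corner = [&](int cx, int cy, int cz) -> int {
    long long key = (long long)cx + CX * ((long long)cy + CY * cz);
    auto it = vid.find(key);
    if (it != vid.end()) return it->second;
    int id = (int)vx.size();
    vid.emplace(key, id);
    vx.push_back(cx - 0.5);
    vy.push_back(cy - 0.5);
    vz.push_back(cz - 0.5);
    return id;
  };
  // 6 face directions; corner offsets chosen so the normal points outward
  const int dirs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  // for each direction, 4 corner offsets (in {0,1}^3) in outward CCW order
  const int quad[6][4][3] = {
    {{1,0,0},{1,1,0},{1,1,1},{1,0,1}},   // +x
    {{0,0,0},{0,0,1},{0,1,1},{0,1,0}},   // -x
    {{0,1,0},{0,1,1},{1,1,1},{1,1,0}},   // +y
    {{0,0,0},{1,0,0},{1,0,1},{0,0,1}},   // -y
    {{0,0,1},{1,0,1},{1,1,1},{0,1,1}},   // +z
    {{0,0,0},{0,1,0},{1,1,0},{1,0,0}}    // -z
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!inside(x, y, z)) continue;
        for (int d = 0; d < 6; ++d) {
          if (inside(x + dirs[d][0], y + dirs[d][1], z + dirs[d][2])) continue;
          int ids[4];
          for (int c = 0; c < 4; ++c)
            ids[c] = corner(x + quad[d][c][0], y + quad[d][c][1], z + quad[d][c][2]);
          f1.push_back(ids[0] + 1); f2.push_back(ids[1] + 1); f3.push_back(ids[2] + 1);
          f1.push_back(ids[0] + 1); f2.push_back(ids[2] + 1); f3.push_back(ids[3] + 1);
        }
      }
  int nv = (int)vx.size(), nf = (int)f1.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i,0) = vx[i]; V(i,1) = vy[i]; V(i,2) = vz[i]; }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) { F(i,0) = f1[i]; F(i,1) = f2[i]; F(i,2) = f3[i]; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ------------------------------------------------------ Taubin smoothing

static double signed_volume_component(const std::vector<double> &v,
                                      const IntegerMatrix &F,
                                      const std::vector<int> &comp,
                                      int target, int nv) {
  double vol = 0;
  for (int f = 0; f < F.nrow(); ++f) {
    int a = F(f,0) - 1, b = F(f,1) - 1, c = F(f,2) - 1;
    if (comp[a] != target) continue;
    const double ax = v[a], ay = v[a + nv], az = v[a + 2*nv];
    const double bx = v[b], by = v[b + nv], bz = v[b + 2*nv];
    const double cx = v[c], cy = v[c + nv], cz = v[c + 2*nv];
    vol += ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) + az * (bx * cy - by * cx);
  }
  return vol / 6.0;
}

// Taubin lambda|mu smoothing with optional per-component volume
// conservation (components rescaled about their centroid after each pass).
// [[Rcpp::export]]
NumericMatrix cpp_taubin(NumericMatrix V, IntegerMatrix F, int iterations,
                         double lambda, double mu, bool conserve_volume) {
  int nv = V.nrow();
  // adjacency (CSR) from face edges
  std::vector<std::vector<int>> adj(nv);
  for (int f = 0; f < F.nrow(); ++f) {
    int a = F(f,0) - 1, b = F(f,1) - 1, c = F(f,2) - 1;
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int i = 0; i < nv; ++i) {
    std::sort(adj[i].begin(), adj[i].end());
    adj[i].erase(std::unique(adj[i].begin(), adj[i].end()), adj[i].end());
  }
  // connected components (vertex graph)
  std::vector<int> comp(nv, -1);
  int ncomp = 0;
  {
    std::vector<int> stack;
    for (int s = 0; s < nv; ++s) {
      if (comp[s] >= 0) continue;
      comp[s] = ncomp;
      stack.push_back(s);
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        for (int w : adj[v]) if (comp[w] < 0) { comp[w] = ncomp; stack.push_back(w); }
      }
      ++ncomp;
    }
  }
  std::vector<double> cur(3 * (size_t)nv), nxt(3 * (size_t)nv);
  for (int i = 0; i < nv; ++i)
    for (int d = 0; d < 3; ++d) cur[i + (size_t)d * nv] = V(i, d);
  std::vector<double> vol0(ncomp);
  for (int c = 0; c < ncomp; ++c)
    vol0[c] = std::fabs(signed_volume_component(cur, F, comp, c, nv));
  auto pass = [&](double w) {
    for (int i = 0; i < nv; ++i) {
      if (adj[i].empty()) {
        for (int d = 0; d < 3; ++d) nxt[i + (size_t)d * nv] = cur[i + (size_t)d * nv];
        continue;
      }
      for (int d = 0; d < 3; ++d) {
        double m = 0;
        for (int j : adj[i]) m += cur[j + (size_t)d * nv];
        m /= adj[i].size();
        double x = cur[i + (size_t)d * nv];
        nxt[i + (size_t)d * nv] = x + w * (m - x);
      }
    }
    cur.swap(nxt);
  };
  for (int it = 0; it < iterations; ++it) {
    pass(lambda);
    pass(mu);
    if (conserve_volume) {
      // centroids
      std::vector<double> cx(ncomp, 0), cy(ncomp, 0), cz(ncomp, 0);
      std::vector<int> cn(ncomp, 0);
      for (int i = 0; i < nv; ++i) {
        cx[comp[i]] += cur[i]; cy[comp[i]] += cur[i + nv]; cz[comp[i]] += cur[i + 2*(size_t)nv];
        ++cn[comp[i]];
      }
      for (int c = 0; c < ncomp; ++c) {
        if (!cn[c]) continue;
        cx[c] /= cn[c]; cy[c] /= cn[c]; cz[c] /= cn[c];
        double vc = std::fabs(signed_volume_component(cur, F, comp, c, nv));
        if (vc <= 0 || vol0[c] <= 0) continue;
        double s = std::cbrt(vol0[c] / vc);
        for (int i = 0; i < nv; ++i) {
          if (comp[i] != c) continue;
          cur[i] = cx[c] + s * (cur[i] - cx[c]);
          cur[i + nv] = cy[c] + s * (cur[i + nv] - cy[c]);
          cur[i + 2*(size_t)nv] = cz[c] + s * (cur[i + 2*(size_t)nv] - cz[c]);
        }
      }
    }
  }
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = cur[i + (size_t)d * nv];
  return out;
}
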
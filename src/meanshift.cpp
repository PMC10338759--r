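// Flat-kernel mean shift in the anisotropic metric (dx, dy, sqrt(vr)*dz),
// accelerated by a uniform 3D grid hash with cell size = bandwidth.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct GridHash {
  double h;
  double ox, oy, oz;
  std::unordered_map<uint64_t, std::vector<int>> cells;

  uint64_t key(int ix, int iy, int iz) const {
    return (uint64_t)(uint32_t)(ix + 1000000) * 4000037ULL * 4000037ULL +
           (uint64_t)(uint32_t)(iy + 1000000) * 4000037ULL +
           (uint64_t)(uint32_t)(iz + 1000000);
  }
  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, double bw) {
    h = bw;
    ox = oy = oz = 0.0;
    for (size_t i = 0; i < x.size(); ++i) {
      int ix = (int)std::floor((x[i] - ox) / h);
      int iy = (int)std::floor((y[i] - oy) / h);
      int iz = (int)std::floor((z[i] - oz) / h);
      cells[key(ix, iy, iz)].push_back((int)i);
    }
  }
  template <typename F>
  void neighbors(double qx, double qy, double qz, F fun) const {
    int ix = (int)std::floor((qx - ox) / h);
    int iy = (int)std::floor((qy - oy) / h);
    int iz = (int)std::floor((qz - oz) / h);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(key(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) fun(j);
        }
  }
};

}  // namespace

// Returns 1-based super-point id per point, plus centers (weighted centroids
// in original coordinates) and integer weights.
// [[Rcpp::export]]
List cpp_meanshift_voxelize(NumericVector x, NumericVector y, NumericVector z,
                            double bandwidth, double vr, double tol,
                            int max_iter) {
  int n = x.size();
  double sv = std::sqrt(vr);
  std::vector<double> sx(n), sy(n), sz(n);
  for (int i = 0; i < n; ++i) { sx[i] = x[i]; sy[i] = y[i]; sz[i] = sv * z[i]; }
  GridHash grid;
  grid.build(sx, sy, sz, bandwidth);
  double h2 = bandwidth * bandwidth;
  double tol2 = tol * tol;
  std::vector<double> mx(n), my(n), mz(n);
  for (int i = 0; i < n; ++i) {
    double cx = sx[i], cy = sy[i], cz = sz[i];
    for (int it = 0; it < max_iter; ++it) {
      double ax = 0, ay = 0, az = 0;
      int cnt = 0;
      grid.neighbors(cx, cy, cz, [&](int j) {
        double dx = sx[j] - cx, dy = sy[j] - cy, dz = sz[j] - cz;
        if (dx * dx + dy * dy + dz * dz <= h2) {
          ax += sx[j]; ay += sy[j]; az += sz[j]; ++cnt;
        }
      });
      if (cnt == 0) break;
      ax /= cnt; ay /= cnt; az /= cnt;
      double dx = ax - cx, dy = ay - cy, dz = az - cz;
      cx = ax; cy = ay; cz = az;
      if (dx * dx + dy * dy + dz * dz < tol2) break;
    }
    mx[i] = cx; my[i] = cy; mz[i] = cz;
  }
  // merge modes within bandwidth/2 (greedy, input order -> deterministic)
  double r2 = 0.25 * h2;
  std::vector<int> assign(n, -1);
  std::vector<double> repx, repy, repz;
  for (int i = 0; i < n; ++i) {
    int found = -1;
    for (int c = 0; c < (int)repx.size(); ++c) {
      double dx = mx[i] - repx[c], dy = my[i] - repy[c], dz = mz[i] - repz[c];
      if (dx * dx + dy * dy + dz * dz <= r2) { found = c; break; }
    }
    if (found < 0) {
      repx.push_back(mx[i]); repy.push_back(my[i]); repz.push_back(mz[i]);
      found = (int)repx.size() - 1;
    }
    assign[i] = found;
  }
  int m = repx.size();
  NumericVector cx(m), cy(m), cz(m);
  IntegerVector w(m), member(n);
  for (int i = 0; i < n; ++i) {
    int c = assign[i];
    cx[c] += x[i]; cy[c] += y[i]; cz[c] += z[i];
    w[c] += 1;
    member[i] = c + 1;
  }
  for (int c = 0; c < m; ++c) { cx[c] /= w[c]; cy[c] /= w[c]; cz[c] /= w[c]; }
  return List::create(_["x"] = cx, _["y"] = cy, _["z"] = cz,
                      _["weight"] = w, _["member"] = member);
}
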
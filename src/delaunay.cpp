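// Incremental Bowyer-Watson Delaunay triangulation with walk-based point
// location, used for linear TIN interpolation of scattered elevations onto
// grid cell centers. Near-degenerate predicates (cocircular lattice points)
// are resolved with a relative tolerance; any triangulation of cocircular
// points is an equally valid linear interpolant.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Tri {
  int v[3];   // vertex indices, CCW
  int nb[3];  // nb[i] = triangle opposite vertex v[i], -1 if none
  bool alive;
};

struct Delaunay {
  std::vector<double> px, py;
  std::vector<Tri> tris;
  int n_input;
  int last_tri = 0;
  double eps;  // absolute predicate tolerance

  double orient(int a, int b, int c) const {
    return (px[b] - px[a]) * (py[c] - py[a]) - (py[b] - py[a]) * (px[c] - px[a]);
  }
  double orientp(int a, int b, double qx, double qy) const {
    return (px[b] - px[a]) * (qy - py[a]) - (py[b] - py[a]) * (qx - px[a]);
  }
  // > 0 if d strictly inside circumcircle of (a,b,c) assumed CCW
  double incircle(int a, int b, int c, int d) const {
    double adx = px[a] - px[d], ady = py[a] - py[d];
    double bdx = px[b] - px[d], bdy = py[b] - py[d];
    double cdx = px[c] - px[d], cdy = py[c] - py[d];
    double ad2 = adx * adx + ady * ady;
    double bd2 = bdx * bdx + bdy * bdy;
    double cd2 = cdx * cdx + cdy * cdy;
    return adx * (bdy * cd2 - cdy * bd2)
         - ady * (bdx * cd2 - cdx * bd2)
         + ad2 * (bdx * cdy - cdx * bdy);
  }

  void build(const NumericVector& x, const NumericVector& y) {
    n_input = x.size();
    px.assign(x.begin(), x.end());
    py.assign(y.begin(), y.end());
    double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
    for (int i = 1; i < n_input; ++i) {
      if (px[i] < xmin) xmin = px[i];
      if (px[i] > xmax) xmax = px[i];
      if (py[i] < ymin) ymin = py[i];
      if (py[i] > ymax) ymax = py[i];
    }
    double span = std::max(xmax - xmin, ymax - ymin);
    if (span <= 0) span = 1.0;
    eps = 1e-12 * span * span;
    double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
    double R = 1e5 * span;
    // super-triangle vertices appended after input points
    px.push_back(cx - 2.0 * R); py.push_back(cy - R);
    px.push_back(cx + 2.0 * R); py.push_back(cy - R);
    px.push_back(cx);           py.push_back(cy + 2.0 * R);
    Tri t0; t0.v[0] = n_input; t0.v[1] = n_input + 1; t0.v[2] = n_input + 2;
    t0.nb[0] = t0.nb[1] = t0.nb[2] = -1; t0.alive = true;
    tris.clear();
    tris.push_back(t0);
    last_tri = 0;
    for (int i = 0; i < n_input; ++i) insert(i);
  }

  // walk from last_tri toward point; returns a triangle whose circumcircle
  // contains the point (falls back to linear scan on pathological walks)
  int locate(double qx, double qy) {
    int t = last_tri;
    if (t < 0 || t >= (int)tris.size() || !tris[t].alive) {
      t = -1;
      for (int i = (int)tris.size() - 1; i >= 0; --i)
        if (tris[i].alive) { t = i; break; }
    }
    size_t guard = 4 * tris.size() + 64;
    for (size_t step = 0; step < guard; ++step) {
      const Tri& tr = tris[t];
      int next = -1;
      for (int e = 0; e < 3; ++e) {
        int a = tr.v[(e + 1) % 3], b = tr.v[(e + 2) % 3];
        if (orientp(a, b, qx, qy) < -eps) { next = tr.nb[e]; break; }
      }
      if (next == -1) return t;  // inside (or on boundary of) t
      t = next;
    }
    // fallback: exhaustive containment test
    for (int i = 0; i < (int)tris.size(); ++i) {
      if (!tris[i].alive) continue;
      const Tri& tr = tris[i];
      bool in = true;
      for (int e = 0; e < 3 && in; ++e) {
        int a = tr.v[(e + 1) % 3], b = tr.v[(e + 2) % 3];
        if (orientp(a, b, qx, qy) < -eps) in = false;
      }
      if (in) return i;
    }
    stop("TIN point location failed");
    return -1;
  }

  void insert(int p) {
    int t0 = locate(px[p], py[p]);
    // cavity = BFS over triangles whose circumcircle contains p
    std::vector<int> cavity;
    std::vector<char> in_cavity(tris.size(), 0);
    std::vector<int> stack;
    stack.push_back(t0);
    in_cavity[t0] = 1;
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      cavity.push_back(t);
      for (int e = 0; e < 3; ++e) {
        int nb = tris[t].nb[e];
        if (nb < 0 || in_cavity[nb]) continue;
        const Tri& tn = tris[nb];
        if (incircle(tn.v[0], tn.v[1], tn.v[2], p) > -eps) {
          in_cavity[nb] = 1;
          stack.push_back(nb);
        }
      }
    }
    // boundary edges (a,b) with outside neighbor
    struct BEdge { int a, b, outer; };
    std::vector<BEdge> boundary;
    for (int t : cavity) {
      for (int e = 0; e < 3; ++e) {
        int nb = tris[t].nb[e];
        if (nb >= 0 && in_cavity[nb]) continue;
        BEdge be;
        be.a = tris[t].v[(e + 1) % 3];
        be.b = tris[t].v[(e + 2) % 3];
        be.outer = nb;
        boundary.push_back(be);
      }
    }
    for (int t : cavity) tris[t].alive = false;
    // fan of new triangles p-a-b
    int first_new = tris.size();
    int nb_count = boundary.size();
    for (int i = 0; i < nb_count; ++i) {
      Tri nt;
      nt.v[0] = p; nt.v[1] = boundary[i].a; nt.v[2] = boundary[i].b;
      if (orient(nt.v[0], nt.v[1], nt.v[2]) < 0) std::swap(nt.v[1], nt.v[2]);
      nt.nb[0] = boundary[i].outer;  // opposite p
      nt.nb[1] = -2; nt.nb[2] = -2;  // filled below
      nt.alive = true;
      int idx = tris.size();
      tris.push_back(nt);
      if (boundary[i].outer >= 0) {
        Tri& out = tris[boundary[i].outer];
        for (int e = 0; e < 3; ++e) {
          int a = out.v[(e + 1) % 3], b = out.v[(e + 2) % 3];
          if ((a == boundary[i].a && b == boundary[i].b) ||
              (a == boundary[i].b && b == boundary[i].a)) out.nb[e] = idx;
        }
      }
    }
    // stitch fan neighbors by shared edge (p, vertex)
    for (int i = first_new; i < (int)tris.size(); ++i) {
      for (int j = first_new; j < (int)tris.size(); ++j) {
        if (i == j) continue;
        for (int ei = 0; ei < 3; ++ei) {
          if (tris[i].nb[ei] != -2) continue;
          int a = tris[i].v[(ei + 1) % 3], b = tris[i].v[(ei + 2) % 3];
          for (int ej = 0; ej < 3; ++ej) {
            int c = tris[j].v[(ej + 1) % 3], d = tris[j].v[(ej + 2) % 3];
            if ((a == c && b == d) || (a == d && b == c)) tris[i].nb[ei] = j;
          }
        }
      }
    }
    for (int i = first_new; i < (int)tris.size(); ++i)
      for (int e = 0; e < 3; ++e)
        if (tris[i].nb[e] == -2) tris[i].nb[e] = -1;
    last_tri = first_new;
  }

  bool is_super(int t) const {
    return tris[t].v[0] >= n_input || tris[t].v[1] >= n_input ||
           tris[t].v[2] >= n_input;
  }
};

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_tin_interp(NumericVector px, NumericVector py,
                             NumericVector pz, NumericVector qx,
                             NumericVector qy, bool nn_fill,
                             double max_edge = 0.0) {
  int n = px.size(), nq = qx.size();
  NumericVector out(nq, NA_REAL);
  if (n < 3) stop("TIN interpolation needs at least 3 points");
  Delaunay d;
  d.build(px, py);
  int cur = -1;
  for (int i = 0; i < (int)d.tris.size(); ++i)
    if (d.tris[i].alive && !d.is_super(i)) { cur = i; break; }
  if (cur < 0) stop("degenerate (collinear) point set: no finite triangles");
  d.last_tri = cur;
  std::vector<int> outside;
  for (int q = 0; q < nq; ++q) {
    int t = d.locate(qx[q], qy[q]);
    if (d.is_super(t)) { outside.push_back(q); continue; }
    const Tri& tr = d.tris[t];
    if (max_edge > 0) {
      // drop triangles with any edge longer than max_edge (leave cell empty)
      bool too_long = false;
      double me2 = max_edge * max_edge;
      for (int e = 0; e < 3 && !too_long; ++e) {
        int a = tr.v[e], b = tr.v[(e + 1) % 3];
        double dx = px[a] - px[b], dy = py[a] - py[b];
        if (dx * dx + dy * dy > me2) too_long = true;
      }
      if (too_long) continue;
    }
    double x1 = px[tr.v[0]], y1 = py[tr.v[0]];
    double x2 = px[tr.v[1]], y2 = py[tr.v[1]];
    double x3 = px[tr.v[2]], y3 = py[tr.v[2]];
    double det = (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3);
    if (det == 0) { outside.push_back(q); continue; }
    double l1 = ((y2 - y3) * (qx[q] - x3) + (x3 - x2) * (qy[q] - y3)) / det;
    double l2 = ((y3 - y1) * (qx[q] - x3) + (x1 - x3) * (qy[q] - y3)) / det;
    double l3 = 1.0 - l1 - l2;
    out[q] = l1 * pz[tr.v[0]] + l2 * pz[tr.v[1]] + l3 * pz[tr.v[2]];
  }
  if (nn_fill && !outside.empty()) {
    for (int q : outside) {
      double best = R_PosInf; int bi = 0;
      for (int i = 0; i < n; ++i) {
        double dx = px[i] - qx[q];
        double dy = py[i] - qy[q];
        double dd = dx * dx + dy * dy;
        if (dd < best) { best = dd; bi = i; }
      }
      out[q] = pz[bi];
    }
  }
  return out;
}
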
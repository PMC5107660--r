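// Bounded planar Voronoi tessellation by half-plane clipping.
//
// Each site's tile starts as the bounding rectangle and is clipped by the
// perpendicular bisector against every other site (Sutherland-Hodgman).
// Sites are visited in order of increasing distance so clipping can stop
// once no remaining bisector can reach the current tile.

#include <Rcpp.h>
#include <algorithm>
#include "voronoi.h"
using namespace Rcpp;

// clip polygon (px, py) by half-plane { q : a . (q - m) <= 0 }
static void clip_halfplane(std::vector<double> &px, std::vector<double> &py,
                           double ax, double ay, double mx, double my) {
  const int n = (int)px.size();
  if (n == 0) return;
  std::vector<double> qx, qy;
  qx.reserve(n + 4);
  qy.reserve(n + 4);
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double fi = ax * (px[i] - mx) + ay * (py[i] - my);
    double fj = ax * (px[j] - mx) + ay * (py[j] - my);
    bool ini = fi <= 0.0, inj = fj <= 0.0;
    if (ini) {
      qx.push_back(px[i]);
      qy.push_back(py[i]);
    }
    if (ini != inj) {
      double t = fi / (fi - fj);
      qx.push_back(px[i] + t * (px[j] - px[i]));
      qy.push_back(py[i] + t * (py[j] - py[i]));
    }
  }
  px.swap(qx);
  py.swap(qy);
}

static double shoelace(const std::vector<double> &px,
                       const std::vector<double> &py) {
  const int n = (int)px.size();
  if (n < 3) return 0.0;
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    s += px[i] * py[j] - px[j] * py[i];
  }
  return std::fabs(s) / 2.0;
}

// tile polygon of site i; other sites visited nearest-first with an early
// stop once d(i, j)/2 exceeds the farthest current vertex.
static void tile_of(int i, const std::vector<double> &x,
                    const std::vector<double> &y,
                    const std::vector<int> &order, const double bounds[4],
                    std::vector<double> &px, std::vector<double> &py) {
  px.assign({bounds[0], bounds[1], bounds[1], bounds[0]});
  py.assign({bounds[2], bounds[2], bounds[3], bounds[3]});
  const double xi = x[i], yi = y[i];
  for (int k : order) {
    if (k == i) continue;
    double dx = x[k] - xi, dy = y[k] - yi;
    double d2 = dx * dx + dy * dy;
    // farthest vertex from the site
    double vmax2 = 0.0;
    for (size_t v = 0; v < px.size(); ++v) {
      double ex = px[v] - xi, ey = py[v] - yi;
      double e2 = ex * ex + ey * ey;
      if (e2 > vmax2) vmax2 = e2;
    }
    if (d2 / 4.0 >= vmax2) break;  // bisector cannot cut the tile
    clip_halfplane(px, py, dx, dy, xi + dx / 2.0, yi + dy / 2.0);
    if (px.empty()) break;
  }
}

std::vector<double> voronoi_areas_core(const std::vector<double> &x,
                                       const std::vector<double> &y,
                                       const double bounds[4]) {
  const int n = (int)x.size();
  std::vector<double> areas(n, 0.0);
  if (n == 0) return areas;
  std::vector<double> px, py;
  for (int i = 0; i < n; ++i) {
    std::vector<int> order(n);
    for (int k = 0; k < n; ++k) order[k] = k;
    const double xi = x[i], yi = y[i];
    std::sort(order.begin(), order.end(), [&](int a, int b) {
      double da = (x[a] - xi) * (x[a] - xi) + (y[a] - yi) * (y[a] - yi);
      double db = (x[b] - xi) * (x[b] - xi) + (y[b] - yi) * (y[b] - yi);
      return da < db;
    });
    tile_of(i, x, y, order, bounds, px, py);
    areas[i] = shoelace(px, py);
  }
  return areas;
}

// [[Rcpp::export(name = ".cpp_voronoi")]]
List cpp_voronoi(NumericVector x, NumericVector y, NumericVector bounds,
                 bool polygons) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (bounds.size() != 4) stop("bounds must be c(xmin, xmax, ymin, ymax)");
  double b[4] = {bounds[0], bounds[1], bounds[2], bounds[3]};
  std::vector<double> vx(x.begin(), x.end()), vy(y.begin(), y.end());

  NumericVector areas(n);
  List polys(polygons ? n : 0);
  std::vector<int> order(n);
  std::vector<double> px, py;
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < n; ++k) order[k] = k;
    const double xi = vx[i], yi = vy[i];
    std::sort(order.begin(), order.end(), [&](int a, int c) {
      double da = (vx[a] - xi) * (vx[a] - xi) + (vy[a] - yi) * (vy[a] - yi);
      double dc = (vx[c] - xi) * (vx[c] - xi) + (vy[c] - yi) * (vy[c] - yi);
      return da < dc;
    });
    tile_of(i, vx, vy, order, b, px, py);
    areas[i] = shoelace(px, py);
    if (polygons) {
      NumericMatrix poly(px.size(), 2);
      for (size_t v = 0; v < px.size(); ++v) {
        poly(v, 0) = px[v];
        poly(v, 1) = py[v];
      }
      polys[i] = poly;
    }
  }
  List out = List::create(_["areas"] = areas);
  if (polygons) out["polygons"] = polys;
  return out;
}
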
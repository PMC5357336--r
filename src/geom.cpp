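#include <Rcpp.h>
using namespace Rcpp;

// Orientation of the ordered triple (a, b, c): >0 left turn, <0 right turn.
static inline double cross3(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

static inline bool on_segment(double ax, double ay, double bx, double by,
                              double px, double py) {
  return px >= std::min(ax, bx) - 1e-12 && px <= std::max(ax, bx) + 1e-12 &&
         py >= std::min(ay, by) - 1e-12 && py <= std::max(ay, by) + 1e-12;
}

static bool segments_intersect(double p1x, double p1y, double p2x, double p2y,
                               double q1x, double q1y, double q2x, double q2y) {
  double d1 = cross3(q1x, q1y, q2x, q2y, p1x, p1y);
  double d2 = cross3(q1x, q1y, q2x, q2y, p2x, p2y);
  double d3 = cross3(p1x, p1y, p2x, p2y, q1x, q1y);
  double d4 = cross3(p1x, p1y, p2x, p2y, q2x, q2y);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
    return true;
  if (d1 == 0 && on_segment(q1x, q1y, q2x, q2y, p1x, p1y)) return true;
  if (d2 == 0 && on_segment(q1x, q1y, q2x, q2y, p2x, p2y)) return true;
  if (d3 == 0 && on_segment(p1x, p1y, p2x, p2y, q1x, q1y)) return true;
  if (d4 == 0 && on_segment(p1x, p1y, p2x, p2y, q2x, q2y)) return true;
  return false;
}

// Simplicity test for a closed polygon given as an n x 2 matrix of vertices
// (no repeated last vertex).  Adjacent edges share an endpoint and are
// exempt; every other edge pair must be disjoint.
// [[Rcpp::export]]
bool poly_is_simple_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 3) return false;
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (j == i || j2 == i || j == i2) continue;  // shared endpoint
      if (segments_intersect(pts(i, 0), pts(i, 1), pts(i2, 0), pts(i2, 1),
                             pts(j, 0), pts(j, 1), pts(j2, 0), pts(j2, 1)))
        return false;
    }
  }
  return true;
}

// Even-odd point-in-polygon test for a batch of query points.
// [[Rcpp::export]]
LogicalVector points_in_polygon_cpp(NumericVector px, NumericVector py,
                                    NumericMatrix poly) {
  int n = poly.nrow(), m = px.size();
  LogicalVector out(m);
  for (int q = 0; q < m; ++q) {
    double x = px[q], y = py[q];
    bool inside = false;
    for (int i = 0, j = n - 1; i < n; j = i++) {
      double xi = poly(i, 0), yi = poly(i, 1);
      double xj = poly(j, 0), yj = poly(j, 1);
      if (((yi > y) != (yj > y)) &&
          (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
        inside = !inside;
    }
    out[q] = inside;
  }
  return out;
}
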
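#include <Rcpp.h>
using namespace Rcpp;

// Project point p onto segment a-b; returns parameter t in [0,1] and squared
// distance. Degenerate segments (|ab| ~ 0) collapse to endpoint a.
static inline double seg_project(double px, double py,
                                 double ax, double ay,
                                 double bx, double by,
                                 double &t) {
  double dx = bx - ax, dy = by - ay;
  double len2 = dx * dx + dy * dy;
  if (len2 < 1e-12) {
    t = 0.0;
    double ex = px - ax, ey = py - ay;
    return ex * ex + ey * ey;
  }
  t = ((px - ax) * dx + (py - ay) * dy) / len2;
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  double qx = ax + t * dx, qy = ay + t * dy;
  double ex = px - qx, ey = py - qy;
  return ex * ex + ey * ey;
}

//' Monotone nearest-node map matching of a fix sequence onto a 1 m polyline.
//'
//' Nodes are assumed 1 m apart so that node index (0-based) equals course
//' distance in metres. Matching is constrained to be monotone non-decreasing
//' in course distance with a bounded per-fix advance, which prevents snapping
//' onto spatially adjacent but distant (in arc length) course sections on a
//' looped course.
//'
//' @noRd
// [[Rcpp::export]]
List match_track_cpp(NumericVector fx, NumericVector fy,
                     NumericVector nx, NumericVector ny,
                     double max_advance, double corridor,
                     double init_window) {
  const int nf = fx.size();
  const int nn = nx.size();
  NumericVector dist(nf);      // continuous matched course distance [m]
  NumericVector offset(nf);    // perpendicular distance fix -> course [m]
  LogicalVector flagged(nf);   // outside corridor
  if (nn < 2) stop("course polyline needs at least 2 nodes");

  int adv = (int)std::ceil(max_advance) + 2;
  double prev = 0.0;           // previous continuous distance
  int cur = 0;                 // previous anchor node index

  for (int i = 0; i < nf; ++i) {
    int lo, hi;
    if (i == 0) {
      lo = 0;
      hi = std::min(nn - 2, (int)init_window);
    } else {
      lo = std::max(0, cur - 1);
      hi = std::min(nn - 2, cur + adv);
    }
    double best = R_PosInf, bestd = prev;
    for (int j = lo; j <= hi; ++j) {
      double t;
      double d2 = seg_project(fx[i], fy[i], nx[j], ny[j], nx[j + 1], ny[j + 1], t);
      if (d2 < best) {
        best = d2;
        bestd = j + t;
      }
    }
    if (i > 0 && bestd < prev) bestd = prev;  // monotone constraint
    prev = bestd;
    cur = (int)bestd;
    if (cur > nn - 2) cur = nn - 2;
    dist[i] = bestd;
    offset[i] = std::sqrt(best);
    flagged[i] = offset[i] > corridor;
  }
  return List::create(_["distance"] = dist,
                      _["offset"] = offset,
                      _["flagged"] = flagged);
}

// Assign each matched course distance to its 1 m bin on the lap, used when
// pooling fixes from all skiers and laps into the reference-course bins.
// [[Rcpp::export]]
IntegerVector lap_bin_cpp(NumericVector dist, double lap_length) {
  const int n = dist.size();
  IntegerVector bin(n);
  for (int i = 0; i < n; ++i) {
    double d = dist[i] - std::floor(dist[i] / lap_length) * lap_length;
    if (d < 0) d += lap_length;
    int b = (int)std::floor(d);
    if (b >= (int)lap_length) b = (int)lap_length - 1;
    bin[i] = b;  // 0-based half-open bin [b, b+1)
  }
  return bin;
}
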
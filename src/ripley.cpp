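#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Area of intersection between a circle of radius t centred at distance r
// from the origin and the disk of radius R centred at the origin.
static double circle_disk_area(double r, double t, double R) {
  if (r + t <= R) return M_PI * t * t;       // search circle fully inside
  if (r >= R + t) return 0.0;                // fully outside (cannot happen
                                             // for points inside the domain)
  if (t >= R + r) return M_PI * R * R;       // domain fully inside circle
  double c1 = (r * r + t * t - R * R) / (2.0 * r * t);
  double c2 = (r * r + R * R - t * t) / (2.0 * r * R);
  c1 = std::max(-1.0, std::min(1.0, c1));
  c2 = std::max(-1.0, std::min(1.0, c2));
  double s = (-r + t + R) * (r + t - R) * (r - t + R) * (r + t + R);
  s = std::max(0.0, s);
  return t * t * std::acos(c1) + R * R * std::acos(c2) - 0.5 * std::sqrt(s);
}

// Ripley's K over a radius grid for points in a disk of radius R centred
// at the origin, with border correction: each neighbour count around
// point i is divided by the fraction of the search-circle area lying
// inside the domain. K(t) = (A / n^2) * sum_i Ntilde_i(t), A = pi R^2.
// [[Rcpp::export]]
NumericVector cpp_ripley_k(NumericVector x, NumericVector y,
                           NumericVector radii, double R) {
  const int n = x.size();
  const int nt = radii.size();
  NumericVector K(nt);
  if (n < 2) return K;
  double maxt = 0.0;
  for (int k = 0; k < nt; ++k) maxt = std::max(maxt, radii[k]);
  const double maxt2 = maxt * maxt;

  std::vector<double> counts((size_t)nt); // per-i cumulative counts
  for (int i = 0; i < n; ++i) {
    std::fill(counts.begin(), counts.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double d2 = dx * dx + dy * dy;
      if (d2 > maxt2) continue;
      double d = std::sqrt(d2);
      // smallest radius bin with radii[k] >= d
      int lo = 0, hi = nt;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (radii[mid] >= d) hi = mid; else lo = mid + 1;
      }
      if (lo < nt) counts[lo] += 1.0;
    }
    // cumulate and weight by the in-domain fraction per radius
    double ri = std::sqrt(x[i] * x[i] + y[i] * y[i]);
    double cum = 0.0;
    for (int k = 0; k < nt; ++k) {
      cum += counts[k];
      if (cum > 0.0 && radii[k] > 0.0) {
        double frac = circle_disk_area(ri, radii[k], R) /
                      (M_PI * radii[k] * radii[k]);
        K[k] += cum / frac;
      }
    }
  }
  double A = M_PI * R * R;
  for (int k = 0; k < nt; ++k) K[k] *= A / ((double)n * (double)n);
  return K;
}
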
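#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Nearest-neighbour distances: for each x in a, min_j |x - b[j]|.
// Both vectors sorted ascending. O(na + nb) sweep.
static std::vector<double> nearest_dist(const NumericVector& a,
                                        const NumericVector& b) {
  const int na = a.size(), nb = b.size();
  std::vector<double> out(na);
  int j = 0;
  for (int i = 0; i < na; ++i) {
    while (j + 1 < nb && std::fabs(b[j + 1] - a[i]) <= std::fabs(b[j] - a[i]))
      ++j;
    out[i] = std::fabs(b[j] - a[i]);
  }
  return out;
}

// Time-averaged SPIKE dissimilarity profile on a uniform grid.
//
// a, b: sorted spike times INCLUDING auxiliary edge spikes at t_start and
// t_end (added by the R wrapper, duplicates removed). t_len = t_end - t_start
// with times already shifted so t_start = 0. The profile S(t) is evaluated at
// the midpoints of m = round(t_len/dt) equal cells and averaged, i.e. a
// midpoint Riemann sum of (1/T) * integral S(t) dt.
// [[Rcpp::export]]
double spike_dist_grid_cpp(NumericVector a, NumericVector b,
                           double t_len, double dt) {
  const int na = a.size(), nb = b.size();
  if (na < 2 || nb < 2) stop("trains must contain the two edge spikes");
  int m = (int)std::lround(t_len / dt);
  if (m < 1) m = 1;
  const double step = t_len / m;

  // distance from each spike of one train to the nearest spike of the other
  std::vector<double> da = nearest_dist(a, b); // \Delta t for spikes of a
  std::vector<double> db = nearest_dist(b, a);

  double acc = 0.0;
  int ia = 0, ib = 0; // index of last spike <= t in each train
  for (int k = 0; k < m; ++k) {
    const double t = (k + 0.5) * step;
    while (ia + 1 < na - 1 && a[ia + 1] <= t) ++ia;
    while (ib + 1 < nb - 1 && b[ib + 1] <= t) ++ib;

    const double xP1 = t - a[ia],      xF1 = a[ia + 1] - t;
    const double xP2 = t - b[ib],      xF2 = b[ib + 1] - t;
    const double isi1 = a[ia + 1] - a[ia];
    const double isi2 = b[ib + 1] - b[ib];

    // per-train weighted interpolation of corner-spike distances
    const double S1 = (da[ia] * xF1 + da[ia + 1] * xP1) / isi1;
    const double S2 = (db[ib] * xF2 + db[ib + 1] * xP2) / isi2;

    const double mean_isi = 0.5 * (isi1 + isi2);
    acc += (S1 * isi2 + S2 * isi1) / (2.0 * mean_isi * mean_isi);
  }
  return acc / m;
}
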
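#include <Rcpp.h>
using namespace Rcpp;

// Greedy stay-point scan over planar coordinates.
//
// Grows a candidate stop from each anchor: point j+1 joins while (a) the gap
// to the previous fix does not exceed gap_break and (b) after joining, every
// member lies within `radius` of the running median of member coordinates.
// A candidate spanning at least min_dur seconds is emitted as a stop and the
// scan restarts after it; otherwise the anchor advances by one fix.
//
// Returns a 2-column integer matrix of 1-based [start, end] member ranges.
// [[Rcpp::export(name = ".staypoint_scan")]]
IntegerMatrix staypoint_scan(NumericVector px, NumericVector py,
                             NumericVector t, double radius,
                             double min_dur, double gap_break) {
  const int n = px.size();
  const double r2 = radius * radius;
  std::vector<int> s0, s1;
  std::vector<double> xs, ys; // sorted member coordinates

  int i = 0;
  while (i < n) {
    xs.assign(1, px[i]);
    ys.assign(1, py[i]);
    int j = i;
    // `dist_bound` is a proven upper bound on the members' distance to the
    // current median: it grows by the median's drift each step, so a full
    // member rescan is needed only when the bound could cross the radius.
    // The accept/reject decisions are identical to the naive full rescan.
    double dist_bound = 0.0;
    double pmedx = px[i], pmedy = py[i];
    while (j + 1 < n) {
      if (t[j + 1] - t[j] > gap_break) break;
      xs.insert(std::upper_bound(xs.begin(), xs.end(), px[j + 1]), px[j + 1]);
      ys.insert(std::upper_bound(ys.begin(), ys.end(), py[j + 1]), py[j + 1]);
      const int m = (int)xs.size();
      const double medx = (m % 2) ? xs[m / 2] : 0.5 * (xs[m / 2 - 1] + xs[m / 2]);
      const double medy = (m % 2) ? ys[m / 2] : 0.5 * (ys[m / 2 - 1] + ys[m / 2]);
      const double shift = std::hypot(medx - pmedx, medy - pmedy);
      const double dnew = std::hypot(px[j + 1] - medx, py[j + 1] - medy);
      dist_bound = std::max(dist_bound + shift, dnew);
      if (dist_bound * dist_bound > r2) {
        double mx2 = 0.0;
        for (int l = i; l <= j + 1; ++l) {
          const double dx = px[l] - medx;
          const double dy = py[l] - medy;
          const double d2 = dx * dx + dy * dy;
          if (d2 > mx2) mx2 = d2;
        }
        if (mx2 > r2) break;
        dist_bound = std::sqrt(mx2);
      }
      pmedx = medx;
      pmedy = medy;
      ++j;
    }
    if (t[j] - t[i] >= min_dur) {
      s0.push_back(i + 1);
      s1.push_back(j + 1);
      i = j + 1;
    } else {
      ++i;
    }
  }

  IntegerMatrix out(s0.size(), 2);
  for (size_t k = 0; k < s0.size(); ++k) {
    out(k, 0) = s0[k];
    out(k, 1) = s1[k];
  }
  return out;
}
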
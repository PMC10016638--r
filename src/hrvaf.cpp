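#include <Rcpp.h>
using namespace Rcpp;

// Beat-by-beat sinus RR generator.  Each interval is
//   RR = mean_rr + drift*(t-t0)/3600 + a_lf*sin(2*pi*f_lf*t) +
//        a_hf*sin(2*pi*f_hf*t) + eps,  eps ~ N(0, noise_sd^2)
// evaluated at the time t (seconds, absolute) of the interval's opening
// beat, then the clock advances by RR.  Values are floored at floor_rr.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector sinus_rr_seq(double duration, double t0, double mean_rr,
                           double a_lf, double f_lf, double a_hf, double f_hf,
                           double noise_sd, double drift, double floor_rr) {
  std::vector<double> rr;
  rr.reserve((size_t)(duration / (mean_rr / 1000.0)) + 16);
  double t = t0, tend = t0 + duration;
  while (t < tend) {
    double x = mean_rr + drift * ((t - t0) / 3600.0) +
               a_lf * std::sin(2.0 * M_PI * f_lf * t) +
               a_hf * std::sin(2.0 * M_PI * f_hf * t);
    if (noise_sd > 0) x += R::rnorm(0.0, noise_sd);
    if (x < floor_rr) x = floor_rr;
    rr.push_back(x);
    t += x / 1000.0;
  }
  return wrap(rr);
}

// Classic Lomb-Scargle normalised-free periodogram (unsmoothed, with the
// time-offset tau that makes the fit a true least squares solution).
// Returns, per frequency, 0.5*[ (sum y cos)^2/sum cos^2 + (sum y sin)^2/sum sin^2 ]
// with y centred; band power in original units is recovered by the caller
// as sum(P)*2/(n*ofac).
// [[Rcpp::export]]
NumericVector lomb_power(NumericVector t, NumericVector y, NumericVector freq) {
  int n = t.size(), nf = freq.size();
  NumericVector p(nf);
  double ybar = 0.0;
  for (int i = 0; i < n; i++) ybar += y[i];
  ybar /= n;
  std::vector<double> yc(n);
  for (int i = 0; i < n; i++) yc[i] = y[i] - ybar;
  for (int k = 0; k < nf; k++) {
    double w = 2.0 * M_PI * freq[k];
    double s2 = 0.0, c2 = 0.0;
    for (int i = 0; i < n; i++) {
      s2 += std::sin(2.0 * w * t[i]);
      c2 += std::cos(2.0 * w * t[i]);
    }
    double tau = std::atan2(s2, c2) / (2.0 * w);
    double sy = 0.0, cy = 0.0, ss = 0.0, cc = 0.0;
    for (int i = 0; i < n; i++) {
      double a = w * (t[i] - tau);
      double sa = std::sin(a), ca = std::cos(a);
      sy += yc[i] * sa;
      cy += yc[i] * ca;
      ss += sa * sa;
      cc += ca * ca;
    }
    p[k] = 0.5 * ((cy * cy) / cc + (sy * sy) / ss);
  }
  return p;
}

// Sliding-window AF-likeness flags.  For each window [start, start+win)
// over beat times t (seconds) with intervals rr (ms), the window is
// flagged when
//   cv (population sd / mean)          >  cv_min    AND
//   lag-1 autocorrelation              <  acf_max   AND
//   sd of normalized successive deltas >  disp_min  AND
//   fraction of |normalized delta| > irr_delta  >  dense_min
// The last criterion separates sustained fibrillatory irregularity
// (nearly every interval differs from its neighbour) from a chance
// cluster of ectopic beats (a few large deltas on a regular baseline).
// Windows with fewer than min_beats beats are never flagged.
// [[Rcpp::export]]
LogicalVector af_window_flags(NumericVector t, NumericVector rr,
                              NumericVector starts, double win,
                              double cv_min, double acf_max, double disp_min,
                              double irr_delta, double dense_min,
                              int min_beats) {
  int n = t.size(), nw = starts.size();
  LogicalVector flag(nw);
  int lo = 0, hi = 0;
  for (int k = 0; k < nw; k++) {
    double s = starts[k], e = s + win;
    while (lo < n && t[lo] < s) lo++;
    if (hi < lo) hi = lo;
    while (hi < n && t[hi] < e) hi++;
    int m = hi - lo;
    flag[k] = false;
    if (m < min_beats) continue;
    double mean = 0.0;
    for (int i = lo; i < hi; i++) mean += rr[i];
    mean /= m;
    double var = 0.0;
    for (int i = lo; i < hi; i++) {
      double d = rr[i] - mean;
      var += d * d;
    }
    var /= m;
    if (var <= 0.0) continue;
    double cv = std::sqrt(var) / mean;
    double acov = 0.0;
    for (int i = lo; i < hi - 1; i++)
      acov += (rr[i] - mean) * (rr[i + 1] - mean);
    acov /= m;
    double r1 = acov / var;
    // normalized successive differences (r_i - r_{i+1})/(r_i + r_{i+1})
    double nd_mean = 0.0, nd_var = 0.0;
    int nd_n = m - 1, n_irr = 0;
    if (nd_n < 2) continue;
    std::vector<double> nd(nd_n);
    for (int i = 0; i < nd_n; i++) {
      double a = rr[lo + i], b = rr[lo + i + 1];
      nd[i] = (a - b) / (a + b);
      nd_mean += nd[i];
      if (std::fabs(nd[i]) > irr_delta) n_irr++;
    }
    nd_mean /= nd_n;
    for (int i = 0; i < nd_n; i++) {
      double d = nd[i] - nd_mean;
      nd_var += d * d;
    }
    nd_var /= nd_n;
    double disp = std::sqrt(nd_var);
    flag[k] = (cv > cv_min) && (r1 < acf_max) && (disp > disp_min) &&
              ((double)n_irr / nd_n > dense_min);
  }
  return flag;
}
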
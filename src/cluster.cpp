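// Cluster-based permutation machinery for time-frequency grids.
//
// Suprathreshold clustering uses 4-connectivity (frequency and time
// neighbours, no diagonals); positive and negative clusters are labeled
// separately. The permutation null is the largest absolute
// suprathreshold-cluster mass per permutation under subject-level sign
// flips (max-statistic family-wise control).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double Z_GUARD = 37.0;  // |z| cap for degenerate variance

// z from a paired/one-sample t via the probit of its two-sided p-value
static inline double t_to_z(double t, double df) {
  if (!R_finite(t)) return t > 0 ? Z_GUARD : -Z_GUARD;
  double p_half = R::pt(-std::fabs(t), df, 1, 0);
  if (p_half <= 0) return t > 0 ? Z_GUARD : -Z_GUARD;
  double z = -R::qnorm(p_half, 0.0, 1.0, 1, 0);
  if (z > Z_GUARD) z = Z_GUARD;
  return t >= 0 ? z : -z;
}

// flood-fill labeling of one sign; returns cluster masses and fills labels
static void label_one_sign(const std::vector<double>& z, int nr, int nc,
                           double zthr, int sign,
                           std::vector<int>& labels, int label_offset,
                           std::vector<double>& masses) {
  std::vector<int> stack;
  for (int start = 0; start < nr * nc; ++start) {
    if (labels[start] != 0) continue;
    double v = z[start] * sign;
    if (!(v > zthr)) continue;
    int lab = label_offset + (int)masses.size() + 1;
    double mass = 0.0;
    stack.clear();
    stack.push_back(start);
    labels[start] = lab;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      mass += z[p];
      int r = p % nr, c = p / nr;
      int nb[4] = {r > 0 ? p - 1 : -1, r < nr - 1 ? p + 1 : -1,
                   c > 0 ? p - nr : -1, c < nc - 1 ? p + nr : -1};
      for (int k = 0; k < 4; ++k) {
        int q = nb[k];
        if (q < 0 || labels[q] != 0) continue;
        if (z[q] * sign > zthr) { labels[q] = lab; stack.push_back(q); }
      }
    }
    masses.push_back(mass);
  }
}

// [[Rcpp::export]]
List cpp_label_clusters(NumericMatrix z, double zthr) {
  int nr = z.nrow(), nc = z.ncol();
  std::vector<double> zv(z.begin(), z.end());
  std::vector<int> labels(nr * nc, 0);
  std::vector<double> pos_mass, neg_mass;
  label_one_sign(zv, nr, nc, zthr, +1, labels, 0, pos_mass);
  label_one_sign(zv, nr, nc, zthr, -1, labels, (int)pos_mass.size(),
                 neg_mass);
  IntegerMatrix lab(nr, nc);
  for (int i = 0; i < nr * nc; ++i) lab[i] = labels[i];
  return List::create(_["labels"] = lab,
                      _["pos_mass"] = wrap(pos_mass),
                      _["neg_mass"] = wrap(neg_mass));
}

// largest |cluster mass| of a z map (helper shared with the null loop)
static double max_abs_mass(const std::vector<double>& z, int nr, int nc,
                           double zthr, std::vector<int>& labels) {
  std::fill(labels.begin(), labels.end(), 0);
  std::vector<double> pos, neg;
  label_one_sign(z, nr, nc, zthr, +1, labels, 0, pos);
  label_one_sign(z, nr, nc, zthr, -1, labels, (int)pos.size(), neg);
  double m = 0.0;
  for (size_t i = 0; i < pos.size(); ++i)
    m = std::max(m, std::fabs(pos[i]));
  for (size_t i = 0; i < neg.size(); ++i)
    m = std::max(m, std::fabs(neg[i]));
  return m;
}

// Permutation null for paired-difference maps: D is n_subj x n_pixels
// (pixels in column-major freq-by-time order, nr*nc columns). Uses R's
// RNG, so results are reproducible under set.seed().
//
// The pre-cluster threshold on |z| is equivalent to the corresponding
// |t| threshold (the probit map is monotone), so the costly t -> z
// conversion is only done for suprathreshold pixels; subthreshold
// pixels are set to z = 0, which neither labeling nor mass summation
// ever reads.
// [[Rcpp::export]]
NumericVector cpp_perm_null(NumericMatrix D, int nr, int nc, double zthr,
                            double tthr, int n_perm) {
  int ns = D.nrow(), np = D.ncol();
  if (np != nr * nc) stop("pixel count mismatch");
  NumericVector null_max(n_perm);
  std::vector<double> z(np);
  std::vector<int> labels(np);
  std::vector<double> signs(ns);
  double df = ns - 1.0;
  double sqrt_n = std::sqrt((double)ns);
  RNGScope scope;
  for (int p = 0; p < n_perm; ++p) {
    for (int s = 0; s < ns; ++s)
      signs[s] = unif_rand() < 0.5 ? -1.0 : 1.0;
    for (int j = 0; j < np; ++j) {
      double m = 0.0, ss = 0.0;
      for (int s = 0; s < ns; ++s) m += signs[s] * D(s, j);
      m /= ns;
      for (int s = 0; s < ns; ++s) {
        double d = signs[s] * D(s, j) - m;
        ss += d * d;
      }
      double sd = std::sqrt(ss / (ns - 1.0));
      double t;
      if (sd <= 0) t = (m == 0.0) ? 0.0 : (m > 0 ? R_PosInf : R_NegInf);
      else t = m / (sd / sqrt_n);
      z[j] = (std::fabs(t) > tthr || !R_finite(t)) ? t_to_z(t, df) : 0.0;
    }
    null_max[p] = max_abs_mass(z, nr, nc, zthr, labels);
  }
  return null_max;
}

// Spearman rank correlation bootstrap (percentile CI support). Average
// ranks for ties; indices resampled with R's RNG.
static void average_ranks(const std::vector<double>& x,
                          std::vector<double>& ranks,
                          std::vector<int>& ord) {
  int n = (int)x.size();
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&x](int a, int b) { return x[a] < x[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[ord[j + 1]] == x[ord[i]]) ++j;
    double r = (i + j) / 2.0 + 1.0;
    for (int k = i; k <= j; ++k) ranks[ord[k]] = r;
    i = j + 1;
  }
}

static double pearson(const std::vector<double>& a,
                      const std::vector<double>& b) {
  int n = (int)a.size();
  double ma = 0, mb = 0;
  for (int i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sab = 0, sa = 0, sb = 0;
  for (int i = 0; i < n; ++i) {
    double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; sa += da * da; sb += db * db;
  }
  if (sa <= 0 || sb <= 0) return NA_REAL;
  return sab / std::sqrt(sa * sb);
}

// [[Rcpp::export]]
NumericVector cpp_spearman_boot(NumericVector x, NumericVector y,
                                int n_boot) {
  int n = x.size();
  NumericVector out(n_boot);
  std::vector<double> xs(n), ys(n), rx(n), ry(n);
  std::vector<int> ord(n);
  RNGScope scope;
  for (int b = 0; b < n_boot; ++b) {
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k == n) k = n - 1;
      xs[i] = x[k]; ys[i] = y[k];
    }
    average_ranks(xs, rx, ord);
    average_ranks(ys, ry, ord);
    out[b] = pearson(rx, ry);
  }
  return out;
}
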
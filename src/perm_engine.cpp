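// Permutation engine for bin-wise and cluster-based tests on
// trial x frequency power maps.  Maps are handled flattened
// column-major (trial fastest): bin j (0-based) <-> trial j % T,
// frequency j / T.  Group sums over permutations are computed in R via
// BLAS matrix products; the functions here do the cheap O(R*B) passes:
// combining sums into t statistics, order-statistic thresholding, and
// connected-component clustering.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Sentinel for a zero-variance bin whose group means still differ.
// Finite so cluster masses stay comparable; never reached by
// continuous data.
static const double T_SENTINEL = 1e12;

static inline double welch_t(double sa, double sa2, int na,
                             double sb, double sb2, int nb) {
  double ma = sa / na, mb = sb / nb;
  double va = (sa2 - na * ma * ma) / (na - 1.0);
  double vb = (sb2 - nb * mb * mb) / (nb - 1.0);
  if (va < 0) va = 0;  // guard FP cancellation
  if (vb < 0) vb = 0;
  double se2 = va / na + vb / nb;
  double d = ma - mb;
  if (se2 <= 0) return d == 0 ? 0.0 : (d > 0 ? T_SENTINEL : -T_SENTINEL);
  return d / std::sqrt(se2);
}

// SA, SA2: R x B group-A sums / sums of squares per relabeling;
// st, st2: length-B totals over all n subjects.  Welch t per cell.
// [[Rcpp::export(name = ".welch_from_sums")]]
NumericMatrix welch_from_sums(const NumericMatrix& SA,
                              const NumericMatrix& SA2,
                              const NumericVector& st,
                              const NumericVector& st2,
                              int na, int nb) {
  const int R = SA.nrow(), B = SA.ncol();
  NumericMatrix out(R, B);
  for (int b = 0; b < B; ++b) {
    const double tb = st[b], tb2 = st2[b];
    const double* sa = &SA(0, b);
    const double* sa2 = &SA2(0, b);
    double* o = &out(0, b);
    for (int r = 0; r < R; ++r)
      o[r] = welch_t(sa[r], sa2[r], na, tb - sa[r], tb2 - sa2[r], nb);
  }
  return out;
}

// SS: R x B signed sums over pairs; sd2: length-B sums of squared
// differences (sign-invariant).  Paired t per cell.
// [[Rcpp::export(name = ".paired_from_sums")]]
NumericMatrix paired_from_sums(const NumericMatrix& SS,
                               const NumericVector& sd2, int np) {
  const int R = SS.nrow(), B = SS.ncol();
  NumericMatrix out(R, B);
  for (int b = 0; b < B; ++b) {
    const double* s = &SS(0, b);
    double* o = &out(0, b);
    for (int r = 0; r < R; ++r) {
      double m = s[r] / np;
      double var = (sd2[b] - np * m * m) / (np - 1.0);
      if (var < 0) var = 0;
      if (var <= 0) o[r] = m == 0 ? 0.0 : (m > 0 ? T_SENTINEL : -T_SENTINEL);
      else o[r] = m / std::sqrt(var / np);
    }
  }
  return out;
}

// Pooled-rank thresholding.  tmat: R x B with row 0 = observed map.
// Per bin, each map's two-sided p is its self-inclusive exceedance
// fraction within the pooled R-map distribution of |t|:
//   p_u = #{v: |t_v| >= |t_u|} / R,
// the add-one Monte Carlo estimator for the observed row.  A map is
// suprathreshold at the bin iff p_u < alpha, which is equivalent to
// |t_u| exceeding the ceil(alpha*R)-th largest |t| — found with a
// partial sort instead of materializing all R*B p-values.  Returns the
// R x B suprathreshold mask and the observed row's exact p-values.
// [[Rcpp::export(name = ".threshold_and_p")]]
List threshold_and_p(const NumericMatrix& tmat, double alpha) {
  const int R = tmat.nrow(), B = tmat.ncol();
  LogicalMatrix sig(R, B);
  NumericVector p_obs(B);
  // p_u < alpha  <=>  ge_u <= m with m = ceil(alpha*R) - 1
  const int m = (int)std::ceil(alpha * R - 1e-12) - 1;
  std::vector<double> buf(R);
  for (int b = 0; b < B; ++b) {
    const double* col = &tmat(0, b);
    for (int r = 0; r < R; ++r) buf[r] = std::fabs(col[r]);
    const double obs = buf[0];
    int ge = 0;
    for (int r = 0; r < R; ++r) if (buf[r] >= obs) ++ge;
    p_obs[b] = (double)ge / R;
    if (m < 0 || m >= R) continue;  // alpha below resolution: nothing passes
    std::nth_element(buf.begin(), buf.begin() + m, buf.end(),
                     std::greater<double>());
    const double thr = buf[m];  // (m+1)-th largest; sig iff |t| > thr
    int* s = &sig(0, b);
    for (int r = 0; r < R; ++r) s[r] = std::fabs(col[r]) > thr;
  }
  return List::create(_["sig"] = sig, _["p_obs"] = p_obs);
}

// Threshold + sign-pure connected components + cluster masses for
// every map; max |mass| per non-observed map for the Monte Carlo
// reference distribution.
// [[Rcpp::export(name = ".cluster_engine")]]
List cluster_engine(const NumericMatrix& tmat, const LogicalMatrix& sigmat,
                    int T, int Fq, int connectivity,
                    const LogicalVector& excluded) {
  const int R = tmat.nrow(), B = tmat.ncol();
  if ((size_t)T * Fq != (size_t)B) stop("grid dimensions do not match map size");
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  static const int dt8[8] = { 1, -1, 0, 0, 1, 1, -1, -1 };
  static const int df8[8] = { 0, 0, 1, -1, 1, -1, 1, -1 };
  const int K = connectivity == 8 ? 8 : 4;

  IntegerVector obs_label(B, 0);
  std::vector<double> obs_mass;
  NumericVector perm_max(std::max(R - 1, 0));
  std::vector<signed char> sig(B);
  std::vector<int> label(B), stack;
  stack.reserve(256);

  for (int r = 0; r < R; ++r) {
    for (int j = 0; j < B; ++j) {
      sig[j] = 0;
      if (!excluded[j] && sigmat(r, j)) {
        double tv = tmat(r, j);
        sig[j] = tv > 0 ? 1 : (tv < 0 ? -1 : 0);
      }
    }
    std::fill(label.begin(), label.end(), 0);
    int ncl = 0;
    double maxmass = 0;
    std::vector<double> masses;
    for (int j0 = 0; j0 < B; ++j0) {
      if (sig[j0] == 0 || label[j0] != 0) continue;
      const signed char sgn = sig[j0];
      ++ncl;
      double mass = 0;
      stack.clear();
      stack.push_back(j0);
      label[j0] = ncl;
      while (!stack.empty()) {
        int u = stack.back();
        stack.pop_back();
        mass += tmat(r, u);
        int t = u % T, f = u / T;
        for (int k = 0; k < K; ++k) {
          int tt = t + dt8[k], ff = f + df8[k];
          if (tt < 0 || tt >= T || ff < 0 || ff >= Fq) continue;
          int v = tt + ff * T;
          if (sig[v] == sgn && label[v] == 0) {
            label[v] = ncl;
            stack.push_back(v);
          }
        }
      }
      masses.push_back(mass);
      if (std::fabs(mass) > maxmass) maxmass = std::fabs(mass);
    }
    if (r == 0) {
      for (int j = 0; j < B; ++j) obs_label[j] = label[j];
      obs_mass = masses;
    } else {
      perm_max[r - 1] = maxmass;
    }
  }
  return List::create(_["obs_label"] = obs_label,
                      _["obs_mass"] = wrap(obs_mass),
                      _["perm_max"] = perm_max);
}
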
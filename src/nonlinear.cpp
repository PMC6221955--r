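#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Chebyshev distance between templates x[i..i+m-1] and x[j..j+m-1]
static inline double cheb(const NumericVector& x, int i, int j, int m) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double v = std::fabs(x[i + k] - x[j + k]);
    if (v > d) d = v;
  }
  return d;
}

// Approximate entropy (self-matches included): phi(m) - phi(m+1),
// phi(m) = mean_i log( C_i^m ), C_i^m = #{j: d(i,j) <= r} / (N-m+1)
// [[Rcpp::export]]
double cpp_apen(NumericVector x, int m, double r) {
  int N = x.size();
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    int n = N - mm + 1;
    if (n < 1) return NA_REAL;
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      int cnt = 0;
      for (int j = 0; j < n; ++j) {
        if (cheb(x, i, j, mm) <= r) ++cnt;
      }
      acc += std::log((double)cnt / n);
    }
    phi[s] = acc / n;
  }
  return phi[0] - phi[1];
}

// Sample entropy (self-matches excluded): -log(A/B) with template pairs
// i<j drawn from the N-m templates for which both lengths are defined.
// Returns c(sampen, A, B); sampen is NA when A or B is zero.
// [[Rcpp::export]]
NumericVector cpp_sampen(NumericVector x, int m, double r) {
  int N = x.size();
  int n = N - m;  // templates of length m and m+1 both defined for i < n
  double A = 0.0, B = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (cheb(x, i, j, m) <= r) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  double se = (A > 0.0 && B > 0.0) ? -std::log(A / B) : NA_REAL;
  return NumericVector::create(se, A, B);
}

// Correlation sums C(r) = 2/(M(M-1)) #{i<j: ||Xi-Xj|| < r} (Euclidean)
// [[Rcpp::export]]
NumericVector cpp_corr_sum(NumericMatrix pts, NumericVector rs) {
  int M = pts.nrow(), d = pts.ncol(), nr = rs.size();
  std::vector<double> r2(nr);
  for (int k = 0; k < nr; ++k) r2[k] = rs[k] * rs[k];
  std::vector<double> counts(nr, 0.0);
  for (int i = 0; i < M; ++i) {
    for (int j = i + 1; j < M; ++j) {
      double dist2 = 0.0;
      for (int c = 0; c < d; ++c) {
        double v = pts(i, c) - pts(j, c);
        dist2 += v * v;
      }
      for (int k = 0; k < nr; ++k) {
        if (dist2 < r2[k]) counts[k] += 1.0;
      }
    }
  }
  NumericVector out(nr);
  double denom = (double)M * (M - 1) / 2.0;
  for (int k = 0; k < nr; ++k) out[k] = counts[k] / denom;
  return out;
}

// Rosenstein largest-Lyapunov curve: for each point, nearest neighbor with
// a Theiler exclusion, then the mean over pairs of log Euclidean divergence
// after k = 0..n_steps steps. Pairs whose initial separation is below
// `min_d0` (a round-off floor relative to attractor size, set by the
// caller) are discarded: they carry no dynamical information and their
// log-distances are numerical noise. Pairs whose distance underflows later
// are floored.
// [[Rcpp::export]]
NumericVector cpp_rosenstein(NumericMatrix pts, int theiler, int n_steps,
                             double min_d0) {
  int M = pts.nrow(), d = pts.ncol();
  std::vector<int> nn(M, -1);
  for (int i = 0; i < M; ++i) {
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < M; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double dist2 = 0.0;
      for (int c = 0; c < d; ++c) {
        double v = pts(i, c) - pts(j, c);
        dist2 += v * v;
      }
      if (dist2 < best) { best = dist2; nn[i] = j; }
    }
    if (nn[i] >= 0 && std::sqrt(best) < min_d0) nn[i] = -1;
  }
  NumericVector out(n_steps + 1);
  for (int k = 0; k <= n_steps; ++k) {
    double acc = 0.0;
    int cnt = 0;
    for (int i = 0; i < M; ++i) {
      int j = nn[i];
      if (j < 0 || i + k >= M || j + k >= M) continue;
      double dist2 = 0.0;
      for (int c = 0; c < d; ++c) {
        double v = pts(i + k, c) - pts(j + k, c);
        dist2 += v * v;
      }
      double dist = std::sqrt(dist2);
      if (dist < 1e-300) dist = 1e-300;
      acc += std::log(dist);
      ++cnt;
    }
    out[k] = cnt > 0 ? acc / cnt : NA_REAL;
  }
  return out;
}
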
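#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exponential fuzzy membership of a Chebyshev distance.
// form 1: exp(-d^n / r)   form 2: exp(-(d/r)^n)
static inline double membership(double d, double r, double n, int form) {
  double a;
  if (n == 2.0) {
    a = (form == 1) ? d * d / r : (d / r) * (d / r);
  } else {
    a = (form == 1) ? std::pow(d, n) / r : std::pow(d / r, n);
  }
  return std::exp(-a);
}

//' Fuzzy measure entropy of a numeric series (C++ kernel).
//'
//' Computes the four mean similarities (local/global at window lengths m and
//' m+1) over all ordered pairs i != j of embedding vectors, then returns
//' ln(phiL_m / phiL_m1) + ln(phiG_m / phiG_m1).
//'
//' @param x numeric series (already z-transformed upstream)
//' @param m embedding dimension
//' @param r_local,r_global similarity thresholds
//' @param n_local,n_global fuzzy weights
//' @param form 1 = exp(-d^n/r), 2 = exp(-(d/r)^n)
//' @return double entropy in nats; stops on underflow of any phi
//' @noRd
// [[Rcpp::export(name = ".fme_cpp")]]
double fme_cpp(NumericVector x, int m, double r_local, double n_local,
               double r_global, double n_global, int form) {
  const int N = x.size();
  if (N < m + 2) stop("series length %d < m + 2 = %d", N, m + 2);
  const int nv = N - m;  // number of template vectors (same for m and m+1)

  // Global-branch vectors subtract the whole-series mean, which cancels in
  // the pairwise differences, so only the window (local) means are needed.
  // window means for lengths m and m+1 (local baselines)
  std::vector<double> mu_m(nv), mu_m1(nv);
  {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += x[k];
    for (int i = 0; i < nv; ++i) {
      mu_m[i] = s / m;
      mu_m1[i] = (s + x[i + m]) / (m + 1);
      if (i + 1 < nv) s += x[i + m] - x[i];
    }
  }

  long double sumLm = 0.0L, sumLm1 = 0.0L, sumGm = 0.0L, sumGm1 = 0.0L;
  for (int i = 0; i < nv - 1; ++i) {
    for (int j = i + 1; j < nv; ++j) {
      double dLm = 0.0, dLm1 = 0.0, dGm = 0.0, dGm1 = 0.0;
      const double bi_m = mu_m[i], bj_m = mu_m[j];
      const double bi_m1 = mu_m1[i], bj_m1 = mu_m1[j];
      for (int k = 0; k <= m; ++k) {
        const double xi = x[i + k], xj = x[j + k];
        const double dg = std::fabs(xi - xj);
        const double dl1 = std::fabs((xi - bi_m1) - (xj - bj_m1));
        if (k < m) {
          const double dl = std::fabs((xi - bi_m) - (xj - bj_m));
          if (dl > dLm) dLm = dl;
          if (dg > dGm) dGm = dg;
        }
        if (dl1 > dLm1) dLm1 = dl1;
        if (dg > dGm1) dGm1 = dg;
      }
      sumLm += membership(dLm, r_local, n_local, form);
      sumLm1 += membership(dLm1, r_local, n_local, form);
      sumGm += membership(dGm, r_global, n_global, form);
      sumGm1 += membership(dGm1, r_global, n_global, form);
    }
  }

  const long double npairs = (long double)nv * (nv - 1) / 2.0L;
  const double phiLm = (double)(sumLm / npairs);
  const double phiLm1 = (double)(sumLm1 / npairs);
  const double phiGm = (double)(sumGm / npairs);
  const double phiGm1 = (double)(sumGm1 / npairs);

  if (phiLm <= 0 || phiLm1 <= 0 || phiGm <= 0 || phiGm1 <= 0)
    stop("fuzzy similarity underflow (phi = 0); increase r or shorten m");

  return std::log(phiLm / phiLm1) + std::log(phiGm / phiGm1);
}
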
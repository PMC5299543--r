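#include <Rcpp.h>
using namespace Rcpp;

// Stratum-wise Cox partial log-likelihood with Efron tie handling, evaluated
// as a function of a scalar random coefficient b multiplying `zmul`:
//   eta_i = eta0_i + b * zmul_i.
// Subjects must be pre-sorted by strictly non-increasing time within the
// stratum; ties in time form Efron groups.  Returns, for each b in `bvals`,
// the log partial likelihood and its first and second derivatives in b.
//
// The linear predictor is centred by its maximum before exponentiation so the
// risk-set sums cannot overflow; the centring constant cancels exactly in the
// partial likelihood and its derivatives.

// [[Rcpp::export]]
NumericMatrix cox_plik_stratum(NumericVector eta0, NumericVector zmul,
                               IntegerVector event, NumericVector time,
                               NumericVector bvals) {
  const int n = eta0.size();
  const int nb = bvals.size();
  NumericMatrix out(nb, 3);

  std::vector<double> eta(n);
  for (int k = 0; k < nb; ++k) {
    const double b = bvals[k];
    double emax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      eta[i] = eta0[i] + b * zmul[i];
      if (eta[i] > emax) emax = eta[i];
    }
    double ll = 0.0, d1 = 0.0, d2 = 0.0;
    double S0 = 0.0, S1 = 0.0, S2 = 0.0;  // running risk-set sums
    int i = 0;
    while (i < n) {
      // tie block [i, jend) of equal times
      int jend = i + 1;
      while (jend < n && time[jend] == time[i]) ++jend;
      double s0d = 0.0, s1d = 0.0, s2d = 0.0;  // sums over deaths in block
      double eta_d = 0.0, z_d = 0.0;
      int d = 0;
      for (int m = i; m < jend; ++m) {
        const double w = std::exp(eta[m] - emax);
        const double zw = zmul[m] * w;
        S0 += w; S1 += zw; S2 += zmul[m] * zw;
        if (event[m] == 1) {
          s0d += w; s1d += zw; s2d += zmul[m] * zw;
          eta_d += eta[m] - emax;
          z_d += zmul[m];
          ++d;
        }
      }
      if (d > 0) {
        ll += eta_d;
        d1 += z_d;
        for (int l = 0; l < d; ++l) {
          const double f = (double)l / d;
          const double a0 = S0 - f * s0d;
          const double a1 = S1 - f * s1d;
          const double a2 = S2 - f * s2d;
          const double r1 = a1 / a0;
          ll -= std::log(a0);
          d1 -= r1;
          d2 -= a2 / a0 - r1 * r1;
        }
      }
      i = jend;
    }
    out(k, 0) = ll;
    out(k, 1) = d1;
    out(k, 2) = d2;
  }
  return out;
}
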
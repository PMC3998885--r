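// Self-consistent WHAM iteration over sampled bins (log space).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// lognm: log total counts per sampled bin (length M)
// Bt:    M x K bias matrix in kT units
// lognk: log sample count per window (length K)
// [[Rcpp::export]]
List wham_iterate_cpp(NumericVector lognm, NumericMatrix Bt,
                      NumericVector lognk, double tol, int max_iter,
                      NumericVector f0) {
  int M = Bt.nrow(), K = Bt.ncol();
  std::vector<double> f(f0.begin(), f0.end()), fnew(K), logP(M);
  std::vector<double> deltas;
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    // logP_m = lognm_m - LSE_k(lognk_k + f_k - B_mk)
    for (int m = 0; m < M; ++m) {
      double mx = -INFINITY;
      for (int k = 0; k < K; ++k) {
        double v = lognk[k] + f[k] - Bt(m, k);
        if (v > mx) mx = v;
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k)
        s += std::exp(lognk[k] + f[k] - Bt(m, k) - mx);
      logP[m] = lognm[m] - (mx + std::log(s));
    }
    // f_k = -LSE_m(logP_m - B_mk)
    for (int k = 0; k < K; ++k) {
      double mx = -INFINITY;
      for (int m = 0; m < M; ++m) {
        double v = logP[m] - Bt(m, k);
        if (v > mx) mx = v;
      }
      double s = 0.0;
      for (int m = 0; m < M; ++m)
        s += std::exp(logP[m] - Bt(m, k) - mx);
      fnew[k] = -(mx + std::log(s));
    }
    double f0 = fnew[0];
    double d = 0.0;
    for (int k = 0; k < K; ++k) {
      fnew[k] -= f0;
      double dk = std::fabs(fnew[k] - f[k]);
      if (dk > d) d = dk;
      f[k] = fnew[k];
    }
    deltas.push_back(d);
    if (d < tol) { converged = true; break; }
    if (iter % 200 == 0) Rcpp::checkUserInterrupt();
  }
  // final bin probabilities at the converged window constants
  for (int m = 0; m < M; ++m) {
    double mx = -INFINITY;
    for (int k = 0; k < K; ++k) {
      double v = lognk[k] + f[k] - Bt(m, k);
      if (v > mx) mx = v;
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k)
      s += std::exp(lognk[k] + f[k] - Bt(m, k) - mx);
    logP[m] = lognm[m] - (mx + std::log(s));
  }
  return List::create(_["f"] = NumericVector(f.begin(), f.end()),
                      _["logP"] = NumericVector(logP.begin(), logP.end()),
                      _["iterations"] = (iter > max_iter ? max_iter : iter),
                      _["converged"] = converged,
                      _["delta_history"] =
                        NumericVector(deltas.begin(), deltas.end()));
}
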
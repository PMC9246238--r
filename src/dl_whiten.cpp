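#include <Rcpp.h>
using namespace Rcpp;

// Durbin-Levinson whitening of the columns of Z against a stationary
// correlation function rho (rho[0] must be 1).  Returns the whitened
// matrix W with W = L^{-1} Z for R = L L', plus log|R|.
//
// The recursion keeps the best-linear-predictor coefficients of order t
// and the scaled one-step prediction variance v_t, so the whole pass is
// O(n^2 (1 + m)) flops with no n x n matrix ever formed.  Coefficients
// are stored in time order (phi[i] multiplies Z[t - 1 - (t - 1 - i)] =
// Z[i]... i.e. phi[i] multiplies observation i+1 of the history), so all
// inner loops are contiguous dot products.
// [[Rcpp::export(name = ".dl_whiten")]]
List dl_whiten(NumericVector rho, NumericMatrix Z) {
  const int n = Z.nrow();
  const int m = Z.ncol();
  if (rho.size() < n)
    stop("rho must supply correlations up to lag n-1");
  if (std::abs(rho[0] - 1.0) > 1e-10)
    stop("rho[0] must equal 1");

  NumericMatrix W(n, m);
  // phi[i] is the weight on Z[i] (history in time order) when predicting
  // Z[t]; equivalently the lag-(t - i) Durbin-Levinson coefficient.
  std::vector<double> phi(n, 0.0), tmp(n, 0.0);
  const double* r = REAL(rho);
  double v = 1.0;
  double logdet = 0.0;

  for (int t = 0; t < n; ++t) {
    const double sv = std::sqrt(v);
    for (int j = 0; j < m; ++j) {
      const double* zj = &Z(0, j);
      double pred = 0.0;
      for (int i = 0; i < t; ++i) pred += phi[i] * zj[i];
      W(t, j) = (zj[t] - pred) / sv;
    }
    logdet += std::log(v);

    if (t < n - 1) {
      // reflection coefficient for order t -> t+1
      // num = rho[t+1] - sum_i phi[i] * rho[i+1]
      double num = r[t + 1];
      for (int i = 0; i < t; ++i) num -= phi[i] * r[i + 1];
      const double kappa = num / v;
      // lag-order update phi'_k = phi_k - kappa * phi_{t+1-k}, rewritten
      // for the time-order storage: psi'[j] = psi[j-1] - kappa*psi[t-j]
      for (int i = 0; i < t; ++i)
        tmp[i + 1] = phi[i] - kappa * phi[t - 1 - i];
      tmp[0] = kappa;
      for (int i = 0; i <= t; ++i) phi[i] = tmp[i];
      v *= (1.0 - kappa * kappa);
      if (!(v > 1e-12))
        stop("correlation sequence is numerically singular");
    }
  }
  return List::create(_["W"] = W, _["logdet"] = logdet);
}
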
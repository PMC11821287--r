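// median absolute error per column of a prediction matrix
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::vec col_mae_cpp(const arma::mat& preds, const arma::vec& y) {
  const int n = preds.n_rows, L = preds.n_cols;
  arma::vec out(L);
  std::vector<double> e(n);
  for (int l = 0; l < L; ++l) {
    for (int i = 0; i < n; ++i) e[i] = std::fabs(preds(i, l) - y[i]);
    std::sort(e.begin(), e.end());
    out[l] = (n % 2 == 1) ? e[n / 2] : (e[n / 2 - 1] + e[n / 2]) / 2.0;
  }
  return out;
}
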
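#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Accumulate the per-CpG sandwich "meat" sum_j w_j' w_j with
// w_j = sum_{k in cluster j} e_k x_k, for all CpGs at once.
//
// X: n x p design (rows sorted by cluster), E: n x C residual matrix on the
// same rows, starts: 0-based first row of each cluster (length m + 1, last
// element n). Returns a (p*p) x C matrix, each column a vectorised meat.
// [[Rcpp::export]]
arma::mat cpp_cluster_meat(const arma::mat& X, const arma::mat& E,
                           const arma::uvec& starts) {
  const uword p = X.n_cols, C = E.n_cols, m = starts.n_elem - 1;
  mat meat(p * p, C, fill::zeros);
  for (uword j = 0; j < m; ++j) {
    const uword a = starts[j], b = starts[j + 1] - 1;
    // W: p x C, column c holds w_j for CpG c
    mat W = X.rows(a, b).t() * E.rows(a, b);
    for (uword c = 0; c < C; ++c) {
      mat outer = W.col(c) * W.col(c).t();
      meat.col(c) += vectorise(outer);
    }
  }
  return meat;
}
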
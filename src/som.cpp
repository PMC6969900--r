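#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Batch Kohonen training over a fixed radius schedule.
//
// X:     genes x samples data matrix
// P0:    units x samples initial prototypes (PCA-plane initialization done in R)
// G2:    units x units squared grid distances (Euclidean on grid coordinates)
// radii: one neighbourhood radius per epoch
//
// Neighbourhood weight is a smooth Gaussian exp(-d^2 / (2 sigma^2)) with
// sigma = r / 2; no truncation, so the weight profile changes continuously
// across epochs.  At the final radius 0.5 the nearest-neighbour weight is
// e^-8, i.e. the last epochs are k-means (Lloyd) steps for all practical
// purposes.  Quantization error per epoch is the mean Euclidean distance of
// every gene to its best-matching unit, measured at assignment time (i.e.
// against the prototypes produced by the previous epoch).
// [[Rcpp::export(".som_batch_cpp")]]
Rcpp::List som_batch_cpp(const arma::mat& X, const arma::mat& P0,
                         const arma::mat& G2, const arma::vec& radii) {
  arma::mat P = P0;
  const arma::uword n = X.n_rows, m = P.n_rows, s = X.n_cols;
  const arma::vec xs = arma::sum(arma::square(X), 1);
  arma::uvec bmu(n, arma::fill::zeros);
  arma::vec qe(radii.n_elem, arma::fill::zeros);

  for (arma::uword e = 0; e < radii.n_elem; ++e) {
    arma::vec ps = arma::sum(arma::square(P), 1);
    arma::mat D = X * P.t();
    D *= -2.0;
    D.each_col() += xs;
    D.each_row() += ps.t();

    double acc = 0.0;
    arma::mat S(m, s, arma::fill::zeros);
    arma::vec cnt(m, arma::fill::zeros);
    for (arma::uword i = 0; i < n; ++i) {
      const arma::uword b = D.row(i).index_min();
      bmu[i] = b;
      const double d2 = D(i, b);
      acc += std::sqrt(d2 > 0.0 ? d2 : 0.0);
      S.row(b) += X.row(i);
      cnt[b] += 1.0;
    }
    qe[e] = acc / static_cast<double>(n);

    const double sigma = radii[e] / 2.0;
    arma::mat W = arma::exp(-G2 / (2.0 * sigma * sigma));
    const arma::mat num = W * S;
    const arma::vec den = W * cnt;
    for (arma::uword u = 0; u < m; ++u)
      if (den[u] > 0.0) P.row(u) = num.row(u) / den[u];
  }

  // final assignment against the trained prototypes
  arma::vec ps = arma::sum(arma::square(P), 1);
  arma::mat D = X * P.t();
  D *= -2.0;
  D.each_col() += xs;
  D.each_row() += ps.t();
  double acc = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    const arma::uword b = D.row(i).index_min();
    bmu[i] = b;
    const double d2 = D(i, b);
    acc += std::sqrt(d2 > 0.0 ? d2 : 0.0);
  }

  return Rcpp::List::create(
      Rcpp::Named("prototypes") = P,
      Rcpp::Named("bmu") = bmu + 1,
      Rcpp::Named("qe") = qe,
      Rcpp::Named("final_qe") = acc / static_cast<double>(n));
}
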
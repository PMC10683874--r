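// Minimal deterministic multilayer perceptron (ReLU hidden layers, linear
// output, mean-squared-error loss) trained with Adam. Self-contained so
// that training is reproducible bit-for-bit from an integer seed.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List mlp_fit_cpp(const arma::mat& X, const arma::mat& Y,
                       Rcpp::IntegerVector hidden, int epochs, int batch,
                       double lr, double l2, int seed) {
  const int n = X.n_rows, d = X.n_cols, q = Y.n_cols;
  std::vector<int> dims;
  dims.push_back(d);
  for (int h : hidden) dims.push_back(h);
  dims.push_back(q);
  const int L = static_cast<int>(dims.size()) - 1;

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<mat> W(L), mW(L), vW(L);
  std::vector<rowvec> b(L), mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    W[l].set_size(dims[l], dims[l + 1]);
    const double sc = std::sqrt(2.0 / dims[l]);  // He initialization
    for (uword i = 0; i < W[l].n_elem; ++i) W[l](i) = gauss(rng) * sc;
    b[l] = rowvec(dims[l + 1], fill::zeros);
    mW[l] = mat(size(W[l]), fill::zeros);
    vW[l] = mat(size(W[l]), fill::zeros);
    mb[l] = rowvec(dims[l + 1], fill::zeros);
    vb[l] = rowvec(dims[l + 1], fill::zeros);
  }

  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  std::vector<uword> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<mat> acts(L + 1);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    for (int s0 = 0; s0 < n; s0 += batch) {
      const int s1 = std::min(n, s0 + batch);
      uvec rows(s1 - s0);
      for (int i = s0; i < s1; ++i) rows[i - s0] = idx[i];
      acts[0] = X.rows(rows);
      for (int l = 0; l < L; ++l) {
        acts[l + 1] = acts[l] * W[l];
        acts[l + 1].each_row() += b[l];
        if (l < L - 1) acts[l + 1].transform(
            [](double v) { return v > 0.0 ? v : 0.0; });
      }
      mat delta = (acts[L] - Y.rows(rows)) * (2.0 / rows.n_elem);
      ++step;
      const double corr1 = 1.0 - std::pow(b1, step);
      const double corr2 = 1.0 - std::pow(b2, step);
      for (int l = L - 1; l >= 0; --l) {
        mat gW = acts[l].t() * delta + l2 * W[l];
        rowvec gb = sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta %= conv_to<mat>::from(acts[l] > 0.0);
        }
        mW[l] = b1 * mW[l] + (1 - b1) * gW;
        vW[l] = b2 * vW[l] + (1 - b2) * square(gW);
        W[l] -= lr * (mW[l] / corr1) / (sqrt(vW[l] / corr2) + eps);
        mb[l] = b1 * mb[l] + (1 - b1) * gb;
        vb[l] = b2 * vb[l] + (1 - b2) * square(gb);
        b[l] -= lr * (mb[l] / corr1) / (sqrt(vb[l] / corr2) + eps);
      }
    }
  }
  Rcpp::List Wl(L), bl(L);
  for (int l = 0; l < L; ++l) {
    Wl[l] = W[l];
    bl[l] = b[l];
  }
  return Rcpp::List::create(Rcpp::Named("W") = Wl, Rcpp::Named("b") = bl);
}

// [[Rcpp::export]]
arma::mat mlp_predict_cpp(const Rcpp::List& fit, const arma::mat& X) {
  const Rcpp::List Wl = fit["W"], bl = fit["b"];
  const int L = Wl.size();
  mat a = X;
  for (int l = 0; l < L; ++l) {
    const mat W = Rcpp::as<mat>(Wl[l]);
    const rowvec b = Rcpp::as<rowvec>(bl[l]);
    a = a * W;
    a.each_row() += b;
    if (l < L - 1) a.transform([](double v) { return v > 0.0 ? v : 0.0; });
  }
  return a;
}
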
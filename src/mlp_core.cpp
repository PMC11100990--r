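// Full-batch Adam training of a dense ReLU network with linear output,
// minimizing mean squared error. Hot loop of the utility-prediction
// networks; semantics mirror the R reference wrapper in R/mlp.R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".mlp_train_core")]]
List mlp_train_core(List W_in, List b_in, List adam_in,
                    const arma::mat& X, const arma::vec& y,
                    int epochs, double lr, double tol) {
  const int L = W_in.size();
  const double n = static_cast<double>(X.n_rows);
  std::vector<arma::mat> W(L), mW(L), vW(L);
  std::vector<arma::vec> b(L), mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(W_in[l]);
    b[l] = as<arma::vec>(b_in[l]);
  }
  int t_adam = 0;
  if (adam_in.isNULL() || adam_in.size() == 0) {
    for (int l = 0; l < L; ++l) {
      mW[l] = arma::zeros<arma::mat>(W[l].n_rows, W[l].n_cols);
      vW[l] = mW[l];
      mb[l] = arma::zeros<arma::vec>(b[l].n_elem);
      vb[l] = mb[l];
    }
  } else {
    List amW = adam_in["mW"], avW = adam_in["vW"];
    List amb = adam_in["mb"], avb = adam_in["vb"];
    t_adam = as<int>(adam_in["t"]);
    for (int l = 0; l < L; ++l) {
      mW[l] = as<arma::mat>(amW[l]); vW[l] = as<arma::mat>(avW[l]);
      mb[l] = as<arma::vec>(amb[l]); vb[l] = as<arma::vec>(avb[l]);
    }
  }
  const double beta1 = 0.9, beta2 = 0.999, eps_adam = 1e-8;
  std::vector<double> trace;
  trace.reserve(epochs);
  std::vector<arma::mat> acts(L + 1);
  for (int ep = 0; ep < epochs; ++ep) {
    acts[0] = X;
    for (int l = 0; l < L; ++l) {
      arma::mat z = acts[l] * W[l];
      z.each_row() += b[l].t();
      if (l < L - 1) z = arma::clamp(z, 0.0, arma::datum::inf);
      acts[l + 1] = z;
    }
    arma::vec pred = acts[L].col(0);
    double mse = arma::mean(arma::square(pred - y));
    trace.push_back(mse);
    if (tol > 0 && ep > 0 &&
        std::fabs(trace[ep - 1] - mse) < tol * std::max(trace[ep - 1], 1e-8))
      break;
    arma::mat delta = (2.0 / n) * (pred - y);
    ++t_adam;
    const double c1 = 1.0 - std::pow(beta1, t_adam);
    const double c2 = 1.0 - std::pow(beta2, t_adam);
    for (int l = L - 1; l >= 0; --l) {
      arma::mat gW = acts[l].t() * delta;
      arma::vec gb = arma::sum(delta, 0).t();
      if (l > 0) {
        arma::mat back = delta * W[l].t();
        delta = back % arma::conv_to<arma::mat>::from(acts[l] > 0.0);
      }
      mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
      vW[l] = beta2 * vW[l] + (1 - beta2) * (gW % gW);
      W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps_adam);
      mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
      vb[l] = beta2 * vb[l] + (1 - beta2) * (gb % gb);
      b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps_adam);
    }
  }
  List W_out(L), b_out(L), mW_out(L), vW_out(L), mb_out(L), vb_out(L);
  for (int l = 0; l < L; ++l) {
    W_out[l] = W[l]; b_out[l] = NumericVector(b[l].begin(), b[l].end());
    mW_out[l] = mW[l]; vW_out[l] = vW[l];
    mb_out[l] = NumericVector(mb[l].begin(), mb[l].end());
    vb_out[l] = NumericVector(vb[l].begin(), vb[l].end());
  }
  return List::create(
    _["W"] = W_out, _["b"] = b_out,
    _["adam"] = List::create(_["mW"] = mW_out, _["vW"] = vW_out,
                             _["mb"] = mb_out, _["vb"] = vb_out,
                             _["t"] = t_adam),
    _["trace"] = trace);
}
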
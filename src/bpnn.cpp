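// Backpropagation neural-network core: sigmoid hidden layers, identity
// output, per-sample (incremental) gradient-descent updates on the squared
// error E_i = 0.5 * (yhat_i - y_i)^2.  The R layer owns weight
// initialization and min-max scaling; everything here is deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static std::vector<arma::mat> get_weights(const List& W) {
  std::vector<arma::mat> out;
  for (R_xlen_t l = 0; l < W.size(); ++l)
    out.push_back(as<arma::mat>(W[l]));
  return out;
}

static std::vector<arma::vec> get_biases(const List& b) {
  std::vector<arma::vec> out;
  for (R_xlen_t l = 0; l < b.size(); ++l)
    out.push_back(as<arma::vec>(b[l]));
  return out;
}

static arma::vec sigmoid(const arma::vec& z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

// forward pass for one sample; fills activations a[0..L]
static void forward_one(const arma::vec& x,
                        const std::vector<arma::mat>& W,
                        const std::vector<arma::vec>& b,
                        std::vector<arma::vec>& a) {
  const size_t L = W.size();
  a[0] = x;
  for (size_t l = 0; l < L; ++l) {
    arma::vec z = W[l].t() * a[l] + b[l];
    a[l + 1] = (l + 1 < L) ? sigmoid(z) : z;
  }
}

// backward pass for one sample: gradient of 0.5 * (yhat - y)^2
static void backward_one(double y,
                         const std::vector<arma::mat>& W,
                         const std::vector<arma::vec>& a,
                         std::vector<arma::mat>& gW,
                         std::vector<arma::vec>& gb) {
  const size_t L = W.size();
  arma::vec delta(1);
  delta(0) = a[L](0) - y;  // identity output unit
  for (size_t l = L; l-- > 0;) {
    gW[l] = a[l] * delta.t();
    gb[l] = delta;
    if (l > 0) {
      arma::vec act = a[l];
      delta = (W[l] * delta) % (act % (1.0 - act));
    }
  }
}

// [[Rcpp::export]]
arma::vec cpp_bpnn_forward(const arma::mat& X, List W_, List b_) {
  std::vector<arma::mat> W = get_weights(W_);
  std::vector<arma::vec> b = get_biases(b_);
  const size_t L = W.size();
  arma::uword n = X.n_rows;
  arma::vec out(n);
  std::vector<arma::vec> a(L + 1);
  for (arma::uword i = 0; i < n; ++i) {
    forward_one(X.row(i).t(), W, b, a);
    out(i) = a[L](0);
  }
  return out;
}

// mean over samples of 0.5 * (yhat - y)^2
// [[Rcpp::export]]
double cpp_bpnn_loss(const arma::mat& X, const arma::vec& y,
                     List W_, List b_) {
  arma::vec e = cpp_bpnn_forward(X, W_, b_) - y;
  return 0.5 * arma::mean(e % e);
}

// analytic gradient of cpp_bpnn_loss with respect to every weight and bias
// [[Rcpp::export]]
List cpp_bpnn_grad(const arma::mat& X, const arma::vec& y,
                   List W_, List b_) {
  std::vector<arma::mat> W = get_weights(W_);
  std::vector<arma::vec> b = get_biases(b_);
  const size_t L = W.size();
  const arma::uword n = X.n_rows;
  std::vector<arma::vec> a(L + 1);
  std::vector<arma::mat> gW(L), accW(L);
  std::vector<arma::vec> gb(L), accb(L);
  for (size_t l = 0; l < L; ++l) {
    accW[l] = arma::zeros<arma::mat>(W[l].n_rows, W[l].n_cols);
    accb[l] = arma::zeros<arma::vec>(b[l].n_elem);
  }
  for (arma::uword i = 0; i < n; ++i) {
    forward_one(X.row(i).t(), W, b, a);
    backward_one(y(i), W, a, gW, gb);
    for (size_t l = 0; l < L; ++l) {
      accW[l] += gW[l];
      accb[l] += gb[l];
    }
  }
  List oW(L), ob(L);
  for (size_t l = 0; l < L; ++l) {
    oW[l] = wrap(accW[l] / double(n));
    ob[l] = wrap(accb[l] / double(n));
  }
  return List::create(_["gW"] = oW, _["gb"] = ob);
}

// Incremental training: one epoch presents every sample once in row order;
// for each sample all layer deltas are computed with the current weights,
// then every weight and bias is updated.  After each epoch the training
// RMSE (on the scaled target) is recorded; training stops early when it
// reaches a finite target_rmse, otherwise after max_epochs epochs.
// Hot loop: flat buffers, no per-sample allocation.
// [[Rcpp::export]]
List cpp_bpnn_train(const arma::mat& X, const arma::vec& y,
                    List W_, List b_, double lr, int max_epochs,
                    double target_rmse) {
  std::vector<arma::mat> W = get_weights(W_);
  std::vector<arma::vec> b = get_biases(b_);
  const size_t L = W.size();
  const arma::uword n = X.n_rows;
  const bool stop_early = std::isfinite(target_rmse);
  // layer sizes and activation/delta buffers
  std::vector<arma::uword> s(L + 1);
  s[0] = X.n_cols;
  for (size_t l = 0; l < L; ++l) s[l + 1] = W[l].n_cols;
  std::vector<std::vector<double> > act(L + 1), del(L + 1);
  for (size_t l = 0; l <= L; ++l) {
    act[l].resize(s[l]);
    del[l].resize(s[l]);
  }
  std::vector<double> trace;
  int epochs = 0;
  for (int ep = 0; ep < max_epochs; ++ep) {
    double sse = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      // forward
      for (arma::uword j = 0; j < s[0]; ++j) act[0][j] = X(i, j);
      for (size_t l = 0; l < L; ++l) {
        const double* w = W[l].memptr();
        for (arma::uword k = 0; k < s[l + 1]; ++k) {
          double z = b[l](k);
          const double* wk = w + k * s[l];
          for (arma::uword j = 0; j < s[l]; ++j) z += wk[j] * act[l][j];
          act[l + 1][k] = (l + 1 < L) ? 1.0 / (1.0 + std::exp(-z)) : z;
        }
      }
      // deltas (with current weights)
      del[L][0] = act[L][0] - y(i);
      for (size_t l = L - 1; l >= 1; --l) {
        const double* w = W[l].memptr();
        for (arma::uword j = 0; j < s[l]; ++j) {
          double acc = 0.0;
          for (arma::uword k = 0; k < s[l + 1]; ++k)
            acc += w[j + k * s[l]] * del[l + 1][k];
          del[l][j] = acc * act[l][j] * (1.0 - act[l][j]);
        }
      }
      // update
      for (size_t l = 0; l < L; ++l) {
        double* w = W[l].memptr();
        for (arma::uword k = 0; k < s[l + 1]; ++k) {
          const double step = lr * del[l + 1][k];
          double* wk = w + k * s[l];
          for (arma::uword j = 0; j < s[l]; ++j) wk[j] -= step * act[l][j];
          b[l](k) -= step;
        }
      }
    }
    epochs = ep + 1;
    // training RMSE after the epoch
    for (arma::uword i = 0; i < n; ++i) {
      for (arma::uword j = 0; j < s[0]; ++j) act[0][j] = X(i, j);
      for (size_t l = 0; l < L; ++l) {
        const double* w = W[l].memptr();
        for (arma::uword k = 0; k < s[l + 1]; ++k) {
          double z = b[l](k);
          const double* wk = w + k * s[l];
          for (arma::uword j = 0; j < s[l]; ++j) z += wk[j] * act[l][j];
          act[l + 1][k] = (l + 1 < L) ? 1.0 / (1.0 + std::exp(-z)) : z;
        }
      }
      double e = act[L][0] - y(i);
      sse += e * e;
    }
    double rmse = std::sqrt(sse / double(n));
    trace.push_back(rmse);
    if (stop_early && rmse <= target_rmse) break;
  }
  List oW(L), ob(L);
  for (size_t l = 0; l < L; ++l) {
    oW[l] = wrap(W[l]);
    ob[l] = wrap(b[l]);
  }
  return List::create(_["W"] = oW, _["b"] = ob, _["epochs"] = epochs,
                      _["rmse_trace"] = wrap(trace));
}
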
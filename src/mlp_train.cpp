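#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Full-batch backpropagation for a 3-layer regression network:
// tanh hidden layer, linear output. Momentum plus an adaptive learning
// rate (increase on improvement, reject the step and decrease when the
// batch loss rises by more than max_perf_inc). Early stopping tracks the
// best weights by validation RMSE. Entirely deterministic: the initial
// weights come from the caller.

static double forward_mse(const std::vector<double>& X, int n, int p,
                          const std::vector<double>& y,
                          const std::vector<double>& W1,
                          const std::vector<double>& b1,
                          const std::vector<double>& w2, double b2,
                          int h) {
  double sse = 0.0;
  for (int i = 0; i < n; ++i) {
    double out = b2;
    for (int j = 0; j < h; ++j) {
      double s = b1[j];
      for (int k = 0; k < p; ++k) s += W1[j * p + k] * X[i * p + k];
      out += w2[j] * std::tanh(s);
    }
    double e = out - y[i];
    sse += e * e;
  }
  return sse / n;
}

// [[Rcpp::export]]
List mlp_train_cpp(NumericMatrix Xr, NumericVector yr,
                   NumericMatrix Xvr, NumericVector yvr,
                   NumericMatrix W1r, NumericVector b1r,
                   NumericVector w2r, double b2,
                   double lr, double momentum,
                   int max_epochs, int patience,
                   double lr_inc, double lr_dec, double max_perf_inc) {
  const int n = Xr.nrow(), p = Xr.ncol(), h = W1r.nrow();
  const int nv = Xvr.nrow();

  // flatten row-major for cache-friendly loops
  std::vector<double> X(n * p), y(yr.begin(), yr.end());
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < p; ++k) X[i * p + k] = Xr(i, k);
  std::vector<double> Xv(nv * p), yv(yvr.begin(), yvr.end());
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < p; ++k) Xv[i * p + k] = Xvr(i, k);

  std::vector<double> W1(h * p), b1(b1r.begin(), b1r.end()),
      w2(w2r.begin(), w2r.end());
  for (int j = 0; j < h; ++j)
    for (int k = 0; k < p; ++k) W1[j * p + k] = W1r(j, k);

  std::vector<double> vW1(h * p, 0.0), vb1(h, 0.0), vw2(h, 0.0);
  double vb2 = 0.0;

  double train_mse = forward_mse(X, n, p, y, W1, b1, w2, b2, h);
  const double init_train_mse = train_mse;
  if (!std::isfinite(train_mse)) {
    return List::create(_["error"] = "non-finite initial loss",
                        _["epoch"] = 0);
  }

  // best-by-validation (falls back to train loss when no val set)
  double val_mse = nv > 0 ? forward_mse(Xv, nv, p, yv, W1, b1, w2, b2, h)
                          : train_mse;
  std::vector<double> bW1 = W1, bb1 = b1, bw2 = w2;
  double bb2 = b2, best_val = val_mse;
  std::vector<double> tW1 = W1, tb1 = b1, tw2 = w2;
  double tb2 = b2, best_train = train_mse;
  int since_best = 0, epoch = 0;

  std::vector<double> gW1(h * p), gb1(h), gw2(h);
  std::vector<double> a(h);

  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    std::fill(gW1.begin(), gW1.end(), 0.0);
    std::fill(gb1.begin(), gb1.end(), 0.0);
    std::fill(gw2.begin(), gw2.end(), 0.0);
    double gb2 = 0.0;

    for (int i = 0; i < n; ++i) {
      double out = b2;
      for (int j = 0; j < h; ++j) {
        double s = b1[j];
        for (int k = 0; k < p; ++k) s += W1[j * p + k] * X[i * p + k];
        a[j] = std::tanh(s);
        out += w2[j] * a[j];
      }
      const double e = 2.0 * (out - y[i]) / n; // d(MSE)/d(out)
      gb2 += e;
      for (int j = 0; j < h; ++j) {
        gw2[j] += e * a[j];
        const double gh = e * w2[j] * (1.0 - a[j] * a[j]);
        gb1[j] += gh;
        for (int k = 0; k < p; ++k) gW1[j * p + k] += gh * X[i * p + k];
      }
    }

    // momentum step
    for (int j = 0; j < h; ++j) {
      for (int k = 0; k < p; ++k) {
        vW1[j * p + k] = momentum * vW1[j * p + k] - lr * gW1[j * p + k];
        W1[j * p + k] += vW1[j * p + k];
      }
      vb1[j] = momentum * vb1[j] - lr * gb1[j];
      b1[j] += vb1[j];
      vw2[j] = momentum * vw2[j] - lr * gw2[j];
      w2[j] += vw2[j];
    }
    vb2 = momentum * vb2 - lr * gb2;
    b2 += vb2;

    const double new_mse = forward_mse(X, n, p, y, W1, b1, w2, b2, h);
    if (!std::isfinite(new_mse) || new_mse > train_mse * max_perf_inc) {
      // reject the step: revert, damp the rate, kill the momentum
      for (int j = 0; j < h; ++j) {
        for (int k = 0; k < p; ++k) {
          W1[j * p + k] -= vW1[j * p + k];
          vW1[j * p + k] = 0.0;
        }
        b1[j] -= vb1[j]; vb1[j] = 0.0;
        w2[j] -= vw2[j]; vw2[j] = 0.0;
      }
      b2 -= vb2; vb2 = 0.0;
      lr *= lr_dec;
      if (lr < 1e-14) break;
      ++since_best;
    } else {
      if (new_mse < train_mse) lr *= lr_inc;
      train_mse = new_mse;
      if (train_mse < best_train) {
        best_train = train_mse;
        tW1 = W1; tb1 = b1; tw2 = w2; tb2 = b2;
      }
      val_mse = nv > 0 ? forward_mse(Xv, nv, p, yv, W1, b1, w2, b2, h)
                       : train_mse;
      if (val_mse < best_val) {
        best_val = val_mse;
        bW1 = W1; bb1 = b1; bw2 = w2; bb2 = b2;
        since_best = 0;
      } else {
        ++since_best;
      }
    }
    if (since_best > patience) break;
  }

  NumericMatrix W1out(h, p), W1tr(h, p);
  for (int j = 0; j < h; ++j)
    for (int k = 0; k < p; ++k) {
      W1out(j, k) = bW1[j * p + k];
      W1tr(j, k) = tW1[j * p + k];
    }
  return List::create(
      _["W1"] = W1out, _["b1"] = NumericVector(bb1.begin(), bb1.end()),
      _["w2"] = NumericVector(bw2.begin(), bw2.end()), _["b2"] = bb2,
      _["W1_train"] = W1tr,
      _["b1_train"] = NumericVector(tb1.begin(), tb1.end()),
      _["w2_train"] = NumericVector(tw2.begin(), tw2.end()),
      _["b2_train"] = tb2,
      _["best_val_rmse"] = std::sqrt(best_val),
      _["best_train_rmse"] = std::sqrt(best_train),
      _["init_train_rmse"] = std::sqrt(init_train_mse),
      _["epochs"] = std::min(epoch, max_epochs), _["final_lr"] = lr);
}
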
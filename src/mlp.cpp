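#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat sigm(const arma::mat &x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// Forward pass returning output-layer activations.
static arma::mat forward(const arma::mat &X, const arma::mat &W1,
                         const arma::rowvec &b1, const arma::mat &W2,
                         const arma::rowvec &b2) {
  arma::mat H = sigm(X * W1 + arma::repmat(b1, X.n_rows, 1));
  return sigm(H * W2 + arma::repmat(b2, H.n_rows, 1));
}

// Single-hidden-layer MLP, sigmoid activations, full-batch gradient descent
// with momentum on squared error; early stop on validation accuracy.
// X/Y: training features (already scaled to [0,1]) and one-hot labels.
// Xval/yval: validation features and 0-based class indices.
// Returns weights of the epoch with the best validation accuracy.
// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat &X, const arma::mat &Y, const arma::mat &Xval,
                   const arma::uvec &yval, int hidden, double lr,
                   double momentum, int max_epochs, int patience, int seed) {
  const int p = X.n_cols, k = Y.n_cols;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(-0.5, 0.5);

  arma::mat W1(p, hidden), W2(hidden, k);
  arma::rowvec b1(hidden), b2(k);
  for (auto &w : W1) w = unif(rng);
  for (auto &w : W2) w = unif(rng);
  for (auto &w : b1) w = unif(rng);
  for (auto &w : b2) w = unif(rng);

  arma::mat vW1(p, hidden, arma::fill::zeros), vW2(hidden, k, arma::fill::zeros);
  arma::rowvec vb1(hidden, arma::fill::zeros), vb2(k, arma::fill::zeros);

  arma::mat bW1 = W1, bW2 = W2;
  arma::rowvec bb1 = b1, bb2 = b2;
  double best_acc = -1.0;
  int best_epoch = 0, stale = 0, epoch = 0;
  const arma::uword n = X.n_rows, batch = 50;

  // epoch = one pass over the training half in shuffled mini-batches
  // (online-style backprop; full-batch descent at this learning rate
  // stalls inside the early-stopping window)
  std::vector<arma::uword> perm(n);
  for (arma::uword i = 0; i < n; i++) perm[i] = i;

  for (epoch = 1; epoch <= max_epochs; epoch++) {
    std::shuffle(perm.begin(), perm.end(), rng);
    for (arma::uword start = 0; start < n; start += batch) {
      arma::uword stop = std::min(start + batch, n) - 1;
      arma::uvec rows(stop - start + 1);
      for (arma::uword r = 0; r <= stop - start; r++) rows[r] = perm[start + r];
      arma::mat Xb = X.rows(rows), Yb = Y.rows(rows);
      arma::mat H = sigm(Xb * W1 + arma::repmat(b1, Xb.n_rows, 1));
      arma::mat O = sigm(H * W2 + arma::repmat(b2, H.n_rows, 1));
      arma::mat dO = (O - Yb) % O % (1.0 - O) / (double)Xb.n_rows;
      arma::mat dH = (dO * W2.t()) % H % (1.0 - H);

      vW2 = momentum * vW2 - lr * (H.t() * dO);
      vb2 = momentum * vb2 - lr * arma::sum(dO, 0);
      vW1 = momentum * vW1 - lr * (Xb.t() * dH);
      vb1 = momentum * vb1 - lr * arma::sum(dH, 0);
      W2 += vW2; b2 += vb2; W1 += vW1; b1 += vb1;
    }

    arma::mat Ov = forward(Xval, W1, b1, W2, b2);
    arma::uvec pred = arma::index_max(Ov, 1);
    double acc = arma::mean(arma::conv_to<arma::vec>::from(pred == yval));
    if (acc > best_acc + 1e-12) {
      best_acc = acc;
      bW1 = W1; bW2 = W2; bb1 = b1; bb2 = b2;
      best_epoch = epoch;
      stale = 0;
    } else if (++stale >= patience) {
      break;
    }
  }

  return List::create(
      _["W1"] = bW1, _["b1"] = bb1, _["W2"] = bW2, _["b2"] = bb2,
      _["val_accuracy"] = 100.0 * best_acc, _["epochs_run"] = epoch,
      _["best_epoch"] = best_epoch);
}

// [[Rcpp::export]]
arma::mat mlp_forward_cpp(const arma::mat &X, const arma::mat &W1,
                          const arma::rowvec &b1, const arma::mat &W2,
                          const arma::rowvec &b2) {
  return forward(X, W1, b1, W2, b2);
}
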
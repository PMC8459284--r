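// Feedforward scorer used by the agents: input -> 16 ReLU -> 16 (batch norm,
// ReLU) -> sigmoid. Trained with minibatch Adam on binary cross-entropy.
// Batch statistics are used during training; running averages at inference.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Net {
  mat W1;               // h1 x n
  rowvec b1;            // h1
  mat W2;               // h2 x h1
  rowvec b2;            // h2
  rowvec gamma, beta;   // batch-norm scale/shift, h2
  rowvec rmean, rvar;   // batch-norm running statistics, h2
  rowvec W3;            // 1 x h2
  double b3;
};

Net unpack(const Rcpp::List& p) {
  Net net;
  net.W1    = Rcpp::as<mat>(p["W1"]);
  net.b1    = Rcpp::as<rowvec>(p["b1"]);
  net.W2    = Rcpp::as<mat>(p["W2"]);
  net.b2    = Rcpp::as<rowvec>(p["b2"]);
  net.gamma = Rcpp::as<rowvec>(p["gamma"]);
  net.beta  = Rcpp::as<rowvec>(p["beta"]);
  net.rmean = Rcpp::as<rowvec>(p["rmean"]);
  net.rvar  = Rcpp::as<rowvec>(p["rvar"]);
  net.W3    = Rcpp::as<rowvec>(p["W3"]);
  net.b3    = Rcpp::as<double>(p["b3"]);
  return net;
}

Rcpp::List pack(const Net& net) {
  return Rcpp::List::create(
    Rcpp::Named("W1") = net.W1, Rcpp::Named("b1") = net.b1,
    Rcpp::Named("W2") = net.W2, Rcpp::Named("b2") = net.b2,
    Rcpp::Named("gamma") = net.gamma, Rcpp::Named("beta") = net.beta,
    Rcpp::Named("rmean") = net.rmean, Rcpp::Named("rvar") = net.rvar,
    Rcpp::Named("W3") = net.W3, Rcpp::Named("b3") = net.b3);
}

inline mat relu(const mat& x) { return clamp(x, 0.0, datum::inf); }

inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

// Adam state for one parameter tensor.
struct AdamState {
  mat m, v;
  AdamState(uword r, uword c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
  void step(mat& w, const mat& g, double lr, double b1, double b2,
            double eps, int t) {
    m = b1 * m + (1.0 - b1) * g;
    v = b2 * v + (1.0 - b2) * square(g);
    mat mhat = m / (1.0 - std::pow(b1, t));
    mat vhat = v / (1.0 - std::pow(b2, t));
    w -= lr * mhat / (sqrt(vhat) + eps);
  }
};

} // namespace

namespace {

vec forward_with_stats(const Net& net, const mat& X, const rowvec& mu,
                       const rowvec& var, double bn_eps) {
  mat h1 = relu(X * net.W1.t() + repmat(net.b1, X.n_rows, 1));
  mat a2 = h1 * net.W2.t() + repmat(net.b2, X.n_rows, 1);
  mat z = (a2 - repmat(mu, X.n_rows, 1)) /
          repmat(sqrt(var + bn_eps), X.n_rows, 1);
  z = z % repmat(net.gamma, X.n_rows, 1) + repmat(net.beta, X.n_rows, 1);
  mat h2 = relu(z);
  vec p = sigmoid(h2 * net.W3.t() + net.b3);
  return clamp(p, 1e-7, 1.0 - 1e-7);
}

} // namespace

// Forward pass normalizing with the stored running statistics:
// probabilities for each row of X, clamped strictly inside (0, 1).
// [[Rcpp::export(name = ".nn_forward")]]
arma::vec nn_forward(Rcpp::List params, const arma::mat& X, double bn_eps) {
  Net net = unpack(params);
  return forward_with_stats(net, X, net.rmean, net.rvar, bn_eps);
}

// Forward pass normalizing with the batch statistics of a reference batch
// (the full structure space in production mode).
// [[Rcpp::export(name = ".nn_forward_ref")]]
arma::vec nn_forward_ref(Rcpp::List params, const arma::mat& X,
                         const arma::mat& Xref, double bn_eps) {
  Net net = unpack(params);
  mat h1 = relu(Xref * net.W1.t() + repmat(net.b1, Xref.n_rows, 1));
  mat a2 = h1 * net.W2.t() + repmat(net.b2, Xref.n_rows, 1);
  rowvec mu = mean(a2, 0);
  rowvec var = mean(square(a2 - repmat(mu, a2.n_rows, 1)), 0);
  return forward_with_stats(net, X, mu, var, bn_eps);
}

// Minibatch Adam training on binary cross-entropy. `perms` holds one
// 1-based permutation of the example indices per epoch (column-wise), so
// the data order is controlled entirely by the caller's RNG.
// [[Rcpp::export(name = ".nn_train")]]
Rcpp::List nn_train(Rcpp::List params, const arma::mat& X, const arma::vec& y,
                    int epochs, int batch_size, double lr, double beta1,
                    double beta2, double adam_eps, double bn_momentum,
                    double bn_eps, const arma::umat& perms) {
  Net net = unpack(params);
  const uword N = X.n_rows;

  AdamState sW1(net.W1.n_rows, net.W1.n_cols), sb1(1, net.b1.n_elem);
  AdamState sW2(net.W2.n_rows, net.W2.n_cols), sb2(1, net.b2.n_elem);
  AdamState sg(1, net.gamma.n_elem), sbt(1, net.beta.n_elem);
  AdamState sW3(1, net.W3.n_elem), sb3(1, 1);

  int t = 0;
  for (int e = 0; e < epochs; ++e) {
    uvec ord = perms.col(e) - 1; // to 0-based
    for (uword start = 0; start < N; start += batch_size) {
      uword stop = std::min<uword>(start + batch_size, N) - 1;
      uvec idx = ord.subvec(start, stop);
      mat Xb = X.rows(idx);
      vec yb = y.elem(idx);
      const double B = static_cast<double>(Xb.n_rows);

      // forward (training mode: batch statistics)
      mat a1 = Xb * net.W1.t() + repmat(net.b1, Xb.n_rows, 1);
      mat h1 = relu(a1);
      mat a2 = h1 * net.W2.t() + repmat(net.b2, Xb.n_rows, 1);
      rowvec mu = mean(a2, 0);
      mat cent = a2 - repmat(mu, a2.n_rows, 1);
      rowvec varb = mean(square(cent), 0); // biased, as used for normalization
      rowvec istd = 1.0 / sqrt(varb + bn_eps);
      mat xhat = cent % repmat(istd, a2.n_rows, 1);
      mat z = xhat % repmat(net.gamma, a2.n_rows, 1) +
              repmat(net.beta, a2.n_rows, 1);
      mat h2 = relu(z);
      vec logits = h2 * net.W3.t() + net.b3;
      vec p = sigmoid(logits);

      // backward
      vec dlogits = (p - yb) / B;
      rowvec dW3 = dlogits.t() * h2;
      double db3 = accu(dlogits);
      mat dh2 = dlogits * net.W3;
      mat dz = dh2 % conv_to<mat>::from(z > 0);
      rowvec dgamma = sum(dz % xhat, 0);
      rowvec dbeta = sum(dz, 0);
      mat dxhat = dz % repmat(net.gamma, dz.n_rows, 1);
      rowvec s1 = sum(dxhat, 0);
      rowvec s2 = sum(dxhat % xhat, 0);
      mat da2 = (dxhat - repmat(s1 / B, dz.n_rows, 1) -
                 xhat % repmat(s2 / B, dz.n_rows, 1)) %
                repmat(istd, dz.n_rows, 1);
      mat dh1 = da2 * net.W2;
      mat da1 = dh1 % conv_to<mat>::from(a1 > 0);
      mat dW2 = da2.t() * h1;
      rowvec db2 = sum(da2, 0);
      mat dW1 = da1.t() * Xb;
      rowvec db1 = sum(da1, 0);

      // running statistics (unbiased variance, as in common frameworks)
      rowvec var_run = (Xb.n_rows > 1) ? rowvec(varb * B / (B - 1.0)) : varb;
      net.rmean = (1.0 - bn_momentum) * net.rmean + bn_momentum * mu;
      net.rvar = (1.0 - bn_momentum) * net.rvar + bn_momentum * var_run;

      ++t;
      sW1.step(net.W1, dW1, lr, beta1, beta2, adam_eps, t);
      { mat b = net.b1; sb1.step(b, mat(db1), lr, beta1, beta2, adam_eps, t); net.b1 = b; }
      sW2.step(net.W2, dW2, lr, beta1, beta2, adam_eps, t);
      { mat b = net.b2; sb2.step(b, mat(db2), lr, beta1, beta2, adam_eps, t); net.b2 = b; }
      { mat g = net.gamma; sg.step(g, mat(dgamma), lr, beta1, beta2, adam_eps, t); net.gamma = g; }
      { mat b = net.beta; sbt.step(b, mat(dbeta), lr, beta1, beta2, adam_eps, t); net.beta = b; }
      { mat w = net.W3; sW3.step(w, mat(dW3), lr, beta1, beta2, adam_eps, t); net.W3 = w; }
      { mat b(1, 1); b(0, 0) = net.b3; mat g(1, 1); g(0, 0) = db3;
        sb3.step(b, g, lr, beta1, beta2, adam_eps, t); net.b3 = b(0, 0); }
    }
  }
  return pack(net);
}
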
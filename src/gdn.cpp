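// Gaussian density network core: a 2-hidden-layer tanh MLP emitting a
// diagonal Gaussian (mean + softplus variance with a positivity floor).
// Kept in C++ because the event filter and gaze controller evaluate these
// networks tens of times per simulated timestep.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat softplus(const arma::mat& x) {
  // stable log(1 + exp(x)); for large x this is x up to ~1e-14
  arma::mat out(arma::size(x));
  for (arma::uword i = 0; i < x.n_elem; ++i) {
    double v = x(i);
    out(i) = v > 30.0 ? v : std::log1p(std::exp(v));
  }
  return out;
}

static inline arma::mat sigmoid(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

struct GdnParams {
  arma::mat W1, W2, Wm, Wv, Ws;
  arma::rowvec b1, b2, bm, bv;
  double floor;
};

static GdnParams unpack(const List& net) {
  GdnParams p;
  p.W1 = as<arma::mat>(net["W1"]);
  p.b1 = as<arma::rowvec>(net["b1"]);
  p.W2 = as<arma::mat>(net["W2"]);
  p.b2 = as<arma::rowvec>(net["b2"]);
  p.Wm = as<arma::mat>(net["Wm"]);
  p.bm = as<arma::rowvec>(net["bm"]);
  p.Wv = as<arma::mat>(net["Wv"]);
  p.bv = as<arma::rowvec>(net["bv"]);
  p.Ws = as<arma::mat>(net["Ws"]);
  p.floor = as<double>(net["var_floor"]);
  return p;
}

// Forward pass: X is n x in, returns mean and variance, each n x d.
// [[Rcpp::export(name = ".gdn_forward_cpp")]]
List gdn_forward_cpp(const List& net, const arma::mat& X) {
  GdnParams p = unpack(net);
  arma::mat H1 = arma::tanh(X * p.W1 + arma::repmat(p.b1, X.n_rows, 1));
  arma::mat H2 = arma::tanh(H1 * p.W2 + arma::repmat(p.b2, X.n_rows, 1));
  arma::mat MU = H2 * p.Wm + X * p.Ws + arma::repmat(p.bm, X.n_rows, 1);
  arma::mat RAW = H2 * p.Wv + arma::repmat(p.bv, X.n_rows, 1);
  arma::mat V = softplus(RAW) + p.floor;
  return List::create(_["mean"] = MU, _["var"] = V);
}

// Forward pass plus forward-mode tangent: dX holds d(input)/d(scalar),
// outputs include d(mean)/d(scalar) and d(var)/d(scalar).
// [[Rcpp::export(name = ".gdn_jvp_cpp")]]
List gdn_jvp_cpp(const List& net, const arma::mat& X, const arma::mat& dX) {
  GdnParams p = unpack(net);
  arma::mat Z1 = X * p.W1 + arma::repmat(p.b1, X.n_rows, 1);
  arma::mat H1 = arma::tanh(Z1);
  arma::mat Z2 = H1 * p.W2 + arma::repmat(p.b2, X.n_rows, 1);
  arma::mat H2 = arma::tanh(Z2);
  arma::mat MU = H2 * p.Wm + X * p.Ws + arma::repmat(p.bm, X.n_rows, 1);
  arma::mat RAW = H2 * p.Wv + arma::repmat(p.bv, X.n_rows, 1);
  arma::mat V = softplus(RAW) + p.floor;

  arma::mat dH1 = (1.0 - arma::square(H1)) % (dX * p.W1);
  arma::mat dH2 = (1.0 - arma::square(H2)) % (dH1 * p.W2);
  arma::mat dMU = dH2 * p.Wm + dX * p.Ws;
  arma::mat dV = sigmoid(RAW) % (dH2 * p.Wv);
  return List::create(_["mean"] = MU, _["var"] = V,
                      _["dmean"] = dMU, _["dvar"] = dV);
}

// Negative log-likelihood of targets Y under the predicted diagonal
// Gaussian (mean over rows, summed over dimensions) and its gradient with
// respect to every network parameter.
// [[Rcpp::export(name = ".gdn_nll_grad_cpp")]]
List gdn_nll_grad_cpp(const List& net, const arma::mat& X, const arma::mat& Y) {
  GdnParams p = unpack(net);
  const double n = static_cast<double>(X.n_rows);
  arma::mat Z1 = X * p.W1 + arma::repmat(p.b1, X.n_rows, 1);
  arma::mat H1 = arma::tanh(Z1);
  arma::mat Z2 = H1 * p.W2 + arma::repmat(p.b2, X.n_rows, 1);
  arma::mat H2 = arma::tanh(Z2);
  arma::mat MU = H2 * p.Wm + X * p.Ws + arma::repmat(p.bm, X.n_rows, 1);
  arma::mat RAW = H2 * p.Wv + arma::repmat(p.bv, X.n_rows, 1);
  arma::mat V = softplus(RAW) + p.floor;

  arma::mat R = Y - MU;
  double loss = arma::accu(0.5 * arma::log(2.0 * M_PI * V) +
                           arma::square(R) / (2.0 * V)) / n;

  arma::mat dMU = (MU - Y) / V / n;
  arma::mat dV = 0.5 * (V - arma::square(R)) / arma::square(V) / n;
  arma::mat dRAW = dV % sigmoid(RAW);

  arma::mat dH2 = dMU * p.Wm.t() + dRAW * p.Wv.t();
  arma::mat dZ2 = dH2 % (1.0 - arma::square(H2));
  arma::mat dH1 = dZ2 * p.W2.t();
  arma::mat dZ1 = dH1 % (1.0 - arma::square(H1));

  return List::create(
    _["loss"] = loss,
    _["gW1"] = X.t() * dZ1, _["gb1"] = arma::sum(dZ1, 0),
    _["gW2"] = H1.t() * dZ2, _["gb2"] = arma::sum(dZ2, 0),
    _["gWm"] = H2.t() * dMU, _["gbm"] = arma::sum(dMU, 0),
    _["gWv"] = H2.t() * dRAW, _["gbv"] = arma::sum(dRAW, 0),
    _["gWs"] = X.t() * dMU);
}
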
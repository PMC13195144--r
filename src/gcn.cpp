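// Fixed-epoch Adam training loop of the featureless graph convolutional
// classifier. The R side prepares normalized adjacencies and initial
// parameters; dropout masks use R's RNG stream so training is a pure
// function of (data, params, config, seed).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Params {
  arma::mat W1, W2, W3;
  arma::vec b1, b2, b3, W4;
  double b4;
};

Params params_from_list(const List& p) {
  Params out;
  out.W1 = as<arma::mat>(p["W1"]);
  out.b1 = as<arma::vec>(p["b1"]);
  out.W2 = as<arma::mat>(p["W2"]);
  out.b2 = as<arma::vec>(p["b2"]);
  out.W3 = as<arma::mat>(p["W3"]);
  out.b3 = as<arma::vec>(p["b3"]);
  out.W4 = as<arma::vec>(p["W4"]);
  out.b4 = as<double>(p["b4"]);
  return out;
}

} // namespace

// [[Rcpp::export]]
List cpp_gcn_train(List ahat_list, NumericVector y_in, List init_params,
                   double lr, int epochs, double dropout, double l2) {
  const int S = ahat_list.size();
  std::vector<arma::mat> A(S);
  for (int s = 0; s < S; ++s) A[s] = as<arma::mat>(ahat_list[s]);
  arma::vec y = as<arma::vec>(y_in);

  Params p = params_from_list(init_params);
  const int n = p.W1.n_rows, c1 = p.W1.n_cols, c2 = p.W2.n_cols,
            m1 = p.W3.n_cols;
  for (int s = 0; s < S; ++s) {
    if ((int)A[s].n_rows != n) stop("graph %d has %d nodes, model expects %d",
                                    s + 1, (int)A[s].n_rows, n);
  }

  // Adam state
  Params m = p, v = p;
  auto zero = [](Params& q) {
    q.W1.zeros(); q.W2.zeros(); q.W3.zeros();
    q.b1.zeros(); q.b2.zeros(); q.b3.zeros(); q.W4.zeros(); q.b4 = 0;
  };
  zero(m); zero(v);

  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  const double keep = 1.0 - dropout;
  double final_loss = NA_REAL;

  std::vector<arma::mat> Z1(S), S2(S), Z2(S), Z2d(S), mask(S);
  arma::mat g(S, c2), H(S, m1);
  arma::vec z(S), prob(S);

  auto forward = [&](bool use_dropout) {
    for (int s = 0; s < S; ++s) {
      Z1[s] = arma::tanh(A[s] * p.W1 + arma::repmat(p.b1.t(), n, 1));
      S2[s] = A[s] * Z1[s];
      Z2[s] = arma::tanh(S2[s] * p.W2 + arma::repmat(p.b2.t(), n, 1));
      if (use_dropout && dropout > 0) {
        mask[s].set_size(n, c2);
        for (int jj = 0; jj < c2; ++jj)
          for (int ii = 0; ii < n; ++ii)
            mask[s](ii, jj) = (R::runif(0, 1) < keep) ? 1.0 / keep : 0.0;
        Z2d[s] = Z2[s] % mask[s];
      } else {
        mask[s].reset();
        Z2d[s] = Z2[s];
      }
      g.row(s) = arma::mean(Z2d[s], 0);
    }
    H = arma::tanh(g * p.W3 + arma::repmat(p.b3.t(), S, 1));
    z = H * p.W4 + p.b4;
    prob = 1.0 / (1.0 + arma::exp(-z));
  };

  int t = 0;
  auto adam_update = [&](arma::mat& par, arma::mat& mm, arma::mat& vv,
                         const arma::mat& gr) {
    mm = beta1 * mm + (1 - beta1) * gr;
    vv = beta2 * vv + (1 - beta2) * (gr % gr);
    par -= lr * (mm / (1 - std::pow(beta1, t))) /
           (arma::sqrt(vv / (1 - std::pow(beta2, t))) + eps);
  };
  auto adam_update_v = [&](arma::vec& par, arma::vec& mm, arma::vec& vv,
                           const arma::vec& gr) {
    mm = beta1 * mm + (1 - beta1) * gr;
    vv = beta2 * vv + (1 - beta2) * (gr % gr);
    par -= lr * (mm / (1 - std::pow(beta1, t))) /
           (arma::sqrt(vv / (1 - std::pow(beta2, t))) + eps);
  };

  for (int ep = 0; ep < epochs; ++ep) {
    forward(true);
    arma::vec dz = (prob - y) / S;
    arma::vec gW4 = H.t() * dz + 2 * l2 * p.W4;
    double gb4 = arma::accu(dz);
    arma::mat dH = dz * p.W4.t();
    arma::mat dPH = dH % (1 - H % H);
    arma::mat gW3 = g.t() * dPH + 2 * l2 * p.W3;
    arma::vec gb3 = arma::sum(dPH, 0).t();
    arma::mat dg = dPH * p.W3.t();           // S x c2
    arma::mat gW1(n, c1, arma::fill::zeros), gW2(c1, c2, arma::fill::zeros);
    arma::vec gb1(c1, arma::fill::zeros), gb2(c2, arma::fill::zeros);
    for (int s = 0; s < S; ++s) {
      arma::mat dZ2d = arma::repmat(dg.row(s) / n, n, 1);
      arma::mat dZ2 = mask[s].is_empty() ? dZ2d : dZ2d % mask[s];
      arma::mat dP2 = dZ2 % (1 - Z2[s] % Z2[s]);
      gW2 += S2[s].t() * dP2;
      gb2 += arma::sum(dP2, 0).t();
      arma::mat dS2 = dP2 * p.W2.t();
      arma::mat dP1 = (A[s] * dS2) % (1 - Z1[s] % Z1[s]);  // A symmetric
      gW1 += A[s] * dP1;
      gb1 += arma::sum(dP1, 0).t();
    }
    gW1 += 2 * l2 * p.W1;
    gW2 += 2 * l2 * p.W2;
    ++t;
    adam_update(p.W1, m.W1, v.W1, gW1);
    adam_update_v(p.b1, m.b1, v.b1, gb1);
    adam_update(p.W2, m.W2, v.W2, gW2);
    adam_update_v(p.b2, m.b2, v.b2, gb2);
    adam_update(p.W3, m.W3, v.W3, gW3);
    adam_update_v(p.b3, m.b3, v.b3, gb3);
    adam_update_v(p.W4, m.W4, v.W4, gW4);
    {
      m.b4 = beta1 * m.b4 + (1 - beta1) * gb4;
      v.b4 = beta2 * v.b4 + (1 - beta2) * gb4 * gb4;
      p.b4 -= lr * (m.b4 / (1 - std::pow(beta1, t))) /
              (std::sqrt(v.b4 / (1 - std::pow(beta2, t))) + eps);
    }
  }

  forward(false);
  const double tiny = 1e-12;
  final_loss = -arma::mean(y % arma::log(prob + tiny) +
                           (1 - y) % arma::log(1 - prob + tiny)) +
               l2 * (arma::accu(p.W1 % p.W1) + arma::accu(p.W2 % p.W2) +
                     arma::accu(p.W3 % p.W3) + arma::accu(p.W4 % p.W4));

  return List::create(
      _["params"] = List::create(
          _["W1"] = p.W1, _["b1"] = p.b1, _["W2"] = p.W2, _["b2"] = p.b2,
          _["W3"] = p.W3, _["b3"] = p.b3, _["W4"] = p.W4, _["b4"] = p.b4),
      _["final_loss"] = final_loss);
}
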
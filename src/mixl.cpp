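// Simulated likelihood kernel for the mixed multinomial logit with
// heterogeneity in the means and variances of the random coefficients.
//
// Parameter packing (must match param_names() on the R side):
//   for each alternative j (spec order): ncol(Xfix[j]) fixed coefficients;
//   then for each random entry e: mean, delta (q_e), sigma, omega (s_e).
//
// The per-observation simulated probability is the average over R draws of
// the logit kernel evaluated at the realized coefficients
//   b_e = mean_e + delta'Z + sigma_e * exp(omega'W) * v.
// The analytic score uses d log softmax and the chain rule through b_e.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// radical-inverse (van der Corput) sequence in a prime base
// [[Rcpp::export]]
NumericVector halton_radical_inverse(NumericVector idx, int base) {
  int n = idx.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double f = 1.0, r = 0.0;
    long long k = (long long) idx[i];
    while (k > 0) {
      f /= base;
      r += f * (k % base);
      k /= base;
    }
    out[i] = r;
  }
  return out;
}

// mode: 0 = log-likelihood; 1 = + gradient; 2 = + per-observation scores;
//       3 = simulated probability matrix (N x J) instead of ll/grad
// [[Rcpp::export]]
List mixl_eval_cpp(const arma::vec& theta, const IntegerVector& y,
                   const List& Xfix, const List& reAlt, const List& reX,
                   const List& reZ, const List& reW,
                   const arma::cube& draws, int mode) {
  const int J = Xfix.size();
  const int E = reX.size();
  int N = 0;
  std::vector<arma::mat> X(J);
  std::vector<int> poff(J + 1, 0);
  for (int j = 0; j < J; ++j) {
    X[j] = as<arma::mat>(Xfix[j]);
    poff[j + 1] = poff[j] + X[j].n_cols;
    N = X[j].n_rows;
  }
  const int Kfix = poff[J];
  // unpack random-entry parameters and precompute per-record pieces
  std::vector<int> alt(E), qe(E), se(E), roff(E + 1, Kfix);
  std::vector<arma::vec> xe(E), mshift(E), scale(E);
  std::vector<arma::mat> Z(E), W(E);
  std::vector<double> sigma(E);
  int i = Kfix;
  for (int e = 0; e < E; ++e) {
    alt[e] = as<int>(reAlt[e]) - 1;
    xe[e] = as<arma::vec>(reX[e]);
    Z[e] = as<arma::mat>(reZ[e]);
    W[e] = as<arma::mat>(reW[e]);
    qe[e] = Z[e].n_cols;
    se[e] = W[e].n_cols;
    double mean = theta[i];
    arma::vec delta = (qe[e] > 0) ? theta.subvec(i + 1, i + qe[e])
                                  : arma::vec();
    sigma[e] = theta[i + qe[e] + 1];
    arma::vec omega = (se[e] > 0) ? theta.subvec(i + qe[e] + 2,
                                                 i + qe[e] + 1 + se[e])
                                  : arma::vec();
    mshift[e] = arma::vec(N, arma::fill::value(mean));
    if (qe[e] > 0) mshift[e] += Z[e] * delta;
    scale[e] = arma::vec(N, arma::fill::ones);
    if (se[e] > 0) scale[e] = arma::exp(W[e] * omega);
    roff[e] = i;
    i += 2 + qe[e] + se[e];
  }
  const int K = i;
  if ((int) theta.n_elem != K) stop("theta length does not match design");
  const int R = (E > 0) ? draws.n_slices : 1;

  // fixed-part utilities
  arma::mat F(N, J, arma::fill::zeros);
  for (int j = 0; j < J; ++j) {
    if (X[j].n_cols > 0)
      F.col(j) = X[j] * theta.subvec(poff[j], poff[j + 1] - 1);
  }

  if (mode == 3) {
    arma::mat P(N, J, arma::fill::zeros);
    arma::vec u(J), p(J);
    for (int n = 0; n < N; ++n) {
      for (int d = 0; d < R; ++d) {
        for (int j = 0; j < J; ++j) u[j] = F(n, j);
        for (int e = 0; e < E; ++e) {
          double b = mshift[e][n] + sigma[e] * scale[e][n] * draws(n, e, d);
          u[alt[e]] += b * xe[e][n];
        }
        double m = u.max(), S = 0.0;
        for (int j = 0; j < J; ++j) { p[j] = std::exp(u[j] - m); S += p[j]; }
        for (int j = 0; j < J; ++j) P(n, j) += p[j] / S;
      }
    }
    P /= R;
    return List::create(_["prob"] = P);
  }

  double ll = 0.0;
  arma::vec grad(K, arma::fill::zeros);
  arma::mat scores;
  if (mode >= 2) scores.zeros(N, K);
  bool zero_prob = false;
  arma::vec u(J), p(J), commonJ(J), A(std::max(E, 1)), B(std::max(E, 1));

  for (int n = 0; n < N; ++n) {
    const int yn = y[n] - 1;
    double Psum = 0.0;
    commonJ.zeros();
    A.zeros(); B.zeros();
    for (int d = 0; d < R; ++d) {
      for (int j = 0; j < J; ++j) u[j] = F(n, j);
      for (int e = 0; e < E; ++e) {
        double b = mshift[e][n] + sigma[e] * scale[e][n] * draws(n, e, d);
        u[alt[e]] += b * xe[e][n];
      }
      double m = u.max(), S = 0.0;
      for (int j = 0; j < J; ++j) { p[j] = std::exp(u[j] - m); S += p[j]; }
      for (int j = 0; j < J; ++j) p[j] /= S;
      const double L = p[yn];
      Psum += L;
      if (mode >= 1) {
        for (int j = 0; j < J; ++j) {
          commonJ[j] += L * (((j == yn) ? 1.0 : 0.0) - p[j]);
        }
        for (int e = 0; e < E; ++e) {
          double ge = L * (((alt[e] == yn) ? 1.0 : 0.0) - p[alt[e]]) * xe[e][n];
          A[e] += ge;
          B[e] += ge * draws(n, e, d);
        }
      }
    }
    double P = Psum / R;
    if (P <= 0.0) { zero_prob = true; P = 1e-300; }
    ll += std::log(P);
    if (mode >= 1) {
      const double w = 1.0 / (R * P);
      for (int j = 0; j < J; ++j) {
        const double cj = w * commonJ[j];
        for (unsigned int c = 0; c < X[j].n_cols; ++c) {
          const double g = cj * X[j](n, c);
          grad[poff[j] + c] += g;
          if (mode >= 2) scores(n, poff[j] + c) = g;
        }
      }
      for (int e = 0; e < E; ++e) {
        const int o = roff[e];
        const double ga = w * A[e];
        const double gb = w * B[e];
        grad[o] += ga;
        if (mode >= 2) scores(n, o) = ga;
        for (int k = 0; k < qe[e]; ++k) {
          const double g = ga * Z[e](n, k);
          grad[o + 1 + k] += g;
          if (mode >= 2) scores(n, o + 1 + k) = g;
        }
        const double gs = gb * scale[e][n];
        grad[o + qe[e] + 1] += gs;
        if (mode >= 2) scores(n, o + qe[e] + 1) = gs;
        for (int k = 0; k < se[e]; ++k) {
          const double g = gs * sigma[e] * W[e](n, k);
          grad[o + qe[e] + 2 + k] += g;
          if (mode >= 2) scores(n, o + qe[e] + 2 + k) = g;
        }
      }
    }
  }
  List out = List::create(_["ll"] = ll, _["zero_prob"] = zero_prob);
  if (mode >= 1) out["grad"] = grad;
  if (mode >= 2) out["scores"] = scores;
  return out;
}
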
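#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Transition structure for one step: stay-probability on the diagonal and a
// common switch-probability off it. e = exp(-d/d0). The generalized
// row-stochastic form is stay = 1/K + (K-1)/K * e, switch = (1-e)/K; the
// "literal" form keeps the printed K = 4 coefficients (1/4 + 3/4 e,
// 1/4 - 1/4 e) and renormalizes the row for other K.
static inline void trans_params(double e, int K, bool literal,
                                double &stay, double &sw) {
  if (K == 1) { stay = 1.0; sw = 0.0; return; }
  if (!literal) {
    stay = 1.0 / K + (double)(K - 1) / K * e;
    sw   = (1.0 - e) / K;
  } else {
    double s0 = 0.25 + 0.75 * e;
    double w0 = 0.25 - 0.25 * e;
    double denom = s0 + (K - 1) * w0;
    stay = s0 / denom;
    sw   = w0 / denom;
  }
}

// Scaled forward-backward pass over one observation series.
//
// m, n   : methylated / total counts per site (n may be 0: emission == 1)
// gaps   : genomic distances between consecutive sites (length T-1)
// w      : per-site exponent applied to the emission log-likelihood
//          (training weight n_t + 2; pass all-1 for the plain likelihood)
//
// Emissions are shifted per site by their row maximum before exponentiation
// so that weighted emissions cannot underflow; the shift is absorbed into
// the returned log-likelihood exactly.
//
// Returns the (weighted) log-likelihood, posterior state probabilities
// gamma, the Baum-Welch sufficient statistics sm_k = sum_t gamma_tk w_t m_t,
// sn_k = sum_t gamma_tk w_t n_t, and gamma at the first site.
// [[Rcpp::export]]
List fb_pass_cpp(NumericVector m, NumericVector n, NumericVector gaps,
                 NumericVector betas, NumericVector pi, double d0,
                 NumericVector w, bool literal) {
  const int T = m.size();
  const int K = betas.size();
  NumericMatrix B(T, K);       // shifted emissions exp(w * logb - shift_t)
  NumericVector shift(T);
  for (int t = 0; t < T; ++t) {
    double mx = R_NegInf;
    for (int k = 0; k < K; ++k) {
      double lb = w[t] * R::dbinom(m[t], n[t], betas[k], 1);
      B(t, k) = lb;
      if (lb > mx) mx = lb;
    }
    shift[t] = mx;
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(B(t, k) - mx);
  }

  NumericMatrix alpha(T, K);
  NumericVector cvec(T);
  double loglik = 0.0;
  {
    double c = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); c += alpha(0, k); }
    if (c <= 0.0) stop("forward pass underflow at site 1");
    for (int k = 0; k < K; ++k) alpha(0, k) /= c;
    cvec[0] = c;
    loglik += std::log(c) + shift[0];
  }
  for (int t = 1; t < T; ++t) {
    double stay, sw;
    trans_params(std::exp(-gaps[t - 1] / d0), K, literal, stay, sw);
    double A = 0.0;
    for (int k = 0; k < K; ++k) A += alpha(t - 1, k);
    double c = 0.0;
    for (int k = 0; k < K; ++k) {
      double pred = sw * A + (stay - sw) * alpha(t - 1, k);
      alpha(t, k) = pred * B(t, k);
      c += alpha(t, k);
    }
    if (c <= 0.0) stop("forward pass underflow at site %d", t + 1);
    for (int k = 0; k < K; ++k) alpha(t, k) /= c;
    cvec[t] = c;
    loglik += std::log(c) + shift[t];
  }

  // backward, scaled by the forward normalizers
  NumericMatrix gamma(T, K);
  std::vector<double> bw(K, 1.0), bw_next(K);
  for (int k = 0; k < K; ++k) gamma(T - 1, k) = alpha(T - 1, k);
  for (int t = T - 2; t >= 0; --t) {
    double stay, sw;
    trans_params(std::exp(-gaps[t] / d0), K, literal, stay, sw);
    double S = 0.0;
    std::vector<double> u(K);
    for (int k = 0; k < K; ++k) { u[k] = B(t + 1, k) * bw[k]; S += u[k]; }
    for (int k = 0; k < K; ++k)
      bw_next[k] = (sw * S + (stay - sw) * u[k]) / cvec[t + 1];
    bw = bw_next;
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * bw[k]; g += gamma(t, k); }
    if (g > 0.0) for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  NumericVector sm(K), sn(K), g1(K);
  for (int k = 0; k < K; ++k) g1[k] = gamma(0, k);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      sm[k] += gamma(t, k) * w[t] * m[t];
      sn[k] += gamma(t, k) * w[t] * n[t];
    }

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["sm"] = sm, _["sn"] = sn, _["g1"] = g1);
}

// Viterbi decoding (plain, unweighted emissions) in log space.
// Returns the 1-based maximum-probability state path and its log probability.
// [[Rcpp::export]]
List viterbi_cpp(NumericVector m, NumericVector n, NumericVector gaps,
                 NumericVector betas, NumericVector pi, double d0,
                 bool literal) {
  const int T = m.size();
  const int K = betas.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k)
    delta(0, k) = std::log(pi[k]) + R::dbinom(m[0], n[0], betas[k], 1);
  for (int t = 1; t < T; ++t) {
    double stay, sw;
    trans_params(std::exp(-gaps[t - 1] / d0), K, literal, stay, sw);
    double lstay = std::log(stay);
    double lsw = (sw > 0.0) ? std::log(sw) : R_NegInf;
    for (int j = 0; j < K; ++j) {
      double best = R_NegInf; int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = delta(t - 1, i) + (i == j ? lstay : lsw);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + R::dbinom(m[t], n[t], betas[j], 1);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return List::create(_["path"] = path, _["logp"] = best);
}
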
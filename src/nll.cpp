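// Per-trial likelihood replay for the UCB+S choice-model family.
//
// Replays a participant's trial log: within each session the GP posterior is
// conditioned on that participant's own past choices and (scaled) rewards,
// option values are m + beta*s + gamma*k(., partner), and the chosen option's
// log softmax probability is accumulated. Sessions are independent (beliefs
// reset at session boundaries).
//
// The Cholesky factor of the Gram matrix grows by one row per observation
// (incremental update), so the whole replay is O(T^2 * n) per session rather
// than refactorizing per trial; the result is bit-for-bit the standard exact
// GP-regression posterior. The kernel matrix is built once per call from a
// lookup table over the distinct integer squared distances of the grid.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// session: per-trial session labels (constant within a block), choice:
// 0-based option indices, reward: scaled rewards, partner: 0-based partner
// cue or -1 when absent. d2: integer-valued squared-distance matrix.
// Returns the log probability of the chosen option at every trial.
// [[Rcpp::export]]
NumericVector cpp_trial_logprobs(IntegerVector session, IntegerVector choice,
                                 NumericVector reward, IntegerVector partner,
                                 NumericMatrix d2, double lambda_hat,
                                 double beta, double gamma, double tau,
                                 bool use_uncertainty, bool use_social,
                                 double noise_var) {
  const int n = d2.nrow();
  const int T = session.size();
  if (lambda_hat <= 0 || tau <= 0 || noise_var <= 0)
    stop("lambda_hat, tau and noise_var must be positive");

  // kernel via lookup over the (few) distinct integer squared distances
  int maxd2 = 0;
  for (int i = 0; i < n * n; ++i)
    if (d2[i] > maxd2) maxd2 = (int)d2[i];
  arma::vec tab(maxd2 + 1);
  for (int v = 0; v <= maxd2; ++v) tab[v] = std::exp(-v / lambda_hat);
  arma::mat K(n, n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      K(i, j) = tab[(int)d2(i, j)];

  NumericVector logp(T);
  arma::mat L(T, T, arma::fill::zeros);  // growing Cholesky factor
  arma::mat W(n, T);                     // column k = L^-1-whitened k(., x_k)
  arma::vec z(T);                        // L^-1 y
  arma::vec m(n), q(n), vvec(n), l(T), b(T);
  std::vector<int> obs(T);

  int t = 0;
  while (t < T) {
    const int sess = session[t];
    int k = 0;  // observations so far this session
    m.zeros();
    q.zeros();
    while (t < T && session[t] == sess) {
      const int c = choice[t];
      if (c < 0 || c >= n) stop("choice index out of range");

      // option values from the current posterior (prior when k == 0)
      if (use_uncertainty) {
        for (int i = 0; i < n; ++i) {
          double s2 = 1.0 - q[i];
          vvec[i] = m[i] + beta * (s2 > 0 ? std::sqrt(s2) : 0.0);
        }
      } else {
        vvec = m;
      }
      if (use_social && partner[t] >= 0) vvec += gamma * K.col(partner[t]);
      vvec /= tau;
      const double zmax = vvec.max();
      logp[t] = vvec[c] - (zmax + std::log(arma::sum(arma::exp(vvec - zmax))));

      // grow the factorization with observation (x_c, y_t)
      for (int i = 0; i < k; ++i) b[i] = K(obs[i], c);
      for (int i = 0; i < k; ++i) {       // forward substitution l = L^-1 b
        double acc = b[i];
        for (int j = 0; j < i; ++j) acc -= L(i, j) * l[j];
        l[i] = acc / L(i, i);
      }
      double dsq = 1.0 + noise_var;
      for (int i = 0; i < k; ++i) dsq -= l[i] * l[i];
      const double d = std::sqrt(dsq > noise_var * 1e-12 ? dsq : noise_var * 1e-12);
      double zk = reward[t];
      for (int i = 0; i < k; ++i) zk -= l[i] * z[i];
      zk /= d;
      // w_k = (k(., x_c) - W[, 1:k] l) / d ; then m += z_k w_k, q += w_k^2
      double* wk = W.colptr(k);
      const double* kc = K.colptr(c);
      std::copy(kc, kc + n, wk);
      for (int j = 0; j < k; ++j) {
        const double lj = l[j];
        if (lj != 0.0) {
          const double* wj = W.colptr(j);
          for (int i = 0; i < n; ++i) wk[i] -= lj * wj[i];
        }
      }
      for (int i = 0; i < n; ++i) {
        wk[i] /= d;
        m[i] += zk * wk[i];
        q[i] += wk[i] * wk[i];
      }
      for (int i = 0; i < k; ++i) L(k, i) = l[i];
      L(k, k) = d;
      z[k] = zk;
      obs[k] = c;
      ++k;
      ++t;
    }
  }
  return logp;
}
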
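#ifndef ENDONER_CRF_CORE_H
#define ENDONER_CRF_CORE_H

#include <RcppArmadillo.h>

// Linear-chain CRF primitives shared by the standalone wrappers and the
// tagger training loop. Scores are unnormalized log-potentials; all sums run
// in log space. Masked transitions use a large negative constant instead of
// -Inf so that (a - b) never produces NaN.

static const double CRF_NEG_INF = -1e30;

inline double logsumexp_vec(const arma::vec &v) {
  double m = v.max();
  if (m <= CRF_NEG_INF / 2) return CRF_NEG_INF;
  return m + std::log(arma::accu(arma::exp(v - m)));
}

// Forward recursion; fills alpha (T x K) and returns log Z.
inline double crf_forward_alpha(const arma::mat &em, const arma::mat &trans,
                                const arma::vec &start, const arma::vec &stop,
                                arma::mat &alpha) {
  const arma::uword T = em.n_rows, K = em.n_cols;
  alpha.set_size(T, K);
  alpha.row(0) = start.t() + em.row(0);
  for (arma::uword t = 1; t < T; ++t) {
    arma::vec prev = alpha.row(t - 1).t();
    for (arma::uword j = 0; j < K; ++j)
      alpha(t, j) = logsumexp_vec(prev + trans.col(j)) + em(t, j);
  }
  return logsumexp_vec(alpha.row(T - 1).t() + stop);
}

inline double crf_log_partition_core(const arma::mat &em, const arma::mat &trans,
                                     const arma::vec &start, const arma::vec &stop) {
  arma::mat alpha;
  return crf_forward_alpha(em, trans, start, stop, alpha);
}

// Score of one tag path (0-based indices).
inline double crf_path_score_core(const arma::mat &em, const arma::ivec &path,
                                  const arma::mat &trans, const arma::vec &start,
                                  const arma::vec &stop) {
  const arma::uword T = em.n_rows;
  double s = start(path(0)) + em(0, path(0));
  for (arma::uword t = 1; t < T; ++t)
    s += trans(path(t - 1), path(t)) + em(t, path(t));
  s += stop(path(T - 1));
  return s;
}

// Forward-backward posteriors. Fills node marginals (T x K) and the expected
// transition counts (K x K); returns log Z. Used for the NLL gradient:
// d logZ / d emissions = node marginals, d logZ / d trans = edge expectations,
// d logZ / d start = marginals at t=0, d logZ / d stop = marginals at t=T-1.
inline double crf_posteriors(const arma::mat &em, const arma::mat &trans,
                             const arma::vec &start, const arma::vec &stop,
                             arma::mat &node_marg, arma::mat &edge_expect) {
  const arma::uword T = em.n_rows, K = em.n_cols;
  arma::mat alpha, beta(T, K);
  double logZ = crf_forward_alpha(em, trans, start, stop, alpha);
  beta.row(T - 1) = stop.t();
  for (arma::uword t = T - 1; t >= 1; --t) {
    arma::vec nxt = em.row(t).t() + beta.row(t).t();
    for (arma::uword i = 0; i < K; ++i)
      beta(t - 1, i) = logsumexp_vec(trans.row(i).t() + nxt);
  }
  node_marg = arma::exp(alpha + beta - logZ);
  edge_expect.zeros(K, K);
  for (arma::uword t = 1; t < T; ++t) {
    arma::vec a = alpha.row(t - 1).t();
    arma::vec b = em.row(t).t() + beta.row(t).t();
    edge_expect += arma::exp((a * arma::ones<arma::rowvec>(K)) + trans +
                             (arma::ones<arma::vec>(K) * b.t()) - logZ);
  }
  return logZ;
}

// Viterbi decoding with optional structural masks. `allowed` (K x K) and
// `allowed_start` (K) contain 0/1; pass null pointers for unconstrained
// decoding. Ties broken toward the lowest tag index (strict > comparison).
// Returns the best path score; fills `path` with 0-based tag indices.
inline double crf_viterbi_core(const arma::mat &em, const arma::mat &trans,
                               const arma::vec &start, const arma::vec &stop,
                               const arma::imat *allowed,
                               const arma::ivec *allowed_start,
                               arma::ivec &path) {
  const arma::uword T = em.n_rows, K = em.n_cols;
  arma::mat delta(T, K);
  arma::imat back(T, K, arma::fill::zeros);
  for (arma::uword j = 0; j < K; ++j) {
    bool ok = !allowed_start || (*allowed_start)(j) != 0;
    delta(0, j) = ok ? start(j) + em(0, j) : CRF_NEG_INF;
  }
  for (arma::uword t = 1; t < T; ++t) {
    for (arma::uword j = 0; j < K; ++j) {
      double best = -arma::datum::inf;
      arma::uword arg = 0;
      for (arma::uword i = 0; i < K; ++i) {
        bool ok = !allowed || (*allowed)(i, j) != 0;
        double v = delta(t - 1, i) + (ok ? trans(i, j) : CRF_NEG_INF);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + em(t, j);
      back(t, j) = static_cast<int>(arg);
    }
  }
  double best = -arma::datum::inf;
  arma::uword arg = 0;
  for (arma::uword j = 0; j < K; ++j) {
    double v = delta(T - 1, j) + stop(j);
    if (v > best) { best = v; arg = j; }
  }
  if (best <= CRF_NEG_INF / 2)
    Rcpp::stop("infeasible decode: no tag sequence permitted by the mask");
  path.set_size(T);
  path(T - 1) = static_cast<int>(arg);
  for (arma::uword t = T - 1; t >= 1; --t)
    path(t - 1) = back(t, path(t));
  return best;
}

#endif
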
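// [[Rcpp::depends(RcppArmadillo)]]
#include "crf_core.h"

using namespace Rcpp;

// Standalone linear-chain CRF entry points. Emissions are a T x K matrix of
// unnormalized per-token tag scores over the non-PAD tag set; `trans` is the
// K x K tag-to-tag score matrix; `start`/`stop` score opening/closing tags.

// [[Rcpp::export]]
double cpp_crf_log_partition(const arma::mat &emissions, const arma::mat &trans,
                             const arma::vec &start, const arma::vec &stop) {
  if (emissions.n_rows == 0)
    Rcpp::stop("emissions must contain at least one token");
  return crf_log_partition_core(emissions, trans, start, stop);
}

// [[Rcpp::export]]
double cpp_crf_path_score(const arma::mat &emissions, const arma::ivec &path,
                          const arma::mat &trans, const arma::vec &start,
                          const arma::vec &stop) {
  if (path.n_elem != emissions.n_rows)
    Rcpp::stop("path length must match emissions rows");
  return crf_path_score_core(emissions, path, trans, start, stop);
}

// [[Rcpp::export]]
double cpp_crf_nll(const arma::mat &emissions, const arma::ivec &path,
                   const arma::mat &trans, const arma::vec &start,
                   const arma::vec &stop) {
  if (path.n_elem != emissions.n_rows)
    Rcpp::stop("path length must match emissions rows");
  return crf_log_partition_core(emissions, trans, start, stop) -
         crf_path_score_core(emissions, path, trans, start, stop);
}

// [[Rcpp::export]]
List cpp_crf_viterbi(const arma::mat &emissions, const arma::mat &trans,
                     const arma::vec &start, const arma::vec &stop,
                     Nullable<IntegerMatrix> allowed = R_NilValue,
                     Nullable<IntegerVector> allowed_start = R_NilValue) {
  if (emissions.n_rows == 0)
    Rcpp::stop("emissions must contain at least one token");
  arma::imat am;
  arma::ivec asv;
  const arma::imat *ap = nullptr;
  const arma::ivec *asp = nullptr;
  if (allowed.isNotNull()) {
    am = as<arma::imat>(allowed.get());
    ap = &am;
  }
  if (allowed_start.isNotNull()) {
    asv = as<arma::ivec>(allowed_start.get());
    asp = &asv;
  }
  arma::ivec path;
  double score = crf_viterbi_core(emissions, trans, start, stop, ap, asp, path);
  return List::create(_["path"] = IntegerVector(path.begin(), path.end()),
                      _["score"] = score);
}
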
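// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;

// Continuous bag-of-words word2vec with negative sampling, single-threaded
// and fully deterministic for a given seed. Context vectors are averaged
// over a per-position dynamic window (the classic word2vec schedule); the
// negative-sampling distribution is the unigram distribution raised to 3/4.
// The learning rate decays linearly over the total number of training words.

// [[Rcpp::export]]
arma::mat cpp_train_cbow(List sentences, int vocab_size, int dim, int window,
                         int negative, int epochs, double alpha,
                         NumericVector counts, int seed) {
  const int n = sentences.size();
  std::vector<std::vector<int>> sents(n);
  long long total_words = 0;
  for (int i = 0; i < n; ++i) {
    IntegerVector v = sentences[i];
    sents[i].assign(v.begin(), v.end());
    total_words += v.size();
  }
  if (total_words == 0) stop("empty corpus");
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> U01(0.0, 1.0);

  arma::mat syn0(vocab_size, dim), syn1(vocab_size, dim, arma::fill::zeros);
  for (int j = 0; j < dim; ++j)
    for (int i = 0; i < vocab_size; ++i)
      syn0(i, j) = (U01(rng) - 0.5) / dim;

  // cumulative table for negative sampling: P(w) proportional to count^0.75
  arma::vec cum(vocab_size);
  double acc = 0.0;
  for (int i = 0; i < vocab_size; ++i) {
    acc += std::pow(std::max(counts[i], 0.0), 0.75);
    cum(i) = acc;
  }
  if (acc <= 0) stop("all word counts are zero");
  auto sample_word = [&]() {
    double r = U01(rng) * acc;
    int lo = 0, hi = vocab_size - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum(mid) < r) lo = mid + 1; else hi = mid;
    }
    return lo;
  };

  const long long train_total = total_words * (long long)epochs;
  long long seen = 0;
  arma::rowvec neu1(dim), neu1e(dim);
  for (int e = 0; e < epochs; ++e) {
    for (int si = 0; si < n; ++si) {
      const std::vector<int> &s = sents[si];
      const int L = (int)s.size();
      for (int pos = 0; pos < L; ++pos) {
        double lr = alpha * (1.0 - (double)seen / (double)(train_total + 1));
        if (lr < alpha * 1e-4) lr = alpha * 1e-4;
        ++seen;
        int b = (int)(U01(rng) * window); // dynamic window shrink
        int lo = std::max(0, pos - window + b);
        int hi = std::min(L - 1, pos + window - b);
        int cw = 0;
        neu1.zeros();
        for (int j = lo; j <= hi; ++j) {
          if (j == pos) continue;
          neu1 += syn0.row(s[j]);
          ++cw;
        }
        if (cw == 0) continue;
        neu1 /= (double)cw;
        neu1e.zeros();
        for (int d = 0; d <= negative; ++d) {
          int target;
          double label;
          if (d == 0) {
            target = s[pos];
            label = 1.0;
          } else {
            target = sample_word();
            if (target == s[pos]) continue;
            label = 0.0;
          }
          double f = arma::dot(neu1, syn1.row(target));
          double g = (label - 1.0 / (1.0 + std::exp(-f))) * lr;
          neu1e += g * syn1.row(target);
          syn1.row(target) += g * neu1;
        }
        for (int j = lo; j <= hi; ++j) {
          if (j == pos) continue;
          syn0.row(s[j]) += neu1e;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return syn0;
}
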
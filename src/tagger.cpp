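// [[Rcpp::depends(RcppArmadillo)]]
#include "crf_core.h"
#include <random>

using namespace Rcpp;

// Bi-LSTM(-CRF) sequence tagger: batched LSTM forward/backward (BPTT), a
// linear projection to per-tag emission scores, and either a linear-chain
// CRF negative log-likelihood or a token-wise softmax loss. Sentences are
// bucketed by length into mini-batches; within a batch, shorter sentences
// carry trailing padding whose emission gradients are zeroed, and the
// reverse-direction LSTM runs on per-sentence reversed token streams so
// padding never precedes real tokens in either direction.

static inline arma::mat sigmoid_m(const arma::mat &x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

struct LstmCache {
  std::vector<arma::mat> G; // B x 4H activated gates (i,f,g,o)
  std::vector<arma::mat> C; // B x H cell states
  std::vector<arma::mat> H; // B x H hidden states
};

static void lstm_forward(const arma::mat &Wx, const arma::mat &Wh,
                         const arma::mat &b, const std::vector<arma::mat> &X,
                         LstmCache &cache) {
  const int T = static_cast<int>(X.size());
  const arma::uword B = X[0].n_rows, H = Wh.n_rows;
  cache.G.resize(T);
  cache.C.resize(T);
  cache.H.resize(T);
  arma::mat hprev(B, H, arma::fill::zeros), cprev(B, H, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    arma::mat A = X[t] * Wx + hprev * Wh;
    A.each_row() += b.row(0);
    arma::mat i = sigmoid_m(A.cols(0, H - 1));
    arma::mat f = sigmoid_m(A.cols(H, 2 * H - 1));
    arma::mat g = arma::tanh(A.cols(2 * H, 3 * H - 1));
    arma::mat o = sigmoid_m(A.cols(3 * H, 4 * H - 1));
    cache.G[t] = arma::join_rows(arma::join_rows(i, f), arma::join_rows(g, o));
    cache.C[t] = f % cprev + i % g;
    cache.H[t] = o % arma::tanh(cache.C[t]);
    hprev = cache.H[t];
    cprev = cache.C[t];
  }
}

static void lstm_backward(const arma::mat &Wx, const arma::mat &Wh,
                          const std::vector<arma::mat> &X,
                          const LstmCache &cache,
                          const std::vector<arma::mat> &dH,
                          arma::mat &dWx, arma::mat &dWh, arma::mat &db,
                          std::vector<arma::mat> *dX) {
  const int T = static_cast<int>(X.size());
  const arma::uword B = X[0].n_rows, H = Wh.n_rows;
  arma::mat dh_next(B, H, arma::fill::zeros), dc_next(B, H, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    arma::mat i = cache.G[t].cols(0, H - 1);
    arma::mat f = cache.G[t].cols(H, 2 * H - 1);
    arma::mat g = cache.G[t].cols(2 * H, 3 * H - 1);
    arma::mat o = cache.G[t].cols(3 * H, 4 * H - 1);
    arma::mat tc = arma::tanh(cache.C[t]);
    arma::mat dh = dH[t] + dh_next;
    arma::mat do_ = dh % tc;
    arma::mat dc = dc_next + dh % o % (1.0 - tc % tc);
    arma::mat cprev =
        t > 0 ? cache.C[t - 1] : arma::mat(B, H, arma::fill::zeros);
    arma::mat di = dc % g, df = dc % cprev, dg = dc % i;
    dc_next = dc % f;
    arma::mat dA = arma::join_rows(
        arma::join_rows(di % i % (1.0 - i), df % f % (1.0 - f)),
        arma::join_rows(dg % (1.0 - g % g), do_ % o % (1.0 - o)));
    dWx += X[t].t() * dA;
    arma::mat hprev =
        t > 0 ? cache.H[t - 1] : arma::mat(B, H, arma::fill::zeros);
    dWh += hprev.t() * dA;
    db.row(0) += arma::sum(dA, 0);
    if (dX) (*dX)[t] = dA * Wx.t();
    dh_next = dA * Wh.t();
  }
}

// ---- parameter bundle ------------------------------------------------------

enum Arch { ARCH_LSTM, ARCH_BILSTM, ARCH_BILSTM_CRF };

static Arch parse_arch(const std::string &a) {
  if (a == "lstm") return ARCH_LSTM;
  if (a == "bilstm") return ARCH_BILSTM;
  if (a == "bilstm-crf") return ARCH_BILSTM_CRF;
  stop("unknown architecture: " + a);
}

struct Params {
  std::vector<arma::mat> p; // Emb, Wxf, Whf, bf, Wxb, Whb, bb, Wo, bo, trans, start, stop
  int H, K, D, V;
  Arch arch;
};

static const char *PARAM_NAMES[12] = {"emb",  "wx_f", "wh_f",  "b_f",
                                      "wx_b", "wh_b", "b_b",   "wo",
                                      "bo",   "trans", "start", "stop"};

static arma::mat glorot(arma::uword r, arma::uword c, std::mt19937 &rng) {
  double lim = std::sqrt(6.0 / (double)(r + c));
  std::uniform_real_distribution<double> U(-lim, lim);
  arma::mat m(r, c);
  for (arma::uword j = 0; j < c; ++j)
    for (arma::uword i = 0; i < r; ++i) m(i, j) = U(rng);
  return m;
}

static Params init_params(const arma::mat &emb_init, int hidden, int K,
                          Arch arch, std::mt19937 &rng) {
  Params P;
  P.arch = arch;
  P.H = hidden;
  P.K = K;
  P.D = emb_init.n_cols;
  P.V = emb_init.n_rows;
  int F = (arch == ARCH_LSTM) ? hidden : 2 * hidden;
  P.p.resize(12);
  P.p[0] = emb_init;
  P.p[1] = glorot(P.D, 4 * hidden, rng);
  P.p[2] = glorot(hidden, 4 * hidden, rng);
  P.p[3] = arma::mat(1, 4 * hidden, arma::fill::zeros);
  P.p[3].cols(hidden, 2 * hidden - 1).fill(1.0); // forget-gate bias
  P.p[4] = glorot(P.D, 4 * hidden, rng);
  P.p[5] = glorot(hidden, 4 * hidden, rng);
  P.p[6] = arma::mat(1, 4 * hidden, arma::fill::zeros);
  P.p[6].cols(hidden, 2 * hidden - 1).fill(1.0);
  P.p[7] = glorot(F, K, rng);
  P.p[8] = arma::mat(1, K, arma::fill::zeros);
  P.p[9] = arma::mat(K, K, arma::fill::zeros);
  P.p[10] = arma::mat(K, 1, arma::fill::zeros);
  P.p[11] = arma::mat(K, 1, arma::fill::zeros);
  return P;
}

// ---- optimizers ------------------------------------------------------------

struct Optimizer {
  std::string kind;
  double lr;
  std::vector<arma::mat> m1, m2;
  long step = 0;
  void init(const std::vector<arma::mat> &p) {
    m1.resize(p.size());
    m2.resize(p.size());
    for (size_t i = 0; i < p.size(); ++i) {
      m1[i].zeros(p[i].n_rows, p[i].n_cols);
      m2[i].zeros(p[i].n_rows, p[i].n_cols);
    }
  }
  void update(std::vector<arma::mat> &p, const std::vector<arma::mat> &g,
              const std::vector<bool> &active) {
    const double eps = 1e-8;
    ++step;
    if (kind == "rmsprop") {
      const double rho = 0.9;
      for (size_t i = 0; i < p.size(); ++i) {
        if (!active[i]) continue;
        m2[i] = rho * m2[i] + (1.0 - rho) * (g[i] % g[i]);
        p[i] -= lr * g[i] / (arma::sqrt(m2[i]) + eps);
      }
    } else if (kind == "adam" || kind == "nadam") {
      const double b1 = 0.9, b2 = 0.999;
      double c1 = 1.0 - std::pow(b1, (double)step);
      double c2 = 1.0 - std::pow(b2, (double)step);
      for (size_t i = 0; i < p.size(); ++i) {
        if (!active[i]) continue;
        m1[i] = b1 * m1[i] + (1.0 - b1) * g[i];
        m2[i] = b2 * m2[i] + (1.0 - b2) * (g[i] % g[i]);
        arma::mat vhat = m2[i] / c2;
        if (kind == "adam") {
          p[i] -= lr * (m1[i] / c1) / (arma::sqrt(vhat) + eps);
        } else { // nadam: Nesterov lookahead on the first moment
          arma::mat mbar = b1 * (m1[i] / c1) + (1.0 - b1) * g[i] / c1;
          p[i] -= lr * mbar / (arma::sqrt(vhat) + eps);
        }
      }
    } else {
      stop("unknown optimizer: " + kind);
    }
  }
};

// ---- batching --------------------------------------------------------------

struct Batch {
  std::vector<int> sent;
  int Tmax;
};

static std::vector<Batch> make_batches(const std::vector<arma::ivec> &words,
                                       int batch_size) {
  std::vector<int> order(words.size());
  for (size_t i = 0; i < words.size(); ++i) order[i] = (int)i;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    return words[a].n_elem < words[b].n_elem;
  });
  std::vector<Batch> batches;
  for (size_t k = 0; k < order.size(); k += batch_size) {
    Batch b;
    int tmax = 0;
    for (size_t j = k; j < std::min(order.size(), k + batch_size); ++j) {
      b.sent.push_back(order[j]);
      tmax = std::max(tmax, (int)words[order[j]].n_elem);
    }
    b.Tmax = tmax;
    batches.push_back(b);
  }
  return batches;
}

// Gather embedding inputs for a batch; direction dir = +1 (forward order) or
// -1 (each sentence reversed within its own length, padding trailing).
static void gather_inputs(const Params &P, const std::vector<arma::ivec> &words,
                          const Batch &b, int dir, std::vector<arma::mat> &X,
                          arma::umat *idx_out) {
  const int B = (int)b.sent.size(), T = b.Tmax;
  X.assign(T, arma::mat());
  arma::umat idx(B, T, arma::fill::zeros); // 0 = PAD row of the embedding
  for (int s = 0; s < B; ++s) {
    const arma::ivec &w = words[b.sent[s]];
    const int L = (int)w.n_elem;
    for (int t = 0; t < L; ++t) {
      int src = dir > 0 ? t : L - 1 - t;
      idx(s, t) = (arma::uword)w(src);
    }
  }
  for (int t = 0; t < T; ++t) X[t] = P.p[0].rows(idx.col(t));
  if (idx_out) *idx_out = idx;
}

// ---- loss at the emission level -------------------------------------------

enum LossKind { LOSS_CRF, LOSS_CCE, LOSS_KL, LOSS_POISSON };

static LossKind parse_loss(Arch arch, const std::string &loss) {
  if (arch == ARCH_BILSTM_CRF) return LOSS_CRF;
  if (loss == "cce") return LOSS_CCE;
  if (loss == "kl") return LOSS_KL;
  if (loss == "poisson") return LOSS_POISSON;
  stop("unknown loss: " + loss);
}

// Token-wise softmax losses for the no-CRF variants. Targets are one-hot, so
// KL divergence reduces to cross-entropy; the Poisson loss treats the
// softmax outputs as predicted rates. Returns summed loss; fills dZ.
static double softmax_loss(const arma::mat &em, const arma::ivec &gold,
                           LossKind kind, arma::mat &dZ) {
  const arma::uword T = em.n_rows, K = em.n_cols;
  arma::mat p(T, K);
  for (arma::uword t = 0; t < T; ++t) {
    arma::rowvec z = em.row(t) - em.row(t).max();
    arma::rowvec e = arma::exp(z);
    p.row(t) = e / arma::accu(e);
  }
  double loss = 0.0;
  dZ.set_size(T, K);
  for (arma::uword t = 0; t < T; ++t) {
    arma::rowvec y(K, arma::fill::zeros);
    y((arma::uword)gold(t)) = 1.0;
    if (kind == LOSS_CCE || kind == LOSS_KL) {
      loss += -std::log(std::max(p(t, (arma::uword)gold(t)), 1e-300));
      dZ.row(t) = p.row(t) - y;
    } else { // Poisson
      arma::rowvec pr = arma::clamp(p.row(t), 1e-12, 1.0);
      loss += arma::accu(pr - y % arma::log(pr));
      arma::rowvec dldp = 1.0 - y / pr;
      dZ.row(t) = pr % (dldp - arma::accu(pr % dldp));
    }
  }
  return loss;
}

// ---- shared forward pass ---------------------------------------------------

struct BatchForward {
  std::vector<arma::mat> Xf, Xb;
  arma::umat idx_f, idx_b;
  LstmCache cf, cb;
  arma::mat Feat;                       // N x F, real tokens only
  std::vector<std::pair<int, int>> pos; // (sentence-in-batch, t) per Feat row
  arma::mat Em;                         // N x K emissions
};

static void batch_forward(const Params &P, const std::vector<arma::ivec> &words,
                          const Batch &b, BatchForward &F) {
  const int B = (int)b.sent.size();
  const bool bidir = P.arch != ARCH_LSTM;
  gather_inputs(P, words, b, +1, F.Xf, &F.idx_f);
  lstm_forward(P.p[1], P.p[2], P.p[3], F.Xf, F.cf);
  if (bidir) {
    gather_inputs(P, words, b, -1, F.Xb, &F.idx_b);
    lstm_forward(P.p[4], P.p[5], P.p[6], F.Xb, F.cb);
  }
  int N = 0;
  for (int s = 0; s < B; ++s) N += (int)words[b.sent[s]].n_elem;
  const int H = P.H, Fdim = bidir ? 2 * H : H;
  F.Feat.set_size(N, Fdim);
  F.pos.clear();
  F.pos.reserve(N);
  int r = 0;
  for (int s = 0; s < B; ++s) {
    const int L = (int)words[b.sent[s]].n_elem;
    for (int t = 0; t < L; ++t) {
      F.Feat.submat(r, 0, r, H - 1) = F.cf.H[t].row(s);
      if (bidir)
        F.Feat.submat(r, H, r, 2 * H - 1) = F.cb.H[L - 1 - t].row(s);
      F.pos.emplace_back(s, t);
      ++r;
    }
  }
  F.Em = F.Feat * P.p[7];
  F.Em.each_row() += P.p[8].row(0);
}

// ---- training entry point --------------------------------------------------

// [[Rcpp::export]]
List cpp_train_tagger(List sentences, List tags, const arma::mat &emb_init,
                      int hidden, int n_tags, std::string arch_s,
                      std::string loss_s, std::string optimizer, double lr,
                      int epochs, int batch_size, bool train_embedding,
                      int seed, double clip) {
  const int n = sentences.size();
  if (n == 0) stop("training set is empty");
  if (tags.size() != n) stop("sentences and tags must align");
  std::vector<arma::ivec> words(n), gold(n);
  for (int i = 0; i < n; ++i) {
    words[i] = as<arma::ivec>(sentences[i]);
    gold[i] = as<arma::ivec>(tags[i]);
    if (words[i].n_elem == 0) stop("empty sentence in training set");
    if (words[i].n_elem != gold[i].n_elem)
      stop("token/tag length mismatch in sentence " + std::to_string(i + 1));
  }
  Arch arch = parse_arch(arch_s);
  LossKind lk = parse_loss(arch, loss_s);
  std::mt19937 rng((unsigned)seed);

  const int K = n_tags;
  for (int i = 0; i < n; ++i)
    if ((int)gold[i].max() >= K || (int)gold[i].min() < 0)
      stop("tag index outside the schema tag set in sentence " +
           std::to_string(i + 1));
  Params P = init_params(emb_init, hidden, K, arch, rng);

  Optimizer opt;
  opt.kind = optimizer;
  opt.lr = lr;
  opt.init(P.p);
  std::vector<bool> active(12, true);
  active[0] = train_embedding;
  if (arch == ARCH_LSTM) active[4] = active[5] = active[6] = false;
  if (arch != ARCH_BILSTM_CRF) active[9] = active[10] = active[11] = false;

  std::vector<Batch> batches = make_batches(words, batch_size);
  const bool bidir = arch != ARCH_LSTM;
  NumericVector epoch_loss(epochs);

  std::vector<arma::mat> G(12);
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(batches.begin(), batches.end(), rng);
    double total = 0.0;
    long ntok = 0;
    for (const Batch &b : batches) {
      const int B = (int)b.sent.size();
      BatchForward F;
      batch_forward(P, words, b, F);
      for (int i = 0; i < 12; ++i) G[i].zeros(P.p[i].n_rows, P.p[i].n_cols);

      // per-sentence loss and emission gradients
      arma::mat dEm(F.Em.n_rows, K, arma::fill::zeros);
      int r0 = 0;
      for (int s = 0; s < B; ++s) {
        const arma::ivec &y = gold[b.sent[s]];
        const int L = (int)y.n_elem;
        arma::mat em = F.Em.rows(r0, r0 + L - 1);
        if (lk == LOSS_CRF) {
          arma::mat marg, edge;
          double logZ = crf_posteriors(em, P.p[9], P.p[10].col(0),
                                       P.p[11].col(0), marg, edge);
          total += logZ - crf_path_score_core(em, y, P.p[9], P.p[10].col(0),
                                              P.p[11].col(0));
          arma::mat d = marg;
          for (int t = 0; t < L; ++t) d(t, (arma::uword)y(t)) -= 1.0;
          dEm.rows(r0, r0 + L - 1) = d;
          G[9] += edge;
          for (int t = 1; t < L; ++t) G[9](y(t - 1), y(t)) -= 1.0;
          G[10].col(0) += marg.row(0).t();
          G[10](y(0), 0) -= 1.0;
          G[11].col(0) += marg.row(L - 1).t();
          G[11](y(L - 1), 0) -= 1.0;
        } else {
          arma::mat dZ;
          total += softmax_loss(em, y, lk, dZ);
          dEm.rows(r0, r0 + L - 1) = dZ;
        }
        ntok += L;
        r0 += L;
      }

      // output layer
      G[7] = F.Feat.t() * dEm;
      G[8].row(0) = arma::sum(dEm, 0);
      arma::mat dFeat = dEm * P.p[7].t();

      // scatter features gradient back into per-timestep dH
      const int H = P.H;
      std::vector<arma::mat> dHf(b.Tmax, arma::mat(B, H, arma::fill::zeros));
      std::vector<arma::mat> dHb;
      if (bidir) dHb.assign(b.Tmax, arma::mat(B, H, arma::fill::zeros));
      for (arma::uword r = 0; r < dFeat.n_rows; ++r) {
        int s = F.pos[r].first, t = F.pos[r].second;
        int L = (int)words[b.sent[s]].n_elem;
        dHf[t].row(s) += dFeat.submat(r, 0, r, H - 1);
        if (bidir) dHb[L - 1 - t].row(s) += dFeat.submat(r, H, r, 2 * H - 1);
      }

      std::vector<arma::mat> dXf(b.Tmax), dXb;
      lstm_backward(P.p[1], P.p[2], F.Xf, F.cf, dHf, G[1], G[2], G[3],
                    train_embedding ? &dXf : nullptr);
      if (bidir) {
        dXb.resize(b.Tmax);
        lstm_backward(P.p[4], P.p[5], F.Xb, F.cb, dHb, G[4], G[5], G[6],
                      train_embedding ? &dXb : nullptr);
      }
      if (train_embedding) {
        for (int t = 0; t < b.Tmax; ++t) {
          for (int s = 0; s < B; ++s) {
            G[0].row(F.idx_f(s, t)) += dXf[t].row(s);
            if (bidir) G[0].row(F.idx_b(s, t)) += dXb[t].row(s);
          }
        }
        G[0].row(0).zeros(); // PAD embedding stays fixed at zero
      }

      for (int i = 0; i < 12; ++i) G[i] /= (double)B;
      if (clip > 0) {
        double nrm2 = 0.0;
        for (int i = 0; i < 12; ++i)
          if (active[i]) nrm2 += arma::accu(G[i] % G[i]);
        double nrm = std::sqrt(nrm2);
        if (nrm > clip)
          for (int i = 0; i < 12; ++i) G[i] *= clip / nrm;
      }
      opt.update(P.p, G, active);
    }
    epoch_loss[e] = total / (double)ntok;
    Rcpp::checkUserInterrupt();
  }

  List w;
  for (int i = 0; i < 12; ++i) w[PARAM_NAMES[i]] = P.p[i];
  return List::create(_["weights"] = w, _["epoch_loss"] = epoch_loss,
                      _["n_tags"] = K, _["hidden"] = hidden,
                      _["arch"] = arch_s);
}

static Params params_from_list(List w, int hidden, Arch arch) {
  Params P;
  P.arch = arch;
  P.H = hidden;
  P.p.resize(12);
  for (int i = 0; i < 12; ++i) P.p[i] = as<arma::mat>(w[PARAM_NAMES[i]]);
  P.D = P.p[0].n_cols;
  P.V = P.p[0].n_rows;
  P.K = P.p[8].n_cols;
  return P;
}

// [[Rcpp::export]]
List cpp_predict_tagger(List weights, List sentences, int hidden,
                        std::string arch_s, int batch_size, bool constrained,
                        Nullable<IntegerMatrix> allowed = R_NilValue,
                        Nullable<IntegerVector> allowed_start = R_NilValue) {
  Arch arch = parse_arch(arch_s);
  Params P = params_from_list(weights, hidden, arch);
  const int n = sentences.size();
  std::vector<arma::ivec> words(n);
  for (int i = 0; i < n; ++i) words[i] = as<arma::ivec>(sentences[i]);
  arma::imat am;
  arma::ivec asv;
  const arma::imat *ap = nullptr;
  const arma::ivec *asp = nullptr;
  if (constrained) {
    if (allowed.isNull() || allowed_start.isNull())
      stop("constrained decoding requires the transition masks");
    am = as<arma::imat>(allowed.get());
    asv = as<arma::ivec>(allowed_start.get());
    ap = &am;
    asp = &asv;
  }
  List out(n);
  std::vector<Batch> batches = make_batches(words, batch_size);
  for (const Batch &b : batches) {
    BatchForward F;
    batch_forward(P, words, b, F);
    int r0 = 0;
    for (size_t s = 0; s < b.sent.size(); ++s) {
      const int L = (int)words[b.sent[s]].n_elem;
      arma::mat em = F.Em.rows(r0, r0 + L - 1);
      IntegerVector path(L);
      if (arch == ARCH_BILSTM_CRF) {
        arma::ivec p;
        crf_viterbi_core(em, P.p[9], P.p[10].col(0), P.p[11].col(0), ap, asp,
                         p);
        for (int t = 0; t < L; ++t) path[t] = (int)p(t);
      } else {
        for (int t = 0; t < L; ++t) {
          arma::uword arg;
          em.row(t).max(arg);
          path[t] = (int)arg;
        }
      }
      out[b.sent[s]] = path;
      r0 += L;
    }
  }
  return out;
}

// Emission scores for one encoded sentence; exposed for the embedding-layer
// seeding contract and for tests of the pluggable scorer interface.
// [[Rcpp::export]]
arma::mat cpp_tagger_emissions(List weights, IntegerVector sentence, int hidden,
                               std::string arch_s) {
  Arch arch = parse_arch(arch_s);
  Params P = params_from_list(weights, hidden, arch);
  std::vector<arma::ivec> words(1);
  words[0] = as<arma::ivec>(sentence);
  Batch b;
  b.sent.push_back(0);
  b.Tmax = (int)words[0].n_elem;
  BatchForward F;
  batch_forward(P, words, b, F);
  return F.Em;
}
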
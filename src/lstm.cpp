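// Bidirectional LSTM sequence labeler: batched forward, full BPTT, Adam.
//
// Architecture: `layers` stacked bidirectional LSTM layers (hidden units h
// per direction, outputs concatenated to 2h), followed by a per-timestep
// fully connected head with ReLU activations and a single sigmoid logit per
// position. Loss is binary cross-entropy plus a weighted soft-Jaccard term
// computed per sequence.
//
// Weight naming: W{l}_{d}, U{l}_{d}, b{l}_{d} for layer l (1-based) and
// direction d (0 forward, 1 backward); HW{k}, Hb{k} for the head stack.
// Gate column layout within the 4h gate matrices: [i | f | g | o].

#include <RcppArmadillo.h>
#include <map>
#include <random>
#include <string>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::rowvec;

typedef std::map<std::string, mat> WeightMap;

static WeightMap list_to_map(const Rcpp::List& weights) {
  WeightMap wm;
  Rcpp::CharacterVector names = weights.names();
  for (int i = 0; i < weights.size(); ++i) {
    wm[Rcpp::as<std::string>(names[i])] = Rcpp::as<mat>(weights[i]);
  }
  return wm;
}

static Rcpp::List map_to_list(const WeightMap& wm) {
  Rcpp::List out;
  for (WeightMap::const_iterator it = wm.begin(); it != wm.end(); ++it) {
    out[it->first] = it->second;
  }
  return out;
}

static std::string key(const char* stem, int l, int d) {
  return std::string(stem) + std::to_string(l) + "_" + std::to_string(d);
}

static std::string hkey(const char* stem, int k) {
  return std::string(stem) + std::to_string(k);
}

static int n_layers(const WeightMap& wm) {
  int L = 0;
  while (wm.count(key("W", L + 1, 0))) ++L;
  return L;
}

static int n_head(const WeightMap& wm) {
  int K = 0;
  while (wm.count(hkey("HW", K + 1))) ++K;
  return K;
}

static mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// per-direction caches for one LSTM layer
struct DirCache {
  std::vector<mat> gi, gf, gg, go, tc, cprev, hprev;
  std::vector<mat> h;  // indexed by actual timestep
};

// run one direction of one LSTM layer over per-timestep inputs A (B x in).
// If cache is non-null, store everything BPTT needs.
static void lstm_dir_forward(const mat& W, const mat& U, const rowvec& b,
                             const std::vector<mat>& A, bool reverse,
                             std::vector<mat>& H, DirCache* cache) {
  int T = (int)A.size();
  int B = (int)A[0].n_rows;
  int h = (int)U.n_rows;
  H.assign(T, mat());
  mat hs(B, h, arma::fill::zeros), cs(B, h, arma::fill::zeros);
  if (cache) {
    cache->gi.assign(T, mat()); cache->gf.assign(T, mat());
    cache->gg.assign(T, mat()); cache->go.assign(T, mat());
    cache->tc.assign(T, mat()); cache->cprev.assign(T, mat());
    cache->hprev.assign(T, mat());
  }
  for (int step = 0; step < T; ++step) {
    int t = reverse ? (T - 1 - step) : step;
    mat Z = A[t] * W + hs * U;
    Z.each_row() += b;
    mat gi = sigmoid(Z.cols(0, h - 1));
    mat gf = sigmoid(Z.cols(h, 2 * h - 1));
    mat gg = arma::tanh(Z.cols(2 * h, 3 * h - 1));
    mat go = sigmoid(Z.cols(3 * h, 4 * h - 1));
    mat cn = gf % cs + gi % gg;
    mat tc = arma::tanh(cn);
    if (cache) {
      cache->gi[t] = gi; cache->gf[t] = gf; cache->gg[t] = gg;
      cache->go[t] = go; cache->tc[t] = tc;
      cache->cprev[t] = cs; cache->hprev[t] = hs;
    }
    cs = cn;
    hs = go % tc;
    H[t] = hs;
  }
}

// BPTT through one direction; accumulates parameter grads and dA.
static void lstm_dir_backward(const mat& W, const mat& U,
                              const std::vector<mat>& A,
                              const std::vector<mat>& dH, bool reverse,
                              const DirCache& cache,
                              mat& gW, mat& gU, rowvec& gb,
                              std::vector<mat>& dA) {
  int T = (int)A.size();
  int B = (int)A[0].n_rows;
  int h = (int)U.n_rows;
  gW.zeros(W.n_rows, W.n_cols);
  gU.zeros(U.n_rows, U.n_cols);
  gb.zeros(4 * h);
  mat dh_carry(B, h, arma::fill::zeros), dc_carry(B, h, arma::fill::zeros);
  for (int step = T - 1; step >= 0; --step) {
    int t = reverse ? (T - 1 - step) : step;
    mat dh = dH[t] + dh_carry;
    const mat& gi = cache.gi[t];
    const mat& gf = cache.gf[t];
    const mat& gg = cache.gg[t];
    const mat& go = cache.go[t];
    const mat& tc = cache.tc[t];
    mat dc = dc_carry + dh % go % (1.0 - tc % tc);
    mat dgo = dh % tc;
    mat dgi = dc % gg;
    mat dgf = dc % cache.cprev[t];
    mat dgg = dc % gi;
    mat dZ(B, 4 * h);
    dZ.cols(0, h - 1) = dgi % gi % (1.0 - gi);
    dZ.cols(h, 2 * h - 1) = dgf % gf % (1.0 - gf);
    dZ.cols(2 * h, 3 * h - 1) = dgg % (1.0 - gg % gg);
    dZ.cols(3 * h, 4 * h - 1) = dgo % go % (1.0 - go);
    gW += A[t].t() * dZ;
    gU += cache.hprev[t].t() * dZ;
    gb += arma::sum(dZ, 0);
    dh_carry = dZ * U.t();
    dc_carry = dc % gf;
    dA[t] += dZ * W.t();
  }
}

struct ForwardCache {
  // layer inputs, per layer: vector over t of (B x in)
  std::vector<std::vector<mat> > inputs;
  std::vector<DirCache> dir;  // 2 per layer: [2*l], [2*l+1]
  std::vector<mat> head_act;  // head activations incl. input, (B*T) x d
  mat P;                      // B x T probabilities
};

// full forward pass; caches retained only when `train` is true
static mat forward_pass(const WeightMap& wm, const mat& X, bool train,
                        ForwardCache* fc) {
  int B = (int)X.n_rows, T = (int)X.n_cols;
  int L = n_layers(wm);
  int K = n_head(wm);
  std::vector<mat> A(T);
  for (int t = 0; t < T; ++t) A[t] = X.col(t);
  if (fc) { fc->inputs.clear(); fc->dir.assign(2 * L, DirCache()); }
  for (int l = 1; l <= L; ++l) {
    if (fc) fc->inputs.push_back(A);
    std::vector<mat> Hf, Hb;
    const rowvec bf = wm.at(key("b", l, 0)).row(0);
    const rowvec bb = wm.at(key("b", l, 1)).row(0);
    lstm_dir_forward(wm.at(key("W", l, 0)), wm.at(key("U", l, 0)), bf, A,
                     false, Hf, train ? &fc->dir[2 * (l - 1)] : 0);
    lstm_dir_forward(wm.at(key("W", l, 1)), wm.at(key("U", l, 1)), bb, A,
                     true, Hb, train ? &fc->dir[2 * (l - 1) + 1] : 0);
    for (int t = 0; t < T; ++t) A[t] = arma::join_rows(Hf[t], Hb[t]);
  }
  // stack timesteps: row r = t*B + b
  int twoH = (int)A[0].n_cols;
  mat M(B * T, twoH);
  for (int t = 0; t < T; ++t) M.rows(t * B, t * B + B - 1) = A[t];
  if (fc) { fc->head_act.clear(); fc->head_act.push_back(M); }
  mat H = M;
  for (int k = 1; k <= K; ++k) {
    H = H * wm.at(hkey("HW", k));
    H.each_row() += wm.at(hkey("Hb", k)).row(0);
    if (k < K) H = arma::clamp(H, 0.0, arma::datum::inf);  // ReLU
    if (fc) fc->head_act.push_back(H);
  }
  mat P(B, T);
  mat probs = sigmoid(H);
  for (int t = 0; t < T; ++t) P.col(t) = probs.rows(t * B, t * B + B - 1);
  if (fc) fc->P = P;
  return P;
}

// BCE + jw * mean(1 - softJaccard) per sequence
static double loss_value(const mat& P, const mat& Y, double jw) {
  const double eps = 1e-7;
  mat Pc = arma::clamp(P, eps, 1.0 - eps);
  double bce = -arma::accu(Y % arma::log(Pc) +
                           (1.0 - Y) % arma::log(1.0 - Pc)) / Pc.n_elem;
  arma::vec s1 = arma::sum(P % Y, 1);
  arma::vec s2 = arma::sum(P + Y - P % Y, 1);
  double jac = 0.0;
  for (arma::uword b = 0; b < s1.n_elem; ++b) {
    double J = (s2(b) > 0.0) ? s1(b) / s2(b) : 1.0;  // both empty: perfect
    jac += 1.0 - J;
  }
  jac /= (double)s1.n_elem;
  return bce + jw * jac;
}

// dLoss/dlogit, same (t,b) stacking as the head matrix
static mat loss_dlogit(const mat& P, const mat& Y, double jw) {
  int B = (int)P.n_rows, T = (int)P.n_cols;
  double N = (double)P.n_elem;
  mat dP_jac(B, T, arma::fill::zeros);
  arma::vec s1 = arma::sum(P % Y, 1);
  arma::vec s2 = arma::sum(P + Y - P % Y, 1);
  for (int b = 0; b < B; ++b) {
    if (s2(b) > 0.0) {
      for (int t = 0; t < T; ++t) {
        double y = Y(b, t);
        double dJ = (y * s2(b) - s1(b) * (1.0 - y)) / (s2(b) * s2(b));
        dP_jac(b, t) = -jw * dJ / (double)B;
      }
    }
  }
  mat dlogit_mat = (P - Y) / N + dP_jac % P % (1.0 - P);
  mat d(B * T, 1);
  for (int t = 0; t < T; ++t) {
    d.rows(t * B, t * B + B - 1) = dlogit_mat.col(t);
  }
  return d;
}

static WeightMap backward_pass(const WeightMap& wm, const mat& X,
                               const mat& Y, double jw,
                               const ForwardCache& fc) {
  int B = (int)X.n_rows, T = (int)X.n_cols;
  int L = n_layers(wm);
  int K = n_head(wm);
  WeightMap g;
  // head backprop
  mat delta = loss_dlogit(fc.P, Y, jw);  // (B*T) x 1
  for (int k = K; k >= 1; --k) {
    const mat& a_in = fc.head_act[k - 1];
    g[hkey("HW", k)] = a_in.t() * delta;
    g[hkey("Hb", k)] = arma::sum(delta, 0);
    delta = delta * wm.at(hkey("HW", k)).t();
    if (k > 1) {
      delta %= arma::conv_to<mat>::from(fc.head_act[k - 1] > 0.0);  // ReLU'
    }
  }
  // delta now (B*T) x 2h w.r.t. top LSTM output; unstack per timestep
  int h = (int)wm.at(key("U", L, 0)).n_rows;
  std::vector<mat> dHf(T), dHb(T);
  for (int t = 0; t < T; ++t) {
    mat rows = delta.rows(t * B, t * B + B - 1);
    dHf[t] = rows.cols(0, h - 1);
    dHb[t] = rows.cols(h, 2 * h - 1);
  }
  for (int l = L; l >= 1; --l) {
    const std::vector<mat>& A = fc.inputs[l - 1];
    std::vector<mat> dA(T);
    for (int t = 0; t < T; ++t) dA[t].zeros(B, A[0].n_cols);
    mat gW, gU;
    rowvec gb;
    lstm_dir_backward(wm.at(key("W", l, 0)), wm.at(key("U", l, 0)), A, dHf,
                      false, fc.dir[2 * (l - 1)], gW, gU, gb, dA);
    g[key("W", l, 0)] = gW; g[key("U", l, 0)] = gU;
    g[key("b", l, 0)] = mat(gb);
    lstm_dir_backward(wm.at(key("W", l, 1)), wm.at(key("U", l, 1)), A, dHb,
                      true, fc.dir[2 * (l - 1) + 1], gW, gU, gb, dA);
    g[key("W", l, 1)] = gW; g[key("U", l, 1)] = gU;
    g[key("b", l, 1)] = mat(gb);
    if (l > 1) {
      for (int t = 0; t < T; ++t) {
        dHf[t] = dA[t].cols(0, h - 1);
        dHb[t] = dA[t].cols(h, 2 * h - 1);
      }
    }
  }
  return g;
}

// [[Rcpp::export]]
Rcpp::List lstm_init_cpp(int seed, int hidden, int layers,
                         Rcpp::IntegerVector head_layers, int in_dim) {
  std::mt19937 rng((unsigned)seed);
  WeightMap wm;
  double k = 1.0 / std::sqrt((double)hidden);
  std::uniform_real_distribution<double> unif(-k, k);
  for (int l = 1; l <= layers; ++l) {
    int in = (l == 1) ? in_dim : 2 * hidden;
    for (int d = 0; d < 2; ++d) {
      mat W(in, 4 * hidden), U(hidden, 4 * hidden), b(1, 4 * hidden);
      for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = unif(rng);
      for (arma::uword i = 0; i < U.n_elem; ++i) U(i) = unif(rng);
      for (arma::uword i = 0; i < b.n_elem; ++i) b(i) = unif(rng);
      // bias the forget gate open at the start of training
      for (int i = hidden; i < 2 * hidden; ++i) b(0, i) += 1.0;
      wm[key("W", l, d)] = W;
      wm[key("U", l, d)] = U;
      wm[key("b", l, d)] = b;
    }
  }
  int din = 2 * hidden;
  std::vector<int> widths;
  for (int i = 0; i < head_layers.size(); ++i) {
    widths.push_back(head_layers[i]);
  }
  widths.push_back(1);  // final logit
  for (size_t kk = 0; kk < widths.size(); ++kk) {
    int dout = widths[kk];
    double kk2 = 1.0 / std::sqrt((double)din);
    std::uniform_real_distribution<double> unif2(-kk2, kk2);
    mat Wk(din, dout), bk(1, dout, arma::fill::zeros);
    for (arma::uword i = 0; i < Wk.n_elem; ++i) Wk(i) = unif2(rng);
    wm[hkey("HW", (int)kk + 1)] = Wk;
    wm[hkey("Hb", (int)kk + 1)] = bk;
    din = dout;
  }
  return map_to_list(wm);
}

// [[Rcpp::export]]
arma::mat lstm_forward_cpp(Rcpp::List weights, arma::mat X) {
  WeightMap wm = list_to_map(weights);
  return forward_pass(wm, X, false, 0);
}

// [[Rcpp::export]]
double lstm_loss_cpp(Rcpp::List weights, arma::mat X, arma::mat Y,
                     double jaccard_weight) {
  WeightMap wm = list_to_map(weights);
  mat P = forward_pass(wm, X, false, 0);
  return loss_value(P, Y, jaccard_weight);
}

// [[Rcpp::export]]
Rcpp::List lstm_gradient_cpp(Rcpp::List weights, arma::mat X, arma::mat Y,
                             double jaccard_weight) {
  WeightMap wm = list_to_map(weights);
  ForwardCache fc;
  forward_pass(wm, X, true, &fc);
  WeightMap g = backward_pass(wm, X, Y, jaccard_weight, fc);
  return map_to_list(g);
}

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(Rcpp::List weights, arma::mat X, arma::mat Y,
                          arma::mat Xval, arma::mat Yval, double lr,
                          int batch_size, int max_epochs, int patience,
                          double jaccard_weight, int seed) {
  WeightMap wm = list_to_map(weights);
  int N = (int)X.n_rows;
  if (batch_size > N) batch_size = N;
  bool has_val = Xval.n_rows > 0;
  std::mt19937 rng((unsigned)seed);
  WeightMap m, v;  // Adam state
  for (WeightMap::iterator it = wm.begin(); it != wm.end(); ++it) {
    m[it->first] = mat(it->second.n_rows, it->second.n_cols,
                       arma::fill::zeros);
    v[it->first] = mat(it->second.n_rows, it->second.n_cols,
                       arma::fill::zeros);
  }
  const double b1 = 0.9, b2 = 0.999, adam_eps = 1e-8;
  long step = 0;
  std::vector<double> train_loss, val_loss;
  double best = arma::datum::inf;
  int best_epoch = 0, since_best = 0;
  WeightMap best_wm = wm;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double epoch_loss = 0.0;
    int n_batches = 0;
    for (int off = 0; off + batch_size <= N; off += batch_size) {
      arma::uvec rows(batch_size);
      for (int i = 0; i < batch_size; ++i) rows(i) = idx[off + i];
      mat Xb = X.rows(rows), Yb = Y.rows(rows);
      ForwardCache fc;
      forward_pass(wm, Xb, true, &fc);
      epoch_loss += loss_value(fc.P, Yb, jaccard_weight);
      ++n_batches;
      WeightMap g = backward_pass(wm, Xb, Yb, jaccard_weight, fc);
      ++step;
      double corr = lr * std::sqrt(1.0 - std::pow(b2, (double)step)) /
                    (1.0 - std::pow(b1, (double)step));
      for (WeightMap::iterator it = wm.begin(); it != wm.end(); ++it) {
        const mat& gk = g[it->first];
        mat& mk = m[it->first];
        mat& vk = v[it->first];
        mk = b1 * mk + (1.0 - b1) * gk;
        vk = b2 * vk + (1.0 - b2) * (gk % gk);
        it->second -= corr * mk / (arma::sqrt(vk) + adam_eps);
      }
    }
    train_loss.push_back(epoch_loss / std::max(n_batches, 1));
    double monitor;
    if (has_val) {
      mat Pv = forward_pass(wm, Xval, false, 0);
      monitor = loss_value(Pv, Yval, jaccard_weight);
      val_loss.push_back(monitor);
    } else {
      monitor = train_loss.back();
    }
    if (monitor < best - 1e-9) {
      best = monitor;
      best_epoch = epoch;
      best_wm = wm;
      since_best = 0;
    } else {
      ++since_best;
      if (since_best >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = map_to_list(best_wm),
      Rcpp::Named("train_loss") = train_loss,
      Rcpp::Named("val_loss") = val_loss,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_val_loss") = best);
}
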
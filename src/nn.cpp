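// Neural-network core: dense feedforward and LSTM sequence regressors with
// MSE loss, Adam optimizer, inverted dropout and early stopping on the
// validation loss. Written against Armadillo; fully deterministic given the
// seed (own mt19937 for shuffling and dropout, single code path).
//
// The layer math is templated on the Armadillo matrix type: the feedforward
// net runs in double precision, the LSTM in single precision (its training
// cost is dominated by many small GEMMs; float roughly halves it, and NN
// training is insensitive to the difference).
//
// LSTM layout: sequences are flattened time-major into (B*T x C) matrices
// (row block t holds the batch at phase step t), so the input-to-gate
// products of all steps collapse into one GEMM; only the recurrent term is
// computed stepwise.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

template <typename MT>
static inline MT sigmoid(const MT& z) { return 1.0 / (1.0 + exp(-z)); }

// ---------------------------------------------------------------------------
// Adam state: one slot per parameter matrix
template <typename MT>
struct Adam {
  std::vector<MT> m, v;
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const std::vector<MT*>& params, double lr_) {
    lr = lr_;
    m.clear(); v.clear();
    for (auto p : params) {
      m.push_back(MT(size(*p), fill::zeros));
      v.push_back(MT(size(*p), fill::zeros));
    }
  }
  void step(std::vector<MT*>& params, const std::vector<MT>& grads) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t), c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t k = 0; k < params.size(); ++k) {
      m[k] = b1 * m[k] + (1 - b1) * grads[k];
      v[k] = b2 * v[k] + (1 - b2) * square(grads[k]);
      *params[k] -= lr * (m[k] / c1) / (sqrt(v[k] / c2) + eps);
    }
  }
};

template <typename MT>
static std::vector<MT> list_to_mats(Rcpp::List L) {
  std::vector<MT> out;
  for (int i = 0; i < L.size(); ++i) {
    out.push_back(conv_to<MT>::from(Rcpp::as<mat>(L[i])));
  }
  return out;
}

template <typename MT>
static Rcpp::List mats_to_list(const std::vector<MT>& v) {
  Rcpp::List L(v.size());
  for (size_t i = 0; i < v.size(); ++i) L[i] = Rcpp::wrap(conv_to<mat>::from(v[i]));
  return L;
}

template <typename MT>
static void fill_dropout_mask(MT& M, double keep, std::mt19937_64& rng) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double inv = 1.0 / keep;
  for (uword k = 0; k < M.n_elem; ++k) M[k] = (unif(rng) < keep) ? inv : 0.0;
}

template <typename MT>
static double mse(const MT& A, const MT& B) {
  return accu(square(conv_to<mat>::from(A) - conv_to<mat>::from(B))) /
    (double)(A.n_rows * A.n_cols);
}

// ---------------------------------------------------------------------------
// Feedforward network (double precision). weights: W[0..L] (layer matrices),
// b[0..L] (row vectors); hidden activation tanh, output sigmoid, dropout
// after every hidden activation.

static mat fnn_forward(const std::vector<mat>& W, const std::vector<mat>& b,
                       const mat& X) {
  mat A = X;
  size_t L = W.size() - 1;
  for (size_t l = 0; l < L; ++l) A = tanh(A * W[l] + repmat(b[l], A.n_rows, 1));
  return sigmoid<mat>(A * W[L] + repmat(b[L], A.n_rows, 1));
}

// [[Rcpp::export]]
arma::mat cpp_fnn_predict(Rcpp::List W_, Rcpp::List b_, const arma::mat& X) {
  return fnn_forward(list_to_mats<mat>(W_), list_to_mats<mat>(b_), X);
}

// [[Rcpp::export]]
Rcpp::List cpp_fnn_train(const arma::mat& Xtr, const arma::mat& Ytr,
                         const arma::mat& Xval, const arma::mat& Yval,
                         Rcpp::List W_, Rcpp::List b_,
                         double dropout, double lr, int batch_size,
                         int max_epochs, int patience, int seed) {
  std::vector<mat> W = list_to_mats<mat>(W_), b = list_to_mats<mat>(b_);
  size_t L = W.size() - 1;  // hidden layers
  std::vector<mat*> params;
  for (auto& w : W) params.push_back(&w);
  for (auto& bb : b) params.push_back(&bb);
  Adam<mat> opt; opt.init(params, lr);

  std::mt19937_64 rng(seed);
  const double keep = 1.0 - dropout;

  uword n = Xtr.n_rows;
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;

  std::vector<double> hist_train, hist_val;
  double best_val = datum::inf;
  std::vector<mat> bestW = W, bestb = b;
  int best_epoch = 0, wait = 0;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0; int nb = 0;
    for (uword start = 0; start < n; start += batch_size) {
      uword stop = std::min(n - 1, start + batch_size - 1);
      uvec bi(stop - start + 1);
      for (uword i = 0; i < bi.n_elem; ++i) bi[i] = idx[start + i];
      mat X = Xtr.rows(bi), Y = Ytr.rows(bi);
      uword B = X.n_rows;

      std::vector<mat> A(L + 1), Hpre(L), Mask(L);
      A[0] = X;
      for (size_t l = 0; l < L; ++l) {
        Hpre[l] = tanh(A[l] * W[l] + repmat(b[l], B, 1));
        mat H = Hpre[l];
        if (dropout > 0) {
          Mask[l].set_size(size(H));
          fill_dropout_mask(Mask[l], keep, rng);
          H %= Mask[l];
        }
        A[l + 1] = H;
      }
      mat Yhat = sigmoid<mat>(A[L] * W[L] + repmat(b[L], B, 1));
      double loss = mse(Yhat, Y);
      if (!std::isfinite(loss)) {
        Rcpp::stop("FNN training diverged (non-finite loss) at epoch %d, batch %d; lr = %g",
                   epoch, nb + 1, lr);
      }
      ep_loss += loss; ++nb;

      std::vector<mat> gW(L + 1), gb(L + 1);
      mat dZ = (2.0 / (double)(B * Y.n_cols)) * (Yhat - Y) % Yhat % (1.0 - Yhat);
      gW[L] = A[L].t() * dZ;
      gb[L] = sum(dZ, 0);
      mat dA = dZ * W[L].t();
      for (int l = (int)L - 1; l >= 0; --l) {
        mat dH = dA;
        if (dropout > 0) dH %= Mask[l];
        mat dZl = dH % (1.0 - square(Hpre[l]));
        gW[l] = A[l].t() * dZl;
        gb[l] = sum(dZl, 0);
        dA = dZl * W[l].t();
      }
      std::vector<mat> grads;
      for (size_t l = 0; l <= L; ++l) grads.push_back(gW[l]);
      for (size_t l = 0; l <= L; ++l) grads.push_back(gb[l]);
      opt.step(params, grads);
    }
    double val = mse(fnn_forward(W, b, Xval), Yval);
    if (!std::isfinite(val)) {
      Rcpp::stop("FNN validation loss non-finite at epoch %d; lr = %g", epoch, lr);
    }
    hist_train.push_back(ep_loss / nb);
    hist_val.push_back(val);
    if (val < best_val - 1e-12) {
      best_val = val; bestW = W; bestb = b; best_epoch = epoch; wait = 0;
    } else if (patience > 0 && ++wait >= patience) break;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = mats_to_list(bestW), Rcpp::Named("b") = mats_to_list(bestb),
    Rcpp::Named("train_loss") = hist_train, Rcpp::Named("val_loss") = hist_val,
    Rcpp::Named("best_epoch") = best_epoch, Rcpp::Named("best_val") = best_val);
}

// LSTM working precision (lmat/lcube): float by default
typedef fmat lmat;
typedef fcube lcube;

// ---------------------------------------------------------------------------
// LSTM (single precision). Per layer: Wx (C x 4H), Wh (H x 4H), bias
// (1 x 4H); gate order [input, forget, cell, output] along the 4H axis.
// Two readout heads:
//   sequence (seq_head = true): a shared dense sigmoid unit (Wd: H x 1) maps
//     each phase step's hidden state to that step's envelope value;
//   final-state (seq_head = false): the last step's hidden state feeds a
//     dense sigmoid layer of all outputs (Wd: H x n_out).
// Dropout acts on each layer's output sequence (and the readout inputs).

struct LSTMCache {
  lmat xin;    // layer input, (B*T x C), time-major row blocks
  lmat gates;  // activated gates, (B*T x 4H)
  lmat c, tc, h;  // cell, tanh(cell), hidden, (B*T x H)
  lmat mask;   // dropout mask on h feeding upward, empty if unused
};

// forward one layer over the whole flattened sequence
static void lstm_layer_forward(const lmat& Wx, const lmat& Wh, const lmat& bias,
                               const lmat& xin, uword B, uword T,
                               LSTMCache* cache, lmat& hout,
                               double keep, std::mt19937_64* rng) {
  uword H = Wh.n_rows;
  lmat Zx = xin * Wx;          // all steps at once
  Zx.each_row() += bias;
  lmat gates(B * T, 4 * H), c(B * T, H), tc(B * T, H), h(B * T, H);
  lmat h_prev(B, H, fill::zeros), c_prev(B, H, fill::zeros);
  lmat z(B, 4 * H), ct(B, H), tct(B, H), ht(B, H);  // step buffers, reused
  for (uword t = 0; t < T; ++t) {
    uword r0 = t * B, r1 = r0 + B - 1;
    z = h_prev * Wh;
    z += Zx.rows(r0, r1);
    // activations computed element-wise in place: [i f | g | o] blocks
    float* zp = z.memptr();
    const uword ncell0 = B * 2 * H, ncell1 = B * 3 * H, nall = B * 4 * H;
    for (uword k = 0; k < ncell0; ++k) zp[k] = 1.0f / (1.0f + std::exp(-zp[k]));
    for (uword k = ncell0; k < ncell1; ++k) zp[k] = std::tanh(zp[k]);
    for (uword k = ncell1; k < nall; ++k) zp[k] = 1.0f / (1.0f + std::exp(-zp[k]));
    ct = z.cols(H, 2 * H - 1) % c_prev + z.cols(0, H - 1) % z.cols(2 * H, 3 * H - 1);
    tct = tanh(ct);
    ht = z.cols(3 * H, 4 * H - 1) % tct;
    gates.rows(r0, r1) = z;
    c.rows(r0, r1) = ct; tc.rows(r0, r1) = tct; h.rows(r0, r1) = ht;
    h_prev = ht; c_prev = ct;
  }
  hout = h;
  if (cache) {
    cache->xin = xin; cache->gates = std::move(gates);
    cache->c = std::move(c); cache->tc = std::move(tc); cache->h = hout;
    if (keep < 1.0) {
      cache->mask.set_size(B * T, H);
      fill_dropout_mask(cache->mask, keep, *rng);
      hout %= cache->mask;
    } else {
      cache->mask.reset();
    }
  }
}

// readout over the (flattened, post-dropout) top-layer sequence h
static lmat lstm_readout(const lmat& h, const lmat& Wd, const lmat& bd,
                         uword B, uword T, bool seq_head) {
  if (seq_head) {
    lmat z = h * Wd;  // (B*T x 1), shared dense unit
    lmat out(B, T);
    for (uword t = 0; t < T; ++t) out.col(t) = z.rows(t * B, t * B + B - 1);
    out += bd(0, 0);
    return sigmoid<lmat>(out);
  }
  lmat hT = h.rows((T - 1) * B, T * B - 1);
  return sigmoid<lmat>(hT * Wd + repmat(bd, B, 1));
}

// prediction-time forward; Xs is (n x C x T) float cube
static lmat lstm_forward_all(const std::vector<lmat>& Wx, const std::vector<lmat>& Wh,
                             const std::vector<lmat>& bias, const lmat& Wd,
                             const lmat& bd, const lcube& Xs, bool seq_head) {
  uword B = Xs.n_rows, T = Xs.n_slices, C = Xs.n_cols;
  lmat xin(B * T, C);
  for (uword t = 0; t < T; ++t) xin.rows(t * B, t * B + B - 1) = Xs.slice(t);
  lmat h;
  for (size_t l = 0; l < Wx.size(); ++l) {
    lstm_layer_forward(Wx[l], Wh[l], bias[l], xin, B, T, nullptr, h, 1.0, nullptr);
    xin = h;
  }
  return lstm_readout(h, Wd, bd, B, T, seq_head);
}

// [[Rcpp::export]]
arma::mat cpp_lstm_predict(Rcpp::List Wx_, Rcpp::List Wh_, Rcpp::List b_,
                           const arma::mat& Wd, const arma::mat& bd,
                           const arma::cube& Xs, bool seq_head) {
  lcube Xf = conv_to<lcube>::from(Xs);
  lmat out = lstm_forward_all(list_to_mats<lmat>(Wx_), list_to_mats<lmat>(Wh_),
                              list_to_mats<lmat>(b_),
                              conv_to<lmat>::from(Wd), conv_to<lmat>::from(bd),
                              Xf, seq_head);
  return conv_to<mat>::from(out);
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_train(const arma::cube& Xtr, const arma::mat& Ytr,
                          const arma::cube& Xval, const arma::mat& Yval,
                          Rcpp::List Wx_, Rcpp::List Wh_, Rcpp::List b_,
                          const arma::mat& Wd0, const arma::mat& bd0,
                          double dropout, double lr, int batch_size,
                          int max_epochs, int patience, int seed,
                          bool seq_head) {
  std::vector<lmat> Wx = list_to_mats<lmat>(Wx_), Wh = list_to_mats<lmat>(Wh_),
    bias = list_to_mats<lmat>(b_);
  lmat Wd = conv_to<lmat>::from(Wd0), bd = conv_to<lmat>::from(bd0);
  lcube Xtrf = conv_to<lcube>::from(Xtr);
  lcube Xvalf = conv_to<lcube>::from(Xval);
  lmat Ytrf = conv_to<lmat>::from(Ytr), Yvalf = conv_to<lmat>::from(Yval);
  size_t Lr = Wx.size();
  uword T = Xtrf.n_slices, H = Wh[0].n_rows;

  std::vector<lmat*> params;
  for (auto& w : Wx) params.push_back(&w);
  for (auto& w : Wh) params.push_back(&w);
  for (auto& w : bias) params.push_back(&w);
  params.push_back(&Wd); params.push_back(&bd);
  Adam<lmat> opt; opt.init(params, lr);

  std::mt19937_64 rng(seed);
  const double keep = 1.0 - dropout;

  uword n = Xtrf.n_rows;
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;

  std::vector<double> hist_train, hist_val;
  double best_val = datum::inf;
  std::vector<lmat> bWx = Wx, bWh = Wh, bb = bias;
  lmat bWd = Wd, bbd = bd;
  int best_epoch = 0, wait = 0;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0; int nb = 0;
    for (uword start = 0; start < n; start += batch_size) {
      uword stop = std::min(n - 1, start + batch_size - 1);
      uvec bi(stop - start + 1);
      for (uword i = 0; i < bi.n_elem; ++i) bi[i] = idx[start + i];
      uword B = bi.n_elem;
      lmat Y = Ytrf.rows(bi);

      // ---- forward
      lmat xin(B * T, Xtrf.n_cols);
      for (uword t = 0; t < T; ++t) {
        lmat sl = Xtrf.slice(t);
        xin.rows(t * B, t * B + B - 1) = sl.rows(bi);
      }
      std::vector<LSTMCache> caches(Lr);
      lmat h;
      for (size_t l = 0; l < Lr; ++l) {
        lstm_layer_forward(Wx[l], Wh[l], bias[l], xin, B, T, &caches[l], h, keep, &rng);
        xin = h;  // dropout already applied inside when keep < 1
      }
      lmat Yhat = lstm_readout(xin, Wd, bd, B, T, seq_head);
      double loss = mse(Yhat, Y);
      if (!std::isfinite(loss)) {
        Rcpp::stop("LSTM training diverged (non-finite loss) at epoch %d, batch %d; lr = %g",
                   epoch, nb + 1, lr);
      }
      ep_loss += loss; ++nb;

      // ---- backward
      lmat dZ = (float)(2.0 / (double)(B * Y.n_cols)) * (Yhat - Y) % Yhat % (1.0f - Yhat);
      lmat gWd, gbd;
      lmat dh_above;  // gradient on the top layer's pre-dropout outputs
      if (seq_head) {
        lmat zst(B * T, 1);
        for (uword t = 0; t < T; ++t) zst.rows(t * B, t * B + B - 1) = dZ.col(t);
        gWd = xin.t() * zst;
        gbd.set_size(1, 1);
        gbd(0, 0) = accu(dZ);
        dh_above = zst * Wd.t();
        if (keep < 1.0) dh_above %= caches[Lr - 1].mask;
      } else {
        lmat hT = xin.rows((T - 1) * B, T * B - 1);
        gWd = hT.t() * dZ;
        gbd = sum(dZ, 0);
        dh_above.zeros(B * T, H);
        lmat d = dZ * Wd.t();
        if (keep < 1.0) d %= caches[Lr - 1].mask.rows((T - 1) * B, T * B - 1);
        dh_above.rows((T - 1) * B, T * B - 1) = d;
      }

      std::vector<lmat> gWx(Lr), gWh(Lr), gb(Lr);
      lmat dh(B, H), dc(B, H), dz(B, 4 * H), dh_next(B, H), dc_next(B, H);
      for (int l = (int)Lr - 1; l >= 0; --l) {
        LSTMCache& cc = caches[l];
        lmat DZ(B * T, 4 * H);  // gate pre-activation gradients, all steps
        dh_next.zeros(); dc_next.zeros();
        for (int t = (int)T - 1; t >= 0; --t) {
          uword r0 = t * B, r1 = r0 + B - 1;
          auto gi = cc.gates(span(r0, r1), span(0, H - 1));
          auto gf = cc.gates(span(r0, r1), span(H, 2 * H - 1));
          auto gg = cc.gates(span(r0, r1), span(2 * H, 3 * H - 1));
          auto go = cc.gates(span(r0, r1), span(3 * H, 4 * H - 1));
          auto tct = cc.tc.rows(r0, r1);
          dh = dh_above.rows(r0, r1);
          dh += dh_next;
          dc = dc_next + dh % go % (1.0f - square(tct));
          dz.cols(3 * H, 4 * H - 1) = (dh % tct) % go % (1.0f - go);
          dz.cols(0, H - 1) = (dc % gg) % gi % (1.0f - gi);
          if (t > 0) {
            dz.cols(H, 2 * H - 1) = (dc % cc.c.rows(r0 - B, r0 - 1)) % gf % (1.0f - gf);
          } else {
            dz.cols(H, 2 * H - 1).zeros();  // c_prev = 0
          }
          DZ.rows(r0, r1) = dz;
          dh_next = dz * Wh[l].t();
          dc_next = dc % gf;
        }
        // h lagged one step (first block zero): one GEMM for the recurrent
        // weight gradient instead of one per step
        lmat Hm1(B * T, H);
        Hm1.rows(0, B - 1).zeros();
        if (T > 1) Hm1.rows(B, B * T - 1) = cc.h.rows(0, B * (T - 1) - 1);
        gWh[l] = Hm1.t() * DZ;
        gWx[l] = cc.xin.t() * DZ;
        gb[l] = sum(DZ, 0);
        if (l > 0) {
          dh_above = DZ * Wx[l].t();
          if (keep < 1.0) dh_above %= caches[l - 1].mask;
        }
      }
      std::vector<lmat> grads;
      for (size_t l = 0; l < Lr; ++l) grads.push_back(gWx[l]);
      for (size_t l = 0; l < Lr; ++l) grads.push_back(gWh[l]);
      for (size_t l = 0; l < Lr; ++l) grads.push_back(gb[l]);
      grads.push_back(gWd); grads.push_back(gbd);
      opt.step(params, grads);
    }
    double val = mse(lstm_forward_all(Wx, Wh, bias, Wd, bd, Xvalf, seq_head), Yvalf);
    if (!std::isfinite(val)) {
      Rcpp::stop("LSTM validation loss non-finite at epoch %d; lr = %g", epoch, lr);
    }
    hist_train.push_back(ep_loss / nb);
    hist_val.push_back(val);
    if (val < best_val - 1e-9) {
      best_val = val;
      bWx = Wx; bWh = Wh; bb = bias; bWd = Wd; bbd = bd;
      best_epoch = epoch; wait = 0;
    } else if (patience > 0 && ++wait >= patience) break;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("Wx") = mats_to_list(bWx), Rcpp::Named("Wh") = mats_to_list(bWh),
    Rcpp::Named("b") = mats_to_list(bb),
    Rcpp::Named("Wd") = Rcpp::wrap(conv_to<mat>::from(bWd)),
    Rcpp::Named("bd") = Rcpp::wrap(conv_to<mat>::from(bbd)),
    Rcpp::Named("train_loss") = hist_train, Rcpp::Named("val_loss") = hist_val,
    Rcpp::Named("best_epoch") = best_epoch, Rcpp::Named("best_val") = best_val);
}
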
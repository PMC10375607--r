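// Convolutional + recurrent sample-wise sequence labeler.
//
// Forward and backward passes for a stack of same-padding 1-D convolutions
// (kernel 3, stride 1, ReLU) followed by a recurrent head (LSTM / BiLSTM /
// GRU / BiGRU), a per-timestep dense layer and a softmax over the four wave
// classes. Loss is categorical cross-entropy restricted to unmasked
// (non-padded) samples. Everything is written for clarity at desk scale:
// sequences are processed one at a time, time is the row dimension.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::span;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// ---- convolution ------------------------------------------------------------

// build [x_{t-1}, x_t, x_{t+1}] (T x 3C) with zero boundary padding
static mat conv_im2row(const mat& X) {
  const arma::uword T = X.n_rows, C = X.n_cols;
  mat M(T, 3 * C, arma::fill::zeros);
  M.cols(C, 2 * C - 1) = X;                                    // x_t
  if (T > 1) {
    M.submat(1, 0, T - 1, C - 1) = X.rows(0, T - 2);           // x_{t-1}
    M.submat(0, 2 * C, T - 2, 3 * C - 1) = X.rows(1, T - 1);   // x_{t+1}
  }
  return M;
}

// scatter gradient of the im2row matrix back onto the input
static mat conv_im2row_back(const mat& dM, arma::uword C) {
  const arma::uword T = dM.n_rows;
  mat dX(T, C, arma::fill::zeros);
  dX += dM.cols(C, 2 * C - 1);
  if (T > 1) {
    dX.rows(0, T - 2) += dM.submat(1, 0, T - 1, C - 1);
    dX.rows(1, T - 1) += dM.submat(0, 2 * C, T - 2, 3 * C - 1);
  }
  return dX;
}

struct ConvCache { mat M; mat A; };

static mat conv_forward(const mat& X, const mat& W, const rowvec& b,
                        ConvCache* cache) {
  mat M = conv_im2row(X);
  mat A = M * W;
  A.each_row() += b;
  A.transform([](double v) { return v > 0.0 ? v : 0.0; });
  if (cache) { cache->M = std::move(M); cache->A = A; }
  return A;
}

// ---- LSTM -------------------------------------------------------------------

struct LstmCache { mat I, F, G, O, C, tC, H; mat X; };

// X: T x D; Wx: D x 4H; Wh: H x 4H; b: 4H. Gate order [i f g o].
static mat lstm_forward(const mat& X, const mat& Wx, const mat& Wh,
                        const rowvec& b, LstmCache* cc) {
  const arma::uword T = X.n_rows, H = Wh.n_rows;
  mat I(T, H), F(T, H), G(T, H), O(T, H), C(T, H), tC(T, H), Hs(T, H);
  mat XP = X * Wx;
  XP.each_row() += b;
  rowvec h(H, arma::fill::zeros), c(H, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    rowvec a = XP.row(t) + h * Wh;
    rowvec i = sigm(a.cols(0, H - 1));
    rowvec f = sigm(a.cols(H, 2 * H - 1));
    rowvec g = arma::tanh(a.cols(2 * H, 3 * H - 1));
    rowvec o = sigm(a.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    rowvec tc = arma::tanh(c);
    h = o % tc;
    I.row(t) = i; F.row(t) = f; G.row(t) = g; O.row(t) = o;
    C.row(t) = c; tC.row(t) = tc; Hs.row(t) = h;
  }
  if (cc) { cc->I = I; cc->F = F; cc->G = G; cc->O = O;
            cc->C = C; cc->tC = tC; cc->H = Hs; cc->X = X; }
  return Hs;
}

// returns dX; fills dWx, dWh, db
static mat lstm_backward(const mat& dH, const LstmCache& cc, const mat& Wx,
                         const mat& Wh, mat& dWx, mat& dWh, rowvec& db) {
  const arma::uword T = dH.n_rows, H = Wh.n_rows;
  dWx.zeros(Wx.n_rows, Wx.n_cols);
  dWh.zeros(Wh.n_rows, Wh.n_cols);
  db.zeros(4 * H);
  mat dX(T, cc.X.n_cols, arma::fill::zeros);
  rowvec dh_next(H, arma::fill::zeros), dc_next(H, arma::fill::zeros);
  for (arma::uword tt = T; tt-- > 0;) {
    rowvec dh = dH.row(tt) + dh_next;
    rowvec i = cc.I.row(tt), f = cc.F.row(tt), g = cc.G.row(tt),
           o = cc.O.row(tt), tc = cc.tC.row(tt);
    rowvec dc = dh % o % (1.0 - tc % tc) + dc_next;
    rowvec c_prev = tt > 0 ? rowvec(cc.C.row(tt - 1))
                           : rowvec(H, arma::fill::zeros);
    rowvec di = dc % g % i % (1.0 - i);
    rowvec df = dc % c_prev % f % (1.0 - f);
    rowvec dg = dc % i % (1.0 - g % g);
    rowvec do_ = dh % tc % o % (1.0 - o);
    rowvec da = arma::join_rows(arma::join_rows(di, df),
                                arma::join_rows(dg, do_));
    rowvec h_prev = tt > 0 ? rowvec(cc.H.row(tt - 1))
                           : rowvec(H, arma::fill::zeros);
    dWx += cc.X.row(tt).t() * da;
    dWh += h_prev.t() * da;
    db += da;
    dX.row(tt) = da * Wx.t();
    dh_next = da * Wh.t();
    dc_next = dc % f;
  }
  return dX;
}

// ---- GRU --------------------------------------------------------------------

struct GruCache { mat R, Z, N, HPn, H; mat X; };

// gate order [r z n]; candidate uses reset-gated hidden projection
static mat gru_forward(const mat& X, const mat& Wx, const mat& Wh,
                       const rowvec& b, GruCache* cc) {
  const arma::uword T = X.n_rows, H = Wh.n_rows;
  mat R(T, H), Z(T, H), N(T, H), HPn(T, H), Hs(T, H);
  mat XP = X * Wx;
  XP.each_row() += b;
  rowvec h(H, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    rowvec hp = h * Wh;
    rowvec r = sigm(XP.row(t).cols(0, H - 1) + hp.cols(0, H - 1));
    rowvec z = sigm(XP.row(t).cols(H, 2 * H - 1) + hp.cols(H, 2 * H - 1));
    rowvec hpn = hp.cols(2 * H, 3 * H - 1);
    rowvec nn = arma::tanh(XP.row(t).cols(2 * H, 3 * H - 1) + r % hpn);
    h = (1.0 - z) % nn + z % h;
    R.row(t) = r; Z.row(t) = z; N.row(t) = nn; HPn.row(t) = hpn;
    Hs.row(t) = h;
  }
  if (cc) { cc->R = R; cc->Z = Z; cc->N = N; cc->HPn = HPn;
            cc->H = Hs; cc->X = X; }
  return Hs;
}

static mat gru_backward(const mat& dH, const GruCache& cc, const mat& Wx,
                        const mat& Wh, mat& dWx, mat& dWh, rowvec& db) {
  const arma::uword T = dH.n_rows, H = Wh.n_rows;
  dWx.zeros(Wx.n_rows, Wx.n_cols);
  dWh.zeros(Wh.n_rows, Wh.n_cols);
  db.zeros(3 * H);
  mat dX(T, cc.X.n_cols, arma::fill::zeros);
  rowvec dh_next(H, arma::fill::zeros);
  for (arma::uword tt = T; tt-- > 0;) {
    rowvec dh = dH.row(tt) + dh_next;
    rowvec r = cc.R.row(tt), z = cc.Z.row(tt), nn = cc.N.row(tt),
           hpn = cc.HPn.row(tt);
    rowvec h_prev = tt > 0 ? rowvec(cc.H.row(tt - 1))
                           : rowvec(H, arma::fill::zeros);
    rowvec dz = dh % (h_prev - nn) % z % (1.0 - z);
    rowvec dn = dh % (1.0 - z) % (1.0 - nn % nn);
    rowvec dr = dn % hpn % r % (1.0 - r);
    rowvec dxp = arma::join_rows(arma::join_rows(dr, dz), dn);
    rowvec dhp = arma::join_rows(arma::join_rows(dr, dz), dn % r);
    dWx += cc.X.row(tt).t() * dxp;
    dWh += h_prev.t() * dhp;
    db += dxp;
    dX.row(tt) = dxp * Wx.t();
    dh_next = dh % z + dhp * Wh.t();
  }
  return dX;
}

// ---- assembled network ------------------------------------------------------

struct NetSpec {
  std::vector<int> filters;
  std::string head;   // lstm | bilstm | gru | bigru
  int units;
  int n_classes;
  bool bidir() const { return head == "bilstm" || head == "bigru"; }
  bool is_gru() const { return head == "gru" || head == "bigru"; }
};

static NetSpec parse_cfg(const List& cfg) {
  NetSpec s;
  IntegerVector f = cfg["conv_filters"];
  s.filters = std::vector<int>(f.begin(), f.end());
  s.head = as<std::string>(cfg["head"]);
  s.units = as<int>(cfg["head_units"]);
  s.n_classes = as<int>(cfg["n_classes"]);
  return s;
}

struct FwdCache {
  std::vector<ConvCache> conv;
  LstmCache lstm_f, lstm_b;
  GruCache gru_f, gru_b;
  mat rnn_in, rnn_out, probs;
};

static mat rnn_dir(const NetSpec& s, const mat& X, const List& params,
                   const std::string& pre, bool reversed, FwdCache* fc) {
  mat Xd = reversed ? mat(arma::flipud(X)) : X;
  mat Wx = params[pre + "_Wx"], Wh = params[pre + "_Wh"];
  rowvec b = params[pre + "_b"];
  mat Hs;
  if (s.is_gru()) {
    GruCache* gc = fc ? (reversed ? &fc->gru_b : &fc->gru_f) : nullptr;
    Hs = gru_forward(Xd, Wx, Wh, b, gc);
  } else {
    LstmCache* lc = fc ? (reversed ? &fc->lstm_b : &fc->lstm_f) : nullptr;
    Hs = lstm_forward(Xd, Wx, Wh, b, lc);
  }
  return reversed ? mat(arma::flipud(Hs)) : Hs;
}

// full forward pass for one sequence; x is T x 1
static mat net_forward(const NetSpec& s, const mat& x, const List& params,
                       FwdCache* fc) {
  mat A = x;
  if (fc) fc->conv.resize(s.filters.size());
  for (size_t l = 0; l < s.filters.size(); ++l) {
    std::string key = "conv" + std::to_string(l + 1);
    mat W = params[key + "_W"];
    rowvec b = params[key + "_b"];
    A = conv_forward(A, W, b, fc ? &fc->conv[l] : nullptr);
  }
  if (fc) fc->rnn_in = A;
  mat Hcat = rnn_dir(s, A, params, "rnn_f", false, fc);
  if (s.bidir()) {
    Hcat = arma::join_rows(Hcat, rnn_dir(s, A, params, "rnn_b", true, fc));
  }
  if (fc) fc->rnn_out = Hcat;
  mat Wd = params["out_W"];
  rowvec bd = params["out_b"];
  mat logits = Hcat * Wd;
  logits.each_row() += bd;
  // row-wise softmax, numerically stabilized
  logits.each_col() -= arma::max(logits, 1);
  mat P = arma::exp(logits);
  P.each_col() /= arma::sum(P, 1);
  if (fc) fc->probs = P;
  return P;
}

//' @noRd
// [[Rcpp::export(name = ".nn_forward_cpp")]]
arma::mat nn_forward_cpp(List params, arma::vec x, List cfg) {
  NetSpec s = parse_cfg(cfg);
  mat X(x.n_elem, 1);
  X.col(0) = x;
  return net_forward(s, X, params, nullptr);
}

// accumulate `g` into the named entry of the gradient list
static void acc(List& grads, const std::string& key, const mat& g) {
  if (grads.containsElementNamed(key.c_str())) {
    mat cur = grads[key];
    grads[key] = cur + g;
  } else {
    grads[key] = g;
  }
}

// one sequence's backward pass; dOut is T x n_classes (dLoss/dLogits)
static void net_backward(const NetSpec& s, const FwdCache& fc,
                         const List& params, const mat& dLogits,
                         List& grads) {
  mat Wd = params["out_W"];
  acc(grads, "out_W", fc.rnn_out.t() * dLogits);
  acc(grads, "out_b", arma::sum(dLogits, 0));
  mat dH = dLogits * Wd.t();

  const arma::uword H = (arma::uword)s.units;
  mat dA;
  {
    mat dWx, dWh; rowvec db;
    mat dHf = dH.cols(0, H - 1);
    mat Wx = params["rnn_f_Wx"], Wh = params["rnn_f_Wh"];
    if (s.is_gru()) dA = gru_backward(dHf, fc.gru_f, Wx, Wh, dWx, dWh, db);
    else dA = lstm_backward(dHf, fc.lstm_f, Wx, Wh, dWx, dWh, db);
    acc(grads, "rnn_f_Wx", dWx); acc(grads, "rnn_f_Wh", dWh);
    acc(grads, "rnn_f_b", db);
  }
  if (s.bidir()) {
    mat dWx, dWh; rowvec db;
    mat dHb = arma::flipud(mat(dH.cols(H, 2 * H - 1)));
    mat Wx = params["rnn_b_Wx"], Wh = params["rnn_b_Wh"];
    mat dAb;
    if (s.is_gru()) dAb = gru_backward(dHb, fc.gru_b, Wx, Wh, dWx, dWh, db);
    else dAb = lstm_backward(dHb, fc.lstm_b, Wx, Wh, dWx, dWh, db);
    dA += arma::flipud(dAb);
    acc(grads, "rnn_b_Wx", dWx); acc(grads, "rnn_b_Wh", dWh);
    acc(grads, "rnn_b_b", db);
  }

  for (size_t l = s.filters.size(); l-- > 0;) {
    std::string key = "conv" + std::to_string(l + 1);
    const ConvCache& cc = fc.conv[l];
    mat dZ = dA % arma::conv_to<mat>::from(cc.A > 0.0);
    acc(grads, key + "_W", cc.M.t() * dZ);
    acc(grads, key + "_b", arma::sum(dZ, 0));
    mat W = params[key + "_W"];
    mat dM = dZ * W.t();
    dA = conv_im2row_back(dM, cc.M.n_cols / 3);
  }
}

//' @noRd
// [[Rcpp::export(name = ".nn_batch_cpp")]]
List nn_batch_cpp(List params, arma::mat X, arma::imat Y, arma::imat M,
                  List cfg, bool grad) {
  NetSpec s = parse_cfg(cfg);
  const arma::uword T = X.n_rows, B = X.n_cols;
  double n_mask = (double)arma::accu(M);
  if (n_mask < 1.0) stop("batch has no unmasked samples");
  double nll = 0.0;
  int correct = 0;
  List grads;
  for (arma::uword b = 0; b < B; ++b) {
    FwdCache fc;
    mat xb(T, 1);
    xb.col(0) = X.col(b);
    mat P = net_forward(s, xb, params, grad ? &fc : nullptr);
    mat dLogits(T, s.n_classes, arma::fill::zeros);
    for (arma::uword t = 0; t < T; ++t) {
      if (M(t, b) == 0) continue;
      int y = Y(t, b);
      double p = std::max(P(t, (arma::uword)y), 1e-12);
      nll += -std::log(p);
      arma::uword pred = 0;
      P.row(t).max(pred);  // ties resolve to the lowest index
      if ((int)pred == y) ++correct;
      if (grad) {
        dLogits.row(t) = P.row(t) / n_mask;
        dLogits(t, (arma::uword)y) -= 1.0 / n_mask;
      }
    }
    if (grad) net_backward(s, fc, params, dLogits, grads);
  }
  List out = List::create(_["loss"] = nll / n_mask,
                          _["correct"] = correct,
                          _["n"] = (int)n_mask);
  if (grad) out["grads"] = grads;
  return out;
}
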
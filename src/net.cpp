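// Hybrid dilated-convolution / BiLSTM / autoencoder network engine.
//
// Layout conventions:
//  - A batch of B windows of T samples x C axes is held as a flat matrix
//    [B*T x C] with row index r = b*T + t (time fastest within a sample).
//  - Dilated causal convolutions are evaluated as im2col matrix products:
//    out(p) = sum_i F(p - d*i) k(i), kernel index i reaching back in time,
//    out-of-range terms zero, so output length equals input length.
//  - The BiLSTM trunk summary is the concatenation of the forward stream's
//    final hidden state and the backward stream's final hidden state.
//  - Heads: 4-way softmax classification, regression of future positions
//    (residual added to the window's last observed sample), sigmoid
//    excessive-motion flag, and an autoencoder bottleneck z feeding a
//    tanh-hidden decoder that reconstructs the clean window.
//
// All computation is double precision; randomness (shuffling, dropout)
// comes from a std::mt19937 seeded explicitly, so training is reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

namespace {

struct NetConfig {
  int T, Cin, K, channels, H, latent, dec_hidden, n_reg, recon_dim;
  std::vector<int> dilations, horizons;
  double lw_cls, lw_reg, lw_rec, lw_exc;
  double dropout;
};

NetConfig read_config(const List& cfg) {
  NetConfig c;
  c.T = Rcpp::as<int>(cfg["window_len"]);
  c.Cin = Rcpp::as<int>(cfg["n_axes"]);
  c.K = Rcpp::as<int>(cfg["kernel_size"]);
  c.channels = Rcpp::as<int>(cfg["channels"]);
  c.H = Rcpp::as<int>(cfg["hidden_size"]);
  c.latent = Rcpp::as<int>(cfg["latent_dim"]);
  c.dec_hidden = Rcpp::as<int>(cfg["decoder_hidden"]);
  c.n_reg = Rcpp::as<int>(cfg["n_reg"]);
  c.recon_dim = Rcpp::as<int>(cfg["recon_dim"]);
  c.dilations = Rcpp::as<std::vector<int>>(cfg["dilations"]);
  c.horizons = Rcpp::as<std::vector<int>>(cfg["horizons"]);
  Rcpp::NumericVector lw = cfg["loss_weights"];
  c.lw_cls = lw[0]; c.lw_reg = lw[1]; c.lw_rec = lw[2]; c.lw_exc = lw[3];
  c.dropout = Rcpp::as<double>(cfg["dropout"]);
  return c;
}

std::vector<mat> params_from_list(const List& p) {
  std::vector<mat> out;
  out.reserve(p.size());
  for (int i = 0; i < p.size(); ++i) out.push_back(Rcpp::as<mat>(p[i]));
  return out;
}

List params_to_list(const std::vector<mat>& v,
                    const Rcpp::CharacterVector& names) {
  List out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = v[i];
  out.attr("names") = names;
  return out;
}

// parameter indexing: per conv layer l (0-based): W, b, ln_gamma, ln_beta
// then fwd lstm Wx, Wh, b; bwd lstm Wx, Wh, b; enc W, b; cls W, b;
// reg W, b; exc W, b; dec W1, b1, W2, b2
struct PIdx {
  int n_layers;
  int conv(int l, int which) const { return 4 * l + which; }
  int lstm(int dir, int which) const { return 4 * n_layers + 3 * dir + which; }
  int enc(int which) const { return 4 * n_layers + 6 + which; }
  int cls(int which) const { return 4 * n_layers + 8 + which; }
  int reg(int which) const { return 4 * n_layers + 10 + which; }
  int exc(int which) const { return 4 * n_layers + 12 + which; }
  int dec(int which) const { return 4 * n_layers + 14 + which; }
  int total() const { return 4 * n_layers + 18; }
};

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

mat im2col(const mat& X, int B, int T, int K, int d) {
  int C = X.n_cols;
  mat M(B * T, C * K, fill::zeros);
  for (int i = 0; i < K; ++i) {
    int lag = d * i;
    if (lag >= T) continue;
    for (int b = 0; b < B; ++b) {
      M.submat(b * T + lag, i * C, b * T + T - 1, (i + 1) * C - 1) =
        X.submat(b * T, 0, b * T + T - 1 - lag, C - 1);
    }
  }
  return M;
}

void col2im_acc(const mat& dM, int B, int T, int K, int d, mat& dX) {
  int C = dX.n_cols;
  for (int i = 0; i < K; ++i) {
    int lag = d * i;
    if (lag >= T) continue;
    for (int b = 0; b < B; ++b) {
      dX.submat(b * T, 0, b * T + T - 1 - lag, C - 1) +=
        dM.submat(b * T + lag, i * C, b * T + T - 1, (i + 1) * C - 1);
    }
  }
}

struct ConvCache {
  std::vector<mat> M;       // im2col input per layer
  std::vector<mat> xhat;    // layer-norm normalized values
  std::vector<vec> inv;     // layer-norm inverse std per row
  std::vector<mat> act;     // post-ReLU activations
  std::vector<mat> mask;    // spatial dropout mask [B x C]
  std::vector<mat> out;     // layer output (input to next layer)
};

struct LSTMCache {
  std::vector<mat> gi, gf, gg, go, c, h_prev;
};

const double LN_EPS = 1e-5;

// forward one direction over a time-major feature matrix Xtm [T*B x C]
// (rows t*B..t*B+B-1 hold step t); the input projection is one large GEMM,
// only the recurrent product stays inside the time loop. Returns the final
// hidden state [B x H].
mat lstm_forward_dir(const mat& Xtm, int B, const mat& Wx, const mat& Wh,
                     const rowvec& b, bool reverse, LSTMCache& cc) {
  int T = Xtm.n_rows / B;
  int H = Wh.n_rows;
  mat proj = Xtm * Wx;
  proj.each_row() += b;
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  cc.gi.resize(T); cc.gf.resize(T); cc.gg.resize(T); cc.go.resize(T);
  cc.c.resize(T); cc.h_prev.resize(T);
  for (int s = 0; s < T; ++s) {
    int t = reverse ? (T - 1 - s) : s;
    mat G = proj.rows(t * B, (t + 1) * B - 1) + h * Wh;
    mat gi = sigmoid(G.cols(0, H - 1));
    mat gf = sigmoid(G.cols(H, 2 * H - 1));
    mat gg = tanh(G.cols(2 * H, 3 * H - 1));
    mat go = sigmoid(G.cols(3 * H, 4 * H - 1));
    cc.h_prev[s] = h;
    c = gf % c + gi % gg;
    h = go % tanh(c);
    cc.gi[s] = std::move(gi); cc.gf[s] = std::move(gf);
    cc.gg[s] = std::move(gg); cc.go[s] = std::move(go);
    cc.c[s] = c;
  }
  return h;
}

void lstm_backward_dir(const mat& Xtm, int B, const mat& Wx, const mat& Wh,
                       bool reverse, const LSTMCache& cc, const mat& dh_final,
                       mat& dWx, mat& dWh, rowvec& db, mat& dXtm) {
  int T = Xtm.n_rows / B;
  int H = Wh.n_rows;
  mat dA_all(T * B, 4 * H);
  mat dh = dh_final, dc(B, H, fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    int t = reverse ? (T - 1 - s) : s;
    mat tc = tanh(cc.c[s]);
    mat do_ = dh % tc;
    dc += dh % cc.go[s] % (1.0 - tc % tc);
    mat di = dc % cc.gg[s];
    mat dg = dc % cc.gi[s];
    mat df = (s == 0) ? mat(B, H, fill::zeros) : mat(dc % cc.c[s - 1]);
    mat dc_prev = dc % cc.gf[s];
    mat dA(B, 4 * H);
    dA.cols(0, H - 1) = di % cc.gi[s] % (1.0 - cc.gi[s]);
    dA.cols(H, 2 * H - 1) = df % cc.gf[s] % (1.0 - cc.gf[s]);
    dA.cols(2 * H, 3 * H - 1) = dg % (1.0 - cc.gg[s] % cc.gg[s]);
    dA.cols(3 * H, 4 * H - 1) = do_ % cc.go[s] % (1.0 - cc.go[s]);
    dWh += cc.h_prev[s].t() * dA;
    dh = dA * Wh.t();
    dc = dc_prev;
    dA_all.rows(t * B, (t + 1) * B - 1) = dA;
  }
  dWx += Xtm.t() * dA_all;
  db += sum(dA_all, 0);
  dXtm += dA_all * Wx.t();
}

struct Forward {
  // head outputs
  mat probs, reg_pred, recon, z, trunk, d1, reg0;
  vec exc_prob;
  // caches for backward
  ConvCache conv;
  LSTMCache lf, lb;
  mat Xtm;                  // conv-stack output, time-major [T*B x channels]
  mat xlast;                // [B x Cin] last observed sample per axis
  mat head_in;              // regression-head features
  mat slope;                // [B x Cin] smoothed local slope per axis
  mat trunk_aug;            // trunk + per-axis window min/max [B x 2H+2*Cin]
  int B;
};

// gather batch rows from data cube [N x T x C] into flat [B*T x C]
mat gather_batch(const cube& X, const uvec& idx, int T, int C) {
  int B = idx.n_elem;
  mat out(B * T, C);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      for (int t = 0; t < T; ++t) out(b * T + t, c) = X(idx[b], t, c);
    }
  }
  return out;
}

void net_forward(const std::vector<mat>& P, const PIdx& pi, const NetConfig& c,
                 const mat& X0, bool training, std::mt19937* rng, Forward& F) {
  int B = X0.n_rows / c.T;
  F.B = B;
  int n_layers = pi.n_layers;
  F.conv.M.resize(n_layers); F.conv.xhat.resize(n_layers);
  F.conv.inv.resize(n_layers); F.conv.act.resize(n_layers);
  F.conv.mask.resize(n_layers); F.conv.out.resize(n_layers);

  F.xlast = mat(B, c.Cin);
  mat xprev(B, c.Cin), xback(B, c.Cin);
  int kslope = std::min(4, c.T - 1);   // smoothed local slope span
  for (int b = 0; b < B; ++b) {
    for (int a = 0; a < c.Cin; ++a) {
      F.xlast(b, a) = X0(b * c.T + c.T - 1, a);
      xprev(b, a) = X0(b * c.T + c.T - 2, a);
      xback(b, a) = X0(b * c.T + c.T - 1 - kslope, a);
    }
  }
  F.slope = (F.xlast - xback) / kslope;
  // per-axis window extrema: layer-normalized conv features are largely
  // scale-invariant, so absolute amplitude is fed to the heads directly
  mat wmin(B, c.Cin), wmax(B, c.Cin);
  for (int b = 0; b < B; ++b) {
    for (int a = 0; a < c.Cin; ++a) {
      double lo = X0(b * c.T, a), hi = lo;
      for (int t = 1; t < c.T; ++t) {
        double v = X0(b * c.T + t, a);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      wmin(b, a) = lo;
      wmax(b, a) = hi;
    }
  }

  std::uniform_real_distribution<double> unif(0.0, 1.0);
  mat cur = X0;
  for (int l = 0; l < n_layers; ++l) {
    const mat& W = P[pi.conv(l, 0)];
    const mat& bb = P[pi.conv(l, 1)];
    const mat& gam = P[pi.conv(l, 2)];
    const mat& bet = P[pi.conv(l, 3)];
    mat M = im2col(cur, B, c.T, c.K, c.dilations[l]);
    mat Y = M * W;
    Y.each_row() += bb.row(0);
    // layer normalization across channels at each (sample, time) position
    vec mu = mean(Y, 1);
    mat xc = Y.each_col() - mu;
    vec va = mean(xc % xc, 1);
    vec inv = 1.0 / sqrt(va + LN_EPS);
    mat xhat = xc.each_col() % inv;
    mat out = xhat.each_row() % gam.row(0);
    out.each_row() += bet.row(0);
    // ReLU
    mat act = out;
    act.elem(find(act < 0.0)).zeros();
    // spatial (channel-wise) dropout
    mat mask(B, out.n_cols, fill::ones);
    if (training && c.dropout > 0.0 && rng != nullptr) {
      double keep = 1.0 - c.dropout;
      for (uword i = 0; i < mask.n_rows; ++i)
        for (uword j = 0; j < mask.n_cols; ++j)
          mask(i, j) = (unif(*rng) < keep) ? 1.0 / keep : 0.0;
    }
    mat dropped = act;
    for (int b = 0; b < B; ++b)
      dropped.rows(b * c.T, (b + 1) * c.T - 1).each_row() %= mask.row(b);
    F.conv.M[l] = M; F.conv.xhat[l] = xhat; F.conv.inv[l] = inv;
    F.conv.act[l] = act; F.conv.mask[l] = mask; F.conv.out[l] = dropped;
    cur = dropped;
  }

  // re-order the conv-stack output to time-major layout for the BiLSTM
  F.Xtm.set_size(c.T * B, c.channels);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < c.T; ++t) F.Xtm.row(t * B + b) = cur.row(b * c.T + t);

  mat hf = lstm_forward_dir(F.Xtm, B, P[pi.lstm(0, 0)], P[pi.lstm(0, 1)],
                            P[pi.lstm(0, 2)].row(0), false, F.lf);
  mat hb = lstm_forward_dir(F.Xtm, B, P[pi.lstm(1, 0)], P[pi.lstm(1, 1)],
                            P[pi.lstm(1, 2)].row(0), true, F.lb);
  F.trunk = join_rows(hf, hb);
  // scaled amplitude statistics (10x window range, centred mean level per
  // axis): layer-normalized conv features are largely scale-invariant, so
  // absolute amplitude is fed to the heads directly, scaled so that
  // class-relevant differences are O(1)
  F.trunk_aug = join_rows(F.trunk, 10.0 * (wmax - wmin),
                          2.0 * (wmax + wmin) - 2.0);

  // autoencoder bottleneck
  F.z = tanh(F.trunk_aug * P[pi.enc(0)] + repmat(P[pi.enc(1)], B, 1));
  F.d1 = tanh(F.z * P[pi.dec(0)] + repmat(P[pi.dec(1)], B, 1));
  F.recon = F.d1 * P[pi.dec(2)] + repmat(P[pi.dec(3)], B, 1);

  // classification (stable softmax)
  mat logits = F.trunk_aug * P[pi.cls(0)] + repmat(P[pi.cls(1)], B, 1);
  vec mx = max(logits, 1);
  mat ex = exp(logits.each_col() - mx);
  F.probs = ex.each_col() / sum(ex, 1);

  // regression: residual relative to a per-horizon linear-extrapolation
  // base (last sample plus horizon times the smoothed local slope); the
  // head reads the trunk summary augmented with the last sample and both
  // one-step and smoothed slopes, and only learns corrections to the base
  F.head_in = join_rows(F.trunk_aug,
                        join_rows(F.xlast, F.xlast - xprev, F.slope));
  F.reg0 = F.head_in * P[pi.reg(0)] + repmat(P[pi.reg(1)], B, 1);
  F.reg_pred = F.reg0;
  int nh = c.n_reg / c.Cin;
  for (int h = 0; h < nh; ++h)
    F.reg_pred.cols(h * c.Cin, (h + 1) * c.Cin - 1) +=
      F.xlast + double(c.horizons[h]) * F.slope;

  vec exc_logit = F.trunk_aug * P[pi.exc(0)].col(0) + P[pi.exc(1)](0, 0);
  F.exc_prob = 1.0 / (1.0 + exp(-exc_logit));
}

struct Targets {
  uvec ycls;   // 0-based class
  mat yreg, yrec;
  vec yexc;
};

vec loss_components(const Forward& F, const Targets& tg, const NetConfig& c) {
  int B = F.B;
  double ce = 0.0;
  for (int b = 0; b < B; ++b)
    ce += -std::log(std::max(F.probs(b, tg.ycls[b]), 1e-12));
  ce /= B;
  double mse = accu(square(F.reg_pred - tg.yreg)) / (double(B) * c.n_reg);
  double mae = accu(abs(F.recon - tg.yrec)) / (double(B) * c.recon_dim);
  vec p = clamp(F.exc_prob, 1e-9, 1.0 - 1e-9);
  double bce = as_scalar(mean(-(tg.yexc % log(p) +
                                (1.0 - tg.yexc) % log(1.0 - p))));
  return {ce, mse, mae, bce};
}

void net_backward(const std::vector<mat>& P, const PIdx& pi, const NetConfig& c,
                  const Forward& F, const Targets& tg, std::vector<mat>& G) {
  int B = F.B;
  // head gradients
  mat dlogits = F.probs;
  for (int b = 0; b < B; ++b) dlogits(b, tg.ycls[b]) -= 1.0;
  dlogits *= c.lw_cls / B;

  mat dreg0 = (F.reg_pred - tg.yreg) * (2.0 * c.lw_reg / (double(B) * c.n_reg));
  mat drecon = sign(F.recon - tg.yrec) * (c.lw_rec / (double(B) * c.recon_dim));
  vec dexc = (F.exc_prob - tg.yexc) * (c.lw_exc / B);

  G[pi.cls(0)] = F.trunk_aug.t() * dlogits;
  G[pi.cls(1)] = sum(dlogits, 0);
  G[pi.reg(0)] = F.head_in.t() * dreg0;
  G[pi.reg(1)] = sum(dreg0, 0);
  G[pi.exc(0)] = F.trunk_aug.t() * dexc;
  G[pi.exc(1)] = mat(1, 1, fill::value(accu(dexc)));

  // decoder
  G[pi.dec(2)] = F.d1.t() * drecon;
  G[pi.dec(3)] = sum(drecon, 0);
  mat da1 = (drecon * P[pi.dec(2)].t()) % (1.0 - F.d1 % F.d1);
  G[pi.dec(0)] = F.z.t() * da1;
  G[pi.dec(1)] = sum(da1, 0);
  mat dz = da1 * P[pi.dec(0)].t();
  mat daz = dz % (1.0 - F.z % F.z);
  G[pi.enc(0)] = F.trunk_aug.t() * daz;
  G[pi.enc(1)] = sum(daz, 0);

  int H = c.H;
  // only the recurrent trunk slice of the head features backpropagates;
  // the window statistics are input-derived
  mat dhead = dreg0 * P[pi.reg(0)].t();
  mat du_aug = dlogits * P[pi.cls(0)].t() + dexc * P[pi.exc(0)].col(0).t() +
               daz * P[pi.enc(0)].t();
  mat du = du_aug.cols(0, 2 * H - 1) + dhead.cols(0, 2 * H - 1);

  mat dhf = du.cols(0, H - 1);
  mat dhb = du.cols(H, 2 * H - 1);

  mat dXtm(c.T * B, c.channels, fill::zeros);
  G[pi.lstm(0, 0)] = mat(size(P[pi.lstm(0, 0)]), fill::zeros);
  G[pi.lstm(0, 1)] = mat(size(P[pi.lstm(0, 1)]), fill::zeros);
  rowvec dbf(4 * H, fill::zeros), dbb(4 * H, fill::zeros);
  G[pi.lstm(1, 0)] = mat(size(P[pi.lstm(1, 0)]), fill::zeros);
  G[pi.lstm(1, 1)] = mat(size(P[pi.lstm(1, 1)]), fill::zeros);
  lstm_backward_dir(F.Xtm, B, P[pi.lstm(0, 0)], P[pi.lstm(0, 1)], false, F.lf,
                    dhf, G[pi.lstm(0, 0)], G[pi.lstm(0, 1)], dbf, dXtm);
  lstm_backward_dir(F.Xtm, B, P[pi.lstm(1, 0)], P[pi.lstm(1, 1)], true, F.lb,
                    dhb, G[pi.lstm(1, 0)], G[pi.lstm(1, 1)], dbb, dXtm);
  G[pi.lstm(0, 2)] = dbf;
  G[pi.lstm(1, 2)] = dbb;

  // scatter time-major gradients back to the flat layout
  int n_layers = pi.n_layers;
  mat dcur(B * c.T, c.channels, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < c.T; ++t) dcur.row(b * c.T + t) = dXtm.row(t * B + b);

  for (int l = n_layers - 1; l >= 0; --l) {
    // through dropout
    for (int b = 0; b < B; ++b)
      dcur.rows(b * c.T, (b + 1) * c.T - 1).each_row() %= F.conv.mask[l].row(b);
    // through ReLU
    dcur %= conv_to<mat>::from(F.conv.act[l] > 0.0);
    // through layer norm
    const mat& gam = P[pi.conv(l, 2)];
    mat dxhat = dcur.each_row() % gam.row(0);
    vec m1 = mean(dxhat, 1);
    vec m2 = mean(dxhat % F.conv.xhat[l], 1);
    mat dY = dxhat;
    dY.each_col() -= m1;
    dY -= F.conv.xhat[l].each_col() % m2;
    dY.each_col() %= F.conv.inv[l];
    G[pi.conv(l, 2)] = sum(dcur % F.conv.xhat[l], 0);
    G[pi.conv(l, 3)] = sum(dcur, 0);
    // through the convolution
    G[pi.conv(l, 0)] = F.conv.M[l].t() * dY;
    G[pi.conv(l, 1)] = sum(dY, 0);
    if (l > 0) {
      mat dM = dY * P[pi.conv(l, 0)].t();
      mat dX(B * c.T, F.conv.out[l - 1].n_cols, fill::zeros);
      col2im_acc(dM, B, c.T, c.K, c.dilations[l], dX);
      dcur = dX;
    }
  }
}

Targets gather_targets(const uvec& ycls_all, const mat& yreg_all,
                       const mat& yrec_all, const vec& yexc_all,
                       const uvec& idx) {
  Targets tg;
  tg.ycls = ycls_all.elem(idx);
  tg.yreg = yreg_all.rows(idx);
  tg.yrec = yrec_all.rows(idx);
  tg.yexc = yexc_all.elem(idx);
  return tg;
}

double eval_loss(const std::vector<mat>& P, const PIdx& pi, const NetConfig& c,
                 const cube& X, const uvec& ycls, const mat& yreg,
                 const mat& yrec, const vec& yexc, const vec& lw) {
  int N = X.n_slices > 0 ? X.n_rows : 0;
  if (N == 0) return NA_REAL;
  int chunk = 256;
  double total = 0.0;
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    uvec idx = regspace<uvec>(s, e - 1);
    mat X0 = gather_batch(X, idx, c.T, c.Cin);
    Forward F;
    net_forward(P, pi, c, X0, false, nullptr, F);
    Targets tg = gather_targets(ycls, yreg, yrec, yexc, idx);
    vec comp = loss_components(F, tg, c);
    total += dot(lw, comp) * (e - s);
  }
  return total / N;
}

}  // namespace

// [[Rcpp::export]]
List cpp_net_loss_grad(List params, arma::cube X, arma::uvec ycls,
                       arma::mat yreg, arma::mat yrec, arma::vec yexc,
                       List cfg, int dropout_seed = -1) {
  NetConfig c = read_config(cfg);
  PIdx pi{(int)c.dilations.size()};
  std::vector<mat> P = params_from_list(params);
  uvec idx = regspace<uvec>(0, X.n_rows - 1);
  mat X0 = gather_batch(X, idx, c.T, c.Cin);
  Forward F;
  std::mt19937 rng(dropout_seed >= 0 ? dropout_seed : 0);
  net_forward(P, pi, c, X0, dropout_seed >= 0, dropout_seed >= 0 ? &rng : nullptr, F);
  Targets tg{ycls, yreg, yrec, yexc};
  vec comp = loss_components(F, tg, c);
  vec lw = {c.lw_cls, c.lw_reg, c.lw_rec, c.lw_exc};
  std::vector<mat> G(pi.total());
  net_backward(P, pi, c, F, tg, G);
  Rcpp::CharacterVector names = params.attr("names");
  return List::create(
    Named("loss") = dot(lw, comp),
    Named("components") = Rcpp::NumericVector::create(
      Named("ce") = comp[0], Named("mse") = comp[1],
      Named("mae") = comp[2], Named("bce") = comp[3]),
    Named("grads") = params_to_list(G, names));
}

// [[Rcpp::export]]
List cpp_net_forward(List params, arma::cube X, List cfg,
                     bool return_conv = false) {
  NetConfig c = read_config(cfg);
  PIdx pi{(int)c.dilations.size()};
  std::vector<mat> P = params_from_list(params);
  int N = X.n_rows;
  mat probs(N, 4), reg(N, c.n_reg), recon(N, c.recon_dim),
      z(N, c.latent), trunk(N, 2 * c.H);
  vec exc(N);
  mat conv_out;
  if (return_conv) conv_out.set_size(N * c.T, c.channels);
  int chunk = 256;
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    uvec idx = regspace<uvec>(s, e - 1);
    mat X0 = gather_batch(X, idx, c.T, c.Cin);
    Forward F;
    net_forward(P, pi, c, X0, false, nullptr, F);
    probs.rows(s, e - 1) = F.probs;
    reg.rows(s, e - 1) = F.reg_pred;
    recon.rows(s, e - 1) = F.recon;
    z.rows(s, e - 1) = F.z;
    trunk.rows(s, e - 1) = F.trunk;
    exc.subvec(s, e - 1) = F.exc_prob;
    if (return_conv)
      conv_out.rows(s * c.T, e * c.T - 1) = F.conv.out[pi.n_layers - 1];
  }
  List out = List::create(
    Named("class_probs") = probs, Named("reg_pred") = reg,
    Named("recon") = recon, Named("z") = z, Named("trunk") = trunk,
    Named("excessive_prob") = exc);
  if (return_conv) out["conv_out"] = conv_out;
  return out;
}

// [[Rcpp::export]]
List cpp_net_train(List params, arma::cube X, arma::uvec ycls, arma::mat yreg,
                   arma::mat yrec, arma::vec yexc,
                   arma::cube Xval, arma::uvec ycls_val, arma::mat yreg_val,
                   arma::mat yrec_val, arma::vec yexc_val,
                   List cfg, int epochs, int batch_size, double lr,
                   double lr_decay, int patience, int seed,
                   bool verbose = false) {
  NetConfig c = read_config(cfg);
  PIdx pi{(int)c.dilations.size()};
  std::vector<mat> P = params_from_list(params);
  vec lw = {c.lw_cls, c.lw_reg, c.lw_rec, c.lw_exc};

  std::vector<mat> M(pi.total()), V(pi.total());
  for (int i = 0; i < pi.total(); ++i) {
    M[i] = mat(size(P[i]), fill::zeros);
    V[i] = mat(size(P[i]), fill::zeros);
  }
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  int N = X.n_rows;
  bool has_val = Xval.n_rows > 0;
  std::mt19937 rng(seed);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  std::vector<double> train_hist, val_hist;
  std::vector<mat> best = P;
  double best_val = datum::inf;
  int best_epoch = 0, bad = 0, ran = 0;
  bool stopped = false;

  for (int ep = 0; ep < epochs; ++ep) {
    double lr_ep = lr * std::pow(lr_decay, ep);
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    long n_seen = 0;
    for (int s = 0; s < N; s += batch_size) {
      int e = std::min(N, s + batch_size);
      uvec idx(e - s);
      for (int i = s; i < e; ++i) idx[i - s] = order[i];
      mat X0 = gather_batch(X, idx, c.T, c.Cin);
      Forward F;
      net_forward(P, pi, c, X0, true, &rng, F);
      Targets tg = gather_targets(ycls, yreg, yrec, yexc, idx);
      vec comp = loss_components(F, tg, c);
      double loss = dot(lw, comp);
      if (!std::isfinite(loss)) Rcpp::stop("Training diverged: non-finite loss.");
      std::vector<mat> G(pi.total());
      net_backward(P, pi, c, F, tg, G);
      ++step;
      double corr = lr_ep * std::sqrt(1.0 - std::pow(b2, (double)step)) /
                    (1.0 - std::pow(b1, (double)step));
      for (int i = 0; i < pi.total(); ++i) {
        M[i] = b1 * M[i] + (1.0 - b1) * G[i];
        V[i] = b2 * V[i] + (1.0 - b2) * (G[i] % G[i]);
        P[i] -= corr * M[i] / (sqrt(V[i]) + eps);
      }
      ep_loss += loss * (e - s);
      n_seen += (e - s);
    }
    ep_loss /= n_seen;
    train_hist.push_back(ep_loss);
    ran = ep + 1;

    double vl = NA_REAL;
    if (has_val) {
      vl = eval_loss(P, pi, c, Xval, ycls_val, yreg_val, yrec_val, yexc_val, lw);
      val_hist.push_back(vl);
      if (vl < best_val - 1e-9) {
        best_val = vl; best = P; best_epoch = ep + 1; bad = 0;
      } else if (++bad >= patience) {
        stopped = true;
      }
    } else {
      val_hist.push_back(NA_REAL);
      best = P; best_epoch = ep + 1;
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << " train " << ep_loss
                  << " val " << vl << std::endl;
    Rcpp::checkUserInterrupt();
    if (stopped) break;
  }

  Rcpp::CharacterVector names = params.attr("names");
  return List::create(
    Named("params") = params_to_list(best, names),
    Named("final_params") = params_to_list(P, names),
    Named("train_loss") = train_hist,
    Named("val_loss") = val_hist,
    Named("best_epoch") = best_epoch,
    Named("epochs_run") = ran,
    Named("stopped_early") = stopped);
}
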
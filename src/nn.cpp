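// CNN--Bi-LSTM per-sample sequence classifier: batched forward pass,
// backpropagation through time, and Adam training loop.
//
// Layout conventions
//   window input   : T x 1 voltages (one column per window in R)
//   conv layer l   : W (C_out x 3*C_in), b (C_out); kernel 3, stride 1,
//                    zero-padded centred alignment, ReLU
//   LSTM direction : Wx (4H x C), Wh (4H x H), b (4H); gate row blocks
//                    [input i; forget f; candidate g; output o];
//                    c_t = f*c_{t-1} + i*g, h_t = o*tanh(c_t); h0 = c0 = 0
//   dense head     : W (K x 2H), b (K); per-timestep softmax over K classes
//
// All arithmetic is single precision; matrix products go through BLAS.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::fmat;
using arma::fcube;
using arma::fvec;

static fmat as_fmat(SEXP m) {
  NumericMatrix nm(m);
  fmat out(nm.nrow(), nm.ncol());
  for (int j = 0; j < nm.ncol(); ++j)
    for (int i = 0; i < nm.nrow(); ++i)
      out(i, j) = static_cast<float>(nm(i, j));
  return out;
}

static NumericMatrix as_rmat(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i)
      out(i, j) = m(i, j);
  return out;
}

struct NNParams {
  std::vector<fmat> conv_W, conv_b;       // per conv layer
  fmat Wx_f, Wh_f, b_f, Wx_b, Wh_b, b_b;  // two LSTM directions
  fmat Wd, bd;                            // dense head
  int H() const { return Wx_f.n_rows / 4; }
  int K() const { return Wd.n_rows; }
};

static NNParams unpack(const List& params) {
  NNParams p;
  List cW = params["conv_W"], cb = params["conv_b"];
  for (int l = 0; l < cW.size(); ++l) {
    p.conv_W.push_back(as_fmat(cW[l]));
    p.conv_b.push_back(as_fmat(cb[l]));
  }
  p.Wx_f = as_fmat(params["Wx_f"]); p.Wh_f = as_fmat(params["Wh_f"]);
  p.b_f = as_fmat(params["b_f"]);
  p.Wx_b = as_fmat(params["Wx_b"]); p.Wh_b = as_fmat(params["Wh_b"]);
  p.b_b = as_fmat(params["b_b"]);
  p.Wd = as_fmat(params["Wd"]); p.bd = as_fmat(params["bd"]);
  return p;
}

static List pack(const NNParams& p) {
  List cW(p.conv_W.size()), cb(p.conv_b.size());
  for (size_t l = 0; l < p.conv_W.size(); ++l) {
    cW[l] = as_rmat(p.conv_W[l]);
    cb[l] = as_rmat(p.conv_b[l]);
  }
  return List::create(
    _["conv_W"] = cW, _["conv_b"] = cb,
    _["Wx_f"] = as_rmat(p.Wx_f), _["Wh_f"] = as_rmat(p.Wh_f),
    _["b_f"] = as_rmat(p.b_f),
    _["Wx_b"] = as_rmat(p.Wx_b), _["Wh_b"] = as_rmat(p.Wh_b),
    _["b_b"] = as_rmat(p.b_b),
    _["Wd"] = as_rmat(p.Wd), _["bd"] = as_rmat(p.bd));
}

// centred kernel-3 im2col with zero borders: rows [t-1; t; t+1]
static fmat im2col3(const fmat& A) {
  const arma::uword C = A.n_rows, T = A.n_cols;
  fmat out(3 * C, T, arma::fill::zeros);
  if (T > 1) {
    out.submat(0, 1, C - 1, T - 1) = A.cols(0, T - 2);
    out.submat(2 * C, 0, 3 * C - 1, T - 2) = A.cols(1, T - 1);
  }
  out.rows(C, 2 * C - 1) = A;
  return out;
}

static inline fmat sigmoidf(const fmat& x) { return 1.0f / (1.0f + arma::exp(-x)); }

// conv stack forward for one window; optionally keep pre-activation
// column stacks for backprop
static fmat conv_forward(const NNParams& p, const fmat& x0,
                         std::vector<fmat>* cols, std::vector<fmat>* acts) {
  fmat A = x0;  // (C x T)
  for (size_t l = 0; l < p.conv_W.size(); ++l) {
    fmat Acol = im2col3(A);
    fmat Z = p.conv_W[l] * Acol;
    Z.each_col() += fvec(p.conv_b[l].col(0));
    A = arma::clamp(Z, 0.0f, std::numeric_limits<float>::max());
    if (cols) cols->push_back(std::move(Acol));
    if (acts) acts->push_back(A);
  }
  return A;
}

struct LstmCache {
  fcube gates;   // 4H x B x T (post-activation)
  fcube cst;     // H x B x T
  fcube tanhc;   // H x B x T
  fcube h;       // H x B x T
};

// one direction over a batch; Xt: C x B x T; reverse = backward pass
static void lstm_forward(const fmat& Wx, const fmat& Wh, const fmat& b,
                         const fcube& Xt, bool reverse, LstmCache& cc) {
  const int C = Xt.n_rows, B = Xt.n_cols, T = Xt.n_slices;
  (void)C;
  const int H = Wx.n_rows / 4;
  cc.gates.set_size(4 * H, B, T);
  cc.cst.set_size(H, B, T);
  cc.tanhc.set_size(H, B, T);
  cc.h.set_size(H, B, T);
  fmat h_prev(H, B, arma::fill::zeros), c_prev(H, B, arma::fill::zeros);
  fvec bias = b.col(0);
  for (int s = 0; s < T; ++s) {
    int t = reverse ? (T - 1 - s) : s;
    fmat G = Wx * Xt.slice(t) + Wh * h_prev;
    G.each_col() += bias;
    fmat i = sigmoidf(G.rows(0, H - 1));
    fmat f = sigmoidf(G.rows(H, 2 * H - 1));
    fmat g = arma::tanh(G.rows(2 * H, 3 * H - 1));
    fmat o = sigmoidf(G.rows(3 * H, 4 * H - 1));
    fmat c = f % c_prev + i % g;
    fmat tc = arma::tanh(c);
    fmat h = o % tc;
    cc.gates.slice(t).rows(0, H - 1) = i;
    cc.gates.slice(t).rows(H, 2 * H - 1) = f;
    cc.gates.slice(t).rows(2 * H, 3 * H - 1) = g;
    cc.gates.slice(t).rows(3 * H, 4 * H - 1) = o;
    cc.cst.slice(t) = c;
    cc.tanhc.slice(t) = tc;
    cc.h.slice(t) = h;
    h_prev = std::move(h);
    c_prev = std::move(c);
  }
}

struct LstmGrads { fmat gWx, gWh, gb; };

// BPTT for one direction; dH: upstream dL/dh (H x B x T); adds input
// gradient into dXt
static void lstm_backward(const fmat& Wx, const fmat& Wh,
                          const fcube& Xt, const LstmCache& cc,
                          const fcube& dH, bool reverse,
                          LstmGrads& gr, fcube& dXt) {
  const int B = Xt.n_cols, T = Xt.n_slices;
  const int H = Wx.n_rows / 4;
  gr.gWx.zeros(Wx.n_rows, Wx.n_cols);
  gr.gWh.zeros(Wh.n_rows, Wh.n_cols);
  gr.gb.zeros(4 * H, 1);
  fmat dh_carry(H, B, arma::fill::zeros), dc_carry(H, B, arma::fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    int t = reverse ? (T - 1 - s) : s;
    bool first = (s == 0);
    int t_prev = reverse ? (t + 1) : (t - 1);
    const fmat i = cc.gates.slice(t).rows(0, H - 1);
    const fmat f = cc.gates.slice(t).rows(H, 2 * H - 1);
    const fmat g = cc.gates.slice(t).rows(2 * H, 3 * H - 1);
    const fmat o = cc.gates.slice(t).rows(3 * H, 4 * H - 1);
    const fmat& tc = cc.tanhc.slice(t);
    fmat h_prev = first ? fmat(H, B, arma::fill::zeros)
                        : fmat(cc.h.slice(t_prev));
    fmat c_prev = first ? fmat(H, B, arma::fill::zeros)
                        : fmat(cc.cst.slice(t_prev));
    fmat dh = dH.slice(t) + dh_carry;
    fmat dto = dh % tc;
    fmat dc = dc_carry + dh % o % (1.0f - tc % tc);
    fmat dG(4 * H, B);
    dG.rows(0, H - 1) = (dc % g) % i % (1.0f - i);
    dG.rows(H, 2 * H - 1) = (dc % c_prev) % f % (1.0f - f);
    dG.rows(2 * H, 3 * H - 1) = (dc % i) % (1.0f - g % g);
    dG.rows(3 * H, 4 * H - 1) = dto % o % (1.0f - o);
    gr.gWx += dG * Xt.slice(t).t();
    gr.gWh += dG * h_prev.t();
    gr.gb += arma::sum(dG, 1);
    dh_carry = Wh.t() * dG;
    dc_carry = dc % f;
    dXt.slice(t) += Wx.t() * dG;
  }
}

// full forward for a batch; returns probability cube (K x B x T) and
// fills caches when training
struct BatchCache {
  std::vector<std::vector<fmat>> cols;  // [window][layer] im2col stacks
  std::vector<std::vector<fmat>> acts;  // [window][layer] post-ReLU
  fcube Xt;                             // C x B x T conv features
  LstmCache fwd, bwd;
  fcube Hcat;                           // 2H x B x T
};

static fcube batch_forward(const NNParams& p, const fmat& X,
                           const arma::uvec& idx, BatchCache* cache) {
  const int T = X.n_rows, B = idx.n_elem;
  const int H = p.H(), K = p.K();
  const int C = p.conv_W.empty()
    ? 1 : p.conv_W.back().n_rows;
  fcube Xt(C, B, T);
  std::vector<std::vector<fmat>> cols(B), acts(B);
  for (int b = 0; b < B; ++b) {
    fmat x0(1, T);
    for (int t = 0; t < T; ++t) x0(0, t) = X(t, idx[b]);
    fmat feat = p.conv_W.empty()
      ? x0
      : conv_forward(p, x0, cache ? &cols[b] : nullptr,
                     cache ? &acts[b] : nullptr);
    for (int t = 0; t < T; ++t) Xt.slice(t).col(b) = feat.col(t);
  }
  LstmCache fwd, bwd;
  lstm_forward(p.Wx_f, p.Wh_f, p.b_f, Xt, false, fwd);
  lstm_forward(p.Wx_b, p.Wh_b, p.b_b, Xt, true, bwd);
  fcube Hcat(2 * H, B, T);
  for (int t = 0; t < T; ++t) {
    Hcat.slice(t).rows(0, H - 1) = fwd.h.slice(t);
    Hcat.slice(t).rows(H, 2 * H - 1) = bwd.h.slice(t);
  }
  fcube P(K, B, T);
  fvec bd = p.bd.col(0);
  for (int t = 0; t < T; ++t) {
    fmat Z = p.Wd * Hcat.slice(t);
    Z.each_col() += bd;
    Z.each_row() -= arma::max(Z, 0);
    fmat E = arma::exp(Z);
    E.each_row() /= arma::sum(E, 0);
    P.slice(t) = E;
  }
  if (cache) {
    cache->cols = std::move(cols);
    cache->acts = std::move(acts);
    cache->Xt = std::move(Xt);
    cache->fwd = std::move(fwd);
    cache->bwd = std::move(bwd);
    cache->Hcat = std::move(Hcat);
  }
  return P;
}

// [[Rcpp::export]]
NumericVector cpp_nn_forward(List params, NumericMatrix X) {
  NNParams p = unpack(params);
  fmat Xf = as_fmat(X);
  const int T = Xf.n_rows, N = Xf.n_cols, K = p.K();
  arma::uvec idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  fcube P = batch_forward(p, Xf, idx, nullptr);
  NumericVector out(K * N * T);
  out.attr("dim") = IntegerVector::create(K, N, T);
  for (int t = 0; t < T; ++t)
    for (int b = 0; b < N; ++b)
      for (int k = 0; k < K; ++k)
        out[k + K * (b + (size_t)N * t)] = P(k, b, t);
  return out;
}

// per-layer outputs for a single window (architecture inspection and
// small-model equivalence checks)
// [[Rcpp::export]]
List cpp_nn_forward_layers(List params, NumericVector x) {
  NNParams p = unpack(params);
  const int T = x.size();
  fmat x0(1, T);
  for (int t = 0; t < T; ++t) x0(0, t) = static_cast<float>(x[t]);
  List out;
  std::vector<fmat> acts;
  fmat feat = p.conv_W.empty() ? x0 : conv_forward(p, x0, nullptr, &acts);
  for (size_t l = 0; l < acts.size(); ++l)
    out.push_back(as_rmat(acts[l]), std::string("conv") + std::to_string(l + 1));
  const int H = p.H(), B = 1;
  fcube Xt(feat.n_rows, B, T);
  for (int t = 0; t < T; ++t) Xt.slice(t).col(0) = feat.col(t);
  LstmCache fwd, bwd;
  lstm_forward(p.Wx_f, p.Wh_f, p.b_f, Xt, false, fwd);
  lstm_forward(p.Wx_b, p.Wh_b, p.b_b, Xt, true, bwd);
  fmat Hcat(2 * H, T);
  for (int t = 0; t < T; ++t) {
    Hcat.submat(0, t, H - 1, t) = fwd.h.slice(t).col(0);
    Hcat.submat(H, t, 2 * H - 1, t) = bwd.h.slice(t).col(0);
  }
  out.push_back(as_rmat(Hcat), "bilstm");
  fmat Z = p.Wd * Hcat;
  Z.each_col() += fvec(p.bd.col(0));
  Z.each_row() -= arma::max(Z, 0);
  fmat E = arma::exp(Z);
  E.each_row() /= arma::sum(E, 0);
  out.push_back(as_rmat(E), "probs");
  return out;
}

// analytic gradient of the mean per-node cross-entropy over all windows
// (exposed for finite-difference verification)
// [[Rcpp::export]]
List cpp_nn_grad(List params, NumericMatrix X, IntegerMatrix Y) {
  NNParams p = unpack(params);
  fmat Xf = as_fmat(X);
  const int T = Xf.n_rows, N = Xf.n_cols;
  const int K = p.K(), H = p.H();
  const size_t Lc = p.conv_W.size();
  arma::uvec idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  BatchCache cc;
  fcube P = batch_forward(p, Xf, idx, &cc);
  const int B = N;
  float scale = 1.0f / (float)(T * B);
  double loss = 0.0;
  fcube dZ = P;
  for (int t = 0; t < T; ++t)
    for (int b = 0; b < B; ++b) {
      int y = Y(t, b);
      loss += -std::log((double)std::max(P(y, b, t), 1e-12f));
      dZ(y, b, t) -= 1.0f;
    }
  dZ *= scale;
  fmat gWd(K, 2 * H, arma::fill::zeros), gbd(K, 1, arma::fill::zeros);
  fcube dHf(H, B, T), dHb(H, B, T);
  for (int t = 0; t < T; ++t) {
    gWd += dZ.slice(t) * cc.Hcat.slice(t).t();
    gbd += arma::sum(dZ.slice(t), 1);
    fmat dHcat = p.Wd.t() * dZ.slice(t);
    dHf.slice(t) = dHcat.rows(0, H - 1);
    dHb.slice(t) = dHcat.rows(H, 2 * H - 1);
  }
  const int C = cc.Xt.n_rows;
  fcube dXt(C, B, T, arma::fill::zeros);
  LstmGrads gf, gb2;
  lstm_backward(p.Wx_f, p.Wh_f, cc.Xt, cc.fwd, dHf, false, gf, dXt);
  lstm_backward(p.Wx_b, p.Wh_b, cc.Xt, cc.bwd, dHb, true, gb2, dXt);
  List gcWr(Lc), gcbr(Lc);
  if (Lc > 0) {
    std::vector<fmat> gcW(Lc), gcb(Lc);
    for (size_t l = 0; l < Lc; ++l) {
      gcW[l].zeros(p.conv_W[l].n_rows, p.conv_W[l].n_cols);
      gcb[l].zeros(p.conv_b[l].n_rows, 1);
    }
    for (int b = 0; b < B; ++b) {
      fmat dA(C, T);
      for (int t = 0; t < T; ++t) dA.col(t) = dXt.slice(t).col(b);
      for (int l = (int)Lc - 1; l >= 0; --l) {
        const fmat& A = cc.acts[b][l];
        fmat dZc = dA % arma::conv_to<fmat>::from(A > 0.0f);
        gcW[l] += dZc * cc.cols[b][l].t();
        gcb[l] += arma::sum(dZc, 1);
        if (l > 0) {
          fmat dCol = p.conv_W[l].t() * dZc;
          const arma::uword Cin = p.conv_W[l].n_cols / 3;
          dA = dCol.rows(Cin, 2 * Cin - 1);
          dA.cols(0, T - 2) += dCol.submat(0, 1, Cin - 1, T - 1);
          dA.cols(1, T - 1) += dCol.submat(2 * Cin, 0, 3 * Cin - 1, T - 2);
        }
      }
    }
    for (size_t l = 0; l < Lc; ++l) {
      gcWr[l] = as_rmat(gcW[l]);
      gcbr[l] = as_rmat(gcb[l]);
    }
  }
  return List::create(
    _["loss"] = loss / (double)(T * B),
    _["conv_W"] = gcWr, _["conv_b"] = gcbr,
    _["Wx_f"] = as_rmat(gf.gWx), _["Wh_f"] = as_rmat(gf.gWh),
    _["b_f"] = as_rmat(gf.gb),
    _["Wx_b"] = as_rmat(gb2.gWx), _["Wh_b"] = as_rmat(gb2.gWh),
    _["b_b"] = as_rmat(gb2.gb),
    _["Wd"] = as_rmat(gWd), _["bd"] = as_rmat(gbd));
}

struct Adam {
  std::vector<fmat> m, v;
  double b1, b2, eps;
  long step = 0;
  void init(const std::vector<fmat*>& ps, double b1_, double b2_, double eps_) {
    b1 = b1_; b2 = b2_; eps = eps_;
    for (auto* p : ps) {
      m.emplace_back(p->n_rows, p->n_cols, arma::fill::zeros);
      v.emplace_back(p->n_rows, p->n_cols, arma::fill::zeros);
    }
  }
  void update(std::vector<fmat*>& ps, const std::vector<fmat*>& gs, double lr) {
    ++step;
    float c1 = 1.0f - std::pow((float)b1, (float)step);
    float c2 = 1.0f - std::pow((float)b2, (float)step);
    for (size_t i = 0; i < ps.size(); ++i) {
      m[i] = (float)b1 * m[i] + (1.0f - (float)b1) * (*gs[i]);
      v[i] = (float)b2 * v[i] + (1.0f - (float)b2) * arma::square(*gs[i]);
      *ps[i] -= (float)lr * (m[i] / c1) / (arma::sqrt(v[i] / c2) + (float)eps);
    }
  }
};

// [[Rcpp::export]]
List cpp_nn_train(List params, NumericMatrix X, IntegerMatrix Y,
                  IntegerMatrix order, int batch_size, double lr,
                  double beta1, double beta2, double eps) {
  NNParams p = unpack(params);
  fmat Xf = as_fmat(X);
  const int T = Xf.n_rows, N = Xf.n_cols;
  const int K = p.K(), H = p.H();
  const int epochs = order.ncol();
  const size_t Lc = p.conv_W.size();

  std::vector<fmat*> pvec;
  for (size_t l = 0; l < Lc; ++l) pvec.push_back(&p.conv_W[l]);
  for (size_t l = 0; l < Lc; ++l) pvec.push_back(&p.conv_b[l]);
  pvec.push_back(&p.Wx_f); pvec.push_back(&p.Wh_f); pvec.push_back(&p.b_f);
  pvec.push_back(&p.Wx_b); pvec.push_back(&p.Wh_b); pvec.push_back(&p.b_b);
  pvec.push_back(&p.Wd); pvec.push_back(&p.bd);
  Adam adam;
  adam.init(pvec, beta1, beta2, eps);

  NumericVector loss_hist(epochs), acc_hist(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    long ep_correct = 0, ep_nodes = 0;
    for (int off = 0; off < N; off += batch_size) {
      int B = std::min(batch_size, N - off);
      arma::uvec idx(B);
      for (int b = 0; b < B; ++b) idx[b] = order(off + b, ep);
      BatchCache cc;
      fcube P = batch_forward(p, Xf, idx, &cc);

      // loss, accuracy, and dL/dZ of the softmax head
      float scale = 1.0f / (float)(T * B);
      fcube dZ = P;  // copy
      for (int t = 0; t < T; ++t) {
        const fmat& Pt = P.slice(t);
        for (int b = 0; b < B; ++b) {
          int y = Y(t, idx[b]);
          float py = std::max(Pt(y, b), 1e-12f);
          ep_loss += -std::log((double)py);
          dZ(y, b, t) -= 1.0f;
          int am = 0;
          float best = Pt(0, b);
          for (int k = 1; k < K; ++k)
            if (Pt(k, b) > best) { best = Pt(k, b); am = k; }
          if (am == y) ++ep_correct;
          ++ep_nodes;
        }
      }
      dZ *= scale;
      if (!std::isfinite(ep_loss))
        stop("non-finite training loss (diverged); reduce the learning rate");

      // dense backward
      fmat gWd(K, 2 * H, arma::fill::zeros);
      fmat gbd(K, 1, arma::fill::zeros);
      fcube dHcat(2 * H, B, T);
      for (int t = 0; t < T; ++t) {
        gWd += dZ.slice(t) * cc.Hcat.slice(t).t();
        gbd += arma::sum(dZ.slice(t), 1);
        dHcat.slice(t) = p.Wd.t() * dZ.slice(t);
      }
      fcube dHf(H, B, T), dHb(H, B, T);
      for (int t = 0; t < T; ++t) {
        dHf.slice(t) = dHcat.slice(t).rows(0, H - 1);
        dHb.slice(t) = dHcat.slice(t).rows(H, 2 * H - 1);
      }

      // LSTM backward, both directions
      const int C = cc.Xt.n_rows;
      fcube dXt(C, B, T, arma::fill::zeros);
      LstmGrads gf, gb2;
      lstm_backward(p.Wx_f, p.Wh_f, cc.Xt, cc.fwd, dHf, false, gf, dXt);
      lstm_backward(p.Wx_b, p.Wh_b, cc.Xt, cc.bwd, dHb, true, gb2, dXt);

      // conv backward per window
      std::vector<fmat> gcW(Lc), gcb(Lc);
      for (size_t l = 0; l < Lc; ++l) {
        gcW[l].zeros(p.conv_W[l].n_rows, p.conv_W[l].n_cols);
        gcb[l].zeros(p.conv_b[l].n_rows, 1);
      }
      if (Lc > 0) {
        for (int b = 0; b < B; ++b) {
          fmat dA(C, T);
          for (int t = 0; t < T; ++t) dA.col(t) = dXt.slice(t).col(b);
          for (int l = (int)Lc - 1; l >= 0; --l) {
            const fmat& A = cc.acts[b][l];       // post-ReLU output
            fmat dZc = dA % arma::conv_to<fmat>::from(A > 0.0f);
            gcW[l] += dZc * cc.cols[b][l].t();
            gcb[l] += arma::sum(dZc, 1);
            if (l > 0) {
              fmat dCol = p.conv_W[l].t() * dZc;  // 3*C_in x T
              const arma::uword Cin = p.conv_W[l].n_cols / 3;
              dA.set_size(Cin, T);
              dA = dCol.rows(Cin, 2 * Cin - 1);
              dA.cols(0, T - 2) += dCol.submat(0, 1, Cin - 1, T - 1);
              dA.cols(1, T - 1) += dCol.submat(2 * Cin, 0, 3 * Cin - 1, T - 2);
            }
          }
        }
      }

      std::vector<fmat*> gvec;
      for (size_t l = 0; l < Lc; ++l) gvec.push_back(&gcW[l]);
      for (size_t l = 0; l < Lc; ++l) gvec.push_back(&gcb[l]);
      gvec.push_back(&gf.gWx); gvec.push_back(&gf.gWh); gvec.push_back(&gf.gb);
      gvec.push_back(&gb2.gWx); gvec.push_back(&gb2.gWh); gvec.push_back(&gb2.gb);
      gvec.push_back(&gWd); gvec.push_back(&gbd);
      adam.update(pvec, gvec, lr);
      Rcpp::checkUserInterrupt();
    }
    loss_hist[ep] = ep_loss / (double)ep_nodes;
    acc_hist[ep] = (double)ep_correct / (double)ep_nodes;
  }

  return List::create(_["params"] = pack(p), _["loss"] = loss_hist,
                      _["accuracy"] = acc_hist);
}
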
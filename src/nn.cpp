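// Minimal sequential neural-network engine used by the GAN and the
// convolutional recurrent classifier.  Batches are (C*H*W) x B matrices,
// flattened channel-fastest: element (c,h,w) sits at row c + C*(h + H*w).
// Gradients accumulate into per-layer buffers; Adam state lives in the Net
// and is allocated lazily so forward-only use of very large nets (the
// full-size generator) never touches optimiser memory.
#include <RcppArmadillo.h>
#include <memory>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Shape {
  int c, h, w;
  int size() const { return c * h * w; }
  std::string str() const {
    return "(" + std::to_string(c) + "," + std::to_string(h) + "," +
           std::to_string(w) + ")";
  }
};

static int conv_out(int in, int k, int s, int p) {
  int o = (in + 2 * p - k) / s + 1;
  return o;
}
static int convt_out(int in, int k, int s, int p, int op) {
  return (in - 1) * s + k - 2 * p + op;
}

class Layer {
 public:
  virtual ~Layer() {}
  virtual Shape configure(Shape in) = 0;  // set shapes, may throw
  virtual mat forward(const mat& X, bool training) = 0;
  virtual mat backward(const mat& G) = 0;
  virtual void init(std::mt19937_64&) {}
  virtual std::vector<mat*> params() { return {}; }
  virtual std::vector<mat*> grads() { return {}; }
  virtual void zero_grads() {
    for (mat* g : grads())
      if (g->n_elem) g->zeros();
  }
  Shape in_shape, out_shape;
};

static void he_normal(mat& W, double fan_in, std::mt19937_64& rng) {
  std::normal_distribution<double> N(0.0, std::sqrt(2.0 / fan_in));
  for (uword i = 0; i < W.n_elem; ++i) W[i] = N(rng);
}

class Dense : public Layer {
 public:
  explicit Dense(int out) : n_out(out) {}
  Shape configure(Shape in) override {
    in_shape = in;
    n_in = in.size();
    W.set_size(n_out, n_in);
    b.zeros(n_out, 1);
    out_shape = {n_out, 1, 1};
    return out_shape;
  }
  void init(std::mt19937_64& rng) override { he_normal(W, n_in, rng); b.zeros(); }
  mat forward(const mat& X, bool) override {
    Xc = X;
    mat Y = W * X;
    Y.each_col() += b.col(0);
    return Y;
  }
  mat backward(const mat& G) override {
    ensure_grads();
    dW += G * Xc.t();
    db += sum(G, 1);
    return W.t() * G;
  }
  void ensure_grads() {
    if (dW.n_elem == 0) { dW.zeros(size(W)); db.zeros(size(b)); }
  }
  std::vector<mat*> params() override { return {&W, &b}; }
  std::vector<mat*> grads() override { return {&dW, &db}; }
  int n_in = 0, n_out;
  mat W, b, dW, db, Xc;
};

class Reshape : public Layer {
 public:
  Reshape(int c, int h, int w) : tgt{c, h, w} {}
  Shape configure(Shape in) override {
    in_shape = in;
    if (in.size() != tgt.size())
      Rcpp::stop("reshape: cannot map %s (size %d) to %s (size %d)",
                 in.str().c_str(), in.size(), tgt.str().c_str(), tgt.size());
    out_shape = tgt;
    return out_shape;
  }
  mat forward(const mat& X, bool) override { return X; }
  mat backward(const mat& G) override { return G; }
  Shape tgt;
};

class LeakyReLU : public Layer {
 public:
  explicit LeakyReLU(double s) : slope(s) {}
  Shape configure(Shape in) override { in_shape = out_shape = in; return in; }
  mat forward(const mat& X, bool) override {
    pos = conv_to<mat>::from(X > 0);
    return X % (pos + slope * (1.0 - pos));
  }
  mat backward(const mat& G) override {
    return G % (pos + slope * (1.0 - pos));
  }
  double slope;
  mat pos;
};

class Dropout : public Layer {
 public:
  Dropout(double p, std::mt19937_64* rng) : p(p), rng(rng) {}
  Shape configure(Shape in) override { in_shape = out_shape = in; return in; }
  mat forward(const mat& X, bool training) override {
    if (!training || p <= 0) { active = false; return X; }
    active = true;
    std::uniform_real_distribution<double> U(0.0, 1.0);
    mask.set_size(X.n_rows, X.n_cols);
    double keep = 1.0 - p;
    for (uword i = 0; i < mask.n_elem; ++i)
      mask[i] = (U(*rng) < keep) ? 1.0 / keep : 0.0;
    return X % mask;
  }
  mat backward(const mat& G) override { return active ? mat(G % mask) : G; }
  double p;
  std::mt19937_64* rng;
  mat mask;
  bool active = false;
};

class Conv2d : public Layer {
 public:
  Conv2d(int co, int kh, int kw, int sh, int sw, int ph, int pw)
      : co(co), kh(kh), kw(kw), sh(sh), sw(sw), ph(ph), pw(pw) {}
  Shape configure(Shape in) override {
    in_shape = in;
    oh = conv_out(in.h, kh, sh, ph);
    ow = conv_out(in.w, kw, sw, pw);
    if (oh < 1 || ow < 1)
      Rcpp::stop("conv: kernel (%d,%d) stride (%d,%d) pad (%d,%d) on input %s gives empty output (%d,%d)",
                 kh, kw, sh, sw, ph, pw, in.str().c_str(), oh, ow);
    W.set_size(co, in.c * kh * kw);
    b.zeros(co, 1);
    out_shape = {co, oh, ow};
    return out_shape;
  }
  void init(std::mt19937_64& rng) override {
    he_normal(W, in_shape.c * kh * kw, rng);
    b.zeros();
  }
  void im2col(const double* x, mat& P) const {
    const int C = in_shape.c, H = in_shape.h, Wd = in_shape.w;
    P.zeros(C * kh * kw, oh * ow);
    for (int wo = 0; wo < ow; ++wo) {
      for (int ho = 0; ho < oh; ++ho) {
        const int col = ho + oh * wo;
        for (int j = 0; j < kw; ++j) {
          const int wi = wo * sw + j - pw;
          if (wi < 0 || wi >= Wd) continue;
          for (int i = 0; i < kh; ++i) {
            const int hi = ho * sh + i - ph;
            if (hi < 0 || hi >= H) continue;
            std::copy(x + C * (hi + H * wi), x + C * (hi + H * wi) + C,
                      P.colptr(col) + C * (i + kh * j));
          }
        }
      }
    }
  }
  void col2im_add(const mat& P, double* x) const {
    const int C = in_shape.c, H = in_shape.h, Wd = in_shape.w;
    for (int wo = 0; wo < ow; ++wo) {
      for (int ho = 0; ho < oh; ++ho) {
        const int col = ho + oh * wo;
        for (int j = 0; j < kw; ++j) {
          const int wi = wo * sw + j - pw;
          if (wi < 0 || wi >= Wd) continue;
          for (int i = 0; i < kh; ++i) {
            const int hi = ho * sh + i - ph;
            if (hi < 0 || hi >= H) continue;
            const double* src = P.colptr(col) + C * (i + kh * j);
            double* dst = x + C * (hi + H * wi);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  mat forward(const mat& X, bool) override {
    Xc = X;
    const int B = X.n_cols;
    mat Y(co * oh * ow, B);
    mat P;
    for (int s = 0; s < B; ++s) {
      im2col(X.colptr(s), P);
      mat Ys = W * P;  // co x (oh*ow)
      Ys.each_col() += b.col(0);
      // reorder: element (c,ho,wo) -> row c + co*(ho + oh*wo); Ys is co x pos
      std::copy(Ys.memptr(), Ys.memptr() + Ys.n_elem, Y.colptr(s));
    }
    return Y;
  }
  mat backward(const mat& G) override {
    if (dW.n_elem == 0) { dW.zeros(size(W)); db.zeros(size(b)); }
    const int B = Xc.n_cols;
    mat dX(in_shape.size(), B, fill::zeros);
    mat P;
    for (int s = 0; s < B; ++s) {
      im2col(Xc.colptr(s), P);
      mat Gs(const_cast<double*>(G.colptr(s)), co, oh * ow, false, true);
      dW += Gs * P.t();
      db += sum(Gs, 1);
      mat dP = W.t() * Gs;
      col2im_add(dP, dX.colptr(s));
    }
    return dX;
  }
  std::vector<mat*> params() override { return {&W, &b}; }
  std::vector<mat*> grads() override { return {&dW, &db}; }
  int co, kh, kw, sh, sw, ph, pw, oh = 0, ow = 0;
  mat W, b, dW, db, Xc;
};

class ConvTranspose2d : public Layer {
 public:
  ConvTranspose2d(int co, int kh, int kw, int sh, int sw, int ph, int pw,
                  int oph, int opw)
      : co(co), kh(kh), kw(kw), sh(sh), sw(sw), ph(ph), pw(pw), oph(oph),
        opw(opw) {}
  Shape configure(Shape in) override {
    in_shape = in;
    oh = convt_out(in.h, kh, sh, ph, oph);
    ow = convt_out(in.w, kw, sw, pw, opw);
    if (oh < 1 || ow < 1)
      Rcpp::stop("convtranspose: kernel (%d,%d) stride (%d,%d) pad (%d,%d) on input %s gives empty output (%d,%d)",
                 kh, kw, sh, sw, ph, pw, in.str().c_str(), oh, ow);
    W.set_size(in.c, co * kh * kw);
    b.zeros(co, 1);
    out_shape = {co, oh, ow};
    return out_shape;
  }
  void init(std::mt19937_64& rng) override {
    he_normal(W, in_shape.c, rng);
    b.zeros();
  }
  // scatter cols (co*kh*kw x H*W positions) into output
  void scatter(const mat& cols, double* y) const {
    const int H = in_shape.h, Wd = in_shape.w;
    for (int wi = 0; wi < Wd; ++wi) {
      for (int hi = 0; hi < H; ++hi) {
        const int col = hi + H * wi;
        for (int j = 0; j < kw; ++j) {
          const int wo = wi * sw + j - pw;
          if (wo < 0 || wo >= ow) continue;
          for (int i = 0; i < kh; ++i) {
            const int ho = hi * sh + i - ph;
            if (ho < 0 || ho >= oh) continue;
            const double* src = cols.colptr(col) + co * (i + kh * j);
            double* dst = y + co * (ho + oh * wo);
            for (int c = 0; c < co; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  void gather(const double* g, mat& cols) const {
    const int H = in_shape.h, Wd = in_shape.w;
    cols.zeros(co * kh * kw, H * Wd);
    for (int wi = 0; wi < Wd; ++wi) {
      for (int hi = 0; hi < H; ++hi) {
        const int col = hi + H * wi;
        for (int j = 0; j < kw; ++j) {
          const int wo = wi * sw + j - pw;
          if (wo < 0 || wo >= ow) continue;
          for (int i = 0; i < kh; ++i) {
            const int ho = hi * sh + i - ph;
            if (ho < 0 || ho >= oh) continue;
            const double* src = g + co * (ho + oh * wo);
            double* dst = cols.colptr(col) + co * (i + kh * j);
            for (int c = 0; c < co; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  mat forward(const mat& X, bool) override {
    Xc = X;
    const int B = X.n_cols;
    mat Y(co * oh * ow, B, fill::zeros);
    for (int s = 0; s < B; ++s) {
      mat Xs(const_cast<double*>(X.colptr(s)), in_shape.c,
             in_shape.h * in_shape.w, false, true);
      mat cols = W.t() * Xs;
      scatter(cols, Y.colptr(s));
      // bias per output channel
      double* y = Y.colptr(s);
      for (int p = 0; p < oh * ow; ++p)
        for (int c = 0; c < co; ++c) y[c + co * p] += b(c, 0);
    }
    return Y;
  }
  mat backward(const mat& G) override {
    if (dW.n_elem == 0) { dW.zeros(size(W)); db.zeros(size(b)); }
    const int B = Xc.n_cols;
    mat dX(in_shape.size(), B);
    mat cols;
    for (int s = 0; s < B; ++s) {
      gather(G.colptr(s), cols);
      mat Xs(const_cast<double*>(Xc.colptr(s)), in_shape.c,
             in_shape.h * in_shape.w, false, true);
      dW += Xs * cols.t();
      const double* g = G.colptr(s);
      for (int p = 0; p < oh * ow; ++p)
        for (int c = 0; c < co; ++c) db(c, 0) += g[c + co * p];
      mat dXs = W * cols;
      std::copy(dXs.memptr(), dXs.memptr() + dXs.n_elem, dX.colptr(s));
    }
    return dX;
  }
  std::vector<mat*> params() override { return {&W, &b}; }
  std::vector<mat*> grads() override { return {&dW, &db}; }
  int co, kh, kw, sh, sw, ph, pw, oph, opw, oh = 0, ow = 0;
  mat W, b, dW, db, Xc;
};

class BatchNorm2d : public Layer {
 public:
  explicit BatchNorm2d(double momentum = 0.1, double eps = 1e-5)
      : momentum(momentum), eps(eps) {}
  Shape configure(Shape in) override {
    in_shape = out_shape = in;
    C = in.c;
    sp = in.h * in.w;
    g.ones(C, 1);
    bt.zeros(C, 1);
    dg.zeros(C, 1);
    db.zeros(C, 1);
    run_mean.zeros(C, 1);
    run_var.ones(C, 1);
    // row indices of each channel, strided by C
    idx.resize(C);
    for (int c = 0; c < C; ++c) {
      uvec v(sp);
      for (int p = 0; p < sp; ++p) v[p] = c + C * p;
      idx[c] = v;
    }
    return in;
  }
  mat forward(const mat& X, bool training) override {
    const int B = X.n_cols;
    mat Y(X.n_rows, B);
    xhat.set_size(X.n_rows, B);
    istd.set_size(C, 1);
    for (int c = 0; c < C; ++c) {
      mat xc = X.rows(idx[c]);  // sp x B
      double mu, var;
      if (training) {
        mu = accu(xc) / xc.n_elem;
        var = accu(square(xc - mu)) / xc.n_elem;
        run_mean(c, 0) = (1 - momentum) * run_mean(c, 0) + momentum * mu;
        run_var(c, 0) = (1 - momentum) * run_var(c, 0) + momentum * var;
      } else {
        mu = run_mean(c, 0);
        var = run_var(c, 0);
      }
      double is = 1.0 / std::sqrt(var + eps);
      istd(c, 0) = is;
      mat xh = (xc - mu) * is;
      xhat.rows(idx[c]) = xh;
      Y.rows(idx[c]) = g(c, 0) * xh + bt(c, 0);
    }
    trained_pass = training;
    return Y;
  }
  mat backward(const mat& G) override {
    const int B = G.n_cols;
    mat dX(G.n_rows, B);
    const double n = double(sp) * B;
    for (int c = 0; c < C; ++c) {
      mat gy = G.rows(idx[c]);
      mat xh = xhat.rows(idx[c]);
      double sdg = accu(gy % xh), sdb = accu(gy);
      dg(c, 0) += sdg;
      db(c, 0) += sdb;
      if (trained_pass) {
        dX.rows(idx[c]) =
            (g(c, 0) * istd(c, 0)) * (gy - sdb / n - xh * (sdg / n));
      } else {
        dX.rows(idx[c]) = (g(c, 0) * istd(c, 0)) * gy;
      }
    }
    return dX;
  }
  std::vector<mat*> params() override { return {&g, &bt}; }
  std::vector<mat*> grads() override { return {&dg, &db}; }
  double momentum, eps;
  int C = 0, sp = 0;
  bool trained_pass = true;
  mat g, bt, dg, db, run_mean, run_var, xhat, istd;
  std::vector<uvec> idx;
};

class MaxPool2d : public Layer {
 public:
  MaxPool2d(int kh, int kw, int sh, int sw) : kh(kh), kw(kw), sh(sh), sw(sw) {}
  Shape configure(Shape in) override {
    in_shape = in;
    oh = conv_out(in.h, kh, sh, 0);
    ow = conv_out(in.w, kw, sw, 0);
    if (oh < 1 || ow < 1)
      Rcpp::stop("maxpool: kernel (%d,%d) stride (%d,%d) on input %s gives empty output",
                 kh, kw, sh, sw, in.str().c_str());
    out_shape = {in.c, oh, ow};
    return out_shape;
  }
  mat forward(const mat& X, bool) override {
    const int B = X.n_cols, C = in_shape.c, H = in_shape.h;
    mat Y(out_shape.size(), B);
    amax.set_size(out_shape.size(), B);
    for (int s = 0; s < B; ++s) {
      const double* x = X.colptr(s);
      double* y = Y.colptr(s);
      for (int wo = 0; wo < ow; ++wo)
        for (int ho = 0; ho < oh; ++ho)
          for (int c = 0; c < C; ++c) {
            double best = -datum::inf;
            int bidx = -1;
            for (int j = 0; j < kw; ++j)
              for (int i = 0; i < kh; ++i) {
                int hi = ho * sh + i, wi = wo * sw + j;
                int id = c + C * (hi + H * wi);
                if (x[id] > best) { best = x[id]; bidx = id; }
              }
            int oid = c + C * (ho + oh * wo);
            y[oid] = best;
            amax(oid, s) = bidx;
          }
    }
    return Y;
  }
  mat backward(const mat& G) override {
    const int B = G.n_cols;
    mat dX(in_shape.size(), B, fill::zeros);
    for (int s = 0; s < B; ++s)
      for (uword r = 0; r < G.n_rows; ++r)
        dX(uword(amax(r, s)), s) += G(r, s);
    return dX;
  }
  int kh, kw, sh, sw, oh = 0, ow = 0;
  imat amax;
};

// Multi-layer LSTM over the width axis of a (C,1,W) input; emits the final
// hidden state of the top layer.  Dropout applied between stacked layers,
// independently per time step.
class LSTM : public Layer {
 public:
  LSTM(int n_layers, int hidden, double dropout, std::mt19937_64* rng)
      : L(n_layers), H(hidden), p_drop(dropout), rng(rng) {}
  Shape configure(Shape in) override {
    in_shape = in;
    if (in.h != 1) Rcpp::stop("lstm expects input shape (C,1,W), got %s", in.str().c_str());
    T = in.w;
    Wi.resize(L); Wh.resize(L); b.resize(L);
    dWi.resize(L); dWh.resize(L); dB.resize(L);
    for (int l = 0; l < L; ++l) {
      int nin = (l == 0) ? in.c : H;
      Wi[l].set_size(4 * H, nin);
      Wh[l].set_size(4 * H, H);
      b[l].zeros(4 * H, 1);
      dWi[l].zeros(size(Wi[l]));
      dWh[l].zeros(size(Wh[l]));
      dB[l].zeros(size(b[l]));
    }
    out_shape = {H, 1, 1};
    return out_shape;
  }
  void init(std::mt19937_64& rngi) override {
    double k = 1.0 / std::sqrt(double(H));
    std::uniform_real_distribution<double> U(-k, k);
    for (int l = 0; l < L; ++l) {
      for (uword i = 0; i < Wi[l].n_elem; ++i) Wi[l][i] = U(rngi);
      for (uword i = 0; i < Wh[l].n_elem; ++i) Wh[l][i] = U(rngi);
      b[l].zeros();
      b[l].rows(H, 2 * H - 1).fill(1.0);  // forget-gate bias
    }
  }
  mat forward(const mat& X, bool training) override {
    const int B = X.n_cols;
    xin.assign(L, {});
    ig.assign(L, {}); fg.assign(L, {}); gg.assign(L, {}); og.assign(L, {});
    cs.assign(L, {}); hs.assign(L, {});
    masks.assign(L, {});
    std::uniform_real_distribution<double> U(0.0, 1.0);
    mat below(in_shape.c, B);
    for (int l = 0; l < L; ++l) {
      mat h(H, B, fill::zeros), c(H, B, fill::zeros);
      for (int t = 0; t < T; ++t) {
        mat xt;
        if (l == 0) {
          xt = X.rows(t * in_shape.c, (t + 1) * in_shape.c - 1);
        } else {
          xt = hs[l - 1][t];
          if (training && p_drop > 0) {
            mat mk(H, B);
            double keep = 1.0 - p_drop;
            for (uword i = 0; i < mk.n_elem; ++i)
              mk[i] = (U(*rng) < keep) ? 1.0 / keep : 0.0;
            masks[l].push_back(mk);
            xt %= mk;
          }
        }
        xin[l].push_back(xt);
        mat z = Wi[l] * xt + Wh[l] * h;
        z.each_col() += b[l].col(0);
        mat i_ = 1.0 / (1.0 + exp(-z.rows(0, H - 1)));
        mat f_ = 1.0 / (1.0 + exp(-z.rows(H, 2 * H - 1)));
        mat g_ = tanh(z.rows(2 * H, 3 * H - 1));
        mat o_ = 1.0 / (1.0 + exp(-z.rows(3 * H, 4 * H - 1)));
        c = f_ % c + i_ % g_;
        h = o_ % tanh(c);
        ig[l].push_back(i_); fg[l].push_back(f_);
        gg[l].push_back(g_); og[l].push_back(o_);
        cs[l].push_back(c); hs[l].push_back(h);
      }
    }
    return hs[L - 1][T - 1];
  }
  mat backward(const mat& G) override {
    const int B = G.n_cols;
    // dh_seq[t] for current layer; top layer only has gradient at last step
    std::vector<mat> dh_next(T, mat(H, B, fill::zeros));
    dh_next[T - 1] = G;
    mat dX(in_shape.size(), B, fill::zeros);
    for (int l = L - 1; l >= 0; --l) {
      std::vector<mat> dh_below(T);
      mat dh(H, B, fill::zeros), dc(H, B, fill::zeros);
      for (int t = T - 1; t >= 0; --t) {
        dh += dh_next[t];
        mat c = cs[l][t];
        mat cprev = (t > 0) ? cs[l][t - 1] : mat(H, B, fill::zeros);
        mat tc = tanh(c);
        mat do_ = dh % tc;
        dc += dh % og[l][t] % (1.0 - square(tc));
        mat di = dc % gg[l][t];
        mat df = dc % cprev;
        mat dg_ = dc % ig[l][t];
        mat dzi = di % ig[l][t] % (1.0 - ig[l][t]);
        mat dzf = df % fg[l][t] % (1.0 - fg[l][t]);
        mat dzg = dg_ % (1.0 - square(gg[l][t]));
        mat dzo = do_ % og[l][t] % (1.0 - og[l][t]);
        mat dz = join_cols(join_cols(dzi, dzf), join_cols(dzg, dzo));
        dWi[l] += dz * xin[l][t].t();
        mat hprev = (t > 0) ? hs[l][t - 1] : mat(H, B, fill::zeros);
        dWh[l] += dz * hprev.t();
        dB[l] += sum(dz, 1);
        mat dxt = Wi[l].t() * dz;
        if (l > 0 && !masks[l].empty()) dxt %= masks[l][t];
        dh_below[t] = dxt;
        dh = Wh[l].t() * dz;
        dc = dc % fg[l][t];
      }
      if (l == 0) {
        for (int t = 0; t < T; ++t)
          dX.rows(t * in_shape.c, (t + 1) * in_shape.c - 1) = dh_below[t];
      } else {
        dh_next = dh_below;
      }
    }
    return dX;
  }
  std::vector<mat*> params() override {
    std::vector<mat*> v;
    for (int l = 0; l < L; ++l) { v.push_back(&Wi[l]); v.push_back(&Wh[l]); v.push_back(&b[l]); }
    return v;
  }
  std::vector<mat*> grads() override {
    std::vector<mat*> v;
    for (int l = 0; l < L; ++l) { v.push_back(&dWi[l]); v.push_back(&dWh[l]); v.push_back(&dB[l]); }
    return v;
  }
  int L, H, T = 0;
  double p_drop;
  std::mt19937_64* rng;
  std::vector<mat> Wi, Wh, b, dWi, dWh, dB;
  std::vector<std::vector<mat>> xin, ig, fg, gg, og, cs, hs, masks;
};

struct Net {
  std::vector<std::unique_ptr<Layer>> layers;
  Shape in_shape;
  std::mt19937_64 rng;
  long t_adam = 0;
  std::vector<mat> m, v;  // lazy Adam state, one per param
  bool adam_ready = false;
};

static Shape as_shape(Rcpp::IntegerVector s) {
  if (s.size() != 3) Rcpp::stop("shape must be length 3 (C,H,W)");
  return {s[0], s[1], s[2]};
}

// [[Rcpp::export]]
SEXP net_create(Rcpp::List layer_specs, Rcpp::IntegerVector in_shape, int seed) {
  auto* net = new Net();
  net->in_shape = as_shape(in_shape);
  net->rng.seed(uint64_t(seed));
  Shape cur = net->in_shape;
  for (int i = 0; i < layer_specs.size(); ++i) {
    Rcpp::List sp = layer_specs[i];
    std::string type = Rcpp::as<std::string>(sp["type"]);
    Layer* L = nullptr;
    auto gi = [&](const char* k, int d) {
      return sp.containsElementNamed(k) ? Rcpp::as<int>(sp[k]) : d;
    };
    auto gd = [&](const char* k, double d) {
      return sp.containsElementNamed(k) ? Rcpp::as<double>(sp[k]) : d;
    };
    if (type == "dense") L = new Dense(gi("out", 1));
    else if (type == "reshape") L = new Reshape(gi("c", 1), gi("h", 1), gi("w", 1));
    else if (type == "flatten") L = new Reshape(cur.size(), 1, 1);
    else if (type == "lrelu") L = new LeakyReLU(gd("slope", 0.2));
    else if (type == "dropout") L = new Dropout(gd("p", 0.5), &net->rng);
    else if (type == "conv")
      L = new Conv2d(gi("out", 1), gi("kh", 1), gi("kw", 1), gi("sh", 1),
                     gi("sw", 1), gi("ph", 0), gi("pw", 0));
    else if (type == "convt")
      L = new ConvTranspose2d(gi("out", 1), gi("kh", 1), gi("kw", 1),
                              gi("sh", 1), gi("sw", 1), gi("ph", 0),
                              gi("pw", 0), gi("oph", 0), gi("opw", 0));
    else if (type == "bn") L = new BatchNorm2d(gd("momentum", 0.1));
    else if (type == "maxpool")
      L = new MaxPool2d(gi("kh", 1), gi("kw", 1), gi("sh", gi("kh", 1)),
                        gi("sw", gi("kw", 1)));
    else if (type == "lstm")
      L = new LSTM(gi("layers", 1), gi("hidden", 64), gd("dropout", 0.0),
                   &net->rng);
    else { delete net; Rcpp::stop("unknown layer type '%s'", type.c_str()); }
    try {
      cur = L->configure(cur);
    } catch (...) {
      delete L;
      delete net;
      throw;
    }
    L->init(net->rng);
    net->layers.emplace_back(L);
  }
  Rcpp::XPtr<Net> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
Rcpp::IntegerVector net_out_shape(SEXP netp) {
  Rcpp::XPtr<Net> net(netp);
  Shape s = net->layers.empty() ? net->in_shape : net->layers.back()->out_shape;
  return Rcpp::IntegerVector::create(s.c, s.h, s.w);
}

// [[Rcpp::export]]
Rcpp::List net_shape_trace(SEXP netp) {
  Rcpp::XPtr<Net> net(netp);
  Rcpp::List out(net->layers.size());
  for (size_t i = 0; i < net->layers.size(); ++i) {
    Shape s = net->layers[i]->out_shape;
    out[i] = Rcpp::IntegerVector::create(s.c, s.h, s.w);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix net_forward(SEXP netp, Rcpp::NumericMatrix x, bool training) {
  Rcpp::XPtr<Net> net(netp);
  if (int(x.nrow()) != net->in_shape.size())
    Rcpp::stop("net_forward: input has %d rows, expected %d", x.nrow(),
               net->in_shape.size());
  mat X(x.begin(), x.nrow(), x.ncol());
  for (auto& L : net->layers) X = L->forward(X, training);
  return Rcpp::wrap(X);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix net_backward(SEXP netp, Rcpp::NumericMatrix g) {
  Rcpp::XPtr<Net> net(netp);
  mat G(g.begin(), g.nrow(), g.ncol());
  for (auto it = net->layers.rbegin(); it != net->layers.rend(); ++it)
    G = (*it)->backward(G);
  return Rcpp::wrap(G);
}

// [[Rcpp::export]]
void net_zero_grads(SEXP netp) {
  Rcpp::XPtr<Net> net(netp);
  for (auto& L : net->layers) L->zero_grads();
}

// [[Rcpp::export]]
void net_adam_step(SEXP netp, double lr, double beta1, double beta2,
                   double eps) {
  Rcpp::XPtr<Net> net(netp);
  if (!net->adam_ready) {
    for (auto& L : net->layers)
      for (mat* p : L->params()) {
        net->m.emplace_back(size(*p), fill::zeros);
        net->v.emplace_back(size(*p), fill::zeros);
      }
    net->adam_ready = true;
  }
  net->t_adam += 1;
  double bc1 = 1.0 - std::pow(beta1, double(net->t_adam));
  double bc2 = 1.0 - std::pow(beta2, double(net->t_adam));
  size_t k = 0;
  for (auto& L : net->layers) {
    auto ps = L->params();
    auto gs = L->grads();
    for (size_t i = 0; i < ps.size(); ++i, ++k) {
      net->m[k] = beta1 * net->m[k] + (1 - beta1) * (*gs[i]);
      net->v[k] = beta2 * net->v[k] + (1 - beta2) * square(*gs[i]);
      *ps[i] -= lr * (net->m[k] / bc1) / (sqrt(net->v[k] / bc2) + eps);
    }
  }
}

// [[Rcpp::export]]
Rcpp::List net_get_params(SEXP netp) {
  Rcpp::XPtr<Net> net(netp);
  Rcpp::List out;
  for (auto& L : net->layers)
    for (mat* p : L->params()) out.push_back(Rcpp::wrap(*p));
  return out;
}

// [[Rcpp::export]]
void net_set_params(SEXP netp, Rcpp::List params) {
  Rcpp::XPtr<Net> net(netp);
  int k = 0;
  for (auto& L : net->layers)
    for (mat* p : L->params()) {
      if (k >= params.size()) Rcpp::stop("net_set_params: too few parameter matrices");
      Rcpp::NumericMatrix q = params[k++];
      if (uword(q.nrow()) != p->n_rows || uword(q.ncol()) != p->n_cols)
        Rcpp::stop("net_set_params: parameter %d has wrong shape", k);
      *p = mat(q.begin(), q.nrow(), q.ncol());
    }
  if (k != params.size()) Rcpp::stop("net_set_params: too many parameter matrices");
}

// [[Rcpp::export]]
Rcpp::List net_get_grads(SEXP netp) {
  Rcpp::XPtr<Net> net(netp);
  Rcpp::List out;
  for (auto& L : net->layers)
    for (mat* g : L->grads()) out.push_back(Rcpp::wrap(*g));
  return out;
}

// TRUE while the external pointer still references a live engine object
// (it does not survive serialization).
// [[Rcpp::export]]
bool xptr_valid(SEXP p) {
  return TYPEOF(p) == EXTPTRSXP && R_ExternalPtrAddr(p) != NULL;
}

// [[Rcpp::export]]
double net_n_params(SEXP netp) {
  Rcpp::XPtr<Net> net(netp);
  double n = 0;
  for (auto& L : net->layers)
    for (mat* p : L->params()) n += double(p->n_elem);
  return n;
}
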
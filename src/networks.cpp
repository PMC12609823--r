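// Hand-built neural networks for raw-biosignal classification.
//
// Two architectures, matching the package's model contracts:
//   * a compact 4-block 2-D CNN over (channel x time) EEG windows
//     (conv 3x3 pad 1 -> batch-norm -> ReLU -> temporal max-pool x2, filters
//     32/64/128/256, adaptive average pool -> 256 -> MLP 128 -> 2 logits);
//   * a 2-layer bidirectional LSTM over univariate EDA windows
//     (hidden 64 per direction, h = [fwd_T ; bwd_1] in R^128, MLP 64 -> 2).
//
// Everything (forward, backprop, AdamW, batch-norm, dropout) is implemented
// here because no deep-learning runtime is linked. Convolutions run as
// im2col + GEMM. Internally float32 is used for speed on a single CPU;
// a double instantiation exists so tests can finite-difference-check the
// analytic gradients at tight tolerance.
//
// Parameters live in one flat vector; layer matrices are Armadillo views
// into it, so the AdamW update is a handful of vectorised expressions.

// [[Rcpp::depends(RcppArmadillo)]]
#ifndef ARMA_NO_DEBUG
#define ARMA_NO_DEBUG
#endif
#include <RcppArmadillo.h>
#include <random>
#include <cmath>
#include <string>
#include <vector>
#include <functional>
#include <limits>

using namespace arma;

static const double ADAM_B1 = 0.9, ADAM_B2 = 0.999, ADAM_EPS = 1e-8;
static const double BN_EPS = 1e-5, BN_MOMENTUM = 0.1;

// ---------------------------------------------------------------------------
// flat parameter store with named views
// ---------------------------------------------------------------------------

struct ParamSlot {
  std::string name;
  uword offset, nrow, ncol; // ncol == 1 for vectors
};

template <typename T>
struct ParamStore {
  Col<T> theta, grad, m, v;
  long step = 0;
  std::vector<ParamSlot> slots;

  uword add(const std::string& name, uword nrow, uword ncol, uword at) {
    slots.push_back({name, at, nrow, ncol});
    return at + nrow * ncol;
  }
  void allocate(uword n) {
    theta.zeros(n); grad.zeros(n); m.zeros(n); v.zeros(n);
  }
  Mat<T> view(const std::string& name, bool of_grad = false) {
    for (const ParamSlot& s : slots)
      if (s.name == name) {
        T* base = (of_grad ? grad.memptr() : theta.memptr()) + s.offset;
        return Mat<T>(base, s.nrow, s.ncol, false, true);
      }
    Rcpp::stop("unknown parameter '%s'", name);
  }
  void adamw(double lr, double wd) {
    ++step;
    m = T(ADAM_B1) * m + T(1 - ADAM_B1) * grad;
    v = T(ADAM_B2) * v + T(1 - ADAM_B2) * square(grad);
    T c1 = T(1.0 / (1.0 - std::pow(ADAM_B1, (double)step)));
    T c2 = T(1.0 / (1.0 - std::pow(ADAM_B2, (double)step)));
    theta -= T(lr) * ((c1 * m) / (sqrt(c2 * v) + T(ADAM_EPS)) + T(wd) * theta);
  }
};

// shared weighted softmax cross-entropy; returns loss, writes dZ (2 x N)
template <typename T>
double ce_loss_grad(const Mat<T>& Z, const ivec& y, const vec& w,
                    Mat<T>* dZ) {
  uword N = Z.n_cols;
  Mat<T> P = Z;
  P.each_row() -= max(P, 0);
  P = exp(P);
  P.each_row() /= sum(P, 0);
  double loss = 0, wsum = 0;
  for (uword i = 0; i < N; ++i) {
    double wi = w[(uword)y[i]];
    loss += -wi * std::log(std::max((double)P(y[i], i), 1e-30));
    wsum += wi;
  }
  loss /= wsum;
  if (dZ) {
    *dZ = P;
    for (uword i = 0; i < N; ++i) {
      (*dZ)(y[i], i) -= T(1);
      dZ->col(i) *= T(w[(uword)y[i]] / wsum);
    }
  }
  return loss;
}

template <typename T>
struct RngDraw {
  std::mt19937_64 eng;
  std::normal_distribution<double> norm{0.0, 1.0};
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  explicit RngDraw(unsigned long seed) : eng(seed) {}
  T normal(double sd) { return T(norm(eng) * sd); }
  T uniform(double lo, double hi) { return T(lo + unif(eng) * (hi - lo)); }
  bool keep(double p) { return unif(eng) < p; }
};

// ---------------------------------------------------------------------------
// CNN
// ---------------------------------------------------------------------------

template <typename T>
struct CNN {
  static const int NB = 4;
  int F[NB + 1] = {1, 32, 64, 128, 256};
  int H;                 // electrode axis (spatial), preserved by pooling
  double dropout_p;
  ParamStore<T> ps;
  Mat<T> rmean[NB], rvar[NB]; // running BN stats (F_i x 1)
  RngDraw<T> rng;

  CNN(int n_channels, double dropout, unsigned long seed)
      : H(n_channels), dropout_p(dropout), rng(seed) {
    uword at = 0;
    for (int l = 0; l < NB; ++l) {
      at = ps.add("conv" + std::to_string(l + 1) + "_w", F[l + 1], 9 * F[l], at);
      at = ps.add("conv" + std::to_string(l + 1) + "_b", F[l + 1], 1, at);
      at = ps.add("bn" + std::to_string(l + 1) + "_gamma", F[l + 1], 1, at);
      at = ps.add("bn" + std::to_string(l + 1) + "_beta", F[l + 1], 1, at);
    }
    at = ps.add("fc1_w", 128, 256, at);
    at = ps.add("fc1_b", 128, 1, at);
    at = ps.add("fc2_w", 2, 128, at);
    at = ps.add("fc2_b", 2, 1, at);
    ps.allocate(at);
    for (int l = 0; l < NB; ++l) {
      Mat<T> W = ps.view("conv" + std::to_string(l + 1) + "_w");
      double sd = std::sqrt(2.0 / (9.0 * F[l]));
      for (uword k = 0; k < W.n_elem; ++k) W(k) = rng.normal(sd);
      ps.view("bn" + std::to_string(l + 1) + "_gamma").fill(T(1));
      rmean[l].zeros(F[l + 1], 1);
      rvar[l].ones(F[l + 1], 1);
    }
    Mat<T> W1 = ps.view("fc1_w");
    double sd1 = std::sqrt(2.0 / 256.0);
    for (uword k = 0; k < W1.n_elem; ++k) W1(k) = rng.normal(sd1);
    Mat<T> W2 = ps.view("fc2_w");
    double sd2 = std::sqrt(2.0 / 128.0);
    for (uword k = 0; k < W2.n_elem; ++k) W2(k) = rng.normal(sd2);
  }

  // A: (Cin, N*H*W), col: (9*Cin, N*H*W), 3x3 pad 1 over (H, W) grid
  void im2col(const Mat<T>& A, uword N, uword W, Mat<T>& col) const {
    uword HW = (uword)H * W, Cin = A.n_rows;
    col.set_size(9 * Cin, N * HW);
    for (uword n = 0; n < N; ++n)
      for (uword h = 0; h < (uword)H; ++h)
        for (uword w = 0; w < W; ++w) {
          uword j = n * HW + h * W + w;
          T* out = col.colptr(j);
          for (int dh = -1; dh <= 1; ++dh)
            for (int dw = -1; dw <= 1; ++dw) {
              long hh = (long)h + dh, ww = (long)w + dw;
              uword k = (uword)((dh + 1) * 3 + (dw + 1));
              if (hh < 0 || hh >= (long)H || ww < 0 || ww >= (long)W) {
                for (uword c = 0; c < Cin; ++c) out[c * 9 + k] = T(0);
              } else {
                const T* in = A.colptr(n * HW + (uword)hh * W + (uword)ww);
                for (uword c = 0; c < Cin; ++c) out[c * 9 + k] = in[c];
              }
            }
        }
  }

  void col2im(const Mat<T>& dcol, uword N, uword W, Mat<T>& dA) const {
    uword HW = (uword)H * W, Cin = dcol.n_rows / 9;
    dA.zeros(Cin, N * HW);
    for (uword n = 0; n < N; ++n)
      for (uword h = 0; h < (uword)H; ++h)
        for (uword w = 0; w < W; ++w) {
          uword j = n * HW + h * W + w;
          const T* dc = dcol.colptr(j);
          for (int dh = -1; dh <= 1; ++dh)
            for (int dw = -1; dw <= 1; ++dw) {
              long hh = (long)h + dh, ww = (long)w + dw;
              if (hh < 0 || hh >= (long)H || ww < 0 || ww >= (long)W) continue;
              uword k = (uword)((dh + 1) * 3 + (dw + 1));
              T* out = dA.colptr(n * HW + (uword)hh * W + (uword)ww);
              for (uword c = 0; c < Cin; ++c) out[c] += dc[c * 9 + k];
            }
        }
  }

  struct Cache {
    std::vector<Mat<T>> col, xhat, act;     // per block
    std::vector<Mat<T>> invstd;             // (F x 1)
    std::vector<Mat<unsigned char>> argmax; // pooled grid, offset 0/1
    std::vector<uword> Wl;                  // time width entering block l
    Mat<T> emb, h1, dropmask;
    uword N = 0, Wout = 0;
  };

  // forward; mode: 0 eval (running stats, no dropout), 1 train (batch stats,
  // dropout, update running), 2 probe (batch stats, no dropout, no update)
  Mat<T> forward(const Mat<T>& X0, uword N, uword W0, int mode, Cache* cc) {
    if ((W0 >> NB) == 0)
      Rcpp::stop("window too short for 4 temporal poolings: need >= 16 samples, got %d",
                 (int)W0);
    Mat<T> A = X0; // (F[l], N*H*W)
    uword W = W0;
    if (cc) { cc->N = N; }
    for (int l = 0; l < NB; ++l) {
      Mat<T> col;
      im2col(A, N, W, col);
      Mat<T> Wm = ps.view("conv" + std::to_string(l + 1) + "_w");
      Mat<T> Y = Wm * col;
      Y.each_col() += ps.view("conv" + std::to_string(l + 1) + "_b").col(0);
      // batch norm
      Mat<T> gamma = ps.view("bn" + std::to_string(l + 1) + "_gamma");
      Mat<T> beta = ps.view("bn" + std::to_string(l + 1) + "_beta");
      Col<T> mu, invstd;
      if (mode == 0) {
        mu = rmean[l].col(0);
        invstd = T(1) / sqrt(rvar[l].col(0) + T(BN_EPS));
      } else {
        mu = mean(Y, 1);
        Col<T> var = mean(square(Y), 1) - square(mu);
        var = clamp(var, T(0), std::numeric_limits<T>::max());
        invstd = T(1) / sqrt(var + T(BN_EPS));
        if (mode == 1) {
          double mcount = (double)Y.n_cols;
          double unb = mcount > 1 ? mcount / (mcount - 1) : 1.0;
          rmean[l].col(0) = T(1 - BN_MOMENTUM) * rmean[l].col(0) + T(BN_MOMENTUM) * mu;
          rvar[l].col(0) = T(1 - BN_MOMENTUM) * rvar[l].col(0) + T(BN_MOMENTUM * unb) * var;
        }
      }
      Y.each_col() -= mu;
      Y.each_col() %= invstd;
      Mat<T> xhat;
      if (cc) xhat = Y;
      Y.each_col() %= gamma.col(0);
      Y.each_col() += beta.col(0);
      // ReLU
      Y.transform([](T x) { return x > T(0) ? x : T(0); });
      // temporal max pool (factor 2, floor)
      uword W2 = W / 2, HW = (uword)H * W, HW2 = (uword)H * W2;
      Mat<T> P(Y.n_rows, N * HW2);
      Mat<unsigned char> am;
      if (cc) am.set_size(Y.n_rows, N * HW2);
      for (uword n = 0; n < N; ++n)
        for (uword h = 0; h < (uword)H; ++h)
          for (uword w2 = 0; w2 < W2; ++w2) {
            uword j0 = n * HW + h * W + 2 * w2;
            uword jj = n * HW2 + h * W2 + w2;
            const T* a = Y.colptr(j0);
            const T* b = Y.colptr(j0 + 1);
            T* o = P.colptr(jj);
            for (uword f = 0; f < Y.n_rows; ++f) {
              bool second = b[f] > a[f];
              o[f] = second ? b[f] : a[f];
              if (cc) am(f, jj) = second ? 1 : 0;
            }
          }
      if (cc) {
        cc->col.push_back(std::move(col));
        cc->xhat.push_back(std::move(xhat));
        Col<T> is = invstd;
        cc->invstd.push_back(Mat<T>(is));
        cc->act.push_back(std::move(Y)); // post-ReLU, pre-pool
        cc->argmax.push_back(std::move(am));
        cc->Wl.push_back(W);
      }
      A = std::move(P);
      W = W2;
    }
    // adaptive average pool -> (256, N)
    uword HWf = (uword)H * W;
    Mat<T> E(256, N);
    for (uword n = 0; n < N; ++n)
      E.col(n) = mean(A.cols(n * HWf, (n + 1) * HWf - 1), 1);
    if (cc) { cc->Wout = W; cc->emb = E; }
    // head
    Mat<T> H1 = ps.view("fc1_w") * E;
    H1.each_col() += ps.view("fc1_b").col(0);
    H1.transform([](T x) { return x > T(0) ? x : T(0); });
    if (mode == 1 && dropout_p > 0) {
      Mat<T> mask(H1.n_rows, H1.n_cols);
      T scale = T(1.0 / (1.0 - dropout_p));
      for (uword k = 0; k < mask.n_elem; ++k)
        mask(k) = rng.keep(1.0 - dropout_p) ? scale : T(0);
      H1 %= mask;
      if (cc) cc->dropmask = mask;
    } else if (cc) {
      cc->dropmask.ones(H1.n_rows, H1.n_cols);
    }
    if (cc) cc->h1 = H1;
    Mat<T> Z = ps.view("fc2_w") * H1;
    Z.each_col() += ps.view("fc2_b").col(0);
    return Z;
  }

  void backward(const Mat<T>& dZ, Cache& cc) {
    ps.grad.zeros();
    uword N = cc.N;
    // head
    ps.view("fc2_w", true) += dZ * cc.h1.t();
    ps.view("fc2_b", true).col(0) += sum(dZ, 1);
    Mat<T> dH1 = ps.view("fc2_w").t() * dZ;
    dH1 %= cc.dropmask;
    // ReLU on h1 (mask where h1 == 0); note dropmask already zeroed dropped units
    for (uword k = 0; k < dH1.n_elem; ++k)
      if (cc.h1(k) <= T(0)) dH1(k) = T(0);
    ps.view("fc1_w", true) += dH1 * cc.emb.t();
    ps.view("fc1_b", true).col(0) += sum(dH1, 1);
    Mat<T> dE = ps.view("fc1_w").t() * dH1; // (256, N)
    // adaptive avg pool backward
    uword W = cc.Wout, HWf = (uword)H * W;
    Mat<T> dA(256, N * HWf);
    for (uword n = 0; n < N; ++n) {
      Col<T> g = dE.col(n) / T(HWf);
      dA.cols(n * HWf, (n + 1) * HWf - 1).each_col() = g;
    }
    for (int l = NB - 1; l >= 0; --l) {
      uword Wl = cc.Wl[(uword)l], W2 = Wl / 2;
      uword HW = (uword)H * Wl, HW2 = (uword)H * W2;
      uword Fo = (uword)F[l + 1];
      // unpool
      Mat<T> dY(Fo, N * HW, fill::zeros);
      for (uword n = 0; n < N; ++n)
        for (uword h = 0; h < (uword)H; ++h)
          for (uword w2 = 0; w2 < W2; ++w2) {
            uword jj = n * HW2 + h * W2 + w2;
            uword j0 = n * HW + h * Wl + 2 * w2;
            const T* g = dA.colptr(jj);
            for (uword f = 0; f < Fo; ++f)
              dY(f, j0 + cc.argmax[(uword)l](f, jj)) += g[f];
          }
      // ReLU backward (act is post-ReLU pre-pool)
      const Mat<T>& act = cc.act[(uword)l];
      for (uword k = 0; k < dY.n_elem; ++k)
        if (act(k) <= T(0)) dY(k) = T(0);
      // BN backward
      std::string tag = std::to_string(l + 1);
      Mat<T> gamma = ps.view("bn" + tag + "_gamma");
      const Mat<T>& xhat = cc.xhat[(uword)l];
      Col<T> dgamma = sum(dY % xhat, 1);
      Col<T> dbeta = sum(dY, 1);
      ps.view("bn" + tag + "_gamma", true).col(0) += dgamma;
      ps.view("bn" + tag + "_beta", true).col(0) += dbeta;
      uword mcols = dY.n_cols;
      Mat<T> dxhat = dY;
      dxhat.each_col() %= gamma.col(0);
      Col<T> s1 = sum(dxhat, 1) / T(mcols);
      Col<T> s2 = sum(dxhat % xhat, 1) / T(mcols);
      Mat<T> dX = dxhat;
      dX.each_col() -= s1;
      dX -= xhat.each_col() % s2;
      dX.each_col() %= cc.invstd[(uword)l].col(0);
      // conv backward
      ps.view("conv" + tag + "_w", true) += dX * cc.col[(uword)l].t();
      ps.view("conv" + tag + "_b", true).col(0) += sum(dX, 1);
      if (l > 0) {
        Mat<T> dcol = ps.view("conv" + tag + "_w").t() * dX;
        col2im(dcol, N, Wl, dA);
      }
    }
  }
};

// ---------------------------------------------------------------------------
// BiLSTM
// ---------------------------------------------------------------------------

template <typename T>
struct LSTM {
  int Din, Hd = 64, layers = 2;
  double dropout_p;
  ParamStore<T> ps;
  RngDraw<T> rng;

  LSTM(int input_dim, double dropout, unsigned long seed)
      : Din(input_dim), dropout_p(dropout), rng(seed) {
    uword at = 0;
    for (int l = 0; l < layers; ++l) {
      int in = (l == 0) ? Din : 2 * Hd;
      for (int d = 0; d < 2; ++d) {
        std::string tag = "l" + std::to_string(l + 1) + (d == 0 ? "f" : "b");
        at = ps.add("wih_" + tag, 4 * Hd, in, at);
        at = ps.add("whh_" + tag, 4 * Hd, Hd, at);
        at = ps.add("b_" + tag, 4 * Hd, 1, at);
      }
    }
    at = ps.add("fc1_w", 64, 2 * Hd, at);
    at = ps.add("fc1_b", 64, 1, at);
    at = ps.add("fc2_w", 2, 64, at);
    at = ps.add("fc2_b", 2, 1, at);
    ps.allocate(at);
    double k = 1.0 / std::sqrt((double)Hd);
    for (const ParamSlot& s : ps.slots) {
      Mat<T> W = ps.view(s.name);
      if (s.name.rfind("fc", 0) == 0) {
        if (s.name.find("_w") != std::string::npos) {
          double sd = std::sqrt(2.0 / (double)W.n_cols);
          for (uword q = 0; q < W.n_elem; ++q) W(q) = rng.normal(sd);
        }
      } else {
        for (uword q = 0; q < W.n_elem; ++q) W(q) = rng.uniform(-k, k);
        if (s.name.rfind("b_", 0) == 0)
          W.rows(Hd, 2 * Hd - 1) += T(1); // forget-gate bias
      }
    }
  }

  struct DirCache {
    std::vector<Mat<T>> i, f, g, o, c, h; // per time step (Hd x N)
  };
  struct Cache {
    DirCache dc[2][2]; // [layer][dir]
    std::vector<Mat<T>> o1; // layer-1 concatenated output per t (2Hd x N)
    Mat<T> hcat, h1, dropmask;
    uword Tlen = 0, N = 0;
  };

  // run one direction of one layer; input supplied per time step via lambda
  void run_dir(int l, int d, uword Tlen, uword N,
               const std::function<Mat<T>(uword)>& xin, DirCache& c0) {
    std::string tag = "l" + std::to_string(l + 1) + (d == 0 ? "f" : "b");
    Mat<T> Wih = ps.view("wih_" + tag), Whh = ps.view("whh_" + tag);
    Col<T> b = ps.view("b_" + tag).col(0);
    Mat<T> h(Hd, N, fill::zeros), c(Hd, N, fill::zeros);
    c0.i.resize(Tlen); c0.f.resize(Tlen); c0.g.resize(Tlen);
    c0.o.resize(Tlen); c0.c.resize(Tlen); c0.h.resize(Tlen);
    for (uword s = 0; s < Tlen; ++s) {
      uword t = (d == 0) ? s : (Tlen - 1 - s);
      Mat<T> z = Wih * xin(t) + Whh * h;
      z.each_col() += b;
      Mat<T> zi = z.rows(0, Hd - 1), zf = z.rows(Hd, 2 * Hd - 1),
             zg = z.rows(2 * Hd, 3 * Hd - 1), zo = z.rows(3 * Hd, 4 * Hd - 1);
      zi.transform([](T x) { return T(1) / (T(1) + std::exp(-(double)x)); });
      zf.transform([](T x) { return T(1) / (T(1) + std::exp(-(double)x)); });
      zg.transform([](T x) { return (T)std::tanh((double)x); });
      zo.transform([](T x) { return T(1) / (T(1) + std::exp(-(double)x)); });
      c = zf % c + zi % zg;
      Mat<T> tc = c;
      tc.transform([](T x) { return (T)std::tanh((double)x); });
      h = zo % tc;
      c0.i[t] = zi; c0.f[t] = zf; c0.g[t] = zg; c0.o[t] = zo;
      c0.c[t] = c; c0.h[t] = h;
    }
  }

  // X: cube-like (Din x N x T) passed as vector of T matrices
  Mat<T> forward_seq(const std::vector<Mat<T>>& X, int mode, Cache* cc) {
    uword Tlen = X.size(), N = X[0].n_cols;
    if (Tlen < 2) Rcpp::stop("sequence too short: need at least 2 samples");
    Cache local;
    Cache& c = cc ? *cc : local;
    c.Tlen = Tlen; c.N = N;
    for (int d = 0; d < 2; ++d)
      run_dir(0, d, Tlen, N, [&](uword t) { return X[t]; }, c.dc[0][d]);
    c.o1.resize(Tlen);
    for (uword t = 0; t < Tlen; ++t)
      c.o1[t] = join_cols(c.dc[0][0].h[t], c.dc[0][1].h[t]);
    for (int d = 0; d < 2; ++d)
      run_dir(1, d, Tlen, N, [&](uword t) { return c.o1[t]; }, c.dc[1][d]);
    c.hcat = join_cols(c.dc[1][0].h[Tlen - 1], c.dc[1][1].h[0]);
    Mat<T> H1 = ps.view("fc1_w") * c.hcat;
    H1.each_col() += ps.view("fc1_b").col(0);
    H1.transform([](T x) { return x > T(0) ? x : T(0); });
    if (mode == 1 && dropout_p > 0) {
      Mat<T> mask(H1.n_rows, H1.n_cols);
      T scale = T(1.0 / (1.0 - dropout_p));
      for (uword k = 0; k < mask.n_elem; ++k)
        mask(k) = rng.keep(1.0 - dropout_p) ? scale : T(0);
      H1 %= mask;
      c.dropmask = mask;
    } else {
      c.dropmask.ones(H1.n_rows, H1.n_cols);
    }
    c.h1 = H1;
    Mat<T> Z = ps.view("fc2_w") * H1;
    Z.each_col() += ps.view("fc2_b").col(0);
    return Z;
  }

  // BPTT for one direction; dh_inject(t) added to dh at step t (may be empty)
  void bptt_dir(int l, int d, Cache& cc,
                const std::function<Mat<T>(uword)>& xin,
                const std::vector<Mat<T>>& dh_inject,
                std::vector<Mat<T>>* dx_out) {
    DirCache& c0 = cc.dc[(uword)l][(uword)d];
    uword Tlen = cc.Tlen, N = cc.N;
    std::string tag = "l" + std::to_string(l + 1) + (d == 0 ? "f" : "b");
    Mat<T> Wih = ps.view("wih_" + tag), Whh = ps.view("whh_" + tag);
    Mat<T> dWih(Wih.n_rows, Wih.n_cols, fill::zeros);
    Mat<T> dWhh(Whh.n_rows, Whh.n_cols, fill::zeros);
    Col<T> db(4 * Hd, fill::zeros);
    Mat<T> dh(Hd, N, fill::zeros), dc(Hd, N, fill::zeros);
    for (uword s = Tlen; s-- > 0;) {
      uword t = (d == 0) ? s : (Tlen - 1 - s); // reverse of processing order
      if (!dh_inject.empty() && dh_inject[t].n_elem > 0) dh += dh_inject[t];
      Mat<T> tc = c0.c[t];
      tc.transform([](T x) { return (T)std::tanh((double)x); });
      Mat<T> d_o = dh % tc;
      dc += dh % c0.o[t] % (T(1) - square(tc));
      // previous cell state (in processing order)
      Mat<T> cprev;
      if (s == 0) cprev.zeros(Hd, N);
      else cprev = c0.c[(d == 0) ? t - 1 : t + 1];
      Mat<T> d_i = dc % c0.g[t];
      Mat<T> d_f = dc % cprev;
      Mat<T> d_g = dc % c0.i[t];
      Mat<T> dc_prev = dc % c0.f[t];
      Mat<T> dzi = d_i % c0.i[t] % (T(1) - c0.i[t]);
      Mat<T> dzf = d_f % c0.f[t] % (T(1) - c0.f[t]);
      Mat<T> dzg = d_g % (T(1) - square(c0.g[t]));
      Mat<T> dzo = d_o % c0.o[t] % (T(1) - c0.o[t]);
      Mat<T> dz = join_cols(join_cols(dzi, dzf), join_cols(dzg, dzo));
      Mat<T> hprev;
      if (s == 0) hprev.zeros(Hd, N);
      else hprev = c0.h[(d == 0) ? t - 1 : t + 1];
      dWih += dz * xin(t).t();
      dWhh += dz * hprev.t();
      db += sum(dz, 1);
      if (dx_out) (*dx_out)[t] += Wih.t() * dz;
      dh = Whh.t() * dz;
      dc = dc_prev;
    }
    ps.view("wih_" + tag, true) += dWih;
    ps.view("whh_" + tag, true) += dWhh;
    ps.view("b_" + tag, true).col(0) += db;
  }

  void backward(const Mat<T>& dZ, const std::vector<Mat<T>>& X, Cache& cc) {
    ps.grad.zeros();
    uword Tlen = cc.Tlen, N = cc.N;
    ps.view("fc2_w", true) += dZ * cc.h1.t();
    ps.view("fc2_b", true).col(0) += sum(dZ, 1);
    Mat<T> dH1 = ps.view("fc2_w").t() * dZ;
    dH1 %= cc.dropmask;
    for (uword k = 0; k < dH1.n_elem; ++k)
      if (cc.h1(k) <= T(0)) dH1(k) = T(0);
    ps.view("fc1_w", true) += dH1 * cc.hcat.t();
    ps.view("fc1_b", true).col(0) += sum(dH1, 1);
    Mat<T> dhcat = ps.view("fc1_w").t() * dH1; // (2Hd, N)
    // layer 2: inject at terminal steps
    std::vector<Mat<T>> inj_f(Tlen), inj_b(Tlen);
    inj_f[Tlen - 1] = dhcat.rows(0, Hd - 1);
    inj_b[0] = dhcat.rows(Hd, 2 * Hd - 1);
    std::vector<Mat<T>> dO1(Tlen);
    for (uword t = 0; t < Tlen; ++t) dO1[t].zeros(2 * Hd, N);
    bptt_dir(1, 0, cc, [&](uword t) { return cc.o1[t]; }, inj_f, &dO1);
    bptt_dir(1, 1, cc, [&](uword t) { return cc.o1[t]; }, inj_b, &dO1);
    // layer 1: split dO1 into per-direction dh injections
    std::vector<Mat<T>> inj1f(Tlen), inj1b(Tlen);
    for (uword t = 0; t < Tlen; ++t) {
      inj1f[t] = dO1[t].rows(0, Hd - 1);
      inj1b[t] = dO1[t].rows(Hd, 2 * Hd - 1);
    }
    bptt_dir(0, 0, cc, [&](uword t) { return X[t]; }, inj1f, nullptr);
    bptt_dir(0, 1, cc, [&](uword t) { return X[t]; }, inj1b, nullptr);
  }
};

// ---------------------------------------------------------------------------
// R interface
// ---------------------------------------------------------------------------

struct NetHandle {
  int kind;      // 0 = cnn, 1 = lstm
  bool single;   // float32?
  CNN<float>* cf = nullptr;
  CNN<double>* cd = nullptr;
  LSTM<float>* lf = nullptr;
  LSTM<double>* ld = nullptr;
  ~NetHandle() { delete cf; delete cd; delete lf; delete ld; }
};

static NetHandle* get_handle(SEXP ptr) {
  Rcpp::XPtr<NetHandle> xp(ptr);
  return xp.get();
}

// [[Rcpp::export]]
SEXP nf_cnn_create(int n_channels, double dropout, int seed,
                   std::string precision) {
  NetHandle* h = new NetHandle();
  h->kind = 0;
  h->single = (precision == "single");
  if (h->single) h->cf = new CNN<float>(n_channels, dropout, (unsigned long)seed);
  else h->cd = new CNN<double>(n_channels, dropout, (unsigned long)seed);
  return Rcpp::XPtr<NetHandle>(h, true);
}

// [[Rcpp::export]]
SEXP nf_lstm_create(int input_dim, double dropout, int seed,
                    std::string precision) {
  NetHandle* h = new NetHandle();
  h->kind = 1;
  h->single = (precision == "single");
  if (h->single) h->lf = new LSTM<float>(input_dim, dropout, (unsigned long)seed);
  else h->ld = new LSTM<double>(input_dim, dropout, (unsigned long)seed);
  return Rcpp::XPtr<NetHandle>(h, true);
}

template <typename T, typename NET>
static Rcpp::List get_params_t(NET* net) {
  Rcpp::List out;
  for (const ParamSlot& s : net->ps.slots) {
    Mat<T> W = net->ps.view(s.name);
    Rcpp::NumericMatrix M(W.n_rows, W.n_cols);
    for (uword j = 0; j < W.n_cols; ++j)
      for (uword i = 0; i < W.n_rows; ++i) M(i, j) = (double)W(i, j);
    out[s.name] = M;
  }
  return out;
}

template <typename T, typename NET>
static void set_params_t(NET* net, Rcpp::List params) {
  for (const ParamSlot& s : net->ps.slots) {
    if (!params.containsElementNamed(s.name.c_str()))
      Rcpp::stop("missing parameter '%s'", s.name);
    Rcpp::NumericMatrix M = params[s.name];
    Mat<T> W = net->ps.view(s.name);
    if ((uword)M.nrow() != W.n_rows || (uword)M.ncol() != W.n_cols)
      Rcpp::stop("shape mismatch for '%s'", s.name);
    for (uword j = 0; j < W.n_cols; ++j)
      for (uword i = 0; i < W.n_rows; ++i) W(i, j) = (T)M(i, j);
  }
}

// [[Rcpp::export]]
Rcpp::List nf_net_get_params(SEXP ptr) {
  NetHandle* h = get_handle(ptr);
  if (h->kind == 0)
    return h->single ? get_params_t<float>(h->cf) : get_params_t<double>(h->cd);
  return h->single ? get_params_t<float>(h->lf) : get_params_t<double>(h->ld);
}

// [[Rcpp::export]]
void nf_net_set_params(SEXP ptr, Rcpp::List params) {
  NetHandle* h = get_handle(ptr);
  if (h->kind == 0) {
    if (h->single) set_params_t<float>(h->cf, params);
    else set_params_t<double>(h->cd, params);
  } else {
    if (h->single) set_params_t<float>(h->lf, params);
    else set_params_t<double>(h->ld, params);
  }
}

template <typename T>
static Rcpp::List cnn_state_t(CNN<T>* net) {
  Rcpp::List out;
  for (int l = 0; l < 4; ++l) {
    std::string tag = std::to_string(l + 1);
    Rcpp::NumericVector rm(net->rmean[l].n_rows), rv(net->rvar[l].n_rows);
    for (uword i = 0; i < net->rmean[l].n_rows; ++i) {
      rm[i] = (double)net->rmean[l](i, 0);
      rv[i] = (double)net->rvar[l](i, 0);
    }
    out["bn" + tag + "_rmean"] = rm;
    out["bn" + tag + "_rvar"] = rv;
  }
  return out;
}

template <typename T>
static void cnn_set_state_t(CNN<T>* net, Rcpp::List st) {
  for (int l = 0; l < 4; ++l) {
    std::string tag = std::to_string(l + 1);
    Rcpp::NumericVector rm = st["bn" + tag + "_rmean"];
    Rcpp::NumericVector rv = st["bn" + tag + "_rvar"];
    for (uword i = 0; i < net->rmean[l].n_rows; ++i) {
      net->rmean[l](i, 0) = (T)rm[i];
      net->rvar[l](i, 0) = (T)rv[i];
    }
  }
}

// [[Rcpp::export]]
Rcpp::List nf_net_get_state(SEXP ptr) {
  NetHandle* h = get_handle(ptr);
  if (h->kind == 0)
    return h->single ? cnn_state_t<float>(h->cf) : cnn_state_t<double>(h->cd);
  return Rcpp::List();
}

// [[Rcpp::export]]
void nf_net_set_state(SEXP ptr, Rcpp::List st) {
  NetHandle* h = get_handle(ptr);
  if (h->kind == 0) {
    if (h->single) cnn_set_state_t<float>(h->cf, st);
    else cnn_set_state_t<double>(h->cd, st);
  }
}

// [[Rcpp::export]]
double nf_net_nparams(SEXP ptr) {
  NetHandle* h = get_handle(ptr);
  if (h->kind == 0)
    return h->single ? (double)h->cf->ps.theta.n_elem : (double)h->cd->ps.theta.n_elem;
  return h->single ? (double)h->lf->ps.theta.n_elem : (double)h->ld->ps.theta.n_elem;
}

// convert R input to internal layout
// CNN: x is array (N, C, T) -> Mat (1, N*C*T) with column n*(C*T) + c*T + t
template <typename T>
static Mat<T> cnn_input(Rcpp::NumericVector x, uword& N, uword& C, uword& W) {
  Rcpp::IntegerVector dim = x.attr("dim");
  if (dim.size() != 3) Rcpp::stop("EEG batch must be a 3-d array (n, channels, time)");
  N = (uword)dim[0]; C = (uword)dim[1]; W = (uword)dim[2];
  Mat<T> A(1, N * C * W);
  const double* xp = x.begin();
  for (uword t = 0; t < W; ++t)
    for (uword c = 0; c < C; ++c)
      for (uword n = 0; n < N; ++n)
        A(0, n * (C * W) + c * W + t) = (T)xp[n + N * (c + C * t)];
  return A;
}

// LSTM: x is matrix (N, T) (univariate) -> vector of T matrices (1 x N)
template <typename T>
static std::vector<Mat<T>> lstm_input(Rcpp::NumericMatrix x) {
  uword N = (uword)x.nrow(), Tlen = (uword)x.ncol();
  std::vector<Mat<T>> out(Tlen);
  for (uword t = 0; t < Tlen; ++t) {
    out[t].set_size(1, N);
    for (uword n = 0; n < N; ++n) out[t](0, n) = (T)x(n, t);
  }
  return out;
}

template <typename T>
static Rcpp::NumericMatrix to_rmat(const Mat<T>& Z) {
  Rcpp::NumericMatrix out(Z.n_cols, Z.n_rows); // N x 2
  for (uword j = 0; j < Z.n_cols; ++j)
    for (uword i = 0; i < Z.n_rows; ++i) out(j, i) = (double)Z(i, j);
  return out;
}

template <typename T>
static Rcpp::NumericMatrix cnn_logits_t(CNN<T>* net, Rcpp::NumericVector x,
                                        int mode) {
  uword N, C, W;
  Mat<T> A = cnn_input<T>(x, N, C, W);
  if ((int)C != net->H) Rcpp::stop("channel count %d does not match network (%d)",
                                   (int)C, net->H);
  Mat<T> Z = net->forward(A, N, W, mode, nullptr);
  return to_rmat(Z);
}

template <typename T>
static Rcpp::NumericMatrix lstm_logits_t(LSTM<T>* net, Rcpp::NumericMatrix x,
                                         int mode) {
  std::vector<Mat<T>> X = lstm_input<T>(x);
  Mat<T> Z = net->forward_seq(X, mode, nullptr);
  return to_rmat(Z);
}

// train_mode=TRUE probes with batch statistics + dropout but leaves the
// running statistics untouched (saved/restored around the pass)
template <typename T>
static Rcpp::NumericMatrix cnn_logits_probe(CNN<T>* net, Rcpp::NumericVector x) {
  Mat<T> save_m[4], save_v[4];
  for (int l = 0; l < 4; ++l) { save_m[l] = net->rmean[l]; save_v[l] = net->rvar[l]; }
  Rcpp::NumericMatrix out = cnn_logits_t(net, x, 1);
  for (int l = 0; l < 4; ++l) { net->rmean[l] = save_m[l]; net->rvar[l] = save_v[l]; }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix nf_net_logits(SEXP ptr, SEXP x, bool train_mode) {
  NetHandle* h = get_handle(ptr);
  if (h->kind == 0) {
    Rcpp::NumericVector xv(x);
    if (train_mode)
      return h->single ? cnn_logits_probe<float>(h->cf, xv)
                       : cnn_logits_probe<double>(h->cd, xv);
    return h->single ? cnn_logits_t<float>(h->cf, xv, 0)
                     : cnn_logits_t<double>(h->cd, xv, 0);
  }
  Rcpp::NumericMatrix xm(x);
  int mode = train_mode ? 1 : 0;
  return h->single ? lstm_logits_t<float>(h->lf, xm, mode)
                   : lstm_logits_t<double>(h->ld, xm, mode);
}

template <typename T>
static double cnn_train_t(CNN<T>* net, Rcpp::NumericVector x, Rcpp::IntegerVector y,
                          Rcpp::NumericVector w, double lr, double wd, double l1,
                          bool update) {
  uword N, C, W;
  Mat<T> A = cnn_input<T>(x, N, C, W);
  typename CNN<T>::Cache cc;
  Mat<T> Z = net->forward(A, N, W, 1, &cc);
  ivec yy(N);
  for (uword i = 0; i < N; ++i) yy[i] = y[i];
  vec ww = {w[0], w[1]};
  Mat<T> dZ;
  double loss = ce_loss_grad(Z, yy, ww, &dZ);
  net->backward(dZ, cc);
  if (l1 > 0) {
    loss += l1 * (double)accu(abs(net->ps.theta));
    net->ps.grad += T(l1) * sign(net->ps.theta);
  }
  if (update) net->ps.adamw(lr, wd);
  return loss;
}

template <typename T>
static double lstm_train_t(LSTM<T>* net, Rcpp::NumericMatrix x, Rcpp::IntegerVector y,
                           Rcpp::NumericVector w, double lr, double wd, double l1,
                           bool update) {
  std::vector<Mat<T>> X = lstm_input<T>(x);
  typename LSTM<T>::Cache cc;
  Mat<T> Z = net->forward_seq(X, 1, &cc);
  uword N = Z.n_cols;
  ivec yy(N);
  for (uword i = 0; i < N; ++i) yy[i] = y[i];
  vec ww = {w[0], w[1]};
  Mat<T> dZ;
  double loss = ce_loss_grad(Z, yy, ww, &dZ);
  net->backward(dZ, X, cc);
  if (l1 > 0) {
    loss += l1 * (double)accu(abs(net->ps.theta));
    net->ps.grad += T(l1) * sign(net->ps.theta);
  }
  if (update) net->ps.adamw(lr, wd);
  return loss;
}

// [[Rcpp::export]]
double nf_net_train_batch(SEXP ptr, SEXP x, Rcpp::IntegerVector y,
                          Rcpp::NumericVector w, double lr, double weight_decay,
                          double l1) {
  NetHandle* h = get_handle(ptr);
  if (h->kind == 0) {
    Rcpp::NumericVector xv(x);
    return h->single ? cnn_train_t<float>(h->cf, xv, y, w, lr, weight_decay, l1, true)
                     : cnn_train_t<double>(h->cd, xv, y, w, lr, weight_decay, l1, true);
  }
  Rcpp::NumericMatrix xm(x);
  return h->single ? lstm_train_t<float>(h->lf, xm, y, w, lr, weight_decay, l1, true)
                   : lstm_train_t<double>(h->ld, xm, y, w, lr, weight_decay, l1, true);
}

// deterministic loss+grad in probe mode (batch-norm batch statistics, dropout
// off, running statistics untouched) -- used by gradient-check tests
template <typename T>
static Rcpp::List cnn_lossgrad_t(CNN<T>* net, Rcpp::NumericVector x,
                                 Rcpp::IntegerVector y, Rcpp::NumericVector w,
                                 double l1, bool want_grad) {
  uword N, C, W;
  Mat<T> A = cnn_input<T>(x, N, C, W);
  double save_p = net->dropout_p;
  net->dropout_p = 0;
  typename CNN<T>::Cache cc;
  Mat<T> Z = net->forward(A, N, W, 2, &cc);
  ivec yy(N);
  for (uword i = 0; i < N; ++i) yy[i] = y[i];
  vec ww = {w[0], w[1]};
  Mat<T> dZ;
  double loss = ce_loss_grad(Z, yy, ww, want_grad ? &dZ : nullptr);
  Rcpp::List out;
  out["loss"] = loss + (l1 > 0 ? l1 * (double)accu(abs(net->ps.theta)) : 0.0);
  if (want_grad) {
    net->backward(dZ, cc);
    if (l1 > 0) net->ps.grad += T(l1) * sign(net->ps.theta);
    Rcpp::NumericVector g(net->ps.grad.n_elem);
    for (uword i = 0; i < net->ps.grad.n_elem; ++i) g[i] = (double)net->ps.grad[i];
    out["grad"] = g;
  }
  net->dropout_p = save_p;
  return out;
}

template <typename T>
static Rcpp::List lstm_lossgrad_t(LSTM<T>* net, Rcpp::NumericMatrix x,
                                  Rcpp::IntegerVector y, Rcpp::NumericVector w,
                                  double l1, bool want_grad) {
  std::vector<Mat<T>> X = lstm_input<T>(x);
  double save_p = net->dropout_p;
  net->dropout_p = 0;
  typename LSTM<T>::Cache cc;
  Mat<T> Z = net->forward_seq(X, 2, &cc);
  uword N = Z.n_cols;
  ivec yy(N);
  for (uword i = 0; i < N; ++i) yy[i] = y[i];
  vec ww = {w[0], w[1]};
  Mat<T> dZ;
  double loss = ce_loss_grad(Z, yy, ww, want_grad ? &dZ : nullptr);
  Rcpp::List out;
  out["loss"] = loss + (l1 > 0 ? l1 * (double)accu(abs(net->ps.theta)) : 0.0);
  if (want_grad) {
    net->backward(dZ, X, cc);
    if (l1 > 0) net->ps.grad += T(l1) * sign(net->ps.theta);
    Rcpp::NumericVector g(net->ps.grad.n_elem);
    for (uword i = 0; i < net->ps.grad.n_elem; ++i) g[i] = (double)net->ps.grad[i];
    out["grad"] = g;
  }
  net->dropout_p = save_p;
  return out;
}

// [[Rcpp::export]]
Rcpp::List nf_net_loss_grad(SEXP ptr, SEXP x, Rcpp::IntegerVector y,
                            Rcpp::NumericVector w, double l1, bool want_grad) {
  NetHandle* h = get_handle(ptr);
  if (h->kind == 0) {
    Rcpp::NumericVector xv(x);
    return h->single ? cnn_lossgrad_t<float>(h->cf, xv, y, w, l1, want_grad)
                     : cnn_lossgrad_t<double>(h->cd, xv, y, w, l1, want_grad);
  }
  Rcpp::NumericMatrix xm(x);
  return h->single ? lstm_lossgrad_t<float>(h->lf, xm, y, w, l1, want_grad)
                   : lstm_lossgrad_t<double>(h->ld, xm, y, w, l1, want_grad);
}

// flat parameter vector access (used for finite differences and checkpoints)
// [[Rcpp::export]]
Rcpp::NumericVector nf_net_get_theta(SEXP ptr) {
  NetHandle* h = get_handle(ptr);
  auto fetch = [](auto* net) {
    Rcpp::NumericVector out(net->ps.theta.n_elem);
    for (uword i = 0; i < net->ps.theta.n_elem; ++i) out[i] = (double)net->ps.theta[i];
    return out;
  };
  if (h->kind == 0) return h->single ? fetch(h->cf) : fetch(h->cd);
  return h->single ? fetch(h->lf) : fetch(h->ld);
}

template <typename T, typename NET>
static void set_theta_t(NET* net, Rcpp::NumericVector th) {
  if ((uword)th.size() != net->ps.theta.n_elem) Rcpp::stop("length mismatch");
  for (uword i = 0; i < net->ps.theta.n_elem; ++i) net->ps.theta[i] = (T)th[i];
}

// [[Rcpp::export]]
void nf_net_set_theta(SEXP ptr, Rcpp::NumericVector th) {
  NetHandle* h = get_handle(ptr);
  if (h->kind == 0) {
    if (h->single) set_theta_t<float>(h->cf, th);
    else set_theta_t<double>(h->cd, th);
  } else {
    if (h->single) set_theta_t<float>(h->lf, th);
    else set_theta_t<double>(h->ld, th);
  }
}
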
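// Single-threaded training/prediction backend for HawksheadNet and the
// transfer-learning head. Convolutions are im2col + GEMM in single
// precision; optimisation is Adam on mean binary cross-entropy. All
// randomness (shuffling, dropout) comes from one std::mt19937 seeded from
// R, so runs are bit-reproducible.
//
// Layout conventions shared with the R side:
//  - images arrive as R arrays dim (s, s, 3, N), column-major, values in
//    [0, 1]; inside C++ a feature map is a (s*s x channels) matrix with
//    spatial index idx = y + s * x, which matches the R array layout
//    exactly (and keeps im2col cache-friendly: every patch row is a
//    contiguous shifted copy of a channel column);
//  - a conv weight matrix has dim (k*k*c_in, f): row r decomposes as
//    ky = r %% k, kx = (r / k) %% k, c = r / (k*k), matching an R array of
//    dim (k, k, c_in, f);
//  - dense weight matrices are (n_in, n_out).

#include <RcppArmadillo.h>
#include <random>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::uword;

namespace {

fmat fm(SEXP x) { return arma::conv_to<fmat>::from(as<arma::mat>(x)); }
fvec fv(SEXP x) { return arma::conv_to<fvec>::from(as<arma::vec>(x)); }

struct AdamState {
  fmat m, v;
  void init(const fmat& w) { m.zeros(w.n_rows, w.n_cols); v.zeros(w.n_rows, w.n_cols); }
  void step(fmat& w, const fmat& g, double lr, double t) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
    m = b1 * m + (1.0f - b1) * g;
    v = b2 * v + (1.0f - b2) * (g % g);
    float corr1 = 1.0f - std::pow(b1, (float)t);
    float corr2 = 1.0f - std::pow(b2, (float)t);
    w -= (float)lr * (m / corr1) / (arma::sqrt(v / corr2) + eps);
  }
};

// zero-padded "same" im2col on an (s*s x c_in) feature map; output
// (s*s x k*k*c_in): column r of the output is channel c shifted by the
// kernel offset (ky, kx), so every copy is a strided pair of contiguous runs
void im2col_same(const fmat& in, int s, int cin, int k, fmat& col) {
  int pad = (k - 1) / 2;
  col.zeros((uword)(s * s), (uword)(k * k * cin));
  for (int c = 0; c < cin; ++c) {
    const float* src = in.colptr((uword)c);
    for (int kx = 0; kx < k; ++kx) {
      int dx = kx - pad;
      for (int ky = 0; ky < k; ++ky) {
        int dy = ky - pad;
        float* dst = col.colptr((uword)(c * k * k + kx * k + ky));
        int x0 = std::max(0, -dx), x1 = std::min(s, s - dx);
        int y0 = std::max(0, -dy), y1 = std::min(s, s - dy);
        for (int x = x0; x < x1; ++x) {
          const float* s_ = src + (size_t)s * (x + dx) + (y0 + dy);
          float* d_ = dst + (size_t)s * x + y0;
          std::memcpy(d_, s_, sizeof(float) * (size_t)(y1 - y0));
        }
      }
    }
  }
}

// scatter-add transpose of im2col_same
void col2im_same(const fmat& col, int s, int cin, int k, fmat& out) {
  int pad = (k - 1) / 2;
  out.zeros((uword)(s * s), (uword)cin);
  for (int c = 0; c < cin; ++c) {
    float* dst = out.colptr((uword)c);
    for (int kx = 0; kx < k; ++kx) {
      int dx = kx - pad;
      for (int ky = 0; ky < k; ++ky) {
        int dy = ky - pad;
        const float* src = col.colptr((uword)(c * k * k + kx * k + ky));
        int x0 = std::max(0, -dx), x1 = std::min(s, s - dx);
        int y0 = std::max(0, -dy), y1 = std::min(s, s - dy);
        for (int x = x0; x < x1; ++x) {
          float* d_ = dst + (size_t)s * (x + dx) + (y0 + dy);
          const float* s_ = src + (size_t)s * x + y0;
          for (int y = 0; y < y1 - y0; ++y) d_[y] += s_[y];
        }
      }
    }
  }
}

// 2x2 max pool on (s*s x ch); records the winning spatial index per cell
void maxpool2(const fmat& in, int s, fmat& out, arma::umat& argmax) {
  int so = s / 2;
  uword ch = in.n_cols;
  out.set_size((uword)(so * so), ch);
  argmax.set_size((uword)(so * so), ch);
  for (uword c = 0; c < ch; ++c) {
    const float* src = in.colptr(c);
    float* dst = out.colptr(c);
    uword* am = argmax.colptr(c);
    for (int x = 0; x < so; ++x) {
      for (int y = 0; y < so; ++y) {
        uword i00 = (uword)(2 * y + s * (2 * x));
        uword i10 = i00 + 1;
        uword i01 = (uword)(2 * y + s * (2 * x + 1));
        uword i11 = i01 + 1;
        float v = src[i00]; uword a = i00;
        if (src[i10] > v) { v = src[i10]; a = i10; }
        if (src[i01] > v) { v = src[i01]; a = i01; }
        if (src[i11] > v) { v = src[i11]; a = i11; }
        dst[y + so * x] = v; am[y + so * x] = a;
      }
    }
  }
}

void maxpool2_backward(const fmat& dout, const arma::umat& argmax, int s, fmat& din) {
  din.zeros((uword)(s * s), dout.n_cols);
  for (uword c = 0; c < dout.n_cols; ++c) {
    const float* src = dout.colptr(c);
    const uword* am = argmax.colptr(c);
    float* dst = din.colptr(c);
    for (uword j = 0; j < dout.n_rows; ++j) dst[am[j]] += src[j];
  }
}

struct Net {
  fmat W1, W2, U1, U2, U3;
  fvec b1, b2, c1, c2, c3;
  int k, cin, f1, f2, s;
  double dropout, l1, l2;
};

Net net_from_list(List w, int s, double dropout, double l1, double l2) {
  Net n;
  n.W1 = fm(w["W1"]); n.b1 = fv(w["b1"]);
  n.W2 = fm(w["W2"]); n.b2 = fv(w["b2"]);
  n.U1 = fm(w["U1"]); n.c1 = fv(w["c1"]);
  n.U2 = fm(w["U2"]); n.c2 = fv(w["c2"]);
  n.U3 = fm(w["U3"]); n.c3 = fv(w["c3"]);
  n.f1 = (int)n.W1.n_cols; n.f2 = (int)n.W2.n_cols;
  n.cin = 3;
  n.k = (int)std::lround(std::sqrt((double)(n.W1.n_rows / n.cin)));
  n.s = s; n.dropout = dropout; n.l1 = l1; n.l2 = l2;
  return n;
}

List net_to_list(const Net& n) {
  return List::create(
    Named("W1") = wrap(arma::conv_to<arma::mat>::from(n.W1)),
    Named("b1") = wrap(arma::conv_to<arma::vec>::from(n.b1)),
    Named("W2") = wrap(arma::conv_to<arma::mat>::from(n.W2)),
    Named("b2") = wrap(arma::conv_to<arma::vec>::from(n.b2)),
    Named("U1") = wrap(arma::conv_to<arma::mat>::from(n.U1)),
    Named("c1") = wrap(arma::conv_to<arma::vec>::from(n.c1)),
    Named("U2") = wrap(arma::conv_to<arma::mat>::from(n.U2)),
    Named("c2") = wrap(arma::conv_to<arma::vec>::from(n.c2)),
    Named("U3") = wrap(arma::conv_to<arma::mat>::from(n.U3)),
    Named("c3") = wrap(arma::conv_to<arma::vec>::from(n.c3)));
}

// per-image workspace, reused across the whole run (forward caches and
// backward temporaries; reuse avoids ~50 MB of allocations per image)
struct Work {
  fmat img, col1, a1, p1, col2, a2, p2;
  fmat dp2, da2, dcol2, dp1, da1;
  arma::umat am1, am2;
  fvec g, h1, h2;
};

float relu_inplace(fmat& a) {
  a.transform([](float v) { return v > 0 ? v : 0; });
  return 0;
}

// forward one image (spatial-major activations); keeps the caches needed
// for backprop in `wk`
float forward_one(const Net& n, const double* px, Work& wk, const fvec* drop_mask) {
  int s = n.s, s2 = s / 2;
  wk.img.set_size((uword)(s * s), 3);
  for (size_t j = 0; j < (size_t)s * s * 3; ++j) wk.img.memptr()[j] = (float)px[j];
  im2col_same(wk.img, s, 3, n.k, wk.col1);
  wk.a1 = wk.col1 * n.W1;
  wk.a1.each_row() += n.b1.t();
  relu_inplace(wk.a1);
  maxpool2(wk.a1, s, wk.p1, wk.am1);
  im2col_same(wk.p1, s2, n.f1, n.k, wk.col2);
  wk.a2 = wk.col2 * n.W2;
  wk.a2.each_row() += n.b2.t();
  relu_inplace(wk.a2);
  maxpool2(wk.a2, s2, wk.p2, wk.am2);
  wk.g = arma::mean(wk.p2, 0).t();      // global average pool -> f2 vector
  if (drop_mask) wk.g %= *drop_mask;
  wk.h1 = n.U1.t() * wk.g + n.c1;
  wk.h1.transform([](float v) { return v > 0 ? v : 0; });
  wk.h2 = n.U2.t() * wk.h1 + n.c2;
  wk.h2.transform([](float v) { return v > 0 ? v : 0; });
  float z = arma::as_scalar(n.U3.t() * wk.h2 + n.c3);
  return 1.0f / (1.0f + std::exp(-z));
}

struct Grads {
  fmat W1, W2, U1, U2, U3;
  fvec b1, b2, c1, c2, c3;
  void zero(const Net& n) {
    W1.zeros(arma::size(n.W1)); W2.zeros(arma::size(n.W2));
    U1.zeros(arma::size(n.U1)); U2.zeros(arma::size(n.U2)); U3.zeros(arma::size(n.U3));
    b1.zeros(n.b1.n_elem); b2.zeros(n.b2.n_elem);
    c1.zeros(n.c1.n_elem); c2.zeros(n.c2.n_elem); c3.zeros(n.c3.n_elem);
  }
};

// backward for one image given the forward cache; accumulates into `g`
void backward_one(const Net& n, Work& wk, float p, float y, const fvec* drop_mask, Grads& g) {
  int s = n.s, s2 = s / 2, s4 = s / 4;
  float dz = p - y;                      // dL/dz for sigmoid + BCE
  g.U3 += wk.h2 * dz;
  g.c3 += fvec{dz};
  fvec dh2 = n.U3.col(0) * dz;
  for (uword i = 0; i < dh2.n_elem; ++i) if (wk.h2(i) <= 0) dh2(i) = 0;
  g.U2 += wk.h1 * dh2.t();
  g.c2 += dh2;
  fvec dh1 = n.U2 * dh2;
  for (uword i = 0; i < dh1.n_elem; ++i) if (wk.h1(i) <= 0) dh1(i) = 0;
  g.U1 += wk.g * dh1.t();
  g.c1 += dh1;
  fvec dg = n.U1 * dh1;
  if (drop_mask) dg %= *drop_mask;
  int npix = s4 * s4;
  wk.dp2.set_size((uword)npix, (uword)n.f2);
  wk.dp2.each_row() = (dg / (float)npix).t();  // GAP backward
  maxpool2_backward(wk.dp2, wk.am2, s2, wk.da2);
  { float* d = wk.da2.memptr(); const float* a = wk.a2.memptr();
    for (uword j = 0; j < wk.da2.n_elem; ++j) if (a[j] <= 0) d[j] = 0; }
  g.W2 += wk.col2.t() * wk.da2;
  g.b2 += arma::sum(wk.da2, 0).t();
  wk.dcol2 = wk.da2 * n.W2.t();
  col2im_same(wk.dcol2, s2, n.f1, n.k, wk.dp1);
  maxpool2_backward(wk.dp1, wk.am1, s, wk.da1);
  { float* d = wk.da1.memptr(); const float* a = wk.a1.memptr();
    for (uword j = 0; j < wk.da1.n_elem; ++j) if (a[j] <= 0) d[j] = 0; }
  g.W1 += wk.col1.t() * wk.da1;
  g.b1 += arma::sum(wk.da1, 0).t();
}

double bce(float p, float y) {
  double pc = std::min(std::max((double)p, 1e-7), 1.0 - 1e-7);
  return -(y * std::log(pc) + (1.0 - y) * std::log(1.0 - pc));
}

} // namespace

// [[Rcpp::export]]
NumericVector cnn_forward_cpp(List weights, NumericVector x, int n_images, int s) {
  Net net = net_from_list(weights, s, 0.0, 0.0, 0.0);
  Work wk;
  NumericVector out(n_images);
  const double* px = x.begin();
  size_t stride = (size_t)s * s * 3;
  for (int i = 0; i < n_images; ++i)
    out[i] = forward_one(net, px + stride * i, wk, nullptr);
  return out;
}

// [[Rcpp::export]]
List cnn_train_cpp(List weights, NumericVector x, NumericVector y, int n_train,
                   NumericVector xv, NumericVector yv, int n_val,
                   int s, double lr, int batch_size, int max_epochs,
                   double dropout, double l1, double l2,
                   int patience, int seed, bool verbose) {
  Net net = net_from_list(weights, s, dropout, l1, l2);
  Work wk;
  Grads grads;
  AdamState aW1, aW2, aU1, aU2, aU3, ab1, ab2, ac1, ac2, ac3;
  aW1.init(net.W1); aW2.init(net.W2); aU1.init(net.U1); aU2.init(net.U2); aU3.init(net.U3);
  fmat b1m(net.b1), b2m(net.b2), c1m(net.c1), c2m(net.c2), c3m(net.c3);
  ab1.init(b1m); ab2.init(b2m); ac1.init(c1m); ac2.init(c2m); ac3.init(c3m);

  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  const double* px = x.begin();
  const double* pxv = xv.begin();
  size_t stride = (size_t)s * s * 3;

  std::vector<int> order(n_train);
  for (int i = 0; i < n_train; ++i) order[i] = i;

  std::vector<double> h_tl, h_ta, h_vl, h_va;
  double step_t = 0;
  double best_val_acc = -1;
  int since_best = 0;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0, acc_sum = 0;
    for (int start = 0; start < n_train; start += batch_size) {
      int bs = std::min(batch_size, n_train - start);
      grads.zero(net);
      for (int b = 0; b < bs; ++b) {
        int i = order[start + b];
        fvec mask;
        fvec* maskp = nullptr;
        if (dropout > 0) {
          mask.set_size((uword)net.f2);
          float keep = 1.0f - (float)dropout;
          for (uword j = 0; j < mask.n_elem; ++j)
            mask(j) = unif(rng) < keep ? 1.0f / keep : 0.0f;
          maskp = &mask;
        }
        float p = forward_one(net, px + stride * i, wk, maskp);
        float yy = (float)y[i];
        loss_sum += bce(p, yy);
        acc_sum += ((p >= 0.5f) == (yy >= 0.5f)) ? 1.0 : 0.0;
        backward_one(net, wk, p, yy, maskp, grads);
      }
      float inv = 1.0f / (float)bs;
      grads.W1 *= inv; grads.W2 *= inv; grads.U1 *= inv; grads.U2 *= inv; grads.U3 *= inv;
      grads.b1 *= inv; grads.b2 *= inv; grads.c1 *= inv; grads.c2 *= inv; grads.c3 *= inv;
      if (l2 > 0 || l1 > 0) {  // penalties on dense weights only
        auto reg = [&](fmat& g, const fmat& w) {
          if (l2 > 0) g += 2.0f * (float)l2 * w;
          if (l1 > 0) g += (float)l1 * arma::sign(w);
        };
        reg(grads.U1, net.U1); reg(grads.U2, net.U2); reg(grads.U3, net.U3);
      }
      step_t += 1;
      aW1.step(net.W1, grads.W1, lr, step_t);
      aW2.step(net.W2, grads.W2, lr, step_t);
      aU1.step(net.U1, grads.U1, lr, step_t);
      aU2.step(net.U2, grads.U2, lr, step_t);
      aU3.step(net.U3, grads.U3, lr, step_t);
      fmat gb;
      gb = grads.b1; ab1.step(b1m, gb, lr, step_t); net.b1 = b1m.col(0);
      gb = grads.b2; ab2.step(b2m, gb, lr, step_t); net.b2 = b2m.col(0);
      gb = grads.c1; ac1.step(c1m, gb, lr, step_t); net.c1 = c1m.col(0);
      gb = grads.c2; ac2.step(c2m, gb, lr, step_t); net.c2 = c2m.col(0);
      gb = grads.c3; ac3.step(c3m, gb, lr, step_t); net.c3 = c3m.col(0);
    }
    double vl = NA_REAL, va = NA_REAL;
    if (n_val > 0) {
      double vls = 0, vas = 0;
      for (int i = 0; i < n_val; ++i) {
        float p = forward_one(net, pxv + stride * i, wk, nullptr);
        float yy = (float)yv[i];
        vls += bce(p, yy);
        vas += ((p >= 0.5f) == (yy >= 0.5f)) ? 1.0 : 0.0;
      }
      vl = vls / n_val; va = vas / n_val;
    }
    h_tl.push_back(loss_sum / n_train);
    h_ta.push_back(acc_sum / n_train);
    h_vl.push_back(vl);
    h_va.push_back(va);
    if (verbose)
      Rcpp::Rcout << "epoch " << (epoch + 1) << "/" << max_epochs
                  << " loss " << h_tl.back() << " acc " << h_ta.back()
                  << " val_loss " << vl << " val_acc " << va << std::endl;
    Rcpp::checkUserInterrupt();
    if (patience >= 0 && n_val > 0) {
      if (va > best_val_acc) { best_val_acc = va; since_best = 0; }
      else if (++since_best >= patience) break;
    }
  }
  return List::create(
    Named("weights") = net_to_list(net),
    Named("train_loss") = wrap(h_tl), Named("train_acc") = wrap(h_ta),
    Named("val_loss") = wrap(h_vl), Named("val_acc") = wrap(h_va));
}

// ---- small dense head (transfer learning) --------------------------------

namespace {
struct Mlp { fmat U1, U2, U3; fvec c1, c2, c3; };

Mlp mlp_from_list(List w) {
  Mlp m;
  m.U1 = fm(w["U1"]); m.c1 = fv(w["c1"]);
  m.U2 = fm(w["U2"]); m.c2 = fv(w["c2"]);
  m.U3 = fm(w["U3"]); m.c3 = fv(w["c3"]);
  return m;
}

float mlp_fwd(const Mlp& m, const fvec& f, fvec& h1, fvec& h2) {
  h1 = m.U1.t() * f + m.c1;
  h1.transform([](float v) { return v > 0 ? v : 0; });
  h2 = m.U2.t() * h1 + m.c2;
  h2.transform([](float v) { return v > 0 ? v : 0; });
  float z = arma::as_scalar(m.U3.t() * h2 + m.c3);
  return 1.0f / (1.0f + std::exp(-z));
}
} // namespace

// [[Rcpp::export]]
NumericVector mlp_forward_cpp(List weights, NumericMatrix feats) {
  Mlp m = mlp_from_list(weights);
  int n = feats.ncol();
  int d = feats.nrow();
  NumericVector out(n);
  fvec f((uword)d), h1, h2;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) f((uword)j) = (float)feats(j, i);
    out[i] = mlp_fwd(m, f, h1, h2);
  }
  return out;
}

// [[Rcpp::export]]
List mlp_train_cpp(List weights, NumericMatrix feats, NumericVector y,
                   NumericMatrix featsv, NumericVector yv,
                   double lr, int batch_size, int max_epochs, double dropout,
                   double lr_decay_rate, int lr_decay_steps,
                   int patience, int seed, bool verbose) {
  Mlp m = mlp_from_list(weights);
  int n = feats.ncol(), d = feats.nrow(), nv = featsv.ncol();
  AdamState aU1, aU2, aU3, ac1, ac2, ac3;
  aU1.init(m.U1); aU2.init(m.U2); aU3.init(m.U3);
  fmat c1m(m.c1), c2m(m.c2), c3m(m.c3);
  ac1.init(c1m); ac2.init(c2m); ac3.init(c3m);
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> h_tl, h_ta, h_vl, h_va;
  double step_t = 0;
  double best_va = -1; int since_best = 0;
  fvec f((uword)d), h1, h2;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0, acc_sum = 0;
    for (int start = 0; start < n; start += batch_size) {
      int bs = std::min(batch_size, n - start);
      fmat gU1(arma::size(m.U1), arma::fill::zeros), gU2(arma::size(m.U2), arma::fill::zeros),
           gU3(arma::size(m.U3), arma::fill::zeros);
      fvec gc1(m.c1.n_elem, arma::fill::zeros), gc2(m.c2.n_elem, arma::fill::zeros),
           gc3(m.c3.n_elem, arma::fill::zeros);
      for (int b = 0; b < bs; ++b) {
        int i = order[start + b];
        for (int j = 0; j < d; ++j) f((uword)j) = (float)feats(j, i);
        if (dropout > 0) {  // dropout on the flattened feature vector
          float keep = 1.0f - (float)dropout;
          for (int j = 0; j < d; ++j)
            f((uword)j) = unif(rng) < keep ? f((uword)j) / keep : 0.0f;
        }
        float p = mlp_fwd(m, f, h1, h2);
        float yy = (float)y[i];
        loss_sum += bce(p, yy);
        acc_sum += ((p >= 0.5f) == (yy >= 0.5f)) ? 1.0 : 0.0;
        float dz = p - yy;
        gU3 += h2 * dz; gc3 += fvec{dz};
        fvec dh2 = m.U3.col(0) * dz;
        for (uword q = 0; q < dh2.n_elem; ++q) if (h2(q) <= 0) dh2(q) = 0;
        gU2 += h1 * dh2.t(); gc2 += dh2;
        fvec dh1 = m.U2 * dh2;
        for (uword q = 0; q < dh1.n_elem; ++q) if (h1(q) <= 0) dh1(q) = 0;
        gU1 += f * dh1.t(); gc1 += dh1;
      }
      float inv = 1.0f / (float)bs;
      gU1 *= inv; gU2 *= inv; gU3 *= inv; gc1 *= inv; gc2 *= inv; gc3 *= inv;
      // exponential learning-rate decay per optimisation step
      double lr_t = lr * std::pow(lr_decay_rate, step_t / (double)lr_decay_steps);
      step_t += 1;
      aU1.step(m.U1, gU1, lr_t, step_t);
      aU2.step(m.U2, gU2, lr_t, step_t);
      aU3.step(m.U3, gU3, lr_t, step_t);
      fmat gb;
      gb = gc1; ac1.step(c1m, gb, lr_t, step_t); m.c1 = c1m.col(0);
      gb = gc2; ac2.step(c2m, gb, lr_t, step_t); m.c2 = c2m.col(0);
      gb = gc3; ac3.step(c3m, gb, lr_t, step_t); m.c3 = c3m.col(0);
    }
    double vl = NA_REAL, va = NA_REAL;
    if (nv > 0) {
      double vls = 0, vas = 0;
      for (int i = 0; i < nv; ++i) {
        for (int j = 0; j < d; ++j) f((uword)j) = (float)featsv(j, i);
        float p = mlp_fwd(m, f, h1, h2);
        float yy = (float)yv[i];
        vls += bce(p, yy);
        vas += ((p >= 0.5f) == (yy >= 0.5f)) ? 1.0 : 0.0;
      }
      vl = vls / nv; va = vas / nv;
    }
    h_tl.push_back(loss_sum / n); h_ta.push_back(acc_sum / n);
    h_vl.push_back(vl); h_va.push_back(va);
    if (verbose)
      Rcpp::Rcout << "epoch " << (epoch + 1) << " loss " << h_tl.back()
                  << " val_acc " << va << std::endl;
    Rcpp::checkUserInterrupt();
    if (patience >= 0 && nv > 0) {
      if (va > best_va) { best_va = va; since_best = 0; }
      else if (++since_best >= patience) break;
    }
  }
  return List::create(
    Named("weights") = List::create(
      Named("U1") = wrap(arma::conv_to<arma::mat>::from(m.U1)),
      Named("c1") = wrap(arma::conv_to<arma::vec>::from(m.c1)),
      Named("U2") = wrap(arma::conv_to<arma::mat>::from(m.U2)),
      Named("c2") = wrap(arma::conv_to<arma::vec>::from(m.c2)),
      Named("U3") = wrap(arma::conv_to<arma::mat>::from(m.U3)),
      Named("c3") = wrap(arma::conv_to<arma::vec>::from(m.c3))),
    Named("train_loss") = wrap(h_tl), Named("train_acc") = wrap(h_ta),
    Named("val_loss") = wrap(h_vl), Named("val_acc") = wrap(h_va));
}

// ---- bilinear resize ------------------------------------------------------

// half-pixel-centre bilinear resample of an (h, w, c) array
// [[Rcpp::export]]
NumericVector resize_bilinear_cpp(NumericVector img, int h, int w, int c,
                                  int oh, int ow) {
  NumericVector out((R_xlen_t)oh * ow * c);
  double sy = (double)h / oh, sx = (double)w / ow;
  for (int ch = 0; ch < c; ++ch) {
    const double* in = img.begin() + (size_t)h * w * ch;
    double* o = out.begin() + (size_t)oh * ow * ch;
    for (int x = 0; x < ow; ++x) {
      double fx = (x + 0.5) * sx - 0.5;
      int x0 = (int)std::floor(fx);
      double wx = fx - x0;
      int x0c = std::min(std::max(x0, 0), w - 1);
      int x1c = std::min(std::max(x0 + 1, 0), w - 1);
      for (int y = 0; y < oh; ++y) {
        double fy = (y + 0.5) * sy - 0.5;
        int y0 = (int)std::floor(fy);
        double wy = fy - y0;
        int y0c = std::min(std::max(y0, 0), h - 1);
        int y1c = std::min(std::max(y0 + 1, 0), h - 1);
        double v00 = in[y0c + (size_t)h * x0c], v01 = in[y0c + (size_t)h * x1c];
        double v10 = in[y1c + (size_t)h * x0c], v11 = in[y1c + (size_t)h * x1c];
        o[y + (size_t)oh * x] =
          (1 - wy) * ((1 - wx) * v00 + wx * v01) + wy * ((1 - wx) * v10 + wx * v11);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(oh, ow, c);
  return out;
}

// ---- sRGB <-> CIELAB (D65) ------------------------------------------------

// vectorised colour conversions for the Reinhard normaliser; operate on
// (n x 3) matrices of sRGB values in [0, 1]

// [[Rcpp::export]]
NumericMatrix srgb_to_lab_cpp(NumericMatrix rgb) {
  static const double M[9] = {0.4124564, 0.3575761, 0.1804375,
                              0.2126729, 0.7151522, 0.0721750,
                              0.0193339, 0.1191920, 0.9503041};
  static const double wp[3] = {0.950470, 1.000000, 1.088830};
  const double d3 = std::pow(6.0 / 29.0, 3.0);
  int n = rgb.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double lin[3], f[3];
    for (int c = 0; c < 3; ++c) {
      double u = std::min(std::max(rgb(i, c), 0.0), 1.0);
      lin[c] = u <= 0.04045 ? u / 12.92 : std::pow((u + 0.055) / 1.055, 2.4);
    }
    for (int c = 0; c < 3; ++c) {
      double t = (M[3 * c] * lin[0] + M[3 * c + 1] * lin[1] + M[3 * c + 2] * lin[2]) / wp[c];
      f[c] = t > d3 ? std::cbrt(t) : t / (3.0 * std::pow(6.0 / 29.0, 2.0)) + 4.0 / 29.0;
    }
    out(i, 0) = 116.0 * f[1] - 16.0;
    out(i, 1) = 500.0 * (f[0] - f[1]);
    out(i, 2) = 200.0 * (f[1] - f[2]);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix lab_to_srgb_cpp(NumericMatrix lab) {
  static const double Minv[9] = { 3.2404542, -1.5371385, -0.4985314,
                                 -0.9692660,  1.8760108,  0.0415560,
                                  0.0556434, -0.2040259,  1.0572252};
  static const double wp[3] = {0.950470, 1.000000, 1.088830};
  const double d = 6.0 / 29.0;
  int n = lab.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double fy = (lab(i, 0) + 16.0) / 116.0;
    double f[3] = {fy + lab(i, 1) / 500.0, fy, fy - lab(i, 2) / 200.0};
    double xyz[3];
    for (int c = 0; c < 3; ++c) {
      xyz[c] = (f[c] > d ? f[c] * f[c] * f[c] : 3.0 * d * d * (f[c] - 4.0 / 29.0)) * wp[c];
    }
    for (int c = 0; c < 3; ++c) {
      double lin = Minv[3 * c] * xyz[0] + Minv[3 * c + 1] * xyz[1] + Minv[3 * c + 2] * xyz[2];
      lin = std::min(std::max(lin, 0.0), 1.0);
      out(i, c) = lin <= 0.0031308 ? 12.92 * lin : 1.055 * std::pow(lin, 1.0 / 2.4) - 0.055;
    }
  }
  return out;
}
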
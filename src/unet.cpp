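// 2-D U-Net with shared-weight triplanar use: float32 forward/backward/Adam.
// Layout conventions:
//   image cube  : (H, W, C) arma::fcube, column-major, pixel index p = i + j*H
//   im2col      : (H*W, C*k*k); column q = c*k*k + dj*k + di
//   conv weight : (c_out, c_in*k*k); conv = col * W^T  (one GEMM per layer)
// Padding: 3x3 "same" (pad 1), 2x2 "same" (pad bottom/right), 1x1 none.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Conv {
  int k = 3, cin = 0, cout = 0;
  bool relu = true;
  fmat W;  fvec b;
  fmat gW; fvec gb;
  fmat mW, vW; fvec mb, vb;

  void init(int k_, int cin_, int cout_, bool relu_, std::mt19937& rng) {
    k = k_; cin = cin_; cout = cout_; relu = relu_;
    const int fan_in = cin * k * k;
    std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / (float)fan_in));
    W.set_size(cout, fan_in);
    for (uword i = 0; i < W.n_elem; ++i) W[i] = nd(rng);
    b.zeros(cout);
    gW.zeros(cout, fan_in); gb.zeros(cout);
    mW.zeros(cout, fan_in); vW.zeros(cout, fan_in);
    mb.zeros(cout); vb.zeros(cout);
  }
};

static void im2col(const fcube& X, int k, fmat& col) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int lo = (k == 3) ? -1 : 0;
  col.zeros((uword)H * W, (uword)C * k * k);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int q = c * k * k + dj * k + di;
        const int oi = di + lo, oj = dj + lo;
        float* dst = col.colptr(q);
        const int i0 = std::max(0, -oi), i1 = std::min(H - 1, H - 1 - oi);
        if (i0 > i1) continue;
        for (int j = 0; j < W; ++j) {
          const int sj = j + oj;
          if (sj < 0 || sj >= W) continue;
          std::memcpy(dst + (size_t)j * H + i0,
                      X.slice_colptr(c, sj) + i0 + oi,
                      (size_t)(i1 - i0 + 1) * sizeof(float));
        }
      }
    }
  }
}

static void col2im(const fmat& dcol, int k, fcube& dX) {
  const int H = dX.n_rows, W = dX.n_cols, C = dX.n_slices;
  const int lo = (k == 3) ? -1 : 0;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int q = c * k * k + dj * k + di;
        const float* src = dcol.colptr(q);
        const int oi = di + lo, oj = dj + lo;
        const int i0 = std::max(0, -oi), i1 = std::min(H - 1, H - 1 - oi);
        if (i0 > i1) continue;
        for (int j = 0; j < W; ++j) {
          const int sj = j + oj;
          if (sj < 0 || sj >= W) continue;
          float* dst = dX.slice_colptr(c, sj) + oi;
          const float* s = src + (size_t)j * H;
          for (int i = i0; i <= i1; ++i) dst[i] += s[i];
        }
      }
    }
  }
}

static fcube conv_fwd(Conv& L, const fcube& X, fmat& col_store) {
  const int H = X.n_rows, W = X.n_cols;
  im2col(X, L.k, col_store);
  fmat Y = col_store * L.W.t();
  Y.each_row() += L.b.t();
  fcube out(H, W, L.cout);
  std::memcpy(out.memptr(), Y.memptr(), sizeof(float) * Y.n_elem);
  if (L.relu) {
    float* p = out.memptr();
    for (uword i = 0; i < out.n_elem; ++i) if (p[i] < 0.0f) p[i] = 0.0f;
  }
  return out;
}

// dOut modified in place (relu mask); returns gradient wrt layer input
static fcube conv_bwd(Conv& L, const fcube& out, const fmat& col, fcube& dOut) {
  const int H = dOut.n_rows, W = dOut.n_cols;
  if (L.relu) {
    const float* o = out.memptr(); float* d = dOut.memptr();
    for (uword i = 0; i < dOut.n_elem; ++i) if (o[i] <= 0.0f) d[i] = 0.0f;
  }
  fmat dY(dOut.memptr(), (uword)H * W, L.cout, false, true);
  L.gW += dY.t() * col;
  L.gb += arma::sum(dY, 0).t();
  fmat dcol = dY * L.W;
  fcube dX(H, W, L.cin, fill::zeros);
  col2im(dcol, L.k, dX);
  return dX;
}

static fcube pool_fwd(const fcube& X, ucube& arg) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int H2 = H / 2, W2 = W / 2;
  fcube out(H2, W2, C);
  arg.set_size(H2, W2, C);
  for (int c = 0; c < C; ++c) {
    const fmat& Xc = X.slice(c);
    for (int j2 = 0; j2 < W2; ++j2) {
      for (int i2 = 0; i2 < H2; ++i2) {
        const int i = 2 * i2, j = 2 * j2;
        float best = Xc(i, j); uword bi = (uword)i + (uword)j * H;
        if (Xc(i + 1, j) > best)     { best = Xc(i + 1, j);     bi = (uword)(i + 1) + (uword)j * H; }
        if (Xc(i, j + 1) > best)     { best = Xc(i, j + 1);     bi = (uword)i + (uword)(j + 1) * H; }
        if (Xc(i + 1, j + 1) > best) { best = Xc(i + 1, j + 1); bi = (uword)(i + 1) + (uword)(j + 1) * H; }
        out(i2, j2, c) = best;
        arg(i2, j2, c) = bi;
      }
    }
  }
  return out;
}

static fcube pool_bwd(const fcube& dY, const ucube& arg, int H, int W) {
  const int C = dY.n_slices;
  fcube dX(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* dxc = dX.slice_memptr(c);
    const float* dyc = dY.slice_memptr(c);
    const uword* ac = arg.slice_memptr(c);
    for (uword p = 0; p < dY.n_rows * dY.n_cols; ++p) dxc[ac[p]] += dyc[p];
  }
  return dX;
}

static fcube up_fwd(const fcube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  fcube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const float v = X(i, j, c);
        out(2 * i, 2 * j, c) = v; out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v; out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

static fcube up_bwd(const fcube& dY) {
  const int H = dY.n_rows / 2, W = dY.n_cols / 2, C = dY.n_slices;
  fcube dX(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dX(i, j, c) = dY(2 * i, 2 * j, c) + dY(2 * i + 1, 2 * j, c) +
                      dY(2 * i, 2 * j + 1, c) + dY(2 * i + 1, 2 * j + 1, c);
  return dX;
}

struct UNet {
  int D = 0, N = 0, K = 2;
  std::vector<int> ch;
  float dropout = 0.5f;
  std::vector<Conv> layers;
  std::mt19937 rng;
  long t_adam = 0;

  int enc_idx(int lvl, int j) const { return 2 * lvl + j; }
  int bot_idx(int j) const { return 2 * (D - 1) + j; }
  int dec_idx(int lvl, int j) const { return 2 * (D - 1) + 2 + 3 * ((D - 2) - lvl) + j; }
  int head_idx() const { return (int)layers.size() - 1; }

  void build(const std::vector<int>& channels, int input_size, int n_classes,
             double drop, int seed) {
    ch = channels; D = (int)ch.size(); N = input_size; K = n_classes;
    dropout = (float)drop;
    rng.seed((unsigned)seed);
    layers.resize(5 * D - 2);
    int cin = 1;
    for (int lvl = 0; lvl <= D - 2; ++lvl) {
      layers[enc_idx(lvl, 0)].init(3, cin, ch[lvl], true, rng);
      layers[enc_idx(lvl, 1)].init(3, ch[lvl], ch[lvl], true, rng);
      cin = ch[lvl];
    }
    layers[bot_idx(0)].init(3, ch[D - 2], ch[D - 1], true, rng);
    layers[bot_idx(1)].init(3, ch[D - 1], ch[D - 1], true, rng);
    for (int lvl = D - 2; lvl >= 0; --lvl) {
      const int cup = (lvl == D - 2) ? ch[D - 1] : ch[lvl + 1];
      layers[dec_idx(lvl, 0)].init(2, cup, ch[lvl], true, rng);
      layers[dec_idx(lvl, 1)].init(3, 2 * ch[lvl], ch[lvl], true, rng);
      layers[dec_idx(lvl, 2)].init(3, ch[lvl], ch[lvl], true, rng);
    }
    layers[head_idx()].init(1, ch[0], K, false, rng);
  }
};

struct Tape {
  std::vector<fmat> cols;
  std::vector<fcube> outs;
  std::vector<fcube> dropmasks;  // one per level (0..D-1), empty if unused
  std::vector<ucube> poolargs;   // per encoder level
  std::vector<fcube> skips;      // post-dropout encoder outputs
  fcube probs;
};

static fcube drop_fwd(UNet& net, const fcube& X, fcube& mask) {
  const float p = net.dropout;
  mask.set_size(X.n_rows, X.n_cols, X.n_slices);
  const float scale = 1.0f / (1.0f - p);
  std::uniform_real_distribution<float> u(0.0f, 1.0f);
  float* m = mask.memptr();
  for (uword i = 0; i < mask.n_elem; ++i) m[i] = (u(net.rng) < p) ? 0.0f : scale;
  return X % mask;
}

static void softmax_channels(fcube& logits) {
  const int H = logits.n_rows, W = logits.n_cols, K = logits.n_slices;
  const uword HW = (uword)H * W;
  float* base = logits.memptr();
  for (uword p = 0; p < HW; ++p) {
    float mx = base[p];
    for (int k = 1; k < K; ++k) mx = std::max(mx, base[p + k * HW]);
    float s = 0.0f;
    for (int k = 0; k < K; ++k) { float e = std::exp(base[p + k * HW] - mx); base[p + k * HW] = e; s += e; }
    for (int k = 0; k < K; ++k) base[p + k * HW] /= s;
  }
}

static void forward(UNet& net, const fcube& input, bool training, Tape& T) {
  const int D = net.D;
  T.cols.resize(net.layers.size());
  T.outs.resize(net.layers.size());
  T.dropmasks.assign(D, fcube());
  T.poolargs.resize(D - 1);
  T.skips.resize(D - 1);
  const bool use_drop = training && net.dropout > 0.0f;

  fcube x = input;
  for (int lvl = 0; lvl <= D - 2; ++lvl) {
    int a = net.enc_idx(lvl, 0), b = net.enc_idx(lvl, 1);
    T.outs[a] = conv_fwd(net.layers[a], x, T.cols[a]);
    T.outs[b] = conv_fwd(net.layers[b], T.outs[a], T.cols[b]);
    x = use_drop ? drop_fwd(net, T.outs[b], T.dropmasks[lvl]) : T.outs[b];
    T.skips[lvl] = x;
    x = pool_fwd(x, T.poolargs[lvl]);
  }
  int a = net.bot_idx(0), b = net.bot_idx(1);
  T.outs[a] = conv_fwd(net.layers[a], x, T.cols[a]);
  T.outs[b] = conv_fwd(net.layers[b], T.outs[a], T.cols[b]);
  x = use_drop ? drop_fwd(net, T.outs[b], T.dropmasks[D - 1]) : T.outs[b];

  for (int lvl = D - 2; lvl >= 0; --lvl) {
    int u = net.dec_idx(lvl, 0), c1 = net.dec_idx(lvl, 1), c2 = net.dec_idx(lvl, 2);
    fcube upped = up_fwd(x);
    T.outs[u] = conv_fwd(net.layers[u], upped, T.cols[u]);
    fcube cat = join_slices(T.outs[u], T.skips[lvl]);
    T.outs[c1] = conv_fwd(net.layers[c1], cat, T.cols[c1]);
    T.outs[c2] = conv_fwd(net.layers[c2], T.outs[c1], T.cols[c2]);
    x = T.outs[c2];
  }
  int h = net.head_idx();
  T.outs[h] = conv_fwd(net.layers[h], x, T.cols[h]);
  T.probs = T.outs[h];
  softmax_channels(T.probs);
}

// labels: H x W integer class ids; accumulates gradients; returns CE loss
static double backward(UNet& net, Tape& T, const imat& y) {
  const int D = net.D;
  const int H = T.probs.n_rows, W = T.probs.n_cols;
  const uword HW = (uword)H * W;
  const float inv = 1.0f / (float)HW;

  double ce = 0.0;
  fcube dlog = T.probs;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const int k = y(i, j);
      ce -= std::log(std::max(1e-12, (double)T.probs(i, j, k)));
      dlog(i, j, k) -= 1.0f;
    }
  ce /= (double)HW;
  dlog *= inv;

  int h = net.head_idx();
  fcube d = conv_bwd(net.layers[h], T.outs[h], T.cols[h], dlog);

  std::vector<fcube> dskip(D - 1);
  for (int lvl = 0; lvl <= D - 2; ++lvl) {
    int u = net.dec_idx(lvl, 0), c1 = net.dec_idx(lvl, 1), c2 = net.dec_idx(lvl, 2);
    d = conv_bwd(net.layers[c2], T.outs[c2], T.cols[c2], d);
    d = conv_bwd(net.layers[c1], T.outs[c1], T.cols[c1], d);
    const int cl = net.ch[lvl];
    fcube d_up = d.slices(0, cl - 1);
    dskip[lvl] = d.slices(cl, 2 * cl - 1);
    d = conv_bwd(net.layers[u], T.outs[u], T.cols[u], d_up);
    d = up_bwd(d);
  }
  if (T.dropmasks[D - 1].n_elem > 0) d %= T.dropmasks[D - 1];
  d = conv_bwd(net.layers[net.bot_idx(1)], T.outs[net.bot_idx(1)], T.cols[net.bot_idx(1)], d);
  d = conv_bwd(net.layers[net.bot_idx(0)], T.outs[net.bot_idx(0)], T.cols[net.bot_idx(0)], d);

  for (int lvl = D - 2; lvl >= 0; --lvl) {
    d = pool_bwd(d, T.poolargs[lvl], T.skips[lvl].n_rows, T.skips[lvl].n_cols);
    d += dskip[lvl];
    if (T.dropmasks[lvl].n_elem > 0) d %= T.dropmasks[lvl];
    int a = net.enc_idx(lvl, 0), b = net.enc_idx(lvl, 1);
    d = conv_bwd(net.layers[b], T.outs[b], T.cols[b], d);
    d = conv_bwd(net.layers[a], T.outs[a], T.cols[a], d);
  }
  return ce;
}

static void adam_step(UNet& net, double lr, int batch) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  net.t_adam += 1;
  const float c1 = 1.0f - std::pow(b1, (float)net.t_adam);
  const float c2 = 1.0f - std::pow(b2, (float)net.t_adam);
  const float scale = 1.0f / (float)batch;
  for (auto& L : net.layers) {
    L.gW *= scale; L.gb *= scale;
    L.mW = b1 * L.mW + (1.0f - b1) * L.gW;
    L.vW = b2 * L.vW + (1.0f - b2) * arma::square(L.gW);
    L.mb = b1 * L.mb + (1.0f - b1) * L.gb;
    L.vb = b2 * L.vb + (1.0f - b2) * arma::square(L.gb);
    L.W -= (float)lr * (L.mW / c1) / (arma::sqrt(L.vW / c2) + eps);
    L.b -= (float)lr * (L.mb / c1) / (arma::sqrt(L.vb / c2) + eps);
    L.gW.zeros(); L.gb.zeros();
  }
}

static fcube image_from_R(const Rcpp::NumericVector& x, int H, int W, size_t offset) {
  fcube img(H, W, 1);
  const double* src = x.begin() + offset;
  float* dst = img.memptr();
  for (size_t i = 0; i < (size_t)H * W; ++i) dst[i] = (float)src[i];
  return img;
}

// [[Rcpp::export]]
SEXP unet_create_cpp(Rcpp::IntegerVector channels, int input_size, int n_classes,
                     double dropout, int seed) {
  std::vector<int> ch(channels.begin(), channels.end());
  UNet* net = new UNet();
  net->build(ch, input_size, n_classes, dropout, seed);
  Rcpp::XPtr<UNet> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
Rcpp::NumericVector unet_predict_cpp(SEXP ptr_, Rcpp::NumericVector x) {
  Rcpp::XPtr<UNet> net(ptr_);
  Rcpp::IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], B = dims[2];
  Rcpp::NumericVector out((size_t)H * W * net->K * B);
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, net->K, B);
  Tape T;
  for (int b = 0; b < B; ++b) {
    fcube img = image_from_R(x, H, W, (size_t)b * H * W);
    forward(*net, img, false, T);
    double* dst = out.begin() + (size_t)b * H * W * net->K;
    const float* src = T.probs.memptr();
    for (size_t i = 0; i < (size_t)H * W * net->K; ++i) dst[i] = (double)src[i];
  }
  return out;
}

// [[Rcpp::export]]
double unet_train_batch_cpp(SEXP ptr_, Rcpp::NumericVector x, Rcpp::IntegerVector y,
                            double lr) {
  Rcpp::XPtr<UNet> net(ptr_);
  Rcpp::IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], B = dims[2];
  double total = 0.0;
  Tape T;
  for (int b = 0; b < B; ++b) {
    fcube img = image_from_R(x, H, W, (size_t)b * H * W);
    imat yb(H, W);
    const int* src = y.begin() + (size_t)b * H * W;
    for (size_t i = 0; i < (size_t)H * W; ++i) yb[i] = src[i];
    forward(*net, img, true, T);
    total += backward(*net, T, yb);
  }
  adam_step(*net, lr, B);
  return total / B;
}

// [[Rcpp::export]]
double unet_loss_cpp(SEXP ptr_, Rcpp::NumericVector x, Rcpp::IntegerVector y) {
  Rcpp::XPtr<UNet> net(ptr_);
  Rcpp::IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], B = dims[2];
  double total = 0.0;
  Tape T;
  for (int b = 0; b < B; ++b) {
    fcube img = image_from_R(x, H, W, (size_t)b * H * W);
    forward(*net, img, false, T);
    const int* src = y.begin() + (size_t)b * H * W;
    const uword HW = (uword)H * W;
    double ce = 0.0;
    for (uword p = 0; p < HW; ++p)
      ce -= std::log(std::max(1e-12, (double)T.probs[p + (uword)src[p] * HW]));
    total += ce / (double)HW;
  }
  return total / B;
}

// [[Rcpp::export]]
Rcpp::List unet_get_weights_cpp(SEXP ptr_) {
  Rcpp::XPtr<UNet> net(ptr_);
  Rcpp::List out(net->layers.size());
  for (size_t i = 0; i < net->layers.size(); ++i) {
    const Conv& L = net->layers[i];
    Rcpp::NumericMatrix W(L.W.n_rows, L.W.n_cols);
    for (uword j = 0; j < L.W.n_elem; ++j) W[j] = (double)L.W[j];
    Rcpp::NumericVector b(L.b.n_elem);
    for (uword j = 0; j < L.b.n_elem; ++j) b[j] = (double)L.b[j];
    out[i] = Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("b") = b);
  }
  return out;
}

// [[Rcpp::export]]
void unet_set_weights_cpp(SEXP ptr_, Rcpp::List w) {
  Rcpp::XPtr<UNet> net(ptr_);
  if ((size_t)w.size() != net->layers.size())
    Rcpp::stop("weight list length does not match layer count");
  for (size_t i = 0; i < net->layers.size(); ++i) {
    Rcpp::List li = w[i];
    Rcpp::NumericMatrix W = li["W"];
    Rcpp::NumericVector b = li["b"];
    Conv& L = net->layers[i];
    if ((uword)W.nrow() != L.W.n_rows || (uword)W.ncol() != L.W.n_cols)
      Rcpp::stop("weight matrix shape mismatch at layer %d", (int)i + 1);
    for (uword j = 0; j < L.W.n_elem; ++j) L.W[j] = (float)W[j];
    for (uword j = 0; j < L.b.n_elem; ++j) L.b[j] = (float)b[j];
  }
}

// [[Rcpp::export]]
double unet_n_params_cpp(SEXP ptr_) {
  Rcpp::XPtr<UNet> net(ptr_);
  double n = 0;
  for (const auto& L : net->layers) n += (double)L.W.n_elem + (double)L.b.n_elem;
  return n;
}

// Numeric gradient support: compute analytic grads for one (image, label) pair
// without an optimizer step; returns them in layer order.
// [[Rcpp::export]]
Rcpp::List unet_grads_cpp(SEXP ptr_, Rcpp::NumericVector x, Rcpp::IntegerVector y) {
  Rcpp::XPtr<UNet> net(ptr_);
  Rcpp::IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1];
  fcube img = image_from_R(x, H, W, 0);
  imat yb(H, W);
  for (size_t i = 0; i < (size_t)H * W; ++i) yb[i] = y[i];
  for (auto& L : net->layers) { L.gW.zeros(); L.gb.zeros(); }
  Tape T;
  forward(*net, img, false, T);
  backward(*net, T, yb);
  Rcpp::List out(net->layers.size());
  for (size_t i = 0; i < net->layers.size(); ++i) {
    const Conv& L = net->layers[i];
    Rcpp::NumericMatrix gW(L.gW.n_rows, L.gW.n_cols);
    for (uword j = 0; j < L.gW.n_elem; ++j) gW[j] = (double)L.gW[j];
    Rcpp::NumericVector gb(L.gb.n_elem);
    for (uword j = 0; j < L.gb.n_elem; ++j) gb[j] = (double)L.gb[j];
    out[i] = Rcpp::List::create(Rcpp::Named("W") = gW, Rcpp::Named("b") = gb);
  }
  for (auto& L : net->layers) { L.gW.zeros(); L.gb.zeros(); }
  return out;
}
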
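// Patch-based U-Net: float32 im2col/BLAS implementation with Adam updates.
//
// Activations are stored channel-major: an arma::fmat with C rows and
// H*W*N columns, where the column index of pixel (r, c) of sample n is
// n*H*W + r*W + c.  All convolutions are 3x3 with unit zero-padding except
// the 1x1 two-class head; pooling is 2x2 max; upsampling is 2x nearest
// neighbour; skip connections concatenate channels.  Everything is
// deterministic for a fixed seed (single gemm call order, first-match
// pooling ties).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

#ifdef __GLIBC__
#include <malloc.h>
// Training allocates and frees multi-megabyte im2col buffers every batch;
// keeping them on the heap instead of mmap avoids re-faulting the pages.
struct MallocTune {
  MallocTune() {
    mallopt(M_MMAP_THRESHOLD, 1 << 30);
    mallopt(M_TRIM_THRESHOLD, 1 << 30);
  }
};
static MallocTune mallocTune;
#endif

using arma::fmat;
using arma::fvec;

static const float CE_EPS = 1e-7f;

struct ConvLayer {
  fmat W;          // cout x (cin*k*k)
  fvec b;          // cout
  fmat mW, vW;     // Adam state
  fvec mb, vb;
  int cin, cout, k;

  void init(int cin_, int cout_, int k_, std::mt19937& rng) {
    cin = cin_; cout = cout_; k = k_;
    const int fan_in = cin * k * k;
    std::normal_distribution<float> g(0.0f, std::sqrt(2.0f / fan_in));
    W.set_size(cout, fan_in);
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = g(rng);
    b.zeros(cout);
    mW.zeros(cout, fan_in); vW.zeros(cout, fan_in);
    mb.zeros(cout); vb.zeros(cout);
  }
};

// ---- spatial primitives -------------------------------------------------

// 3x3, pad 1 im2col: rows ordered tap-major (tap index k = 3*(dr+1)+(dc+1),
// row block k*C .. k*C+C-1). Raw pointer loops: per output pixel, each tap
// contributes C contiguous floats.
static fmat im2col3(const fmat& A, int H, int W, int N) {
  const int C = A.n_rows;
  fmat cols(C * 9, A.n_cols, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const size_t off = (size_t)n * H * W;
    for (int k = 0; k < 9; ++k) {
      const int dr = k / 3 - 1, dc = k % 3 - 1;
      const int c0 = std::max(0, -dc), c1 = std::min(W - 1, W - 1 - dc);
      const int len = c1 - c0 + 1;
      if (len <= 0) continue;
      for (int r = 0; r < H; ++r) {
        const int sr = r + dr;
        if (sr < 0 || sr >= H) continue;
        // source pixels are one contiguous C*len block; destination pixels
        // are C-blocks strided by 9C
        const float* src = A.colptr(off + (size_t)sr * W + c0 + dc);
        float* dst = cols.colptr(off + (size_t)r * W + c0) + (size_t)k * C;
        for (int c = 0; c < len; ++c) {
          const float* s = src + (size_t)c * C;
          float* d = dst + (size_t)c * 9 * C;
          for (int ch = 0; ch < C; ++ch) d[ch] = s[ch];
        }
      }
    }
  }
  return cols;
}

static fmat col2im3(const fmat& cols, int C, int H, int W, int N) {
  fmat A(C, (size_t)H * W * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const size_t off = (size_t)n * H * W;
    for (int k = 0; k < 9; ++k) {
      const int dr = k / 3 - 1, dc = k % 3 - 1;
      const int c0 = std::max(0, -dc), c1 = std::min(W - 1, W - 1 - dc);
      const int len = c1 - c0 + 1;
      if (len <= 0) continue;
      for (int r = 0; r < H; ++r) {
        const int sr = r + dr;
        if (sr < 0 || sr >= H) continue;
        float* dst = A.colptr(off + (size_t)sr * W + c0 + dc);
        const float* src = cols.colptr(off + (size_t)r * W + c0) +
                           (size_t)k * C;
        for (int c = 0; c < len; ++c) {
          const float* s = src + (size_t)c * 9 * C;
          float* d = dst + (size_t)c * C;
          for (int ch = 0; ch < C; ++ch) d[ch] += s[ch];
        }
      }
    }
  }
  return A;
}

static fmat maxpool2(const fmat& A, int H, int W, int N,
                     arma::Mat<unsigned char>& idx) {
  const int C = A.n_rows, H2 = H / 2, W2 = W / 2;
  fmat P(C, (size_t)H2 * W2 * N);
  idx.set_size(C, (size_t)H2 * W2 * N);
  for (int n = 0; n < N; ++n)
    for (int r2 = 0; r2 < H2; ++r2)
      for (int c2 = 0; c2 < W2; ++c2) {
        const size_t o = (size_t)n * H2 * W2 + (size_t)r2 * W2 + c2;
        const size_t i00 = (size_t)n * H * W + (size_t)(2 * r2) * W + 2 * c2;
        const float* a0 = A.colptr(i00);
        const float* a1 = A.colptr(i00 + 1);
        const float* a2 = A.colptr(i00 + W);
        const float* a3 = A.colptr(i00 + W + 1);
        float* p = P.colptr(o);
        unsigned char* ix = idx.colptr(o);
        for (int ch = 0; ch < C; ++ch) {
          float m = a0[ch]; unsigned char mi = 0;
          if (a1[ch] > m) { m = a1[ch]; mi = 1; }
          if (a2[ch] > m) { m = a2[ch]; mi = 2; }
          if (a3[ch] > m) { m = a3[ch]; mi = 3; }
          p[ch] = m; ix[ch] = mi;
        }
      }
  return P;
}

static fmat maxpool2_back(const fmat& dP, const arma::Mat<unsigned char>& idx,
                          int H, int W, int N) {
  const int C = dP.n_rows, H2 = H / 2, W2 = W / 2;
  fmat dA(C, (size_t)H * W * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int r2 = 0; r2 < H2; ++r2)
      for (int c2 = 0; c2 < W2; ++c2) {
        const size_t o = (size_t)n * H2 * W2 + (size_t)r2 * W2 + c2;
        const size_t i00 = (size_t)n * H * W + (size_t)(2 * r2) * W + 2 * c2;
        const float* dp = dP.colptr(o);
        const unsigned char* ix = idx.colptr(o);
        for (int ch = 0; ch < C; ++ch) {
          const size_t tgt = i00 + (ix[ch] / 2) * W + (ix[ch] % 2);
          dA.colptr(tgt)[ch] += dp[ch];
        }
      }
  return dA;
}

static fmat upsample2(const fmat& A, int H2, int W2, int N) {
  const int C = A.n_rows, H = 2 * H2, W = 2 * W2;
  fmat U(C, (size_t)H * W * N);
  for (int n = 0; n < N; ++n)
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c) {
        const size_t src = (size_t)n * H2 * W2 + (size_t)(r / 2) * W2 + c / 2;
        const size_t dst = (size_t)n * H * W + (size_t)r * W + c;
        U.col(dst) = A.col(src);
      }
  return U;
}

static fmat upsample2_back(const fmat& dU, int H2, int W2, int N) {
  const int C = dU.n_rows, H = 2 * H2, W = 2 * W2;
  fmat dA(C, (size_t)H2 * W2 * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c) {
        const size_t src = (size_t)n * H2 * W2 + (size_t)(r / 2) * W2 + c / 2;
        const size_t dst = (size_t)n * H * W + (size_t)r * W + c;
        dA.col(src) += dU.col(dst);
      }
  return dA;
}

// ---- network ------------------------------------------------------------

class UNet {
public:
  int depth, base, cin, nclass;
  std::vector<ConvLayer> layers;  // 2*depth enc + 2 bottleneck + 2*depth dec + head
  long long tstep = 0;

  UNet(int depth_, int base_, int cin_, int nclass_, unsigned int seed)
      : depth(depth_), base(base_), cin(cin_), nclass(nclass_) {
    std::mt19937 rng(seed);
    layers.resize(4 * depth + 3);
    int li = 0;
    int prev = cin;
    for (int i = 0; i < depth; ++i) {
      const int f = base << i;
      layers[li++].init(prev, f, 3, rng);
      layers[li++].init(f, f, 3, rng);
      prev = f;
    }
    const int fb = base << depth;
    layers[li++].init(prev, fb, 3, rng);
    layers[li++].init(fb, fb, 3, rng);
    prev = fb;
    for (int i = depth - 1; i >= 0; --i) {
      const int f = base << i;
      layers[li++].init(f + prev, f, 3, rng);
      layers[li++].init(f, f, 3, rng);
      prev = f;
    }
    // zero-init the head: training starts from the uniform prediction,
    // avoiding a random initial class bias that can destabilize narrow
    // networks in the first epochs
    layers[li].init(prev, nclass, 1, rng);
    layers[li].W.zeros();
    ++li;
  }

  long long n_params() const {
    long long n = 0;
    for (const auto& L : layers) n += (long long)L.W.n_elem + L.b.n_elem;
    return n;
  }

  struct Cache {
    std::vector<fmat> conv_cols; // im2col input of each 3x3 conv layer
    std::vector<fmat> conv_out;  // post-ReLU output (ReLU mask source)
    fmat head_in;                // input activation of the 1x1 head
    std::vector<arma::Mat<unsigned char>> pool_idx;
    std::vector<int> Hs;         // spatial side at each encoder level
    fmat probs;                  // nclass x HWN
  };

  // forward pass; X is cin x (H*H*N)
  fmat forward(const fmat& X, int H, int N, Cache* cache) {
    Cache local;
    Cache& cc = cache ? *cache : local;
    const bool keep = cache != nullptr;
    cc.conv_cols.assign(layers.size(), fmat());
    cc.conv_out.assign(layers.size(), fmat());
    cc.pool_idx.assign(depth, arma::Mat<unsigned char>());
    cc.Hs.assign(depth + 1, 0);

    std::vector<fmat> skips(depth);
    fmat cur = X;
    int h = H, li = 0;
    for (int i = 0; i < depth; ++i) {
      cc.Hs[i] = h;
      cur = conv_relu(cur, h, N, li, cc, keep); ++li;
      cur = conv_relu(cur, h, N, li, cc, keep); ++li;
      skips[i] = cur;
      cur = maxpool2(cur, h, h, N, cc.pool_idx[i]);
      h /= 2;
    }
    cc.Hs[depth] = h;
    cur = conv_relu(cur, h, N, li, cc, keep); ++li;
    cur = conv_relu(cur, h, N, li, cc, keep); ++li;
    for (int i = depth - 1; i >= 0; --i) {
      cur = upsample2(cur, h, h, N);
      h *= 2;
      cur = arma::join_cols(skips[i], cur);
      cur = conv_relu(cur, h, N, li, cc, keep); ++li;
      cur = conv_relu(cur, h, N, li, cc, keep); ++li;
    }
    // 1x1 head + row-wise softmax
    ConvLayer& Lh = layers[li];
    if (keep) cc.head_in = cur;
    fmat logits = Lh.W * cur;
    logits.each_col() += Lh.b;
    fmat mx = arma::max(logits, 0);
    logits.each_row() -= mx;
    fmat ex = arma::exp(logits);
    fmat sm = arma::sum(ex, 0);
    ex.each_row() /= sm;
    cc.probs = ex;
    return ex;
  }

  // backward + Adam step; Y is 1 x HWN vessel labels in {0,1}; returns loss
  double train_batch(const fmat& X, const fmat& Y, int H, int N,
                     double lr, double beta1, double beta2, double eps) {
    Cache cc;
    forward(X, H, N, &cc);
    const size_t M = cc.probs.n_cols;

    // cross-entropy on the two-class softmax
    double loss = 0.0;
    for (size_t j = 0; j < M; ++j) {
      const float p1 = std::min(std::max(cc.probs(1, j), CE_EPS), 1.0f - CE_EPS);
      loss -= Y(0, j) > 0.5f ? std::log((double)p1) : std::log((double)(1.0f - p1));
    }
    loss /= (double)M;

    // dLogits = probs - onehot(Y), averaged over pixels
    fmat dcur = cc.probs;
    for (size_t j = 0; j < M; ++j) {
      if (Y(0, j) > 0.5f) dcur(1, j) -= 1.0f; else dcur(0, j) -= 1.0f;
    }
    dcur /= (float)M;

    std::vector<fmat> dW(layers.size());
    std::vector<fvec> db(layers.size());
    std::vector<fmat> skip_grad(depth);

    int li = (int)layers.size() - 1;
    // head (1x1): no ReLU
    dW[li] = dcur * cc.head_in.t();
    db[li] = arma::sum(dcur, 1);
    dcur = layers[li].W.t() * dcur;
    --li;

    int h = H;
    // decoder levels i = 0 .. depth-1 (in reverse build order)
    for (int i = 0; i < depth; ++i) {
      dcur = conv_relu_back(dcur, h, N, li, cc, dW, db); --li;
      dcur = conv_relu_back(dcur, h, N, li, cc, dW, db); --li;
      const int fskip = base << i;
      skip_grad[i] = dcur.rows(0, fskip - 1);
      fmat dup = dcur.rows(fskip, dcur.n_rows - 1);
      h /= 2;
      dcur = upsample2_back(dup, h, h, N);
    }
    // bottleneck
    dcur = conv_relu_back(dcur, h, N, li, cc, dW, db); --li;
    dcur = conv_relu_back(dcur, h, N, li, cc, dW, db); --li;
    // encoder in reverse
    for (int i = depth - 1; i >= 0; --i) {
      const int hh = cc.Hs[i];
      dcur = maxpool2_back(dcur, cc.pool_idx[i], hh, hh, N);
      dcur += skip_grad[i];
      h = hh;
      dcur = conv_relu_back(dcur, h, N, li, cc, dW, db); --li;
      dcur = conv_relu_back(dcur, h, N, li, cc, dW, db); --li;
    }

    // Adam
    ++tstep;
    const double bc1 = 1.0 - std::pow(beta1, (double)tstep);
    const double bc2 = 1.0 - std::pow(beta2, (double)tstep);
    for (size_t k = 0; k < layers.size(); ++k) {
      ConvLayer& L = layers[k];
      L.mW = (float)beta1 * L.mW + (float)(1 - beta1) * dW[k];
      L.vW = (float)beta2 * L.vW + (float)(1 - beta2) * arma::square(dW[k]);
      L.W -= (float)lr * (L.mW / (float)bc1) /
             (arma::sqrt(L.vW / (float)bc2) + (float)eps);
      L.mb = (float)beta1 * L.mb + (float)(1 - beta1) * db[k];
      L.vb = (float)beta2 * L.vb + (float)(1 - beta2) * arma::square(db[k]);
      L.b -= (float)lr * (L.mb / (float)bc1) /
             (arma::sqrt(L.vb / (float)bc2) + (float)eps);
    }
    return loss;
  }

  double eval_loss(const fmat& X, const fmat& Y, int H, int N) {
    fmat probs = forward(X, H, N, nullptr);
    const size_t M = probs.n_cols;
    double loss = 0.0;
    for (size_t j = 0; j < M; ++j) {
      const float p1 = std::min(std::max(probs(1, j), CE_EPS), 1.0f - CE_EPS);
      loss -= Y(0, j) > 0.5f ? std::log((double)p1) : std::log((double)(1.0f - p1));
    }
    return loss / (double)M;
  }

private:
  fmat conv_relu(const fmat& A, int h, int N, int li, Cache& cc, bool keep) {
    ConvLayer& L = layers[li];
    fmat cols = im2col3(A, h, h, N);
    fmat Z = L.W * cols;
    Z.each_col() += L.b;
    float* z = Z.memptr();
    for (arma::uword e = 0; e < Z.n_elem; ++e) if (z[e] < 0.0f) z[e] = 0.0f;
    if (keep) {
      cc.conv_cols[li] = std::move(cols);
      cc.conv_out[li] = Z;
    }
    return Z;
  }

  // backward through conv+ReLU layer li given upstream grad on its output
  fmat conv_relu_back(fmat dOut, int h, int N, int li, const Cache& cc,
                      std::vector<fmat>& dW, std::vector<fvec>& db) {
    ConvLayer& L = layers[li];
    const float* out = cc.conv_out[li].memptr();
    float* d = dOut.memptr();
    for (arma::uword e = 0; e < dOut.n_elem; ++e)
      if (out[e] <= 0.0f) d[e] = 0.0f;
    const fmat& cols = cc.conv_cols[li];
    dW[li] = dOut * cols.t();
    db[li] = arma::sum(dOut, 1);
    fmat dcols = L.W.t() * dOut;
    return col2im3(dcols, L.cin, h, h, N);
  }
};

// ---- R interface --------------------------------------------------------

static fmat r_to_act(const Rcpp::NumericVector& x, int H, int W, int C, int N) {
  fmat A(C, (size_t)H * W * N);
  const double* p = x.begin();
  for (int n = 0; n < N; ++n)
    for (int ch = 0; ch < C; ++ch)
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          A(ch, (size_t)n * H * W + (size_t)h * W + w) =
            (float)p[(size_t)h + (size_t)H * w + (size_t)H * W * ch +
                     (size_t)H * W * C * n];
        }
  return A;
}

static void check_x(const Rcpp::NumericVector& x, int cin) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 4) Rcpp::stop("input must be a 4-d array (H, W, C, N)");
  if (d[0] != d[1]) Rcpp::stop("patches must be square");
  if (d[2] != cin) Rcpp::stop("channel count %d does not match model (%d)", (int)d[2], cin);
}

// [[Rcpp::export(name = ".unet_create")]]
SEXP unet_create(int depth, int base_filters, int in_channels, int n_classes,
                 int seed) {
  if (depth < 1 || base_filters < 1 || in_channels < 1 || n_classes < 2)
    Rcpp::stop("invalid U-Net configuration");
  Rcpp::XPtr<UNet> p(new UNet(depth, base_filters, in_channels, n_classes,
                              (unsigned int)seed), true);
  return p;
}

// [[Rcpp::export(name = ".unet_n_params")]]
double unet_n_params(SEXP ptr) {
  Rcpp::XPtr<UNet> p(ptr);
  return (double)p->n_params();
}

// [[Rcpp::export(name = ".unet_forward")]]
Rcpp::NumericVector unet_forward(SEXP ptr, Rcpp::NumericVector x, bool full) {
  Rcpp::XPtr<UNet> p(ptr);
  check_x(x, p->cin);
  Rcpp::IntegerVector d = x.attr("dim");
  const int H = d[0], C = d[2], N = d[3];
  if (N == 0) {
    Rcpp::NumericVector out(0);
    out.attr("dim") = full ? Rcpp::IntegerVector::create(H, H, p->nclass, 0)
                           : Rcpp::IntegerVector::create(H, H, 0);
    return out;
  }
  if (H % (1 << p->depth) != 0)
    Rcpp::stop("patch side %d not divisible by 2^depth", H);
  fmat A = r_to_act(x, H, H, C, N);
  fmat probs = p->forward(A, H, N, nullptr);
  if (full) {
    Rcpp::NumericVector out((size_t)H * H * p->nclass * N);
    for (int n = 0; n < N; ++n)
      for (int k = 0; k < p->nclass; ++k)
        for (int w = 0; w < H; ++w)
          for (int h = 0; h < H; ++h)
            out[(size_t)h + (size_t)H * w + (size_t)H * H * k +
                (size_t)H * H * p->nclass * n] =
              probs(k, (size_t)n * H * H + (size_t)h * H + w);
    out.attr("dim") = Rcpp::IntegerVector::create(H, H, p->nclass, N);
    return out;
  }
  Rcpp::NumericVector out((size_t)H * H * N);
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < H; ++w)
      for (int h = 0; h < H; ++h)
        out[(size_t)h + (size_t)H * w + (size_t)H * H * n] =
          probs(1, (size_t)n * H * H + (size_t)h * H + w);
  out.attr("dim") = Rcpp::IntegerVector::create(H, H, N);
  return out;
}

// [[Rcpp::export(name = ".unet_train_batch")]]
double unet_train_batch(SEXP ptr, Rcpp::NumericVector x, Rcpp::NumericVector y,
                        double lr, double beta1, double beta2, double eps) {
  Rcpp::XPtr<UNet> p(ptr);
  check_x(x, p->cin);
  Rcpp::IntegerVector d = x.attr("dim");
  const int H = d[0], C = d[2], N = d[3];
  if (N < 1) Rcpp::stop("empty batch");
  fmat A = r_to_act(x, H, H, C, N);
  fmat Y(1, (size_t)H * H * N);
  const double* py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < H; ++w)
      for (int h = 0; h < H; ++h)
        Y(0, (size_t)n * H * H + (size_t)h * H + w) =
          (float)py[(size_t)h + (size_t)H * w + (size_t)H * H * n];
  return p->train_batch(A, Y, H, N, lr, beta1, beta2, eps);
}

// [[Rcpp::export(name = ".unet_eval_loss")]]
double unet_eval_loss(SEXP ptr, Rcpp::NumericVector x, Rcpp::NumericVector y) {
  Rcpp::XPtr<UNet> p(ptr);
  check_x(x, p->cin);
  Rcpp::IntegerVector d = x.attr("dim");
  const int H = d[0], C = d[2], N = d[3];
  if (N < 1) Rcpp::stop("empty batch");
  fmat A = r_to_act(x, H, H, C, N);
  fmat Y(1, (size_t)H * H * N);
  const double* py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < H; ++w)
      for (int h = 0; h < H; ++h)
        Y(0, (size_t)n * H * H + (size_t)h * H + w) =
          (float)py[(size_t)h + (size_t)H * w + (size_t)H * H * n];
  return p->eval_loss(A, Y, H, N);
}

// [[Rcpp::export(name = ".unet_get_weights")]]
Rcpp::List unet_get_weights(SEXP ptr) {
  Rcpp::XPtr<UNet> p(ptr);
  Rcpp::List out(p->layers.size());
  for (size_t i = 0; i < p->layers.size(); ++i) {
    const ConvLayer& L = p->layers[i];
    Rcpp::NumericMatrix W(L.W.n_rows, L.W.n_cols);
    for (arma::uword j = 0; j < L.W.n_elem; ++j) W[j] = L.W(j);
    Rcpp::NumericVector b(L.b.n_elem);
    for (arma::uword j = 0; j < L.b.n_elem; ++j) b[j] = L.b(j);
    out[i] = Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("b") = b,
                                Rcpp::Named("k") = L.k);
  }
  return out;
}

// [[Rcpp::export(name = ".unet_set_weights")]]
void unet_set_weights(SEXP ptr, Rcpp::List weights) {
  Rcpp::XPtr<UNet> p(ptr);
  if ((size_t)weights.size() != p->layers.size())
    Rcpp::stop("weight list has %d layers; model has %d",
               (int)weights.size(), (int)p->layers.size());
  for (size_t i = 0; i < p->layers.size(); ++i) {
    Rcpp::List li = weights[i];
    Rcpp::NumericMatrix W = li["W"];
    Rcpp::NumericVector b = li["b"];
    ConvLayer& L = p->layers[i];
    if ((arma::uword)W.nrow() != L.W.n_rows ||
        (arma::uword)W.ncol() != L.W.n_cols ||
        (arma::uword)b.size() != L.b.n_elem)
      Rcpp::stop("layer %d weight shape mismatch", (int)i + 1);
    for (arma::uword j = 0; j < L.W.n_elem; ++j) L.W(j) = (float)W[j];
    for (arma::uword j = 0; j < L.b.n_elem; ++j) L.b(j) = (float)b[j];
  }
}
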
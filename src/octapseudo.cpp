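// Numerical core: bilinear rigid warping and a small patch U-Net
// (batched im2col + GEMM convolutions, hand-written backprop, SGD with
// momentum). Single precision internally; interfaces use R doubles.
//
// Feature maps are held in a canonical batched layout: an (N*H*W) x C
// matrix, column-major, pixel index p = r + c*H inside item n occupying
// rows [n*H*W, (n+1)*H*W).

#include <RcppArmadillo.h>
#if defined(__SSE2__)
#include <xmmintrin.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Flush denormal floats to zero inside the network kernels: the residual
// head starts near zero, so tiny gradients/velocities otherwise drift into
// denormal range, whose hardware penalty varies wildly between CPUs.
struct DenormGuard {
#if defined(__SSE2__)
  unsigned int old_csr;
  DenormGuard() { old_csr = _mm_getcsr(); _mm_setcsr(old_csr | 0x8040u); }
  ~DenormGuard() { _mm_setcsr(old_csr); }
#endif
};

// ---------------------------------------------------------------------------
// Bilinear rigid warp. Mirrors the R-side convention: the output shows the
// input scene moved by (dx, dy, theta about the image centre); pixels whose
// source falls outside the frame are `fill` and flagged invalid.
// [[Rcpp::export]]
Rcpp::List cpp_warp_bilinear(const arma::mat& px, double dx, double dy,
                             double theta, double fill) {
  const int h = px.n_rows, w = px.n_cols;
  const double cr = (h + 1) / 2.0, cc = (w + 1) / 2.0;
  const double ct = std::cos(theta), st = std::sin(theta);
  arma::mat out(h, w);
  arma::imat valid(h, w);
  for (int c = 0; c < w; ++c) {
    const double xs0 = (c + 1) - cc - dx;
    for (int r = 0; r < h; ++r) {
      const double ys = (r + 1) - cr - dy;
      const double sx = ct * xs0 + st * ys + cc;
      const double sy = -st * xs0 + ct * ys + cr;
      if (sx < 1.0 || sx > w || sy < 1.0 || sy > h) {
        out(r, c) = fill; valid(r, c) = 0; continue;
      }
      int x0 = (int)std::floor(sx); if (x0 > w - 1) x0 = w - 1; if (x0 < 1) x0 = 1;
      int y0 = (int)std::floor(sy); if (y0 > h - 1) y0 = h - 1; if (y0 < 1) y0 = 1;
      double fx = sx - x0, fy = sy - y0;
      if (fx < 0) fx = 0; if (fx > 1) fx = 1;
      if (fy < 0) fy = 0; if (fy > 1) fy = 1;
      const double v00 = px(y0 - 1, x0 - 1), v01 = px(y0 - 1, x0);
      const double v10 = px(y0, x0 - 1),     v11 = px(y0, x0);
      out(r, c) = (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v01 +
                  (1 - fx) * fy * v10 + fx * fy * v11;
      valid(r, c) = 1;
    }
  }
  return Rcpp::List::create(Rcpp::Named("pixels") = out,
                            Rcpp::Named("valid") = valid);
}

// ---------------------------------------------------------------------------
// U-Net plumbing.
//
// Layer order (levels L, channels ch[0..L-1], 2 convs per level):
//   encA[0], encB[0], ..., encA[L-1], encB[L-1],
//   then for i = L-2 .. 0: up[i], decA[i], decB[i],
//   final 1x1 conv ch[0] -> 1.
// Weight matrices are stored as (cin * k * k) x cout, feature index
// c*k*k + (dr+1)*k + (dc+1); biases are length-cout vectors.

struct Layers {
  std::vector<fmat> W;   // (cin*k*k) x cout
  std::vector<fvec> b;
  std::vector<int> k, cin, cout;
};

static void layer_dims(const ivec& ch, std::vector<int>& k,
                       std::vector<int>& cin, std::vector<int>& cout) {
  const int L = ch.n_elem;
  k.clear(); cin.clear(); cout.clear();
  for (int i = 0; i < L; ++i) {
    cin.push_back(i == 0 ? 1 : ch[i - 1]); cout.push_back(ch[i]); k.push_back(3);
    cin.push_back(ch[i]); cout.push_back(ch[i]); k.push_back(3);
  }
  for (int i = L - 2; i >= 0; --i) {
    cin.push_back(ch[i + 1]); cout.push_back(ch[i]); k.push_back(1);   // up (1x1 after NN upsample)
    cin.push_back(2 * ch[i]); cout.push_back(ch[i]); k.push_back(3);   // decA
    cin.push_back(ch[i]); cout.push_back(ch[i]); k.push_back(3);       // decB
  }
  cin.push_back(ch[0]); cout.push_back(1); k.push_back(1);             // out
}

static Layers unpack_layers(const Rcpp::List& layers, const ivec& ch) {
  Layers L;
  layer_dims(ch, L.k, L.cin, L.cout);
  if ((int)layers.size() != (int)L.k.size())
    Rcpp::stop("weight list has %d layers, expected %d",
               (int)layers.size(), (int)L.k.size());
  for (int l = 0; l < (int)layers.size(); ++l) {
    Rcpp::List lay = layers[l];
    Rcpp::NumericMatrix Wr = lay["W"];
    Rcpp::NumericVector br = lay["b"];
    if (Wr.nrow() != L.cin[l] * L.k[l] * L.k[l] || Wr.ncol() != L.cout[l])
      Rcpp::stop("layer %d: weight matrix is %d x %d, expected %d x %d",
                 l + 1, Wr.nrow(), Wr.ncol(),
                 L.cin[l] * L.k[l] * L.k[l], L.cout[l]);
    fmat W(Wr.nrow(), Wr.ncol());
    for (int j = 0; j < Wr.ncol(); ++j)
      for (int i = 0; i < Wr.nrow(); ++i) W(i, j) = (float)Wr(i, j);
    fvec b(br.size());
    for (int i = 0; i < br.size(); ++i) b[i] = (float)br[i];
    L.W.push_back(std::move(W)); L.b.push_back(std::move(b));
  }
  return L;
}

static Rcpp::List pack_layers(const Layers& L) {
  Rcpp::List out(L.W.size());
  for (size_t l = 0; l < L.W.size(); ++l) {
    Rcpp::NumericMatrix Wr(L.W[l].n_rows, L.W[l].n_cols);
    for (size_t j = 0; j < L.W[l].n_cols; ++j)
      for (size_t i = 0; i < L.W[l].n_rows; ++i) Wr(i, j) = L.W[l](i, j);
    Rcpp::NumericVector br(L.b[l].n_elem);
    for (size_t i = 0; i < L.b[l].n_elem; ++i) br[i] = L.b[l][i];
    out[l] = Rcpp::List::create(Rcpp::Named("W") = Wr, Rcpp::Named("b") = br);
  }
  return out;
}

// Batched im2col for 3x3, pad 1: (N*H*W) x (C*9).
static fmat im2col3(const fmat& F, int N, int H, int W) {
  const int C = F.n_cols, HW = H * W;
  fmat col(N * HW, C * 9, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        const int feat = c * 9 + (dr + 1) * 3 + (dc + 1);
        float* dst0 = col.colptr(feat);
        const float* src0 = F.colptr(c);
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        for (int n = 0; n < N; ++n) {
          float* dst = dst0 + n * HW;
          const float* src = src0 + n * HW;
          for (int cl = 0; cl < W; ++cl) {
            const int sc = cl + dc;
            if (sc < 0 || sc >= W) continue;
            std::memcpy(dst + cl * H + r0, src + sc * H + r0 + dr,
                        sizeof(float) * (r1 - r0));
          }
        }
      }
  return col;
}

static fmat col2im3(const fmat& dcol, int N, int H, int W, int C) {
  const int HW = H * W;
  fmat dF(N * HW, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        const int feat = c * 9 + (dr + 1) * 3 + (dc + 1);
        const float* src0 = dcol.colptr(feat);
        float* dst0 = dF.colptr(c);
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        for (int n = 0; n < N; ++n) {
          const float* src = src0 + n * HW;
          float* dst = dst0 + n * HW;
          for (int cl = 0; cl < W; ++cl) {
            const int sc = cl + dc;
            if (sc < 0 || sc >= W) continue;
            float* d = dst + sc * H + dr;
            const float* s = src + cl * H;
            for (int r = r0; r < r1; ++r) d[r] += s[r];
          }
        }
      }
  return dF;
}

static fmat conv_fwd(const Layers& L, int l, const fmat& F,
                     int N, int H, int W) {
  fmat y = (L.k[l] == 1) ? fmat(F * L.W[l]) : fmat(im2col3(F, N, H, W) * L.W[l]);
  y.each_row() += L.b[l].t();
  return y;
}

// Gradient wrt input; accumulates weight/bias grads (im2col recomputed).
static fmat conv_bwd(const Layers& L, int l, const fmat& F, const fmat& dY,
                     int N, int H, int W, fmat& gW, fvec& gb) {
  gb += sum(dY, 0).t();
  if (L.k[l] == 1) {
    gW += F.t() * dY;
    return dY * L.W[l].t();
  }
  fmat col = im2col3(F, N, H, W);
  gW += col.t() * dY;
  fmat dcol = dY * L.W[l].t();
  return col2im3(dcol, N, H, W, F.n_cols);
}

static void relu_(fmat& x) {
  float* p = x.memptr();
  for (size_t i = 0; i < x.n_elem; ++i) if (p[i] < 0) p[i] = 0;
}
static void relu_bwd_(fmat& d, const fmat& y) {
  float* pd = d.memptr(); const float* py = y.memptr();
  for (size_t i = 0; i < y.n_elem; ++i) if (py[i] <= 0) pd[i] = 0;
}

// 2x2 max pooling; idx records the winning absolute row per output row.
static fmat maxpool_fwd(const fmat& F, int N, int H, int W, umat& idx) {
  const int Ho = H / 2, Wo = W / 2, C = F.n_cols;
  const int HW = H * W, HWo = Ho * Wo;
  fmat y(N * HWo, C); idx.set_size(N * HWo, C);
  for (int c = 0; c < C; ++c) {
    const float* src = F.colptr(c);
    float* dst = y.colptr(c);
    uword* id = idx.colptr(c);
    for (int n = 0; n < N; ++n)
      for (int cl = 0; cl < Wo; ++cl)
        for (int r = 0; r < Ho; ++r) {
          float best = -1e30f; uword bi = 0;
          for (int j = 0; j < 2; ++j)
            for (int i = 0; i < 2; ++i) {
              const uword s = n * HW + (2 * cl + j) * H + (2 * r + i);
              if (src[s] > best) { best = src[s]; bi = s; }
            }
          const uword o = n * HWo + cl * Ho + r;
          dst[o] = best; id[o] = bi;
        }
  }
  return y;
}

static fmat maxpool_bwd(const fmat& dY, const umat& idx, int N, int H, int W) {
  const int C = dY.n_cols;
  fmat dF(N * H * W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const float* src = dY.colptr(c);
    const uword* id = idx.colptr(c);
    float* dst = dF.colptr(c);
    for (size_t o = 0; o < dY.n_rows; ++o) dst[id[o]] += src[o];
  }
  return dF;
}

// nearest-neighbour 2x upsampling
static fmat upsample_fwd(const fmat& F, int N, int H, int W) {
  const int Ho = 2 * H, Wo = 2 * W, C = F.n_cols;
  const int HW = H * W, HWo = Ho * Wo;
  fmat y(N * HWo, C);
  for (int c = 0; c < C; ++c) {
    const float* src = F.colptr(c);
    float* dst = y.colptr(c);
    for (int n = 0; n < N; ++n)
      for (int cl = 0; cl < W; ++cl)
        for (int r = 0; r < H; ++r) {
          const float v = src[n * HW + cl * H + r];
          float* d = dst + n * HWo + (2 * cl) * Ho + 2 * r;
          d[0] = v; d[1] = v; d[Ho] = v; d[Ho + 1] = v;
        }
  }
  return y;
}

static fmat upsample_bwd(const fmat& dY, int N, int H, int W) {
  // (H, W) is the *input* (coarse) size
  const int Ho = 2 * H, HWo = 4 * H * W, HW = H * W, C = dY.n_cols;
  fmat dF(N * HW, C);
  for (int c = 0; c < C; ++c) {
    const float* src = dY.colptr(c);
    float* dst = dF.colptr(c);
    for (int n = 0; n < N; ++n)
      for (int cl = 0; cl < W; ++cl)
        for (int r = 0; r < H; ++r) {
          const float* s = src + n * HWo + (2 * cl) * Ho + 2 * r;
          dst[n * HW + cl * H + r] = s[0] + s[1] + s[Ho] + s[Ho + 1];
        }
  }
  return dF;
}

struct Cache {
  std::vector<fmat> A, B, P, U, UA, K, DA, DB;
  std::vector<umat> PIdx;
  fmat y;        // output in [0,1], (N*H*W) x 1
  fmat dgate;    // d(output)/d(pre-activation), same shape
};

// head_linear = false: y = sigmoid(logit(x) + g)   (logit-residual head)
// head_linear = true:  y = clamp(x + g, 0, 1)      (linear-residual head)
static void unet_forward_batch(const Layers& L, const ivec& ch,
                               const fmat& x, int N, int H0, int W0,
                               Cache& cc, bool head_linear) {
  const int nl = ch.n_elem;
  cc.A.assign(nl, fmat()); cc.B.assign(nl, fmat());
  cc.P.assign(nl, fmat()); cc.PIdx.assign(nl, umat());
  cc.U.assign(nl, fmat()); cc.UA.assign(nl, fmat());
  cc.K.assign(nl, fmat()); cc.DA.assign(nl, fmat()); cc.DB.assign(nl, fmat());
  int H = H0, W = W0;
  for (int i = 0; i < nl; ++i) {
    const fmat& src = (i == 0) ? x : cc.P[i - 1];
    cc.A[i] = conv_fwd(L, 2 * i, src, N, H, W);         relu_(cc.A[i]);
    cc.B[i] = conv_fwd(L, 2 * i + 1, cc.A[i], N, H, W); relu_(cc.B[i]);
    if (i < nl - 1) {
      cc.P[i] = maxpool_fwd(cc.B[i], N, H, W, cc.PIdx[i]);
      H /= 2; W /= 2;
    }
  }
  const fmat* h = &cc.B[nl - 1];
  for (int i = nl - 2; i >= 0; --i) {
    const int base = 2 * nl + 3 * (nl - 2 - i);
    cc.U[i] = upsample_fwd(*h, N, H, W);
    H *= 2; W *= 2;
    cc.UA[i] = conv_fwd(L, base, cc.U[i], N, H, W); relu_(cc.UA[i]);
    cc.K[i] = join_rows(cc.B[i], cc.UA[i]);
    cc.DA[i] = conv_fwd(L, base + 1, cc.K[i], N, H, W); relu_(cc.DA[i]);
    cc.DB[i] = conv_fwd(L, base + 2, cc.DA[i], N, H, W); relu_(cc.DB[i]);
    h = &cc.DB[i];
  }
  fmat pre = conv_fwd(L, (int)L.W.size() - 1, cc.DB[0], N, H0, W0);
  // global residual: the head predicts a correction to the input, so an
  // all-zero head is exactly the identity map
  if (head_linear) {
    pre += x;
    cc.y = clamp(pre, 0.0f, 1.0f);
    cc.dgate.set_size(pre.n_rows, pre.n_cols);
    for (size_t i = 0; i < pre.n_elem; ++i)
      cc.dgate[i] = (pre[i] > 0.0f && pre[i] < 1.0f) ? 1.0f : 0.0f;
  } else {
    fmat xc = clamp(x, 1e-3f, 1.0f - 1e-3f);
    pre += log(xc / (1.0f - xc));
    cc.y = 1.0f / (1.0f + exp(-pre));
    cc.dgate = cc.y % (1.0f - cc.y);
  }
}

// dLdy: gradient of the loss wrt the sigmoid output, (N*H0*W0) x 1.
static void unet_backward_batch(const Layers& L, const ivec& ch,
                                const fmat& x, int N, int H0, int W0,
                                Cache& cc, const fmat& dLdy,
                                std::vector<fmat>& gW, std::vector<fvec>& gb) {
  const int nl = ch.n_elem;
  const int last = (int)L.W.size() - 1;
  fmat dpre = dLdy % cc.dgate;
  int H = H0, W = W0;
  fmat dh = conv_bwd(L, last, cc.DB[0], dpre, N, H, W, gW[last], gb[last]);

  std::vector<fmat> dBskip(nl);
  for (int i = 0; i <= nl - 2; ++i) {
    const int base = 2 * nl + 3 * (nl - 2 - i);
    relu_bwd_(dh, cc.DB[i]);
    fmat dDA = conv_bwd(L, base + 2, cc.DA[i], dh, N, H, W,
                        gW[base + 2], gb[base + 2]);
    relu_bwd_(dDA, cc.DA[i]);
    fmat dK = conv_bwd(L, base + 1, cc.K[i], dDA, N, H, W,
                       gW[base + 1], gb[base + 1]);
    const int C = ch[i];
    dBskip[i] = dK.cols(0, C - 1);
    fmat dUA = dK.cols(C, 2 * C - 1);
    relu_bwd_(dUA, cc.UA[i]);
    fmat dU = conv_bwd(L, base, cc.U[i], dUA, N, H, W, gW[base], gb[base]);
    H /= 2; W /= 2;
    dh = upsample_bwd(dU, N, H, W);
  }
  // dh now holds the gradient wrt the bottleneck B[nl-1] at (H, W).
  fmat dP = dh;
  for (int i = nl - 1; i >= 0; --i) {
    fmat dB;
    if (i == nl - 1) dB = dP;
    else {
      H *= 2; W *= 2;
      dB = maxpool_bwd(dP, cc.PIdx[i], N, H, W);
      dB += dBskip[i];
    }
    relu_bwd_(dB, cc.B[i]);
    fmat dA = conv_bwd(L, 2 * i + 1, cc.A[i], dB, N, H, W,
                       gW[2 * i + 1], gb[2 * i + 1]);
    relu_bwd_(dA, cc.A[i]);
    const fmat& src = (i == 0) ? x : cc.P[i - 1];
    dP = conv_bwd(L, 2 * i, src, dA, N, H, W, gW[2 * i], gb[2 * i]);
  }
}

// D4 augmentation: bit 4 = transpose (applied first), bit 1 = flip cols,
// bit 2 = flip rows.
static fmat augment(const fmat& x, int code) {
  fmat y = (code & 4) ? fmat(x.t()) : x;
  if (code & 1) y = fliplr(y);
  if (code & 2) y = flipud(y);
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_unet_forward(const Rcpp::List& layers,
                            const Rcpp::IntegerVector& channels,
                            const arma::cube& inputs, bool head_linear) {
  DenormGuard dg;
  ivec ch = Rcpp::as<ivec>(channels);
  Layers L = unpack_layers(layers, ch);
  const int H = inputs.n_rows, W = inputs.n_cols, n = inputs.n_slices;
  const int HW = H * W;
  // batch in groups to bound memory at large n
  const int group = std::max(1, (int)(1 << 24) / HW);
  cube out(H, W, n);
  Cache cc;
  for (int s = 0; s < n; s += group) {
    const int N = std::min(group, n - s);
    fmat x(N * HW, 1);
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < HW; ++j)
        x(i * HW + j, 0) = (float)inputs.slice(s + i)[j];
    unet_forward_batch(L, ch, x, N, H, W, cc, head_linear);
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < HW; ++j)
        out.slice(s + i)[j] = (double)cc.y(i * HW + j, 0);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_unet_train(const Rcpp::List& layers,
                          const Rcpp::IntegerVector& channels,
                          const arma::cube& inputs, const arma::cube& targets,
                          const arma::cube& masks,
                          const Rcpp::List& sched_idx,
                          const Rcpp::List& sched_aug,
                          double lr, double momentum, int batch_size,
                          bool head_linear) {
  DenormGuard dg;
  ivec ch = Rcpp::as<ivec>(channels);
  Layers L = unpack_layers(layers, ch);
  const int nlay = (int)L.W.size();
  const int H = inputs.n_rows, W = inputs.n_cols, HW = H * W;
  std::vector<fmat> vW(nlay), gW(nlay);
  std::vector<fvec> vb(nlay), gb(nlay);
  for (int l = 0; l < nlay; ++l) {
    vW[l].zeros(L.W[l].n_rows, L.W[l].n_cols);
    vb[l].zeros(L.b[l].n_elem);
  }
  const int n_epochs = sched_idx.size();
  Rcpp::NumericVector loss_hist(n_epochs);

  // pre-convert the pair tensors once
  std::vector<fmat> X(inputs.n_slices), T(inputs.n_slices), M(inputs.n_slices);
  for (size_t i = 0; i < inputs.n_slices; ++i) {
    X[i] = conv_to<fmat>::from(inputs.slice(i));
    T[i] = conv_to<fmat>::from(targets.slice(i));
    M[i] = conv_to<fmat>::from(masks.slice(i));
  }

  Cache cc;
  for (int e = 0; e < n_epochs; ++e) {
    Rcpp::IntegerVector idx = sched_idx[e];
    Rcpp::IntegerVector aug = sched_aug[e];
    double ep_abs = 0.0, ep_n = 0.0;
    for (int s0 = 0; s0 < idx.size(); s0 += batch_size) {
      const int N = std::min(batch_size, (int)idx.size() - s0);
      fmat xb(N * HW, 1), tb(N * HW, 1), mb(N * HW, 1);
      for (int j = 0; j < N; ++j) {
        const int i = idx[s0 + j] - 1;
        const int a = aug[s0 + j];
        fmat xa = augment(X[i], a), ta = augment(T[i], a), ma = augment(M[i], a);
        std::memcpy(xb.colptr(0) + j * HW, xa.memptr(), sizeof(float) * HW);
        std::memcpy(tb.colptr(0) + j * HW, ta.memptr(), sizeof(float) * HW);
        std::memcpy(mb.colptr(0) + j * HW, ma.memptr(), sizeof(float) * HW);
      }
      for (int l = 0; l < nlay; ++l) {
        gW[l].zeros(L.W[l].n_rows, L.W[l].n_cols);
        gb[l].zeros(L.b[l].n_elem);
      }
      unet_forward_batch(L, ch, xb, N, H, W, cc, head_linear);
      fmat diff = cc.y - tb;
      // masked L1, per-patch mean over that patch's valid pixels
      fmat dLdy(N * HW, 1, fill::zeros);
      int used = 0;
      for (int j = 0; j < N; ++j) {
        float nvalid = 0, sabs = 0;
        const float* m = mb.colptr(0) + j * HW;
        const float* d = diff.colptr(0) + j * HW;
        for (int p = 0; p < HW; ++p) { nvalid += m[p]; sabs += std::fabs(d[p]) * m[p]; }
        if (nvalid < 1.0f) continue;
        used++;
        ep_abs += sabs; ep_n += nvalid;
        float* g = dLdy.colptr(0) + j * HW;
        for (int p = 0; p < HW; ++p)
          g[p] = (d[p] > 0 ? 1.0f : (d[p] < 0 ? -1.0f : 0.0f)) * m[p] / nvalid;
      }
      if (used == 0) continue;
      unet_backward_batch(L, ch, xb, N, H, W, cc, dLdy, gW, gb);
      for (int l = 0; l < nlay; ++l) {
        vW[l] = (float)momentum * vW[l] - (float)(lr / used) * gW[l];
        vb[l] = (float)momentum * vb[l] - (float)(lr / used) * gb[l];
        L.W[l] += vW[l]; L.b[l] += vb[l];
      }
    }
    const double ep_loss = ep_n > 0 ? ep_abs / ep_n : NA_REAL;
    if (!std::isfinite(ep_loss))
      Rcpp::stop("training diverged: non-finite loss at epoch %d", e + 1);
    loss_hist[e] = ep_loss;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("layers") = pack_layers(L),
                            Rcpp::Named("loss") = loss_hist);
}
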
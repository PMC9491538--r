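// Small U-Net-style encoder-decoder for glottis segmentation.
//
// Layout: activations are (H*W) x C matrices (column-major pixels, one
// column per channel), single precision. Convolutions are 3x3, zero-padded,
// realised as im2col + GEMM. Downsampling is 2x2 max-pooling, upsampling is
// nearest-neighbour, skip connections are channel concatenation. The head is
// a 1x1 convolution with a sigmoid. Training minimises soft Dice loss with
// Adam; all randomness (init, shuffling) lives on the R side so the C++
// path is fully deterministic.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::fmat;
using arma::umat;

namespace {

struct ConvSpec {
  int cin, cout, k;  // k = kernel size (3 or 1)
};

// conv order: enc1..encd, bottleneck, dec_d..dec_1, out
std::vector<ConvSpec> layer_plan(int depth, int base, int in_ch) {
  std::vector<ConvSpec> plan;
  for (int i = 1; i <= depth; ++i) {
    int cin = (i == 1) ? in_ch : base << (i - 2);
    plan.push_back({cin, base << (i - 1), 3});
  }
  plan.push_back({base << (depth - 1), base << depth, 3});
  for (int i = depth; i >= 1; --i) {
    int up = (i == depth) ? (base << depth) : (base << i);
    plan.push_back({up + (base << (i - 1)), base << (i - 1), 3});
  }
  plan.push_back({base, 1, 1});
  return plan;
}

// 3x3 zero-padded im2col: A is (H*W) x C, result (H*W) x 9C.
fmat im2col3(const fmat& A, int H, int W) {
  const int C = A.n_cols;
  fmat P(A.n_rows, 9 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    for (int k = 0; k < 9; ++k) {
      int di = k % 3 - 1, dj = k / 3 - 1;
      float* dst = P.colptr(c * 9 + k);
      int jlo = std::max(0, -dj), jhi = std::min(W - 1, W - 1 - dj);
      int ilo = std::max(0, -di), ihi = std::min(H - 1, H - 1 - di);
      int len = ihi - ilo + 1;
      if (len <= 0) continue;
      for (int j = jlo; j <= jhi; ++j) {
        std::memcpy(dst + (size_t)j * H + ilo,
                    src + (size_t)(j + dj) * H + (ilo + di),
                    sizeof(float) * len);
      }
    }
  }
  return P;
}

// adjoint of im2col3: dP is (H*W) x 9C, result (H*W) x C.
fmat col2im3(const fmat& dP, int H, int W, int C) {
  fmat dA(dP.n_rows, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* dst = dA.colptr(c);
    for (int k = 0; k < 9; ++k) {
      int di = k % 3 - 1, dj = k / 3 - 1;
      const float* src = dP.colptr(c * 9 + k);
      int jlo = std::max(0, -dj), jhi = std::min(W - 1, W - 1 - dj);
      int ilo = std::max(0, -di), ihi = std::min(H - 1, H - 1 - di);
      if (ihi < ilo) continue;
      for (int j = jlo; j <= jhi; ++j) {
        const float* s = src + (size_t)j * H + ilo;
        float* d = dst + (size_t)(j + dj) * H + (ilo + di);
        for (int i = 0; i <= ihi - ilo; ++i) d[i] += s[i];
      }
    }
  }
  return dA;
}

// 2x2 max pool, stride 2; records the winning source pixel row per output.
void maxpool2(const fmat& A, int H, int W, fmat& out, umat& arg) {
  const int C = A.n_cols, H2 = H / 2, W2 = W / 2;
  out.set_size((size_t)H2 * W2, C);
  arg.set_size((size_t)H2 * W2, C);
  for (int c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    for (int j = 0; j < W2; ++j) {
      for (int i = 0; i < H2; ++i) {
        size_t base0 = (size_t)(2 * j) * H + 2 * i;
        size_t cand[4] = {base0, base0 + 1, base0 + H, base0 + H + 1};
        size_t best = cand[0];
        for (int q = 1; q < 4; ++q)
          if (src[cand[q]] > src[best]) best = cand[q];
        out((size_t)j * H2 + i, c) = src[best];
        arg((size_t)j * H2 + i, c) = best;
      }
    }
  }
}

fmat maxpool2_back(const fmat& dOut, const umat& arg, size_t n_in) {
  fmat dA(n_in, dOut.n_cols, arma::fill::zeros);
  for (size_t c = 0; c < dOut.n_cols; ++c)
    for (size_t r = 0; r < dOut.n_rows; ++r)
      dA(arg(r, c), c) += dOut(r, c);
  return dA;
}

// nearest-neighbour 2x upsample: (H*W) x C -> (2H*2W) x C
fmat upsample2(const fmat& A, int H, int W) {
  const int C = A.n_cols, H2 = 2 * H, W2 = 2 * W;
  fmat out((size_t)H2 * W2, C);
  for (int c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    float* dst = out.colptr(c);
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i)
        dst[(size_t)j * H2 + i] = src[(size_t)(j / 2) * H + i / 2];
  }
  return out;
}

fmat upsample2_back(const fmat& dOut, int H, int W) {
  // H, W are the *input* (coarse) dims
  const int C = dOut.n_cols, H2 = 2 * H;
  fmat dA((size_t)H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const float* src = dOut.colptr(c);
    float* dst = dA.colptr(c);
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < H2; ++i)
        dst[(size_t)(j / 2) * H + i / 2] += src[(size_t)j * H2 + i];
  }
  return dA;
}

struct Weights {
  std::vector<fmat> W;           // cout x (k*k*cin)
  std::vector<arma::frowvec> b;  // 1 x cout
};

Weights unpack(const List& params, const std::vector<ConvSpec>& plan) {
  Weights wt;
  if ((int)params.size() != 2 * (int)plan.size())
    stop("parameter list has %d entries, expected %d", (int)params.size(),
         2 * (int)plan.size());
  for (size_t l = 0; l < plan.size(); ++l) {
    NumericMatrix Wl = params[2 * l];
    NumericVector bl = params[2 * l + 1];
    if ((int)Wl.nrow() != plan[l].cout ||
        (int)Wl.ncol() != plan[l].k * plan[l].k * plan[l].cin)
      stop("weight matrix %d has wrong shape", (int)l + 1);
    wt.W.push_back(arma::conv_to<fmat>::from(
        arma::mat(Wl.begin(), Wl.nrow(), Wl.ncol(), false)));
    wt.b.push_back(arma::conv_to<arma::frowvec>::from(
        arma::rowvec(bl.begin(), bl.size(), false)));
  }
  return wt;
}

List repack(const Weights& wt, CharacterVector names) {
  List out(2 * wt.W.size());
  for (size_t l = 0; l < wt.W.size(); ++l) {
    out[2 * l] = wrap(arma::conv_to<arma::mat>::from(wt.W[l]));
    out[2 * l + 1] = wrap(arma::conv_to<std::vector<double>>::from(wt.b[l]));
  }
  out.attr("names") = names;
  return out;
}

struct FwdCache {
  std::vector<fmat> P;        // im2col inputs per conv (train only)
  std::vector<fmat> A;        // post-ReLU conv outputs per conv
  std::vector<umat> poolarg;  // per encoder level
  std::vector<int> Hs, Ws;    // dims entering each encoder level
};

// forward pass; if cache != nullptr, keeps intermediates for backward
fmat unet_forward_one(const Weights& wt, const std::vector<ConvSpec>& plan,
                      fmat x, int H, int W, int depth, FwdCache* cache) {
  std::vector<fmat> skips(depth + 1);
  std::vector<int> skipH(depth + 1), skipW(depth + 1);
  fmat A = x;
  size_t l = 0;
  auto conv = [&](fmat& Ain, int h, int w) {
    fmat P = (plan[l].k == 3) ? im2col3(Ain, h, w) : Ain;
    fmat Z = P * wt.W[l].t();
    Z.each_row() += wt.b[l];
    if (l + 1 < plan.size()) Z.transform([](float v) { return v > 0 ? v : 0; });
    if (cache) {
      cache->P.push_back(std::move(P));
      cache->A.push_back(Z);
    }
    ++l;
    return Z;
  };
  for (int i = 1; i <= depth; ++i) {
    if (cache) {
      cache->Hs.push_back(H);
      cache->Ws.push_back(W);
    }
    A = conv(A, H, W);
    skips[i] = A;
    skipH[i] = H;
    skipW[i] = W;
    fmat pooled;
    umat arg;
    maxpool2(A, H, W, pooled, arg);
    if (cache) cache->poolarg.push_back(arg);
    A = std::move(pooled);
    H /= 2;
    W /= 2;
  }
  A = conv(A, H, W);  // bottleneck
  for (int i = depth; i >= 1; --i) {
    A = upsample2(A, H, W);
    H *= 2;
    W *= 2;
    A = arma::join_horiz(A, skips[i]);
    A = conv(A, H, W);
  }
  fmat Z = conv(A, H, W);  // 1x1 head, linear
  return 1.0f / (1.0f + arma::exp(-Z));
}

double dice_loss_grad(const fmat& p, const fmat& g, float smooth, fmat& dp) {
  double sp = arma::accu(p), sg = arma::accu(g), spg = arma::accu(p % g);
  double den = sp + sg + smooth, num = 2.0 * spg + smooth;
  dp = -((2.0 * den) * g - num) / (den * den);
  return 1.0 - num / den;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix unet_forward_cpp(List params, NumericMatrix x, int H, int W,
                               int depth, int base, int in_ch) {
  auto plan = layer_plan(depth, base, in_ch);
  Weights wt = unpack(params, plan);
  fmat xin = arma::conv_to<fmat>::from(
      arma::mat(x.begin(), x.nrow(), x.ncol(), false));
  fmat p = unet_forward_one(wt, plan, xin, H, W, depth, nullptr);
  return wrap(arma::conv_to<arma::mat>::from(p));
}

// X: (H*W) x N matrix of single-channel inputs; returns (H*W) x N probs
// [[Rcpp::export]]
NumericMatrix unet_predict_cpp(List params, NumericMatrix X, int H, int W,
                               int depth, int base) {
  auto plan = layer_plan(depth, base, 1);
  Weights wt = unpack(params, plan);
  arma::mat Xd(X.begin(), X.nrow(), X.ncol(), false);
  arma::mat out(X.nrow(), X.ncol());
  for (int n = 0; n < (int)X.ncol(); ++n) {
    fmat x = arma::conv_to<fmat>::from(Xd.col(n));
    fmat p = unet_forward_one(wt, plan, x, H, W, depth, nullptr);
    out.col(n) = arma::conv_to<arma::vec>::from(p.col(0));
  }
  return wrap(out);
}

// [[Rcpp::export]]
double unet_loss_cpp(List params, NumericMatrix X, NumericMatrix Y, int H,
                     int W, int depth, int base, double smooth) {
  auto plan = layer_plan(depth, base, 1);
  Weights wt = unpack(params, plan);
  arma::mat Xd(X.begin(), X.nrow(), X.ncol(), false);
  arma::mat Yd(Y.begin(), Y.nrow(), Y.ncol(), false);
  double total = 0;
  fmat dp;
  for (int n = 0; n < (int)X.ncol(); ++n) {
    fmat x = arma::conv_to<fmat>::from(Xd.col(n));
    fmat g = arma::conv_to<fmat>::from(Yd.col(n));
    fmat p = unet_forward_one(wt, plan, x, H, W, depth, nullptr);
    total += dice_loss_grad(p, g, (float)smooth, dp);
  }
  return total / X.ncol();
}

// Adam fine-tuning / training. `order` is a 0-based index vector over the
// columns of X/Y, concatenated over epochs (length = epochs * N); losses are
// averaged per epoch. Returns updated params and the per-epoch loss trace.
// [[Rcpp::export]]
List unet_train_cpp(List params, NumericMatrix X, NumericMatrix Y,
                    IntegerVector order, int epoch_len, int H, int W,
                    int depth, int base, double lr, double beta1, double beta2,
                    double eps, double smooth) {
  auto plan = layer_plan(depth, base, 1);
  Weights wt = unpack(params, plan);
  const int L = plan.size();
  std::vector<fmat> mW(L), vW(L);
  std::vector<arma::frowvec> mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    mW[l].zeros(arma::size(wt.W[l]));
    vW[l].zeros(arma::size(wt.W[l]));
    mb[l].zeros(arma::size(wt.b[l]));
    vb[l].zeros(arma::size(wt.b[l]));
  }
  arma::mat Xd(X.begin(), X.nrow(), X.ncol(), false);
  arma::mat Yd(Y.begin(), Y.nrow(), Y.ncol(), false);
  const int n_epochs = order.size() / std::max(epoch_len, 1);
  arma::vec epoch_loss(std::max(n_epochs, 1), arma::fill::zeros);
  long t = 0;
  for (int s = 0; s < (int)order.size(); ++s) {
    int n = order[s];
    if (n < 0 || n >= (int)X.ncol()) stop("training index out of range");
    fmat x = arma::conv_to<fmat>::from(Xd.col(n));
    fmat g = arma::conv_to<fmat>::from(Yd.col(n));

    FwdCache cache;
    fmat p = unet_forward_one(wt, plan, x, H, W, depth, &cache);
    fmat dp;
    double loss = dice_loss_grad(p, g, (float)smooth, dp);
    int e = std::min((int)(s / std::max(epoch_len, 1)),
                     (int)epoch_loss.n_elem - 1);
    epoch_loss[e] += loss / std::max(epoch_len, 1);

    // backward
    std::vector<fmat> dW(L);
    std::vector<arma::frowvec> db(L);
    fmat dZ = dp % p % (1.0f - p);  // sigmoid head
    int l = L - 1;
    // head (1x1): P == input activation
    dW[l] = dZ.t() * cache.P[l];
    db[l] = arma::sum(dZ, 0);
    fmat dA = dZ * wt.W[l];
    --l;
    // decoder convs unwind from i=1 upward (forward ran dec_d..dec_1)
    std::vector<fmat> dSkip(depth + 1);
    for (int i = 1; i <= depth; ++i) {
      // currently dA is grad at output of dec_i conv (full chain unwinds
      // from i=1 upward since forward ran dec_d..dec_1)
      fmat dZl = dA;
      dZl.elem(arma::find(cache.A[l] <= 0)).zeros();
      // dims at this decoder level
      int hh = cache.Hs[i - 1], ww = cache.Ws[i - 1];
      dW[l] = dZl.t() * cache.P[l];
      db[l] = arma::sum(dZl, 0);
      fmat dP = dZl * wt.W[l];
      fmat dAin = col2im3(dP, hh, ww, plan[l].cin);
      int up_ch = plan[l].cin - (base << (i - 1));
      dSkip[i] = dAin.cols(up_ch, dAin.n_cols - 1);
      dA = upsample2_back(dAin.cols(0, up_ch - 1), hh / 2, ww / 2);
      --l;
    }
    // bottleneck
    {
      fmat dZl = dA;
      dZl.elem(arma::find(cache.A[l] <= 0)).zeros();
      int hh = cache.Hs[depth - 1] / 2, ww = cache.Ws[depth - 1] / 2;
      dW[l] = dZl.t() * cache.P[l];
      db[l] = arma::sum(dZl, 0);
      fmat dP = dZl * wt.W[l];
      dA = col2im3(dP, hh, ww, plan[l].cin);
      --l;
    }
    // encoder convs, deepest first
    for (int i = depth; i >= 1; --i) {
      int hh = cache.Hs[i - 1], ww = cache.Ws[i - 1];
      fmat dPool = maxpool2_back(dA, cache.poolarg[i - 1], (size_t)hh * ww);
      dPool += dSkip[i];
      fmat dZl = std::move(dPool);
      dZl.elem(arma::find(cache.A[l] <= 0)).zeros();
      dW[l] = dZl.t() * cache.P[l];
      db[l] = arma::sum(dZl, 0);
      if (i > 1) {
        fmat dP = dZl * wt.W[l];
        dA = col2im3(dP, hh, ww, plan[l].cin);
      }
      --l;
    }

    // Adam update
    ++t;
    double bc1 = 1.0 - std::pow(beta1, (double)t);
    double bc2 = 1.0 - std::pow(beta2, (double)t);
    for (int q = 0; q < L; ++q) {
      mW[q] = (float)beta1 * mW[q] + (float)(1 - beta1) * dW[q];
      vW[q] = (float)beta2 * vW[q] + (float)(1 - beta2) * (dW[q] % dW[q]);
      wt.W[q] -= (float)(lr / bc1) * mW[q] /
                 (arma::sqrt(vW[q] / (float)bc2) + (float)eps);
      mb[q] = (float)beta1 * mb[q] + (float)(1 - beta1) * db[q];
      vb[q] = (float)beta2 * vb[q] + (float)(1 - beta2) * (db[q] % db[q]);
      wt.b[q] -= (float)(lr / bc1) * mb[q] /
                 (arma::sqrt(vb[q] / (float)bc2) + (float)eps);
    }
    if (s % 64 == 0) checkUserInterrupt();
  }
  CharacterVector nm = params.attr("names");
  return List::create(_["params"] = repack(wt, nm),
                      _["epoch_loss"] = wrap(epoch_loss));
}

// [[Rcpp::export]]
IntegerVector unet_n_params_cpp(int depth, int base, int in_ch) {
  auto plan = layer_plan(depth, base, in_ch);
  int total = 0;
  for (auto& p : plan) total += p.cout * (p.k * p.k * p.cin) + p.cout;
  return IntegerVector::create(total);
}
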
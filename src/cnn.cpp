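// Small convolutional window classifier for 12x100 inertial blocks.
//
// Architecture (valid convolutions, no padding):
//   input 12x100x1
//   -> conv 3x3, 32 filters, ReLU      -> 10x98x32
//   -> max pool 2x2                    -> 5x49x32
//   -> conv 3x3, 64 filters, ReLU      -> 3x47x64
//   -> max pool 2x2 (remainder dropped)-> 1x23x64
//   -> flatten (1472)
//   -> dense 4096, ReLU, dropout 0.80
//   -> dense n_classes, softmax
//
// Convolutions are im2col + GEMM with the im2col matrices of a whole
// mini-batch concatenated column-wise, so every GEMM is large and BLAS
// friendly. Training is mini-batch Adam with categorical cross-entropy,
// validation-loss early stopping and best-epoch weight restoration.
// Single precision internally.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::umat;

namespace {

constexpr int H0 = 12, W0 = 100;          // input block
constexpr int C1 = 32, H1 = 10, W1n = 98; // conv1 output map
constexpr int S1 = H1 * W1n;              // spatial size per sample (980)
constexpr int P1H = 5, P1W = 49;
constexpr int Q1 = P1H * P1W;             // 245
constexpr int C2 = 64, H2 = 3, W2n = 47;
constexpr int S2 = H2 * W2n;              // 141
constexpr int P2W = 23;                   // pool2 output is 1x23
constexpr int FLAT = C2 * P2W;            // 1472
constexpr int DENSE = 4096;

struct Weights {
  fmat W1, W2, W3, W4;
  fvec b1, b2, b3, b4;
};

Weights weights_from_list(const List& wl) {
  Weights w;
  w.W1 = arma::conv_to<fmat>::from(as<arma::mat>(wl["W1"]));
  w.b1 = arma::conv_to<fvec>::from(as<arma::vec>(wl["b1"]));
  w.W2 = arma::conv_to<fmat>::from(as<arma::mat>(wl["W2"]));
  w.b2 = arma::conv_to<fvec>::from(as<arma::vec>(wl["b2"]));
  w.W3 = arma::conv_to<fmat>::from(as<arma::mat>(wl["W3"]));
  w.b3 = arma::conv_to<fvec>::from(as<arma::vec>(wl["b3"]));
  w.W4 = arma::conv_to<fmat>::from(as<arma::mat>(wl["W4"]));
  w.b4 = arma::conv_to<fvec>::from(as<arma::vec>(wl["b4"]));
  if (w.W1.n_rows != C1 || w.W1.n_cols != 9 ||
      w.W2.n_rows != C2 || w.W2.n_cols != 9 * C1 ||
      w.W3.n_cols != (arma::uword)FLAT || w.W3.n_rows != DENSE ||
      w.W4.n_cols != DENSE)
    stop("weight shapes do not match the fixed architecture");
  return w;
}

List weights_to_list(const Weights& w) {
  return List::create(
      _["W1"] = wrap(arma::conv_to<arma::mat>::from(w.W1)),
      _["b1"] = wrap(arma::conv_to<arma::vec>::from(w.b1)),
      _["W2"] = wrap(arma::conv_to<arma::mat>::from(w.W2)),
      _["b2"] = wrap(arma::conv_to<arma::vec>::from(w.b2)),
      _["W3"] = wrap(arma::conv_to<arma::mat>::from(w.W3)),
      _["b3"] = wrap(arma::conv_to<arma::vec>::from(w.b3)),
      _["W4"] = wrap(arma::conv_to<arma::mat>::from(w.W4)),
      _["b4"] = wrap(arma::conv_to<arma::vec>::from(w.b4)));
}

// Mini-batch intermediates for backprop. Sample i occupies the column
// ranges [i*S1, (i+1)*S1) after conv1, [i*S2, (i+1)*S2) after conv2.
struct BatchCache {
  fmat col1;  // 9 x S1*B
  fmat a1;    // C1 x S1*B, post-ReLU
  umat arg1;  // C1 x Q1*B, winning (global) column in a1
  fmat p1;    // C1 x Q1*B
  fmat col2;  // 288 x S2*B
  fmat a2;    // C2 x S2*B, post-ReLU
  umat arg2;  // C2 x P2W*B, winning (global) column in a2
  fmat F;     // FLAT x B
};

inline void relu_inplace(fmat& m) {
  float* p = m.memptr();
  const arma::uword n = m.n_elem;
  for (arma::uword k = 0; k < n; ++k)
    if (p[k] < 0.f) p[k] = 0.f;
}

// Forward pass of the convolutional front end for a set of samples.
void forward_conv_batch(const fmat& X, const std::vector<arma::uword>& idx,
                        const Weights& w, BatchCache& c) {
  const int B = (int)idx.size();
  c.col1.set_size(9, (arma::uword)S1 * B);
  for (int i = 0; i < B; ++i) {
    const float* x = X.colptr(idx[i]);
    const arma::uword off = (arma::uword)S1 * i;
    for (int wq = 0; wq < W1n; ++wq)
      for (int h = 0; h < H1; ++h) {
        float* dst = c.col1.colptr(off + h + H1 * wq);
        for (int dw = 0; dw < 3; ++dw)
          for (int dh = 0; dh < 3; ++dh)
            dst[dh + 3 * dw] = x[(h + dh) + H0 * (wq + dw)];
      }
  }
  c.a1 = w.W1 * c.col1;
  c.a1.each_col() += w.b1;
  relu_inplace(c.a1);

  // pool1: 10x98 -> 5x49 per channel per sample
  c.p1.set_size(C1, (arma::uword)Q1 * B);
  c.arg1.set_size(C1, (arma::uword)Q1 * B);
  for (int i = 0; i < B; ++i) {
    const arma::uword in0 = (arma::uword)S1 * i;
    const arma::uword out0 = (arma::uword)Q1 * i;
    for (int pw = 0; pw < P1W; ++pw)
      for (int ph = 0; ph < P1H; ++ph) {
        const arma::uword oc = out0 + ph + P1H * pw;
        const arma::uword cand[4] = {
            in0 + (2 * ph) + H1 * (2 * pw),
            in0 + (2 * ph + 1) + H1 * (2 * pw),
            in0 + (2 * ph) + H1 * (2 * pw + 1),
            in0 + (2 * ph + 1) + H1 * (2 * pw + 1)};
        for (int ch = 0; ch < C1; ++ch) {
          arma::uword best = cand[0];
          float bv = c.a1(ch, cand[0]);
          for (int k = 1; k < 4; ++k) {
            const float v = c.a1(ch, cand[k]);
            if (v > bv) { bv = v; best = cand[k]; }
          }
          c.p1(ch, oc) = bv;
          c.arg1(ch, oc) = best;
        }
      }
  }

  c.col2.set_size(9 * C1, (arma::uword)S2 * B);
  for (int i = 0; i < B; ++i) {
    const arma::uword in0 = (arma::uword)Q1 * i;
    const arma::uword off = (arma::uword)S2 * i;
    for (int wq = 0; wq < W2n; ++wq)
      for (int h = 0; h < H2; ++h) {
        float* dst = c.col2.colptr(off + h + H2 * wq);
        for (int dw = 0; dw < 3; ++dw)
          for (int dh = 0; dh < 3; ++dh) {
            const float* src = c.p1.colptr(in0 + (h + dh) + P1H * (wq + dw));
            const int r0 = dh + 3 * dw;
            for (int ch = 0; ch < C1; ++ch)
              dst[r0 + 9 * ch] = src[ch];
          }
      }
  }
  c.a2 = w.W2 * c.col2;
  c.a2.each_col() += w.b2;
  relu_inplace(c.a2);

  // pool2: 3x47 -> 1x23 (remainder row/column dropped); flatten into F
  c.F.set_size(FLAT, B);
  c.arg2.set_size(C2, (arma::uword)P2W * B);
  for (int i = 0; i < B; ++i) {
    const arma::uword in0 = (arma::uword)S2 * i;
    for (int pw = 0; pw < P2W; ++pw) {
      const arma::uword cand[4] = {
          in0 + 0 + H2 * (2 * pw), in0 + 1 + H2 * (2 * pw),
          in0 + 0 + H2 * (2 * pw + 1), in0 + 1 + H2 * (2 * pw + 1)};
      for (int ch = 0; ch < C2; ++ch) {
        arma::uword best = cand[0];
        float bv = c.a2(ch, cand[0]);
        for (int k = 1; k < 4; ++k) {
          const float v = c.a2(ch, cand[k]);
          if (v > bv) { bv = v; best = cand[k]; }
        }
        c.F(ch + C2 * pw, i) = bv;
        c.arg2(ch, (arma::uword)P2W * i + pw) = best;
      }
    }
  }
}

void softmax_inplace(fmat& z) {
  for (arma::uword j = 0; j < z.n_cols; ++j) {
    z.col(j) -= z.col(j).max();
    z.col(j) = arma::exp(z.col(j));
    z.col(j) /= arma::accu(z.col(j));
  }
}

// Softmax probabilities for a set of samples (no dropout).
fmat forward_proba(const fmat& X, const std::vector<arma::uword>& idx,
                   const Weights& w) {
  BatchCache c;
  forward_conv_batch(X, idx, w, c);
  fmat a3 = w.W3 * c.F;
  a3.each_col() += w.b3;
  relu_inplace(a3);
  fmat z4 = w.W4 * a3;
  z4.each_col() += w.b4;
  softmax_inplace(z4);
  return z4;
}

double eval_loss(const fmat& X, const arma::ivec& y, const Weights& w,
                 const std::vector<arma::uword>& idx) {
  if (idx.empty()) return NA_REAL;
  double total = 0.0;
  const size_t B = 256;
  for (size_t s0 = 0; s0 < idx.size(); s0 += B) {
    const size_t s1 = std::min(idx.size(), s0 + B);
    std::vector<arma::uword> part(idx.begin() + s0, idx.begin() + s1);
    fmat p = forward_proba(X, part, w);
    for (size_t i = 0; i < part.size(); ++i)
      total -= std::log((double)std::max(p(y[part[i]], i), 1e-12f));
  }
  return total / idx.size();
}

struct Adam {
  fmat mW1, vW1, mW2, vW2, mW3, vW3, mW4, vW4;
  fvec mb1, vb1, mb2, vb2, mb3, vb3, mb4, vb4;
  long t = 0;
  double lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-7;

  explicit Adam(const Weights& w, double lr_) : lr(lr_) {
    auto zm = [](const fmat& m) { return fmat(m.n_rows, m.n_cols, arma::fill::zeros); };
    auto zv = [](const fvec& v) { return fvec(v.n_elem, arma::fill::zeros); };
    mW1 = zm(w.W1); vW1 = zm(w.W1); mW2 = zm(w.W2); vW2 = zm(w.W2);
    mW3 = zm(w.W3); vW3 = zm(w.W3); mW4 = zm(w.W4); vW4 = zm(w.W4);
    mb1 = zv(w.b1); vb1 = zv(w.b1); mb2 = zv(w.b2); vb2 = zv(w.b2);
    mb3 = zv(w.b3); vb3 = zv(w.b3); mb4 = zv(w.b4); vb4 = zv(w.b4);
  }

  template <typename M>
  void step_one(M& w, M& m, M& v, const M& g, double corr1, double corr2) {
    m = (float)beta1 * m + (float)(1 - beta1) * g;
    v = (float)beta2 * v + (float)(1 - beta2) * (g % g);
    w -= (float)(lr / corr1) * (m / (arma::sqrt(v / (float)corr2) + (float)eps));
  }

  void step(Weights& w, const Weights& g) {
    ++t;
    const double c1 = 1.0 - std::pow(beta1, (double)t);
    const double c2 = 1.0 - std::pow(beta2, (double)t);
    step_one(w.W1, mW1, vW1, g.W1, c1, c2); step_one(w.b1, mb1, vb1, g.b1, c1, c2);
    step_one(w.W2, mW2, vW2, g.W2, c1, c2); step_one(w.b2, mb2, vb2, g.b2, c1, c2);
    step_one(w.W3, mW3, vW3, g.W3, c1, c2); step_one(w.b3, mb3, vb3, g.b3, c1, c2);
    step_one(w.W4, mW4, vW4, g.W4, c1, c2); step_one(w.b4, mb4, vb4, g.b4, c1, c2);
  }
};

// Forward + backward over one mini-batch; returns mean loss, fills grads.
double batch_grads(const fmat& X, const arma::ivec& y, const Weights& w,
                   const std::vector<arma::uword>& batch, float keep_prob,
                   std::mt19937* rng, Weights& g) {
  const int B = (int)batch.size();
  BatchCache c;
  forward_conv_batch(X, batch, w, c);

  fmat z3 = w.W3 * c.F;
  z3.each_col() += w.b3;
  fmat a3 = z3;
  relu_inplace(a3);

  fmat mask;
  if (keep_prob < 1.f) {
    mask.set_size(a3.n_rows, a3.n_cols);
    std::uniform_real_distribution<float> unif(0.f, 1.f);
    for (arma::uword j = 0; j < mask.n_cols; ++j)
      for (arma::uword i = 0; i < mask.n_rows; ++i)
        mask(i, j) = unif(*rng) < keep_prob ? 1.f / keep_prob : 0.f;
    a3 %= mask;
  }

  fmat p = w.W4 * a3;
  p.each_col() += w.b4;
  softmax_inplace(p);

  double loss = 0.0;
  fmat dz4 = p;
  for (int i = 0; i < B; ++i) {
    loss -= std::log((double)std::max(p(y[batch[i]], i), 1e-12f));
    dz4(y[batch[i]], i) -= 1.f;
  }
  loss /= B;
  dz4 /= (float)B;

  g.W4 = dz4 * a3.t();
  g.b4 = arma::sum(dz4, 1);
  fmat da3 = w.W4.t() * dz4;
  if (keep_prob < 1.f) da3 %= mask;
  fmat dz3 = da3;
  {
    const float* zp = z3.memptr();
    float* dp = dz3.memptr();
    for (arma::uword k = 0; k < dz3.n_elem; ++k)
      if (zp[k] <= 0.f) dp[k] = 0.f;
  }
  g.W3 = dz3 * c.F.t();
  g.b3 = arma::sum(dz3, 1);
  fmat dF = w.W3.t() * dz3;  // FLAT x B

  // unflatten + pool2 backward -> da2
  fmat da2(C2, (arma::uword)S2 * B, arma::fill::zeros);
  for (int i = 0; i < B; ++i) {
    const float* df = dF.colptr(i);
    for (int pw = 0; pw < P2W; ++pw)
      for (int ch = 0; ch < C2; ++ch)
        da2(ch, c.arg2(ch, (arma::uword)P2W * i + pw)) += df[ch + C2 * pw];
  }
  {
    const float* ap = c.a2.memptr();
    float* dp = da2.memptr();
    for (arma::uword k = 0; k < da2.n_elem; ++k)
      if (ap[k] <= 0.f) dp[k] = 0.f;
  }
  g.W2 = da2 * c.col2.t();
  g.b2 = arma::sum(da2, 1);
  fmat dcol2 = w.W2.t() * da2;  // 288 x S2*B

  // col2im + pool1 backward -> da1
  fmat dp1(C1, (arma::uword)Q1 * B, arma::fill::zeros);
  for (int i = 0; i < B; ++i) {
    const arma::uword in0 = (arma::uword)Q1 * i;
    const arma::uword off = (arma::uword)S2 * i;
    for (int wq = 0; wq < W2n; ++wq)
      for (int h = 0; h < H2; ++h) {
        const float* src = dcol2.colptr(off + h + H2 * wq);
        for (int dw = 0; dw < 3; ++dw)
          for (int dh = 0; dh < 3; ++dh) {
            float* dst = dp1.colptr(in0 + (h + dh) + P1H * (wq + dw));
            const int r0 = dh + 3 * dw;
            for (int ch = 0; ch < C1; ++ch)
              dst[ch] += src[r0 + 9 * ch];
          }
      }
  }
  fmat da1(C1, (arma::uword)S1 * B, arma::fill::zeros);
  for (arma::uword oc = 0; oc < dp1.n_cols; ++oc)
    for (int ch = 0; ch < C1; ++ch)
      da1(ch, c.arg1(ch, oc)) += dp1(ch, oc);
  {
    const float* ap = c.a1.memptr();
    float* dp = da1.memptr();
    for (arma::uword k = 0; k < da1.n_elem; ++k)
      if (ap[k] <= 0.f) dp[k] = 0.f;
  }
  g.W1 = da1 * c.col1.t();
  g.b1 = arma::sum(da1, 1);
  return loss;
}

// X arrives as an n x 1200 R matrix; store transposed (1200 x n, float) so
// each sample is one contiguous column.
fmat load_X(const NumericMatrix& X) {
  if (X.ncol() != H0 * W0)
    stop("each window must have %d values (12 channels x 100 samples)", H0 * W0);
  fmat out(H0 * W0, X.nrow());
  for (int i = 0; i < X.nrow(); ++i)
    for (int j = 0; j < X.ncol(); ++j)
      out(j, i) = (float)X(i, j);
  return out;
}

arma::ivec load_y(const IntegerVector& y, int n_classes) {
  arma::ivec out(y.size());
  for (int i = 0; i < y.size(); ++i) {
    if (y[i] < 0 || y[i] >= n_classes) stop("class label out of range");
    out[i] = y[i];
  }
  return out;
}

std::vector<arma::uword> all_indices(arma::uword n) {
  std::vector<arma::uword> v(n);
  for (arma::uword i = 0; i < n; ++i) v[i] = i;
  return v;
}

}  // namespace

// [[Rcpp::export]]
List cnn_train_cpp(NumericMatrix X, IntegerVector y, List weights,
                   int n_classes, double lr, int batch_size, int max_epochs,
                   int patience, IntegerVector train_idx,
                   IntegerVector val_idx, double keep_prob, int seed) {
  fmat Xf = load_X(X);
  arma::ivec yv = load_y(y, n_classes);
  Weights w = weights_from_list(weights);
  if ((int)w.W4.n_rows != n_classes) stop("output layer width != n_classes");

  std::vector<arma::uword> tr(train_idx.size()), va(val_idx.size());
  for (int i = 0; i < train_idx.size(); ++i) tr[i] = train_idx[i] - 1;
  for (int i = 0; i < val_idx.size(); ++i) va[i] = val_idx[i] - 1;
  if (tr.empty()) stop("empty training set");

  std::mt19937 rng((unsigned)seed);
  Adam adam(w, lr);
  Weights g = w;  // shape template; overwritten every batch

  const bool have_val = !va.empty();
  std::vector<double> train_losses, val_losses;
  double best_monitor = std::numeric_limits<double>::infinity();
  Weights best = w;
  int best_epoch = 0, wait = 0, epoch = 0;
  std::string reason = "max_epochs";

  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(tr.begin(), tr.end(), rng);
    double epoch_loss = 0.0;
    size_t nb = 0;
    for (size_t s0 = 0; s0 < tr.size(); s0 += batch_size) {
      const size_t s1 = std::min(tr.size(), s0 + (size_t)batch_size);
      std::vector<arma::uword> batch(tr.begin() + s0, tr.begin() + s1);
      epoch_loss += batch_grads(Xf, yv, w, batch, (float)keep_prob, &rng, g) *
                    batch.size();
      adam.step(w, g);
      nb += batch.size();
    }
    train_losses.push_back(epoch_loss / nb);
    const double monitor = have_val ? eval_loss(Xf, yv, w, va)
                                    : train_losses.back();
    val_losses.push_back(have_val ? monitor : NA_REAL);

    if (monitor < best_monitor) {
      best_monitor = monitor;
      best = w;
      best_epoch = epoch;
      wait = 0;
    } else if (++wait >= patience) {
      reason = "early_stop";
      break;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["weights"] = weights_to_list(best),
      _["train_loss"] = wrap(train_losses),
      _["val_loss"] = wrap(val_losses),
      _["stop_epoch"] = std::min(epoch, max_epochs),
      _["best_epoch"] = best_epoch,
      _["best_monitor"] = best_monitor,
      _["stop_reason"] = reason);
}

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(NumericMatrix X, List weights, int n_classes) {
  fmat Xf = load_X(X);
  Weights w = weights_from_list(weights);
  if ((int)w.W4.n_rows != n_classes) stop("output layer width != n_classes");
  const arma::uword n = Xf.n_cols;
  NumericMatrix out((int)n, n_classes);
  const arma::uword B = 256;
  for (arma::uword s0 = 0; s0 < n; s0 += B) {
    const arma::uword s1 = std::min(n, s0 + B);
    std::vector<arma::uword> part;
    for (arma::uword i = s0; i < s1; ++i) part.push_back(i);
    fmat p = forward_proba(Xf, part, w);
    for (arma::uword i = s0; i < s1; ++i)
      for (int k = 0; k < n_classes; ++k)
        out((int)i, k) = p(k, i - s0);
  }
  return out;
}

// Full-batch gradients without dropout; used by the finite-difference
// gradient audit in the test suite.
// [[Rcpp::export]]
List cnn_grad_cpp(NumericMatrix X, IntegerVector y, List weights,
                  int n_classes) {
  fmat Xf = load_X(X);
  arma::ivec yv = load_y(y, n_classes);
  Weights w = weights_from_list(weights);
  Weights g = w;
  const double loss = batch_grads(Xf, yv, w, all_indices(Xf.n_cols), 1.f,
                                  nullptr, g);
  List out = weights_to_list(g);
  out["loss"] = loss;
  return out;
}

// Mean cross-entropy without dropout.
// [[Rcpp::export]]
double cnn_loss_cpp(NumericMatrix X, IntegerVector y, List weights,
                    int n_classes) {
  fmat Xf = load_X(X);
  arma::ivec yv = load_y(y, n_classes);
  Weights w = weights_from_list(weights);
  return eval_loss(Xf, yv, w, all_indices(Xf.n_cols));
}
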
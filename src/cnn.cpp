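// Small convolutional network for SNP-matrix images: two 3x3 "same" conv
// layers with ReLU and max-pooling, one ReLU dense layer and a softmax or
// linear head, trained with Adam on mini-batches. Implemented via im2col +
// BLAS gemm in single precision (the layers are shallow and the inputs are a
// three-letter alphabet, so float dominates neither accuracy nor
// determinism); feature maps are stored as (positions x filters) matrices
// with position index pos = b*R*C + c*R + r so the row dimension is
// contiguous.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
typedef fmat rmat;
typedef fvec rvec;
typedef frowvec rrowvec;

namespace {

struct NetCfg {
  int rows, cols, cin, f1, f2, p1r, p1c, p2r, p2c, hidden, nout;
  int epochs, batch, task; // task: 0 classify, 1 regress
  double lr, lr_decay, dropout;
  unsigned int seed;
  int r1p, c1p, r2, c2, r2p, c2p, flat;
};

NetCfg read_cfg(const Rcpp::List& cfg) {
  NetCfg c;
  c.rows = cfg["rows"]; c.cols = cfg["cols"]; c.cin = cfg["cin"];
  c.f1 = cfg["f1"]; c.f2 = cfg["f2"];
  c.p1r = cfg["p1r"]; c.p1c = cfg["p1c"];
  c.p2r = cfg["p2r"]; c.p2c = cfg["p2c"];
  c.hidden = cfg["hidden"]; c.nout = cfg["nout"];
  c.epochs = cfg["epochs"]; c.batch = cfg["batch"];
  c.task = cfg["task"]; c.lr = cfg["lr"];
  c.dropout = cfg.containsElementNamed("dropout") ?
    Rcpp::as<double>(cfg["dropout"]) : 0.0;
  c.lr_decay = cfg.containsElementNamed("lr_decay") ?
    Rcpp::as<double>(cfg["lr_decay"]) : 1.0;
  c.seed = (unsigned int) Rcpp::as<double>(cfg["seed"]);
  c.r1p = c.rows / c.p1r; c.c1p = c.cols / c.p1c;
  c.r2 = c.r1p; c.c2 = c.c1p;
  c.r2p = c.r2 / c.p2r; c.c2p = c.c2 / c.p2c;
  c.flat = c.r2p * c.c2p * c.f2;
  if (c.r1p < 1 || c.c1p < 1 || c.r2p < 1 || c.c2p < 1)
    Rcpp::stop("image too small for the configured pooling");
  return c;
}

// raw (byte/200) columns -> (R*C*B, cin) matrix
rmat expand_raw(const Rcpp::RawMatrix& X, const NetCfg& c,
                const std::vector<int>& idx) {
  const int rc = c.rows * c.cols, B = (int) idx.size();
  rmat A((uword)(rc * B), (uword) c.cin);
  for (int b = 0; b < B; ++b) {
    const Rbyte* src = &X(0, idx[b]);
    for (int ch = 0; ch < c.cin; ++ch) {
      float* dst = A.colptr(ch) + (size_t) b * rc;
      const Rbyte* s = src + (size_t) ch * rc;
      for (int i = 0; i < rc; ++i) dst[i] = s[i] * 0.005f;
    }
  }
  return A;
}

// A: (R*C*B, cin) -> X: (R*C*B, cin*9), 3x3 same padding (zeros)
rmat im2col3(const rmat& A, int R, int C, int B, int cin) {
  const int rc = R * C;
  rmat X((uword)(rc * B), (uword)(cin * 9), fill::zeros);
  for (int ch = 0; ch < cin; ++ch) {
    const float* a = A.colptr(ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int k = (dc + 1) * 3 + (dr + 1);
        float* x = X.colptr(ch * 9 + k);
        const int r0 = std::max(0, -dr), r1 = std::min(R, R - dr);
        if (r1 <= r0) continue;
        for (int b = 0; b < B; ++b) {
          for (int cc = std::max(0, -dc); cc < std::min(C, C - dc); ++cc) {
            const size_t dst = (size_t) b * rc + (size_t) cc * R + r0;
            const size_t src = (size_t) b * rc + (size_t)(cc + dc) * R
              + (r0 + dr);
            std::memcpy(x + dst, a + src, (size_t)(r1 - r0) * sizeof(float));
          }
        }
      }
    }
  }
  return X;
}

// accumulate dX (R*C*B, cin*9) back into dA (R*C*B, cin)
void col2im3(const rmat& dX, rmat& dA, int R, int C, int B, int cin) {
  const int rc = R * C;
  dA.zeros();
  for (int ch = 0; ch < cin; ++ch) {
    float* a = dA.colptr(ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int k = (dc + 1) * 3 + (dr + 1);
        const float* x = dX.colptr(ch * 9 + k);
        const int r0 = std::max(0, -dr), r1 = std::min(R, R - dr);
        if (r1 <= r0) continue;
        for (int b = 0; b < B; ++b) {
          for (int cc = std::max(0, -dc); cc < std::min(C, C - dc); ++cc) {
            const size_t dst = (size_t) b * rc + (size_t)(cc + dc) * R
              + (r0 + dr);
            const size_t src = (size_t) b * rc + (size_t) cc * R + r0;
            for (int r = 0; r < r1 - r0; ++r) a[dst + r] += x[src + r];
          }
        }
      }
    }
  }
}

inline void relu_inplace(rmat& A) {
  float* p = A.memptr();
  const size_t n = A.n_elem;
  for (size_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
}

// zero the entries of dA where the activation A was clipped
inline void relu_mask(rmat& dA, const rmat& A) {
  float* d = dA.memptr();
  const float* a = A.memptr();
  const size_t n = A.n_elem;
  for (size_t i = 0; i < n; ++i) if (a[i] <= 0) d[i] = 0;
}

// (R*C*B, F) -> (Rp*Cp*B, F), argmax kept for backward
rmat maxpool(const rmat& A, int R, int C, int B, int F, int pr, int pc,
             Mat<unsigned int>& amax) {
  const int Rp = R / pr, Cp = C / pc, rcp = Rp * Cp, rc = R * C;
  rmat P((uword)(rcp * B), (uword) F);
  amax.set_size((uword)(rcp * B), (uword) F);
  for (int f = 0; f < F; ++f) {
    const float* a = A.colptr(f);
    float* p = P.colptr(f);
    unsigned int* am = amax.colptr(f);
    for (int b = 0; b < B; ++b) {
      for (int cp = 0; cp < Cp; ++cp) {
        for (int rp = 0; rp < Rp; ++rp) {
          float best = -datum::inf; size_t bi = 0;
          for (int dc = 0; dc < pc; ++dc) {
            const size_t base = (size_t) b * rc + (size_t)(cp * pc + dc) * R
              + rp * pr;
            for (int dr = 0; dr < pr; ++dr) {
              if (a[base + dr] > best) { best = a[base + dr]; bi = base + dr; }
            }
          }
          const size_t o = (size_t) b * rcp + (size_t) cp * Rp + rp;
          p[o] = best; am[o] = (unsigned int) bi;
        }
      }
    }
  }
  return P;
}

void unpool(const rmat& dP, rmat& dA, const Mat<unsigned int>& amax) {
  dA.zeros();
  for (uword f = 0; f < dP.n_cols; ++f) {
    const float* dp = dP.colptr(f);
    const unsigned int* am = amax.colptr(f);
    float* da = dA.colptr(f);
    for (uword i = 0; i < dP.n_rows; ++i) da[am[i]] += dp[i];
  }
}

// pooled maps (rcp*B, F) -> flattened columns (rcp*F, B)
rmat flatten_maps(const rmat& P, int rcp, int B) {
  const int F = (int) P.n_cols;
  rmat Xf((uword)(rcp * F), (uword) B);
  for (int f = 0; f < F; ++f) {
    const float* p = P.colptr(f);
    for (int b = 0; b < B; ++b) {
      std::memcpy(Xf.colptr(b) + (size_t) f * rcp, p + (size_t) b * rcp,
                  (size_t) rcp * sizeof(float));
    }
  }
  return Xf;
}

void unflatten_maps(const rmat& dXf, rmat& dP, int rcp, int B) {
  const int F = (int) dP.n_cols;
  for (int f = 0; f < F; ++f) {
    float* p = dP.colptr(f);
    for (int b = 0; b < B; ++b) {
      std::memcpy(p + (size_t) b * rcp, dXf.colptr(b) + (size_t) f * rcp,
                  (size_t) rcp * sizeof(float));
    }
  }
}

struct Adam {
  rmat m, v; double b1 = 0.9, b2 = 0.999, eps = 1e-8; int t = 0;
  void init(const rmat& w) { m.zeros(size(w)); v.zeros(size(w)); }
  void step(rmat& w, const rmat& g, double lr) {
    ++t;
    m = (float) b1 * m + (float)(1 - b1) * g;
    v = (float) b2 * v + (float)(1 - b2) * square(g);
    const float a = (float)(lr * std::sqrt(1 - std::pow(b2, t)) /
                            (1 - std::pow(b1, t)));
    w -= a * (m / (sqrt(v) + (float) eps));
  }
};

// batch normalization state for one layer (per feature/unit)
struct BN {
  rvec gamma, beta, rmean, rvar;   // learned scale/shift + running stats
  void init(int f) {
    gamma.ones(f); beta.zeros(f); rmean.zeros(f); rvar.ones(f);
  }
};

struct Net {
  rmat W1, W2, Wd, Wo;      // W1: (cin*9, f1), W2: (f1*9, f2),
                            // Wd: (hidden, flat), Wo: (nout, hidden)
  BN bn1, bn2, bnd;         // after conv1, conv2 and the dense layer
  rvec bo;

  void init(const NetCfg& c, std::mt19937& rng) {
    std::normal_distribution<double> N(0.0, 1.0);
    auto fill_mat = [&](rmat& w, uword nr, uword nc, double sd) {
      w.set_size(nr, nc);
      for (uword j = 0; j < nc; ++j)
        for (uword i = 0; i < nr; ++i) w(i, j) = (float)(N(rng) * sd);
    };
    fill_mat(W1, (uword)(c.cin * 9), (uword) c.f1,
             std::sqrt(2.0 / (c.cin * 9)));
    fill_mat(W2, (uword)(c.f1 * 9), (uword) c.f2,
             std::sqrt(2.0 / (c.f1 * 9)));
    fill_mat(Wd, (uword) c.hidden, (uword) c.flat, std::sqrt(2.0 / c.flat));
    fill_mat(Wo, (uword) c.nout, (uword) c.hidden,
             std::sqrt(1.0 / c.hidden));
    bn1.init(c.f1); bn2.init(c.f2); bnd.init(c.hidden);
    bo.zeros(c.nout);
  }
};

// Batch normalization over the rows of Z (one column per feature). In
// training mode the batch statistics are used and the running averages
// updated; in inference mode the running statistics are used. Saves the
// normalized activations and inverse sd for the backward pass.
struct BNCache { rmat xhat; rvec istd; };

void bn_forward(rmat& Z, BN& bn, bool train, BNCache* cache,
                double momentum = 0.9) {
  const float eps = 1e-5f;
  const uword n = Z.n_rows;
  if (cache) { cache->xhat.set_size(size(Z)); cache->istd.set_size(Z.n_cols); }
  for (uword f = 0; f < Z.n_cols; ++f) {
    float mu, var;
    float* zf = Z.colptr(f);
    if (train) {
      double s1 = 0, s2 = 0;
      for (uword i = 0; i < n; ++i) { s1 += zf[i]; s2 += zf[i] * (double) zf[i]; }
      mu = (float)(s1 / n);
      var = (float)(s2 / n - (s1 / n) * (s1 / n));
      if (var < 0) var = 0;
      bn.rmean(f) = (float)(momentum * bn.rmean(f) + (1 - momentum) * mu);
      bn.rvar(f) = (float)(momentum * bn.rvar(f) + (1 - momentum) * var);
    } else {
      mu = bn.rmean(f); var = bn.rvar(f);
    }
    const float istd = 1.0f / std::sqrt(var + eps);
    float* z = Z.colptr(f);
    if (cache) {
      float* xh = cache->xhat.colptr(f);
      for (uword i = 0; i < n; ++i) {
        xh[i] = (z[i] - mu) * istd;
        z[i] = bn.gamma(f) * xh[i] + bn.beta(f);
      }
      cache->istd(f) = istd;
    } else {
      const float a = bn.gamma(f) * istd;
      const float b = bn.beta(f) - mu * a;
      for (uword i = 0; i < n; ++i) z[i] = a * z[i] + b;
    }
  }
}

// dZ in place: gradient through batch normalization; accumulates dgamma/dbeta
void bn_backward(rmat& dZ, const BNCache& cache, const BN& bn,
                 rvec& dgamma, rvec& dbeta) {
  const uword n = dZ.n_rows;
  dgamma.set_size(dZ.n_cols); dbeta.set_size(dZ.n_cols);
  for (uword f = 0; f < dZ.n_cols; ++f) {
    const float* xh = cache.xhat.colptr(f);
    float* d = dZ.colptr(f);
    double sd = 0, sdx = 0;
    for (uword i = 0; i < n; ++i) { sd += d[i]; sdx += d[i] * xh[i]; }
    dgamma(f) = (float) sdx; dbeta(f) = (float) sd;
    const float a = bn.gamma(f) * cache.istd(f);
    const float mdx = (float)(sdx / n), md = (float)(sd / n);
    for (uword i = 0; i < n; ++i)
      d[i] = a * (d[i] - md - xh[i] * mdx);
  }
}

struct ForwardState {
  rmat X1c, A1, P1, X2c, A2, P2, Xf, H, O;
  Mat<unsigned int> am1, am2;
  BNCache c1, c2, cd;
};

// forward pass over a batch; outputs in st.O (nout x B). `train` selects
// batch statistics (and caches) for the batch-norm layers.
void forward(Net& net, const NetCfg& c, const rmat& A0, int B,
             ForwardState& st, bool keep, bool train) {
  st.X1c = im2col3(A0, c.rows, c.cols, B, c.cin);
  st.A1 = st.X1c * net.W1;
  bn_forward(st.A1, net.bn1, train, keep ? &st.c1 : (BNCache*) 0);
  relu_inplace(st.A1);
  st.P1 = maxpool(st.A1, c.rows, c.cols, B, c.f1, c.p1r, c.p1c, st.am1);
  if (!keep) { st.X1c.reset(); st.A1.reset(); }
  st.X2c = im2col3(st.P1, c.r2, c.c2, B, c.f1);
  st.A2 = st.X2c * net.W2;
  bn_forward(st.A2, net.bn2, train, keep ? &st.c2 : (BNCache*) 0);
  relu_inplace(st.A2);
  st.P2 = maxpool(st.A2, c.r2, c.c2, B, c.f2, c.p2r, c.p2c, st.am2);
  if (!keep) { st.X2c.reset(); st.A2.reset(); st.P1.reset(); }
  st.Xf = flatten_maps(st.P2, c.r2p * c.c2p, B);
  rmat Ht = net.Wd * st.Xf;
  st.H = Ht.t();            // BN normalizes per unit = per column
  bn_forward(st.H, net.bnd, train, keep ? &st.cd : (BNCache*) 0);
  st.H = st.H.t();
  relu_inplace(st.H);
  st.O = net.Wo * st.H;
  st.O.each_col() += net.bo;
  if (c.task == 0) { // softmax columns
    st.O.each_row() -= max(st.O, 0);
    st.O = exp(st.O);
    st.O.each_row() /= sum(st.O, 0);
  }
}

} // namespace

// [[Rcpp::export(name = ".cnn_train")]]
Rcpp::List cnn_train_cpp(Rcpp::RawMatrix X, Rcpp::NumericMatrix Y,
                         Rcpp::List cfg) {
  const NetCfg c = read_cfg(cfg);
  const int N = X.ncol();
  if (Y.nrow() != N) Rcpp::stop("target rows must match image count");
  if (Y.ncol() != c.nout) Rcpp::stop("target columns must match `nout`");
  mat Yd(Y.begin(), N, c.nout, false);
  rmat Yt = conv_to<rmat>::from(Yd); // rows = samples

  std::mt19937 rng(c.seed);
  Net net;
  net.init(c, rng);
  Adam oW1, oW2, oWd, oWo, obo;
  Adam og1, obe1, og2, obe2, ogd, obed;
  oW1.init(net.W1); oW2.init(net.W2); oWd.init(net.Wd); oWo.init(net.Wo);
  obo.init(net.bo);
  og1.init(net.bn1.gamma); obe1.init(net.bn1.beta);
  og2.init(net.bn2.gamma); obe2.init(net.bn2.beta);
  ogd.init(net.bnd.gamma); obed.init(net.bnd.beta);

  std::vector<int> perm(N);
  for (int i = 0; i < N; ++i) perm[i] = i;
  mat history(c.epochs, 2, fill::zeros);
  ForwardState st;
  const int rcp2 = c.r2p * c.c2p;

  for (int ep = 0; ep < c.epochs; ++ep) {
    const double lr_ep = c.lr * std::pow(c.lr_decay, ep);
    std::shuffle(perm.begin(), perm.end(), rng);
    double loss_sum = 0, correct = 0; long seen = 0;
    for (int off = 0; off < N; off += c.batch) {
      const int B = std::min(c.batch, N - off);
      std::vector<int> idx(perm.begin() + off, perm.begin() + off + B);
      rmat A0 = expand_raw(X, c, idx);
      forward(net, c, A0, B, st, true, true);
      rmat drop_mask;
      if (c.dropout > 0) { // inverted dropout on the dense layer
        drop_mask.set_size(st.H.n_rows, st.H.n_cols);
        std::uniform_real_distribution<double> U(0.0, 1.0);
        const float scale = (float)(1.0 / (1.0 - c.dropout));
        for (uword i = 0; i < drop_mask.n_elem; ++i)
          drop_mask(i) = U(rng) < c.dropout ? 0.0f : scale;
        st.H %= drop_mask;
      }

      rmat Yb(c.nout, B);
      for (int b = 0; b < B; ++b)
        for (int k = 0; k < c.nout; ++k) Yb(k, b) = Yt(idx[b], k);

      rmat dO;
      if (c.task == 0) {
        for (int b = 0; b < B; ++b) {
          uword pred; st.O.col(b).max(pred);
          uword truth; Yb.col(b).max(truth);
          if (pred == truth) correct += 1;
          loss_sum += -std::log(std::max(1e-12,
            (double) dot(st.O.col(b), Yb.col(b))));
        }
        dO = (st.O - Yb) / (float) B;
      } else {
        const rmat diff = st.O - Yb;
        loss_sum += accu(square(diff)) / (double) c.nout;
        dO = 2.0f * diff / (float)(B * c.nout);
      }
      seen += B;

      // dense head
      rmat dWo = dO * st.H.t();
      rvec dbo = sum(dO, 1);
      rmat dH = net.Wo.t() * dO;
      if (c.dropout > 0) dH %= drop_mask;
      relu_mask(dH, st.H);
      rvec dgd, dbed_;
      { rmat dHt = dH.t();
        bn_backward(dHt, st.cd, net.bnd, dgd, dbed_);
        dH = dHt.t(); }
      rmat dWd = dH * st.Xf.t();
      rmat dXf = net.Wd.t() * dH;
      // conv block 2
      rmat dP2(st.P2.n_rows, st.P2.n_cols);
      unflatten_maps(dXf, dP2, rcp2, B);
      rmat dA2(st.A2.n_rows, st.A2.n_cols);
      unpool(dP2, dA2, st.am2);
      relu_mask(dA2, st.A2);
      rvec dg2, dbe2_;
      bn_backward(dA2, st.c2, net.bn2, dg2, dbe2_);
      rmat dW2 = st.X2c.t() * dA2;
      rmat dX2c = dA2 * net.W2.t();
      // conv block 1
      rmat dP1(st.P1.n_rows, st.P1.n_cols);
      col2im3(dX2c, dP1, c.r2, c.c2, B, c.f1);
      rmat dA1(st.A1.n_rows, st.A1.n_cols);
      unpool(dP1, dA1, st.am1);
      relu_mask(dA1, st.A1);
      rvec dg1, dbe1_;
      bn_backward(dA1, st.c1, net.bn1, dg1, dbe1_);
      rmat dW1 = st.X1c.t() * dA1;

      oWo.step(net.Wo, dWo, lr_ep);
      obo.step(net.bo, dbo, lr_ep);
      oWd.step(net.Wd, dWd, lr_ep);
      ogd.step(net.bnd.gamma, dgd, lr_ep);
      obed.step(net.bnd.beta, dbed_, lr_ep);
      oW2.step(net.W2, dW2, lr_ep);
      og2.step(net.bn2.gamma, dg2, lr_ep);
      obe2.step(net.bn2.beta, dbe2_, lr_ep);
      oW1.step(net.W1, dW1, lr_ep);
      og1.step(net.bn1.gamma, dg1, lr_ep);
      obe1.step(net.bn1.beta, dbe1_, lr_ep);
      Rcpp::checkUserInterrupt();
    }
    history(ep, 0) = loss_sum / seen;
    history(ep, 1) = c.task == 0 ? correct / seen : datum::nan;
  }

  auto bn_list = [](const BN& bn) {
    return Rcpp::List::create(
      Rcpp::Named("gamma") = conv_to<vec>::from(bn.gamma),
      Rcpp::Named("beta") = conv_to<vec>::from(bn.beta),
      Rcpp::Named("rmean") = conv_to<vec>::from(bn.rmean),
      Rcpp::Named("rvar") = conv_to<vec>::from(bn.rvar));
  };
  return Rcpp::List::create(
    Rcpp::Named("W1") = conv_to<mat>::from(net.W1),
    Rcpp::Named("bn1") = bn_list(net.bn1),
    Rcpp::Named("W2") = conv_to<mat>::from(net.W2),
    Rcpp::Named("bn2") = bn_list(net.bn2),
    Rcpp::Named("Wd") = conv_to<mat>::from(net.Wd),
    Rcpp::Named("bnd") = bn_list(net.bnd),
    Rcpp::Named("Wo") = conv_to<mat>::from(net.Wo),
    Rcpp::Named("bo") = conv_to<vec>::from(net.bo),
    Rcpp::Named("history") = history);
}

// [[Rcpp::export(name = ".cnn_predict")]]
Rcpp::NumericMatrix cnn_predict_cpp(Rcpp::List weights, Rcpp::RawMatrix X,
                                    Rcpp::List cfg) {
  const NetCfg c = read_cfg(cfg);
  Net net;
  auto bn_read = [](Rcpp::List l, BN& bn) {
    bn.gamma = conv_to<rvec>::from(Rcpp::as<vec>(l["gamma"]));
    bn.beta = conv_to<rvec>::from(Rcpp::as<vec>(l["beta"]));
    bn.rmean = conv_to<rvec>::from(Rcpp::as<vec>(l["rmean"]));
    bn.rvar = conv_to<rvec>::from(Rcpp::as<vec>(l["rvar"]));
  };
  net.W1 = conv_to<rmat>::from(Rcpp::as<mat>(weights["W1"]));
  bn_read(weights["bn1"], net.bn1);
  net.W2 = conv_to<rmat>::from(Rcpp::as<mat>(weights["W2"]));
  bn_read(weights["bn2"], net.bn2);
  net.Wd = conv_to<rmat>::from(Rcpp::as<mat>(weights["Wd"]));
  bn_read(weights["bnd"], net.bnd);
  net.Wo = conv_to<rmat>::from(Rcpp::as<mat>(weights["Wo"]));
  net.bo = conv_to<rvec>::from(Rcpp::as<vec>(weights["bo"]));
  const int N = X.ncol();
  Rcpp::NumericMatrix out(N, c.nout);
  ForwardState st;
  const int chunk = std::max(1, c.batch);
  for (int off = 0; off < N; off += chunk) {
    const int B = std::min(chunk, N - off);
    std::vector<int> idx(B);
    for (int b = 0; b < B; ++b) idx[b] = off + b;
    rmat A0 = expand_raw(X, c, idx);
    forward(net, c, A0, B, st, false, false);
    for (int b = 0; b < B; ++b)
      for (int k = 0; k < c.nout; ++k) out(off + b, k) = st.O(k, b);
  }
  return out;
}
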
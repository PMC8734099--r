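// Convolutional backbone for per-gene expression vectors.
//
// Layout conventions (all column-major, Armadillo):
//  - a batch of feature maps is a matrix (H*W*B, C): column c holds channel c
//    for all pixels of all samples, rows ordered b*HW + r*W + cc so that the
//    pixels of one image row are contiguous (enables memcpy in im2col);
//  - conv weights are (Cin*9, Cout), row c*9 + (kr+1)*3 + (kc+1) for the
//    3x3 kernel offset (kr, kc) in {-1,0,1}^2; stride 1, zero padding 1;
//  - linear weights are (in, out), activations (B, features).
//
// The spatial side s is ceil(sqrt(n)) for an n-sample vector, zero-padded at
// the tail; all eight conv layers preserve s, a single kernel-2 max pool
// halves it (skipped when s < 2), and an adaptive max pool collapses it to
// 1x1 so the linear stack sees exactly C8 features for any n.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::uword;
typedef arma::fmat mat;   // single precision: the standard training dtype
typedef arma::fvec vec;
typedef float real_t;

namespace {

struct Net {
  std::vector<mat> conv_w;   // (Cin*9, Cout)
  std::vector<vec> conv_b;   // Cout
  std::vector<mat> lin_w;    // (in, out)
  std::vector<vec> lin_b;    // out
};

Net unpack(const List& params) {
  Net net;
  List cw = params["conv_w"], cb = params["conv_b"];
  List lw = params["lin_w"], lb = params["lin_b"];
  for (int i = 0; i < cw.size(); ++i) {
    net.conv_w.push_back(arma::conv_to<mat>::from(as<arma::mat>(cw[i])));
    net.conv_b.push_back(arma::conv_to<vec>::from(as<arma::vec>(cb[i])));
  }
  for (int i = 0; i < lw.size(); ++i) {
    net.lin_w.push_back(arma::conv_to<mat>::from(as<arma::mat>(lw[i])));
    net.lin_b.push_back(arma::conv_to<vec>::from(as<arma::vec>(lb[i])));
  }
  return net;
}

List pack(const Net& net) {
  List cw(net.conv_w.size()), cb(net.conv_b.size());
  List lw(net.lin_w.size()), lb(net.lin_b.size());
  for (size_t i = 0; i < net.conv_w.size(); ++i) {
    cw[i] = arma::conv_to<arma::mat>::from(net.conv_w[i]);
    cb[i] = arma::conv_to<arma::vec>::from(net.conv_b[i]);
  }
  for (size_t i = 0; i < net.lin_w.size(); ++i) {
    lw[i] = arma::conv_to<arma::mat>::from(net.lin_w[i]);
    lb[i] = arma::conv_to<arma::vec>::from(net.lin_b[i]);
  }
  return List::create(_["conv_w"] = cw, _["conv_b"] = cb,
                      _["lin_w"] = lw, _["lin_b"] = lb);
}

// im2col for 3x3 / stride 1 / pad 1 on square side H.
// A: (HW*B, C) -> K: (HW*B, C*9)
mat im2col(const mat& A, int H, int B) {
  const int HW = H * H;
  const int C = A.n_cols;
  mat K(A.n_rows, (uword)C * 9, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const real_t* src = A.colptr(c);
    for (int kr = -1; kr <= 1; ++kr) {
      for (int kc = -1; kc <= 1; ++kc) {
        real_t* dst = K.colptr((uword)c * 9 + (kr + 1) * 3 + (kc + 1));
        const int cc0 = kc < 0 ? -kc : 0;          // first valid output col
        const int len = H - std::abs(kc);          // contiguous run length
        if (len <= 0) continue;
        for (int b = 0; b < B; ++b) {
          for (int r = 0; r < H; ++r) {
            const int sr = r + kr;
            if (sr < 0 || sr >= H) continue;
            std::memcpy(dst + (size_t)b * HW + (size_t)r * H + cc0,
                        src + (size_t)b * HW + (size_t)sr * H + cc0 + kc,
                        sizeof(real_t) * len);
          }
        }
      }
    }
  }
  return K;
}

// adjoint of im2col: accumulate dK back onto the input map
mat col2im(const mat& dK, int H, int B, int C) {
  const int HW = H * H;
  mat dA((uword)HW * B, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    real_t* dst = dA.colptr(c);
    for (int kr = -1; kr <= 1; ++kr) {
      for (int kc = -1; kc <= 1; ++kc) {
        const real_t* src = dK.colptr((uword)c * 9 + (kr + 1) * 3 + (kc + 1));
        const int cc0 = kc < 0 ? -kc : 0;
        const int len = H - std::abs(kc);
        if (len <= 0) continue;
        for (int b = 0; b < B; ++b) {
          for (int r = 0; r < H; ++r) {
            const int sr = r + kr;
            if (sr < 0 || sr >= H) continue;
            real_t* d = dst + (size_t)b * HW + (size_t)sr * H + cc0 + kc;
            const real_t* s = src + (size_t)b * HW + (size_t)r * H + cc0;
            for (int j = 0; j < len; ++j) d[j] += s[j];
          }
        }
      }
    }
  }
  return dA;
}

inline void relu_(mat& Z) {
  Z.for_each([](real_t& x) { if (x < 0) x = 0; });
}

struct Cache {
  std::vector<mat> K;        // im2col inputs per conv layer
  std::vector<mat> A;        // post-ReLU conv outputs
  mat pooled;                // after kernel-2 max pool
  arma::umat pool_idx;       // argmax row (into pre-pool map) per (pixel, c)
  mat feat;                  // (B, C8) after adaptive pool
  arma::umat feat_idx;       // argmax row per (b, c)
  std::vector<mat> L;        // linear activations, L[0] = feat, post-ReLU
  bool pooled_used = false;
};

// forward pass; X is (B, n) raw vectors. Returns logits (B, arity).
mat forward(const Net& net, const mat& X, Cache* cache) {
  const int B = X.n_rows, n = X.n_cols;
  const int s = (int)std::ceil(std::sqrt((double)n));
  const int HW = s * s;

  mat A((uword)HW * B, 1, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < n; ++p)
      A((uword)b * HW + p, 0) = X(b, p);

  const int n_conv = net.conv_w.size();
  for (int i = 0; i < n_conv; ++i) {
    mat K = im2col(A, s, B);
    mat Z = K * net.conv_w[i];
    Z.each_row() += net.conv_b[i].t();
    relu_(Z);
    if (cache) {
      cache->K.push_back(std::move(K));
      cache->A.push_back(Z);
    }
    A = std::move(Z);
  }

  // single kernel-2 max pool (floor, stride 2); skipped for side < 2
  int s2 = s, HW2 = HW;
  mat P;
  arma::umat Pidx;
  const int C8 = A.n_cols;
  if (s >= 2) {
    s2 = s / 2;
    HW2 = s2 * s2;
    P.set_size((uword)HW2 * B, C8);
    Pidx.set_size((uword)HW2 * B, C8);
    for (int c = 0; c < C8; ++c) {
      const real_t* src = A.colptr(c);
      for (int b = 0; b < B; ++b) {
        for (int r = 0; r < s2; ++r) {
          for (int cc = 0; cc < s2; ++cc) {
            const size_t base = (size_t)b * HW;
            size_t i00 = base + (size_t)(2 * r) * s + 2 * cc;
            size_t cand[4] = {i00, i00 + 1, i00 + s, i00 + s + 1};
            size_t best = cand[0];
            real_t bv = src[cand[0]];
            for (int k = 1; k < 4; ++k)
              if (src[cand[k]] > bv) { bv = src[cand[k]]; best = cand[k]; }
            P((uword)b * HW2 + (uword)r * s2 + cc, c) = bv;
            Pidx((uword)b * HW2 + (uword)r * s2 + cc, c) = best;
          }
        }
      }
    }
  } else {
    P = A;
  }
  if (cache) {
    cache->pooled = P;
    cache->pool_idx = Pidx;
    cache->pooled_used = (s >= 2);
  }

  // adaptive max pool to 1x1: global max over the HW2 pixels of each sample
  mat F(B, C8);
  arma::umat Fidx(B, C8);
  for (int c = 0; c < C8; ++c) {
    const real_t* src = P.colptr(c);
    for (int b = 0; b < B; ++b) {
      size_t best = (size_t)b * HW2;
      real_t bv = src[best];
      for (int p = 1; p < HW2; ++p) {
        const size_t i = (size_t)b * HW2 + p;
        if (src[i] > bv) { bv = src[i]; best = i; }
      }
      F(b, c) = bv;
      Fidx(b, c) = best;
    }
  }
  if (cache) {
    cache->feat = F;
    cache->feat_idx = Fidx;
    cache->L.push_back(F);
  }

  const int n_lin = net.lin_w.size();
  mat Z = F;
  for (int i = 0; i < n_lin; ++i) {
    Z = Z * net.lin_w[i];
    Z.each_row() += net.lin_b[i].t();
    if (i < n_lin - 1) {
      relu_(Z);
      if (cache) cache->L.push_back(Z);
    }
  }
  return Z;  // raw scores, no activation after the last linear layer
}

struct Grads {
  std::vector<mat> conv_w;
  std::vector<vec> conv_b;
  std::vector<mat> lin_w;
  std::vector<vec> lin_b;
};

// backward from dlogits (B, arity); fills grads
void backward(const Net& net, const Cache& cache, const mat& X,
              const mat& dlogits, Grads& g) {
  const int B = X.n_rows, n = X.n_cols;
  const int s = (int)std::ceil(std::sqrt((double)n));
  const int HW = s * s;
  const int n_lin = net.lin_w.size();
  const int n_conv = net.conv_w.size();

  g.lin_w.resize(n_lin);
  g.lin_b.resize(n_lin);
  g.conv_w.resize(n_conv);
  g.conv_b.resize(n_conv);

  mat dZ = dlogits;
  for (int i = n_lin - 1; i >= 0; --i) {
    g.lin_w[i] = cache.L[i].t() * dZ;
    g.lin_b[i] = arma::sum(dZ, 0).t();
    if (i > 0) {
      mat dA = dZ * net.lin_w[i].t();
      dZ = dA % arma::conv_to<mat>::from(cache.L[i] > 0);
    } else {
      dZ = dZ * net.lin_w[i].t();  // gradient w.r.t. pooled features
    }
  }

  // adaptive pool backward: route each feature gradient to its argmax pixel
  const int C8 = cache.pooled.n_cols;
  mat dP(cache.pooled.n_rows, C8, arma::fill::zeros);
  for (int c = 0; c < C8; ++c)
    for (int b = 0; b < B; ++b)
      dP(cache.feat_idx(b, c), c) += dZ(b, c);

  // kernel-2 max pool backward
  mat dA;
  if (cache.pooled_used) {
    dA.zeros((uword)HW * B, C8);
    const int HW2 = dP.n_rows / B;
    for (int c = 0; c < C8; ++c) {
      real_t* dst = dA.colptr(c);
      const real_t* src = dP.colptr(c);
      for (uword j = 0; j < (uword)HW2 * B; ++j)
        dst[cache.pool_idx(j, c)] += src[j];
    }
  } else {
    dA = dP;
  }

  for (int i = n_conv - 1; i >= 0; --i) {
    mat dZc = dA % arma::conv_to<mat>::from(cache.A[i] > 0);
    g.conv_w[i] = cache.K[i].t() * dZc;
    g.conv_b[i] = arma::sum(dZc, 0).t();
    if (i > 0) {
      mat dK = dZc * net.conv_w[i].t();
      dA = col2im(dK, s, B, net.conv_w[i - 1].n_cols);
    }
  }
}

struct AdamState {
  std::vector<mat> m_cw, v_cw, m_lw, v_lw;
  std::vector<vec> m_cb, v_cb, m_lb, v_lb;
  long t = 0;
};

AdamState unpack_state(const List& st, const Net& net) {
  AdamState a;
  if (st.size() == 0 || !st.containsElementNamed("t")) {
    for (auto& w : net.conv_w) { a.m_cw.push_back(mat(arma::size(w), arma::fill::zeros)); a.v_cw.push_back(mat(arma::size(w), arma::fill::zeros)); }
    for (auto& b : net.conv_b) { a.m_cb.push_back(vec(b.n_elem, arma::fill::zeros)); a.v_cb.push_back(vec(b.n_elem, arma::fill::zeros)); }
    for (auto& w : net.lin_w) { a.m_lw.push_back(mat(arma::size(w), arma::fill::zeros)); a.v_lw.push_back(mat(arma::size(w), arma::fill::zeros)); }
    for (auto& b : net.lin_b) { a.m_lb.push_back(vec(b.n_elem, arma::fill::zeros)); a.v_lb.push_back(vec(b.n_elem, arma::fill::zeros)); }
    a.t = 0;
    return a;
  }
  List m = st["m"], v = st["v"];
  List mcw = m["conv_w"], mcb = m["conv_b"], mlw = m["lin_w"], mlb = m["lin_b"];
  List vcw = v["conv_w"], vcb = v["conv_b"], vlw = v["lin_w"], vlb = v["lin_b"];
  for (int i = 0; i < mcw.size(); ++i) { a.m_cw.push_back(arma::conv_to<mat>::from(as<arma::mat>(mcw[i]))); a.v_cw.push_back(arma::conv_to<mat>::from(as<arma::mat>(vcw[i]))); }
  for (int i = 0; i < mcb.size(); ++i) { a.m_cb.push_back(arma::conv_to<vec>::from(as<arma::vec>(mcb[i]))); a.v_cb.push_back(arma::conv_to<vec>::from(as<arma::vec>(vcb[i]))); }
  for (int i = 0; i < mlw.size(); ++i) { a.m_lw.push_back(arma::conv_to<mat>::from(as<arma::mat>(mlw[i]))); a.v_lw.push_back(arma::conv_to<mat>::from(as<arma::mat>(vlw[i]))); }
  for (int i = 0; i < mlb.size(); ++i) { a.m_lb.push_back(arma::conv_to<vec>::from(as<arma::vec>(mlb[i]))); a.v_lb.push_back(arma::conv_to<vec>::from(as<arma::vec>(vlb[i]))); }
  a.t = as<long>(st["t"]);
  return a;
}

List pack_state(const AdamState& a) {
  auto lmat = [](const std::vector<mat>& v) { List l(v.size()); for (size_t i = 0; i < v.size(); ++i) l[i] = arma::conv_to<arma::mat>::from(v[i]); return l; };
  auto lvec = [](const std::vector<vec>& v) { List l(v.size()); for (size_t i = 0; i < v.size(); ++i) l[i] = arma::conv_to<arma::vec>::from(v[i]); return l; };
  List m = List::create(_["conv_w"] = lmat(a.m_cw), _["conv_b"] = lvec(a.m_cb),
                        _["lin_w"] = lmat(a.m_lw), _["lin_b"] = lvec(a.m_lb));
  List v = List::create(_["conv_w"] = lmat(a.v_cw), _["conv_b"] = lvec(a.v_cb),
                        _["lin_w"] = lmat(a.v_lw), _["lin_b"] = lvec(a.v_lb));
  return List::create(_["m"] = m, _["v"] = v, _["t"] = (double)a.t);
}

template <typename T>
inline void adam_step(T& w, T& m, T& v, const T& grad, long t,
                      double lr, double b1, double b2, double eps, double wd) {
  T g = grad;
  if (wd != 0) g += (real_t)wd * w;
  m = (real_t)b1 * m + (real_t)(1 - b1) * g;
  v = (real_t)b2 * v + (real_t)(1 - b2) * (g % g);
  const double c1 = 1 - std::pow(b1, (double)t);
  const double c2 = 1 - std::pow(b2, (double)t);
  w -= (real_t)lr * (m / (real_t)c1) / (arma::sqrt(v / (real_t)c2) + (real_t)eps);
}

// loss and gradient at the logits; y is 0-based class labels.
// loss "ce": softmax cross-entropy, mean over batch (3-class path);
// loss "bce": sigmoid cross-entropy against one-hot targets, mean over all
// elements (2-class fine-tune path).
double loss_grad(const mat& logits, const arma::ivec& y, const std::string& loss,
                 mat& dlogits) {
  const int B = logits.n_rows, K = logits.n_cols;
  dlogits.set_size(B, K);
  double total = 0;
  if (loss == "ce") {
    for (int b = 0; b < B; ++b) {
      arma::frowvec z = logits.row(b);
      const real_t zmax = z.max();
      arma::frowvec ez = arma::exp(z - zmax);
      const real_t Zs = arma::accu(ez);
      arma::frowvec p = ez / Zs;
      total += -(double)(z(y(b)) - zmax - std::log(Zs));
      dlogits.row(b) = p / (real_t)B;
      dlogits(b, y(b)) -= (real_t)(1.0 / B);
    }
    return total / B;
  }
  // bce: targets one-hot over K columns
  const double denom = (double)B * K;
  for (int b = 0; b < B; ++b) {
    for (int k = 0; k < K; ++k) {
      const double z = logits(b, k);
      const double t = (y(b) == k) ? 1.0 : 0.0;
      // log(1 + exp(-|z|)) formulation for stability
      total += std::max(z, 0.0) - z * t + std::log1p(std::exp(-std::abs(z)));
      const double sig = 1.0 / (1.0 + std::exp(-z));
      dlogits(b, k) = (real_t)((sig - t) / denom);
    }
  }
  return total / denom;
}

}  // namespace

// [[Rcpp::export(name = ".cnn_forward_cpp")]]
arma::mat cnn_forward_cpp(List params, const arma::mat& X) {
  Net net = unpack(params);
  mat Xf = arma::conv_to<mat>::from(X);
  return arma::conv_to<arma::mat>::from(forward(net, Xf, nullptr));
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(List params, List opt_state, const arma::mat& X,
                   const arma::ivec& y, std::string loss,
                   const arma::imat& perms, int batch_size,
                   double lr, double beta1, double beta2, double eps,
                   double weight_decay) {
  Net net = unpack(params);
  AdamState st = unpack_state(opt_state, net);
  mat Xf = arma::conv_to<mat>::from(X);
  const int N = Xf.n_rows;
  const int epochs = perms.n_rows;
  arma::vec trace(epochs, arma::fill::zeros);

  for (int e = 0; e < epochs; ++e) {
    double esum = 0;
    long nseen = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int bs = std::min(batch_size, N - start);
      mat Xb(bs, Xf.n_cols);
      arma::ivec yb(bs);
      for (int j = 0; j < bs; ++j) {
        const int idx = perms(e, start + j) - 1;  // 1-based from R
        Xb.row(j) = Xf.row(idx);
        yb(j) = y(idx);
      }
      Cache cache;
      mat logits = forward(net, Xb, &cache);
      mat dlogits;
      const double l = loss_grad(logits, yb, loss, dlogits);
      esum += l * bs;
      nseen += bs;
      Grads g;
      backward(net, cache, Xb, dlogits, g);
      st.t += 1;
      for (size_t i = 0; i < net.conv_w.size(); ++i) {
        adam_step(net.conv_w[i], st.m_cw[i], st.v_cw[i], g.conv_w[i], st.t, lr, beta1, beta2, eps, weight_decay);
        adam_step(net.conv_b[i], st.m_cb[i], st.v_cb[i], g.conv_b[i], st.t, lr, beta1, beta2, eps, weight_decay);
      }
      for (size_t i = 0; i < net.lin_w.size(); ++i) {
        adam_step(net.lin_w[i], st.m_lw[i], st.v_lw[i], g.lin_w[i], st.t, lr, beta1, beta2, eps, weight_decay);
        adam_step(net.lin_b[i], st.m_lb[i], st.v_lb[i], g.lin_b[i], st.t, lr, beta1, beta2, eps, weight_decay);
      }
    }
    trace(e) = esum / nseen;
  }
  return List::create(_["params"] = pack(net), _["opt_state"] = pack_state(st),
                      _["loss_trace"] = trace);
}
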
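// Minimal convolutional network engine for the yield surrogate.
//
// Architecture (fixed topology, configurable sizes):
//   input  H x W, single channel
//   conv1  KxK kernel, stride 1, zero padding P, C1 maps, ReLU
//   conv2  KxK kernel, stride 1, zero padding P, C2 maps, ReLU
//   flatten -> dense hidden (Hd units, ReLU) -> dense scalar output
//
// Convolutions are evaluated as im2col + GEMM so the bulk of the cost
// sits in BLAS. Everything is double precision. Samples are processed in
// fixed-size chunks whose workspace buffers are allocated once per call
// and operated on as whole matrices (a smaller workspace handles the
// remainder chunk); the zero-padding cells of the im2col buffers never
// change, so they are zeroed once and only data cells are rewritten.
// All functions are pure: identical inputs give bit-identical outputs.
//
// Layout conventions (must match the R side in cnn.R):
//   - a feature map of size H x W x C is stored as an (H*W) x C matrix
//     with spatial index p = h + H*w (column-major within the map);
//   - im2col column index for (channel c, kernel offset kh, kw) is
//     c*K*K + kw*K + kh;
//   - the flattened conv2 output is vectorise(npos2 x C2 matrix), i.e.
//     position-major within each channel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// The network runs in single precision (sgemm doubles the throughput of
// this memory-bound workload); master weights, the optimizer state, and
// everything on the R side stay double.
typedef Mat<float> fm;
typedef Col<float> fv;

namespace {

struct Dims {
  int H, W, K, P, C1, C2, Hd;
  int H1, W1, H2, W2, npos1, npos2, F;
};

Dims read_dims(const Rcpp::List& d) {
  Dims z;
  z.H = d["H"]; z.W = d["W"]; z.K = d["K"]; z.P = d["P"];
  z.C1 = d["C1"]; z.C2 = d["C2"]; z.Hd = d["Hd"];
  z.H1 = z.H + 2 * z.P - z.K + 1;
  z.W1 = z.W + 2 * z.P - z.K + 1;
  z.H2 = z.H1 + 2 * z.P - z.K + 1;
  z.W2 = z.W1 + 2 * z.P - z.K + 1;
  z.npos1 = z.H1 * z.W1;
  z.npos2 = z.H2 * z.W2;
  z.F = z.npos2 * z.C2;
  return z;
}

void relu_inplace(fm& A) {
  float* p = A.memptr();
  const uword n = A.n_elem;
  for (uword i = 0; i < n; ++i) if (p[i] < 0.0f) p[i] = 0.0f;
}

// Zero entries of D wherever the matching post-ReLU activation is zero.
void mask_by_activation(fm& D, const fm& A) {
  float* pd = D.memptr();
  const float* pa = A.memptr();
  const uword n = D.n_elem;
  for (uword i = 0; i < n; ++i) if (pa[i] == 0.0f) pd[i] = 0.0f;
}

// Write one sample's (H*W) x C map into rows [r0, r0+npos) of `col`.
// Only in-range (non-padding) cells are touched; padding cells of `col`
// must already be zero and stay zero.
void im2col(const fm& A, int H, int W, int C, int K, int P,
            fm& col, uword r0) {
  const int Ho = H + 2 * P - K + 1, Wo = W + 2 * P - K + 1;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const uword cc = (uword)(c * K * K + kw * K + kh);
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow - P + kw;
          if (iw < 0 || iw >= W) continue;
          const int oh_lo = std::max(0, P - kh);
          const int oh_hi = std::min(Ho - 1, H - 1 + P - kh);
          const float* src = A.colptr(c) + (uword)(H * iw);
          float* dst = col.colptr(cc) + r0 + (uword)(Ho * ow);
          for (int oh = oh_lo; oh <= oh_hi; ++oh) {
            dst[oh] = src[oh - P + kh];
          }
        }
      }
    }
  }
}

// Adjoint of im2col: accumulate rows [r0, r0+npos) of dcol into rows
// [q0, q0+H*W) of dA (which must be pre-zeroed).
void col2im(const fm& dcol, uword r0, int H, int W, int C, int K, int P,
            fm& dA, uword q0) {
  const int Ho = H + 2 * P - K + 1, Wo = W + 2 * P - K + 1;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const uword cc = (uword)(c * K * K + kw * K + kh);
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow - P + kw;
          if (iw < 0 || iw >= W) continue;
          const int oh_lo = std::max(0, P - kh);
          const int oh_hi = std::min(Ho - 1, H - 1 + P - kh);
          const float* src = dcol.colptr(cc) + r0 + (uword)(Ho * ow);
          float* dst = dA.colptr(c) + q0 + (uword)(H * iw);
          for (int oh = oh_lo; oh <= oh_hi; ++oh) {
            dst[oh - P + kh] += src[oh];
          }
        }
      }
    }
  }
}

struct Params {
  fm W1, W2, W2t, Wd;
  fv b1, b2, bd, Wo;
  float bo;
};

Params read_params(const Rcpp::List& p) {
  Params q;
  q.W1 = conv_to<fm>::from(Rcpp::as<mat>(p["W1"]));
  q.b1 = conv_to<fv>::from(Rcpp::as<vec>(p["b1"]));
  q.W2 = conv_to<fm>::from(Rcpp::as<mat>(p["W2"]));
  q.W2t = q.W2.t();
  q.b2 = conv_to<fv>::from(Rcpp::as<vec>(p["b2"]));
  q.Wd = conv_to<fm>::from(Rcpp::as<mat>(p["Wd"]));
  q.bd = conv_to<fv>::from(Rcpp::as<vec>(p["bd"]));
  q.Wo = conv_to<fv>::from(Rcpp::as<vec>(p["Wo"]));
  q.bo = (float)Rcpp::as<double>(p["bo"]);
  return q;
}

// Workspace holding exactly n samples' activations.
struct Work {
  uword n;
  fm colX, A1, colA1, A2, Zt, Hm;
  fv pred;
  Work(const Dims& d, uword n_) : n(n_) {
    colX.zeros(n * d.npos1, (uword)(d.K * d.K));
    colA1.zeros(n * d.npos2, (uword)(d.C1 * d.K * d.K));
  }
};

// Forward pass on samples [i0, i0+w.n) of X.
void chunk_forward(const Params& q, const Dims& d, const cube& X,
                   uword i0, Work& w) {
  fm A((uword)(d.H * d.W), 1);
  for (uword i = 0; i < w.n; ++i) {
    const double* xs = X.slice(i0 + i).memptr();
    float* af = A.memptr();
    for (int j = 0; j < d.H * d.W; ++j) af[j] = (float)xs[j];
    im2col(A, d.H, d.W, 1, d.K, d.P, w.colX, i * d.npos1);
  }
  w.A1 = w.colX * q.W1;
  w.A1.each_row() += q.b1.t();
  relu_inplace(w.A1);

  for (uword i = 0; i < w.n; ++i) {
    // rows of a col-major matrix are not a dense block; copy the sample
    fm b = w.A1.rows(i * d.npos1, (i + 1) * d.npos1 - 1);
    im2col(b, d.H1, d.W1, d.C1, d.K, d.P, w.colA1, i * d.npos2);
  }
  w.A2 = w.colA1 * q.W2;
  w.A2.each_row() += q.b2.t();
  relu_inplace(w.A2);

  // flatten: Zt is F x n so each sample occupies one contiguous column
  w.Zt.set_size((uword)d.F, w.n);
  for (uword i = 0; i < w.n; ++i) {
    float* dst = w.Zt.colptr(i);
    for (int c = 0; c < d.C2; ++c) {
      const float* src = w.A2.colptr(c) + i * d.npos2;
      std::copy(src, src + d.npos2, dst + (uword)c * d.npos2);
    }
  }
  w.Hm = w.Zt.t() * q.Wd;
  w.Hm.each_row() += q.bd.t();
  relu_inplace(w.Hm);
  w.pred = w.Hm * q.Wo + q.bo;
}

struct Grads {
  fm W1, W2, Wd;
  fv b1, b2, bd, Wo;
  float bo;
};

// Backward from dpred down to dA1; accumulates parameter gradients into
// G when given.
void chunk_backward(const Params& q, const Dims& d, Work& w,
                    const fv& dpred, Grads* G, fm* dA1_out) {
  fm dH = dpred * q.Wo.t();
  mask_by_activation(dH, w.Hm);
  if (G) {
    G->Wo += w.Hm.t() * dpred;
    G->bo += accu(dpred);
    G->Wd += w.Zt * dH;
    G->bd += sum(dH, 0).t();
  }
  fm dZt = q.Wd * dH.t();              // F x n, contiguous per sample

  fm dA2(w.n * d.npos2, (uword)d.C2);
  for (uword i = 0; i < w.n; ++i) {
    const float* src = dZt.colptr(i);
    for (int c = 0; c < d.C2; ++c) {
      float* dst = dA2.colptr(c) + i * d.npos2;
      std::copy(src + (uword)c * d.npos2, src + (uword)(c + 1) * d.npos2, dst);
    }
  }
  mask_by_activation(dA2, w.A2);

  if (G) {
    G->W2 += w.colA1.t() * dA2;
    G->b2 += sum(dA2, 0).t();
  }
  fm dcol2 = dA2 * q.W2t;
  fm& dA1 = *dA1_out;
  dA1.zeros(w.n * d.npos1, (uword)d.C1);
  for (uword i = 0; i < w.n; ++i)
    col2im(dcol2, i * d.npos2, d.H1, d.W1, d.C1, d.K, d.P,
           dA1, i * d.npos1);
  mask_by_activation(dA1, w.A1);

  if (G) {
    G->W1 += w.colX.t() * dA1;
    G->b1 += sum(dA1, 0).t();
  }
}

// Pick the right workspace (main for full chunks, lazily built tail for
// the remainder).
Work& pick_work(const Dims& d, uword n, Work& main,
                std::unique_ptr<Work>& tail) {
  if (n == main.n) return main;
  if (!tail || tail->n != n) tail.reset(new Work(d, n));
  return *tail;
}

} // namespace

// [[Rcpp::export]]
arma::vec cnn_predict_cpp(Rcpp::List params, arma::cube X, Rcpp::List dims,
                          int chunk = 32) {
  Params q = read_params(params);
  Dims d = read_dims(dims);
  const uword N = X.n_slices;
  vec out(N);
  const uword cap = std::min((uword)chunk, std::max(N, (uword)1));
  Work w(d, cap);
  std::unique_ptr<Work> tail;
  for (uword i0 = 0; i0 < N; i0 += cap) {
    uword n = std::min(cap, N - i0);
    Work& wk = pick_work(d, n, w, tail);
    chunk_forward(q, d, X, i0, wk);
    out.subvec(i0, i0 + n - 1) = conv_to<vec>::from(wk.pred);
  }
  return out;
}

// Mean-squared-error loss and its gradient with respect to every
// parameter, averaged over all N samples.
// [[Rcpp::export]]
Rcpp::List cnn_loss_grad_cpp(Rcpp::List params, arma::cube X, arma::vec y,
                             Rcpp::List dims, int chunk = 32) {
  Params q = read_params(params);
  Dims d = read_dims(dims);
  const uword N = X.n_slices;
  if (y.n_elem != N) Rcpp::stop("length(y) must equal the number of inputs");

  Grads G;
  G.W1.zeros(size(q.W1)); G.W2.zeros(size(q.W2)); G.Wd.zeros(size(q.Wd));
  G.b1.zeros(size(q.b1)); G.b2.zeros(size(q.b2)); G.bd.zeros(size(q.bd));
  G.Wo.zeros(size(q.Wo)); G.bo = 0.0;
  double loss = 0.0;

  const uword cap = std::min((uword)chunk, std::max(N, (uword)1));
  Work w(d, cap);
  std::unique_ptr<Work> tail;
  fm dA1;
  for (uword i0 = 0; i0 < N; i0 += cap) {
    uword n = std::min(cap, N - i0);
    Work& wk = pick_work(d, n, w, tail);
    chunk_forward(q, d, X, i0, wk);
    fv r = wk.pred - conv_to<fv>::from(y.subvec(i0, i0 + n - 1));
    loss += dot(conv_to<vec>::from(r), conv_to<vec>::from(r));
    fv dpred = (float)(2.0 / (double)N) * r;
    chunk_backward(q, d, wk, dpred, &G, &dA1);
  }
  loss /= (double)N;

  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("W1") = conv_to<mat>::from(G.W1),
          Rcpp::Named("b1") = conv_to<vec>::from(G.b1),
          Rcpp::Named("W2") = conv_to<mat>::from(G.W2),
          Rcpp::Named("b2") = conv_to<vec>::from(G.b2),
          Rcpp::Named("Wd") = conv_to<mat>::from(G.Wd),
          Rcpp::Named("bd") = conv_to<vec>::from(G.bd),
          Rcpp::Named("Wo") = conv_to<vec>::from(G.Wo),
          Rcpp::Named("bo") = (double)G.bo));
}

// Gradient of each sample's scalar output with respect to its own input
// cells (the raw material of a saliency map). Returns a cube shaped
// like X.
// [[Rcpp::export]]
arma::cube cnn_input_grad_cpp(Rcpp::List params, arma::cube X,
                              Rcpp::List dims, int chunk = 32) {
  Params q = read_params(params);
  Dims d = read_dims(dims);
  const uword N = X.n_slices;
  cube out(X.n_rows, X.n_cols, N, fill::zeros);

  const uword cap = std::min((uword)chunk, std::max(N, (uword)1));
  Work w(d, cap);
  std::unique_ptr<Work> tail;
  fm dA1;
  for (uword i0 = 0; i0 < N; i0 += cap) {
    uword n = std::min(cap, N - i0);
    Work& wk = pick_work(d, n, w, tail);
    chunk_forward(q, d, X, i0, wk);
    fv dpred = ones<fv>(n);              // d pred_i / d pred_i
    chunk_backward(q, d, wk, dpred, nullptr, &dA1);
    fm dcol1 = dA1 * q.W1.t();           // (n*npos1) x K*K
    fm dX((uword)(d.H * d.W), 1);
    for (uword i = 0; i < n; ++i) {
      dX.zeros();
      col2im(dcol1, i * d.npos1, d.H, d.W, 1, d.K, d.P, dX, 0);
      out.slice(i0 + i) =
          reshape(conv_to<mat>::from(dX), X.n_rows, X.n_cols);
    }
  }
  return out;
}

// One fused Adam step over the full parameter list, with a per-tensor
// learning rate. Returns fresh parameter/moment objects (no in-place
// mutation of R objects).
// [[Rcpp::export]]
Rcpp::List adam_step_cpp(Rcpp::List params, Rcpp::List grads,
                         Rcpp::List m, Rcpp::List v, int t,
                         Rcpp::NumericVector lr,
                         double beta1 = 0.9, double beta2 = 0.999,
                         double eps = 1e-8) {
  const int K = params.size();
  if (lr.size() != K && lr.size() != 1) Rcpp::stop("lr must have length 1 or K");
  Rcpp::List p_out(K), m_out(K), v_out(K);
  p_out.names() = params.names();
  m_out.names() = params.names();
  v_out.names() = params.names();
  const double bc1 = 1.0 - std::pow(beta1, (double)t);
  const double bc2 = 1.0 - std::pow(beta2, (double)t);
  for (int k = 0; k < K; ++k) {
    Rcpp::NumericVector pk = params[k], gk = grads[k], mk = m[k], vk = v[k];
    const R_xlen_t n = pk.size();
    const double lrk = lr.size() == 1 ? lr[0] : lr[k];
    Rcpp::NumericVector po(n), mo(n), vo(n);
    po.attr("dim") = pk.attr("dim");
    for (R_xlen_t i = 0; i < n; ++i) {
      const double mi = beta1 * mk[i] + (1.0 - beta1) * gk[i];
      const double vi = beta2 * vk[i] + (1.0 - beta2) * gk[i] * gk[i];
      mo[i] = mi;
      vo[i] = vi;
      po[i] = pk[i] - lrk * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
    }
    p_out[k] = po; m_out[k] = mo; v_out[k] = vo;
  }
  return Rcpp::List::create(Rcpp::Named("params") = p_out,
                            Rcpp::Named("m") = m_out,
                            Rcpp::Named("v") = v_out);
}
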
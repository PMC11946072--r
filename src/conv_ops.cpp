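// Batched 2-D convolution / pooling / attention kernels for the
// restoration network.  Spatial tensors are R arrays in channel-last
// (H, W, N, C) layout (column-major, H fastest); each channel is then a
// contiguous block, which the convolution exploits below.

#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// C := alpha * op(A) * op(B) + beta * C, column-major with explicit LDs
static void gemm(char ta, char tb, int m, int n, int k, double alpha,
                 const double* A, int lda, const double* B, int ldb,
                 double beta, double* C, int ldc) {
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta,
                  C, &ldc FCONE FCONE);
}

// Convolution via per-offset GEMM on a zero-padded copy of the input.
// Layout is (H, W, N, C): each channel is a contiguous (H*W*N) block, so
// the padded tensor views directly as an ((H+2)*(W+2)*N x C) matrix and
// each of the 9 kernel taps is a constant row offset -- no gather needed.

static NumericVector pad_input(const NumericVector& x, int H, int W, int N,
                               int C) {
  const int Hp = H + 2, Wp = W + 2;
  const size_t P = static_cast<size_t>(Hp) * Wp;
  NumericVector xp(P * N * C); // zero-initialized
  const size_t HW = static_cast<size_t>(H) * W;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const double* src = x.begin() + (static_cast<size_t>(c) * N + n) * HW;
      double* dst = xp.begin() + (static_cast<size_t>(c) * N + n) * P;
      for (int j = 0; j < W; ++j)
        std::copy(src + j * H, src + (j + 1) * H, dst + (j + 1) * Hp + 1);
    }
  return xp;
}

static arma::mat weight_slice(const NumericVector& w, int C, int Cout,
                              int dy, int dx) {
  // w is (3, 3, C, Cout); slice for one tap offset
  arma::mat Wk(C, Cout);
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < C; ++c)
      Wk(c, o) = w[(dy + 1) + 3 * (dx + 1) + 9 * (c + static_cast<size_t>(C) * o)];
  return Wk;
}

// [[Rcpp::export]]
NumericVector conv3x3_fwd(NumericVector x, NumericVector w, NumericVector b,
                          bool relu = false) {
  IntegerVector dx_ = x.attr("dim");
  IntegerVector dw_ = w.attr("dim");
  const int H = dx_[0], W = dx_[1], N = dx_[2], C = dx_[3];
  const int Cout = dw_[3];
  if (dw_[2] != C) stop("conv3x3_fwd: channel mismatch");
  const int Hp = H + 2, Wp = W + 2;
  const size_t P = static_cast<size_t>(Hp) * Wp;
  const size_t PN = P * N;
  NumericVector xp = pad_input(x, H, W, N, C);
  const long r0 = Hp + 1, r1 = PN - Hp - 2; // inclusive window
  const int M = static_cast<int>(r1 - r0 + 1);
  std::vector<double> Y(PN * Cout);
  bool first = true;
  for (int ddx = -1; ddx <= 1; ++ddx)
    for (int dy = -1; dy <= 1; ++dy) {
      arma::mat Wk = weight_slice(w, C, Cout, dy, ddx);
      const long o = dy + Hp * ddx;
      gemm('N', 'N', M, Cout, C, 1.0, xp.begin() + r0 + o, (int)PN,
           Wk.memptr(), C, first ? 0.0 : 1.0, Y.data() + r0, (int)PN);
      first = false;
    }
  NumericVector out(static_cast<size_t>(H) * W * N * Cout);
  out.attr("dim") = IntegerVector::create(H, W, N, Cout);
  const size_t HW = static_cast<size_t>(H) * W;
  for (int o = 0; o < Cout; ++o) {
    const double* src = Y.data() + static_cast<size_t>(o) * PN;
    const double bo = b[o];
    for (int n = 0; n < N; ++n) {
      double* dst = out.begin() + (static_cast<size_t>(o) * N + n) * HW;
      const double* sp = src + static_cast<size_t>(n) * P;
      for (int j = 0; j < W; ++j) {
        const double* s = sp + (j + 1) * Hp + 1;
        double* d = dst + j * H;
        if (relu) {
          for (int i = 0; i < H; ++i) {
            const double v = s[i] + bo;
            d[i] = v > 0.0 ? v : 0.0;
          }
        } else {
          for (int i = 0; i < H; ++i) d[i] = s[i] + bo;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv3x3_bwd(NumericVector x, NumericVector w, NumericVector dy,
                 Nullable<NumericVector> relu_y = R_NilValue) {
  IntegerVector dx_ = x.attr("dim");
  IntegerVector dw_ = w.attr("dim");
  const int H = dx_[0], W = dx_[1], N = dx_[2], C = dx_[3];
  const int Cout = dw_[3];
  const int Hp = H + 2, Wp = W + 2;
  const size_t P = static_cast<size_t>(Hp) * Wp;
  const size_t PN = P * N;
  NumericVector xp = pad_input(x, H, W, N, C);
  NumericVector dyp = pad_input(dy, H, W, N, Cout);
  if (relu_y.isNotNull()) {
    // fused ReLU adjoint: mask the padded upstream gradient where the
    // (post-ReLU) activation was clamped
    NumericVector yv(relu_y);
    const double* yp = yv.begin();
    for (int o = 0; o < Cout; ++o)
      for (int n = 0; n < N; ++n) {
        const double* ysrc = yp + (static_cast<size_t>(o) * N + n) *
                                      static_cast<size_t>(H) * W;
        double* gdst = dyp.begin() + (static_cast<size_t>(o) * N + n) * P;
        for (int j = 0; j < W; ++j) {
          const double* yv2 = ysrc + j * H;
          double* g = gdst + (j + 1) * Hp + 1;
          for (int i = 0; i < H; ++i)
            if (yv2[i] <= 0.0) g[i] = 0.0;
        }
      }
  }
  const long r0 = Hp + 1, r1 = PN - Hp - 2;
  const int M = static_cast<int>(r1 - r0 + 1);
  std::vector<double> dXp(PN * C, 0.0);
  NumericVector dwv(static_cast<size_t>(9) * C * Cout);
  dwv.attr("dim") = IntegerVector::create(3, 3, C, Cout);
  arma::mat dWk(C, Cout);
  for (int ddx = -1; ddx <= 1; ++ddx)
    for (int dy_ = -1; dy_ <= 1; ++dy_) {
      const long o = dy_ + Hp * ddx;
      arma::mat Wk = weight_slice(w, C, Cout, dy_, ddx);
      // dW_k = X(shifted window)^T * dY(window)
      gemm('T', 'N', C, Cout, M, 1.0, xp.begin() + r0 + o, (int)PN,
           dyp.begin() + r0, (int)PN, 0.0, dWk.memptr(), C);
      for (int oo = 0; oo < Cout; ++oo)
        for (int c = 0; c < C; ++c)
          dwv[(dy_ + 1) + 3 * (ddx + 1) +
              9 * (c + static_cast<size_t>(C) * oo)] = dWk(c, oo);
      // dX(shifted window) += dY(window) * W_k^T
      gemm('N', 'T', M, C, Cout, 1.0, dyp.begin() + r0, (int)PN,
           Wk.memptr(), C, 1.0, dXp.data() + r0 + o, (int)PN);
    }
  NumericVector dxv(static_cast<size_t>(H) * W * N * C);
  dxv.attr("dim") = IntegerVector::create(H, W, N, C);
  const size_t HW = static_cast<size_t>(H) * W;
  for (int c = 0; c < C; ++c) {
    const double* src = dXp.data() + static_cast<size_t>(c) * PN;
    for (int n = 0; n < N; ++n) {
      double* dst = dxv.begin() + (static_cast<size_t>(c) * N + n) * HW;
      const double* sp = src + static_cast<size_t>(n) * P;
      for (int j = 0; j < W; ++j)
        std::copy(sp + (j + 1) * Hp + 1, sp + (j + 1) * Hp + 1 + H,
                  dst + j * H);
    }
  }
  NumericVector dbv(Cout);
  for (int o = 0; o < Cout; ++o) {
    double s = 0.0;
    const double* g = dyp.begin() + static_cast<size_t>(o) * PN;
    for (size_t i = 0; i < PN; ++i) s += g[i];
    dbv[o] = s;
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<size_t>(Ho) * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const int HW = H * W, HWo = Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = x.begin() + (static_cast<size_t>(n) * C + c) * HW;
      double* dst = y.begin() + (static_cast<size_t>(n) * C + c) * HWo;
      int* id = idx.begin() + (static_cast<size_t>(n) * C + c) * HWo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          int best = (2 * j) * H + 2 * i;
          double bv = src[best];
          const int cand[3] = {(2 * j) * H + 2 * i + 1,
                               (2 * j + 1) * H + 2 * i,
                               (2 * j + 1) * H + 2 * i + 1};
          for (int k = 0; k < 3; ++k)
            if (src[cand[k]] > bv) { bv = src[cand[k]]; best = cand[k]; }
          dst[j * Ho + i] = bv;
          id[j * Ho + i] = best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx,
                           IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  const int HW = H * W, HWo = Ho * Wo;
  NumericVector dx(static_cast<size_t>(HW) * C * N);
  dx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* g = dy.begin() + (static_cast<size_t>(n) * C + c) * HWo;
      const int* id = idx.begin() + (static_cast<size_t>(n) * C + c) * HWo;
      double* out = dx.begin() + (static_cast<size_t>(n) * C + c) * HW;
      for (int p = 0; p < HWo; ++p) out[id[p]] += g[p];
    }
  return dx;
}

// [[Rcpp::export]]
NumericVector avgpool_fwd(NumericVector x, int f) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / f, Wo = W / f;
  NumericVector y(static_cast<size_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const int HW = H * W, HWo = Ho * Wo;
  const double scale = 1.0 / (f * f);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = x.begin() + (static_cast<size_t>(n) * C + c) * HW;
      double* dst = y.begin() + (static_cast<size_t>(n) * C + c) * HWo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double s = 0.0;
          for (int fj = 0; fj < f; ++fj)
            for (int fi = 0; fi < f; ++fi)
              s += src[(j * f + fj) * H + i * f + fi];
          dst[j * Ho + i] = s * scale;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool_bwd(NumericVector dy, int f, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / f, Wo = W / f;
  const int HW = H * W, HWo = Ho * Wo;
  const double scale = 1.0 / (f * f);
  NumericVector dx(static_cast<size_t>(HW) * C * N);
  dx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* g = dy.begin() + (static_cast<size_t>(n) * C + c) * HWo;
      double* out = dx.begin() + (static_cast<size_t>(n) * C + c) * HW;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          const double v = g[j * Ho + i] * scale;
          for (int fj = 0; fj < f; ++fj)
            for (int fi = 0; fi < f; ++fi)
              out[(j * f + fj) * H + i * f + fi] = v;
        }
    }
  return dx;
}

// [[Rcpp::export]]
NumericVector upsample2_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(static_cast<size_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const int HW = H * W, HWo = Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = x.begin() + (static_cast<size_t>(n) * C + c) * HW;
      double* dst = y.begin() + (static_cast<size_t>(n) * C + c) * HWo;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const double v = src[j * H + i];
          dst[(2 * j) * Ho + 2 * i] = v;
          dst[(2 * j) * Ho + 2 * i + 1] = v;
          dst[(2 * j + 1) * Ho + 2 * i] = v;
          dst[(2 * j + 1) * Ho + 2 * i + 1] = v;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd(NumericVector dy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  const int HW = H * W, HWo = Ho * Wo;
  NumericVector dx(static_cast<size_t>(HW) * C * N);
  dx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* g = dy.begin() + (static_cast<size_t>(n) * C + c) * HWo;
      double* out = dx.begin() + (static_cast<size_t>(n) * C + c) * HW;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          out[j * H + i] = g[(2 * j) * Ho + 2 * i] +
                           g[(2 * j) * Ho + 2 * i + 1] +
                           g[(2 * j + 1) * Ho + 2 * i] +
                           g[(2 * j + 1) * Ho + 2 * i + 1];
    }
  return dx;
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* s = x.begin();
  double* d = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) d[i] = s[i] > 0.0 ? s[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* g = dy.begin();
  const double* v = y.begin();
  double* d = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) d[i] = v[i] > 0.0 ? g[i] : 0.0;
  return dx;
}

// one attention head over a batch of token blocks: Q, K, V are
// (N*T x hd); returns ctx (N*T x hd) and the attention weights A as a
// (T x T x N) cube (rows attend over columns within each sample block)
// [[Rcpp::export]]
List attn_head_fwd(NumericMatrix Q, NumericMatrix K, NumericMatrix V,
                   int Tn) {
  const int NT = Q.nrow(), hd = Q.ncol();
  const int N = NT / Tn;
  const double scale = 1.0 / std::sqrt((double)hd);
  arma::mat Qm(Q.begin(), NT, hd, false), Km(K.begin(), NT, hd, false),
      Vm(V.begin(), NT, hd, false);
  arma::cube A(Tn, Tn, N);
  arma::mat ctx(NT, hd);
  for (int n = 0; n < N; ++n) {
    const int r = n * Tn;
    arma::mat S = Qm.rows(r, r + Tn - 1) * Km.rows(r, r + Tn - 1).t() * scale;
    for (int i = 0; i < Tn; ++i) {
      double mx = S.row(i).max();
      arma::rowvec e = arma::exp(S.row(i) - mx);
      A.slice(n).row(i) = e / arma::accu(e);
    }
    ctx.rows(r, r + Tn - 1) = A.slice(n) * Vm.rows(r, r + Tn - 1);
  }
  NumericMatrix ctxR(NT, hd);
  std::copy(ctx.begin(), ctx.end(), ctxR.begin());
  NumericVector Av(A.begin(), A.end());
  Av.attr("dim") = IntegerVector::create(Tn, Tn, N);
  return List::create(_["ctx"] = ctxR, _["A"] = Av);
}

// [[Rcpp::export]]
List attn_head_bwd(NumericMatrix dctx, NumericVector A, NumericMatrix Q,
                   NumericMatrix K, NumericMatrix V, int Tn) {
  const int NT = Q.nrow(), hd = Q.ncol();
  const int N = NT / Tn;
  const double scale = 1.0 / std::sqrt((double)hd);
  arma::mat dC(dctx.begin(), NT, hd, false);
  arma::mat Qm(Q.begin(), NT, hd, false), Km(K.begin(), NT, hd, false),
      Vm(V.begin(), NT, hd, false);
  arma::cube Ac(A.begin(), Tn, Tn, N, false);
  arma::mat dQ(NT, hd), dK(NT, hd), dV(NT, hd);
  for (int n = 0; n < N; ++n) {
    const int r = n * Tn;
    const arma::mat& An = Ac.slice(n);
    arma::mat dA = dC.rows(r, r + Tn - 1) * Vm.rows(r, r + Tn - 1).t();
    dV.rows(r, r + Tn - 1) = An.t() * dC.rows(r, r + Tn - 1);
    arma::mat dS = (dA - arma::repmat(arma::sum(dA % An, 1), 1, Tn)) % An;
    dS *= scale;
    dQ.rows(r, r + Tn - 1) = dS * Km.rows(r, r + Tn - 1);
    dK.rows(r, r + Tn - 1) = dS.t() * Qm.rows(r, r + Tn - 1);
  }
  NumericMatrix dQr(NT, hd), dKr(NT, hd), dVr(NT, hd);
  std::copy(dQ.begin(), dQ.end(), dQr.begin());
  std::copy(dK.begin(), dK.end(), dKr.begin());
  std::copy(dV.begin(), dV.end(), dVr.begin());
  return List::create(_["dQ"] = dQr, _["dK"] = dKr, _["dV"] = dVr);
}

// exact GELU x * Phi(x) and its derivative, elementwise
// [[Rcpp::export]]
NumericVector gelu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double isq2 = 1.0 / std::sqrt(2.0);
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] * 0.5 * (1.0 + std::erf(x[i] * isq2));
  return y;
}

// [[Rcpp::export]]
NumericVector gelu_bwd_cpp(NumericVector dy, NumericVector x) {
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  const double isq2 = 1.0 / std::sqrt(2.0);
  const double inv_sqrt2pi = 0.3989422804014327;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double phi = 0.5 * (1.0 + std::erf(x[i] * isq2));
    dx[i] = dy[i] * (phi + x[i] * inv_sqrt2pi * std::exp(-0.5 * x[i] * x[i]));
  }
  return dx;
}
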
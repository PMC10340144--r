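// 3D convolution primitives (im2col + GEMM), transposed convolution,
// max-pooling and connected-component labeling for volumetric blocks.
//
// Array layout follows R column-major order with dims (D, H, W, C):
// index = d + D*(h + H*(w + W*c)).  Convolution weights have dims
// (KD, KH, KW, Cin, Cout) so that matrix(w, KD*KH*KW*Cin, Cout) lines up
// with the im2col row ordering (kd fastest, then kh, kw, cin).
//
// GEMMs and the im2col buffers run in single precision: the networks are
// trained with losses of magnitude ~1 and float32 accumulation is standard
// for convolutional training; everything exposed to R stays double.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

static arma::fvec to_f(const double* x, size_t n) {
  arma::fvec out(n);
  float* o = out.memptr();
  for (size_t i = 0; i < n; ++i) o[i] = (float)x[i];
  return out;
}

static NumericVector to_d(const float* x, size_t n, IntegerVector dim) {
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = x[i];
  out.attr("dim") = dim;
  return out;
}

// Fill `cols` (K3*Cin x Nout) from x (D,H,W,C).  Out-of-range taps are 0.
static void im2col_3d(const float* x, int D, int H, int W, int C,
                      int K, int S, int P, int Do, int Ho, int Wo,
                      arma::fmat& cols) {
  const int K3C = K * K * K * C;
  cols.zeros(K3C, (arma::uword)Do * Ho * Wo);
  float* cp = cols.memptr();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int dd = 0; dd < Do; ++dd) {
        const arma::uword colidx = (arma::uword)dd + (arma::uword)Do * (ho + (arma::uword)Ho * wo);
        float* dst = cp + colidx * K3C;
        const int d_base = dd * S - P;
        const bool d_interior = d_base >= 0 && d_base + K <= D;
        for (int c = 0; c < C; ++c) {
          for (int kw = 0; kw < K; ++kw) {
            const int w0 = wo * S - P + kw;
            for (int kh = 0; kh < K; ++kh) {
              const int h0 = ho * S - P + kh;
              float* drow = dst + K * (kh + K * (kw + K * c));
              if (w0 < 0 || w0 >= W || h0 < 0 || h0 >= H) continue;
              const float* src = x + (size_t)D * (h0 + (size_t)H * (w0 + (size_t)W * c)) + d_base;
              if (d_interior) {
                for (int kd = 0; kd < K; ++kd) drow[kd] = src[kd];
              } else {
                for (int kd = 0; kd < K; ++kd) {
                  const int d0 = d_base + kd;
                  if (d0 >= 0 && d0 < D) drow[kd] = src[kd];
                }
              }
            }
          }
        }
      }
    }
  }
}

// Adjoint of im2col_3d: scatter-add `cols` back into gx (D,H,W,C).
static void col2im_3d(const arma::fmat& cols, int D, int H, int W, int C,
                      int K, int S, int P, int Do, int Ho, int Wo,
                      float* gx) {
  const int K3C = K * K * K * C;
  const float* cp = cols.memptr();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int dd = 0; dd < Do; ++dd) {
        const arma::uword colidx = (arma::uword)dd + (arma::uword)Do * (ho + (arma::uword)Ho * wo);
        const float* src0 = cp + colidx * K3C;
        const int d_base = dd * S - P;
        const bool d_interior = d_base >= 0 && d_base + K <= D;
        for (int c = 0; c < C; ++c) {
          for (int kw = 0; kw < K; ++kw) {
            const int w0 = wo * S - P + kw;
            if (w0 < 0 || w0 >= W) continue;
            for (int kh = 0; kh < K; ++kh) {
              const int h0 = ho * S - P + kh;
              if (h0 < 0 || h0 >= H) continue;
              const float* srow = src0 + K * (kh + K * (kw + K * c));
              float* dst = gx + (size_t)D * (h0 + (size_t)H * (w0 + (size_t)W * c)) + d_base;
              if (d_interior) {
                for (int kd = 0; kd < K; ++kd) dst[kd] += srow[kd];
              } else {
                for (int kd = 0; kd < K; ++kd) {
                  const int d0 = d_base + kd;
                  if (d0 >= 0 && d0 < D) dst[kd] += srow[kd];
                }
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector bias, int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int K = wdim[0], Cout = wdim[4];
  const int Do = out_extent(D, K, stride, pad);
  const int Ho = out_extent(H, K, stride, pad);
  const int Wo = out_extent(W, K, stride, pad);
  if (Do < 1 || Ho < 1 || Wo < 1) stop("conv3d: output extent < 1");
  arma::fvec xf = to_f(x.begin(), x.size());
  arma::fmat cols;
  im2col_3d(xf.memptr(), D, H, W, C, K, stride, pad, Do, Ho, Wo, cols);
  arma::fvec wf = to_f(w.begin(), w.size());
  arma::fmat Wm(wf.memptr(), K * K * K * C, Cout, false, true);
  arma::fmat y = cols.t() * Wm;               // Nout x Cout
  arma::fvec bf = to_f(bias.begin(), bias.size());
  y.each_row() += bf.t();
  return to_d(y.memptr(), y.n_elem, IntegerVector::create(Do, Ho, Wo, Cout));
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector gy, int stride, int pad, bool need_gx) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int K = wdim[0], Cout = wdim[4];
  const int Do = out_extent(D, K, stride, pad);
  const int Ho = out_extent(H, K, stride, pad);
  const int Wo = out_extent(W, K, stride, pad);
  const arma::uword Nout = (arma::uword)Do * Ho * Wo;
  arma::fvec xf = to_f(x.begin(), x.size());
  arma::fmat cols;
  im2col_3d(xf.memptr(), D, H, W, C, K, stride, pad, Do, Ho, Wo, cols);
  arma::fvec gyf = to_f(gy.begin(), gy.size());
  arma::fmat Gy(gyf.memptr(), Nout, Cout, false, true);
  arma::fmat gW = cols * Gy;                  // K3C x Cout
  arma::frowvec gB = arma::sum(Gy, 0);
  List out = List::create(
    _["gx"] = R_NilValue,
    _["gw"] = to_d(gW.memptr(), gW.n_elem, wdim),
    _["gb"] = NumericVector(gB.begin(), gB.end()));
  if (need_gx) {
    arma::fvec wf = to_f(w.begin(), w.size());
    arma::fmat Wm(wf.memptr(), K * K * K * C, Cout, false, true);
    arma::fmat gcols = Wm * Gy.t();           // K3C x Nout
    arma::fvec gxf(x.size(), arma::fill::zeros);
    col2im_3d(gcols, D, H, W, C, K, stride, pad, Do, Ho, Wo, gxf.memptr());
    out["gx"] = to_d(gxf.memptr(), gxf.n_elem, xdim);
  }
  return out;
}

// Transposed conv: weight dims (K,K,K,Cout,Cin); spatial output dims given
// explicitly (must satisfy out_extent(out, K, stride, pad) == input extent).
// [[Rcpp::export]]
NumericVector cpp_convt3d_fwd(NumericVector u, IntegerVector udim,
                              NumericVector w, IntegerVector wdim,
                              NumericVector bias, int stride, int pad,
                              IntegerVector outdim) {
  const int Du = udim[0], Hu = udim[1], Wu = udim[2], Cu = udim[3];
  const int K = wdim[0], Cv = wdim[3];
  const int Dv = outdim[0], Hv = outdim[1], Wv = outdim[2];
  if (out_extent(Dv, K, stride, pad) != Du || out_extent(Hv, K, stride, pad) != Hu ||
      out_extent(Wv, K, stride, pad) != Wu)
    stop("convt3d: output dims inconsistent with stride geometry");
  const arma::uword Nu = (arma::uword)Du * Hu * Wu;
  arma::fvec uf = to_f(u.begin(), u.size());
  arma::fmat Um(uf.memptr(), Nu, Cu, false, true);
  arma::fvec wf = to_f(w.begin(), w.size());
  arma::fmat Wm(wf.memptr(), K * K * K * Cv, Cu, false, true);
  arma::fmat M = Wm * Um.t();                 // K3Cv x Nu
  arma::fvec vf((size_t)Dv * Hv * Wv * Cv, arma::fill::zeros);
  col2im_3d(M, Dv, Hv, Wv, Cv, K, stride, pad, Du, Hu, Wu, vf.memptr());
  float* vp = vf.memptr();
  const size_t sp = (size_t)Dv * Hv * Wv;
  for (int c = 0; c < Cv; ++c) {
    const float bc = (float)bias[c];
    for (size_t i = 0; i < sp; ++i) vp[(size_t)c * sp + i] += bc;
  }
  return to_d(vf.memptr(), vf.n_elem, IntegerVector::create(Dv, Hv, Wv, Cv));
}

// [[Rcpp::export]]
List cpp_convt3d_bwd(NumericVector u, IntegerVector udim,
                     NumericVector w, IntegerVector wdim,
                     NumericVector gv, IntegerVector outdim,
                     int stride, int pad) {
  const int Du = udim[0], Hu = udim[1], Wu = udim[2], Cu = udim[3];
  const int K = wdim[0], Cv = wdim[3];
  const int Dv = outdim[0], Hv = outdim[1], Wv = outdim[2];
  const arma::uword Nu = (arma::uword)Du * Hu * Wu;
  arma::fvec gvf = to_f(gv.begin(), gv.size());
  arma::fmat gcols;
  im2col_3d(gvf.memptr(), Dv, Hv, Wv, Cv, K, stride, pad, Du, Hu, Wu, gcols);
  arma::fvec uf = to_f(u.begin(), u.size());
  arma::fmat Um(uf.memptr(), Nu, Cu, false, true);
  arma::fvec wf = to_f(w.begin(), w.size());
  arma::fmat Wm(wf.memptr(), K * K * K * Cv, Cu, false, true);
  arma::fmat Gu = gcols.t() * Wm;             // Nu x Cu
  arma::fmat gW = gcols * Um;                 // K3Cv x Cu
  NumericVector gb(Cv);
  const size_t sp = (size_t)Dv * Hv * Wv;
  const float* gvp = gvf.memptr();
  for (int c = 0; c < Cv; ++c) {
    double s = 0;
    for (size_t i = 0; i < sp; ++i) s += gvp[(size_t)c * sp + i];
    gb[c] = s;
  }
  return List::create(_["gu"] = to_d(Gu.memptr(), Gu.n_elem, udim),
                      _["gw"] = to_d(gW.memptr(), gW.n_elem, wdim),
                      _["gb"] = gb);
}

// 2x2x2 max pooling, stride 2; returns pooled values and 1-based argmax
// indices into the flattened input.
// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x, IntegerVector xdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  if (D % 2 || H % 2 || W % 2) stop("maxpool3d: spatial dims must be even");
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Do * Ho * Wo * C);
  IntegerVector idx(y.size());
  const double* xp = x.begin();
  size_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int dd = 0; dd < Do; ++dd, ++o) {
          double best = -INFINITY; size_t bi = 0;
          for (int kw = 0; kw < 2; ++kw)
            for (int kh = 0; kh < 2; ++kh)
              for (int kd = 0; kd < 2; ++kd) {
                const size_t i = (size_t)(2 * dd + kd) +
                  (size_t)D * ((2 * ho + kh) + (size_t)H * ((2 * wo + kw) + (size_t)W * c));
                if (xp[i] > best) { best = xp[i]; bi = i; }
              }
          y[o] = best; idx[o] = (int)(bi + 1);
        }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector gy, IntegerVector idx, double n_in) {
  NumericVector gx((R_xlen_t)n_in);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  return gx;
}

// 6-connectivity labeling of a 3D binary mask; labels 1..n, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2];
  IntegerVector lab((size_t)D * H * W);
  int next = 0;
  std::queue<size_t> q;
  const int off_d[6] = {-1, 1, 0, 0, 0, 0};
  const int off_h[6] = {0, 0, -1, 1, 0, 0};
  const int off_w[6] = {0, 0, 0, 0, -1, 1};
  for (size_t s = 0; s < (size_t)D * H * W; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      size_t i = q.front(); q.pop();
      const int d = i % D, h = (i / D) % H, w = i / ((size_t)D * H);
      for (int k = 0; k < 6; ++k) {
        const int dn = d + off_d[k], hn = h + off_h[k], wn = w + off_w[k];
        if (dn < 0 || dn >= D || hn < 0 || hn >= H || wn < 0 || wn >= W) continue;
        const size_t j = (size_t)dn + (size_t)D * (hn + (size_t)H * wn);
        if (mask[j] && !lab[j]) { lab[j] = next; q.push(j); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
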
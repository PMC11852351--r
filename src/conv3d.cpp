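// 3D convolution kernels for the dual-path network.
//
// Layout conventions (column-major, matching R arrays):
//   feature grids  x : (d, h, w, cin)
//   kernels        W : (k, k, k, cin, cout)
// Convolutions are cross-correlations (deep-learning convention), zero
// padded. The volume is processed one output width-slab at a time via
// im2col + GEMM: slab-wise columns keep peak memory bounded even for 7^3
// kernels on 64^3 grids, and the inner copies run along the depth axis,
// which is contiguous in memory. Arithmetic is float32 — the working
// precision of the network — which halves memory traffic on these
// bandwidth-bound kernels; inputs and results cross the R boundary as
// doubles.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

static inline int out_extent(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static arma::fvec to_float(const NumericVector &v) {
  arma::fvec f(v.size());
  const double *p = v.begin();
  for (size_t i = 0; i < f.n_elem; ++i) f[i] = (float)p[i];
  return f;
}

// Fill M (od*oh x k^3*cin) with the im2col columns of output slab ox.
static void im2col_slab(const float *x, int d, int h, int w, int cin,
                        int k, int s, int p, int od, int oh, int ox,
                        arma::fmat &M) {
  M.zeros();
  const int k3 = k * k * k;
  for (int ci = 0; ci < cin; ++ci) {
    const float *xc = x + (size_t)ci * d * h * w;
    for (int c = 0; c < k; ++c) {      // width tap
      const int iw = ox * s - p + c;
      if (iw < 0 || iw >= w) continue;
      for (int b = 0; b < k; ++b) {    // height tap
        int oy0 = (p - b + s - 1) / s; if (oy0 < 0) oy0 = 0;
        int oy1 = (h - 1 + p - b) / s; if (oy1 > oh - 1) oy1 = oh - 1;
        for (int a = 0; a < k; ++a) {  // depth tap
          const int col = a + k * b + k * k * c + k3 * ci;
          float *Mcol = M.colptr(col);
          int oz0 = (p - a + s - 1) / s; if (oz0 < 0) oz0 = 0;
          int oz1 = (d - 1 + p - a) / s; if (oz1 > od - 1) oz1 = od - 1;
          const int run = oz1 - oz0 + 1;
          if (run <= 0) continue;
          for (int oy = oy0; oy <= oy1; ++oy) {
            const int ih = oy * s - p + b;
            const float *src = xc + (oz0 * s - p + a) + (size_t)d * ih +
                               (size_t)d * h * iw;
            float *dst = Mcol + oz0 + (size_t)od * oy;
            if (s == 1) {
              std::memcpy(dst, src, run * sizeof(float));
            } else {
              for (int oz = 0; oz < run; ++oz) dst[oz] = src[(size_t)oz * s];
            }
          }
        }
      }
    }
  }
}

// Scatter-add the columns G (od*oh x k^3*cin) of output slab ox into gx.
static void col2im_slab(float *gx, int d, int h, int w, int cin,
                        int k, int s, int p, int od, int oh, int ox,
                        const arma::fmat &G) {
  const int k3 = k * k * k;
  for (int ci = 0; ci < cin; ++ci) {
    float *gxc = gx + (size_t)ci * d * h * w;
    for (int c = 0; c < k; ++c) {
      const int iw = ox * s - p + c;
      if (iw < 0 || iw >= w) continue;
      for (int b = 0; b < k; ++b) {
        int oy0 = (p - b + s - 1) / s; if (oy0 < 0) oy0 = 0;
        int oy1 = (h - 1 + p - b) / s; if (oy1 > oh - 1) oy1 = oh - 1;
        for (int a = 0; a < k; ++a) {
          const int col = a + k * b + k * k * c + k3 * ci;
          const float *Gcol = G.colptr(col);
          int oz0 = (p - a + s - 1) / s; if (oz0 < 0) oz0 = 0;
          int oz1 = (d - 1 + p - a) / s; if (oz1 > od - 1) oz1 = od - 1;
          const int run = oz1 - oz0 + 1;
          if (run <= 0) continue;
          for (int oy = oy0; oy <= oy1; ++oy) {
            const int ih = oy * s - p + b;
            float *dst = gxc + (oz0 * s - p + a) + (size_t)d * ih +
                         (size_t)d * h * iw;
            const float *src = Gcol + oz0 + (size_t)od * oy;
            if (s == 1) {
              for (int oz = 0; oz < run; ++oz) dst[oz] += src[oz];
            } else {
              for (int oz = 0; oz < run; ++oz) dst[(size_t)oz * s] += src[oz];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, NumericVector W,
                            int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  const int d = xd[0], h = xd[1], w = xd[2], cin = xd[3];
  const int k = wd[0], cout = wd[4];
  if (wd[3] != cin) stop("conv3d: channel mismatch");
  const int od = out_extent(d, k, stride, pad);
  const int oh = out_extent(h, k, stride, pad);
  const int ow = out_extent(w, k, stride, pad);
  const int k3cin = k * k * k * cin;

  arma::fvec xf = to_float(x), wf = to_float(W);
  arma::fmat Wm(wf.memptr(), k3cin, cout, false, true);
  arma::fmat M(od * oh, k3cin), Y(od * oh, cout);
  NumericVector y(NumericVector((size_t)od * oh * ow * cout));
  y.attr("dim") = IntegerVector::create(od, oh, ow, cout);
  double *yp = y.begin();

  for (int ox = 0; ox < ow; ++ox) {
    im2col_slab(xf.memptr(), d, h, w, cin, k, stride, pad, od, oh, ox, M);
    Y = M * Wm;
    // slab rows (oz fastest, then oy) are contiguous in y for fixed ox
    for (int co = 0; co < cout; ++co) {
      const float *src = Y.colptr(co);
      double *dst = yp + (size_t)od * oh * ox + (size_t)od * oh * ow * co;
      for (int i = 0; i < od * oh; ++i) dst[i] = src[i];
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, NumericVector W, NumericVector gy,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  const int d = xd[0], h = xd[1], w = xd[2], cin = xd[3];
  const int k = wd[0], cout = wd[4];
  const int od = out_extent(d, k, stride, pad);
  const int oh = out_extent(h, k, stride, pad);
  const int ow = out_extent(w, k, stride, pad);
  const int k3cin = k * k * k * cin;

  arma::fvec xf = to_float(x), wf = to_float(W), gyf = to_float(gy);
  arma::fmat Wm(wf.memptr(), k3cin, cout, false, true);
  arma::fmat M(od * oh, k3cin), Gs(od * oh, cout), Gc(od * oh, k3cin);
  arma::fmat gWm(k3cin, cout, arma::fill::zeros);
  arma::fvec gxf((size_t)d * h * w * cin, arma::fill::zeros);

  for (int ox = 0; ox < ow; ++ox) {
    im2col_slab(xf.memptr(), d, h, w, cin, k, stride, pad, od, oh, ox, M);
    for (int co = 0; co < cout; ++co)
      std::memcpy(Gs.colptr(co),
                  gyf.memptr() + (size_t)od * oh * ox + (size_t)od * oh * ow * co,
                  (size_t)od * oh * sizeof(float));
    gWm += M.t() * Gs;
    Gc = Gs * Wm.t();
    col2im_slab(gxf.memptr(), d, h, w, cin, k, stride, pad, od, oh, ox, Gc);
  }

  NumericVector gx(gxf.n_elem), gW(gWm.n_elem);
  for (size_t i = 0; i < gxf.n_elem; ++i) gx[i] = gxf[i];
  const float *gwp = gWm.memptr();
  for (size_t i = 0; i < gWm.n_elem; ++i) gW[i] = gwp[i];
  gx.attr("dim") = IntegerVector::create(d, h, w, cin);
  gW.attr("dim") = IntegerVector::create(k, k, k, cin, cout);
  return List::create(_["gx"] = gx, _["gW"] = gW);
}
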
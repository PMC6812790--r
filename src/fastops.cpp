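// Convolution and pooling kernels for the clip classifier. The im2col
// layout matches the R-side weight matrices: patch entries enumerate
// frame offset fastest, then band offset, then input channel; positions
// enumerate the frame axis fastest.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// x: flat (H, W, C, B) array (column-major). wmat: (kh*kw*C) x F.
// Returns out: (OH, OW, F, B) array; col ((OH*OW*B) x kh*kw*C) when
// want_col (row (b*npos + pos), pos = oh + OH*ow).
// [[Rcpp::export]]
List cpp_conv2d(const NumericVector& x, const IntegerVector& dims,
                const NumericMatrix& wmat, const NumericVector& bias,
                int kh, int kw, bool want_col, bool relu) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const int OH = H - kh + 1, OW = W - kw + 1;
  const int F = wmat.ncol();
  const int npos = OH * OW;
  arma::mat col(((arma::uword)npos) * B, kh * kw * C);
  const double* xp = REAL(x);
  for (int b = 0; b < B; ++b) {
    const double* xb = xp + (size_t)b * H * W * C;
    const arma::uword r0 = (arma::uword)b * npos;
    int pcol = 0;
    for (int c = 0; c < C; ++c) {
      for (int dw = 0; dw < kw; ++dw) {
        for (int dh = 0; dh < kh; ++dh) {
          double* dst = col.colptr(pcol) + r0;
          const double* src = xb + (size_t)c * H * W + (size_t)dw * H + dh;
          arma::uword i = 0;
          for (int ow = 0; ow < OW; ++ow) {
            const double* s2 = src + (size_t)ow * H;
            for (int oh = 0; oh < OH; ++oh) dst[i++] = s2[oh];
          }
          ++pcol;
        }
      }
    }
  }
  const arma::mat wm(const_cast<double*>(REAL(wmat)), wmat.nrow(), wmat.ncol(),
                     false, true);
  arma::mat prod = col * wm;
  const double* bp = REAL(bias);
  for (int f = 0; f < F; ++f) prod.col(f) += bp[f];
  if (relu) prod.transform([](double v) { return v > 0.0 ? v : 0.0; });
  NumericVector out((R_xlen_t)npos * F * B);
  double* op = REAL(out);
  for (int b = 0; b < B; ++b) {
    for (int f = 0; f < F; ++f) {
      const double* src = prod.colptr(f) + (arma::uword)b * npos;
      double* dst = op + (size_t)npos * (f + (size_t)F * b);
      std::copy(src, src + npos, dst);
    }
  }
  out.attr("dim") = IntegerVector::create(OH, OW, F, B);
  if (want_col) return List::create(_["out"] = out, _["col"] = col);
  return List::create(_["out"] = out);
}

// Non-overlapping (ph, pw) max pooling with floor cropping. Optionally
// records the flat (1-based) argmax of each pooled cell for the backward
// pass.
// [[Rcpp::export]]
List cpp_maxpool(const NumericVector& x, const IntegerVector& dims, int ph,
                 int pw, bool want_argmax, int h0, int hn) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  if (hn < 0) hn = H - h0;
  const int Hp = hn / ph, Wp = W / pw;
  NumericVector out((R_xlen_t)Hp * Wp * C * B);
  IntegerVector amax(want_argmax ? out.size() : 0);
  double* op = REAL(out);
  int* ap = want_argmax ? INTEGER(amax) : (int*)nullptr;
  const double* xp = REAL(x);
  for (int cb = 0; cb < C * B; ++cb) {
    const double* plane = xp + (size_t)cb * H * W;
    const size_t obase = (size_t)cb * Hp * Wp;
    for (int ow = 0; ow < Wp; ++ow) {
      for (int oh = 0; oh < Hp; ++oh) {
        double m = -HUGE_VAL;
        size_t mi = 0;
        for (int dw = 0; dw < pw; ++dw) {
          const size_t coff = (size_t)(ow * pw + dw) * H + h0 + oh * ph;
          const double* colp = plane + coff;
          for (int dh = 0; dh < ph; ++dh) {
            if (colp[dh] > m) { m = colp[dh]; mi = coff + dh; }
          }
        }
        const size_t oi = obase + oh + (size_t)Hp * ow;
        op[oi] = m;
        if (ap) ap[oi] = (int)((size_t)cb * H * W + mi) + 1;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Hp, Wp, C, B);
  if (want_argmax) return List::create(_["out"] = out, _["argmax"] = amax);
  return List::create(_["out"] = out);
}

// Scatter pooled gradients back to the argmax positions.
// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(const NumericVector& dout,
                                   const IntegerVector& argmax,
                                   const IntegerVector& in_dims) {
  R_xlen_t n = (R_xlen_t)in_dims[0] * in_dims[1] * in_dims[2] * in_dims[3];
  NumericVector dx(n);
  double* dp = REAL(dx);
  const double* gp = REAL(dout);
  const int* ap = INTEGER(argmax);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dp[ap[i] - 1] += gp[i];
  dx.attr("dim") = in_dims;
  return dx;
}

// Windowed, zero-padded analysis frames: column j holds
// x[(j0+j-1)*hop + 1 .. +wl] * win, padded to nfft rows.
// [[Rcpp::export]]
ComplexMatrix cpp_pack_frames(const NumericVector& x, int f0, int nc, int hop,
                              const NumericVector& win, int nfft) {
  const int wl = win.size();
  const int npair = (nc + 1) / 2;
  ComplexMatrix z(nfft, npair);
  const double* xp = REAL(x);
  const double* wp = REAL(win);
  std::fill((double*)z.begin(), (double*)z.begin() + 2 * (size_t)nfft * npair,
            0.0);
  for (int j = 0; j < nc; ++j) {
    const double* src = xp + (size_t)(f0 + j - 1) * hop;
    Rcomplex* dst = z.begin() + (size_t)(j / 2) * nfft;
    if (j % 2 == 0) {
      for (int i = 0; i < wl; ++i) dst[i].r = src[i] * wp[i];
    } else {
      for (int i = 0; i < wl; ++i) dst[i].i = src[i] * wp[i];
    }
  }
  return z;
}

// Split the FFT of two packed real frames into their power spectra.
// Z: nfft x npair complex. Returns n_bins x (2*npair) power matrix.
// [[Rcpp::export]]
NumericMatrix cpp_split_power(const ComplexMatrix& Z, int n_bins) {
  const int nfft = Z.nrow(), npair = Z.ncol();
  NumericMatrix out(n_bins, 2 * npair);
  for (int j = 0; j < npair; ++j) {
    const Rcomplex* zc = Z.begin() + (size_t)j * nfft;
    double* po = &out(0, 2 * j);
    double* pe = &out(0, 2 * j + 1);
    for (int k = 0; k < n_bins; ++k) {
      const int kc = (nfft - k) % nfft;
      const double ar = zc[k].r, ai = zc[k].i;
      const double br = zc[kc].r, bi = -zc[kc].i;
      const double fr = 0.5 * (ar + br), fi = 0.5 * (ai + bi);
      const double gr = 0.5 * (ai - bi), gi = -0.5 * (ar - br);
      po[k] = fr * fr + fi * fi;
      pe[k] = gr * gr + gi * gi;
    }
  }
  return out;
}
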
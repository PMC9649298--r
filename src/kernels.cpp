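#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored per sample as R arrays dim (H, W, C), column-major,
// so the linear index of (h, w, c) is h + H*w + H*W*c.
//
// im2col patch matrix layout: row = dh + k*dw + k*k*c (kernel row offset
// fastest, then kernel column, then input channel); column = oh + Ho*ow.
// A weight array dim (k, k, Cin, Cout) reshaped with matrix(w, k*k*Cin, Cout)
// lines up with these rows, so convolution is a single GEMM.

static inline int out_extent(int n, int k, int pad, int stride, int dilation) {
  int eff = dilation * (k - 1) + 1;
  return (n + 2 * pad - eff) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int k, int pad, int stride, int dilation) {
  int Ho = out_extent(H, k, pad, stride, dilation);
  int Wo = out_extent(W, k, pad, stride, dilation);
  if (Ho < 1 || Wo < 1)
    stop("feature map too small for this kernel/padding/dilation");
  NumericMatrix cols(k * k * C, Ho * Wo);
  const double *px = x.begin();
  double *pc = cols.begin();
  int nrow = k * k * C;
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      int col = oh + Ho * ow;
      double *dst = pc + (size_t)col * nrow;
      for (int c = 0; c < C; ++c) {
        const double *xc = px + (size_t)c * H * W;
        for (int dw = 0; dw < k; ++dw) {
          int w = ow * stride - pad + dw * dilation;
          bool win = (w >= 0 && w < W);
          for (int dh = 0; dh < k; ++dh) {
            int h = oh * stride - pad + dh * dilation;
            double v = 0.0;
            if (win && h >= 0 && h < H) v = xc[h + (size_t)H * w];
            dst[dh + k * dw + k * k * c] = v;
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add adjoint of cpp_im2col; returns an (H, W, C) array.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int k, int pad, int stride, int dilation) {
  int Ho = out_extent(H, k, pad, stride, dilation);
  int Wo = out_extent(W, k, pad, stride, dilation);
  if (cols.nrow() != k * k * C || cols.ncol() != Ho * Wo)
    stop("cols has the wrong shape for these extents");
  NumericVector x(H * W * C);
  double *px = x.begin();
  const double *pc = cols.begin();
  int nrow = k * k * C;
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      int col = oh + Ho * ow;
      const double *src = pc + (size_t)col * nrow;
      for (int c = 0; c < C; ++c) {
        double *xc = px + (size_t)c * H * W;
        for (int dw = 0; dw < k; ++dw) {
          int w = ow * stride - pad + dw * dilation;
          if (w < 0 || w >= W) continue;
          for (int dh = 0; dh < k; ++dh) {
            int h = oh * stride - pad + dh * dilation;
            if (h < 0 || h >= H) continue;
            xc[h + (size_t)H * w] += src[dh + k * dw + k * k * c];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// Max pooling with optional ceiling mode (windows clipped at the border),
// recording 0-based argmax indices into the input for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int H, int W, int C,
                 int k, int stride, bool ceil_mode) {
  int Ho, Wo;
  if (ceil_mode) {
    Ho = (H - k + stride - 1) / stride + 1;
    Wo = (W - k + stride - 1) / stride + 1;
    if ((Ho - 1) * stride >= H) --Ho;
    if ((Wo - 1) * stride >= W) --Wo;
  } else {
    Ho = (H - k) / stride + 1;
    Wo = (W - k) / stride + 1;
  }
  if (Ho < 1 || Wo < 1) stop("pooling kernel larger than feature extents");
  NumericVector y(Ho * Wo * C);
  IntegerVector arg(Ho * Wo * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = px + (size_t)c * H * W;
    for (int ow = 0; ow < Wo; ++ow) {
      int w0 = ow * stride, w1 = std::min(w0 + k, W);
      for (int oh = 0; oh < Ho; ++oh) {
        int h0 = oh * stride, h1 = std::min(h0 + k, H);
        double best = R_NegInf;
        int besti = -1;
        for (int w = w0; w < w1; ++w)
          for (int h = h0; h < h1; ++h) {
            double v = xc[h + (size_t)H * w];
            if (v > best) { best = v; besti = h + H * w + H * W * c; }
          }
        size_t o = oh + (size_t)Ho * ow + (size_t)Ho * Wo * c;
        y[o] = best;
        arg[o] = besti;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector argmax,
                                   int H, int W, int C) {
  NumericVector dx(H * W * C);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[argmax[i]] += dy[i];
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}
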
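#include <Rcpp.h>
using namespace Rcpp;

// Tensors are column-major R arrays with dim (N, C, H, W).
// Linear index of x[n, c, h, w] (0-based): n + N*(c + C*(h + H*w)).

// Unfold k x k patches (stride 1, zero padding `pad`) into a matrix with
// C*k*k rows and N*H*W columns; column j = n + N*(h + H*w), row
// r = c + C*(dy + k*dx). A convolution is then W_mat %*% out with
// W_mat = matrix(weights, Cout, C*k*k) for weights dim (Cout, C, k, k).
// [[Rcpp::export]]
NumericMatrix im2col_nchw(NumericVector x, int N, int C, int H, int W,
                          int k, int pad) {
  NumericMatrix out(C * k * k, N * H * W);
  double *po = out.begin();
  const double *px = x.begin();
  const int nrow = C * k * k;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      for (int n = 0; n < N; ++n) {
        const int col = n + N * (h + H * w);
        double *pcol = po + (R_xlen_t)col * nrow;
        for (int dx = 0; dx < k; ++dx) {
          const int ws = w + dx - pad;
          if (ws < 0 || ws >= W) continue;
          for (int dy = 0; dy < k; ++dy) {
            const int hs = h + dy - pad;
            if (hs < 0 || hs >= H) continue;
            const int rbase = C * (dy + k * dx);
            const double *pxs = px + (R_xlen_t)n + (R_xlen_t)N * (C * (hs + (R_xlen_t)H * ws));
            for (int c = 0; c < C; ++c)
              pcol[c + rbase] = pxs[(R_xlen_t)N * c];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_nchw: scatter-add patch-gradient columns back onto the
// (N, C, H, W) input gradient.
// [[Rcpp::export]]
NumericVector col2im_nchw(NumericMatrix cols, int N, int C, int H, int W,
                          int k, int pad) {
  NumericVector dx_(N * (R_xlen_t)C * H * W);
  double *pdx = dx_.begin();
  const double *pc = cols.begin();
  const int nrow = C * k * k;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      for (int n = 0; n < N; ++n) {
        const int col = n + N * (h + H * w);
        const double *pcol = pc + (R_xlen_t)col * nrow;
        for (int dx = 0; dx < k; ++dx) {
          const int ws = w + dx - pad;
          if (ws < 0 || ws >= W) continue;
          for (int dy = 0; dy < k; ++dy) {
            const int hs = h + dy - pad;
            if (hs < 0 || hs >= H) continue;
            const int rbase = C * (dy + k * dx);
            double *pxs = pdx + (R_xlen_t)n + (R_xlen_t)N * (C * (hs + (R_xlen_t)H * ws));
            for (int c = 0; c < C; ++c)
              pxs[(R_xlen_t)N * c] += pcol[c + rbase];
          }
        }
      }
    }
  }
  dx_.attr("dim") = IntegerVector::create(N, C, H, W);
  return dx_;
}

// Max pooling with kernel == stride == k, ceil mode (border windows are
// clipped). Returns the pooled map plus 1-based argmax linear indices into
// the input for the backward pass.
// [[Rcpp::export]]
List maxpool_nchw(NumericVector x, int N, int C, int H, int W, int k) {
  const int Ho = (H + k - 1) / k, Wo = (W + k - 1) / k;
  NumericVector out((R_xlen_t)N * C * Ho * Wo);
  IntegerVector arg((R_xlen_t)N * C * Ho * Wo);
  const double *px = x.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    const int w0 = wo * k, w1 = std::min(w0 + k, W);
    for (int ho = 0; ho < Ho; ++ho) {
      const int h0 = ho * k, h1 = std::min(h0 + k, H);
      for (int c = 0; c < C; ++c) {
        for (int n = 0; n < N; ++n) {
          double best = R_NegInf;
          R_xlen_t besti = 0;
          for (int w = w0; w < w1; ++w) {
            for (int h = h0; h < h1; ++h) {
              R_xlen_t idx = (R_xlen_t)n + (R_xlen_t)N * (c + (R_xlen_t)C * (h + (R_xlen_t)H * w));
              if (px[idx] > best) { best = px[idx]; besti = idx; }
            }
          }
          R_xlen_t o = (R_xlen_t)n + (R_xlen_t)N * (c + (R_xlen_t)C * (ho + (R_xlen_t)Ho * wo));
          out[o] = best;
          arg[o] = (int)(besti + 1);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// Backward of maxpool_nchw: route each output gradient to its argmax.
// [[Rcpp::export]]
NumericVector maxpool_bwd_nchw(NumericVector grad, IntegerVector argmax,
                               int N, int C, int H, int W) {
  NumericVector dx_((R_xlen_t)N * C * H * W);
  for (R_xlen_t i = 0; i < grad.size(); ++i)
    dx_[argmax[i] - 1] += grad[i];
  dx_.attr("dim") = IntegerVector::create(N, C, H, W);
  return dx_;
}
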
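#include <Rcpp.h>
using namespace Rcpp;

// Activations are stored as (h*w*b) x c matrices, pixel index running
// column-major within each image, images stacked along rows.

// Unfold k x k neighbourhoods (zero padding) into a (oh*ow*b) x (k*k*c)
// matrix so convolution becomes a single BLAS matmul.  Column order is
// (dx, dy) within kernel fastest, then input channel, matching the
// row order of the packed weight matrix.
// [[Rcpp::export]]
NumericMatrix nk_im2col(const NumericMatrix& x, int h, int w, int b,
                        int k, int pad, int stride) {
  const int c = x.ncol();
  const int oh = (h - k + 2 * pad) / stride + 1;
  const int ow = (w - k + 2 * pad) / stride + 1;
  const int opix = oh * ow;
  NumericMatrix out(opix * b, k * k * c);
  for (int ch = 0; ch < c; ++ch) {
    const double* xc = &x(0, ch);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* oc = &out(0, ch * k * k + kj * k + ki);
        for (int bi = 0; bi < b; ++bi) {
          const double* xb = xc + (R_xlen_t)bi * h * w;
          double* ob = oc + (R_xlen_t)bi * opix;
          for (int oj = 0; oj < ow; ++oj) {
            const int ij = oj * stride - pad + kj;
            double* ocol = ob + oj * oh;
            if (ij < 0 || ij >= w) {
              for (int oi = 0; oi < oh; ++oi) ocol[oi] = 0.0;
              continue;
            }
            const double* icol = xb + ij * h;
            for (int oi = 0; oi < oh; ++oi) {
              const int ii = oi * stride - pad + ki;
              ocol[oi] = (ii < 0 || ii >= h) ? 0.0 : icol[ii];
            }
          }
        }
      }
    }
  }
  return out;
}

// Max pooling over k x k windows with given stride and symmetric zero-ish
// padding (padded cells are -Inf so they never win).  Returns the pooled
// matrix and the flat row index of each winner for the backward pass.
// [[Rcpp::export]]
List nk_maxpool(const NumericMatrix& x, int h, int w, int b,
                int k, int pad, int stride) {
  const int c = x.ncol();
  const int oh = (h - k + 2 * pad) / stride + 1;
  const int ow = (w - k + 2 * pad) / stride + 1;
  const int opix = oh * ow;
  NumericMatrix out(opix * b, c);
  IntegerMatrix arg(opix * b, c);
  for (int ch = 0; ch < c; ++ch) {
    const double* xc = &x(0, ch);
    double* oc = &out(0, ch);
    int* ac = &arg(0, ch);
    for (int bi = 0; bi < b; ++bi) {
      const double* xb = xc + (R_xlen_t)bi * h * w;
      for (int oj = 0; oj < ow; ++oj) {
        for (int oi = 0; oi < oh; ++oi) {
          double best = R_NegInf;
          int besti = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int ij = oj * stride - pad + kj;
            if (ij < 0 || ij >= w) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int ii = oi * stride - pad + ki;
              if (ii < 0 || ii >= h) continue;
              const double v = xb[ij * h + ii];
              if (v > best) { best = v; besti = ij * h + ii; }
            }
          }
          const R_xlen_t orow = (R_xlen_t)bi * opix + oj * oh + oi;
          oc[orow] = best;
          // 1-based row index into the full (h*w*b) x c activation matrix
          ac[orow] = (int)((R_xlen_t)bi * h * w + besti + 1);
        }
      }
    }
  }
  return List::create(_["values"] = out, _["argmax"] = arg);
}

// Scatter pooled gradients back onto the winning input positions.
// [[Rcpp::export]]
NumericMatrix nk_maxpool_backward(const NumericMatrix& dy,
                                  const IntegerMatrix& arg,
                                  int in_rows) {
  const int c = dy.ncol();
  const int n = dy.nrow();
  NumericMatrix dx(in_rows, c);
  for (int ch = 0; ch < c; ++ch) {
    const double* dc = &dy(0, ch);
    const int* ac = &arg(0, ch);
    double* xc = &dx(0, ch);
    for (int i = 0; i < n; ++i) xc[ac[i] - 1] += dc[i];
  }
  return dx;
}
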
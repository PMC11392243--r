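// Convolution / pooling primitives for the package's network engine.
// Tensors are R arrays in (H, W, C) layout (column-major, so element
// (i, j, c) sits at i + H*j + H*W*c). Convolutions are implemented as
// im2col + GEMM so they ride on the BLAS R is linked against.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Build the im2col matrix: rows = output pixels (io + Ho*jo), cols = patch
// entries ordered (di, dj, ci) to match the (kh, kw, Cin, Cout) weight layout.
static arma::mat im2col(const arma::cube &x, int kh, int kw, int stride, int pad,
                        int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat M(Ho * (size_t)Wo, (size_t)kh * kw * C, arma::fill::zeros);
  const double *xp = x.memptr();
  double *mp = M.memptr();
  for (int ci = 0; ci < C; ++ci) {
    const double *xc = xp + (size_t)H * W * ci;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const size_t col = di + kh * (dj + (size_t)kw * ci);
        double *mcol = mp + col * (size_t)Ho * Wo;
        // valid output-row range for this kernel offset
        int io0 = 0, io1 = Ho - 1;
        while (io0 <= io1 && io0 * stride - pad + di < 0) ++io0;
        while (io1 >= io0 && io1 * stride - pad + di >= H) --io1;
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride - pad + dj;
          if (j < 0 || j >= W) continue;
          const double *src = xc + (size_t)H * j;
          double *dst = mcol + (size_t)Ho * jo;
          if (stride == 1) {
            const int i0 = io0 - pad + di;
            std::copy(src + i0, src + i0 + (io1 - io0 + 1), dst + io0);
          } else {
            for (int io = io0; io <= io1; ++io) {
              dst[io] = src[io * stride - pad + di];
            }
          }
        }
      }
    }
  }
  return M;
}

// Scatter-add the columns matrix back onto an image (adjoint of im2col).
static arma::cube col2im(const arma::mat &M, int H, int W, int C, int kh, int kw,
                         int stride, int pad, int Ho, int Wo) {
  arma::cube x(H, W, C, arma::fill::zeros);
  double *xp = x.memptr();
  const double *mp = M.memptr();
  for (int ci = 0; ci < C; ++ci) {
    double *xc = xp + (size_t)H * W * ci;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const size_t col = di + kh * (dj + (size_t)kw * ci);
        const double *mcol = mp + col * (size_t)Ho * Wo;
        int io0 = 0, io1 = Ho - 1;
        while (io0 <= io1 && io0 * stride - pad + di < 0) ++io0;
        while (io1 >= io0 && io1 * stride - pad + di >= H) --io1;
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride - pad + dj;
          if (j < 0 || j >= W) continue;
          double *dst = xc + (size_t)H * j;
          const double *src = mcol + (size_t)Ho * jo;
          for (int io = io0; io <= io1; ++io) {
            dst[io * stride - pad + di] += src[io];
          }
        }
      }
    }
  }
  return x;
}

static arma::cube as_cube(const NumericVector &a) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array (H, W, C)");
  arma::cube x(a.begin(), d[0], d[1], d[2]);  // copies
  return x;
}

static NumericVector cube_to_r(const arma::cube &x) {
  NumericVector out(x.begin(), x.end());
  out.attr("dim") = IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd(NumericVector x_, NumericVector w_, NumericVector b_,
                          int stride, int pad) {
  arma::cube x = as_cube(x_);
  IntegerVector wd = w_.attr("dim");
  if (wd.size() != 4) stop("weights must be a 4-d array (kh, kw, Cin, Cout)");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if ((int)x.n_slices != Cin) stop("input channel mismatch");
  const int Ho = out_size(x.n_rows, kh, stride, pad);
  const int Wo = out_size(x.n_cols, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");
  arma::mat M = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat Wm(w_.begin(), (size_t)kh * kw * Cin, Cout);  // copies
  arma::mat Y = M * Wm;
  arma::rowvec b(b_.begin(), Cout);
  Y.each_row() += b;
  arma::cube y(Y.memptr(), Ho, Wo, Cout);
  return cube_to_r(y);
}

// [[Rcpp::export]]
List nn_conv_bwd(NumericVector x_, NumericVector w_, NumericVector dy_,
                 int stride, int pad) {
  arma::cube x = as_cube(x_);
  arma::cube dy = as_cube(dy_);
  IntegerVector wd = w_.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  arma::mat M = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat dY(dy.memptr(), (size_t)Ho * Wo, Cout);
  arma::mat Wm(w_.begin(), (size_t)kh * kw * Cin, Cout);
  arma::mat dW = M.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dM = dY * Wm.t();
  arma::cube dx = col2im(dM, x.n_rows, x.n_cols, Cin, kh, kw, stride, pad, Ho, Wo);
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  return List::create(_["dx"] = cube_to_r(dx), _["dw"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Max pooling; returns pooled values and the linear (0-based) argmax index
// into the input array, so the backward pass is a scatter.
// [[Rcpp::export]]
List nn_maxpool_fwd(NumericVector x_, int kh, int kw, int sh, int sw) {
  arma::cube x = as_cube(x_);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H - kh) / sh + 1, Wo = (W - kw) / sw + 1;
  if (Ho < 1 || Wo < 1) stop("pooling output would be empty");
  arma::cube y(Ho, Wo, C);
  IntegerVector idx(Ho * (size_t)Wo * C);
  size_t p = 0;
  for (int c = 0; c < C; ++c)
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io) {
        double best = -std::numeric_limits<double>::infinity();
        size_t bidx = 0;
        for (int dj = 0; dj < kw; ++dj)
          for (int di = 0; di < kh; ++di) {
            const int i = io * sh + di, j = jo * sw + dj;
            const double v = x(i, j, c);
            if (v > best) { best = v; bidx = i + (size_t)H * j + (size_t)H * W * c; }
          }
        y(io, jo, c) = best;
        idx[p++] = (int)bidx;
      }
  // match y's column-major order when filling idx: iterate io fastest per (jo, c)
  // (loop order above is c, jo, io => matches (Ho, Wo, C) column-major)
  return List::create(_["y"] = cube_to_r(y), _["idx"] = idx);
}

// Adaptive max pooling onto a fixed (oh, ow) grid (torch-style bin edges).
// [[Rcpp::export]]
List nn_adaptive_maxpool_fwd(NumericVector x_, int oh, int ow) {
  arma::cube x = as_cube(x_);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H < oh || W < ow) stop("input smaller than adaptive pooling grid");
  arma::cube y(oh, ow, C);
  IntegerVector idx(oh * (size_t)ow * C);
  size_t p = 0;
  for (int c = 0; c < C; ++c)
    for (int jo = 0; jo < ow; ++jo)
      for (int io = 0; io < oh; ++io) {
        const int i0 = (io * H) / oh, i1 = ((io + 1) * H + oh - 1) / oh;
        const int j0 = (jo * W) / ow, j1 = ((jo + 1) * W + ow - 1) / ow;
        double best = -std::numeric_limits<double>::infinity();
        size_t bidx = 0;
        for (int j = j0; j < j1; ++j)
          for (int i = i0; i < i1; ++i) {
            const double v = x(i, j, c);
            if (v > best) { best = v; bidx = i + (size_t)H * j + (size_t)H * W * c; }
          }
        y(io, jo, c) = best;
        idx[p++] = (int)bidx;
      }
  return List::create(_["y"] = cube_to_r(y), _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bwd(NumericVector dy_, IntegerVector idx, IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2]);
  for (R_xlen_t k = 0; k < dy_.size(); ++k) dx[idx[k]] += dy_[k];
  dx.attr("dim") = xdim;
  return dx;
}

// [[Rcpp::export]]
NumericVector nn_relu_cpp(NumericVector x) {
  NumericVector y = clone(x);
  for (R_xlen_t i = 0; i < y.size(); ++i) {
    if (y[i] < 0) y[i] = 0;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_relu_bwd_cpp(NumericVector dy, NumericVector y) {
  NumericVector dx = clone(dy);
  for (R_xlen_t i = 0; i < dx.size(); ++i) {
    if (y[i] <= 0) dx[i] = 0;
  }
  return dx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector nn_upsample2_fwd(NumericVector x_) {
  arma::cube x = as_cube(x_);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v; y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v; y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return cube_to_r(y);
}

// [[Rcpp::export]]
NumericVector nn_upsample2_bwd(NumericVector dy_) {
  arma::cube dy = as_cube(dy_);
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  arma::cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return cube_to_r(dx);
}
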
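// Dense optical flow by pyramidal polynomial expansion (Farneback-style).
// Each frame is locally modelled as f(x) ~ x'Ax + b'x + c under a Gaussian
// applicability; the displacement field follows from the change in the
// linear coefficient between the two frames, accumulated over an averaging
// window and refined iteratively over an image pyramid.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct PolyExp {
  // per-pixel polynomial coefficients: f ~ c + bx*x + by*y + axx*x^2 +
  // ayy*y^2 + axy*x*y  (x = column offset, y = row offset)
  arma::mat bx, by, axx, ayy, axy;
};

// Separable correlation helpers with replicated borders.
// Row pass runs along columns (x direction), col pass along rows (y).
arma::mat corr_x(const arma::mat &f, const arma::vec &k, int n) {
  const int H = f.n_rows, W = f.n_cols;
  arma::mat out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) out(i, j) = 0.0;
  }
  for (int j = 0; j < W; ++j)
    for (int d = -n; d <= n; ++d) {
      int js = std::min(std::max(j + d, 0), W - 1);
      out.col(j) += k(d + n) * f.col(js);
    }
  return out;
}

arma::mat corr_y(const arma::mat &f, const arma::vec &k, int n) {
  const int H = f.n_rows, W = f.n_cols;
  arma::mat out(H, W, arma::fill::zeros);
  for (int d = -n; d <= n; ++d) {
    int lo = std::max(0, -d), hi = std::min(H, H - d);
    // rows i take source row i + d (clamped)
    for (int i = 0; i < H; ++i) {
      int is = std::min(std::max(i + d, 0), H - 1);
      out.row(i) += k(d + n) * f.row(is);
    }
    (void)lo; (void)hi;
  }
  return out;
}

PolyExp poly_expand(const arma::mat &f, int n, double sigma) {
  const int W = 2 * n + 1;
  arma::vec g(W), xg(W), xxg(W);
  for (int d = -n; d <= n; ++d) {
    g(d + n) = std::exp(-0.5 * d * d / (sigma * sigma));
  }
  g /= arma::accu(g);
  for (int d = -n; d <= n; ++d) {
    xg(d + n) = d * g(d + n);
    xxg(d + n) = d * d * g(d + n);
  }

  // dual metric G over basis (1, x, y, x^2, y^2, xy)
  arma::mat G(6, 6, arma::fill::zeros);
  for (int dy = -n; dy <= n; ++dy)
    for (int dx = -n; dx <= n; ++dx) {
      double a = g(dx + n) * g(dy + n);
      arma::vec b = {1.0, (double)dx, (double)dy, (double)dx * dx,
                     (double)dy * dy, (double)dx * dy};
      G += a * b * b.t();
    }
  arma::mat Ginv = arma::inv_sympd(G);

  // separable projections of a*b_i against f
  arma::mat t0 = corr_x(f, g, n), t1 = corr_x(f, xg, n), t2 = corr_x(f, xxg, n);
  arma::mat v1 = corr_y(t0, g, n);
  arma::mat vx = corr_y(t1, g, n);
  arma::mat vy = corr_y(t0, xg, n);
  arma::mat vxx = corr_y(t2, g, n);
  arma::mat vyy = corr_y(t0, xxg, n);
  arma::mat vxy = corr_y(t1, xg, n);

  // coefficient planes as linear combinations of the projection planes
  const arma::mat *V[6] = {&v1, &vx, &vy, &vxx, &vyy, &vxy};
  auto combine = [&](int row) {
    arma::mat out(f.n_rows, f.n_cols, arma::fill::zeros);
    for (int jj = 0; jj < 6; ++jj) {
      const double w = Ginv(row, jj);
      if (std::abs(w) > 1e-14) out += w * (*V[jj]);
    }
    return out;
  };
  PolyExp P;
  P.bx = combine(1);
  P.by = combine(2);
  P.axx = combine(3);
  P.ayy = combine(4);
  P.axy = combine(5);
  return P;
}

// normalized box filter via running sums, in place
void box_filter(arma::mat &f, int win) {
  const int n = win / 2;
  const int H = f.n_rows, W = f.n_cols;
  arma::mat tmp(H, W);
  // horizontal
  for (int i = 0; i < H; ++i) {
    double s = 0.0;
    for (int d = -n; d <= n; ++d) s += f(i, std::min(std::max(d, 0), W - 1));
    for (int j = 0; j < W; ++j) {
      tmp(i, j) = s / win;
      int jout = std::min(std::max(j - n, 0), W - 1);
      int jin = std::min(std::max(j + n + 1, 0), W - 1);
      s += f(i, jin) - f(i, jout);
    }
  }
  // vertical
  for (int j = 0; j < W; ++j) {
    double s = 0.0;
    for (int d = -n; d <= n; ++d) s += tmp(std::min(std::max(d, 0), H - 1), j);
    for (int i = 0; i < H; ++i) {
      f(i, j) = s / win;
      int iout = std::min(std::max(i - n, 0), H - 1);
      int iin = std::min(std::max(i + n + 1, 0), H - 1);
      s += tmp(iin, j) - tmp(iout, j);
    }
  }
}

// one displacement-refinement sweep at a single scale; `sig` is the
// box-averaged joint signal energy: where it is exactly zero (both frames
// black over the whole window) there is no motion evidence and the flow is
// pinned to zero instead of extrapolating from distant structure
void update_flow(const PolyExp &P1, const PolyExp &P2, const arma::mat &sig,
                 arma::mat &u, arma::mat &v, int win) {
  const int H = P1.bx.n_rows, W = P1.bx.n_cols;
  arma::mat m11(H, W), m12(H, W), m22(H, W), h1(H, W), h2(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double du = u(i, j), dv = v(i, j);
      int j2 = (int)std::lround(j + du), i2 = (int)std::lround(i + dv);
      j2 = std::min(std::max(j2, 0), W - 1);
      i2 = std::min(std::max(i2, 0), H - 1);
      const double A11 = 0.5 * (P1.axx(i, j) + P2.axx(i2, j2));
      const double A22 = 0.5 * (P1.ayy(i, j) + P2.ayy(i2, j2));
      const double A12 = 0.25 * (P1.axy(i, j) + P2.axy(i2, j2));
      const double dbx = -0.5 * (P2.bx(i2, j2) - P1.bx(i, j)) + A11 * du + A12 * dv;
      const double dby = -0.5 * (P2.by(i2, j2) - P1.by(i, j)) + A12 * du + A22 * dv;
      m11(i, j) = A11 * A11 + A12 * A12;
      m12(i, j) = A12 * (A11 + A22);
      m22(i, j) = A22 * A22 + A12 * A12;
      h1(i, j) = A11 * dbx + A12 * dby;
      h2(i, j) = A12 * dbx + A22 * dby;
    }
  box_filter(m11, win); box_filter(m12, win); box_filter(m22, win);
  box_filter(h1, win); box_filter(h2, win);
  const double eps = 1e-9;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (sig(i, j) <= 1e-12) { u(i, j) = 0.0; v(i, j) = 0.0; continue; }
      const double a = m11(i, j) + eps, b = m12(i, j), c = m22(i, j) + eps;
      const double det = a * c - b * b;
      u(i, j) = (c * h1(i, j) - b * h2(i, j)) / det;
      v(i, j) = (a * h2(i, j) - b * h1(i, j)) / det;
    }
}

// 5-tap Gaussian blur + decimate by 2
arma::mat pyr_down(const arma::mat &f) {
  static const double k[5] = {1.0 / 16, 4.0 / 16, 6.0 / 16, 4.0 / 16, 1.0 / 16};
  const int H = f.n_rows, W = f.n_cols;
  arma::mat t(H, W, arma::fill::zeros), b(H, W, arma::fill::zeros);
  for (int j = 0; j < W; ++j)
    for (int d = -2; d <= 2; ++d)
      t.col(j) += k[d + 2] * f.col(std::min(std::max(j + d, 0), W - 1));
  for (int i = 0; i < H; ++i)
    for (int d = -2; d <= 2; ++d)
      b.row(i) += k[d + 2] * t.row(std::min(std::max(i + d, 0), H - 1));
  const int H2 = (H + 1) / 2, W2 = (W + 1) / 2;
  arma::mat out(H2, W2);
  for (int j = 0; j < W2; ++j)
    for (int i = 0; i < H2; ++i) out(i, j) = b(std::min(2 * i, H - 1), std::min(2 * j, W - 1));
  return out;
}

// upscale a flow field to (H, W), doubling its magnitude
arma::mat flow_up(const arma::mat &f, int H, int W) {
  arma::mat out(H, W);
  const int h = f.n_rows, w = f.n_cols;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = 2.0 * f(std::min(i / 2, h - 1), std::min(j / 2, w - 1));
  return out;
}

std::vector<arma::mat> build_pyramid(const arma::mat &f, int levels) {
  std::vector<arma::mat> pyr;
  pyr.push_back(f);
  for (int l = 1; l < levels; ++l) {
    const arma::mat &prev = pyr.back();
    if ((int)prev.n_rows < 16 || (int)prev.n_cols < 16) break;
    pyr.push_back(pyr_down(prev));
  }
  return pyr;
}

}  // namespace

// Flow for every consecutive pair of a (H, W, T) frame stack. Returns a
// (H, W, 2, T-1) array: slice (, , 1, t) = u (horizontal, +right),
// (, , 2, t) = v (vertical, +down). Polynomial expansions are computed once
// per frame per pyramid level and shared between the two pairs using them.
// [[Rcpp::export]]
NumericVector flow_stack_cpp(NumericVector frames, int levels, int winsize,
                             int iters, int poly_n, double poly_sigma) {
  IntegerVector d = frames.attr("dim");
  if (d.size() != 3) stop("frames must be a (H, W, T) array");
  const int H = d[0], W = d[1], T = d[2];
  if (T < 2) stop("need at least two frames");
  if (winsize < 3 || winsize % 2 == 0) stop("winsize must be odd and >= 3");

  NumericVector out((size_t)H * W * 2 * (T - 1));
  out.attr("dim") = IntegerVector::create(H, W, 2, T - 1);

  auto frame_at = [&](int t) {
    arma::mat f(H, W);
    std::copy(frames.begin() + (size_t)H * W * t,
              frames.begin() + (size_t)H * W * (t + 1), f.memptr());
    return f;
  };

  // expansions for the current frame, reused as "previous" next iteration
  std::vector<arma::mat> pyr_prev = build_pyramid(frame_at(0), levels);
  std::vector<PolyExp> exp_prev;
  for (auto &p : pyr_prev) exp_prev.push_back(poly_expand(p, poly_n, poly_sigma));

  for (int t = 1; t < T; ++t) {
    std::vector<arma::mat> pyr_cur = build_pyramid(frame_at(t), levels);
    std::vector<PolyExp> exp_cur;
    for (auto &p : pyr_cur) exp_cur.push_back(poly_expand(p, poly_n, poly_sigma));

    const int L = std::min(pyr_prev.size(), pyr_cur.size());
    arma::mat u, v;
    for (int l = L - 1; l >= 0; --l) {
      const int h = pyr_prev[l].n_rows, w = pyr_prev[l].n_cols;
      if (l == L - 1) {
        u.zeros(h, w); v.zeros(h, w);
      } else {
        u = flow_up(u, h, w);
        v = flow_up(v, h, w);
      }
      arma::mat sig = arma::abs(pyr_prev[l]) + arma::abs(pyr_cur[l]);
      box_filter(sig, winsize);
      for (int it = 0; it < iters; ++it)
        update_flow(exp_prev[l], exp_cur[l], sig, u, v, winsize);
    }
    std::copy(u.begin(), u.end(), out.begin() + (size_t)H * W * 2 * (t - 1));
    std::copy(v.begin(), v.end(), out.begin() + (size_t)H * W * 2 * (t - 1) + (size_t)H * W);
    pyr_prev.swap(pyr_cur);
    exp_prev.swap(exp_cur);
  }
  return out;
}
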
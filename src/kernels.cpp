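// Numeric kernels for the registration network and DVF algebra.
//
// Tensor layout everywhere: column-major R arrays dim (H, W, C, N);
// flows are (H, W, 2, N) with channel 1 = row displacement, 2 = column
// displacement, in pixels, backward-map convention.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword idx4(int i, int j, int c, int n,
                               int H, int W, int C) {
  return (arma::uword)i + (arma::uword)H * ((arma::uword)j +
         (arma::uword)W * ((arma::uword)c + (arma::uword)C * (arma::uword)n));
}

// im2col for a 3x3 kernel, zero padding 1, stride 1.
// Output: (H*W) x (9*Cin); column index k = ki + 3*(kj + 3*ci), offsets
// ki, kj in {0,1,2} meaning source pixel (i + ki - 1, j + kj - 1).
static void im2col3(const double* x, int H, int W, int Cin, int n,
                    arma::mat& col) {
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        int k = ki + 3 * (kj + 3 * ci);
        double* dst = col.colptr(k);
        for (int j = 0; j < W; ++j) {
          int sj = j + kj - 1;
          for (int i = 0; i < H; ++i) {
            int si = i + ki - 1;
            double v = 0.0;
            if (si >= 0 && si < H && sj >= 0 && sj < W)
              v = x[idx4(si, sj, ci, n, H, W, Cin)];
            dst[i + H * j] = v;
          }
        }
      }
    }
  }
}

// Scatter-add of a (H*W) x (9*Cin) gradient back onto the padded input.
static void col2im3(const arma::mat& gcol, int H, int W, int Cin, int n,
                    double* gx) {
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        int k = ki + 3 * (kj + 3 * ci);
        const double* src = gcol.colptr(k);
        for (int j = 0; j < W; ++j) {
          int sj = j + kj - 1;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            int si = i + ki - 1;
            if (si < 0 || si >= H) continue;
            gx[idx4(si, sj, ci, n, H, W, Cin)] += src[i + H * j];
          }
        }
      }
    }
  }
}

// Forward conv with optional im2col cache (reused by the backward pass).
// [[Rcpp::export]]
List cpp_conv3_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                   bool want_col) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], Cin = d[2], N = d[3];
  int Cout = w.ncol();
  if (w.nrow() != 9 * Cin) stop("conv3: weight rows != 9*Cin");
  arma::mat wm(w.begin(), w.nrow(), Cout, false);
  NumericVector out((R_xlen_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  NumericVector colstore;
  if (want_col) {
    colstore = NumericVector((R_xlen_t)H * W * 9 * Cin * N);
    colstore.attr("dim") = IntegerVector::create(H * W, 9 * Cin, N);
  }
  arma::mat col(H * W, 9 * Cin);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin(), H, W, Cin, n, col);
    if (want_col)
      std::copy(col.begin(), col.end(),
                colstore.begin() + (R_xlen_t)H * W * 9 * Cin * n);
    arma::mat o = col * wm;
    o.each_row() += arma::rowvec(b.begin(), Cout, false);
    std::copy(o.begin(), o.end(), out.begin() + (R_xlen_t)H * W * Cout * n);
  }
  if (want_col) return List::create(_["out"] = out, _["col"] = colstore);
  return List::create(_["out"] = out);
}

// Backward pass from a cached im2col matrix.
// [[Rcpp::export]]
List cpp_conv3_bwd(NumericVector colstore, NumericMatrix w,
                   NumericVector gout, int H, int W, int Cin) {
  IntegerVector d = gout.attr("dim");
  int Cout = d[2], N = d[3];
  arma::mat wm(w.begin(), w.nrow(), Cout, false);
  NumericVector gx((R_xlen_t)H * W * Cin * N);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericMatrix gw(9 * Cin, Cout);
  arma::mat gwm(gw.begin(), 9 * Cin, Cout, false);
  NumericVector gb(Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat col(colstore.begin() + (R_xlen_t)H * W * 9 * Cin * n,
                  H * W, 9 * Cin, false);
    arma::mat gm(gout.begin() + (R_xlen_t)H * W * Cout * n, H * W, Cout,
                 false);
    gwm += col.t() * gm;
    arma::rowvec gbs = arma::sum(gm, 0);
    for (int c = 0; c < Cout; ++c) gb[c] += gbs[c];
    arma::mat gcol = gm * wm.t();
    col2im3(gcol, H, W, Cin, n, gx.begin());
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_conv3(NumericVector x, NumericMatrix w, NumericVector b) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], Cin = d[2], N = d[3];
  int Cout = w.ncol();
  if (w.nrow() != 9 * Cin) stop("conv3: weight rows != 9*Cin");
  arma::mat wm(w.begin(), w.nrow(), Cout, false);
  NumericVector out(H * W * Cout * (R_xlen_t)N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat col(H * W, 9 * Cin);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin(), H, W, Cin, n, col);
    arma::mat o = col * wm;          // (HW x Cout)
    o.each_row() += arma::rowvec(b.begin(), Cout, false);
    std::copy(o.begin(), o.end(), out.begin() + (R_xlen_t)H * W * Cout * n);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_backward(NumericVector x, NumericMatrix w, NumericVector gout) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], Cin = d[2], N = d[3];
  int Cout = w.ncol();
  arma::mat wm(w.begin(), w.nrow(), Cout, false);
  NumericVector gx(x.size());
  gx.attr("dim") = d;
  NumericMatrix gw(9 * Cin, Cout);
  arma::mat gwm(gw.begin(), 9 * Cin, Cout, false);
  NumericVector gb(Cout);
  arma::mat col(H * W, 9 * Cin);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin(), H, W, Cin, n, col);
    arma::mat gm(gout.begin() + (R_xlen_t)H * W * Cout * n, H * W, Cout, false);
    gwm += col.t() * gm;
    arma::rowvec gbs = arma::sum(gm, 0);
    for (int c = 0; c < Cout; ++c) gb[c] += gbs[c];
    arma::mat gcol = gm * wm.t();    // (HW x 9Cin)
    col2im3(gcol, H, W, Cin, n, gx.begin());
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max-pool, stride 2; also returns the argmax offset (0..3, in-block
// column-major: offset = di + 2*dj) needed for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int h = H / 2, w = W / 2;
  NumericVector out(h * (R_xlen_t)w * C * N);
  IntegerVector amax(out.size());
  out.attr("dim") = IntegerVector::create(h, w, C, N);
  amax.attr("dim") = IntegerVector::create(h, w, C, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < w; ++j)
        for (int i = 0; i < h; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          int barg = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              double v = xp[idx4(2 * i + di, 2 * j + dj, c, n, H, W, C)];
              if (v > best) { best = v; barg = di + 2 * dj; }
            }
          arma::uword o = idx4(i, j, c, n, h, w, C);
          out[o] = best;
          amax[o] = barg;
        }
  return List::create(_["out"] = out, _["amax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector gout, IntegerVector amax,
                                    int H, int W) {
  IntegerVector d = gout.attr("dim");
  int h = d[0], w = d[1], C = d[2], N = d[3];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < w; ++j)
        for (int i = 0; i < h; ++i) {
          arma::uword o = idx4(i, j, c, n, h, w, C);
          int di = amax[o] % 2, dj = amax[o] / 2;
          gx[idx4(2 * i + di, 2 * j + dj, c, n, H, W, C)] += gout[o];
        }
  return gx;
}

// Backward bilinear warp: out(i,j,c) = img(i + u1(i,j), j + u2(i,j), c),
// constant fill outside the domain (out-of-domain corner weight goes to
// fill). One flow per sample, shared across channels.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector img, NumericVector flow, double fill) {
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector out(img.size());
  out.attr("dim") = d;
  const double* ip = img.begin();
  const double* fp = flow.begin();
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double r = i + fp[idx4(i, j, 0, n, H, W, 2)];
        double cc = j + fp[idx4(i, j, 1, n, H, W, 2)];
        int r0 = (int)std::floor(r), c0 = (int)std::floor(cc);
        double fr = r - r0, fc = cc - c0;
        double w00 = (1 - fr) * (1 - fc), w10 = fr * (1 - fc);
        double w01 = (1 - fr) * fc, w11 = fr * fc;
        bool in00 = r0 >= 0 && r0 < H && c0 >= 0 && c0 < W;
        bool in10 = r0 + 1 >= 0 && r0 + 1 < H && c0 >= 0 && c0 < W;
        bool in01 = r0 >= 0 && r0 < H && c0 + 1 >= 0 && c0 + 1 < W;
        bool in11 = r0 + 1 >= 0 && r0 + 1 < H && c0 + 1 >= 0 && c0 + 1 < W;
        for (int c = 0; c < C; ++c) {
          double v = 0.0;
          v += w00 * (in00 ? ip[idx4(r0, c0, c, n, H, W, C)] : fill);
          v += w10 * (in10 ? ip[idx4(r0 + 1, c0, c, n, H, W, C)] : fill);
          v += w01 * (in01 ? ip[idx4(r0, c0 + 1, c, n, H, W, C)] : fill);
          v += w11 * (in11 ? ip[idx4(r0 + 1, c0 + 1, c, n, H, W, C)] : fill);
          out[idx4(i, j, c, n, H, W, C)] = v;
        }
      }
  return out;
}

// Gradient of cpp_warp with respect to the image argument only.
// [[Rcpp::export]]
NumericVector cpp_warp_backward_img(NumericVector gout, NumericVector flow) {
  IntegerVector d = gout.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector gimg(gout.size());
  gimg.attr("dim") = d;
  const double* gp = gout.begin();
  const double* fp = flow.begin();
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double r = i + fp[idx4(i, j, 0, n, H, W, 2)];
        double cc = j + fp[idx4(i, j, 1, n, H, W, 2)];
        int r0 = (int)std::floor(r), c0 = (int)std::floor(cc);
        double fr = r - r0, fc = cc - c0;
        double w00 = (1 - fr) * (1 - fc), w10 = fr * (1 - fc);
        double w01 = (1 - fr) * fc, w11 = fr * fc;
        for (int c = 0; c < C; ++c) {
          double g = gp[idx4(i, j, c, n, H, W, C)];
          if (g == 0.0) continue;
          if (r0 >= 0 && r0 < H && c0 >= 0 && c0 < W)
            gimg[idx4(r0, c0, c, n, H, W, C)] += w00 * g;
          if (r0 + 1 >= 0 && r0 + 1 < H && c0 >= 0 && c0 < W)
            gimg[idx4(r0 + 1, c0, c, n, H, W, C)] += w10 * g;
          if (r0 >= 0 && r0 < H && c0 + 1 >= 0 && c0 + 1 < W)
            gimg[idx4(r0, c0 + 1, c, n, H, W, C)] += w01 * g;
          if (r0 + 1 >= 0 && r0 + 1 < H && c0 + 1 >= 0 && c0 + 1 < W)
            gimg[idx4(r0 + 1, c0 + 1, c, n, H, W, C)] += w11 * g;
        }
      }
  return gimg;
}
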
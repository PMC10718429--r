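// Low-level tensor ops for the segmentation networks.
// Layout convention everywhere: feature tensors are R arrays with
// dim = c(H, W, C, B) (column-major); conv weights are c(k, k, Cin, Cout).
// Convolutions are cross-correlations (CNN convention), stride 1,
// zero "same" padding; the depthwise sharpening op uses edge replication.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static Rcpp::NumericVector arr4(int a, int b, int c, int d) {
  Rcpp::NumericVector v(Rcpp::no_init((R_xlen_t)a * b * c * d));
  std::fill(v.begin(), v.end(), 0.0);
  v.attr("dim") = Rcpp::IntegerVector::create(a, b, c, d);
  return v;
}

static Rcpp::IntegerVector iarr4(int a, int b, int c, int d) {
  Rcpp::IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = Rcpp::IntegerVector::create(a, b, c, d);
  return v;
}

// col(H*W, k*k*C): row = output pixel (oi + oj*H), col = tap (i + j*k + c*k*k)
static void im2col_zero(const double* x, int H, int W, int C, int k, int pad,
                        mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        double* dst = col.colptr(i + k * j + k * k * c);
        for (int oj = 0; oj < W; ++oj) {
          int sj = oj + j - pad;
          double* d = dst + (size_t)oj * H;
          if (sj < 0 || sj >= W) {
            std::fill(d, d + H, 0.0);
            continue;
          }
          const double* xcol = xc + (size_t)sj * H;
          for (int oi = 0; oi < H; ++oi) {
            int si = oi + i - pad;
            d[oi] = (si < 0 || si >= H) ? 0.0 : xcol[si];
          }
        }
      }
    }
  }
}

// adjoint of im2col_zero: scatter-add dcol back onto dx
static void col2im_zero(const mat& dcol, int H, int W, int C, int k, int pad,
                        double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const double* src = dcol.colptr(i + k * j + k * k * c);
        for (int oj = 0; oj < W; ++oj) {
          int sj = oj + j - pad;
          if (sj < 0 || sj >= W) continue;
          double* xcol = xc + (size_t)sj * H;
          const double* s = src + (size_t)oj * H;
          for (int oi = 0; oi < H; ++oi) {
            int si = oi + i - pad;
            if (si >= 0 && si < H) xcol[si] += s[oi];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_conv_fwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                                Rcpp::NumericVector b) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin)
    Rcpp::stop("weight dims inconsistent with input");
  int pad = (k - 1) / 2;
  mat Wm(w.begin(), k * k * Cin, Cout, false);
  Rcpp::NumericVector y = arr4(H, W, Cout, B);
  mat col(H * W, k * k * Cin);
  for (int bi = 0; bi < B; ++bi) {
    im2col_zero(x.begin() + (size_t)bi * H * W * Cin, H, W, Cin, k, pad, col);
    mat Y(y.begin() + (size_t)bi * H * W * Cout, H * W, Cout, false, true);
    Y = col * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List nn_conv_bwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                       Rcpp::NumericVector dy) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  int k = wd[0], Cout = wd[3];
  int pad = (k - 1) / 2;
  mat Wm(w.begin(), k * k * Cin, Cout, false);
  Rcpp::NumericVector dx = arr4(H, W, Cin, B);
  Rcpp::NumericVector dw = arr4(k, k, Cin, Cout);
  Rcpp::NumericVector db(Cout);
  mat dWm(dw.begin(), k * k * Cin, Cout, false, true);
  mat col(H * W, k * k * Cin);
  for (int bi = 0; bi < B; ++bi) {
    im2col_zero(x.begin() + (size_t)bi * H * W * Cin, H, W, Cin, k, pad, col);
    mat dY(const_cast<double*>(dy.begin()) + (size_t)bi * H * W * Cout,
           H * W, Cout, false);
    dWm += col.t() * dY;
    for (int co = 0; co < Cout; ++co) db[co] += accu(dY.col(co));
    mat dcol = dY * Wm.t();
    col2im_zero(dcol, H, W, Cin, k, pad,
                dx.begin() + (size_t)bi * H * W * Cin);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// 2x2 max-pooling with stride 2; idx stores the winning offset 0..3
// (di + 2*dj) for the backward scatter. H and W must be even.
// [[Rcpp::export]]
Rcpp::List nn_maxpool_fwd(Rcpp::NumericVector x) {
  Rcpp::IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  if (H % 2 || W % 2) Rcpp::stop("maxpool needs even spatial dims");
  int Ho = H / 2, Wo = W / 2;
  Rcpp::NumericVector y = arr4(Ho, Wo, C, B);
  Rcpp::IntegerVector idx = iarr4(Ho, Wo, C, B);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int bc = 0; bc < B * C; ++bc) {
    const double* xs = xp + (size_t)bc * H * W;
    double* ys = yp + (size_t)bc * Ho * Wo;
    int* is = ip + (size_t)bc * Ho * Wo;
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        int best = 0;
        double bv = xs[2 * oi + (size_t)(2 * oj) * H];
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double v = xs[2 * oi + di + (size_t)(2 * oj + dj) * H];
            if (v > bv) { bv = v; best = di + 2 * dj; }
          }
        ys[oi + (size_t)oj * Ho] = bv;
        is[oi + (size_t)oj * Ho] = best;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_maxpool_bwd(Rcpp::IntegerVector idx,
                                   Rcpp::NumericVector dy) {
  Rcpp::IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], B = yd[3];
  int H = 2 * Ho, W = 2 * Wo;
  Rcpp::NumericVector dx = arr4(H, W, C, B);
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  for (int bc = 0; bc < B * C; ++bc) {
    const double* ds = dyp + (size_t)bc * Ho * Wo;
    const int* is = ip + (size_t)bc * Ho * Wo;
    double* xs = dxp + (size_t)bc * H * W;
    for (int oj = 0; oj < Wo; ++oj)
      for (int oi = 0; oi < Ho; ++oi) {
        int q = is[oi + (size_t)oj * Ho];
        xs[2 * oi + (q & 1) + (size_t)(2 * oj + (q >> 1)) * H] +=
            ds[oi + (size_t)oj * Ho];
      }
  }
  return dx;
}

// 2x2, stride-2 transposed convolution (learned upsampling); output windows
// do not overlap, so each output pixel receives exactly one contribution.
// [[Rcpp::export]]
Rcpp::NumericVector nn_tconv_fwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                                 Rcpp::NumericVector b) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  int Cout = wd[3];
  if (wd[0] != 2 || wd[1] != 2 || wd[2] != Cin)
    Rcpp::stop("tconv weight must be (2,2,Cin,Cout)");
  int Ho = 2 * H, Wo = 2 * W;
  Rcpp::NumericVector y = arr4(Ho, Wo, Cout, B);
  const double* wp = w.begin();
  for (int bi = 0; bi < B; ++bi) {
    mat X(const_cast<double*>(x.begin()) + (size_t)bi * H * W * Cin,
          H * W, Cin, false);
    double* yb = y.begin() + (size_t)bi * Ho * Wo * Cout;
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        mat Wab(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wab(ci, co) = wp[di + 2 * dj + 4 * ci + (size_t)4 * Cin * co];
        mat Yab = X * Wab;  // (H*W, Cout)
        for (int co = 0; co < Cout; ++co) {
          double* yc = yb + (size_t)co * Ho * Wo;
          const double* s = Yab.colptr(co);
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              yc[2 * i + di + (size_t)(2 * j + dj) * Ho] =
                  s[i + (size_t)j * H] + b[co];
        }
      }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List nn_tconv_bwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                        Rcpp::NumericVector dy) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  int Cout = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  Rcpp::NumericVector dx = arr4(H, W, Cin, B);
  Rcpp::NumericVector dw = arr4(2, 2, Cin, Cout);
  Rcpp::NumericVector db(Cout);
  const double* wp = w.begin();
  double* dwp = dw.begin();
  for (int bi = 0; bi < B; ++bi) {
    mat X(const_cast<double*>(x.begin()) + (size_t)bi * H * W * Cin,
          H * W, Cin, false);
    mat dX(dx.begin() + (size_t)bi * H * W * Cin, H * W, Cin, false, true);
    const double* dyb = dy.begin() + (size_t)bi * Ho * Wo * Cout;
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        mat dYab(H * W, Cout);
        for (int co = 0; co < Cout; ++co) {
          const double* dyc = dyb + (size_t)co * Ho * Wo;
          double* d = dYab.colptr(co);
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              d[i + (size_t)j * H] =
                  dyc[2 * i + di + (size_t)(2 * j + dj) * Ho];
        }
        mat Wab(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wab(ci, co) = wp[di + 2 * dj + 4 * ci + (size_t)4 * Cin * co];
        dX += dYab * Wab.t();
        mat dWab = X.t() * dYab;
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            dwp[di + 2 * dj + 4 * ci + (size_t)4 * Cin * co] += dWab(ci, co);
      }
    // bias gradient: every output pixel carries the bias once
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = dyb + (size_t)co * Ho * Wo;
      double s = 0.0;
      for (size_t t = 0; t < (size_t)Ho * Wo; ++t) s += dyc[t];
      db[co] += s;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// Depthwise 3x3 cross-correlation with a fixed kernel and edge-replicate
// padding (constant maps are fixed points of a DC-preserving kernel).
// [[Rcpp::export]]
Rcpp::NumericVector nn_sharpen_fwd(Rcpp::NumericVector x,
                                   Rcpp::NumericMatrix k3) {
  Rcpp::IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  Rcpp::NumericVector y = arr4(H, W, C, B);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int bc = 0; bc < B * C; ++bc) {
    const double* xs = xp + (size_t)bc * H * W;
    double* ys = yp + (size_t)bc * H * W;
    for (int oj = 0; oj < W; ++oj)
      for (int oi = 0; oi < H; ++oi) {
        double s = 0.0;
        for (int dj = -1; dj <= 1; ++dj) {
          int sj = clampi(oj + dj, 0, W - 1);
          for (int di = -1; di <= 1; ++di) {
            int si = clampi(oi + di, 0, H - 1);
            s += k3(di + 1, dj + 1) * xs[si + (size_t)sj * H];
          }
        }
        ys[oi + (size_t)oj * H] = s;
      }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_sharpen_bwd(Rcpp::NumericVector dy,
                                   Rcpp::NumericMatrix k3) {
  Rcpp::IntegerVector xd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  Rcpp::NumericVector dx = arr4(H, W, C, B);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int bc = 0; bc < B * C; ++bc) {
    const double* ds = dyp + (size_t)bc * H * W;
    double* xs = dxp + (size_t)bc * H * W;
    for (int oj = 0; oj < W; ++oj)
      for (int oi = 0; oi < H; ++oi) {
        double g = ds[oi + (size_t)oj * H];
        for (int dj = -1; dj <= 1; ++dj) {
          int sj = clampi(oj + dj, 0, W - 1);
          for (int di = -1; di <= 1; ++di) {
            int si = clampi(oi + di, 0, H - 1);
            xs[si + (size_t)sj * H] += k3(di + 1, dj + 1) * g;
          }
        }
      }
  }
  return dx;
}
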
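// Minimal CPU kernels for the small convolutional networks used by the
// slice classifier and the encoder-decoder segmenter.  Layout conventions:
//   feature maps: arma::cube (H, W, C), matching R arrays dim(H, W, C)
//   conv weights: arma::mat (C_out, C_in * 9), patch feature order
//                 f = c_in * 9 + (di + 1) * 3 + (dj + 1), di/dj in {-1,0,1}
// All 3x3 convolutions use stride 1 and zero ("same") padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col3(const cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col(C * 9, H * W, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int di = -1; di <= 1; ++di) {
      for (int dj = -1; dj <= 1; ++dj) {
        const uword f = c * 9 + (di + 1) * 3 + (dj + 1);
        for (uword j = 0; j < W; ++j) {
          const int js = (int)j + dj;
          if (js < 0 || js >= (int)W) continue;
          for (uword i = 0; i < H; ++i) {
            const int is = (int)i + di;
            if (is < 0 || is >= (int)H) continue;
            col(f, j * H + i) = xs(is, js);
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
arma::cube conv3x3_fwd(const arma::cube& x, const arma::mat& w,
                       const arma::vec& b) {
  const uword H = x.n_rows, W = x.n_cols;
  const uword Cout = w.n_rows;
  mat col = im2col3(x);
  mat out = w * col;           // (Cout, H*W)
  out.each_col() += b;
  cube y(H, W, Cout);
  for (uword c = 0; c < Cout; ++c)
    y.slice(c) = reshape(out.row(c), H, W);
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv3x3_bwd(const arma::cube& x, const arma::mat& w,
                       const arma::cube& dout) {
  const uword H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const uword Cout = w.n_rows;
  mat col = im2col3(x);
  mat dom(Cout, H * W);
  for (uword c = 0; c < Cout; ++c)
    dom.row(c) = vectorise(dout.slice(c)).t();
  mat dw = dom * col.t();
  vec db = sum(dom, 1);
  mat dcol = w.t() * dom;      // (Cin*9, H*W)
  cube dx(H, W, Cin, fill::zeros);
  for (uword c = 0; c < Cin; ++c) {
    mat& dxs = dx.slice(c);
    for (int di = -1; di <= 1; ++di) {
      for (int dj = -1; dj <= 1; ++dj) {
        const uword f = c * 9 + (di + 1) * 3 + (dj + 1);
        for (uword j = 0; j < W; ++j) {
          const int js = (int)j + dj;
          if (js < 0 || js >= (int)W) continue;
          for (uword i = 0; i < H; ++i) {
            const int is = (int)i + di;
            if (is < 0 || is >= (int)H) continue;
            dxs(is, js) += dcol(f, j * H + i);
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2.  H and W must be even (checked in R).
// [[Rcpp::export]]
Rcpp::List maxpool2_fwd(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  cube arg(Ho, Wo, C);         // 0..3: within-block index (2*dj + di)
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < Wo; ++j) {
      for (uword i = 0; i < Ho; ++i) {
        double best = -datum::inf; uword bk = 0;
        for (uword dj = 0; dj < 2; ++dj)
          for (uword di = 0; di < 2; ++di) {
            double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bk = 2 * dj + di; }
          }
        y(i, j, c) = best;
        arg(i, j, c) = (double)bk;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = y,
                            Rcpp::Named("arg") = arg);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::cube& dout, const arma::cube& arg,
                        int H, int W) {
  const uword Ho = dout.n_rows, Wo = dout.n_cols, C = dout.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < Wo; ++j)
      for (uword i = 0; i < Ho; ++i) {
        const uword k = (uword)arg(i, j, c);
        dx(2 * i + (k % 2), 2 * j + (k / 2), c) += dout(i, j, c);
      }
  return dx;
}

// Nearest-neighbour 2x upsampling and its adjoint.
// [[Rcpp::export]]
arma::cube upsample2_fwd(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube upsample2_bwd(const arma::cube& dout) {
  const uword H = dout.n_rows / 2, W = dout.n_cols / 2, C = dout.n_slices;
  cube dx(H, W, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i)
        dx(i, j, c) = dout(2 * i, 2 * j, c) + dout(2 * i + 1, 2 * j, c) +
                      dout(2 * i, 2 * j + 1, c) + dout(2 * i + 1, 2 * j + 1, c);
  return dx;
}
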
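// Dense kernels for the encoder-decoder reconstruction network.
//
// Feature maps are arma::cube (H, W, C), received from R as 3D arrays.
// Convolution weights: mat (k*k*Cin, Cout), row index r = a + b*k + c*k*k
// for kernel offset (a, b) (rows/cols, 0-based) and input channel c.
// Transposed-convolution (2x2, stride 2) weights: mat (Cin, 4*Cout) with
// column index co*4 + a + 2*b addressing output sub-pixel (a, b).
// All convolutions use same-size zero padding.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int half = k / 2;
  arma::mat cols(k * k * C, (size_t)H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const int r = a + b * k + c * k * k;
        const int di = a - half, dj = b - half;
        // source window in x overlapping output pixel (i, j) -> x(i+di, j+dj)
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          const double* src = xs.colptr(j + dj) + (i0 + di);
          double* dst = cols.colptr((size_t)j * H + i0) + r;
          for (int i = i0; i < i1; ++i) {
            *dst = *src;
            ++src;
            dst += cols.n_rows;
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_add(arma::cube& x, const arma::mat& cols, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int half = k / 2;
  for (int c = 0; c < C; ++c) {
    arma::mat& xs = x.slice(c);
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const int r = a + b * k + c * k * k;
        const int di = a - half, dj = b - half;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          double* dst = xs.colptr(j + dj) + (i0 + di);
          const double* src = cols.colptr((size_t)j * H + i0) + r;
          for (int i = i0; i < i1; ++i) {
            *dst += *src;
            ++dst;
            src += cols.n_rows;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv_fwd_cpp(const arma::cube& x, const arma::mat& w,
                        const arma::vec& bias, int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  arma::mat cols = im2col(x, k);
  arma::mat y = w.t() * cols;           // Cout x (H*W)
  y.each_col() += bias;
  arma::cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = arma::reshape(y.row(c), H, W);
  return out;
}

// [[Rcpp::export]]
List conv_bwd_cpp(const arma::cube& x, const arma::mat& w,
                  const arma::cube& dy, int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  arma::mat dymat(Cout, (size_t)H * W);
  for (int c = 0; c < Cout; ++c)
    dymat.row(c) = arma::vectorise(dy.slice(c)).t();
  arma::mat cols = im2col(x, k);
  arma::mat dw = cols * dymat.t();      // (k*k*Cin) x Cout
  arma::vec db = arma::sum(dymat, 1);
  arma::mat dcols = w * dymat;          // (k*k*Cin) x (H*W)
  arma::cube dx(H, W, Cin, arma::fill::zeros);
  col2im_add(dx, dcols, k);
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("max-pooling requires even spatial dimensions");
  arma::cube y(H / 2, W / 2, C);
  arma::ucube idx(H / 2, W / 2, C);   // linear index into each input slice
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    for (int j = 0; j < W / 2; ++j) {
      for (int i = 0; i < H / 2; ++i) {
        double best = xs(2 * i, 2 * j);
        arma::uword bi = 2 * i + (size_t)(2 * j) * H;
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            double v = xs(2 * i + a, 2 * j + b);
            if (v > best) { best = v; bi = (2 * i + a) + (size_t)(2 * j + b) * H; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool_bwd_cpp(const arma::cube& dy, const arma::ucube& idx,
                           int H, int W) {
  const int C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& dxs = dx.slice(c);
    for (size_t q = 0; q < dy.n_rows * dy.n_cols; ++q)
      dxs(idx.slice(c)(q)) += dy.slice(c)(q);
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube upconv_fwd_cpp(const arma::cube& x, const arma::mat& w,
                          const arma::vec& bias) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_cols / 4;
  arma::mat xm((size_t)H * W, Cin);
  for (int c = 0; c < Cin; ++c)
    xm.col(c) = arma::vectorise(x.slice(c));
  arma::mat y4 = xm * w;                // (H*W) x (4*Cout)
  arma::cube out(2 * H, 2 * W, Cout);
  for (int co = 0; co < Cout; ++co) {
    arma::mat& os = out.slice(co);
    for (int b = 0; b < 2; ++b)
      for (int a = 0; a < 2; ++a) {
        arma::mat blk = arma::reshape(y4.col(co * 4 + a + 2 * b), H, W);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            os(2 * i + a, 2 * j + b) = blk(i, j) + bias[co];
      }
  }
  return out;
}

// [[Rcpp::export]]
List upconv_bwd_cpp(const arma::cube& x, const arma::mat& w,
                    const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  arma::mat dy4((size_t)H * W, 4 * Cout);
  arma::vec db(Cout, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co) {
    const arma::mat& ds = dy.slice(co);
    db[co] = arma::accu(ds);
    for (int b = 0; b < 2; ++b)
      for (int a = 0; a < 2; ++a) {
        arma::mat blk(H, W);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            blk(i, j) = ds(2 * i + a, 2 * j + b);
        dy4.col(co * 4 + a + 2 * b) = arma::vectorise(blk);
      }
  }
  arma::mat xm((size_t)H * W, Cin);
  for (int c = 0; c < Cin; ++c)
    xm.col(c) = arma::vectorise(x.slice(c));
  arma::mat dw = xm.t() * dy4;          // Cin x (4*Cout)
  arma::mat dxm = dy4 * w.t();          // (H*W) x Cin
  arma::cube dx(H, W, Cin);
  for (int c = 0; c < Cin; ++c)
    dx.slice(c) = arma::reshape(dxm.col(c), H, W);
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}
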
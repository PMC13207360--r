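#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Column layout throughout: one column per map, linear index h + H*w + H*W*c
// (column-major spatial, channels last). im2col rows: c*9 + (kj+1)*3 + (ki+1)
// (channels outermost, then kernel column, then kernel row). Loops are ordered
// so that writes to the large patch matrix are sequential while reads hit the
// small per-map block held in cache.

// Per-map im2col into a reused cache-resident buffer.
static void im2col_map(const double* xcol, int H, int W, int C, arma::mat& P) {
  const arma::uword R = P.n_rows;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      double* out = P.memptr() + R * (h + (arma::uword)H * w);
      for (int c = 0; c < C; ++c) {
        const double* xc = xcol + (arma::uword)H * W * c;
        for (int kj = -1; kj <= 1; ++kj) {
          const int ws = w + kj;
          const bool wok = ws >= 0 && ws < W;
          const double* xw = xc + (arma::uword)H * ws;
          for (int ki = -1; ki <= 1; ++ki) {
            const int hs = h + ki;
            *out++ = (wok && hs >= 0 && hs < H) ? xw[hs] : 0.0;
          }
        }
      }
    }
  }
}

// 3x3 same-padding convolution, batched over maps: X (H*W*C) x N,
// Wm [F x 9C], b length F; output (H*W*F) x N in map layout.
// [[Rcpp::export]]
arma::mat cpp_conv3_fwd(const arma::mat& X, const arma::mat& Wm,
                        const arma::vec& b, int H, int W, int C) {
  const int N = X.n_cols, F = Wm.n_rows, HW = H * W;
  arma::mat out((arma::uword)HW * F, N);
  arma::mat P(9 * C, HW);
  arma::mat Yt(F, HW);
  for (int n = 0; n < N; ++n) {
    im2col_map(X.colptr(n), H, W, C, P);
    Yt = Wm * P;
    Yt.each_col() += b;
    arma::mat ymap(out.colptr(n), HW, F, false, true);
    ymap = Yt.t();
  }
  return out;
}

// Backward pass: recomputes the per-map patch buffer. dOut (H*W*F) x N.
// Returns dX, dW, db.
// [[Rcpp::export]]
List cpp_conv3_bwd(const arma::mat& X, const arma::mat& dOut,
                   const arma::mat& Wm, int H, int W, int C) {
  const int N = X.n_cols, F = Wm.n_rows, HW = H * W;
  arma::mat dX(X.n_rows, N, arma::fill::zeros);
  arma::mat dW(F, 9 * C, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  arma::mat P(9 * C, HW);
  arma::mat dYt(F, HW);
  arma::mat dP(9 * C, HW);
  const arma::uword R = 9 * C;
  for (int n = 0; n < N; ++n) {
    im2col_map(X.colptr(n), H, W, C, P);
    const arma::mat dymap(const_cast<double*>(dOut.colptr(n)), HW, F, false, true);
    dYt = dymap.t();
    dW += dYt * P.t();
    db += arma::sum(dYt, 1);
    dP = Wm.t() * dYt;
    // col2im scatter-add into this map
    double* xcol = dX.colptr(n);
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double* in = dP.memptr() + R * (h + (arma::uword)H * w);
        for (int c = 0; c < C; ++c) {
          double* xc = xcol + (arma::uword)H * W * c;
          for (int kj = -1; kj <= 1; ++kj) {
            const int ws = w + kj;
            const bool wok = ws >= 0 && ws < W;
            double* xw = xc + (arma::uword)H * ws;
            for (int ki = -1; ki <= 1; ++ki) {
              const int hs = h + ki;
              if (wok && hs >= 0 && hs < H) xw[hs] += *in;
              ++in;
            }
          }
        }
      }
    }
  }
  return List::create(Named("dX") = dX, Named("dW") = dW, Named("db") = db);
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based argmax linear
// indices into the input column (for the backward pass).
// [[Rcpp::export]]
List cpp_maxpool2(const arma::mat& X, int H, int W, int C) {
  const int N = X.n_cols, Ho = H / 2, Wo = W / 2;
  arma::mat Y((arma::uword)Ho * Wo * C, N);
  arma::umat idx((arma::uword)Ho * Wo * C, N);
  for (int n = 0; n < N; ++n) {
    const double* xcol = X.colptr(n);
    double* ycol = Y.colptr(n);
    arma::uword* icol = idx.colptr(n);
    for (int c = 0; c < C; ++c) {
      const arma::uword coff = (arma::uword)H * W * c;
      const arma::uword ooff = (arma::uword)Ho * Wo * c;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = 2 * ho, w0 = 2 * wo;
          arma::uword best = coff + h0 + (arma::uword)H * w0;
          double bv = xcol[best];
          const arma::uword cand[3] = {
            coff + h0 + 1 + (arma::uword)H * w0,
            coff + h0 + (arma::uword)H * (w0 + 1),
            coff + h0 + 1 + (arma::uword)H * (w0 + 1)};
          for (int k = 0; k < 3; ++k) {
            if (xcol[cand[k]] > bv) { bv = xcol[cand[k]]; best = cand[k]; }
          }
          ycol[ooff + ho + (arma::uword)Ho * wo] = bv;
          icol[ooff + ho + (arma::uword)Ho * wo] = best + 1;
        }
      }
    }
  }
  return List::create(Named("out") = Y, Named("idx") = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool2_bwd(const arma::mat& dY, const arma::umat& idx,
                           int in_len) {
  const int N = dY.n_cols;
  arma::mat dX(in_len, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    double* xcol = dX.colptr(n);
    const double* dcol = dY.colptr(n);
    const arma::uword* icol = idx.colptr(n);
    for (arma::uword i = 0; i < dY.n_rows; ++i) {
      xcol[icol[i] - 1] += dcol[i];
    }
  }
  return dX;
}

// Rearrange conv output [F, HW*N] (filters x positions) into map layout
// [HW*F, N] and back, avoiding R-level aperm copies.
// [[Rcpp::export]]
arma::mat cpp_filters_to_maps(const arma::mat& Y, int HW, int N) {
  const int F = Y.n_rows;
  arma::mat out((arma::uword)HW * F, N);
  for (int n = 0; n < N; ++n) {
    double* ocol = out.colptr(n);
    const double* ycol = Y.colptr((arma::uword)HW * n);
    for (int p = 0; p < HW; ++p) {
      const double* yp = ycol + (arma::uword)F * p;
      for (int f = 0; f < F; ++f) ocol[p + (arma::uword)HW * f] = yp[f];
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_maps_to_filters(const arma::mat& X, int HW, int N) {
  const int F = X.n_rows / HW;
  arma::mat out(F, (arma::uword)HW * N);
  for (int n = 0; n < N; ++n) {
    const double* xcol = X.colptr(n);
    double* ycol = out.colptr((arma::uword)HW * n);
    for (int p = 0; p < HW; ++p) {
      double* yp = ycol + (arma::uword)F * p;
      for (int f = 0; f < F; ++f) yp[f] = xcol[p + (arma::uword)HW * f];
    }
  }
  return out;
}
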
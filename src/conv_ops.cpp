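#include <Rcpp.h>
using namespace Rcpp;

// Layout conventions (column-major, 0-based in C++):
//   image batch x: dim (H, W, C, N), linear index y + H*(x + W*(c + C*n))
//   im2col matrix: (k*k*C) rows x (H*W*N) cols, same padding, stride 1;
//     row r = ky + k*(kx + k*c), col j = y + H*x + H*W*n
// The filter matrix multiplied against these columns in R is
// (Cout x k*k*C), so conv output comes back as (Cout x H*W*N).

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, IntegerVector dims, int k) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int pad = (k - 1) / 2;
  NumericMatrix out(k * k * C, H * W * N);
  const double *px = REAL(x);
  double *po = REAL(out);
  const int nrow = k * k * C;
  for (int n = 0; n < N; ++n) {
    for (int xx = 0; xx < W; ++xx) {
      for (int yy = 0; yy < H; ++yy) {
        const R_xlen_t col = (R_xlen_t)yy + (R_xlen_t)H * xx + (R_xlen_t)H * W * n;
        double *pcol = po + col * nrow;
        for (int c = 0; c < C; ++c) {
          const R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
          for (int kx = 0; kx < k; ++kx) {
            const int sx = xx + kx - pad;
            for (int ky = 0; ky < k; ++ky) {
              const int sy = yy + ky - pad;
              const int r = ky + k * (kx + k * c);
              if (sx >= 0 && sx < W && sy >= 0 && sy < H)
                pcol[r] = px[base + sy + (R_xlen_t)H * sx];
              else
                pcol[r] = 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add column gradients back to image positions.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, IntegerVector dims, int k) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int pad = (k - 1) / 2;
  NumericVector out((R_xlen_t)H * W * C * N);
  double *po = REAL(out);
  const double *pc = REAL(cols);
  const int nrow = k * k * C;
  for (int n = 0; n < N; ++n) {
    for (int xx = 0; xx < W; ++xx) {
      for (int yy = 0; yy < H; ++yy) {
        const R_xlen_t col = (R_xlen_t)yy + (R_xlen_t)H * xx + (R_xlen_t)H * W * n;
        const double *pcol = pc + col * nrow;
        for (int c = 0; c < C; ++c) {
          const R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
          for (int kx = 0; kx < k; ++kx) {
            const int sx = xx + kx - pad;
            if (sx < 0 || sx >= W) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int sy = yy + ky - pad;
              if (sy < 0 || sy >= H) continue;
              po[base + sy + (R_xlen_t)H * sx] += pcol[ky + k * (kx + k * c)];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// 2x2 max pooling, stride 2; H and W must be even.  Returns the pooled
// array and the 1-based linear index of each winning input element (first
// maximum wins on ties) for the backward pass.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const double *px = REAL(x);
  double *po = REAL(out);
  int *pi = INTEGER(idx);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int xo = 0; xo < Wo; ++xo) {
        for (int yo = 0; yo < Ho; ++yo) {
          double best = R_NegInf;
          R_xlen_t besti = -1;
          for (int dx = 0; dx < 2; ++dx) {
            for (int dy = 0; dy < 2; ++dy) {
              const R_xlen_t ii = base + (2 * yo + dy) + (R_xlen_t)H * (2 * xo + dx);
              if (px[ii] > best) { best = px[ii]; besti = ii; }
            }
          }
          po[o] = best;
          pi[o] = (int)(besti + 1);
          ++o;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dout, IntegerVector idx,
                              IntegerVector in_dims) {
  const R_xlen_t n_in = (R_xlen_t)in_dims[0] * in_dims[1] * in_dims[2] * in_dims[3];
  NumericVector dx(n_in);
  double *pd = REAL(dx);
  const double *po = REAL(dout);
  const int *pi = INTEGER(idx);
  const R_xlen_t n_out = dout.size();
  for (R_xlen_t i = 0; i < n_out; ++i) pd[pi[i] - 1] += po[i];
  dx.attr("dim") = in_dims;
  return dx;
}
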
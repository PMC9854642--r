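#include <RcppArmadillo.h>
using namespace Rcpp;

// Patch layout shared with the R side: within a column, dy varies fastest,
// then dx, then channel, matching matrix(w, k*k*C, Cout) for w[k, k, C, Cout].
// Output rows enumerate (oy, ox) with oy fastest, matching array(v, c(Ho, Wo)).

// [[Rcpp::export]]
arma::mat im2col_cpp(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat out(Ho * Wo, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dx = 0; dx < k; ++dx)
      for (int dy = 0; dy < k; ++dy) {
        const int col = dy + dx * k + c * k * k;
        for (int ox = 0; ox < Wo; ++ox) {
          const int sx = ox * stride + dx - pad;
          if (sx < 0 || sx >= W) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            const int sy = oy * stride + dy - pad;
            if (sy < 0 || sy >= H) continue;
            out(oy + ox * Ho, col) = x(sy, sx, c);
          }
        }
      }
  return out;
}

// Adjoint of im2col: scatter-add column gradients back onto the input grid.
// [[Rcpp::export]]
arma::cube col2im_cpp(const arma::mat& cols, int H, int W, int C,
                      int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dx = 0; dx < k; ++dx)
      for (int dy = 0; dy < k; ++dy) {
        const int col = dy + dx * k + c * k * k;
        for (int ox = 0; ox < Wo; ++ox) {
          const int sx = ox * stride + dx - pad;
          if (sx < 0 || sx >= W) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            const int sy = oy * stride + dy - pad;
            if (sy < 0 || sy >= H) continue;
            out(sy, sx, c) += cols(oy + ox * Ho, col);
          }
        }
      }
  return out;
}

// Non-overlapping 2x2 max pooling; H and W must be even. Returns the pooled
// cube and the 0-based linear index of each winning cell for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube out(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);
  int p = 0;
  for (int c = 0; c < C; ++c)
    for (int ox = 0; ox < Wo; ++ox)
      for (int oy = 0; oy < Ho; ++oy) {
        double best = -1e300;
        int besti = 0;
        for (int dx = 0; dx < 2; ++dx)
          for (int dy = 0; dy < 2; ++dy) {
            const int sy = 2 * oy + dy, sx = 2 * ox + dx;
            const double v = x(sy, sx, c);
            if (v > best) { best = v; besti = sy + sx * H + c * H * W; }
          }
        out(oy, ox, c) = best;
        idx[p++] = besti;
      }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd_cpp(const arma::cube& g, const IntegerVector& idx,
                            int H, int W) {
  const int Ho = g.n_rows, Wo = g.n_cols, C = g.n_slices;
  arma::cube out(H, W, C, arma::fill::zeros);
  int p = 0;
  double* mem = out.memptr();
  for (int c = 0; c < C; ++c)
    for (int ox = 0; ox < Wo; ++ox)
      for (int oy = 0; oy < Ho; ++oy)
        mem[idx[p++]] += g(oy, ox, c);
  return out;
}
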
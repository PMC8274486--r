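// Compute kernels for the surrogate networks: spline-kernel graph
// convolution (forward/backward) and zero-padded strided 2-D convolution
// via im2col (forward/backward). Dense algebra through Armadillo (BLAS).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Spline convolution forward.
// F: V x in node features; src,tgt: 0-based directed edge endpoints (E);
// bidx: E x nb 0-based tensor-product basis indices; bw: E x nb weights;
// invdeg: V in-neighbor count reciprocal (0 for isolated nodes);
// W: (in*out) x K matrix, column p holding kernel matrix W_p (in x out,
// column-major); root: in x out; bias: out.
// out_i = invdeg_i * sum_{e: tgt=i} sum_m bw_em * F[src_e,] W_{bidx_em}
//         + F[i,] root + bias
// [[Rcpp::export]]
arma::mat spline_conv_fwd(const arma::mat& F, const arma::ivec& src,
                          const arma::ivec& tgt, const arma::imat& bidx,
                          const arma::mat& bw, const arma::vec& invdeg,
                          const arma::mat& W, const arma::mat& root,
                          const arma::vec& bias) {
  const int in = F.n_cols, out = root.n_cols;
  const int E = src.n_elem, nb = bidx.n_cols;
  const arma::mat Ft = F.t();                 // in x V, contiguous per node
  arma::mat Ot(out, F.n_rows, arma::fill::zeros);
  for (int e = 0; e < E; ++e) {
    const int s = src[e], t = tgt[e];
    const double id = invdeg[t];
    if (id == 0.0) continue;
    const double* fs = Ft.colptr(s);
    double* ot = Ot.colptr(t);
    for (int m = 0; m < nb; ++m) {
      const double w = bw(e, m) * id;
      if (w == 0.0) continue;
      const double* Wp = W.colptr(bidx(e, m));
      for (int o = 0; o < out; ++o) {
        double acc = 0.0;
        const double* col = Wp + (size_t)o * in;
        for (int i = 0; i < in; ++i) acc += fs[i] * col[i];
        ot[o] += w * acc;
      }
    }
  }
  arma::mat O = Ot.t() + F * root;
  O.each_row() += bias.t();
  return O;
}

// Spline convolution backward: returns gradients wrt F, W, root, bias.
// G: V x out upstream gradient.
// [[Rcpp::export]]
List spline_conv_bwd(const arma::mat& F, const arma::ivec& src,
                     const arma::ivec& tgt, const arma::imat& bidx,
                     const arma::mat& bw, const arma::vec& invdeg,
                     const arma::mat& W, const arma::mat& root,
                     const arma::mat& G) {
  const int in = F.n_cols, out = root.n_cols;
  const int E = src.n_elem, nb = bidx.n_cols;
  const arma::mat Ft = F.t();                 // in x V
  const arma::mat Gt = G.t();                 // out x V
  arma::mat gFt(in, F.n_rows, arma::fill::zeros);
  arma::mat groot = F.t() * G;
  arma::vec gbias = arma::sum(G, 0).t();
  arma::mat gW(W.n_rows, W.n_cols, arma::fill::zeros);
  for (int e = 0; e < E; ++e) {
    const int s = src[e], t = tgt[e];
    const double id = invdeg[t];
    if (id == 0.0) continue;
    const double* fs = Ft.colptr(s);
    const double* gt = Gt.colptr(t);
    double* gfs = gFt.colptr(s);
    for (int m = 0; m < nb; ++m) {
      const double w = bw(e, m) * id;
      if (w == 0.0) continue;
      const int p = bidx(e, m);
      const double* Wp = W.colptr(p);
      double* gWp = gW.colptr(p);
      for (int o = 0; o < out; ++o) {
        const double g = w * gt[o];
        if (g == 0.0) continue;
        const double* col = Wp + (size_t)o * in;
        double* gcol = gWp + (size_t)o * in;
        for (int i = 0; i < in; ++i) {
          gcol[i] += g * fs[i];
          gfs[i] += g * col[i];
        }
      }
    }
  }
  arma::mat gF = gFt.t() + G * root.t();
  return List::create(_["gF"] = gF, _["gW"] = gW, _["groot"] = groot,
                      _["gbias"] = gbias);
}

static arma::mat im2col(const arma::cube& X, int kh, int kw, int stride,
                        int pad, int Ho, int Wo) {
  const int H = X.n_rows, Wd = X.n_cols, C = X.n_slices;
  arma::mat col(Ho * Wo, kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const int cc = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride + kj - pad;
          if (j < 0 || j >= Wd) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            col(oi + Ho * oj, cc) = X(i, j, c);
          }
        }
      }
  return col;
}

// 2-D convolution forward. X: H x W x Cin cube; K: (kh*kw*Cin) x Cout
// matrix with rows ordered ki fastest, then kj, then channel; bias: Cout.
// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& X, const arma::mat& K,
                      const arma::vec& bias, int kh, int kw, int stride,
                      int pad) {
  const int H = X.n_rows, Wd = X.n_cols;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (Wd + 2 * pad - kw) / stride + 1;
  const int Cout = K.n_cols;
  arma::mat col = im2col(X, kh, kw, stride, pad, Ho, Wo);
  arma::mat out = col * K;
  out.each_row() += bias.t();
  arma::cube O(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    O.slice(c) = arma::reshape(out.col(c), Ho, Wo);
  return O;
}

// 2-D convolution backward. G: Ho x Wo x Cout upstream gradient.
// Returns gX, gK, gbias.
// [[Rcpp::export]]
List conv2d_bwd(const arma::cube& X, const arma::mat& K, const arma::cube& G,
                int kh, int kw, int stride, int pad) {
  const int H = X.n_rows, Wd = X.n_cols, Cin = X.n_slices;
  const int Ho = G.n_rows, Wo = G.n_cols, Cout = G.n_slices;
  arma::mat Gm(Ho * Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    Gm.col(c) = arma::vectorise(G.slice(c));
  arma::mat col = im2col(X, kh, kw, stride, pad, Ho, Wo);
  arma::mat gK = col.t() * Gm;
  arma::vec gbias = arma::sum(Gm, 0).t();
  arma::mat gcol = Gm * K.t();
  arma::cube gX(H, Wd, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const int cc = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride + kj - pad;
          if (j < 0 || j >= Wd) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            gX(i, j, c) += gcol(oi + Ho * oj, cc);
          }
        }
      }
  return List::create(_["gX"] = gX, _["gK"] = gK, _["gbias"] = gbias);
}
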
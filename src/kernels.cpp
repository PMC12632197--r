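// Hot numerical kernels for the neural-network engine. Logic mirrors the
// R reference implementations in R/nn-ops.R; control flow and caching stay
// in R. All matrices are column-major doubles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// X * W with a broadcast row bias
// [[Rcpp::export]]
arma::mat cpp_linear(const arma::mat& X, const arma::mat& W,
                     const arma::rowvec& b) {
  arma::mat out = X * W;
  out.each_row() += b;
  return out;
}

// [[Rcpp::export]]
List cpp_layernorm_fw(const arma::mat& X, const arma::vec& gamma,
                      const arma::vec& beta, double eps) {
  arma::vec mu = arma::mean(X, 1);
  arma::mat xc = X.each_col() - mu;
  arma::vec v = arma::mean(arma::square(xc), 1);
  arma::vec inv = 1.0 / arma::sqrt(v + eps);
  arma::mat xhat = xc.each_col() % inv;
  arma::mat out = xhat.each_row() % gamma.t();
  out.each_row() += beta.t();
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export]]
List cpp_layernorm_bw(const arma::mat& dY, const arma::mat& xhat,
                      const arma::vec& inv, const arma::vec& gamma) {
  arma::vec dgamma = arma::sum(dY % xhat, 0).t();
  arma::vec dbeta = arma::sum(dY, 0).t();
  arma::mat dxhat = dY.each_row() % gamma.t();
  arma::vec m1 = arma::mean(dxhat, 1);
  arma::vec m2 = arma::mean(dxhat % xhat, 1);
  arma::mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= inv;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

static inline double norm_cdf(double x) {
  return 0.5 * std::erfc(-x * M_SQRT1_2);
}
static inline double norm_pdf(double x) {
  return 0.3989422804014327 * std::exp(-0.5 * x * x);
}

// [[Rcpp::export]]
arma::mat cpp_gelu_fw(const arma::mat& X) {
  arma::mat out(X.n_rows, X.n_cols);
  const double* xi = X.memptr();
  double* oi = out.memptr();
  for (arma::uword i = 0; i < X.n_elem; ++i) oi[i] = xi[i] * norm_cdf(xi[i]);
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_gelu_bw(const arma::mat& dY, const arma::mat& X) {
  arma::mat out(X.n_rows, X.n_cols);
  const double* xi = X.memptr();
  const double* di = dY.memptr();
  double* oi = out.memptr();
  for (arma::uword i = 0; i < X.n_elem; ++i) {
    oi[i] = di[i] * (norm_cdf(xi[i]) + xi[i] * norm_pdf(xi[i]));
  }
  return out;
}

// multi-head attention, one query token per sample.
// Q: (B x d); K, V: ((B*nk) x d); kperm/vperm: 0-based permutations of
// 0..nk-1. Returns Ctx (B x d) and per-head attention A ((nk*B) x H).
// [[Rcpp::export]]
List cpp_mha_vec1_fw(const arma::mat& Q, const arma::mat& K,
                     const arma::mat& V, int n_heads,
                     const arma::uvec& kperm, const arma::uvec& vperm) {
  const int B = Q.n_rows, d = Q.n_cols;
  const int nk = K.n_rows / B, dh = d / n_heads;
  const double scl = 1.0 / std::sqrt((double)dh);
  arma::mat Ctx(B, d, arma::fill::zeros);
  arma::mat A_all(nk * B, n_heads);
  arma::vec s(nk);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < n_heads; ++h) {
      const int c0 = h * dh;
      double smax = -arma::datum::inf;
      for (int j = 0; j < nk; ++j) {
        double acc = 0.0;
        const int kr = b * nk + (int)kperm[j];
        for (int c = 0; c < dh; ++c) acc += Q(b, c0 + c) * K(kr, c0 + c);
        s[j] = acc * scl;
        if (s[j] > smax) smax = s[j];
      }
      double z = 0.0;
      for (int j = 0; j < nk; ++j) { s[j] = std::exp(s[j] - smax); z += s[j]; }
      for (int j = 0; j < nk; ++j) {
        const double a = s[j] / z;
        A_all(b * nk + j, h) = a;
        const int vr = b * nk + (int)vperm[j];
        for (int c = 0; c < dh; ++c) Ctx(b, c0 + c) += a * V(vr, c0 + c);
      }
    }
  }
  return List::create(_["Ctx"] = Ctx, _["A"] = A_all);
}

// backward of cpp_mha_vec1_fw. dCtx: (B x d).
// [[Rcpp::export]]
List cpp_mha_vec1_bw(const arma::mat& dCtx, const arma::mat& Q,
                     const arma::mat& K, const arma::mat& V,
                     const arma::mat& A_all, int n_heads,
                     const arma::uvec& kperm, const arma::uvec& vperm) {
  const int B = Q.n_rows, d = Q.n_cols;
  const int nk = K.n_rows / B, dh = d / n_heads;
  const double scl = 1.0 / std::sqrt((double)dh);
  arma::mat dQ(B, d, arma::fill::zeros);
  arma::mat dK(B * nk, d, arma::fill::zeros);
  arma::mat dV(B * nk, d, arma::fill::zeros);
  arma::vec dA(nk), dS(nk);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < n_heads; ++h) {
      const int c0 = h * dh;
      double dot = 0.0;
      for (int j = 0; j < nk; ++j) {
        const int vr = b * nk + (int)vperm[j];
        double acc = 0.0;
        for (int c = 0; c < dh; ++c) acc += V(vr, c0 + c) * dCtx(b, c0 + c);
        dA[j] = acc;
        dot += acc * A_all(b * nk + j, h);
      }
      for (int j = 0; j < nk; ++j) {
        dS[j] = (dA[j] - dot) * A_all(b * nk + j, h) * scl;
      }
      for (int j = 0; j < nk; ++j) {
        const int kr = b * nk + (int)kperm[j];
        const int vr = b * nk + (int)vperm[j];
        const double a = A_all(b * nk + j, h);
        for (int c = 0; c < dh; ++c) {
          dQ(b, c0 + c) += dS[j] * K(kr, c0 + c);
          dK(kr, c0 + c) += dS[j] * Q(b, c0 + c);
          dV(vr, c0 + c) += a * dCtx(b, c0 + c);
        }
      }
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}

// general multi-head self/cross attention (nq tokens per sample).
// Q: ((B*nq) x d); K, V: ((B*nk) x d). Returns Ctx and attention as a
// ((B*nq*n_heads) x nk) matrix, blocks ordered head-major within sample.
// [[Rcpp::export]]
List cpp_mha_gen_fw(const arma::mat& Q, const arma::mat& K,
                    const arma::mat& V, int n_heads, int B, int nq, int nk,
                    const arma::uvec& kperm, const arma::uvec& vperm) {
  const int d = Q.n_cols, dh = d / n_heads;
  const double scl = 1.0 / std::sqrt((double)dh);
  arma::mat Ctx(B * nq, d, arma::fill::zeros);
  arma::mat A_all(B * nq * n_heads, nk);
  arma::vec s(nk);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < n_heads; ++h) {
      const int c0 = h * dh;
      for (int i = 0; i < nq; ++i) {
        const int qr = b * nq + i;
        double smax = -arma::datum::inf;
        for (int j = 0; j < nk; ++j) {
          const int kr = b * nk + (int)kperm[j];
          double acc = 0.0;
          for (int c = 0; c < dh; ++c) acc += Q(qr, c0 + c) * K(kr, c0 + c);
          s[j] = acc * scl;
          if (s[j] > smax) smax = s[j];
        }
        double z = 0.0;
        for (int j = 0; j < nk; ++j) {
          s[j] = std::exp(s[j] - smax); z += s[j];
        }
        const int ar = (b * n_heads + h) * nq + i;
        for (int j = 0; j < nk; ++j) {
          const double a = s[j] / z;
          A_all(ar, j) = a;
          const int vr = b * nk + (int)vperm[j];
          for (int c = 0; c < dh; ++c) Ctx(qr, c0 + c) += a * V(vr, c0 + c);
        }
      }
    }
  }
  return List::create(_["Ctx"] = Ctx, _["A"] = A_all);
}

// [[Rcpp::export]]
List cpp_mha_gen_bw(const arma::mat& dCtx, const arma::mat& Q,
                    const arma::mat& K, const arma::mat& V,
                    const arma::mat& A_all, int n_heads, int B, int nq,
                    int nk, const arma::uvec& kperm,
                    const arma::uvec& vperm) {
  const int d = Q.n_cols, dh = d / n_heads;
  const double scl = 1.0 / std::sqrt((double)dh);
  arma::mat dQ(B * nq, d, arma::fill::zeros);
  arma::mat dK(B * nk, d, arma::fill::zeros);
  arma::mat dV(B * nk, d, arma::fill::zeros);
  arma::vec dA(nk), dS(nk);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < n_heads; ++h) {
      const int c0 = h * dh;
      for (int i = 0; i < nq; ++i) {
        const int qr = b * nq + i;
        const int ar = (b * n_heads + h) * nq + i;
        double dot = 0.0;
        for (int j = 0; j < nk; ++j) {
          const int vr = b * nk + (int)vperm[j];
          double acc = 0.0;
          for (int c = 0; c < dh; ++c) acc += V(vr, c0 + c) * dCtx(qr, c0 + c);
          dA[j] = acc;
          dot += acc * A_all(ar, j);
        }
        for (int j = 0; j < nk; ++j) dS[j] = (dA[j] - dot) * A_all(ar, j) * scl;
        for (int j = 0; j < nk; ++j) {
          const int kr = b * nk + (int)kperm[j];
          const int vr = b * nk + (int)vperm[j];
          const double a = A_all(ar, j);
          for (int c = 0; c < dh; ++c) {
            dQ(qr, c0 + c) += dS[j] * K(kr, c0 + c);
            dK(kr, c0 + c) += dS[j] * Q(qr, c0 + c);
            dV(vr, c0 + c) += a * dCtx(qr, c0 + c);
          }
        }
      }
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}

// gather entries of a padded image array into the im2col matrix
// (1-based linear indices, as produced in R); copy-free inputs
// [[Rcpp::export]]
NumericMatrix cpp_gather(NumericVector xp, IntegerMatrix idx) {
  NumericMatrix out(idx.nrow(), idx.ncol());
  const double* xpp = REAL(xp);
  const int* ip = INTEGER(idx);
  double* op = REAL(out);
  const R_xlen_t n = (R_xlen_t)idx.nrow() * idx.ncol();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = xpp[ip[i] - 1];
  return out;
}

// scatter-add the im2col gradient back into the padded image volume
// [[Rcpp::export]]
NumericVector cpp_scatter_add(NumericMatrix dcol, IntegerMatrix idx,
                              int vol) {
  NumericVector out(vol);
  double* op = REAL(out);
  const double* dp = REAL(dcol);
  const int* ip = INTEGER(idx);
  const R_xlen_t n = (R_xlen_t)idx.nrow() * idx.ncol();
  for (R_xlen_t i = 0; i < n; ++i) op[ip[i] - 1] += dp[i];
  return out;
}

// fused Adam update for one parameter leaf; returns updated (param, m, v);
// the param output keeps the input's dim attribute
// [[Rcpp::export]]
List cpp_adam_leaf(NumericVector param, NumericVector g, NumericVector m,
                   NumericVector v, double lr, double beta1, double beta2,
                   double eps, double bc1, double bc2) {
  const R_xlen_t n = param.size();
  NumericVector p2(n), m2(n), v2(n);
  const double* pp = REAL(param);
  const double* gp = REAL(g);
  const double* mp = REAL(m);
  const double* vp = REAL(v);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double mi = beta1 * mp[i] + (1.0 - beta1) * gp[i];
    const double vi = beta2 * vp[i] + (1.0 - beta2) * gp[i] * gp[i];
    m2[i] = mi;
    v2[i] = vi;
    p2[i] = pp[i] - lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
  }
  p2.attr("dim") = param.attr("dim");
  return List::create(_["param"] = p2, _["m"] = m2, _["v"] = v2);
}
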
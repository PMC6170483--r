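// PLS1 (NIPALS with deflation) and k-fold cross-validation kernels.
// All inputs are plain matrices; randomness (fold assignment, row
// subsampling) is drawn on the R side so the R RNG is the single source
// of stochasticity.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

// Fit PLS1 on centered X (n x p) and centered y (n). Returns weights W,
// x-loadings P, y-loadings q, scores T and the cumulative coefficient
// matrix B (p x A) whose column a gives the regression vector using the
// first a latent variables. Stops early (ncomp_used < ncomp) when the
// residual covariance X'y is numerically zero (rank exhausted).
static void pls1_core(const mat& X, const vec& y, int ncomp,
                      mat& W, mat& P, mat& T, vec& q, mat& B,
                      int& used) {
  const int n = X.n_rows, p = X.n_cols;
  int A = std::min(ncomp, std::min(n - 1, p));
  if (A < 1) A = 0;
  W.set_size(p, A); P.set_size(p, A); T.set_size(n, A); q.set_size(A);
  mat Xd = X;
  vec yd = y;
  used = 0;
  double scale0 = -1.0;
  for (int a = 0; a < A; ++a) {
    vec w = Xd.t() * yd;
    double nw = norm(w, 2);
    if (scale0 < 0) scale0 = nw;
    if (nw <= 1e-12 * std::max(1.0, scale0)) break;
    w /= nw;
    vec t = Xd * w;
    double tt = dot(t, t);
    if (tt <= 1e-24 * std::max(1.0, scale0)) break;
    vec pl = Xd.t() * t / tt;
    double qa = dot(yd, t) / tt;
    Xd -= t * pl.t();
    yd -= qa * t;
    W.col(a) = w; P.col(a) = pl; T.col(a) = t; q(a) = qa;
    ++used;
  }
  // Cumulative coefficients: b_a = W_a (P_a' W_a)^{-1} q_a.
  B.zeros(p, used);
  if (used > 0) {
    mat Wu = W.cols(0, used - 1);
    mat PtW = P.cols(0, used - 1).t() * Wu;
    for (int a = 0; a < used; ++a) {
      vec ba = Wu.cols(0, a) *
        solve(trimatu(PtW.submat(0, 0, a, a)), q.subvec(0, a));
      B.col(a) = ba;
    }
  }
}

// [[Rcpp::export(name = ".cpp_pls1")]]
List cpp_pls1(const arma::mat& X, const arma::vec& y, int ncomp) {
  mat W, P, T, B; vec q; int used = 0;
  pls1_core(X, y, ncomp, W, P, T, q, B, used);
  if (used == 0)
    return List::create(_["ncomp"] = 0);
  return List::create(
    _["W"] = W.cols(0, used - 1),
    _["P"] = P.cols(0, used - 1),
    _["T"] = T.cols(0, used - 1),
    _["q"] = q.subvec(0, used - 1),
    _["B"] = B,
    _["ncomp"] = used);
}

// Out-of-fold predictions for each candidate number of latent variables.
// foldid is 1-based fold labels; centering is re-estimated inside each
// training fold. If a fold's fit stops early the last achieved
// coefficient vector is carried forward (predictions stop changing once
// the rank is exhausted). Returns an n x Amax matrix of predictions.
static mat cv_oof(const mat& X, const vec& y, const ivec& foldid, int Amax) {
  const int n = X.n_rows;
  const int k = foldid.max();
  mat oof(n, Amax, fill::zeros);
  for (int f = 1; f <= k; ++f) {
    uvec te = find(foldid == f);
    uvec tr = find(foldid != f);
    mat Xtr = X.rows(tr);
    rowvec xm = mean(Xtr, 0);
    Xtr.each_row() -= xm;
    vec ytr = y.elem(tr);
    double ym = mean(ytr);
    ytr -= ym;
    mat W, P, T, B; vec q; int used = 0;
    pls1_core(Xtr, ytr, Amax, W, P, T, q, B, used);
    mat Xte = X.rows(te);
    Xte.each_row() -= xm;
    for (int a = 0; a < Amax; ++a) {
      vec pr;
      if (used == 0) pr = zeros<vec>(te.n_elem);
      else pr = Xte * B.col(std::min(a, used - 1));
      oof(te, uvec{(unsigned) a}) = pr + ym;
    }
  }
  return oof;
}

// [[Rcpp::export(name = ".cpp_cv_oof")]]
arma::mat cpp_cv_oof(const arma::mat& X, const arma::vec& y,
                     const arma::ivec& foldid, int Amax) {
  return cv_oof(X, y, foldid, Amax);
}

// RMSECV profile (one value per candidate A) for a single column subset.
static vec cv_rmsecv(const mat& X, const vec& y, const ivec& foldid,
                     int Amax) {
  mat oof = cv_oof(X, y, foldid, Amax);
  vec out(Amax);
  for (int a = 0; a < Amax; ++a)
    out(a) = std::sqrt(mean(square(y - oof.col(a))));
  return out;
}

// Evaluate many column subsets under one shared fold assignment.
// subsets holds 1-based column indices. Returns a matrix with one row
// per subset: [min RMSECV, best A (1-based, lowest on ties)].
// [[Rcpp::export(name = ".cpp_cv_subsets")]]
arma::mat cpp_cv_subsets(const arma::mat& X, const arma::vec& y,
                         const arma::ivec& foldid, List subsets,
                         int Amax) {
  const int ns = subsets.size();
  const int n = X.n_rows;
  const int k = foldid.max();
  int ntr_min = n;
  for (int f = 1; f <= k; ++f) {
    int ntr = n - accu(foldid == f);
    if (ntr < ntr_min) ntr_min = ntr;
  }
  mat res(ns, 2);
  for (int s = 0; s < ns; ++s) {
    uvec cols = as<uvec>(subsets[s]) - 1;
    int A = std::min(Amax, std::min(ntr_min - 1, (int) cols.n_elem));
    if (A < 1) A = 1;
    mat Xs = X.cols(cols);
    vec prof = cv_rmsecv(Xs, y, foldid, A);
    uword best = prof.index_min();
    res(s, 0) = prof(best);
    res(s, 1) = best + 1;
  }
  return res;
}

// Monte Carlo coefficient streams for MCUVE stability. rows is a
// (n_runs x M) 1-based row-index matrix drawn in R; each run centers its
// subsample, fits PLS1 with nlv components and records the coefficient
// vector (at the highest achieved component count if rank stops early).
// [[Rcpp::export(name = ".cpp_mc_coefs")]]
arma::mat cpp_mc_coefs(const arma::mat& X, const arma::vec& y,
                       const arma::imat& rows, int nlv) {
  const int nruns = rows.n_rows, p = X.n_cols;
  mat out(nruns, p, fill::zeros);
  for (int r = 0; r < nruns; ++r) {
    uvec idx = conv_to<uvec>::from(rows.row(r).t()) - 1;
    mat Xr = X.rows(idx);
    rowvec xm = mean(Xr, 0);
    Xr.each_row() -= xm;
    vec yr = y.elem(idx);
    yr -= mean(yr);
    mat W, P, T, B; vec q; int used = 0;
    pls1_core(Xr, yr, nlv, W, P, T, q, B, used);
    if (used > 0) out.row(r) = B.col(used - 1).t();
  }
  return out;
}
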
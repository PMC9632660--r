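// Multichannel AR model fitting via the Yule-Walker normal equations,
// solved for all orders 1..max_order with the multichannel Levinson
// (Whittle) recursion, plus the frequency-domain coefficient transforms
// shared by the spectral connectivity estimators.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Lagged covariance matrices R(k) = (1/n) sum_t x_t x_{t-k}^T, k = 0..p,
// after column demeaning.  Biased normalization keeps the block-Toeplitz
// system positive definite.
static arma::cube lag_cov(const arma::mat& X, int p) {
  int n = X.n_rows, N = X.n_cols;
  arma::mat Xc = X;
  Xc.each_row() -= arma::mean(X, 0);
  arma::cube R(N, N, p + 1);
  for (int k = 0; k <= p; ++k) {
    R.slice(k) = Xc.rows(k, n - 1).t() * Xc.rows(0, n - 1 - k) / double(n);
  }
  return R;
}

// Whittle recursion: forward coefficients (regression form
// x_t = sum_k A_k x_{t-k} + e_t) and residual covariance at every order.
// Fills `dets` with det(P_m) (m = 1..p) and returns the coefficient set
// and residual covariance at the requested order `keep`.
static void whittle(const arma::cube& R, int p, int keep,
                    arma::vec& dets, arma::cube& A_keep, arma::mat& P_keep) {
  int N = R.n_rows;
  arma::mat P = R.slice(0), Q = R.slice(0);
  std::vector<arma::mat> A, B;
  dets.set_size(p);
  for (int m = 0; m < p; ++m) {
    arma::mat Delta = R.slice(m + 1);
    for (int k = 1; k <= m; ++k) Delta -= A[k - 1] * R.slice(m + 1 - k);
    arma::mat Qi, Pi;
    if (!arma::inv_sympd(Qi, arma::symmatu(Q)) ||
        !arma::inv_sympd(Pi, arma::symmatu(P))) {
      stop("degenerate covariance structure (near-singular channel)");
    }
    arma::mat Anew = Delta * Qi;
    arma::mat Bnew = Delta.t() * Pi;
    std::vector<arma::mat> A2(m + 1), B2(m + 1);
    for (int k = 1; k <= m; ++k) {
      A2[k - 1] = A[k - 1] - Anew * B[m - k];
      B2[k - 1] = B[k - 1] - Bnew * A[m - k];
    }
    A2[m] = Anew;
    B2[m] = Bnew;
    P = P - Anew * Delta.t();
    Q = Q - Bnew * Delta;
    A.swap(A2);
    B.swap(B2);
    dets(m) = arma::det(arma::symmatu(P));
    if (m + 1 == keep) {
      A_keep.set_size(N, N, keep);
      for (int k = 0; k < keep; ++k) A_keep.slice(k) = A[k];
      P_keep = arma::symmatu(P);
    }
  }
}

// [[Rcpp::export(name = ".mvar_fit_cpp")]]
List mvar_fit_cpp(const arma::mat& X, int max_order) {
  int n = X.n_rows, N = X.n_cols;
  int pmax = std::min(max_order, (n - 2) / N);
  if (pmax < 1) stop("segment too short for the requested model order");
  arma::rowvec v = arma::var(X, 0, 0);
  if (v.min() <= 1e-14) stop("degenerate input: (near-)constant channel");
  arma::cube R = lag_cov(X, pmax);

  // first pass: residual determinants at every order -> FPE
  arma::vec dets;
  arma::cube Adummy;
  arma::mat Pdummy;
  whittle(R, pmax, pmax, dets, Adummy, Pdummy);

  arma::vec fpe(pmax);
  for (int m = 1; m <= pmax; ++m) {
    double np = double(N) * m;
    fpe(m - 1) = dets(m - 1) *
      std::pow((n + np + 1.0) / (n - np - 1.0), double(N));
  }
  int best = 1;
  for (int m = 2; m <= pmax; ++m) {
    if (fpe(m - 1) < fpe(best - 1)) best = m;  // strict: ties -> smaller p
  }

  arma::cube A_best;
  arma::mat P_best;
  arma::vec dets2;
  whittle(R, best, best, dets2, A_best, P_best);

  return List::create(_["order"] = best, _["coeffs"] = A_best,
                      _["noise_cov"] = P_best, _["fpe"] = fpe);
}

// [[Rcpp::export(name = ".mvar_fit_segments_cpp")]]
List mvar_fit_segments_cpp(const arma::cube& segs, int max_order) {
  int S = segs.n_slices;
  List out(S);
  for (int s = 0; s < S; ++s) out[s] = mvar_fit_cpp(segs.slice(s), max_order);
  return out;
}

// A(f) = I - sum_j A_j exp(-i 2 pi f dt j) on a frequency grid; optionally
// its inverse H(f) (the transfer matrix used by the directed transfer
// function).  Returns N x N x F complex cubes.
// [[Rcpp::export(name = ".ar_spectra_cpp")]]
List ar_spectra_cpp(const arma::cube& coeffs, const arma::vec& freqs,
                    double dt, bool need_H) {
  int N = coeffs.n_rows, p = coeffs.n_slices, F = freqs.n_elem;
  arma::cx_cube Af(N, N, F), Hf;
  if (need_H) Hf.set_size(N, N, F);
  arma::cx_mat I = arma::cx_mat(arma::eye(N, N), arma::zeros(N, N));
  for (int f = 0; f < F; ++f) {
    arma::cx_mat Acc = I;
    for (int j = 1; j <= p; ++j) {
      std::complex<double> z =
        std::exp(std::complex<double>(0.0, -2.0 * M_PI * freqs(f) * dt * j));
      Acc -= coeffs.slice(j - 1) * z;
    }
    Af.slice(f) = Acc;
    if (need_H) {
      arma::cx_mat H;
      if (!arma::inv(H, Acc)) {
        stop("coefficient matrix not invertible at %.3f Hz", freqs(f));
      }
      Hf.slice(f) = H;
    }
  }
  if (need_H) return List::create(_["A"] = Af, _["H"] = Hf);
  return List::create(_["A"] = Af);
}
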
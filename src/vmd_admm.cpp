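// Variational mode decomposition: frequency-domain ADMM.
//
// Works on the positive half-spectrum only (the input is real); per
// iteration each mode gets a Wiener update
//   u_k = (f - sum_{i != k} u_i - lambda/2) / (1 + 2 alpha (w - w_k)^2)
// and its centre frequency moves to the power-weighted spectral centroid.
// The dual variable ascends with step tau. Iteration stops when the summed
// relative change of the modes drops below `tol` or `max_iter` is reached.
// The inner loop is written allocation-free: it is the hot path of the
// sparrow-search parameter tuning (hundreds of decompositions per run).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List vmd_admm_cpp(const arma::vec& signal, int K, double alpha,
                        double tau, double tol, int max_iter,
                        const arma::vec& omega_init, bool dc) {
  const uword N = signal.n_elem;
  const uword H = N / 2 + 1;  // bins 0 .. N/2 (freq h/N cycles/sample)

  cx_vec f_hat = fft(signal);
  cx_vec f_plus = f_hat.head(H);  // positive half, full amplitude

  vec freqs(H);
  for (uword h = 0; h < H; ++h) freqs(h) = double(h) / double(N);

  cx_mat u(H, K, fill::zeros);
  cx_vec lambda(H, fill::zeros);
  cx_vec sum_all(H, fill::zeros);
  vec omega(K);
  for (int k = 0; k < K; ++k) omega(k) = omega_init(k);
  if (dc) omega(0) = 0.0;

  int n_iter = 0;
  double udiff = tol + 1.0;
  const double eps = 2.2204460492503131e-16;

  for (int it = 0; it < max_iter && udiff > tol; ++it) {
    udiff = 0.0;
    for (int k = 0; k < K; ++k) {
      std::complex<double>* uk = u.colptr(k);
      const std::complex<double>* fp = f_plus.memptr();
      std::complex<double>* sa = sum_all.memptr();
      const std::complex<double>* lm = lambda.memptr();
      const double* fr = freqs.memptr();
      const double wk = omega(k);
      double num = 0.0, den = 0.0, psum = 0.0, fpsum = 0.0;
      for (uword h = 0; h < H; ++h) {
        const std::complex<double> uold = uk[h];
        const double dw = fr[h] - wk;
        const std::complex<double> unew =
          (fp[h] - (sa[h] - uold) - 0.5 * lm[h]) / (1.0 + 2.0 * alpha * dw * dw);
        sa[h] += unew - uold;
        uk[h] = unew;
        num += std::norm(unew - uold);
        den += std::norm(uold);
        const double p = std::norm(unew);
        psum += p;
        fpsum += fr[h] * p;
      }
      if (!(dc && k == 0) && psum > 0.0) omega(k) = fpsum / psum;
      udiff += num / (den + eps);
    }
    if (tau != 0.0) lambda += tau * (sum_all - f_plus);
    n_iter = it + 1;
  }

  // back to time domain: rebuild the conjugate-symmetric full spectrum
  mat modes(N, K);
  for (int k = 0; k < K; ++k) {
    cx_vec full(N, fill::zeros);
    full(0) = cx_double(u(0, k).real(), 0.0);  // DC must be real
    for (uword h = 1; h < H; ++h) {
      if (h == N - h) {  // Nyquist bin (even N): real
        full(h) = cx_double(u(h, k).real(), 0.0);
      } else {
        full(h) = u(h, k);
        full(N - h) = std::conj(u(h, k));
      }
    }
    modes.col(k) = real(ifft(full));
  }

  return Rcpp::List::create(
    Rcpp::Named("modes") = modes,
    Rcpp::Named("omega") = omega,
    Rcpp::Named("n_iter") = n_iter,
    Rcpp::Named("udiff") = udiff);
}
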
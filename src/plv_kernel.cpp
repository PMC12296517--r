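#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

// Across-trial phase-locking values for every unordered channel pair.
//
// coef: complex wavelet coefficients, n_out x (n_ch * n_tr); column
//   (tr - 1) * n_ch + ch holds one channel's coefficient series in one
//   trial. Coefficients are reduced to unit phasors here; entries whose
//   modulus falls below `floor_amp` contribute a zero phasor instead of
//   an undefined phase (degenerate samples pull the PLV toward 0 rather
//   than propagating NaN).
//
// Returns n_pairs x n_out, pairs enumerated as combn(n_ch, 2) columns:
// (1,2), (1,3), ..., (1,n), (2,3), ...
// [[Rcpp::export]]
arma::mat plv_pairs_cpp(const arma::cx_mat& coef, const int n_ch,
                        const int n_tr, const double floor_amp) {
  const arma::uword n_out = coef.n_rows;
  if (coef.n_cols != static_cast<arma::uword>(n_ch) * n_tr)
    Rcpp::stop("coef has %d columns, expected n_ch * n_tr = %d",
               coef.n_cols, n_ch * n_tr);
  if (n_tr < 2) Rcpp::stop("PLV requires at least 2 trials");

  // transpose so each output sample is a contiguous column
  arma::cx_mat ct = coef.st();                    // (n_ch*n_tr) x n_out
  for (arma::uword i = 0; i < ct.n_elem; ++i) {
    const double m = std::abs(ct(i));
    ct(i) = (m < floor_amp) ? std::complex<double>(0.0, 0.0) : ct(i) / m;
  }

  const int n_pairs = n_ch * (n_ch - 1) / 2;
  arma::mat out(n_pairs, n_out);

  for (arma::uword t = 0; t < n_out; ++t) {
    const arma::cx_mat z(const_cast<std::complex<double>*>(ct.colptr(t)),
                         n_ch, n_tr, false, true);
    // G(i, j) = sum_n z_i conj(z_j); PLV = |G| / N
    const arma::cx_mat g = z * z.t();             // .t() = conjugate transpose
    int k = 0;
    for (int i = 0; i < n_ch - 1; ++i)
      for (int j = i + 1; j < n_ch; ++j)
        out(k++, t) = std::abs(g(i, j)) / n_tr;
  }
  return out;
}

// Assemble one subject's epoch array: electrode signal = cos(global
// oscillator phase + segmentwise area offset + segmentwise electrode
// jitter) + scaled noise. Returns channels x samples x trials.
//
// G: samples x trials global oscillator phase; alpha: (n_seg, n_area,
// n_tr) cube of area offsets; theta: (n_seg, n_ch, n_tr) electrode
// jitter; seg_id / area_of are 1-based lookups; noise: samples x
// (n_ch * n_tr), column (tr * n_ch + ch).
// [[Rcpp::export]]
Rcpp::NumericVector assemble_epochs_cpp(const arma::mat& G,
                                        const arma::cube& alpha,
                                        const arma::cube& theta,
                                        const arma::ivec& seg_id,
                                        const arma::ivec& area_of,
                                        const arma::mat& noise,
                                        const double noise_scale) {
  const arma::uword n_s = G.n_rows, n_tr = G.n_cols;
  const arma::uword n_ch = theta.n_cols;
  Rcpp::NumericVector out(n_ch * n_s * n_tr);
  double* o = out.begin();
  for (arma::uword n = 0; n < n_tr; ++n) {
    const double* g = G.colptr(n);
    for (arma::uword t = 0; t < n_s; ++t) {
      const arma::uword s = static_cast<arma::uword>(seg_id(t) - 1);
      const double gt = g[t];
      double* orow = o + n * n_ch * n_s + t * n_ch;
      for (arma::uword c = 0; c < n_ch; ++c) {
        const arma::uword a = static_cast<arma::uword>(area_of(c) - 1);
        orow[c] = std::cos(gt + alpha(s, a, n) + theta(s, c, n)) +
          noise(t, n * n_ch + c) * noise_scale;
      }
    }
  }
  out.attr("dim") = Rcpp::IntegerVector::create(n_ch, n_s, n_tr);
  return out;
}

// Standard-normal matrix from a dedicated 64-bit Mersenne Twister stream.
// Used for bulk noise synthesis where R's rnorm would dominate the
// generator's run time; the stream seed itself is drawn from R's RNG so
// all randomness still derives from the root seed.
// [[Rcpp::export]]
arma::mat gauss_mat_cpp(const int n, const int m, const double seed) {
  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  arma::mat out(n, m);
  for (arma::uword i = 0; i < out.n_elem; ++i) out(i) = gauss(rng);
  return out;
}
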
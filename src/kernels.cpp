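// Numeric kernels for the signal path: zero-phase FFT filtering, epoch
// extraction, Welch periodogram accumulation, and random-phase spectral
// synthesis.  All randomness stays on the R side (phases are drawn there),
// so determinism contracts are unaffected.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::uword;

// Zero-phase frequency-domain filter with reflective padding.
// x: n x nch (real).  gain: length np = n + pad + pad_r, two-sided grid.
// Two real channels share one complex transform (the gain is real and
// even, so re/im parts filter independently).
// [[Rcpp::export]]
arma::mat cpp_fft_filter(const arma::mat& x, const arma::vec& gain,
                         const int pad, const int pad_r) {
  const int n = x.n_rows, nch = x.n_cols;
  const int np = n + pad + pad_r;
  if ((int)gain.n_elem != np) Rcpp::stop("gain length mismatch");
  const int npair = (nch + 1) / 2;
  arma::cx_mat z(np, npair);
  for (int p = 0; p < npair; ++p) {
    const int j1 = 2 * p, j2 = 2 * p + 1;
    const bool two = j2 < nch;
    for (int t = 0; t < np; ++t) {
      int s = t - pad;                      // reflect at both ends
      if (s < 0) s = -s;
      else if (s >= n) s = 2 * (n - 1) - s;
      z(t, p) = std::complex<double>(x(s, j1), two ? x(s, j2) : 0.0);
    }
  }
  arma::cx_mat Z = arma::fft(z);
  for (int p = 0; p < npair; ++p)
    for (int t = 0; t < np; ++t) Z(t, p) *= gain(t);
  arma::cx_mat y = arma::ifft(Z);
  arma::mat out(n, nch);
  for (int p = 0; p < npair; ++p) {
    const int j1 = 2 * p, j2 = 2 * p + 1;
    for (int t = 0; t < n; ++t) {
      out(t, j1) = y(t + pad, p).real();
      if (j2 < nch) out(t, j2) = y(t + pad, p).imag();
    }
  }
  return out;
}

// Subtract the instantaneous mean across channels from every sample.
// [[Rcpp::export]]
arma::mat cpp_average_reference(const arma::mat& x) {
  arma::mat out = x;
  out.each_col() -= arma::mean(x, 1);
  return out;
}

// Cut consecutive epochs: signal (n x nch) -> cube (nep x len x nch),
// starts are 0-based sample offsets.
// [[Rcpp::export]]
arma::cube cpp_extract_epochs(const arma::mat& x, const arma::uvec& starts,
                              const int len) {
  const int nep = starts.n_elem, nch = x.n_cols;
  arma::cube ep(nep, len, nch);
  for (int c = 0; c < nch; ++c)
    for (int e = 0; e < nep; ++e) {
      const uword s0 = starts(e);
      for (int t = 0; t < len; ++t) ep(e, t, c) = x(s0 + t, c);
    }
  return ep;
}

// Per-epoch maximum (over channels) peak-to-peak amplitude.
// [[Rcpp::export]]
arma::vec cpp_epoch_ptp(const arma::cube& ep) {
  const int nep = ep.n_rows, len = ep.n_cols, nch = ep.n_slices;
  arma::vec out(nep, arma::fill::zeros);
  for (int c = 0; c < nch; ++c)
    for (int e = 0; e < nep; ++e) {
      double mn = ep(e, 0, c), mx = mn;
      for (int t = 1; t < len; ++t) {
        const double v = ep(e, t, c);
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      if (mx - mn > out(e)) out(e) = mx - mn;
    }
  return out;
}

// Welch one-sided power averaged over segments of retained epochs.
// ep: nep x ep_len x nch cube; keep, seg_starts 0-based; w: taper (len L).
// Returns nf x nch, density-scaled (uV^2/Hz), segments mean-detrended.
// [[Rcpp::export]]
arma::mat cpp_welch_power(const arma::cube& ep, const arma::uvec& keep,
                          const arma::uvec& seg_starts, const int L,
                          const arma::vec& w, const double fs) {
  const int nk = keep.n_elem, nch = ep.n_slices, nseg = seg_starts.n_elem;
  const int nf = L / 2 + 1;
  const int total = nseg * nk;            // segments per channel
  const int npair = (total + 1) / 2;
  arma::mat power(nf, nch, arma::fill::zeros);
  arma::cx_mat z(L, npair);
  for (int c = 0; c < nch; ++c) {
    z.zeros();
    int col = 0;
    for (int k = 0; k < nk; ++k) {
      const uword e = keep(k);
      for (int s = 0; s < nseg; ++s, ++col) {
        const uword st = seg_starts(s);
        double mean = 0;
        for (int t = 0; t < L; ++t) mean += ep(e, st + t, c);
        mean /= L;
        const int pc = col / 2;
        if (col % 2 == 0) {
          for (int t = 0; t < L; ++t)
            z(t, pc) = std::complex<double>((ep(e, st + t, c) - mean) * w(t),
                                            0.0);
        } else {
          for (int t = 0; t < L; ++t)
            z(t, pc) += std::complex<double>(0.0,
                                             (ep(e, st + t, c) - mean) * w(t));
        }
      }
    }
    const arma::cx_mat Z = arma::fft(z);
    for (int pc = 0; pc < npair; ++pc) {
      const bool second = (2 * pc + 1) < total;
      for (int f = 0; f < nf; ++f) {
        const std::complex<double> a = Z(f, pc);
        const std::complex<double> b = std::conj(Z(f == 0 ? 0 : L - f, pc));
        const double fac =
          (f == 0 || (L % 2 == 0 && f == nf - 1)) ? 0.5 : 1.0;
        power(f, c) += 0.25 * std::norm(a + b) * fac;
        if (second) power(f, c) += 0.25 * std::norm(a - b) * fac;
      }
    }
  }
  power *= 2.0 / (fs * arma::dot(w, w)) / total;
  return power;
}

// Fused per-recording chain: average reference, reflective-padded
// zero-phase filter, epoch cutting, per-epoch peak-to-peak, and Welch
// accumulation over retained epochs — one call, no intermediate R copies.
// Numerically identical to applying the individual kernels in sequence.
// [[Rcpp::export]]
Rcpp::List cpp_preprocess_welch(const arma::mat& x, const arma::vec& gain,
                                const int pad, const int pad_r,
                                const arma::uvec& ep_starts, const int ep_len,
                                const double ptp_thr,
                                const arma::uvec& seg_starts, const int L,
                                const arma::vec& w, const double fs) {
  const int n = x.n_rows, nch = x.n_cols;
  // instantaneous channel mean (average reference, applied on the fly)
  arma::vec cm(n);
  for (int t = 0; t < n; ++t) {
    double m = 0;
    for (int c = 0; c < nch; ++c) m += x(t, c);
    cm(t) = m / nch;
  }
  // zero-phase filter (same maths as cpp_fft_filter)
  const int np = n + pad + pad_r;
  if ((int)gain.n_elem != np) Rcpp::stop("gain length mismatch");
  const int npair = (nch + 1) / 2;
  arma::cx_mat z(np, npair);
  for (int p = 0; p < npair; ++p) {
    const int j1 = 2 * p, j2 = 2 * p + 1;
    const bool two = j2 < nch;
    for (int t = 0; t < np; ++t) {
      int s = t - pad;
      if (s < 0) s = -s;
      else if (s >= n) s = 2 * (n - 1) - s;
      z(t, p) = std::complex<double>(x(s, j1) - cm(s),
                                     two ? x(s, j2) - cm(s) : 0.0);
    }
  }
  arma::cx_mat Z = arma::fft(z);
  for (int p = 0; p < npair; ++p)
    for (int t = 0; t < np; ++t) Z(t, p) *= gain(t);
  arma::cx_mat yf = arma::ifft(Z);
  arma::mat y(n, nch);
  for (int p = 0; p < npair; ++p) {
    const int j1 = 2 * p, j2 = 2 * p + 1;
    for (int t = 0; t < n; ++t) {
      y(t, j1) = yf(t + pad, p).real();
      if (j2 < nch) y(t, j2) = yf(t + pad, p).imag();
    }
  }
  // per-epoch peak-to-peak and retained flags
  const int nep = ep_starts.n_elem;
  arma::vec ptp(nep, arma::fill::zeros);
  for (int c = 0; c < nch; ++c)
    for (int e = 0; e < nep; ++e) {
      const uword s0 = ep_starts(e);
      double mn = y(s0, c), mx = mn;
      for (int t = 1; t < ep_len; ++t) {
        const double v = y(s0 + t, c);
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      if (mx - mn > ptp(e)) ptp(e) = mx - mn;
    }
  arma::uvec keep = arma::find(ptp <= ptp_thr);
  const int nk = keep.n_elem;
  const int nseg = seg_starts.n_elem;
  const int nf = L / 2 + 1;
  arma::mat power(nf, nch, arma::fill::zeros);
  if (nk > 0) {
    const int total = nseg * nk;
    const int spair = (total + 1) / 2;
    arma::cx_mat zs(L, spair);
    for (int c = 0; c < nch; ++c) {
      zs.zeros();
      int col = 0;
      for (int k = 0; k < nk; ++k) {
        const uword e0 = ep_starts(keep(k));
        for (int s = 0; s < nseg; ++s, ++col) {
          const uword st = e0 + seg_starts(s);
          double mean = 0;
          for (int t = 0; t < L; ++t) mean += y(st + t, c);
          mean /= L;
          const int pc = col / 2;
          if (col % 2 == 0)
            for (int t = 0; t < L; ++t)
              zs(t, pc) = std::complex<double>((y(st + t, c) - mean) * w(t),
                                               0.0);
          else
            for (int t = 0; t < L; ++t)
              zs(t, pc) += std::complex<double>(0.0,
                                                (y(st + t, c) - mean) * w(t));
        }
      }
      const arma::cx_mat ZS = arma::fft(zs);
      for (int pc = 0; pc < spair; ++pc) {
        const bool second = (2 * pc + 1) < total;
        for (int f = 0; f < nf; ++f) {
          const std::complex<double> a = ZS(f, pc);
          const std::complex<double> b =
            std::conj(ZS(f == 0 ? 0 : L - f, pc));
          const double fac =
            (f == 0 || (L % 2 == 0 && f == nf - 1)) ? 0.5 : 1.0;
          power(f, c) += 0.25 * std::norm(a + b) * fac;
          if (second) power(f, c) += 0.25 * std::norm(a - b) * fac;
        }
      }
    }
    power *= 2.0 / (fs * arma::dot(w, w)) / total;
  }
  return Rcpp::List::create(Rcpp::Named("power") = power,
                            Rcpp::Named("retained") = ptp <= ptp_thr,
                            Rcpp::Named("n_retained") = nk);
}

// Random-phase synthesis from a desired PSD: rows 1..nf of S map to FFT
// bins 1..nf.  Optionally pre-compensates for average-reference mixing
// (S_gen = max((S - rowsum(S)*c2)/c1, floor)); amplitude per bin is
// scale*sqrt(S_gen) with scale = n*sqrt(df/2).  Returns n x nch real.
// [[Rcpp::export]]
arma::mat cpp_synth_from_psd(const arma::mat& S, const arma::mat& phase,
                             const int n, const double c1, const double c2,
                             const double floor_v, const double scale) {
  const int nf = S.n_rows, nch = S.n_cols;
  const int npair = (nch + 1) / 2;
  arma::vec rs(nf, arma::fill::zeros);
  if (c2 != 0.0)
    for (int j = 0; j < nch; ++j)
      for (int k = 0; k < nf; ++k) rs(k) += S(k, j);
  arma::cx_mat X(n, npair, arma::fill::zeros);
  const std::complex<double> I(0.0, 1.0);
  for (int p = 0; p < npair; ++p) {
    const int j1 = 2 * p, j2 = 2 * p + 1;
    const bool two = j2 < nch;
    for (int k = 0; k < nf; ++k) {
      double s1 = (S(k, j1) - rs(k) * c2) / c1;
      double s2 = two ? (S(k, j2) - rs(k) * c2) / c1 : 0.0;
      if (s1 < floor_v) s1 = floor_v;
      if (s2 < floor_v) s2 = floor_v;
      const std::complex<double> z1 =
        std::polar(scale * std::sqrt(s1), phase(k, j1));
      const std::complex<double> z2 =
        two ? std::polar(scale * std::sqrt(s2), phase(k, j2))
            : std::complex<double>(0.0, 0.0);
      X(k + 1, p) = z1 + I * z2;
      X(n - 1 - k, p) = std::conj(z1) + I * std::conj(z2);
    }
  }
  const arma::cx_mat y = arma::ifft(X);
  arma::mat out(n, nch);
  for (int p = 0; p < npair; ++p) {
    const int j1 = 2 * p, j2 = 2 * p + 1;
    for (int t = 0; t < n; ++t) {
      out(t, j1) = y(t, p).real();
      if (j2 < nch) out(t, j2) = y(t, p).imag();
    }
  }
  return out;
}
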
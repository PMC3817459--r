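# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: FFT band energies for synthesis checks, bisection
# for the cochlear map inverse, and brute-force likelihood maximization for
# the logistic fitter.

rms <- function(x) sqrt(mean(x^2))

# band-integrated energy of a waveform around a center frequency (FFT-based)
band_energy <- function(w, center_hz, width_hz) {
  s <- abs(stats::fft(w$samples))^2
  n <- length(s) %/% 2
  fr <- (seq_len(n) - 1) * w$rate_hz / length(s)
  sum(s[seq_len(n)][fr >= center_hz - width_hz / 2 &
                      fr <= center_hz + width_hz / 2])
}

# fraction of total (positive-frequency) energy inside [lo, hi]
band_energy_fraction <- function(w, lo_hz, hi_hz) {
  s <- abs(stats::fft(w$samples))^2
  n <- length(s) %/% 2
  fr <- (seq_len(n) - 1) * w$rate_hz / length(s)
  sum(s[seq_len(n)][fr >= lo_hz & fr <= hi_hz]) / sum(s[seq_len(n)])
}

# invert the Greenwood function by bisection (never uses greenwood_place)
bisect_place <- function(freq_hz, A = 165.4, a = 0.06, k = 0.88,
                         lo = 0, hi = 35, tol = 1e-10) {
  f <- function(x) A * (10^(a * x) - k) - freq_hz
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Bernoulli log-likelihood of a logistic model at given coefficients
bernoulli_loglik <- function(beta, mm, yy) {
  eta <- drop(mm %*% beta)
  sum(yy * stats::plogis(eta, log.p = TRUE) +
        (1 - yy) * stats::plogis(-eta, log.p = TRUE))
}

# brute-force maximum likelihood: coarse grid over coefficients followed by
# Nelder-Mead refinement from the best grid point (independent of IRLS)
grid_refine_loglik <- function(mm, yy, span = 20, by = 1) {
  p <- ncol(mm)
  grids <- rep(list(seq(-span, span, by = by)), p)
  grid <- as.matrix(expand.grid(grids))
  lls <- apply(grid, 1, function(b) bernoulli_loglik(b, mm, yy))
  start <- grid[which.max(lls), ]
  opt <- stats::optim(start, function(b) -bernoulli_loglik(b, mm, yy),
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  -opt$value
}

# smoothed long-term log-power spectrum (coarse bins) for spectral-shape
# comparisons
smoothed_spectrum_db <- function(w, n_bins = 60) {
  s <- abs(stats::fft(w$samples))^2
  n <- length(s) %/% 2
  grp <- cut(seq_len(n), n_bins)
  10 * log10(as.numeric(tapply(s[seq_len(n)], grp, mean)))
}

# broadband envelope (rectify + 50 Hz low-pass), for envelope-preservation
# checks
broadband_envelope <- function(w, cutoff_hz = 50) {
  lp <- signal::butter(4, cutoff_hz / (w$rate_hz / 2), type = "low")
  as.numeric(signal::filter(lp, pmax(w$samples, 0)))
}

# candidate term sets used by selection tests
exp1_candidates <- function() {
  c("x", "voice_gender", "vowel", "transition",
    "x:voice_gender", "x:vowel", "x:transition",
    "voice_gender:vowel", "voice_gender:transition", "vowel:transition")
}
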
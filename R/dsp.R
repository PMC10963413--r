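# Internal DSP helpers shared by modality modules.

# Welch power spectral density, one-sided, density scaling (units^2/Hz).
# Hamming-windowed sub-segments with 50% overlap (detrended by mean removal).
welch_psd <- function(x, fs, nperseg, noverlap = floor(nperseg / 2)) {
  nperseg <- min(nperseg, length(x))
  step <- nperseg - noverlap
  starts <- seq(1, length(x) - nperseg + 1, by = step)
  w <- signal::hamming(nperseg)
  U <- sum(w^2)
  nfft <- nperseg
  nf <- floor(nfft / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)
    acc <- acc + Mod(X[seq_len(nf)])^2
  }
  psd <- acc / length(starts) / (fs * U)
  # one-sided: double all bins except DC (and Nyquist when nfft is even)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (nfft %% 2 == 0) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / nfft, psd = psd * dbl)
}

# Rectangular integration of a PSD over [lo, hi).
integrate_band <- function(freq, psd, lo, hi) {
  df <- freq[2] - freq[1]
  sum(psd[freq >= lo & freq < hi]) * df
}

# Zero-phase Butterworth filtering (forward-backward), per column.
butter_filtfilt <- function(x, fs, order, band, type) {
  bf <- signal::butter(order, band / (fs / 2), type = type)
  apply_cols(x, function(v) signal::filtfilt(bf, v))
}

# Butterworth low/high-pass as a cascade of bilinear-transformed biquads.
# Expanding a high-order design into one transfer function is numerically
# unstable for cutoffs far below Nyquist; keeping pole pairs separate is not.
butter_sos <- function(order, w, type = c("low", "high")) {
  type <- match.arg(type)
  W <- tan(pi * w / 2)                      # prewarped analog cutoff
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # analog prototype
  pa <- if (type == "low") W * p else W / p
  zd <- (1 + pa) / (1 - pa)                 # bilinear transform of poles
  zz <- if (type == "low") -1 else 1        # transformed zeros
  # pair complex-conjugate poles (and a lone real pole) into biquads
  cplx <- zd[Im(zd) > 1e-12]
  real <- Re(zd[abs(Im(zd)) <= 1e-12])
  sos <- list()
  for (pp in cplx) {
    sos[[length(sos) + 1]] <- list(
      b = c(1, -2 * zz, 1),
      a = c(1, -2 * Re(pp), Mod(pp)^2))
  }
  for (pp in real) {
    sos[[length(sos) + 1]] <- list(b = c(1, -zz, 0), a = c(1, -pp, 0))
  }
  # normalise overall gain at DC (low-pass) or Nyquist (high-pass)
  zref <- if (type == "low") 1 else -1
  g <- prod(vapply(sos, function(s) {
    abs(sum(s$b * zref^(0:-2)) / sum(s$a * zref^(0:-2)))
  }, numeric(1)))
  sos[[1]]$b <- sos[[1]]$b / g
  sos
}

# forward-backward application of a biquad cascade
sos_filtfilt <- function(x, fs, order, cutoff_hz, type) {
  sos <- butter_sos(order, cutoff_hz / (fs / 2), type)
  apply_cols(x, function(v) {
    for (s in sos) {
      v <- signal::filtfilt(signal::Arma(b = s$b, a = s$a), v)
    }
    v
  })
}

apply_cols <- function(x, f) {
  if (is.vector(x)) return(f(x))
  out <- x
  for (j in seq_len(ncol(x))) out[, j] <- f(x[, j])
  out
}

# Canonical double-gamma haemodynamic impulse response (peak 6 s,
# undershoot 16 s, undershoot ratio 1/6), normalised to unit peak.
hrf_double_gamma <- function(t) {
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# 1/f ("pink") noise via spectral shaping; unit variance.
pink_noise <- function(n) {
  white <- rnorm(n)
  X <- fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # mirror for negative frequencies
  X <- X / sqrt(f)
  x <- Re(fft(X, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# Band-limited Gaussian noise with unit variance.
band_noise <- function(n, fs, lo, hi, order = 4) {
  x <- rnorm(n)
  hi <- min(hi, fs / 2 * 0.99)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  y / sd(y)
}

# OLS slope of y against time (s); the block "slope" feature.
ols_slope <- function(t, y) {
  tc <- t - mean(t)
  sum(tc * (y - mean(y))) / sum(tc^2)
}
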
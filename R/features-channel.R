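# ---- per-channel features: TF (11) + FF (14) + WL/WLP (23) + AR (14) + EY (1) = 63

#' Time-domain features (family TF, 11 values)
#'
#' IEMG (sum |x|), AEMG/MAV (mean |x|), RMS, variance, waveform length
#' (sum |dx|), zero-crossing count, slope-sign-change count, Willison
#' amplitude (threshold `wamp_eps_sd` standard deviations), log detector,
#' skewness, kurtosis (excess). Skewness and kurtosis are 0 by convention
#' for zero-variance input.
#'
#' @param signal a [channel_signal()] (or bare numeric vector).
#' @param wamp_eps_sd Willison threshold as a multiple of the signal SD.
#' @return named numeric vector of length 11 (`TF_01`..`TF_11`).
#' @export
time_domain_features <- function(signal, wamp_eps_sd = 0.01) {
  x <- signal_values(signal)
  n <- length(x)
  if (n < 2) stop("time-domain features need at least 2 samples")
  d <- diff(x)
  s <- sd(x)
  zc <- sum(x[-n] * x[-1] < 0)
  ssc <- if (n >= 3) sum(d[-(n - 1)] * d[-1] < 0) else 0
  wamp <- sum(abs(d) > wamp_eps_sd * s)
  logd <- exp(mean(log(pmax(abs(x), 1e-300))))
  if (s > 0) {
    skew <- e1071::skewness(x)
    kurt <- e1071::kurtosis(x)
  } else {
    skew <- 0; kurt <- 0
  }
  out <- c(sum(abs(x)), mean(abs(x)), sqrt(mean(x^2)), var(x),
           sum(abs(d)), zc, ssc, wamp, logd, skew, kurt)
  names(out) <- sprintf("TF_%02d", 1:11)
  out
}

#' Welch power spectral density
#'
#' Hann-windowed segment-averaged one-sided PSD.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length (clipped to the signal length).
#' @return list with `freq` (Hz) and `power` (density, x^2/Hz).
#' @export
welch_psd <- function(x, fs, nperseg = 512) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1))
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  U <- sum(win^2)
  acc <- numeric(nperseg)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nperseg - 1L)]
    acc <- acc + Mod(fft(seg * win))^2 / U
  }
  acc <- acc / length(starts)
  half <- nperseg %/% 2
  p <- acc[1:(half + 1)]
  if (half > 1) p[2:half] <- 2 * p[2:half]
  list(freq = (0:half) * fs / nperseg, power = p / fs)
}

band_power <- function(freq, power, lo, hi) {
  sel <- freq >= lo & freq < hi
  if (!any(sel)) return(0)
  df <- freq[2] - freq[1]
  sum(power[sel]) * df
}

#' Frequency-domain features (family FF, 14 values)
#'
#' From the Welch one-sided PSD (DC excluded): median frequency, mean power
#' frequency, peak frequency, total power, spectral moments 1-3 (absolute,
#' sum of f^k P df), low/high frequency ratio (20-150 Hz over 150-450 Hz),
#' power-spectrum ratio within +-10 Hz of the peak, variance of central
#' frequency, and four absolute band powers (20-50, 50-100, 100-150,
#' 150-450 Hz).
#'
#' @param signal a [channel_signal()] or numeric vector.
#' @param fs sampling rate (taken from the signal when available).
#' @param nperseg Welch segment length.
#' @return named numeric vector of length 14 (`FF_01`..`FF_14`).
#' @export
frequency_domain_features <- function(signal, fs = NULL, nperseg = 512) {
  x <- signal_values(signal)
  if (is.null(fs)) fs <- signal_fs(signal)
  if (length(x) < 256) stop("frequency-domain features need >= 256 samples")
  ps <- welch_psd(x, fs, nperseg)
  keep <- ps$freq > 0
  f <- ps$freq[keep]; p <- ps$power[keep]
  df <- f[2] - f[1]
  tot <- sum(p) * df
  if (tot <= 0) stop("degenerate spectrum")
  cum <- cumsum(p) * df
  # interpolated half-power crossing
  i <- which(cum >= tot / 2)[1]
  mf <- if (i == 1) f[1] else {
    f[i - 1] + (tot / 2 - cum[i - 1]) / (cum[i] - cum[i - 1]) * (f[i] - f[i - 1])
  }
  mpf <- sum(f * p) / sum(p)
  pk <- f[which.max(p)]
  sm <- vapply(1:3, function(k) sum(f^k * p) * df, numeric(1))
  frat <- band_power(f, p, 20, 150) /
    max(band_power(f, p, 150, 450), .Machine$double.xmin)
  psr <- band_power(f, p, pk - 10, pk + 10) / tot
  vcf <- sum(p * (f - mpf)^2) / sum(p)
  bp <- c(band_power(f, p, 20, 50), band_power(f, p, 50, 100),
          band_power(f, p, 100, 150), band_power(f, p, 150, 450))
  out <- c(mf, mpf, pk, tot, sm, frat, psr, vcf, bp)
  names(out) <- sprintf("FF_%02d", 1:14)
  out
}

# Daubechies-4 (8-tap) orthonormal analysis filters
DB4_LO <- c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
            -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965)
DB4_HI <- c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589,
            -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
            -0.0328830116668852, -0.010597401785069032)

# one periodized analysis step; the circulant [H; G] operator is orthogonal
# for Daubechies filters, so energy is conserved exactly
dwt_step <- function(x) {
  n <- length(x)
  half <- n %/% 2L
  idx0 <- 2L * (seq_len(half) - 1L)
  a <- numeric(half); d <- numeric(half)
  for (m in seq_along(DB4_LO)) {
    xi <- x[((idx0 + (m - 1L)) %% n) + 1L]
    a <- a + DB4_LO[m] * xi
    d <- d + DB4_HI[m] * xi
  }
  list(a = a, d = d)
}

#' Wavelet and wavelet-packet energy features (families WL + WLP, 23 values)
#'
#' WL (7): energies of the db4 discrete-wavelet subbands D1..D4 and A4 from a
#' 4-level decomposition, total energy, and the Shannon entropy of the
#' relative subband energies. WLP (16): absolute and relative energies of the
#' 8 terminal nodes of a 3-level db4 wavelet-packet decomposition. The
#' analysis length is the largest multiple of 16 so periodization is exactly
#' orthogonal.
#'
#' @param signal a [channel_signal()] or numeric vector.
#' @return named numeric vector of length 23 (`WL_01`..`WL_07`,
#'   `WLP_01`..`WLP_16`).
#' @export
wavelet_features <- function(signal) {
  x <- signal_values(signal)
  if (length(x) < 128) stop("wavelet features need >= 128 samples")
  n <- (length(x) %/% 16L) * 16L
  x <- x[seq_len(n)]
  # 4-level DWT
  det_energy <- numeric(4)
  a <- x
  for (lev in 1:4) {
    st <- dwt_step(a)
    det_energy[lev] <- sum(st$d^2)
    a <- st$a
  }
  a4_energy <- sum(a^2)
  bands <- c(det_energy, a4_energy)         # D1..D4, A4
  total <- sum(bands)
  rel <- bands / total
  went <- -sum(ifelse(rel > 0, rel * log(rel), 0))
  wl <- c(bands, total, went)
  # 3-level wavelet packet: full binary split, natural order
  nodes <- list(x)
  for (lev in 1:3) {
    nodes <- unlist(lapply(nodes, function(v) {
      st <- dwt_step(v)
      list(st$a, st$d)
    }), recursive = FALSE)
  }
  pe <- vapply(nodes, function(v) sum(v^2), numeric(1))
  wlp <- c(pe, pe / sum(pe))
  out <- c(wl, wlp)
  names(out) <- c(sprintf("WL_%02d", 1:7), sprintf("WLP_%02d", 1:16))
  out
}

#' Autoregressive coefficients (family AR, 14 values)
#'
#' Coefficients of an order-14 AR model fitted by the Burg method, sign
#' convention `x_t ~ sum_k a_k x_(t-k)`.
#'
#' @param signal a [channel_signal()] or numeric vector.
#' @param order model order (default 14).
#' @return named numeric vector of length `order` (`AR_01`..).
#' @export
ar_features <- function(signal, order = 14) {
  x <- signal_values(signal)
  if (length(x) <= 10 * order)
    stop("AR features need more than ", 10 * order, " samples")
  if (sd(x) == 0) stop("zero-variance input")
  fit <- stats::ar(x, aic = FALSE, order.max = order, method = "burg",
                   demean = TRUE)
  out <- as.numeric(fit$ar)
  names(out) <- sprintf("AR_%02d", seq_len(order))
  out
}

#' Sample entropy (family EY, 1 value)
#'
#' Negative log conditional probability that templates similar at length `m`
#' (Chebyshev distance within `r`) remain similar at length `m + 1`;
#' self-matches excluded. Zero-variance input returns 0 by convention; if a
#' template-match count is zero the value is capped at `log(N - m)`.
#'
#' @param signal a [channel_signal()] or numeric vector.
#' @param m embedding dimension.
#' @param r_factor tolerance as a multiple of the signal SD (the SD of the
#'   analysed window).
#' @param max_n analysis-window cap: longer signals are analysed on their
#'   central `max_n` samples, the usual practice for this quadratic-cost
#'   statistic.
#' @return named numeric scalar `EY_01`.
#' @export
sample_entropy <- function(signal, m = 2, r_factor = 0.2, max_n = 2000L) {
  x <- signal_values(signal)
  if (length(x) < 100) stop("sample entropy needs >= 100 samples")
  if (length(x) > max_n) {
    start <- (length(x) - max_n) %/% 2L
    x <- x[start + seq_len(max_n)]
  }
  s <- sd(x)
  val <- if (s == 0) 0 else sampen_cpp(x, as.integer(m), r_factor * s)
  c(EY_01 = val)
}

# accept either a channel_signal or a bare numeric vector
signal_values <- function(signal) {
  if (inherits(signal, "channel_signal")) signal$values else as.numeric(signal)
}

signal_fs <- function(signal) {
  if (inherits(signal, "channel_signal")) signal$fs
  else stop("fs must be given for a bare numeric signal")
}

#' All 63 features of one channel
#'
#' @param signal a [channel_signal()].
#' @param fs sampling rate override.
#' @return named numeric vector of length 63 (TF, FF, WL, WLP, AR, EY order).
#' @export
channel_features <- function(signal, fs = NULL) {
  c(time_domain_features(signal),
    frequency_domain_features(signal, fs = fs),
    wavelet_features(signal),
    ar_features(signal),
    sample_entropy(signal))
}
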
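# Shared signal-processing primitives: analytic signal, FFT resampling,
# spectrally shaped (1/f) noise, centered moving average.

#' Analytic signal via the frequency domain
#'
#' Complex extension of a real series whose modulus is the instantaneous
#' amplitude (Hilbert envelope) and whose argument is the instantaneous
#' phase. Computed by zeroing negative frequencies and doubling positive
#' ones in the FFT.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) return(complex(real = x, imaginary = 0))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

fft_resample_core <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- fft(x)
  Y <- complex(length.out = n_out)
  K <- min(n, n_out)
  kpos <- ceiling(K / 2)
  Y[seq_len(kpos)] <- X[seq_len(kpos)]
  kneg <- K - kpos
  if (kneg > 0)
    Y[(n_out - kneg + 1):n_out] <- X[(n - kneg + 1):n]
  Re(fft(Y, inverse = TRUE)) / n
}

#' Anti-aliased resampling of a uniformly sampled series
#'
#' FFT-domain resampling (spectrum truncation): content below the output
#' Nyquist is preserved essentially exactly, content above is removed.
#' The series is reflection-padded so that the rational rate ratio maps
#' onto an integer number of output samples; output sample `k` sits at
#' time `k / rate_out` exactly. Event times expressed in seconds are
#' unaffected by resampling.
#'
#' @param x numeric vector.
#' @param rate_in,rate_out input/output sampling rates in Hz (integer Hz;
#'   `rate_out <= rate_in`).
#' @return numeric vector of `floor(length(x) * rate_out / rate_in)`
#'   samples (at least covering the original duration minus one sample).
#' @export
resample_signal <- function(x, rate_in, rate_out) {
  if (rate_out > rate_in)
    stop("upsampling (rate_out > rate_in) is unsupported", call. = FALSE)
  if (rate_out == rate_in) return(x)
  p <- as.integer(round(rate_out))
  q <- as.integer(round(rate_in))
  g <- gcd_int(p, q)
  p <- p %/% g; q <- q %/% g
  n <- length(x)
  n_pad <- as.integer(ceiling(n / q) * q)
  if (n_pad > n) {
    extra <- n_pad - n
    tail_ref <- x[n - seq_len(min(extra, n - 1))]  # reflected continuation
    pad <- rep(tail_ref, length.out = extra)
    xp <- c(x, pad)
  } else xp <- x
  y <- fft_resample_core(xp, n_pad %/% q * p)
  m <- (n * p) %/% q
  if ((n * p) %% q != 0) m <- m + 1L
  y[seq_len(min(m, length(y)))]
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Spectrally shaped background noise
#'
#' Gaussian white noise shaped in the frequency domain so that power
#' falls off as `1/f^exponent` (pink noise for exponent 1), the standard
#' stand-in for broadband electrophysiological background. The DC bin is
#' zeroed and the series is standardized to unit variance.
#'
#' @param n number of samples.
#' @param rate sampling rate in Hz.
#' @param exponent spectral slope of the power spectrum (>= 0).
#' @return numeric vector of length `n`, mean ~0, sd 1.
#' @export
one_over_f_noise <- function(n, rate, exponent = 1) {
  w <- rnorm(n)
  if (exponent == 0) return(w)
  X <- fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * rate / n
  scale <- c(0, f[-1]^(-exponent / 2))
  y <- Re(fft(X * scale, inverse = TRUE)) / n
  (y - mean(y)) / sd(y)
}

#' Centered moving average
#'
#' @param x numeric vector.
#' @param w window length in samples (>= 1).
#' @return numeric vector of the same length; edges are computed on a
#'   reflection-padded extension so no values are lost.
#' @export
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  half <- w %/% 2
  n <- length(x)
  left <- x[pmin(half:1 + 1, n)]
  right <- x[pmax(n - (1:half), 1)]
  xp <- c(left, x, right)
  cs <- c(0, cumsum(xp))
  # output j averages xp[j .. j + w - 1] = x[j - half .. j + half - 1]
  (cs[(w + 1):(w + n)] - cs[1:n]) / w
}

# Gaussian envelope with a given full width at half maximum (seconds).
gaussian_envelope <- function(t, center, fwhm) {
  exp(-4 * log(2) * (t - center)^2 / fwhm^2)
}
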
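# Filter design and zero-phase application.
#
# No DSP dependency is assumed: the broadband band-pass is a Hamming
# windowed-sinc FIR applied as a centered (zero-phase) convolution; the notch
# and the per-band filters are IIR (biquad notch, Butterworth band-pass)
# applied forward-backward. Contracts are on the magnitude response, not on
# matching any particular toolbox's coefficients.

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

# linear-phase FIR band-pass via difference of windowed-sinc low-passes
fir_bandpass_kernel <- function(low_hz, high_hz, rate_hz,
                                transition_hz = 0.5 * low_hz) {
  ntaps <- ceiling(3.3 * rate_hz / transition_hz)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  m <- (ntaps - 1) / 2
  k <- seq(-m, m)
  lp <- function(fc) 2 * fc / rate_hz * sinc(2 * fc / rate_hz * k)
  # cutoffs at band-edge +- half transition keep the stated edges in-band
  h <- lp(min(high_hz + transition_hz / 2, rate_hz / 2 * 0.999)) -
    lp(max(low_hz - transition_hz / 2, transition_hz / 4))
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, ntaps - 1) / (ntaps - 1))
  h * w
}

# centered convolution (zero phase for a symmetric kernel), FFT-based,
# edges handled by odd reflection
fir_apply <- function(x, h) {
  n <- length(x)
  m <- (length(h) - 1) / 2
  p <- min(m, n - 1)
  left <- 2 * x[1] - x[seq(p + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - p)]
  xp <- c(left, x, right)
  L <- length(xp) + length(h) - 1
  nfft <- stats::nextn(L, 2)
  y <- Re(fft(fft(c(xp, rep(0, nfft - length(xp)))) *
              fft(c(h, rep(0, nfft - length(h)))), inverse = TRUE)) / nfft
  y[(m + p + 1):(m + p + n)]
}

# direct-form ARMA filter, zero initial conditions (C-backed via stats::filter)
filter_arma <- function(b, a, x) {
  stopifnot(abs(a[1] - 1) < 1e-12)
  p <- length(b)
  v <- stats::filter(c(rep(0, p - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[p:(p + length(x) - 1)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# forward-backward (zero-phase) IIR filtering with odd-reflection padding
filtfilt <- function(b, a, x) {
  n <- length(x)
  padlen <- min(3 * (max(length(a), length(b)) - 1) * 10, n - 1)
  left <- 2 * x[1] - x[seq(padlen + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  xp <- c(left, x, right)
  y <- filter_arma(b, a, xp)
  y <- rev(filter_arma(b, a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

# expand polynomial from complex roots; returns real coefficients
poly_from_roots <- function(r) {
  p <- 1
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  re <- Re(p)
  if (max(abs(Im(p))) > 1e-6 * max(abs(re), 1)) {
    stop("polynomial roots are not conjugate-symmetric")
  }
  re
}

#' Butterworth band-pass filter design
#'
#' Digital Butterworth band-pass via the analog prototype, band transform and
#' bilinear transform, normalized to unit gain at the geometric center
#' frequency.
#'
#' @param order analog prototype order (the band-pass has `2*order` poles)
#' @param low_hz,high_hz band edges in Hz
#' @param rate_hz sampling rate in Hz
#' @return list with numerator `b` and denominator `a`
#' @export
butter_bandpass <- function(order, low_hz, high_hz, rate_hz) {
  stopifnot(low_hz > 0, low_hz < high_hz, high_hz < rate_hz / 2)
  fs2 <- 2 * rate_hz
  w1 <- fs2 * tan(pi * low_hz / rate_hz)
  w2 <- fs2 * tan(pi * high_hz / rate_hz)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # low-pass -> band-pass: each prototype pole p maps to the two roots of
  # s^2 - p*bw*s + w0^2 = 0
  pb <- proto * bw
  disc <- sqrt(pb^2 / 4 - w0^2 + 0i)
  s_poles <- c(pb / 2 + disc, pb / 2 - disc)
  z_poles <- (fs2 + s_poles) / (fs2 - s_poles)
  z_zeros <- c(rep(1 + 0i, order), rep(-1 + 0i, order))
  b <- poly_from_roots(z_zeros)
  a <- poly_from_roots(z_poles)
  a <- a / a[1]
  b <- b / a[1]
  wc <- 2 * pi * sqrt(low_hz * high_hz) / rate_hz
  g <- freq_response(b, a, wc)
  list(b = b / Mod(g), a = a)
}

#' Biquad notch filter design
#'
#' Second-order IIR notch with a zero pair on the unit circle at the center
#' frequency and bandwidth `high_hz - low_hz`.
#'
#' @inheritParams butter_bandpass
#' @export
biquad_notch <- function(low_hz, high_hz, rate_hz) {
  stopifnot(low_hz > 0, low_hz < high_hz, high_hz < rate_hz / 2)
  f0 <- (low_hz + high_hz) / 2
  bw <- high_hz - low_hz
  w0 <- 2 * pi * f0 / rate_hz
  q <- f0 / bw
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

freq_response <- function(b, a, w) {
  z <- exp(-1i * w * seq(0, max(length(a), length(b)) - 1))
  sum(b * z[seq_along(b)]) / sum(a * z[seq_along(a)])
}
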
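# Independent brute-force oracles used against the package implementations.
# These are deliberately naive (double loops, direct formulas) and share no
# code with the package internals.

oracle_sampen <- function(x, m, r) {
  N <- length(x)
  n <- N - m
  A <- 0; B <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A > 0 && B > 0) -log(A / B) else NA_real_
}

oracle_apen <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    n <- N - mm + 1
    cs <- vapply(seq_len(n), function(i) {
      cnt <- 0
      for (j in seq_len(n)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) {
          cnt <- cnt + 1
        }
      }
      cnt / n
    }, numeric(1))
    mean(log(cs))
  }
  phi(m) - phi(m + 1)
}

oracle_corr_sum <- function(pts, rs) {
  M <- nrow(pts)
  cnt <- numeric(length(rs))
  for (i in seq_len(M - 1)) {
    for (j in seq(i + 1, M)) {
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      cnt <- cnt + (d < rs)
    }
  }
  cnt / (M * (M - 1) / 2)
}

oracle_autocorr_lag <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  a <- vapply(0:(n - 2), function(k) {
    sum(xc[seq_len(n - k)] * xc[seq_len(n - k) + k]) / denom
  }, numeric(1))
  for (k in 2:(length(a) - 1)) {
    if (a[k] < a[k - 1] && a[k] < a[k + 1]) return(k - 1L)
  }
  zc <- which(a < 0)
  if (length(zc)) return(zc[1] - 1L)
  max(1L, n %/% 10L)
}

# rejection criteria recomputed from the definition
oracle_reject <- function(ep, abs_uV, prob_z) {
  d <- dim(ep$data)
  extreme <- vapply(seq_len(d[1]), function(t) {
    any(abs(ep$data[t, , ]) > abs_uV)
  }, logical(1))
  ll <- rep(0, d[1])
  for (c in seq_len(d[2])) {
    vals <- ep$data[, c, ]
    mu <- mean(vals); s <- sd(as.vector(vals))
    if (s == 0) next
    for (t in seq_len(d[1])) {
      ll[t] <- ll[t] + sum(dnorm(ep$data[t, c, ], mu, s, log = TRUE))
    }
  }
  s_ll <- sd(ll)
  improb <- if (is.na(s_ll) || s_ll == 0) rep(FALSE, d[1]) else
    abs(ll - mean(ll)) > prob_z * s_ll
  extreme | improb
}

# single-sided periodogram band power of one series
oracle_band_power <- function(x, rate_hz, low_hz, high_hz) {
  n <- length(x)
  p <- abs(fft(x))^2 / n
  f <- (seq_len(n) - 1) * rate_hz / n
  sum(p[f >= low_hz & f <= high_hz])
}

# spectral amplitude of a sinusoid component
oracle_peak_amp <- function(x, rate_hz, f_hz) {
  n <- length(x)
  k <- round(f_hz * n / rate_hz)
  2 * Mod(fft(x))[k + 1] / n
}

# tiny epoch_set constructor for feature/preprocess tests
make_epochs <- function(data, rate_hz, window_start_ms,
                        condition = rep("happy", dim(data)[1])) {
  structure(list(
    data = data, rate_hz = rate_hz,
    window = c(window_start_ms,
               window_start_ms + dim(data)[3] / rate_hz * 1000),
    condition = condition, rejected = rep(FALSE, dim(data)[1]),
    events = NULL, montage = NULL), class = "epoch_set")
}
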
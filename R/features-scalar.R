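# Time/frequency-domain features and regularity statistics on the scalar
# series. Summary conventions (documented interpretations): envelope is the
# mean magnitude of the analytic signal, Teager energy the mean of the
# Teager-Kaiser operator psi[n] = x[n]^2 - x[n-1] x[n+1], instantaneous
# power the mean squared amplitude.

# analytic signal via FFT (one-sided spectrum doubling)
analytic_signal <- function(x) {
  n <- length(x)
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

#' Scalar signal features
#'
#' `feat_envelope`: mean magnitude of the analytic (Hilbert) signal.
#' `feat_teager`: mean Teager-Kaiser energy
#' `psi[n] = x[n]^2 - x[n-1] x[n+1]` over the valid interior samples.
#' `feat_power`: mean instantaneous power `mean(x^2)`.
#'
#' @param x numeric series (length >= 3)
#' @return scalar feature value
#' @export
feat_envelope <- function(x) {
  stopifnot(length(x) >= 3)
  mean(Mod(analytic_signal(x)))
}

#' @rdname feat_envelope
#' @export
feat_teager <- function(x) {
  n <- length(x)
  if (n < 3) stop("Teager energy needs at least 3 samples")
  i <- 2:(n - 1)
  mean(x[i]^2 - x[i - 1] * x[i + 1])
}

#' @rdname feat_envelope
#' @export
feat_power <- function(x) {
  stopifnot(length(x) >= 3)
  mean(x^2)
}

#' Approximate and sample entropy
#'
#' Regularity statistics counting Chebyshev template matches of length `m`
#' (and `m+1`) within tolerance `r * sd(x)`. Approximate entropy includes
#' self-matches (Pincus); sample entropy excludes them (Richman-Moorman) and
#' is `NA` (documented sentinel) when no template pair matches.
#'
#' @param x numeric series, length >= 10*m
#' @param m template length (default 2)
#' @param r tolerance as a multiple of `sd(x)` (default 0.2)
#' @return scalar entropy (nats); `feat_sampen` is `NA` if undefined
#' @export
feat_apen <- function(x, m = 2L, r = 0.2) {
  check_entropy_args(x, m, r)
  cpp_apen(as.numeric(x), as.integer(m), r * sd(x))
}

#' @rdname feat_apen
#' @export
feat_sampen <- function(x, m = 2L, r = 0.2) {
  check_entropy_args(x, m, r)
  cpp_sampen(as.numeric(x), as.integer(m), r * sd(x))[1]
}

check_entropy_args <- function(x, m, r) {
  if (length(x) < 10 * m) {
    stop("entropy needs at least 10*m samples")
  }
  if (r <= 0) stop("tolerance r must be > 0")
  if (sd(x) == 0) stop("constant signal: entropy tolerance r*sd(x) is zero")
  invisible(TRUE)
}
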
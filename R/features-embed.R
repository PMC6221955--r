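# Time-delay phase-space reconstruction.

#' Embedding lag from the autocorrelation's first local minimum
#'
#' Returns the smallest lag `k >= 1` with `acf(k) < acf(k-1)` and
#' `acf(k) < acf(k+1)`. If no local minimum exists the fallback is the first
#' zero crossing of the acf, else `floor(length(x)/10)` (at least 1).
#'
#' @param x numeric series (length >= 3)
#' @return integer lag in samples
#' @export
autocorr_lag <- function(x) {
  n <- length(x)
  stopifnot(n >= 3)
  if (sd(x) == 0) {
    warning("constant signal: autocorrelation undefined, using fallback lag")
    return(max(1L, n %/% 10L))
  }
  a <- as.numeric(acf(x, lag.max = n - 2, plot = FALSE, demean = TRUE)$acf)
  # a[1] = lag 0
  for (k in 2:(length(a) - 1)) {
    if (a[k] < a[k - 1] && a[k] < a[k + 1]) return(k - 1L)
  }
  zc <- which(a < 0)
  if (length(zc)) return(zc[1] - 1L)
  max(1L, n %/% 10L)
}

#' Time-delay embedding
#'
#' Maps a scalar series into delay vectors
#' `X(t_i) = [x(t_i), x(t_i + tau), ..., x(t_i + (m-1) tau)]`,
#' giving `M = N - (m-1) tau` phase-space points.
#'
#' @param x numeric series of length N
#' @param m embedding dimension
#' @param tau delay in samples
#' @return an `embedding`: `$points` (M x m matrix), `$m`, `$tau`, `$N`, `$M`
#' @export
embed_delay <- function(x, m, tau) {
  n <- length(x)
  need <- (m - 1) * tau + 1
  if (n < need) {
    stop(sprintf("series too short for embedding: need at least %d samples, got %d",
                 need, n))
  }
  M <- n - (m - 1) * tau
  pts <- vapply(seq_len(m) - 1L, function(j) x[seq_len(M) + j * tau],
                numeric(M))
  if (M == 1) pts <- matrix(pts, nrow = 1)
  structure(list(points = pts, m = m, tau = as.integer(tau), N = n, M = M),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> m=%d tau=%d: %d points from %d samples\n",
              x$m, x$tau, x$M, x$N))
  invisible(x)
}
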
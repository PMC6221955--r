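# Phase-space (embedding-based) features: spatial filling index, largest
# Lyapunov exponent (Rosenstein nearest-neighbor divergence), correlation
# dimension (Grassberger-Procaccia).

#' Spatial filling index of a 2-D phase portrait
#'
#' The trajectory is min-max normalized to the unit square per axis and
#' binned on a `grid x grid` lattice; with occupancy fractions `p_ij`,
#' `SFI = sum(p_ij^2) / grid^2`. Concentrated trajectories give larger
#' values (a single occupied cell gives `1/grid^2`, exactly uniform
#' occupancy `1/grid^4`).
#'
#' @param emb an `embedding` with `m = 2`
#' @param grid lattice size per axis (default 10)
#' @return scalar SFI
#' @export
feat_sfi <- function(emb, grid = 10L) {
  stopifnot(inherits(emb, "embedding"), emb$m == 2, emb$M >= 2)
  pts <- emb$points
  degenerate <- FALSE
  norm_axis <- function(v) {
    rg <- range(v)
    if (rg[2] == rg[1]) {
      degenerate <<- TRUE
      return(rep(0, length(v)))
    }
    (v - rg[1]) / (rg[2] - rg[1])
  }
  u <- norm_axis(pts[, 1])
  v <- norm_axis(pts[, 2])
  if (degenerate) warning("degenerate embedding axis (zero range) in SFI")
  ix <- pmin(grid, floor(u * grid) + 1L)
  iy <- pmin(grid, floor(v * grid) + 1L)
  p <- tabulate(ix + (iy - 1L) * grid, nbins = grid * grid) / emb$M
  sum(p^2) / grid^2
}

#' Largest Lyapunov exponent (Rosenstein method)
#'
#' For every phase-space point the nearest neighbor outside a Theiler
#' exclusion window is found; the mean log divergence of the pairs is
#' tracked over `fit_steps` forward steps and the exponent is the slope of
#' that curve, in nats per sample (multiply by the sampling rate for
#' nats/second).
#'
#' @param emb an `embedding` with `m = 3` and at least 50 points
#' @param rate_hz if given, the estimate is returned in nats/second
#' @param fit_steps integer steps of the divergence curve used for the
#'   linear fit. The default (1:6) skips step 0: nearest-neighbor selection
#'   biases the initial separation low, which would inflate the slope on
#'   regular signals.
#' @param theiler temporal exclusion window (default `max(tau, 1)`)
#' @return scalar exponent estimate
#' @export
feat_lyapunov <- function(emb, rate_hz = NULL, fit_steps = 1:6,
                          theiler = NULL) {
  stopifnot(inherits(emb, "embedding"), emb$m == 3)
  if (emb$M < 50) stop("Lyapunov estimate needs at least 50 embedded points")
  if (is.null(theiler)) theiler <- max(emb$tau, 1L)
  diameter <- sqrt(sum((apply(emb$points, 2, max) -
                        apply(emb$points, 2, min))^2))
  curve <- cpp_rosenstein(emb$points, as.integer(theiler),
                          as.integer(max(fit_steps)),
                          1e-10 * max(diameter, .Machine$double.eps))
  k <- fit_steps
  y <- curve[k + 1]
  ok <- is.finite(y)
  # all neighbor pairs at round-off separation: numerically periodic orbit
  if (!any(ok)) return(0)
  if (sum(ok) < 2) stop("divergence curve degenerate")
  slope <- slope_fit(k[ok], y[ok])
  if (!is.null(rate_hz)) slope <- slope * rate_hz
  unname(slope)
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Correlation sums `C(r) = 2/(M(M-1)) #\{i<j: ||Xi - Xj|| < r\}` are
#' evaluated on a log-spaced radius grid between the 5th and 50th
#' percentile of pairwise distances; the dimension is the slope of
#' `log C(r)` versus `log r` over that scaling region.
#'
#' @param emb an `embedding` (typically `m = 3`) with at least 100 points
#' @param n_r number of radii (default 10)
#' @param max_points embeddings with more points are thinned evenly to this
#'   size before pair counting (default 250)
#' @return scalar dimension estimate
#' @export
feat_corrdim <- function(emb, n_r = 10L, max_points = 250L) {
  stopifnot(inherits(emb, "embedding"))
  if (emb$M < 100) stop("correlation dimension needs at least 100 points")
  pts <- emb$points
  if (emb$M > max_points) {
    pts <- pts[round(seq(1, emb$M, length.out = max_points)), , drop = FALSE]
  }
  dists <- as.numeric(stats::dist(pts))
  qs <- quantile(dists[dists > 0], c(0.05, 0.5))
  if (!all(is.finite(qs)) || qs[1] <= 0 || qs[2] <= qs[1]) {
    stop("degenerate pairwise distances: cannot form a scaling region")
  }
  rs <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_r))
  cr <- cpp_corr_sum(pts, rs)
  ok <- cr > 0
  if (sum(ok) < 2) stop("correlation sums vanish over the scaling region")
  slope_fit(log(rs[ok]), log(cr[ok]))
}

# least-squares slope without model-frame overhead
slope_fit <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}
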
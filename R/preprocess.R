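# Offline preprocessing: filtering, referencing, epoching, bad-epoch
# rejection, baseline correction and ERP averaging. All filters are applied
# zero-phase (symmetric FIR, or forward-backward IIR): this is offline
# analysis and latency-sensitive features must not be phase-shifted.

#' Zero-phase FIR band-pass filter of a recording
#'
#' Hamming windowed-sinc band-pass, default 1-100 Hz.
#'
#' @param rec a `recording`
#' @param low_hz,high_hz band edges (Hz); defaults 1 and 100
#' @return filtered `recording`
#' @export
bandpass <- function(rec, low_hz = 1, high_hz = 100) {
  nyq <- rec$rate_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("band edges must satisfy 0 < low < high < rate/2")
  }
  h <- fir_bandpass_kernel(low_hz, high_hz, rec$rate_hz)
  apply_channels(rec, function(x) fir_apply(x, h))
}

#' Zero-phase IIR notch filter (power-line interference)
#'
#' Biquad notch applied forward-backward; default stopband 47.5-52.5 Hz.
#'
#' @inheritParams bandpass
#' @export
notch <- function(rec, low_hz = 47.5, high_hz = 52.5) {
  nyq <- rec$rate_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("band edges must satisfy 0 < low < high < rate/2")
  }
  ba <- biquad_notch(low_hz, high_hz, rec$rate_hz)
  apply_channels(rec, function(x) filtfilt(ba$b, ba$a, x))
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean over good channels from every
#' channel. Pairwise channel differences are preserved exactly.
#'
#' @param rec a `recording`
#' @export
rereference_average <- function(rec) {
  good <- good_channels(rec)
  if (length(good) < 2) stop("average reference needs at least 2 good channels")
  ref <- colMeans(rec$data[good, , drop = FALSE])
  out <- rec
  out$data <- sweep(rec$data, 2, ref)
  out
}

#' Identity hook for component-based artifact removal
#'
#' Placeholder for an ICA-style artifact-removal stage. The default is the
#' identity; supply `fun(data, rate_hz)` returning a cleaned channels x
#' samples matrix to plug in an external decomposition.
#'
#' @param rec a `recording`
#' @param fun optional cleaning function
#' @export
remove_artifact_components <- function(rec, fun = NULL) {
  if (is.null(fun)) return(rec)
  out <- rec
  out$data <- fun(rec$data, rec$rate_hz)
  stopifnot(identical(dim(out$data), dim(rec$data)))
  dimnames(out$data) <- dimnames(rec$data)
  out
}

#' Epoch a recording around events
#'
#' Cuts one trial per event whose label matches `lock_label`, with a
#' half-open window `[start_ms, end_ms)` relative to the event onset.
#' Sample indices are rounded to the nearest sample (ties toward +Inf).
#' Events whose window exceeds the recording bounds are dropped with a
#' warning.
#'
#' @param rec a `recording`
#' @param lock_label event label to lock to
#' @param start_ms,end_ms window in ms relative to the event (start < end)
#' @return An `epoch_set`: `$data` trials x channels x samples array,
#'   `$window`, `$rate_hz`, `$condition` per trial, `$rejected` logical mask.
#' @export
epoch <- function(rec, lock_label, start_ms, end_ms) {
  stopifnot(start_ms < end_ms)
  ev <- rec$events[rec$events$label == lock_label, , drop = FALSE]
  rate <- rec$rate_hz
  nsamp <- round(end_ms * rate / 1000) - round(start_ms * rate / 1000)
  nch <- nrow(rec$data)
  first <- ev$sample + round(start_ms * rate / 1000)
  last <- first + nsamp - 1
  ok <- first >= 1 & last <= ncol(rec$data)
  if (any(!ok)) {
    warning(sprintf("dropping %d epoch(s) exceeding recording bounds",
                    sum(!ok)))
    ev <- ev[ok, , drop = FALSE]
    first <- first[ok]
  }
  n <- nrow(ev)
  data <- array(0, dim = c(n, nch, nsamp),
                dimnames = list(NULL, rownames(rec$data), NULL))
  for (i in seq_len(n)) {
    data[i, , ] <- rec$data[, first[i]:(first[i] + nsamp - 1)]
  }
  structure(list(data = data, window = c(start_ms, end_ms), rate_hz = rate,
                 condition = if (n) ev$condition else character(),
                 events = ev, rejected = rep(FALSE, n),
                 montage = rec$montage),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d ch x %d samples, window [%g, %g) ms, %d rejected\n",
              d[1], d[2], d[3], x$window[1], x$window[2], sum(x$rejected)))
  invisible(x)
}

# per-trial joint log-likelihood under per-channel normal fits pooled
# across trials (a transparent stand-in for histogram-based joint
# probability rejection)
epoch_logprob <- function(ep) {
  d <- dim(ep$data)
  ll <- numeric(d[1])
  for (c in seq_len(d[2])) {
    x <- ep$data[, c, , drop = FALSE]
    mu <- mean(x)
    s <- sd(as.vector(x))
    if (s == 0) next
    ll <- ll + apply(ep$data[, c, , drop = FALSE], 1, function(v) {
      sum(stats::dnorm(v, mu, s, log = TRUE))
    })
  }
  ll
}

#' Semi-automatic bad-epoch rejection
#'
#' Flags a trial if any sample exceeds `abs_uV` in absolute value, or if its
#' joint log-probability (per-channel amplitude-distribution estimate pooled
#' across trials) deviates from the across-trial mean by more than `prob_z`
#' standard deviations. Data are preserved; only the rejection mask changes.
#'
#' @param ep an `epoch_set`
#' @param abs_uV absolute amplitude threshold in microvolts (default 100)
#' @param prob_z z-threshold on the joint log-probability (default 5)
#' @export
reject_bad_epochs <- function(ep, abs_uV = 100, prob_z = 5) {
  stopifnot(abs_uV > 0, prob_z > 0)
  n <- dim(ep$data)[1]
  if (n == 0) return(ep)
  extreme <- apply(ep$data, 1, function(tr) max(abs(tr)) > abs_uV)
  ll <- epoch_logprob(ep)
  s <- sd(ll)
  improbable <- if (is.na(s) || s == 0) rep(FALSE, n) else
    abs(ll - mean(ll)) > prob_z * s
  ep$rejected <- ep$rejected | extreme | improbable
  ep
}

#' Baseline correction
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' `[base_start_ms, base_end_ms)` (relative to the locking event).
#'
#' @param ep an `epoch_set`
#' @param base_start_ms,base_end_ms baseline window in ms; must lie within
#'   the epoch window
#' @export
baseline_correct <- function(ep, base_start_ms, base_end_ms) {
  idx <- window_indices(ep, base_start_ms, base_end_ms)
  if (length(idx) == 0) stop("empty baseline window")
  base <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - array(base, dim = dim(ep$data))
  ep
}

# sample indices of [start_ms, end_ms) within the epoch window
window_indices <- function(ep, start_ms, end_ms) {
  rate <- ep$rate_hz
  if (start_ms < ep$window[1] || end_ms > ep$window[2]) {
    stop("window outside epoch bounds")
  }
  off <- round(ep$window[1] * rate / 1000)
  first <- round(start_ms * rate / 1000) - off + 1
  last <- round(end_ms * rate / 1000) - off
  if (last < first) return(integer())
  seq(first, last)
}

#' Event-related potential of one condition
#'
#' Element-wise mean over the non-rejected trials of `condition`.
#'
#' @param ep an `epoch_set`
#' @param condition condition label ("happy" or "sad" for the built-in
#'   schedules)
#' @return channels x samples matrix
#' @export
compute_erp <- function(ep, condition) {
  keep <- which(!ep$rejected & ep$condition == condition)
  if (length(keep) == 0) stop("no surviving trials for condition ", condition)
  erp <- apply(ep$data[keep, , , drop = FALSE], c(2, 3), mean)
  rownames(erp) <- dimnames(ep$data)[[2]]
  erp
}
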
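# Continuous multi-channel recording container.

#' Construct a recording
#'
#' @param data channels x samples numeric matrix, in microvolts; rownames are
#'   channel labels.
#' @param rate_hz sampling rate (Hz)
#' @param montage a `montage` (see [default_montage()])
#' @param events data.frame with at least `label` and `sample` (1-based
#'   sample index of the event onset); extra columns (condition, trial, ...)
#'   are carried along.
#' @param bad_channels character vector of channel labels to exclude from
#'   referencing and analysis.
#' @return A `recording` object.
#' @export
new_recording <- function(data, rate_hz, montage, events = NULL,
                          bad_channels = character()) {
  stopifnot(is.matrix(data), rate_hz > 0)
  if (is.null(rownames(data))) rownames(data) <- montage$channels
  if (is.null(events)) {
    events <- data.frame(label = character(), sample = integer())
  }
  if (nrow(events) && (any(events$sample < 1) ||
                       any(events$sample > ncol(data)))) {
    stop("event sample indices must lie within the recording")
  }
  structure(list(data = data, rate_hz = rate_hz, montage = montage,
                 events = events, bad_channels = bad_channels),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d ch x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$rate_hz, nrow(x$events)))
  invisible(x)
}

good_channels <- function(rec) setdiff(rownames(rec$data), rec$bad_channels)

apply_channels <- function(rec, fun) {
  out <- rec
  out$data <- t(apply(rec$data, 1, fun))
  dimnames(out$data) <- dimnames(rec$data)
  out
}
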
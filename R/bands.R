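# Canonical frequency bands for all band-limited features.

#' EEG frequency bands
#'
#' The five analysis bands: theta 4-8 Hz, alpha 8-12 Hz, low beta 12-21 Hz,
#' high beta 21-30 Hz, gamma 30-40 Hz.
#'
#' @return named list of `c(low_hz, high_hz)` pairs
#' @export
eeg_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 12), low_beta = c(12, 21),
       high_beta = c(21, 30), gamma = c(30, 40))
}

band_def <- function(name) {
  bands <- eeg_bands()
  if (!name %in% names(bands)) {
    stop("unknown band '", name, "'; expected one of ",
         paste(names(bands), collapse = ", "))
  }
  bands[[name]]
}
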
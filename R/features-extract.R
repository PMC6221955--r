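# Windowed, band-limited feature extraction over an epoch set.
#
# Per (trial, channel, band, window): three time/frequency features
# (envelope, Teager energy, power) and five non-linear features (SFI on an
# m=2 embedding, Lyapunov exponent and correlation dimension on m=3
# embeddings, approximate and sample entropy on the scalar series). The
# embedding lag is the first local minimum of the window's autocorrelation,
# recomputed per band. Undefined features (too-short embeddings, no entropy
# template matches) are recorded as NA sentinels; downstream averaging
# skips them and logs the counts.

FEATURES_TF <- c("env", "teag", "pow")
FEATURES_NL <- c("sfi", "lyap", "corrdim", "apen", "sampen")
ALL_FEATURES <- c(FEATURES_TF, FEATURES_NL)

#' Zero-phase IIR band filter for one series
#'
#' Order-4 Butterworth band-pass at the band edges, applied
#' forward-backward. Order 4 keeps leakage between adjacent bands (which
#' share an edge, e.g. theta/alpha at 8 Hz) small.
#'
#' @param x numeric series
#' @param band band name (see [eeg_bands()]) or `c(low_hz, high_hz)`
#' @param rate_hz sampling rate
#' @param order Butterworth prototype order (default 4)
#' @return filtered series, same length
#' @export
band_filter <- function(x, band, rate_hz, order = 4L) {
  edges <- if (is.character(band)) band_def(band) else band
  if (edges[2] >= rate_hz / 2) stop("band exceeds the Nyquist frequency")
  ba <- butter_bandpass(order, edges[1], edges[2], rate_hz)
  filtfilt(ba$b, ba$a, x)
}

#' Feature windows of the imagery paradigm
#'
#' Window bounds in ms relative to the instruction onset (the epoch-locking
#' event): baseline is the 500 ms before the instruction; the emotion and
#' neutral windows run from 500 ms to 3500 ms after the imagery and neutral
#' cues respectively.
#'
#' @param segments named segment durations (ms) of an imagery trial
#' @param pad_ms,len_ms window start offset after the cue and window length
#' @return named list of `c(start_ms, end_ms)` windows
#' @export
imagery_feature_windows <- function(segments = IMAGERY_SEGMENTS,
                                    pad_ms = 500, len_ms = 3000) {
  imagery_on <- unname(segments[["instruction"]] + segments[["preparation"]])
  neutral_on <- imagery_on + unname(segments[["imagery"]])
  list(baseline = c(-500, 0),
       emotion = imagery_on + c(pad_ms, pad_ms + len_ms),
       neutral = neutral_on + c(pad_ms, pad_ms + len_ms))
}

features_of_window <- function(x, rate_hz, sfi_grid = 10L) {
  out <- c(env = feat_envelope(x), teag = feat_teager(x),
           pow = feat_power(x),
           sfi = NA_real_, lyap = NA_real_, corrdim = NA_real_,
           apen = NA_real_, sampen = NA_real_)
  if (sd(x) == 0) return(out)
  tau <- suppressWarnings(autocorr_lag(x))
  n <- length(x)
  if (n - tau >= 2) {
    out["sfi"] <- feat_sfi(embed_delay(x, 2L, tau), grid = sfi_grid)
  }
  if (n - 2 * tau >= 100) {
    e3 <- embed_delay(x, 3L, tau)
    out["lyap"] <- tryCatch(feat_lyapunov(e3), error = function(e) NA_real_)
    out["corrdim"] <- tryCatch(feat_corrdim(e3), error = function(e) NA_real_)
  }
  if (n >= 20) {
    out["apen"] <- cpp_apen(x, 2L, 0.2 * sd(x))
    out["sampen"] <- cpp_sampen(x, 2L, 0.2 * sd(x))[1]
  }
  out
}

#' Extract all windowed band-limited features
#'
#' For every non-rejected trial, channel, band and window, computes the 8
#' features on the band-filtered window. The whole epoch is band-filtered
#' once per (trial, channel, band) and the windows are sliced from the
#' filtered series, so window edges do not interact with filter edges.
#'
#' @param ep an `epoch_set` locked to the instruction onset
#' @param montage montage (used for channel labels)
#' @param bands named list of band edges (default [eeg_bands()])
#' @param windows named list of `c(start_ms, end_ms)` windows relative to
#'   the locking event (default [imagery_feature_windows()])
#' @param channels channel subset (default: all channels in the epoch set)
#' @param sfi_grid lattice size for the spatial filling index
#' @return a `windowed_features` [data.table::data.table] with columns
#'   trial, channel, band, window, feature, value
#' @export
extract_all <- function(ep, montage = ep$montage, bands = eeg_bands(),
                        windows = imagery_feature_windows(),
                        channels = NULL, sfi_grid = 10L) {
  chs <- dimnames(ep$data)[[2]]
  if (!is.null(channels)) chs <- intersect(chs, channels)
  trials <- which(!ep$rejected)
  idx <- lapply(windows, function(w) window_indices(ep, w[1], w[2]))
  rate <- ep$rate_hz
  nfeat <- length(ALL_FEATURES)
  res <- vector("list", length(trials) * length(chs) * length(bands))
  k <- 0L
  for (tr in trials) {
    for (ch in chs) {
      series <- ep$data[tr, ch, ]
      for (bn in names(bands)) {
        filtered <- band_filter(series, bands[[bn]], rate)
        vals <- lapply(names(windows), function(wn) {
          features_of_window(filtered[idx[[wn]]], rate, sfi_grid)
        })
        k <- k + 1L
        res[[k]] <- data.table::data.table(
          trial = tr, channel = ch, band = bn,
          window = rep(names(windows), each = nfeat),
          feature = rep(ALL_FEATURES, times = length(windows)),
          value = unlist(vals, use.names = FALSE))
      }
    }
  }
  wf <- data.table::rbindlist(res)
  data.table::setattr(wf, "class",
                      c("windowed_features", class(wf)))
  data.table::setattr(wf, "normalized", FALSE)
  wf[]
}

#' Baseline-normalize the time/frequency features
#'
#' Replaces the envelope, Teager-energy and power values of the emotion and
#' neutral windows by their difference from the same feature in the baseline
#' window of the same (trial, channel, band). Non-linear features keep their
#' absolute values, bit-exactly.
#'
#' @param wf a `windowed_features` table containing a baseline window
#' @return normalized `windowed_features`
#' @export
normalize_features <- function(wf) {
  if (!"baseline" %in% wf$window) stop("baseline window missing")
  out <- data.table::copy(wf)
  base <- out[window == "baseline" & feature %in% FEATURES_TF,
              list(trial, channel, band, feature, .baseline = value)]
  out[base, .baseline := i..baseline,
      on = c("trial", "channel", "band", "feature")]
  out[window != "baseline" & feature %in% FEATURES_TF & !is.na(.baseline),
      value := value - .baseline]
  out[, .baseline := NULL]
  data.table::setattr(out, "class", class(wf))
  data.table::setattr(out, "normalized", TRUE)
  out[]
}
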
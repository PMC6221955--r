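# Synthetic two-group EEG cohorts: 1/f background plus band-limited
# oscillations plus white sensor noise, with group effects injected as
# multiplicative amplitude gains on one band's oscillation, restricted to a
# channel cluster and a trial window (emotion imagery, neutral period, or
# both). Effects are time-locked to the schedule with short raised-cosine
# ramps so gating does not inject broadband edges.

#' Cohort specification
#'
#' Describes a synthetic two-group cohort. Defaults state the emulated
#' paradigm: 17 subjects per group, 1000 Hz, pink (1/f) background of about
#' 10 uV RMS, alpha-dominant band-limited oscillations, 2 uV white sensor
#' noise, and group effects in the clinical group ("asd"): theta, high-beta
#' and gamma amplitude elevation in right parieto-occipital clusters during
#' emotion imagery.
#'
#' @param n_per_group subjects per group (>= 2)
#' @param sampling_rate_hz sampling rate; must exceed twice the highest band
#'   edge (40 Hz)
#' @param background list(exponent, amplitude_uV): 1/f^exponent spectrum,
#'   target RMS amplitude
#' @param oscillations named numeric vector: per-band oscillation RMS (uV)
#' @param group_effects list of effects, each
#'   `list(band, cluster, window = "emotion"|"neutral"|"both", gain, group)`
#' @param noise_sd white-noise SD (uV)
#' @param seed master seed; per-subject seeds are derived from it
#' @return A validated `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_group = 17L,
                        sampling_rate_hz = 1000,
                        background = list(exponent = 1, amplitude_uV = 10),
                        oscillations = c(theta = 2, alpha = 3,
                                         low_beta = 1.5, high_beta = 1,
                                         gamma = 0.8),
                        group_effects = default_group_effects(),
                        noise_sd = 2,
                        seed = 1L) {
  spec <- structure(list(n_per_group = as.integer(n_per_group),
                         sampling_rate_hz = sampling_rate_hz,
                         background = background,
                         oscillations = oscillations,
                         group_effects = group_effects,
                         noise_sd = noise_sd, seed = as.integer(seed)),
                    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' @rdname cohort_spec
#' @export
default_group_effects <- function() {
  list(list(band = "theta", cluster = "C4", window = "emotion",
            gain = 1.5, group = "asd"),
       list(band = "high_beta", cluster = "C4", window = "emotion",
            gain = 1.3, group = "asd"),
       list(band = "gamma", cluster = "C5", window = "emotion",
            gain = 1.3, group = "asd"))
}

validate_cohort_spec <- function(spec) {
  bands <- eeg_bands()
  top <- max(vapply(bands, max, numeric(1)))
  if (spec$sampling_rate_hz <= 2 * top) {
    stop("sampling_rate_hz must exceed twice the highest band edge (",
         2 * top, " Hz)")
  }
  if (spec$n_per_group < 2) stop("n_per_group must be >= 2")
  if (!all(names(spec$oscillations) %in% names(bands))) {
    stop("unknown oscillation band name")
  }
  for (ef in spec$group_effects) {
    if (!ef$band %in% names(bands)) {
      stop("group effect names unknown band '", ef$band, "'")
    }
    if (!is.numeric(ef$gain) || ef$gain <= 0) stop("gains must be > 0")
    if (!ef$window %in% c("emotion", "neutral", "both")) {
      stop("effect window must be emotion, neutral or both")
    }
  }
  invisible(spec)
}

#' Read / write a cohort specification as YAML
#'
#' @param path file path
#' @param spec a `cohort_spec`
#' @export
write_cohort_spec <- function(spec, path) {
  x <- unclass(spec)
  x$oscillations <- as.list(x$oscillations)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  cohort_spec(n_per_group = x$n_per_group,
              sampling_rate_hz = x$sampling_rate_hz,
              background = x$background,
              oscillations = unlist(x$oscillations),
              group_effects = x$group_effects,
              noise_sd = x$noise_sd,
              seed = x$seed)
}

# 1/f^alpha noise by spectral shaping of white gaussian coefficients
pink_noise <- function(n, exponent, rate_hz) {
  nf <- floor((n - 1) / 2)  # strictly positive, non-Nyquist frequencies
  f <- seq_len(nf) * rate_hz / n
  amp <- f^(-exponent / 2)
  coefs <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * amp
  full <- complex(length.out = n)  # DC = 0
  full[2:(nf + 1)] <- coefs
  full[seq(n, n - nf + 1)] <- Conj(coefs)
  if (n %% 2 == 0) {
    full[n / 2 + 1] <- complex(real = rnorm(1) * (rate_hz / 2)^(-exponent / 2))
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  x / sd(x)
}

# gating envelope: 1 outside the target windows, `gain` inside, with
# raised-cosine ramps of `ramp_s` seconds
gain_envelope <- function(n, rate_hz, onsets_ms, durations_ms, gain,
                          ramp_s = 0.05) {
  env <- rep(1, n)
  ramp_n <- max(2L, round(ramp_s * rate_hz))
  up <- (1 - cos(seq(0, pi, length.out = ramp_n))) / 2
  for (i in seq_along(onsets_ms)) {
    a <- round(onsets_ms[i] * rate_hz / 1000) + 1
    b <- min(n, a + round(durations_ms[i] * rate_hz / 1000) - 1)
    if (a > n || b < a) next
    seg <- rep(1, b - a + 1)
    k <- min(ramp_n, length(seg))
    seg[seq_len(k)] <- up[seq_len(k)]
    seg[seq(length(seg), length.out = k, by = -1)] <- up[seq_len(k)]
    env[a:b] <- env[a:b] + (gain - 1) * pmin(seg, 1)
  }
  env
}

effect_windows <- function(schedule, window) {
  seg <- schedule$segments
  labels <- switch(window,
    emotion = if (schedule$task == "imagery") "imagery" else
      c("morph", "static", "unmorph"),
    neutral = "neutral",
    both = names(seg))
  ev <- schedule_events(schedule)
  ev <- ev[ev$label %in% labels, , drop = FALSE]
  list(onsets_ms = ev$time_ms, durations_ms = unname(seg[ev$label]))
}

#' Simulate one subject's continuous recording
#'
#' Signal model per channel: scaled 1/f background + per-band band-limited
#' oscillations (Butterworth-filtered white noise at the band edges, scaled
#' to the configured RMS) + white sensor noise. For a subject in a group
#' targeted by a group effect, the affected band's oscillation amplitude is
#' multiplied by the effect gain inside the schedule windows it names, on
#' the channels of its cluster only. Event markers are embedded for every
#' segment boundary. Deterministic given `seed`.
#'
#' @param spec a `cohort_spec`
#' @param group group label, `"asd"` or `"td"`
#' @param schedule a `trial_schedule`
#' @param seed integer seed for this subject
#' @param montage montage, default [default_montage()]
#' @return a `recording`
#' @export
simulate_subject <- function(spec, group, schedule, seed,
                             montage = default_montage()) {
  validate_cohort_spec(spec)
  stopifnot(nrow(schedule$trials) > 0)
  set.seed(seed)
  rate <- spec$sampling_rate_hz
  n <- ceiling(schedule_duration_ms(schedule) * rate / 1000)
  nch <- length(montage$channels)
  data <- matrix(0, nch, n, dimnames = list(montage$channels, NULL))
  bands <- eeg_bands()
  # precompute gain envelopes per (band) x channel set
  effects <- Filter(function(e) identical(e$group, group), spec$group_effects)
  for (ch in seq_len(nch)) {
    x <- spec$background$amplitude_uV *
      pink_noise(n, spec$background$exponent, rate)
    for (bn in names(spec$oscillations)) {
      edges <- bands[[bn]]
      # order 4: the oscillation should be band-limited to its stated band,
      # with little energy leaking past the shared edges of adjacent bands
      ba <- butter_bandpass(4, edges[1], edges[2], rate)
      osc <- filtfilt(ba$b, ba$a, rnorm(n))
      osc <- spec$oscillations[[bn]] * osc / sd(osc)
      for (ef in effects) {
        if (ef$band != bn) next
        if (!montage$channels[ch] %in% montage$clusters[[ef$cluster]]) next
        w <- effect_windows(schedule, ef$window)
        osc <- osc * gain_envelope(n, rate, w$onsets_ms, w$durations_ms,
                                   ef$gain)
      }
      x <- x + osc
    }
    data[ch, ] <- x + rnorm(n, sd = spec$noise_sd)
  }
  ev <- schedule_events(schedule)
  events <- data.frame(label = ev$label,
                       sample = round(ev$time_ms * rate / 1000) + 1L,
                       condition = ev$condition, block = ev$block,
                       trial = ev$trial, stringsAsFactors = FALSE)
  new_recording(data, rate, montage, events)
}

subject_seed <- function(master, i) {
  (as.integer(master) %% 1000003L) * 2011L + 17L * i
}

#' Simulate a full two-group cohort
#'
#' One recording per subject, 2 x `n_per_group` in total; each subject gets
#' its own randomized schedule and a seed derived reproducibly from
#' `spec$seed`.
#'
#' @param spec a `cohort_spec`
#' @param schedule_fun function(seed) -> `trial_schedule`; default the
#'   imagery paradigm
#' @param montage montage shared by all subjects
#' @return list with one element per subject:
#'   `list(recording, group, subject)`
#' @export
simulate_cohort <- function(spec, schedule_fun = make_imagery_schedule,
                            montage = default_montage()) {
  groups <- rep(c("asd", "td"), each = spec$n_per_group)
  lapply(seq_along(groups), function(i) {
    sd_i <- subject_seed(spec$seed, i)
    sched <- schedule_fun(sd_i + 1L)
    rec <- simulate_subject(spec, groups[i], sched, sd_i, montage)
    list(recording = rec, group = groups[i],
         subject = sprintf("S%02d", i), schedule = sched)
  })
}
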
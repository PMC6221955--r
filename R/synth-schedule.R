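# Trial schedules for the two experimental paradigms.
#
# Visual task: the avatar morphs from neutral into a happy or sad expression
# (250 ms), holds it (1000 ms) and morphs back (250 ms); inter-trial interval
# is 1 s plus a uniform jitter of at most 500 ms, with the neutral face on
# screen throughout. Imagery task: an instruction (the avatar performing the
# expression), 1.5 s preparation, an auditory cue starting 4 s of mental
# imagery, and a second cue starting the neutral period.

VISUAL_SEGMENTS  <- c(morph = 250, static = 1000, unmorph = 250)
IMAGERY_SEGMENTS <- c(instruction = 1500, preparation = 1500,
                      imagery = 4000, neutral = 4000)
INTER_BLOCK_GAP_MS <- 20000

new_trial_schedule <- function(task, trials) {
  structure(list(task = task, trials = trials), class = "trial_schedule")
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> task=%s, %d trials in %d block(s)\n",
              x$task, nrow(x$trials), length(unique(x$trials$block))))
  invisible(x)
}

balanced_conditions <- function(n_per_condition) {
  sample(rep(c("happy", "sad"), each = n_per_condition))
}

build_schedule <- function(task, trials_per_block, segments, seed,
                           iti_base_ms = 1000, iti_jitter_ms = 500,
                           n_blocks = 2L) {
  stopifnot(trials_per_block %% 2 == 0, trials_per_block >= 2)
  set.seed(seed)
  trial_dur <- sum(segments)
  rows <- vector("list", n_blocks)
  t0 <- 3000  # lead-in so pre-trial baselines fit inside the recording
  for (b in seq_len(n_blocks)) {
    cond <- balanced_conditions(trials_per_block / 2)
    iti <- iti_base_ms + runif(trials_per_block, 0, iti_jitter_ms)
    onset <- t0 + cumsum(c(0, head(trial_dur + iti, -1)))
    rows[[b]] <- data.frame(block = b, condition = cond,
                            onset_ms = onset, stringsAsFactors = FALSE)
    t0 <- onset[trials_per_block] + trial_dur + iti[trials_per_block] +
      INTER_BLOCK_GAP_MS
  }
  trials <- do.call(rbind, rows)
  sched <- new_trial_schedule(task, trials)
  sched$segments <- segments
  sched
}

#' Visual-stimulation trial schedule
#'
#' Two blocks of 120 randomized trials (60 happy, 60 sad each), 240 trials in
#' total. Each trial lasts 1.5 s (250 ms morph, 1 s static expression, 250 ms
#' unmorph); the inter-trial interval is 1 s plus a uniform jitter of up to
#' 500 ms.
#'
#' @param seed integer seed; the seed fixes the within-block condition order
#'   and the jitter draws.
#' @param trials_per_block even integer, default 120. Smaller values give the
#'   same structure at reduced length for quick simulations.
#' @return A `trial_schedule` with `$trials` (block, condition, onset_ms) and
#'   `$segments` (named segment durations in ms).
#' @export
make_visual_schedule <- function(seed, trials_per_block = 120L) {
  build_schedule("visual", trials_per_block, VISUAL_SEGMENTS, seed)
}

#' Mental-imagery trial schedule
#'
#' Two blocks of 40 randomized trials (20 per expression), 80 trials in total.
#' Each trial: instruction (1.5 s, the avatar performs the expression to be
#' imagined), 1.5 s preparation, cue, 4 s imagery, cue, 4 s neutral period.
#'
#' @inheritParams make_visual_schedule
#' @param trials_per_block even integer, default 40.
#' @export
make_imagery_schedule <- function(seed, trials_per_block = 40L) {
  build_schedule("imagery", trials_per_block, IMAGERY_SEGMENTS, seed,
                 iti_base_ms = 1000, iti_jitter_ms = 500)
}

#' Segment-onset event table of a schedule
#'
#' One event per segment boundary of every trial: the event label is the
#' segment name and the time is the segment onset.
#'
#' @param sched a `trial_schedule`
#' @return data.frame with columns label, time_ms, condition, block, trial.
#' @export
schedule_events <- function(sched) {
  seg <- sched$segments
  offs <- cumsum(c(0, head(seg, -1)))
  n <- nrow(sched$trials)
  data.frame(
    label = rep(names(seg), times = n),
    time_ms = rep(sched$trials$onset_ms, each = length(seg)) +
      rep(offs, times = n),
    condition = rep(sched$trials$condition, each = length(seg)),
    block = rep(sched$trials$block, each = length(seg)),
    trial = rep(seq_len(n), each = length(seg)),
    stringsAsFactors = FALSE
  )
}

schedule_duration_ms <- function(sched) {
  n <- nrow(sched$trials)
  sched$trials$onset_ms[n] + sum(sched$segments) + 2000
}
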
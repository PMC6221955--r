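# Filtering, referencing, epoching, rejection, baseline, ERP.

flat_montage <- function(labels) {
  # minimal montage stand-in for preprocessing tests
  structure(list(channels = labels,
                 positions = matrix(0, length(labels), 3),
                 clusters = list()), class = "montage")
}

sine_rec <- function(f_hz, rate_hz = 1000, dur_s = 5, nch = 2) {
  t <- seq_len(dur_s * rate_hz) / rate_hz
  data <- matrix(rep(sin(2 * pi * f_hz * t), nch), nrow = nch, byrow = TRUE)
  labels <- paste0("ch", seq_len(nch))
  rownames(data) <- labels
  new_recording(data, rate_hz, flat_montage(labels))
}

test_that("bandpass removes DC, passes in-band sinusoids, is linear", {
  expect_equal(eval(formals(bandpass)$low_hz), 1)
  expect_equal(eval(formals(bandpass)$high_hz), 100)
  # DC removal
  m <- flat_montage(c("a", "b"))
  dc <- new_recording(matrix(5, 2, 4000, dimnames = list(c("a", "b"), NULL)),
                      1000, m)
  out <- bandpass(dc)
  expect_lt(mean(out$data^2) / mean(dc$data^2), 0.01)
  # 10 Hz unit sinusoid passes within 5% (FFT oracle on the steady state)
  r10 <- sine_rec(10)
  y <- bandpass(r10)$data[1, 1001:4000]
  expect_equal(oracle_peak_amp(y, 1000, 10), 1, tolerance = 0.05)
  # stopband: 0.5 Hz attenuated by >= 20 dB
  r05 <- sine_rec(0.5)
  y05 <- bandpass(r05)$data[1, 1001:4000]
  expect_lt(oracle_peak_amp(y05, 1000, 0.5), 0.1)
  # Nyquist violation
  expect_error(bandpass(r10, 1, 600), "band edges")
  # linearity within 1e-6 relative tolerance
  set.seed(1)
  xa <- rnorm(2000); xb <- rnorm(2000)
  mk <- function(x) new_recording(matrix(x, 1, dimnames = list("a", NULL)),
                                  1000, flat_montage("a"))
  fa <- bandpass(mk(xa))$data[1, ]
  fb <- bandpass(mk(xb))$data[1, ]
  fab <- bandpass(mk(2 * xa + 3 * xb))$data[1, ]
  expect_equal(fab, 2 * fa + 3 * fb, tolerance = 1e-6)
})

test_that("notch kills 50 Hz and spares 10 Hz", {
  expect_equal(eval(formals(notch)$low_hz), 47.5)
  expect_equal(eval(formals(notch)$high_hz), 52.5)
  y50 <- notch(sine_rec(50))$data[1, 1001:4000]
  expect_lt(max(abs(y50)), 0.1)
  y10 <- notch(sine_rec(10))$data[1, 1001:4000]
  expect_equal(oracle_peak_amp(y10, 1000, 10), 1, tolerance = 0.05)
  expect_error(notch(sine_rec(10), 400, 600), "band edges")
})

test_that("average reference zeroes channel means and preserves differences", {
  m <- flat_montage(c("a", "b"))
  rec <- new_recording(matrix(c(1, 3), 2, 1,
                              dimnames = list(c("a", "b"), NULL)), 100, m)
  out <- rereference_average(rec)
  expect_equal(unname(out$data[, 1]), c(-1, 1))
  set.seed(2)
  rec2 <- new_recording(matrix(rnorm(4 * 50), 4, 50,
                               dimnames = list(letters[1:4], NULL)),
                        100, flat_montage(letters[1:4]))
  out2 <- rereference_average(rec2)
  expect_equal(max(abs(colMeans(out2$data))), 0, tolerance = 1e-9)
  # idempotent; pairwise differences preserved to round-off
  expect_equal(rereference_average(out2)$data, out2$data, tolerance = 1e-12)
  expect_equal(out2$data["a", ] - out2$data["b", ],
               rec2$data["a", ] - rec2$data["b", ], tolerance = 1e-12)
  # bad channels excluded from the reference; all-bad errors
  rec2$bad_channels <- c("a", "b")
  ref1 <- rereference_average(rec2)
  expect_equal(max(abs(colMeans(ref1$data[c("c", "d"), ]))), 0,
               tolerance = 1e-9)
  rec2$bad_channels <- letters[1:4]
  expect_error(rereference_average(rec2), "2 good channels")
})

test_that("epoching aligns, sizes and degrades as specified", {
  # 240 visual onsets, window (-100, 900) ms at 1000 Hz -> 240 x 64 x 1000
  sched <- make_visual_schedule(3)
  m <- default_montage()
  n <- ceiling((max(sched$trials$onset_ms) + 2000) / 1000 * 1000)
  data <- matrix(0, 64, n, dimnames = list(m$channels, NULL))
  ev <- schedule_events(sched)
  events <- data.frame(label = ev$label,
                       sample = round(ev$time_ms) + 1L,
                       condition = ev$condition)
  rec <- new_recording(data, 1000, m, events)
  ep <- epoch(rec, "morph", -100, 900)
  expect_equal(dim(ep$data), c(240, 64, 1000))
  # impulse alignment: event at sample s appears at in-epoch index 101
  # (0-based 100) for a -100 ms window start
  rec$data[1, events$sample[1]] <- 7
  ep2 <- epoch(rec, "morph", -100, 900)
  expect_equal(unname(ep2$data[1, 1, 101]), 7)
  expect_true(all(ep2$data[1, 1, -101] == 0))
  # no matching events: empty epoch set, no error
  ep0 <- epoch(rec, "no_such_label", -100, 900)
  expect_equal(dim(ep0$data)[1], 0)
  # out-of-bounds windows drop trials with a warning
  short <- new_recording(
    matrix(0, 2, 5000, dimnames = list(c("a", "b"), NULL)), 1000,
    flat_montage(c("a", "b")),
    data.frame(label = "morph", sample = c(200L, 450L, 4990L),
               condition = "happy"))
  expect_warning(ep3 <- epoch(short, "morph", -100, 900), "dropping 1")
  expect_equal(dim(ep3$data)[1], 2)
})

test_that("epoching consecutive windows reconstructs the signal exactly", {
  set.seed(4)
  x <- matrix(rnorm(2 * 1000), 2, dimnames = list(c("a", "b"), NULL))
  ev <- data.frame(label = "seg", sample = c(101L, 301L, 501L))
  rec <- new_recording(x, 100, flat_montage(c("a", "b")), ev)
  ep <- epoch(rec, "seg", 0, 2000)  # 200 samples each, contiguous
  recon <- do.call(cbind, lapply(1:3, function(t) ep$data[t, , ]))
  expect_identical(recon, x[, 101:700])
})

test_that("bad-epoch rejection matches an independent reimplementation", {
  set.seed(5)
  data <- array(rnorm(20 * 3 * 50, sd = 10), dim = c(20, 3, 50))
  data[7, 2, 25] <- 500  # extreme-value trial
  data[13, , ] <- rnorm(3 * 50, sd = 60)  # improbable trial
  ep <- make_epochs(data, 100, 0)
  out <- reject_bad_epochs(ep, abs_uV = 100, prob_z = 2)
  expect_true(out$rejected[7])
  expect_identical(out$rejected, oracle_reject(ep, 100, 2))
  expect_identical(out$data, ep$data)  # data preserved
  # identical trials: none rejected at any prob_z >= 1
  same <- make_epochs(array(rep(1:50, each = 4 * 2), dim = c(4, 2, 50)),
                      100, 0)
  for (z in c(1, 3)) {
    expect_false(any(reject_bad_epochs(same, 100, z)$rejected))
  }
})

test_that("baseline correction subtracts the window mean", {
  # constant trial becomes all zeros
  const <- make_epochs(array(5, dim = c(1, 2, 100)), 100, -200)
  out <- baseline_correct(const, -200, 0)
  expect_equal(max(abs(out$data)), 0)
  # linear ramp: closed-form subtraction
  ramp <- array(rep(seq_len(100), each = 1), dim = c(1, 1, 100))
  ep <- make_epochs(ramp, 100, -200)
  out2 <- baseline_correct(ep, -100, 0)
  base_mean <- mean(ramp[1, 1, 11:20])
  expect_equal(out2$data[1, 1, ], ramp[1, 1, ] - base_mean)
  # random epochs: post-correction baseline means ~ 0
  set.seed(6)
  ep3 <- make_epochs(array(rnorm(5 * 2 * 100), dim = c(5, 2, 100)), 100, -200)
  out3 <- baseline_correct(ep3, -200, -100)
  bmeans <- apply(out3$data[, , 1:10, drop = FALSE], c(1, 2), mean)
  expect_equal(max(abs(bmeans)), 0, tolerance = 1e-9)
  expect_error(baseline_correct(ep3, -500, -300), "outside epoch")
})

test_that("ERP averages non-rejected trials of a condition", {
  d <- array(0, dim = c(3, 2, 10))
  d[1, , ] <- 1; d[2, , ] <- 3; d[3, , ] <- 100
  ep <- make_epochs(d, 100, 0, condition = c("happy", "happy", "sad"))
  expect_equal(compute_erp(ep, "happy"), matrix(2, 2, 10),
               ignore_attr = TRUE)
  # rejection excludes trials
  ep$rejected[2] <- TRUE
  expect_equal(compute_erp(ep, "happy"), matrix(1, 2, 10),
               ignore_attr = TRUE)
  # ERP of identical trials is the trial
  expect_equal(compute_erp(ep, "sad"), matrix(100, 2, 10),
               ignore_attr = TRUE)
  ep$rejected[3] <- TRUE
  expect_error(compute_erp(ep, "sad"), "no surviving")
})
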
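# Band filters, embeddings, and the eight features against closed forms
# and brute-force oracles.

test_that("band filters pass in-band and reject out-of-band sinusoids", {
  bands <- eeg_bands()
  expect_equal(bands$theta, c(4, 8))
  expect_equal(bands$alpha, c(8, 12))
  expect_equal(bands$low_beta, c(12, 21))
  expect_equal(bands$high_beta, c(21, 30))
  expect_equal(bands$gamma, c(30, 40))
  fs <- 250
  t <- seq_len(10 * fs) / fs
  mid <- 500:2000
  y6 <- band_filter(sin(2 * pi * 6 * t), "theta", fs)
  expect_equal(oracle_peak_amp(y6[mid], fs, 6), 1, tolerance = 0.1)
  y25 <- band_filter(sin(2 * pi * 25 * t), "theta", fs)
  expect_lt(max(abs(y25[mid])), 0.1)
  expect_error(band_filter(sin(t), "delta", fs), "unknown band")
  expect_error(band_filter(sin(t), "gamma", 60), "Nyquist")
})

test_that("autocorrelation lag finds the first local minimum", {
  # sinusoid of period P: first acf minimum at ~P/2
  for (P in c(20, 50)) {
    x <- sin(2 * pi * seq_len(1000) / P)
    expect_equal(autocorr_lag(x), P / 2, tolerance = 1)
  }
  # white noise: always >= 1, usually 1
  set.seed(7)
  lags <- replicate(20, autocorr_lag(rnorm(300)))
  expect_true(all(lags >= 1))
  expect_gt(mean(lags == 1), 0.5)
  # equals the brute-force acf scan on arbitrary signals
  for (i in 1:10) {
    x <- as.numeric(arima.sim(list(ar = 0.7), 120)) + sin(seq_len(120) / 5)
    expect_identical(autocorr_lag(x), oracle_autocorr_lag(x))
  }
  expect_warning(lag_const <- autocorr_lag(rep(3, 50)), "constant")
  expect_gte(lag_const, 1)
})

test_that("time-delay embedding satisfies its defining identity", {
  e <- embed_delay(1:5, 2, 1)
  expect_equal(e$points, cbind(1:4, 2:5))
  expect_equal(e$M, 4)
  # m = 1: identity embedding
  e1 <- embed_delay(1:7, 1, 3)
  expect_equal(as.numeric(e1$points), 1:7)
  expect_equal(e1$M, 7)
  expect_equal(embed_delay(1:10, 3, 2)$M, 6)
  expect_error(embed_delay(1:5, 3, 3), "at least 7 samples")
  # property: points[i, j] == x[i + (j-1) tau] on random cases
  set.seed(8)
  for (i in 1:20) {
    n <- sample(20:60, 1); m <- sample(1:4, 1)
    tau <- sample(1:5, 1)
    if (n <= (m - 1) * tau) next
    x <- rnorm(n)
    e <- embed_delay(x, m, tau)
    expect_equal(e$M, n - (m - 1) * tau)
    for (j in seq_len(m)) {
      expect_identical(e$points[, j], x[seq_len(e$M) + (j - 1) * tau])
    }
  }
})

test_that("envelope, Teager energy and power match closed forms", {
  n <- seq_len(5000)
  # constant: teager 0, power c^2
  expect_equal(feat_teager(rep(3, 100)), 0)
  expect_equal(feat_power(rep(3, 100)), 9)
  # unit sinusoid: env ~ 1, pow ~ 0.5
  s <- sin(0.3 * n)
  expect_equal(feat_envelope(s), 1, tolerance = 0.02)
  expect_equal(feat_power(s), 0.5, tolerance = 0.02)
  # Teager-Kaiser closed form A^2 sin^2(omega)
  for (A in c(1, 2.5)) {
    for (om in c(0.3, 1.1)) {
      expect_equal(feat_teager(A * sin(om * n)), A^2 * sin(om)^2,
                   tolerance = 0.02 * A^2 * sin(om)^2)
    }
  }
  # scaling laws: pow ~ a^2, env ~ a, teag ~ a^2
  set.seed(9)
  x <- rnorm(500); a <- 3.7
  expect_equal(feat_power(a * x), a^2 * feat_power(x), tolerance = 1e-12)
  expect_equal(feat_envelope(a * x), a * feat_envelope(x), tolerance = 1e-12)
  expect_equal(feat_teager(a * x), a^2 * feat_teager(x), tolerance = 1e-12)
  expect_error(feat_teager(c(1, 2)), "3 samples")
})

test_that("spatial filling index matches its occupancy definition", {
  # all points identical -> one occupied cell -> 1/grid^2
  same <- structure(list(points = matrix(2, 50, 2), m = 2, tau = 1L,
                         N = 51, M = 50), class = "embedding")
  expect_warning(v <- feat_sfi(same, grid = 10), "degenerate")
  expect_equal(v, 1 / 100)
  # exactly uniform occupancy -> 1/grid^4
  g <- 5
  centers <- (seq_len(g) - 0.5) / g
  pts <- as.matrix(expand.grid(centers, centers))
  unif <- structure(list(points = pts, m = 2, tau = 1L,
                         N = g^2 + 1, M = g^2), class = "embedding")
  expect_equal(feat_sfi(unif, grid = g), 1 / g^4)
  # random trajectory equals a brute-force cell recount
  set.seed(10)
  x <- cumsum(rnorm(200))
  emb <- embed_delay(x, 2, 3)
  grid <- 10
  u <- (emb$points[, 1] - min(emb$points[, 1])) / diff(range(emb$points[, 1]))
  v <- (emb$points[, 2] - min(emb$points[, 2])) / diff(range(emb$points[, 2]))
  cell <- paste(pmin(grid, floor(u * grid) + 1),
                pmin(grid, floor(v * grid) + 1))
  p <- as.numeric(table(cell)) / emb$M
  expect_equal(feat_sfi(emb, grid), sum(p^2) / grid^2, tolerance = 1e-12)
})

test_that("Lyapunov estimates: chaotic, periodic, deterministic", {
  x <- numeric(2000)
  x[1] <- 0.4
  for (i in 2:2000) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  est <- feat_lyapunov(embed_delay(x, 3, 1))
  expect_equal(est, log(2), tolerance = 0.2 * log(2))
  # pure sinusoids are non-chaotic
  for (P in c(50, 47.3)) {
    s <- sin(2 * pi * seq_len(2000) / P)
    expect_lte(abs(feat_lyapunov(embed_delay(s, 3, autocorr_lag(s)))), 0.05)
  }
  # deterministic given input and config
  expect_identical(feat_lyapunov(embed_delay(x, 3, 1)),
                   feat_lyapunov(embed_delay(x, 3, 1)))
  expect_error(feat_lyapunov(embed_delay(x[1:30], 3, 1)), "at least 50")
})

test_that("correlation dimension: line ~ 1, square ~ 2, oracle C(r)", {
  set.seed(11)
  u <- sort(runif(300))
  expect_equal(feat_corrdim(embed_delay(u, 3, 1)), 1, tolerance = 0.2)
  sq <- structure(list(points = cbind(runif(400), runif(400)), m = 2,
                       tau = 1L, N = 401, M = 400), class = "embedding")
  expect_equal(feat_corrdim(sq), 2, tolerance = 0.3)
  # correlation sums equal brute-force pair counting (M <= 200)
  pts <- matrix(rnorm(150 * 3), ncol = 3)
  rs <- unname(quantile(as.numeric(dist(pts)), c(0.1, 0.3, 0.6)))
  expect_equal(as.numeric(emobio:::cpp_corr_sum(pts, rs)),
               oracle_corr_sum(pts, rs), tolerance = 1e-12)
  degenerate <- structure(list(points = matrix(1, 150, 3), m = 3, tau = 1L,
                               N = 152, M = 150), class = "embedding")
  expect_error(feat_corrdim(degenerate), "degenerate")
})

test_that("ApEn/SampEn match brute-force template counting", {
  expect_equal(eval(formals(feat_apen)$m), 2L)
  expect_equal(eval(formals(feat_apen)$r), 0.2)
  # periodic short-period signal: SampEn ~ 0
  expect_equal(feat_sampen(rep(c(1, 2), 30)), 0)
  # oracle equivalence on seeded random sequences
  set.seed(12)
  for (i in 1:25) {
    n <- sample(25:50, 1)
    x <- if (i %% 2) rnorm(n) else sin(seq_len(n) / 2) + rnorm(n, sd = 0.3)
    r_abs <- 0.2 * sd(x)
    expect_equal(emobio:::cpp_apen(x, 2L, r_abs), oracle_apen(x, 2, r_abs),
                 tolerance = 1e-10)
    se <- emobio:::cpp_sampen(x, 2L, r_abs)[1]
    expect_equal(se, oracle_sampen(x, 2, r_abs), tolerance = 1e-10)
  }
  # scale invariance with r proportional to SD
  set.seed(13)
  x <- rnorm(120)
  expect_equal(feat_sampen(5 * x), feat_sampen(x), tolerance = 1e-9)
  expect_equal(feat_apen(5 * x), feat_apen(x), tolerance = 1e-9)
  expect_error(feat_apen(rep(1, 100)), "constant")
  expect_error(feat_apen(rnorm(15)), "10\\*m")
})

burst_epochs <- function() {
  # one trial, one channel; 6 Hz burst confined to the emotion window
  rate <- 100
  w <- imagery_feature_windows()
  n <- round((10500 + 500) * rate / 1000)
  t <- seq_len(n) / rate
  x <- rnorm(n, sd = 0.3)
  # epoch starts at -500 ms: time T ms sits at sample (T+500)*rate/1000
  idx <- (round((w$emotion[1] + 500) * rate / 1000) + 1):
    round((w$emotion[2] + 500) * rate / 1000)
  x[idx] <- x[idx] + 2 * sin(2 * pi * 6 * t[idx])
  arr <- array(x, dim = c(1, 1, n), dimnames = list(NULL, "PO4", NULL))
  make_epochs(arr, rate, -500)
}

test_that("extract_all produces 8 features per band and window", {
  set.seed(14)
  ep <- burst_epochs()
  wf <- extract_all(ep)
  # 1 trial x 1 channel x 5 bands x 3 windows x 8 features
  expect_equal(nrow(wf), 5 * 3 * 8)
  expect_equal(nrow(wf[window == "emotion"]), 40)
  # injected 6 Hz burst raises theta power in the emotion window
  pow_emo <- wf[band == "theta" & window == "emotion" &
                feature == "pow"]$value
  pow_base <- wf[band == "theta" & window == "baseline" &
                 feature == "pow"]$value
  expect_gt(pow_emo, 10 * pow_base)
  # determinism
  expect_identical(wf$value, extract_all(ep)$value)
})

test_that("normalization subtracts baseline for time/frequency only", {
  set.seed(15)
  ep <- burst_epochs()
  wf <- extract_all(ep)
  norm <- normalize_features(wf)
  join <- c("trial", "channel", "band", "window", "feature")
  merged <- merge(wf, norm, by = join, suffixes = c("", ".norm"))
  tf <- merged[feature %in% c("env", "teag", "pow") & window != "baseline"]
  base <- wf[window == "baseline"]
  for (i in seq_len(nrow(tf))) {
    b <- base[band == tf$band[i] & feature == tf$feature[i]]$value
    expect_equal(tf$value.norm[i], tf$value[i] - b)
  }
  # non-linear features unchanged bit-exactly
  nl <- merged[!feature %in% c("env", "teag", "pow")]
  expect_identical(nl$value.norm, nl$value)
  # baseline-less table errors
  expect_error(normalize_features(wf[window != "baseline"]), "baseline")
})
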
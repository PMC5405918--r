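test_that("wavelet approximations preserve length, constants and energy order", {
  # constant input reproduced at every level
  ws <- wavelet_approximations(bcg_record(rep(2.5, 256)), levels = 5)
  for (a in ws$approximations) {
    expect_length(a, 256)
    expect_true(all(abs(a - 2.5) < 1e-9))
  }

  # white noise: RMS of the approximation strictly decreases with level
  set.seed(1)
  wn <- wavelet_approximations(rnorm(2048), levels = 5)
  rms <- vapply(wn$approximations, function(a) sqrt(mean(a^2)), numeric(1))
  expect_true(all(diff(rms) < 0))

  # 1 Hz sine at 100 Hz: layer-4 troughs within 2 samples of the raw ones
  rec <- gen_sine_bcg(synthetic_spec(n_periods = 64, snr_db = Inf))
  a4 <- wavelet_approximations(rec)$approximations[[4]]
  per <- 100
  shift <- vapply(1:60, function(j) {
    w <- ((j - 1) * per + 1):(j * per)
    abs(which.min(a4[w]) - which.min(rec$samples[w]))
  }, numeric(1))
  expect_true(all(shift <= 2))

  expect_error(wavelet_approximations(rnorm(16), levels = 5), "at least")
})

test_that("trough detector recovers periodic beats and breaks ties early", {
  rec <- gen_sine_bcg(synthetic_spec(n_periods = 100, snr_db = Inf))
  rr <- detect_troughs(rec)
  expect_true(all(abs(rr$rr - 1.0) < 1e-9))

  # two identical minima inside one window: earlier sample kept
  sig <- rep(0, 300)
  sig[c(40, 60)] <- -1
  rr2 <- detect_troughs(sig, fs = 100)
  idx <- attr(rr2, "beat_idx")
  expect_true(40 %in% idx)
  expect_false(60 %in% idx)

  # refractory consolidation merges nearby candidates keeping the deeper
  sig3 <- rep(0, 400)
  sig3[100] <- -0.5; sig3[110] <- -1  # 0.1 s apart at 100 Hz
  idx3 <- attr(detect_troughs(sig3, consolidate = "refractory"), "beat_idx")
  expect_false(100 %in% idx3)
  expect_true(110 %in% idx3)

  expect_warning(detect_troughs(rnorm(50)), "shorter")
  expect_error(detect_troughs(rnorm(500), window = 50, step = 80), "window")
})

test_that("RR correction implements the leak and fault rules exactly", {
  base <- rep(1, 10)
  # leak: RR = 2.0 against local mean 1.0 -> split into 2 x 1.0
  out <- quiet_correct(c(base, 2.0, base))
  expect_length(out, 22)
  expect_true(all(abs(out - 1) < 1e-9))

  # leak: RR = 3.4, mean 1.0 -> k = floor(3.9) = 3 -> three intervals
  out2 <- quiet_correct(c(base, 3.4, base))
  expect_length(out2, 23)
  expect_equal(sum(abs(out2 - 3.4 / 3) < 1e-9), 3)

  # fault, neighbours close: mass split equally between both neighbours
  x3 <- c(rep(1, 8), 1.0, 0.4, 0.9, rep(1, 8))
  out3 <- quiet_correct(x3)
  expect_length(out3, length(x3) - 1)
  expect_true(any(abs(out3 - 1.2) < 1e-9))
  expect_true(any(abs(out3 - 1.1) < 1e-9))

  # fault, neighbours far apart: merged wholly into the smaller neighbour
  # (0.6 -> 1.0); the 1.8 is then itself a leak against its local mean and
  # is split, so total duration is conserved throughout
  x4 <- c(rep(1, 8), 0.6, 0.4, 1.8, rep(1, 8))
  out4 <- quiet_correct(x4)
  expect_length(out4, 19)
  expect_equal(out4[9], 1.0, tolerance = 1e-12)
  expect_equal(out4[10:11], c(0.9, 0.9), tolerance = 1e-12)
  expect_equal(sum(out4), sum(x4), tolerance = 1e-9)

  # clean series untouched; duration always conserved
  expect_identical(quiet_correct(rep(1, 15)), rep(1, 15))
  set.seed(2)
  for (i in 1:5) {
    x <- runif(200, 0.2, 2.2)
    expect_equal(sum(quiet_correct(x)), sum(x), tolerance = 1e-9)
  }

  expect_warning(correct_rr(rep(1, 5)), "passthrough")
})

test_that("RR correction is idempotent on leak/fault fixtures", {
  x <- c(rep(1, 10), 2.1, rep(1, 5), 0.3, rep(1, 10), 3.05, rep(1, 10))
  once <- quiet_correct(x)
  twice <- quiet_correct(once)
  expect_equal(twice, once, tolerance = 1e-12)
})

test_that("tachogram resampling spans the beats at the requested rate", {
  # constant RR stays constant
  rr <- rr_series(seq(0, 30, by = 1))
  tach <- resample_rr(rr)
  expect_true(all(abs(tach$rr - 1) < 1e-9))
  expect_equal(tach$fs, 4)

  # a linear RR ramp is reproduced exactly (cubic spline is exact on lines)
  bt <- cumsum(c(0, seq(0.8, 1.2, length.out = 40)))
  rrl <- rr_series(bt)
  tl <- resample_rr(rrl)
  ref <- approx(bt[-1], rrl$rr, xout = tl$t, rule = 2)$y
  interior <- tl$t >= bt[2] & tl$t <= max(bt)
  expect_lt(max(abs(tl$rr[interior] - ref[interior])), 1e-4)

  # 60 s of beats -> 240 +- 1 samples at 4 Hz
  expect_lt(abs(length(resample_rr(rr_series(0:60))$rr) - 240), 2)

  expect_error(resample_rr(rr_series(c(0, 1, 2))), "at least 4")
})
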
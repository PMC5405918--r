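test_that("critical values match the Brownian-bridge quantiles", {
  expect_equal(round(critical_value(0.99), 3), 1.628)
  expect_equal(round(critical_value(0.95), 3), 1.358)
  # threshold decreases monotonically to zero with confidence
  conf <- c(0.99, 0.9, 0.5, 0.2, 0.05, 0.001)
  q <- vapply(conf, critical_value, numeric(1))
  expect_true(all(diff(q) < 0))
  expect_lt(q[length(q)], 0.4)
  expect_error(critical_value(1), "confidence")
})

test_that("the CUSUM statistic is scale invariant and matches its oracle", {
  set.seed(11)
  x <- rnorm(500)
  r <- cusum_statistic(x)
  r5 <- cusum_statistic(5 * x)
  expect_equal(r$kappa2, r5$kappa2, tolerance = 1e-12)
  expect_identical(r$t_star, r5$t_star)

  # exhaustive-argmax oracle equivalence for short series
  for (n in c(16, 33, 64)) {
    y <- rnorm(n, 0, ifelse(seq_len(n) > n / 2, 2, 1))
    got <- cusum_statistic(y)
    want <- oracle_kappa2(y)
    expect_equal(got$kappa2, want$kappa2, tolerance = 1e-10)
    expect_identical(got$t_star, want$t_star)
  }

  expect_warning(r0 <- cusum_statistic(rep(1, 50)), "zero-variance")
  expect_equal(r0$kappa2, 0)
  expect_error(cusum_statistic(rnorm(5)), "at least 8")
})

test_that("the statistic localises a variance break", {
  set.seed(21)
  hits <- replicate(100, {
    x <- c(rnorm(500, 0, 1), rnorm(500, 0, 2))
    abs(cusum_statistic(x)$t_star - 500) <= 25
  })
  expect_gte(mean(hits), 0.95)
})

test_that("iterative segmentation controls false alarms and finds breaks", {
  set.seed(31)
  # constant-variance null: no change points in at least 99/100 runs
  empty <- replicate(100, length(icss_segment(rnorm(800))) == 0)
  expect_gte(mean(empty), 0.97)

  # two planted breaks (sd 1 -> 3 -> 1), each localised within 5 s at 4 Hz
  set.seed(32)
  found <- replicate(20, {
    x <- c(rnorm(400, 0, 1), rnorm(200, 0, 3), rnorm(400, 0, 1))
    cps <- icss_segment(x)
    length(cps) == 2 && abs(cps[1] - 400) <= 20 && abs(cps[2] - 600) <= 20
  })
  expect_gte(mean(found), 0.9)

  expect_identical(icss_segment(rnorm(7)), integer(0))
})

test_that("physio constraints mask Wake, block by the hour, floor at 10 s", {
  cfg <- changepoint_config(block_s = 600)  # 10-minute blocks to keep n small
  fs <- 4
  set.seed(41)
  # 20 min with 4 planted episodes in the first half
  n <- 20 * 60 * fs
  x <- rnorm(n, 0, 0.03)
  truth <- data.frame(start = c(100, 250, 400, 520),
                      end = c(120, 275, 415, 545))
  for (i in seq_len(nrow(truth))) {
    ii <- (truth$start[i] * fs):(truth$end[i] * fs)
    u <- seq_along(ii) / length(ii)
    x[ii] <- rnorm(length(ii), 0, 0.06) - 0.15 * sin(2 * pi * u)
  }
  st <- stage_track(rep("NREM", 40), epoch_s = 30)
  fset <- physio_icss(x, fs = fs, stages = st, config = cfg)
  expect_equal(fset$n_blocks, 2L)
  keep <- fset$fragments[fset$fragments$status == 1, ]
  # every planted episode overlaps an examine-status fragment (Jaccard >= 0.5)
  jac <- vapply(seq_len(nrow(truth)), function(i) {
    ov <- pmin(truth$end[i], keep$end_s) - pmax(truth$start[i], keep$start_s)
    un <- pmax(truth$end[i], keep$end_s) - pmin(truth$start[i], keep$start_s)
    max(ov / un)
  }, numeric(1))
  expect_true(all(jac >= 0.5))
  # no fragment below the 10 s floor has examine status
  expect_true(all(keep$raw_len_s >= 10))
  # capped length never exceeds the configured maximum
  expect_true(all(fset$fragments$capped_len_s <= cfg$max_segment_s))

  # all-Wake track: nothing to analyse
  stw <- stage_track(rep("Wake", 40), epoch_s = 30)
  expect_equal(physio_icss(x, fs = fs, stages = stw, config = cfg)$n_blocks, 0L)

  # sub-block residual discarded: 9 minutes of data, 10-minute blocks
  x9 <- rnorm(9 * 60 * fs, 0, 0.03)
  st9 <- stage_track(rep("NREM", 18), epoch_s = 30)
  expect_equal(physio_icss(x9, fs = fs, stages = st9, config = cfg)$n_blocks, 0L)

  # missing stages: warns and treats everything as NREM
  expect_warning(physio_icss(x, fs = fs, config = cfg), "NREM")
})

test_that("a 6 s variance episode is never an examine-status fragment", {
  cfg <- changepoint_config(block_s = 600)
  fs <- 4
  set.seed(51)
  x <- rnorm(600 * fs, 0, 0.03)
  ii <- (300 * fs):(306 * fs)
  x[ii] <- rnorm(length(ii), 0, 0.2)
  st <- stage_track(rep("NREM", 20), epoch_s = 30)
  fset <- physio_icss(x, fs = fs, stages = st, config = cfg)
  keep <- fset$fragments[fset$fragments$status == 1, ]
  ov <- pmin(306, keep$end_s) - pmax(300, keep$start_s)
  # any fragment covering the episode must be much longer than the episode
  expect_true(all(keep$raw_len_s >= 10))
  short_hits <- keep$raw_len_s < 10 & ov > 0
  expect_false(any(short_hits))
})
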
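test_that("time-domain features match hand-computed values", {
  f <- time_features(c(1, 1, 1))
  expect_equal(unname(f[c("Mean", "Var", "RMSSD", "PNN50", "CV")]),
               c(1, 0, 0, 0, 0))

  f2 <- time_features(c(0.8, 1.0, 1.2))
  expect_equal(unname(f2["RMSSD"]), 0.2, tolerance = 1e-12)
  expect_equal(unname(f2["SDSD"]), 0, tolerance = 1e-12)
  expect_equal(unname(f2[c("Max", "Min", "Mean")]), c(1.2, 0.8, 1.0))

  # both successive differences are 60 ms > 50 ms
  expect_equal(unname(time_features(c(1.00, 1.06, 1.00))["PNN50"]), 100)

  expect_true(all(is.na(time_features(c(1, 1)))))

  # invariant to time origin: features depend only on the intervals
  set.seed(1)
  rr <- runif(50, 0.8, 1.2)
  expect_identical(time_features(rr), time_features(rr))
})

test_that("Burg spectra are flat for white noise and peaked for a tone", {
  set.seed(2)
  x <- rnorm(4096)
  psd <- ar_spectrum(x, fs = 4)
  expect_true(all(psd$psd >= 0))
  # total power within 5% of the series variance
  pw <- sum(diff(psd$freq) * (head(psd$psd, -1) + tail(psd$psd, -1)) / 2)
  expect_lt(abs(pw / var(x) - 1), 0.05)
  # flat within 3 dB of the median across the band
  expect_lt(max(abs(10 * log10(psd$psd / median(psd$psd)))), 3)

  # 0.25 Hz tone + small noise: peak within 0.02 Hz
  t <- seq(0, 1024, by = 0.25)
  y <- sin(2 * pi * 0.25 * t) + rnorm(length(t), 0, 0.05)
  psd2 <- ar_spectrum(y, fs = 4)
  expect_lt(abs(psd2$freq[which.max(psd2$psd)] - 0.25), 0.02)

  expect_error(ar_spectrum(rep(1, 100)), "zero-variance")
  expect_warning(ar_spectrum(rnorm(30), order = 16), "order")
})

test_that("band powers follow the stated band edges and normalisation", {
  flat <- list(freq = seq(0, 2, length.out = 2001), psd = rep(1, 2001))
  f <- freq_features(flat)
  expect_equal(unname(f["vLF"]), 0.0367, tolerance = 1e-3)
  expect_equal(unname(f["LF"]), 0.11, tolerance = 1e-3)
  expect_equal(unname(f["HF"]), 0.25, tolerance = 1e-3)
  expect_equal(unname(f["vHF"]), 0.10, tolerance = 1e-3)
  expect_equal(unname(f["TF"]), 0.50, tolerance = 1e-3)
  expect_equal(unname(f["LF_nor"] + f["HF_nor"]), 1, tolerance = 1e-12)
  expect_equal(unname(f["LF_nor"]), 0.11 / 0.36, tolerance = 1e-3)

  # all power concentrated in [0.2, 0.3]: HF only, LF_nor ~ 0
  conc <- list(freq = seq(0, 0.5, length.out = 501),
               psd = as.numeric(seq(0, 0.5, length.out = 501) >= 0.2 &
                                  seq(0, 0.5, length.out = 501) <= 0.3))
  fc <- freq_features(conc)
  expect_equal(unname(fc["LF_nor"]), 0, tolerance = 1e-6)
  expect_equal(unname(fc["HF"]), unname(fc["TF"]), tolerance = 1e-2)

  # zero LF + HF: normalised features flagged missing
  z <- list(freq = seq(0, 0.5, length.out = 501), psd = rep(0, 501))
  expect_true(all(is.na(freq_features(z)[c("LF_nor", "HF_nor", "LF_HF")])))
})

test_that("normalised LF and HF always sum to one when defined", {
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(600, 1, 0.05)
    f <- freq_features(ar_spectrum(x, fs = 4))
    expect_equal(unname(f["LF_nor"] + f["HF_nor"]), 1, tolerance = 1e-12)
  }
})

test_that("DFA recovers the known exponents of canonical processes", {
  set.seed(4)
  expect_lt(abs(dfa_alpha(rnorm(5000)) - 0.5), 0.1)
  expect_lt(abs(dfa_alpha(cumsum(rnorm(5000))) - 1.5), 0.15)
  expect_true(is.na(dfa_alpha(rep(1, 5000))))
  expect_true(is.na(dfa_alpha(rnorm(100))))  # below 4 * s_min
  # shorter-than-4*s_max series shrink the top scale and flag it
  a <- dfa_alpha(rnorm(700))
  expect_false(is.na(a))
  expect_lt(attr(a, "s_max_used"), 320)
})

test_that("sample entropy matches the brute-force oracle and known regimes", {
  set.seed(5)
  for (n in c(80, 150, 200)) {
    x <- runif(n)
    expect_equal(sample_entropy(x), oracle_sampen(x), tolerance = 1e-12)
  }
  # strictly periodic series: template matches always extend, entropy 0
  per <- rep(c(0.1, 0.5, 0.9, 0.3, 0.7), 100)
  expect_equal(sample_entropy(per), 0)
  # i.i.d. uniform noise near the known value, via the same-draw oracle
  y <- runif(1000)
  se <- sample_entropy(y)
  expect_equal(se, oracle_sampen(y), tolerance = 1e-12)
  expect_lt(abs(se - 2.2), 0.3)
  expect_true(is.na(sample_entropy(runif(30))))
})

test_that("the fragment feature vector has the fixed 18-name layout", {
  set.seed(6)
  fv <- fragment_features(rnorm(80, 1, 0.05), rnorm(500, 1, 0.05))
  expect_identical(names(fv), hrv_feature_names())
  expect_length(fv, 18)
  expect_true(fv["Min"] <= fv["Mean"] && fv["Mean"] <= fv["Max"])
  expect_gte(fv["Var"], 0)
  expect_true(all(fv[c("vLF", "LF", "HF", "vHF", "TF")] >= 0))
})
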
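# HRV feature extraction: 18 features per RR fragment.
# Fixed order: Mean, Var, Max, Min, RMSSD, SDSD, PNN50, CV,
#              vLF, LF, HF, vHF, LF_nor, HF_nor, LF_HF, TF, DFA, SampEN.

#' Names of the 18 HRV features, in their fixed order
#' @return Character vector of length 18.
#' @export
hrv_feature_names <- function() {
  c("Mean", "Var", "Max", "Min", "RMSSD", "SDSD", "PNN50", "CV",
    "vLF", "LF", "HF", "vHF", "LF_nor", "HF_nor", "LF_HF", "TF",
    "DFA", "SampEN")
}

#' Time-domain HRV features of an RR fragment
#'
#' Mean, variance, maximum, minimum and coefficient of variation of the
#' intervals; RMSSD (root mean square of successive differences), SDSD
#' (standard deviation of successive differences, ddof 1) and PNN50
#' (percentage of successive differences exceeding 50 ms).
#'
#' @param rr numeric vector of RR intervals, seconds (at least 3).
#' @return Named numeric vector of the 8 time features; all `NA` (with no
#'   error) if the fragment is too short.
#' @export
time_features <- function(rr) {
  out <- c(Mean = NA_real_, Var = NA_real_, Max = NA_real_, Min = NA_real_,
           RMSSD = NA_real_, SDSD = NA_real_, PNN50 = NA_real_, CV = NA_real_)
  if (length(rr) < 3) return(out)
  d <- diff(rr)
  out["Mean"] <- mean(rr)
  out["Var"] <- var(rr)
  out["Max"] <- max(rr)
  out["Min"] <- min(rr)
  out["RMSSD"] <- sqrt(mean(d^2))
  out["SDSD"] <- sd(d)
  out["PNN50"] <- 100 * mean(abs(d) > 0.05)
  out["CV"] <- sd(rr) / mean(rr)
  out
}

#' Burg autoregressive power spectral density of a tachogram fragment
#'
#' Fits an AR model by Burg's method (order 16 by default) to the demeaned
#' series and evaluates the one-sided PSD on a uniform frequency grid over
#' `[0, fs/2]`.  The PSD is scaled so that its integral over `[0, fs/2]`
#' equals the driving-noise contribution to the series variance (for white
#' noise, the series variance).  If the requested order cannot be fitted
#' (near-singular short fragment), the order is reduced with a warning.
#'
#' @param x numeric series (a 4 Hz tachogram fragment); needs at least
#'   `3 * order` samples for the full order.
#' @param fs sampling rate, Hz (default 4).
#' @param order AR order (default 16).
#' @param n_freq grid resolution (default 512).
#' @return List of class `ar_psd`: `freq` (Hz), `psd`, `order`, `fs`.
#' @export
ar_spectrum <- function(x, fs = 4, order = 16, n_freq = 512) {
  if (var(x) == 0) stop("zero-variance input", call. = FALSE)
  ord <- min(order, max(1L, floor(length(x) / 3)))
  if (ord < order)
    warning(sprintf("fragment too short for AR order %d; using %d",
                    order, ord))
  fit <- NULL
  while (is.null(fit) && ord >= 1) {
    fit <- tryCatch(
      ar(x, aic = FALSE, order.max = ord, method = "burg", demean = TRUE),
      error = function(e) NULL)
    if (is.null(fit)) {
      ord <- ord - 1L
      warning(sprintf("Burg fit near-singular; falling back to order %d", ord))
    }
  }
  if (is.null(fit)) stop("AR fit failed at every order", call. = FALSE)
  f <- seq(0, fs / 2, length.out = n_freq)
  a <- fit$ar
  # transfer denominator |1 - sum a_k exp(-i 2 pi f k / fs)|^2
  ek <- exp(-2i * pi * outer(f / fs, seq_along(a)))
  den <- abs(1 - drop(ek %*% a))^2
  psd <- (fit$var.pred / fs) * 2 / den   # one-sided
  structure(list(freq = f, psd = psd, order = ord, fs = fs),
            class = "ar_psd")
}

#' Frequency-domain HRV features from a power spectral density
#'
#' Band powers by trapezoidal integration of the PSD over the standard HRV
#' bands: vLF 0.0033-0.04 Hz, LF 0.04-0.15 Hz, HF 0.15-0.4 Hz, vHF
#' 0.4-0.5 Hz and TF 0-0.5 Hz; normalised powers
#' `LF_nor = LF / (LF + HF)`, `HF_nor = HF / (HF + LF)` and the `LF/HF`
#' ratio.
#'
#' @param psd an [ar_spectrum()] result (or list with `freq`, `psd`
#'   covering `[0, 0.5]` Hz).
#' @return Named numeric vector of the 8 frequency features; the normalised
#'   features are `NA` when `LF + HF` is zero.
#' @export
freq_features <- function(psd) {
  if (max(psd$freq) < 0.5)
    stop("PSD must cover [0, 0.5] Hz", call. = FALSE)
  band <- function(lo, hi) {
    f <- psd$freq
    grid <- sort(unique(c(lo, hi, f[f > lo & f < hi])))
    v <- approx(f, psd$psd, xout = grid)$y
    sum(diff(grid) * (head(v, -1) + tail(v, -1)) / 2)
  }
  vLF <- band(0.0033, 0.04)
  LF <- band(0.04, 0.15)
  HF <- band(0.15, 0.4)
  vHF <- band(0.4, 0.5)
  TF <- band(0, 0.5)
  if (LF + HF > 0) {
    LF_nor <- LF / (LF + HF)
    HF_nor <- HF / (HF + LF)
    LF_HF <- LF / HF
  } else {
    LF_nor <- HF_nor <- LF_HF <- NA_real_
  }
  c(vLF = vLF, LF = LF, HF = HF, vHF = vHF, LF_nor = LF_nor,
    HF_nor = HF_nor, LF_HF = LF_HF, TF = TF)
}

#' Short-term detrended fluctuation analysis exponent
#'
#' Integrates the demeaned series, splits the profile into non-overlapping
#' windows of size `s`, removes a least-squares line per window, and
#' regresses `log F(s)` on `log s` over `n_scales` log-spaced window sizes
#' in `[s_min, s_max]`.  White noise gives an exponent near 0.5, integrated
#' white noise near 1.5.  Scale units are samples of the input series.
#'
#' @param x numeric series; needs at least `4 * s_min` samples, otherwise
#'   `NA` is returned.  If shorter than `4 * s_max`, the largest scale is
#'   shrunk accordingly (flagged via attribute `"s_max_used"`).
#' @param s_min,s_max scale range in samples (default 40 to 320).
#' @param n_scales number of log-spaced scales (default 10).
#' @return The scaling exponent alpha (`NA` for constant or too-short input).
#' @export
dfa_alpha <- function(x, s_min = 40, s_max = 320, n_scales = 10) {
  n <- length(x)
  if (n < 4 * s_min || var(x) == 0) return(NA_real_)
  s_max_used <- min(s_max, floor(n / 4))
  scales <- unique(round(exp(seq(log(s_min), log(s_max_used),
                                 length.out = n_scales))))
  y <- cumsum(x - mean(x))
  Fs <- vapply(scales, function(s) {
    k <- n %/% s
    res2 <- 0
    tloc <- seq_len(s)
    sx <- sum(tloc); sxx <- sum(tloc^2)
    det <- s * sxx - sx^2
    for (w in seq_len(k)) {
      seg <- y[((w - 1) * s + 1):(w * s)]
      sy <- sum(seg); sxy <- sum(tloc * seg)
      b <- (s * sxy - sx * sy) / det
      a <- (sy - b * sx) / s
      res2 <- res2 + sum((seg - a - b * tloc)^2)
    }
    sqrt(res2 / (k * s))
  }, numeric(1))
  keep <- Fs > 0
  if (sum(keep) < 2) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, log(scales[keep])), log(Fs[keep]))
  alpha <- unname(fit$coefficients[2])
  attr(alpha, "s_max_used") <- s_max_used
  alpha
}

#' Sample entropy of a series
#'
#' `-log(A / B)` where `B` counts pairs of length-`m` templates matching
#' within tolerance `r` under the Chebyshev distance and `A` counts pairs
#' still matching at length `m + 1`; self-matches are excluded.  The pair
#' counting runs in compiled code.
#'
#' @param x numeric series of length at least 50.
#' @param m template length (default 2).
#' @param r tolerance; default `0.2 * sd(x)`.
#' @return Sample entropy, or `NA` when `A` or `B` is zero (no matches --
#'   the conditional probability is undefined) or the series is too short.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  if (length(x) < 50 || !is.finite(r) || r <= 0) return(NA_real_)
  cnt <- sampen_counts(as.numeric(x), as.integer(m), r)
  if (cnt[1] == 0 || cnt[2] == 0) return(NA_real_)
  -log(cnt[1] / cnt[2])
}

#' The 18-feature HRV vector of one fragment
#'
#' Time-domain features are computed on the raw (unresampled) RR intervals
#' of the fragment; spectral, DFA and sample-entropy features on the
#' uniformly resampled 4 Hz tachogram samples, following the usual HRV
#' convention.
#'
#' @param rr_frag numeric vector of raw RR intervals in the fragment,
#'   seconds.
#' @param tach_frag numeric vector of 4 Hz tachogram samples in the
#'   fragment.
#' @param fs tachogram rate (default 4).
#' @return Named numeric vector of length 18 (order as
#'   [hrv_feature_names()]); undefined entries are `NA`.
#' @export
fragment_features <- function(rr_frag, tach_frag, fs = 4) {
  tf <- time_features(rr_frag)
  ff <- c(vLF = NA_real_, LF = NA_real_, HF = NA_real_, vHF = NA_real_,
          LF_nor = NA_real_, HF_nor = NA_real_, LF_HF = NA_real_,
          TF = NA_real_)
  if (length(tach_frag) >= 8 && var(tach_frag) > 0) {
    psd <- suppressWarnings(ar_spectrum(tach_frag, fs = fs))
    ff <- freq_features(psd)
  }
  dfa <- if (length(tach_frag) > 0) dfa_alpha(tach_frag) else NA_real_
  se <- if (length(tach_frag) > 0) sample_entropy(tach_frag) else NA_real_
  out <- c(tf, ff, DFA = as.numeric(dfa), SampEN = se)
  stopifnot(length(out) == 18)
  names(out) <- hrv_feature_names()
  out
}

#' Feature matrix for all examine-status fragments of a fragment set
#'
#' @param fset a [physio_icss()] result.
#' @param tachogram the tachogram the fragment set was computed on.
#' @param rr the raw [rr_series()] (for the time-domain features); intervals
#'   are assigned to fragments by the time of their ending beat.
#' @return A data.frame: `fragment_id`, `start_s`, `end_s`, the 18 feature
#'   columns.  Only fragments with status 1 are included.
#' @export
fragment_feature_matrix <- function(fset, tachogram, rr) {
  sel <- which(fset$fragments$status == 1)
  rows <- lapply(sel, function(i) {
    fr <- fset$fragments[i, ]
    idx <- fset$index[[i]]
    tach_frag <- tachogram$rr[idx]
    bt <- rr$beat_times[-1]
    lim <- fr$start_s + fr$capped_len_s
    rr_frag <- rr$rr[bt >= fr$start_s & bt <= min(fr$end_s, lim)]
    c(fragment_id = i, start_s = fr$start_s, end_s = fr$end_s,
      fragment_features(rr_frag, tach_frag, fs = tachogram$fs))
  })
  as.data.frame(do.call(rbind, rows))
}
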
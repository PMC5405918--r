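#' An RR-interval series with provenance flags
#'
#' @param beat_times strictly increasing beat times, seconds.
#' @param flags optional per-interval provenance, one of `"raw"`,
#'   `"split-from-leak"`, `"merged-from-fault"`.
#' @return Object of class `rr_series`: list with `beat_times`, `rr`
#'   (intervals, seconds) and `flags`.
#' @export
rr_series <- function(beat_times, flags = NULL) {
  beat_times <- as.numeric(beat_times)
  rr <- diff(beat_times)
  if (any(rr <= 0))
    stop("beat times must be strictly increasing", call. = FALSE)
  if (is.null(flags)) flags <- rep("raw", length(rr))
  if (length(flags) != length(rr))
    stop("one flag per interval required", call. = FALSE)
  structure(list(beat_times = beat_times, rr = rr, flags = flags),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d intervals, span %.1f s, mean RR %.3f s\n",
              length(x$rr), sum(x$rr), mean(x$rr)))
  invisible(x)
}

#' Detect heartbeat troughs with an overlapped sliding window
#'
#' Slides a window of `window` samples in steps of `step` samples over the
#' signal; the minimum of each window is a candidate beat (ties broken to
#' the earliest sample).  Candidates found by several windows at the same
#' sample are consolidated to one beat.  With
#' `consolidate = "refractory"`, candidates closer than `refractory`
#' seconds are additionally merged keeping the deeper one; the default
#' (`"dedup"`) keeps all distinct window minima and leaves short spurious
#' intervals to the downstream RR correction stage, which is what the
#' rule-based corrector is designed to clean up.
#'
#' @param signal numeric vector, a [bcg_record()], or a [wavelet_stack()]
#'   approximation (pass the vector).
#' @param fs sampling rate in Hz (taken from the record if one is given).
#' @param window window length in samples (default 100, i.e. 1 s at 100 Hz).
#' @param step sliding step in samples (default 80); must be < window.
#' @param consolidate candidate consolidation rule, see Details.
#' @param refractory refractory gap in seconds for
#'   `consolidate = "refractory"` (default 0.25).
#' @return An [rr_series()]; attribute `"beat_idx"` holds the 1-based sample
#'   indices of the kept beats.
#' @export
detect_troughs <- function(signal, fs = 100, window = 100, step = 80,
                           consolidate = c("dedup", "refractory"),
                           refractory = 0.25) {
  consolidate <- match.arg(consolidate)
  if (inherits(signal, "bcg_record")) {
    fs <- signal$fs
    signal <- signal$samples
  }
  if (!(window > step && step > 0))
    stop("need window > step > 0", call. = FALSE)
  n <- length(signal)
  if (n < window) {
    warning("signal shorter than one window; no beats detected")
    return(structure(list(beat_times = numeric(0), rr = numeric(0),
                          flags = character(0)), class = "rr_series"))
  }
  starts <- as.integer(seq.int(1L, n - window + 1L, by = step))
  idx <- vapply(starts, function(s) {
    s + which.min(signal[s:(s + window - 1L)]) - 1L
  }, integer(1))
  idx <- sort(unique(idx))
  if (consolidate == "refractory") {
    gap <- refractory * fs
    repeat {
      d <- diff(idx)
      j <- which(d < gap)
      if (!length(j)) break
      j <- j[1]
      drop <- if (signal[idx[j]] <= signal[idx[j + 1]]) j + 1 else j
      idx <- idx[-drop]
    }
  }
  if (length(idx) < 2) {
    warning("fewer than two beats detected")
    return(structure(list(beat_times = (idx - 1) / fs, rr = numeric(0),
                          flags = character(0)), class = "rr_series"))
  }
  out <- rr_series((idx - 1) / fs)
  attr(out, "beat_idx") <- idx
  out
}

#' Rule-based correction of leak- and fault-checked RR intervals
#'
#' Scans the interval series left to right.  For each interval the local
#' mean over up to `2 * omega` surrounding intervals (excluding the interval
#' itself, truncated at the boundaries) is the reference.  An interval
#' longer than 1.5 times the reference is a *leak check* (missed beats): it
#' is split into `k = floor(RR / mean + 1/2)` equal parts.  An interval
#' shorter than half the reference is a *fault check* (spurious beat): it is
#' removed, its mass redistributed to its neighbours -- split equally between
#' both neighbours when they differ by less than the reference, otherwise
#' merged wholly into the smaller neighbour.  Total duration is conserved
#' exactly; corrections are applied in place so later reference means see
#' the already-corrected series.
#'
#' @param rr an [rr_series()] (or bare numeric vector of intervals).
#' @param omega half-width of the reference neighbourhood in intervals
#'   (default 5, i.e. the mean of 10 surrounding intervals).
#' @return An [rr_series()] with updated provenance flags.
#' @examples
#' r <- rr_series(cumsum(c(0, 1, 1, 1, 1, 1, 2.0, 1, 1, 1, 1, 1)))
#' sum(correct_rr(r)$rr) == sum(r$rr)
#' @export
correct_rr <- function(rr, omega = 5) {
  vec_in <- !inherits(rr, "rr_series")
  x <- if (vec_in) as.numeric(rr) else rr$rr
  t0 <- if (vec_in) 0 else rr$beat_times[1]
  flags <- if (vec_in) rep("raw", length(x)) else rr$flags
  if (length(x) < 2 * omega + 1) {
    warning("series shorter than the correction neighbourhood; passthrough")
    return(if (vec_in) rr else rr)
  }
  i <- 1L
  while (i <= length(x)) {
    n <- length(x)
    nb <- setdiff(max(1L, i - omega):min(n, i + omega), i)
    m <- mean(x[nb])
    if (x[i] > 1.5 * m) {
      k <- floor(x[i] / m + 0.5)
      if (k >= 2) {
        x <- append(x[-i], rep(x[i] / k, k), after = i - 1L)
        flags <- append(flags[-i], rep("split-from-leak", k), after = i - 1L)
        i <- i + k
        next
      }
    } else if (x[i] < 0.5 * m) {
      if (i == 1L) {
        x[2] <- x[2] + x[1]
        flags[2] <- "merged-from-fault"
        x <- x[-1]; flags <- flags[-1]
        next
      }
      if (i == length(x)) {
        x[i - 1] <- x[i - 1] + x[i]
        flags[i - 1] <- "merged-from-fault"
        x <- x[-i]; flags <- flags[-i]
        break
      }
      if (max(x[i - 1], x[i + 1]) - min(x[i - 1], x[i + 1]) < m) {
        x[i - 1] <- x[i - 1] + 0.5 * x[i]
        x[i + 1] <- x[i + 1] + 0.5 * x[i]
        flags[c(i - 1, i + 1)] <- "merged-from-fault"
      } else {
        w <- if (x[i - 1] <= x[i + 1]) i - 1L else i + 1L
        x[w] <- x[w] + x[i]
        flags[w] <- "merged-from-fault"
      }
      x <- x[-i]; flags <- flags[-i]
      next
    }
    i <- i + 1L
  }
  out <- rr_series(t0 + c(0, cumsum(x)), flags = flags)
  if (vec_in) out$rr else out
}

#' Resample an RR series to a uniform tachogram by cubic spline
#'
#' Each interval is attributed to the time of its ending beat; a cubic
#' spline through these points is evaluated on a uniform grid spanning
#' `[first beat, last beat]` at `fs_out` Hz.
#'
#' @param rr an [rr_series()].
#' @param fs_out output sampling rate, Hz (default 4).
#' @return A list of class `tachogram`: `t` (seconds), `rr` (interpolated
#'   intervals, seconds), `fs`.
#' @export
resample_rr <- function(rr, fs_out = 4) {
  stopifnot(inherits(rr, "rr_series"))
  if (length(rr$rr) < 4)
    stop("need at least 4 beats to resample", call. = FALSE)
  tt <- rr$beat_times[-1]
  grid <- seq(rr$beat_times[1], rr$beat_times[length(rr$beat_times)],
              by = 1 / fs_out)
  val <- spline(tt, rr$rr, xout = grid, method = "fmm")$y
  structure(list(t = grid, rr = val, fs = fs_out), class = "tachogram")
}

#' @export
print.tachogram <- function(x, ...) {
  cat(sprintf("<tachogram> %d samples @ %g Hz\n", length(x$rr), x$fs))
  invisible(x)
}

#' Extract a corrected RR series from a raw BCG record
#'
#' Convenience wrapper running the preprocessing chain: wavelet
#' approximation (level `level`), overlapped sliding-window trough
#' detection, and rule-based RR correction.
#'
#' @param record a [bcg_record()].
#' @param level wavelet approximation level fed to the detector (default 4);
#'   `0` skips the wavelet stage and detects on the raw signal.
#' @param window,step,consolidate,refractory passed to [detect_troughs()].
#' @param omega passed to [correct_rr()].
#' @return An [rr_series()].
#' @export
extract_rr <- function(record, level = 4, window = 100, step = 80,
                       consolidate = "dedup", refractory = 0.25, omega = 5) {
  sig <- if (level > 0) {
    wavelet_approximations(record, levels = max(level, 4))$approximations[[level]]
  } else {
    record$samples
  }
  rr <- detect_troughs(sig, fs = record$fs, window = window, step = step,
                       consolidate = consolidate, refractory = refractory)
  correct_rr(rr, omega = omega)
}

#' Write an RR series as CSV (beat_time_s, rr_s, flag)
#' @param rr an [rr_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rr_csv <- function(rr, path) {
  write.csv(data.frame(beat_time_s = rr$beat_times[-1], rr_s = rr$rr,
                       flag = rr$flags), path, row.names = FALSE)
  invisible(path)
}

#' Read an RR series from CSV written by [write_rr_csv()]
#' @param path input file.
#' @return An [rr_series()].
#' @export
read_rr_csv <- function(path) {
  d <- read.csv(path)
  rr_series(c(d$beat_time_s[1] - d$rr_s[1], d$beat_time_s),
            flags = as.character(d$flag))
}
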
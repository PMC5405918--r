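#' Specification for the synthetic sine-wave BCG validation signal
#'
#' Describes the standard validation recipe for the RR extraction and
#' correction stage: a pure sine (one trough per period, emulating one
#' heartbeat per second at the default sampling rate), additive white
#' Gaussian noise at a prescribed SNR, and a number of randomly placed
#' trough-like replacement points that act as potential leak/fault checks.
#'
#' @param n_periods number of sine periods (default 10000).
#' @param samples_per_period samples per period; also the sampling rate in Hz,
#'   so that one period lasts one second (default 100).
#' @param snr_db signal-to-noise ratio in dB (signal power / noise power);
#'   `Inf` disables noise. Default 10.
#' @param n_artifacts number of replacement artifacts (default 1000).
#' @param artifact_y_range amplitude interval the artifacts are drawn from,
#'   uniformly (default `c(-1.2, -0.8)`, bracketing the sine trough at -1).
#' @param seed integer seed fixing the generated record bit-exactly.
#'
#' @return An object of class `synthetic_spec`.
#' @seealso [gen_sine_bcg()], [inject_artifacts()]
#' @export
synthetic_spec <- function(n_periods = 10000, samples_per_period = 100,
                           snr_db = 10, n_artifacts = 1000,
                           artifact_y_range = c(-1.2, -0.8), seed = 1L) {
  if (!is.numeric(n_periods) || n_periods < 1 ||
      !is.numeric(samples_per_period) || samples_per_period < 2)
    stop("invalid synthetic spec: counts must be positive", call. = FALSE)
  if (length(artifact_y_range) != 2 ||
      artifact_y_range[1] >= artifact_y_range[2])
    stop("invalid synthetic spec: artifact_y_range lower must be < upper",
         call. = FALSE)
  if (n_artifacts < 0 || n_artifacts > n_periods * samples_per_period)
    stop("invalid synthetic spec: artifact count exceeds total samples",
         call. = FALSE)
  structure(list(n_periods = as.integer(n_periods),
                 samples_per_period = as.integer(samples_per_period),
                 snr_db = snr_db, n_artifacts = as.integer(n_artifacts),
                 artifact_y_range = artifact_y_range,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' A uniformly sampled BCG record
#'
#' @param samples numeric amplitude sequence.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample, seconds.
#' @return An object of class `bcg_record`.
#' @export
bcg_record <- function(samples, fs = 100, t0 = 0) {
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (any(!is.finite(samples))) stop("samples must be finite", call. = FALSE)
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "bcg_record")
}

#' @export
print.bcg_record <- function(x, ...) {
  cat(sprintf("<bcg_record> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Generate the sine-wave validation BCG signal
#'
#' Produces `n_periods * samples_per_period` samples of a unit-amplitude sine
#' with additive white Gaussian noise scaled so that the empirical power
#' ratio matches `snr_db`.  The noiseless signal has exactly one trough per
#' period, at sample offsets `0.75 * samples_per_period` within each period
#' (0-based).
#'
#' @param spec a [synthetic_spec()].
#' @return A [bcg_record()] with attribute `"trough_idx"` giving the 1-based
#'   sample indices of the analytic troughs.
#' @examples
#' rec <- gen_sine_bcg(synthetic_spec(n_periods = 50, seed = 1))
#' length(rec$samples)  # 5000
#' @export
gen_sine_bcg <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$samples_per_period
  n <- spec$n_periods * p
  t <- seq_len(n) - 1
  sig <- sin(2 * pi * t / p)
  if (is.finite(spec$snr_db)) {
    set.seed(spec$seed)
    noise_sd <- sqrt(mean(sig^2) / 10^(spec$snr_db / 10))
    sig <- sig + rnorm(n, 0, noise_sd)
  }
  rec <- bcg_record(sig, fs = p)
  attr(rec, "trough_idx") <- as.integer(round(0.75 * p) + 1 +
                                          p * (seq_len(spec$n_periods) - 1))
  rec
}

#' Inject trough-like replacement artifacts into a BCG record
#'
#' Replaces `n_artifacts` samples (positions drawn uniformly without
#' replacement) with amplitudes uniform in `artifact_y_range`, emulating
#' spurious trough-like disturbances (e.g. limb movements).  The artifact
#' draw continues the RNG stream of the record generator, so a full
#' `gen_sine_bcg() |> inject_artifacts()` run is reproduced by the seed in
#' the spec alone.
#'
#' @param record a [bcg_record()].
#' @param spec a [synthetic_spec()].
#' @return A list with elements `record` (modified [bcg_record()]) and
#'   `positions` (1-based indices of the replaced samples, sorted).
#' @export
inject_artifacts <- function(record, spec) {
  stopifnot(inherits(record, "bcg_record"), inherits(spec, "synthetic_spec"))
  n <- length(record$samples)
  if (spec$n_artifacts > n)
    stop("artifact count exceeds record length", call. = FALSE)
  if (spec$n_artifacts == 0L)
    return(list(record = record, positions = integer(0)))
  pos <- sort(sample.int(n, spec$n_artifacts))
  record$samples[pos] <- runif(spec$n_artifacts,
                               spec$artifact_y_range[1],
                               spec$artifact_y_range[2])
  list(record = record, positions = pos)
}

#' Specify apnea/hypopnoea episodes for the RR generator
#'
#' @param start episode onsets, seconds.
#' @param duration episode durations, seconds; each must be at least 10 s
#'   (shorter respiratory pauses are by definition not scoreable events).
#' @return A data.frame with columns `start`, `end`, `duration`.
#' @export
apnea_episodes <- function(start, duration) {
  if (length(start) != length(duration))
    stop("start and duration lengths differ", call. = FALSE)
  if (any(duration < 10))
    stop("invalid episode: duration below the 10 s event floor",
         call. = FALSE)
  o <- order(start)
  start <- start[o]; duration <- duration[o]
  end <- start + duration
  if (length(start) > 1 && any(start[-1] < end[-length(end)]))
    stop("invalid episodes: overlapping", call. = FALSE)
  data.frame(start = start, end = end, duration = duration)
}

#' Generate an RR-interval series containing apnea episodes
#'
#' Baseline beats are `base_rr` plus white Gaussian jitter.  Inside each
#' episode the jitter standard deviation is scaled by `sqrt(var_mult)` and a
#' single cyclic bradycardia--tachycardia swing of amplitude `cyclic_amp`
#' (seconds, one full cycle per episode) is superimposed, emulating the
#' cyclic variation of heart rate that accompanies obstructive events.  The
#' final interval is trimmed (or the penultimate one extended) so that the
#' cumulative RR sum equals `duration` exactly.
#'
#' @param duration total duration, seconds.
#' @param base_rr baseline RR interval in seconds, within `[0.4, 2]`.
#' @param episodes `NULL` or an [apnea_episodes()] table.
#' @param jitter_sd baseline beat-to-beat jitter SD, seconds (default 0.03).
#' @param var_mult multiplicative jitter-variance change inside episodes
#'   (default 4).
#' @param cyclic_amp amplitude of the in-episode cyclic RR swing, seconds
#'   (default 0.15).
#' @param seed integer seed.
#' @param stages optional [gen_sleep_stages()] track; if supplied, all
#'   episodes must lie inside non-Wake epochs.
#' @return A list with elements `rr` (an [rr_series()]) and `events`
#'   (data.frame `start`, `end`, `duration`).
#' @export
gen_rr_with_events <- function(duration, base_rr = 1.0, episodes = NULL,
                               jitter_sd = 0.03, var_mult = 4,
                               cyclic_amp = 0.15, seed = 1L, stages = NULL) {
  if (base_rr < 0.4 || base_rr > 2.0)
    stop("base_rr must lie in [0.4, 2] s", call. = FALSE)
  if (!is.null(episodes)) {
    if (!all(c("start", "end") %in% names(episodes)))
      stop("episodes must come from apnea_episodes()", call. = FALSE)
    if (any(episodes$end - episodes$start < 10))
      stop("invalid episode: duration below the 10 s event floor",
           call. = FALSE)
    if (nrow(episodes) > 1 &&
        any(episodes$start[-1] < episodes$end[-nrow(episodes)]))
      stop("invalid episodes: overlapping", call. = FALSE)
    if (any(episodes$end > duration))
      stop("episodes extend beyond the requested duration", call. = FALSE)
    if (!is.null(stages) && !all(in_stage(episodes, stages, "Wake") == 0))
      stop("episodes must lie inside non-Wake epochs", call. = FALSE)
  }
  set.seed(seed)
  n_max <- ceiling(duration / base_rr * 1.5) + 10
  rr <- numeric(n_max); t <- 0; i <- 0
  ep_i <- 1L
  while (t < duration) {
    i <- i + 1
    in_ep <- FALSE
    if (!is.null(episodes) && nrow(episodes)) {
      while (ep_i <= nrow(episodes) && t >= episodes$end[ep_i])
        ep_i <- ep_i + 1L
      in_ep <- ep_i <= nrow(episodes) && t >= episodes$start[ep_i]
    }
    if (in_ep) {
      u <- (t - episodes$start[ep_i]) /
        (episodes$end[ep_i] - episodes$start[ep_i])
      x <- base_rr - cyclic_amp * sin(2 * pi * u) +
        rnorm(1, 0, jitter_sd * sqrt(var_mult))
    } else {
      x <- base_rr + rnorm(1, 0, jitter_sd)
    }
    rr[i] <- max(x, 0.25 * base_rr)
    t <- t + rr[i]
  }
  rr <- rr[seq_len(i)]
  # close the record exactly on `duration`
  excess <- t - duration
  if (rr[i] - excess >= 0.25 * base_rr) {
    rr[i] <- rr[i] - excess
  } else {
    rr <- rr[-i]
    m <- length(rr)
    rr[m] <- duration - sum(rr[-m])
  }
  events <- if (is.null(episodes)) {
    data.frame(start = numeric(0), end = numeric(0), duration = numeric(0))
  } else {
    data.frame(start = episodes$start, end = episodes$end,
               duration = episodes$end - episodes$start)
  }
  list(rr = rr_series(beat_times = c(0, cumsum(rr))), events = events)
}

#' Generate an epoch-wise sleep-stage track
#'
#' Stages are drawn from a first-order Markov chain over Wake/NREM/REM with
#' strong self-transition (0.92), giving realistic multi-epoch bouts.  The
#' initial state is NREM; `p_wake` tunes how often the chain visits Wake
#' (set it to 0 for an uninterrupted sleep track).
#'
#' @param duration total duration, seconds.
#' @param epoch epoch length, seconds (default 30, the standard scoring
#'   epoch). Duration is truncated to a whole number of epochs.
#' @param seed integer seed.
#' @param p_wake relative propensity of switching into Wake (default 0.05).
#' @return An object of class `stage_track`: a data.frame with `start_s`,
#'   `end_s`, `label`, and attribute `epoch_s`.
#' @export
gen_sleep_stages <- function(duration, epoch = 30, seed = 1L, p_wake = 0.05) {
  n <- floor(duration / epoch)
  set.seed(seed)
  states <- c("Wake", "NREM", "REM")
  lab <- character(n)
  cur <- "NREM"
  for (k in seq_len(n)) {
    lab[k] <- cur
    if (runif(1) > 0.92) {
      others <- setdiff(states, cur)
      w <- ifelse(others == "Wake", p_wake, 1)
      cur <- sample(others, 1, prob = w / sum(w))
    }
  }
  stage_track(lab, epoch_s = epoch)
}

#' Construct a stage track from epoch labels
#'
#' @param labels character vector of epoch labels in `Wake`, `NREM`, `REM`.
#' @param epoch_s epoch length in seconds.
#' @param t0 start time of the first epoch, seconds.
#' @return A `stage_track` data.frame.
#' @export
stage_track <- function(labels, epoch_s = 30, t0 = 0) {
  if (!all(labels %in% c("Wake", "NREM", "REM")))
    stop("labels must be Wake, NREM or REM", call. = FALSE)
  n <- length(labels)
  out <- data.frame(start_s = t0 + (seq_len(n) - 1) * epoch_s,
                    end_s = t0 + seq_len(n) * epoch_s,
                    label = labels, stringsAsFactors = FALSE)
  attr(out, "epoch_s") <- epoch_s
  class(out) <- c("stage_track", "data.frame")
  out
}

# seconds of each interval table row spent in epochs of `label`
in_stage <- function(intervals, stages, label) {
  sel <- stages$label == label
  if (!any(sel)) return(rep(0, nrow(intervals)))
  st <- stages[sel, , drop = FALSE]
  vapply(seq_len(nrow(intervals)), function(i) {
    sum(pmax(0, pmin(intervals$end[i], st$end_s) -
               pmax(intervals$start[i], st$start_s)))
  }, numeric(1))
}

#' Place non-overlapping apnea episodes uniformly inside non-Wake sleep
#'
#' Utility used to build whole-night simulations with a planted event count.
#' Episode durations are uniform in `dur_range`; onsets are drawn so that
#' episodes do not overlap, keep at least `gap` seconds apart, and lie inside
#' non-Wake epochs of `stages` (when given).
#'
#' @param n number of episodes.
#' @param duration night duration, seconds.
#' @param dur_range episode duration range, seconds (default `c(10, 40)`).
#' @param gap minimum separation between episodes, seconds (default 15).
#' @param stages optional [stage_track()].
#' @param seed integer seed.
#' @return An [apnea_episodes()] table.
#' @export
place_episodes <- function(n, duration, dur_range = c(10, 40), gap = 15,
                           stages = NULL, seed = 1L) {
  set.seed(seed)
  starts <- numeric(0); ends <- numeric(0)
  tries <- 0
  while (length(starts) < n && tries < n * 200) {
    tries <- tries + 1
    d <- runif(1, dur_range[1], dur_range[2])
    s <- runif(1, 0, duration - d)
    if (length(starts) &&
        any(s < ends + gap & s + d > starts - gap)) next
    if (!is.null(stages)) {
      cand <- data.frame(start = s, end = s + d)
      if (in_stage(cand, stages, "Wake") > 0) next
      # must be fully covered by scored epochs
      if (s + d > max(stages$end_s)) next
    }
    starts <- c(starts, s); ends <- c(ends, s + d)
  }
  if (length(starts) < n)
    stop("could not place the requested number of episodes", call. = FALSE)
  apnea_episodes(starts, ends - starts)
}

#' Write a signal, events or stages to plain-text CSV
#'
#' @param x a [bcg_record()], events data.frame or [stage_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path) {
  if (inherits(x, "bcg_record")) {
    write.csv(data.frame(sample_index = seq_along(x$samples) - 1,
                         amplitude = x$samples),
              path, row.names = FALSE)
  } else if (inherits(x, "stage_track")) {
    write.csv(data.frame(start_s = x$start_s, end_s = x$end_s,
                         label = x$label), path, row.names = FALSE)
  } else {
    write.csv(x, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a two-column (sample_index, amplitude) CSV as a BCG record
#'
#' @param path input CSV file.
#' @param fs sampling rate in Hz (default 100).
#' @return A [bcg_record()].
#' @export
read_bcg_csv <- function(path, fs = 100) {
  d <- read.csv(path)
  bcg_record(d[[2]], fs = fs)
}
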
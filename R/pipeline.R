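# Whole-night orchestration: synthetic nights, fragment labelling against
# ground truth, classifier training, severity scoring, and the sine-wave
# RR extraction/correction validation experiment.

#' Simulate a whole night of RR intervals with planted breathing events
#'
#' Builds a sleep-stage track, plants `round(ahi * hours)` non-overlapping
#' apnea episodes inside non-Wake sleep, and generates the RR series with
#' [gen_rr_with_events()].
#'
#' @param duration_s night duration, seconds (default 6 h).
#' @param ahi planted apnea-hypopnoea index, events per non-Wake hour.
#' @param seed integer seed.
#' @param p_wake Wake propensity of the stage generator (default 0: an
#'   uninterrupted sleep track, so the planted AHI is exact over whole
#'   scored hours).
#' @param dur_range episode duration range, seconds (default `c(10, 40)`).
#' @param ... further arguments to [gen_rr_with_events()] (jitter, effect
#'   sizes).
#' @return List of class `synthetic_night`: `rr`, `stages`, `events`,
#'   `ahi_true`, `seed`.
#' @export
simulate_night <- function(duration_s = 6 * 3600, ahi = 10, seed = 1L,
                           p_wake = 0, dur_range = c(10, 40), ...) {
  stages <- gen_sleep_stages(duration_s, seed = seed, p_wake = p_wake)
  nonwake_h <- sum(stages$label != "Wake") * attr(stages, "epoch_s") / 3600
  n_ev <- round(ahi * floor(nonwake_h))
  eps <- if (n_ev > 0) {
    place_episodes(n_ev, duration_s, dur_range = dur_range,
                   stages = stages, seed = seed + 1L)
  } else NULL
  g <- gen_rr_with_events(duration_s, episodes = eps, seed = seed + 2L, ...)
  structure(list(rr = g$rr, stages = stages, events = g$events,
                 ahi_true = if (floor(nonwake_h) > 0) n_ev / floor(nonwake_h) else NA,
                 seed = seed),
            class = "synthetic_night")
}

#' Label examine-status fragments against ground-truth events
#'
#' A fragment is labelled `"SBE"` when it covers at least `min_overlap` of
#' some truth event, `"NSBE"` otherwise.
#'
#' @param fset a [physio_icss()] fragment set.
#' @param events truth table with `start`, `end` (seconds).
#' @param min_overlap fraction of the event duration (default 0.5).
#' @return Character vector, one label per status-1 fragment.
#' @export
label_fragments <- function(fset, events, min_overlap = 0.5) {
  fr <- fset$fragments[fset$fragments$status == 1, ]
  vapply(seq_len(nrow(fr)), function(i) {
    if (!nrow(events)) return("NSBE")
    ov <- pmin(fr$end_s[i], events$end) - pmax(fr$start_s[i], events$start)
    if (any(ov >= min_overlap * (events$end - events$start))) "SBE" else "NSBE"
  }, character(1))
}

#' Train an SBE/NSBE classifier on labelled synthetic nights
#'
#' Runs detection and feature extraction on each training night, labels the
#' fragments against the planted ground truth, and fits a classifier by
#' nested cross-validation.
#'
#' @param nights list of [simulate_night()] objects.
#' @param spec a [classifier_spec()] (default: RBF SVM with the compact
#'   grid).
#' @param config a [changepoint_config()].
#' @param seed RNG seed.
#' @param ... passed to [nested_cv_train()].
#' @return A [nested_cv_train()] fit.
#' @export
train_sbe_classifier <- function(nights, spec = classifier_spec("svm"),
                                 config = changepoint_config(), seed = 1L,
                                 ...) {
  feats <- list(); labs <- character(0)
  for (night in nights) {
    tach <- resample_rr(night$rr)
    fset <- physio_icss(tach$rr, fs = tach$fs, stages = night$stages,
                        config = config)
    if (!sum(fset$fragments$status == 1)) next
    fm <- fragment_feature_matrix(fset, tach, night$rr)
    feats[[length(feats) + 1]] <- fm[, hrv_feature_names()]
    labs <- c(labs, label_fragments(fset, night$events))
  }
  X <- do.call(rbind, feats)
  nested_cv_train(X, labs, spec, seed = seed, ...)
}

#' Run the full severity-assessment pipeline on one night
#'
#' Resamples the (corrected) RR series to a 4 Hz tachogram, detects
#' candidate fragments per non-Wake hour with [physio_icss()], extracts the
#' 18 HRV features for every examine-status fragment, classifies them with
#' the supplied model, and computes the AHI and severity class.
#'
#' @param night a [simulate_night()] object, or a list with elements `rr`
#'   (an [rr_series()]) and `stages` (a [stage_track()] or `NULL`).
#' @param classifier a [nested_cv_train()] fit; `NULL` counts every
#'   examine-status fragment as an SBE (detector-only mode).
#' @param config a [changepoint_config()].
#' @param out_dir if non-`NULL`, per-stage artifacts (fragments CSV,
#'   features CSV, predictions CSV, report JSON) are written there.
#' @return List of class `pipeline_result`: `report` (a
#'   [compute_ahi()] severity report), `fragments`, `features`,
#'   `labels`.
#' @export
run_pipeline <- function(night, classifier = NULL,
                         config = changepoint_config(), out_dir = NULL) {
  tach <- resample_rr(night$rr)
  fset <- physio_icss(tach$rr, fs = tach$fs, stages = night$stages,
                      config = config)
  if (fset$n_blocks == 0)
    stop("pipeline stage 'detect': no whole non-Wake block to analyse",
         call. = FALSE)
  examine <- fset$fragments$status == 1
  if (!any(examine)) {
    report <- compute_ahi(character(0), fset$n_blocks)
    return(structure(list(report = report, fragments = fset,
                          features = NULL, labels = character(0)),
                     class = "pipeline_result"))
  }
  fm <- fragment_feature_matrix(fset, tach, night$rr)
  labels <- if (is.null(classifier)) {
    rep("SBE", nrow(fm))
  } else {
    as.character(predict(classifier, fm[, hrv_feature_names()]))
  }
  report <- compute_ahi(labels, fset$n_blocks)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fragments_csv(fset, file.path(out_dir, "fragments.csv"))
    write.csv(fm, file.path(out_dir, "features.csv"), row.names = FALSE)
    write.csv(data.frame(fragment_id = fm$fragment_id, label = labels),
              file.path(out_dir, "predictions.csv"), row.names = FALSE)
    write_severity_json(report, file.path(out_dir, "report.json"))
  }
  structure(list(report = report, fragments = fset, features = fm,
                 labels = labels),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Score leak- and fault-checked intervals against a known beat period
#'
#' For the sine-wave validation signal the true RR interval is constant,
#' so an extracted interval is scored as a *leak check* when it exceeds 1.5
#' times the true interval and as a *fault check* when it is below half the
#' true interval (the same thresholds the correction algorithm applies to
#' the local mean).  The error rate is the percentage of scored intervals.
#'
#' @param rr numeric intervals or an [rr_series()].
#' @param true_rr the known beat period, seconds (default 1).
#' @return List with `n`, `leak`, `fault`, `error_rate` (percent).
#' @export
score_rr_errors <- function(rr, true_rr = 1.0) {
  x <- if (inherits(rr, "rr_series")) rr$rr else as.numeric(rr)
  leak <- sum(x > 1.5 * true_rr)
  fault <- sum(x < 0.5 * true_rr)
  list(n = length(x), leak = leak, fault = fault,
       error_rate = 100 * (leak + fault) / length(x))
}

#' The sine-wave RR extraction/correction validation experiment
#'
#' Repeats the standard validation recipe: generate the noisy sine signal
#' with trough-like artifacts ([gen_sine_bcg()] + [inject_artifacts()]),
#' extract intervals with the overlapped sliding window
#' ([detect_troughs()]), score leak/fault checks against the known period,
#' apply [correct_rr()], and rescore.
#'
#' @param n_reps number of replicates (default 100).
#' @param seed base seed; replicate `r` uses `seed + r`.
#' @param spec a [synthetic_spec()] template (its seed field is overridden
#'   per replicate).
#' @param window,step,consolidate passed to [detect_troughs()].
#' @param omega passed to [correct_rr()].
#' @return data.frame with one row per replicate: `seed`, `pre`, `post`
#'   (error rates, percent), `n_intervals`.
#' @export
rr_extraction_experiment <- function(n_reps = 100, seed = 1L,
                                     spec = synthetic_spec(),
                                     window = 100, step = 80,
                                     consolidate = "dedup", omega = 5) {
  res <- lapply(seq_len(n_reps), function(r) {
    sp <- spec
    sp$seed <- as.integer(seed + r)
    rec <- gen_sine_bcg(sp)
    rec <- inject_artifacts(rec, sp)$record
    rr <- detect_troughs(rec, window = window, step = step,
                         consolidate = consolidate)
    pre <- score_rr_errors(rr)
    rrc <- suppressWarnings(correct_rr(rr, omega = omega))
    post <- score_rr_errors(rrc)
    data.frame(seed = sp$seed, pre = pre$error_rate, post = post$error_rate,
               n_intervals = pre$n)
  })
  do.call(rbind, res)
}
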
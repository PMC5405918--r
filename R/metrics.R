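#' Event-detection error metrics
#'
#' From true-positive, false-positive and false-negative counts, computes
#' the error rate `ER = (FN + FP) / (TP + FN)`, the sensitivity rate
#' `SR = TP / (TP + FN)` and the positive prediction rate
#' `PPR = TP / (TP + FP)`, reported as percentages.  Note `ER` can exceed
#' 100% when false positives outnumber the true events.
#'
#' @param tp,fp,fn non-negative integer counts; `tp + fn` (true events) and
#'   `tp + fp` (detections) must both be positive.
#' @return List of class `detection_metrics` with the counts,
#'   `total_event_num`, `total_detected_num`, and `er`, `sr`, `ppr` in
#'   percent.
#' @examples
#' m <- detection_metrics(tp = 17707, fp = 1285, fn = 239)
#' round(c(m$er, m$sr, m$ppr), 1)  # 8.5 98.7 93.2
#' @export
detection_metrics <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0) || any(c(tp, fp, fn) %% 1 != 0))
    stop("counts must be non-negative integers", call. = FALSE)
  if (tp + fn == 0)
    stop("zero denominator: no true events (tp + fn = 0)", call. = FALSE)
  if (tp + fp == 0)
    stop("zero denominator: no detections (tp + fp = 0)", call. = FALSE)
  structure(list(tp = tp, fp = fp, fn = fn,
                 total_event_num = tp + fn, total_detected_num = tp + fp,
                 er = 100 * (fn + fp) / (tp + fn),
                 sr = 100 * tp / (tp + fn),
                 ppr = 100 * tp / (tp + fp)),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("<detection_metrics> TP %d FP %d FN %d | ER %.2f%% SR %.1f%% PPR %.1f%%\n",
              x$tp, x$fp, x$fn, x$er, x$sr, x$ppr))
  invisible(x)
}

#' Match detected fragments against ground-truth events
#'
#' Greedy one-to-one matching in time order: each truth event is matched to
#' the unmatched detected fragment with the largest overlap, provided the
#' overlap covers at least `min_overlap` of the truth duration.
#'
#' @param detected data.frame with `start` and `end` columns (seconds),
#'   non-overlapping; columns `start_s`/`end_s` are accepted too.
#' @param truth data.frame with `start` and `end` columns, non-overlapping.
#' @param min_overlap required overlap as a fraction of the truth event
#'   duration (default 0.5).
#' @return List with `tp`, `fp`, `fn` and the logical `matched` vectors for
#'   both tables.
#' @export
match_events <- function(detected, truth, min_overlap = 0.5) {
  norm <- function(d) {
    if (!"start" %in% names(d) && "start_s" %in% names(d))
      d <- data.frame(start = d$start_s, end = d$end_s)
    d[order(d$start), c("start", "end")]
  }
  detected <- norm(detected); truth <- norm(truth)
  check_no_overlap <- function(d, what) {
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)] - 1e-9))
      stop(sprintf("overlapping %s events", what), call. = FALSE)
  }
  check_no_overlap(truth, "truth")
  check_no_overlap(detected, "detected")
  used <- logical(nrow(detected))
  hit <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    ov <- pmin(truth$end[i], detected$end) - pmax(truth$start[i], detected$start)
    ov[used] <- -Inf
    if (nrow(detected) && max(ov) >= min_overlap * (truth$end[i] - truth$start[i])) {
      j <- which.max(ov)
      used[j] <- TRUE
      hit[i] <- TRUE
    }
  }
  list(tp = sum(hit), fp = sum(!used), fn = sum(!hit),
       matched_truth = hit, matched_detected = used)
}
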
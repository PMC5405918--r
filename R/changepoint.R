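#' Configuration for variance change-point detection
#'
#' @param confidence confidence level of the detection threshold (default
#'   0.99).
#' @param g_star decision threshold on the sup statistic; by default derived
#'   from `confidence` via [critical_value()] (0.99 gives 1.628).
#' @param min_event_s minimum scoreable event duration, seconds (default 10;
#'   shorter fragments get status 0).
#' @param max_segment_s cap on the effective fragment length used downstream,
#'   seconds (default 600).
#' @param block_s analysis block length, seconds (default 3600: detection
#'   runs independently per non-Wake hour).
#' @param lrv_estimator long-run scale estimator for the normalisation:
#'   `"fourth-moment"` (simple centred fourth moment of the squares) or
#'   `"bartlett"` (kernel-weighted HAC with bandwidth `floor(4 (T/100)^{2/9})`).
#' @param min_seg smallest segment (samples) the iterative search will test
#'   (default 8).
#' @param max_iter refinement iteration cap (default 20).
#' @return A list of class `changepoint_config`.
#' @export
changepoint_config <- function(confidence = 0.99, g_star = NULL,
                               min_event_s = 10, max_segment_s = 600,
                               block_s = 3600,
                               lrv_estimator = c("fourth-moment", "bartlett"),
                               min_seg = 8, max_iter = 20) {
  lrv_estimator <- match.arg(lrv_estimator)
  if (is.null(g_star)) g_star <- critical_value(confidence)
  if (g_star <= 0) stop("g_star must be > 0", call. = FALSE)
  if (min_event_s >= max_segment_s)
    stop("min_event_s must be < max_segment_s", call. = FALSE)
  structure(list(confidence = confidence, g_star = g_star,
                 min_event_s = min_event_s, max_segment_s = max_segment_s,
                 block_s = block_s, lrv_estimator = lrv_estimator,
                 min_seg = min_seg, max_iter = max_iter),
            class = "changepoint_config")
}

#' Critical value of the sup-normalised CUSUM-of-squares statistic
#'
#' Under the null of constant variance the statistic converges to the
#' sup-norm of a standard Brownian bridge, whose distribution function is
#' the Kolmogorov series
#' \deqn{P(\sup_t |B(t)| \le x) = 1 - 2\sum_{k\ge1} (-1)^{k+1} e^{-2k^2x^2}.}
#' The threshold is obtained by root finding on this series.
#'
#' @param confidence confidence level in (0, 1).
#' @return The threshold; `critical_value(0.99)` is 1.628 to three decimals.
#' @examples
#' round(critical_value(0.99), 3)  # 1.628
#' round(critical_value(0.95), 3)  # 1.358
#' @export
critical_value <- function(confidence) {
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0, 1)", call. = FALSE)
  cdf <- function(x) {
    if (x <= 0) return(0)
    if (x < 1) {
      # theta-transformed series, accurate for small x
      k <- 1:200
      sqrt(2 * pi) / x * sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * x^2)))
    } else {
      k <- 1:200
      1 - 2 * sum((-1)^(k + 1) * exp(-2 * k^2 * x^2))
    }
  }
  stats::uniroot(function(x) cdf(x) - confidence,
                 lower = 1e-8, upper = 5, tol = 1e-12)$root
}

#' Centred cumulative-sum-of-squares change statistic
#'
#' Computes the normalised centred CUSUM-of-squares process of a series
#' `x` (demeaned internally): with \eqn{C_t = \sum_{k\le t} e_k^2},
#' \eqn{G_t = (C_t - (t/T) C_T)/\sqrt{\hat\lambda}} where \eqn{\hat\lambda}
#' is a long-run estimate of the variance of the squares, and the test
#' statistic is \eqn{\kappa_2 = \sup_t |T^{-1/2} G_t|}.  The statistic is
#' invariant to rescaling of `x` and, asymptotically, its null law is the
#' sup of a Brownian bridge (threshold via [critical_value()]).
#'
#' @param x numeric series, length at least 8.
#' @param config a [changepoint_config()].
#' @return List of class `cusum_result`: `kappa2`, `t_star` (maximising
#'   index, ties to the smallest), `G` (the normalised process), `n`.
#'   Zero-variance input yields `kappa2 = 0` with a warning.
#' @export
cusum_statistic <- function(x, config = changepoint_config()) {
  n <- length(x)
  if (n < 8) stop("need at least 8 observations", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values", call. = FALSE)
  e <- x - mean(x)
  s2 <- e^2
  lam <- switch(config$lrv_estimator,
    "fourth-moment" = mean((s2 - mean(s2))^2),
    "bartlett" = {
      z <- s2 - mean(s2)
      bw <- max(0L, floor(4 * (n / 100)^(2 / 9)))
      g0 <- mean(z^2)
      acc <- g0
      for (l in seq_len(bw)) {
        w <- 1 - l / (bw + 1)
        acc <- acc + 2 * w * mean(z[seq_len(n - l)] * z[(l + 1):n])
      }
      max(acc, 0)
    })
  if (lam <= 0 || !is.finite(lam)) {
    warning("zero-variance input; kappa2 set to 0")
    return(structure(list(kappa2 = 0, t_star = 1L, G = rep(0, n), n = n),
                     class = "cusum_result"))
  }
  C <- cumsum(s2)
  G <- (C - (seq_len(n) / n) * C[n]) / sqrt(lam)
  k <- abs(G[-n]) / sqrt(n)
  t_star <- which.max(k)          # ties broken to the smallest index
  structure(list(kappa2 = k[t_star], t_star = t_star, G = G / sqrt(n), n = n),
            class = "cusum_result")
}

#' Iterative CUSUM-of-squares segmentation (variance change points)
#'
#' Recursive binary segmentation driven by [cusum_statistic()]: whenever the
#' statistic of a (sub)segment exceeds the threshold, the maximising index
#' is recorded and both sides are searched again.  The candidate set is then
#' refined: each point is re-estimated on the span between its neighbours
#' and the set is iterated until it is unchanged (or `max_iter` passes, with
#' a warning).  On exit no segment between adjacent points yields a
#' statistic above the threshold.
#'
#' @param x numeric series.
#' @param config a [changepoint_config()].
#' @return Integer vector of change-point indices (last index of the left
#'   segment), possibly empty.  Series shorter than 8 return an empty set.
#' @export
icss_segment <- function(x, config = changepoint_config()) {
  n <- length(x)
  if (n < max(8, 2 * config$min_seg)) return(integer(0))
  cps <- integer(0)
  search <- function(a, b) {
    if (b - a + 1 < 2 * config$min_seg) return()
    r <- suppressWarnings(cusum_statistic(x[a:b], config))
    if (r$kappa2 <= config$g_star) return()
    t <- a - 1L + r$t_star
    cps <<- c(cps, t)
    search(a, t)
    search(t + 1L, b)
  }
  search(1L, n)
  cps <- sort(unique(cps))
  converged <- length(cps) == 0
  seen <- list(cps)
  for (iter in seq_len(config$max_iter)) {
    if (!length(cps)) { converged <- TRUE; break }
    bounds <- c(0L, cps, n)
    new <- integer(0)
    for (j in seq_along(cps)) {
      a <- bounds[j] + 1L
      b <- bounds[j + 2]
      if (b - a + 1 < 2 * config$min_seg) next
      r <- suppressWarnings(cusum_statistic(x[a:b], config))
      if (r$kappa2 > config$g_star) new <- c(new, a - 1L + r$t_star)
    }
    new <- sort(unique(new))
    if (identical(new, cps)) { converged <- TRUE; break }
    # refinement can enter a short cycle; treat revisiting a state as
    # converged and keep the current set
    if (any(vapply(seen, identical, logical(1), y = new))) {
      cps <- new
      converged <- TRUE
      break
    }
    seen[[length(seen) + 1]] <- new
    cps <- new
  }
  if (!converged)
    warning("change-point refinement did not converge; returning current set")
  cps
}

#' Physiologically constrained change-point fragmentation (Physio-ICSS)
#'
#' Runs [icss_segment()] independently on each whole non-Wake block of
#' `block_s` seconds (sub-block residual time is discarded, mirroring the
#' hour-wise scoring of the AHI), then converts the change points of each
#' block into candidate fragments.  Fragment boundaries (`PF`) are the block
#' edges plus the detected change points; the status array `S` marks
#' fragments shorter than `min_event_s` as skip (0) -- too short to be a
#' scoreable breathing event -- and all others as examine (1).  The
#' effective length of each fragment is capped at `max_segment_s` for
#' downstream feature extraction, so that occasional missed boundaries do
#' not produce unbounded segments.
#'
#' @param x numeric series (typically a 4 Hz tachogram or BCG-derived
#'   amplitude series), sample `i` at time `t0 + (i-1)/fs`.
#' @param fs sampling rate of `x`, Hz.
#' @param stages optional [stage_track()] aligned with `x`; Wake epochs are
#'   excluded from analysis.  Missing stages treat the whole record as NREM
#'   (with a warning).
#' @param config a [changepoint_config()].
#' @param t0 time of the first sample, seconds.
#' @return A list of class `fragment_set`: `fragments` (data.frame with
#'   `start_s`, `end_s`, `raw_len_s`, `capped_len_s`, `status`, `block`),
#'   `n_blocks`, and `index` (list of per-fragment sample-index ranges into
#'   `x`, capped).
#' @export
physio_icss <- function(x, fs = 4, stages = NULL,
                        config = changepoint_config(), t0 = 0) {
  n <- length(x)
  tt <- t0 + (seq_len(n) - 1) / fs
  if (is.null(stages)) {
    warning("no stage track supplied; treating the whole record as NREM")
    keep <- rep(TRUE, n)
  } else {
    keep <- rep(FALSE, n)
    for (j in seq_len(nrow(stages))) {
      if (stages$label[j] != "Wake")
        keep <- keep | (tt >= stages$start_s[j] & tt < stages$end_s[j])
    }
  }
  sel <- which(keep)
  blk <- as.integer(round(config$block_s * fs))
  n_blocks <- length(sel) %/% blk
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      raw_len_s = numeric(0), capped_len_s = numeric(0),
                      status = integer(0), block = integer(0))
  if (n_blocks == 0)
    return(structure(list(fragments = empty, n_blocks = 0L, index = list()),
                     class = "fragment_set"))
  frags <- empty
  index <- list()
  for (b in seq_len(n_blocks)) {
    bi <- sel[((b - 1) * blk + 1):(b * blk)]
    cps <- icss_segment(x[bi], config)
    bounds <- c(0L, cps, blk)
    for (j in seq_len(length(bounds) - 1)) {
      i0 <- bounds[j] + 1L
      i1 <- bounds[j + 1]
      raw_len <- (i1 - i0 + 1) / fs
      capped <- min(config$max_segment_s, raw_len)
      status <- as.integer(raw_len >= config$min_event_s)
      i1_cap <- i0 + as.integer(round(capped * fs)) - 1L
      frags <- rbind(frags, data.frame(
        start_s = tt[bi[i0]], end_s = tt[bi[i1]] + 1 / fs,
        raw_len_s = raw_len, capped_len_s = capped,
        status = status, block = b))
      index[[length(index) + 1]] <- bi[i0:i1_cap]
    }
  }
  structure(list(fragments = frags, n_blocks = n_blocks, index = index),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  f <- x$fragments
  cat(sprintf("<fragment_set> %d fragments over %d block(s); %d to examine\n",
              nrow(f), x$n_blocks, sum(f$status == 1)))
  invisible(x)
}

#' Write a fragment set as CSV
#' @param fs a [physio_icss()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fragments_csv <- function(fs, path) {
  write.csv(fs$fragments, path, row.names = FALSE)
  invisible(path)
}
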
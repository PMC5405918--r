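#' Map an apnea-hypopnoea index to an AASM severity class
#'
#' Half-open bins: `[0, 5)` healthy, `[5, 15)` mild, `[15, 30)` moderate,
#' `[30, Inf)` severe.
#'
#' @param ahi events per hour, non-negative.
#' @return Character vector of severity classes.
#' @export
severity_class <- function(ahi) {
  if (any(ahi < 0)) stop("AHI must be non-negative", call. = FALSE)
  cut(ahi, breaks = c(0, 5, 15, 30, Inf), right = FALSE,
      labels = c("healthy", "mild", "moderate", "severe")) |>
    as.character()
}

#' Compute the AHI and severity report from classified fragments
#'
#' The AHI is the number of fragments classified as sleep-related breathing
#' events divided by the number of scored (whole, non-Wake) hours.
#'
#' @param labels per-fragment labels (`"SBE"` / `"NSBE"`), one per
#'   examine-status fragment.
#' @param hours_scored number of whole non-Wake hours analysed (e.g. the
#'   `n_blocks` of a [physio_icss()] result with hourly blocks).
#' @return List of class `severity_report`: `hours_scored`, `sbe_count`,
#'   `ahi`, `severity`.
#' @examples
#' compute_ahi(rep(c("SBE", "NSBE"), c(24, 10)), hours_scored = 6)$ahi  # 4
#' @export
compute_ahi <- function(labels, hours_scored) {
  if (hours_scored < 1) stop("zero scored hours", call. = FALSE)
  sbe <- sum(labels == "SBE")
  ahi <- sbe / hours_scored
  structure(list(hours_scored = hours_scored, sbe_count = sbe,
                 ahi = ahi, severity = severity_class(ahi)),
            class = "severity_report")
}

#' @export
print.severity_report <- function(x, ...) {
  cat(sprintf("<severity_report> %d SBEs over %g h: AHI = %.2f /h -> %s\n",
              x$sbe_count, x$hours_scored, x$ahi, x$severity))
  invisible(x)
}

#' Write a severity report as JSON
#' @param report a [compute_ahi()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_severity_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
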
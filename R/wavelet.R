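# Periodized orthogonal DWT with the Symlet-8 filter, plus reconstruction of
# the approximation branch at the original signal length.  Implemented
# in-package: the analysis operator W maps a length-N block to N/2
# approximation + N/2 detail coefficients; its adjoint is the exact inverse
# (orthonormal rows), so reconstructing with the detail branch zeroed is the
# orthogonal projection onto the approximation space.  The projection is a
# symmetric operator, hence zero-phase: trough locations are not shifted.

# Symlet-8 decomposition low-pass filter (16 taps, sums to sqrt(2)).
SYM8_LO <- c(-0.00338241595100613, -0.00054213233179115, 0.03169508781149298,
             0.00760748732491761, -0.14329423835080970, -0.06127335906765852,
             0.48135965125837220, 0.77718575170052350, 0.36444189483533140,
             -0.05194583810770904, -0.02721902991705600, 0.04913717967360751,
             0.00380875201389062, -0.01495225833704823, -0.00030292051472137,
             0.00188995033275946)

# one analysis step: x (length N, even) -> list(a, d) each length N/2
.dwt_step <- function(x, lo) {
  n <- length(x)
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)  # QMF high-pass
  half <- n / 2
  L <- length(lo)
  idx <- outer(2 * (seq_len(half) - 1), seq_len(L) - 1, "+") %% n + 1
  xm <- matrix(x[idx], nrow = half)
  list(a = drop(xm %*% lo), d = drop(xm %*% hi))
}

# adjoint of .dwt_step with detail zeroed: a (length N/2) -> length N
.idwt_step_approx <- function(a, lo, n) {
  half <- n / 2
  L <- length(lo)
  out <- numeric(n)
  for (m in seq_len(L)) {
    # for fixed m the positions are pairwise distinct, so this is safe
    pos <- (2 * (seq_len(half) - 1) + (m - 1)) %% n + 1
    out[pos] <- out[pos] + a * lo[m]
  }
  out
}

#' Multiresolution wavelet approximations of a BCG record
#'
#' Computes the level-1..L approximation branches of a periodized orthogonal
#' Symlet-8 wavelet decomposition, each reconstructed back to the original
#' signal length (orthogonal projection onto the approximation space, which
#' is zero-phase).  Successive levels are progressively smoother; the
#' fourth level is the one consumed by the trough detector by default,
#' because it suppresses the high-frequency noise riding on the heartbeat
#' troughs without distorting the waveform the way deeper levels do.
#'
#' Signals whose length is not a multiple of `2^levels` are reflected at the
#' right edge up to the next multiple and trimmed after reconstruction.
#'
#' @param record a [bcg_record()] (or plain numeric vector).
#' @param wavelet filter name; only `"sym8"` is built in.
#' @param levels decomposition depth L (default 5).
#' @return An object of class `wavelet_stack`: list with `approximations`
#'   (list of L numeric vectors, original length), `wavelet`, `levels`.
#' @examples
#' rec <- gen_sine_bcg(synthetic_spec(n_periods = 8, snr_db = Inf))
#' ws <- wavelet_approximations(rec, levels = 4)
#' length(ws$approximations[[4]]) == length(rec$samples)
#' @export
wavelet_approximations <- function(record, wavelet = "sym8", levels = 5) {
  x <- if (inherits(record, "bcg_record")) record$samples else as.numeric(record)
  if (wavelet != "sym8")
    stop("only the sym8 wavelet is built in", call. = FALSE)
  if (length(x) < 2^levels)
    stop(sprintf("record too short: need at least %d samples for %d levels",
                 2^levels, levels), call. = FALSE)
  n0 <- length(x)
  blk <- 2^levels
  if (n0 %% blk != 0) {
    pad <- blk - n0 %% blk
    x <- c(x, rev(x)[seq_len(pad)])
  }
  approx <- vector("list", levels)
  a <- x
  lens <- integer(levels)
  coefs <- vector("list", levels)
  for (l in seq_len(levels)) {
    st <- .dwt_step(a, SYM8_LO)
    a <- st$a
    coefs[[l]] <- a
    lens[l] <- length(a)
  }
  for (l in seq_len(levels)) {
    r <- coefs[[l]]
    for (j in rev(seq_len(l))) {
      n_up <- if (j == 1) length(x) else lens[j - 1]
      r <- .idwt_step_approx(r, SYM8_LO, n_up)
    }
    approx[[l]] <- r[seq_len(n0)]
  }
  structure(list(approximations = approx, wavelet = wavelet, levels = levels),
            class = "wavelet_stack")
}

#' @export
print.wavelet_stack <- function(x, ...) {
  cat(sprintf("<wavelet_stack> %s, %d levels, %d samples\n", x$wavelet,
              x$levels, length(x$approximations[[1]])))
  invisible(x)
}
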
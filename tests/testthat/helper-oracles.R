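# Independent brute-force oracles used across tests.

# CUSUM-of-squares statistic computed from the definition, term by term.
oracle_kappa2 <- function(x) {
  n <- length(x)
  e <- x - mean(x)
  s2 <- e^2
  lam <- mean((s2 - mean(s2))^2)
  best <- -Inf
  t_star <- NA_integer_
  for (t in 1:(n - 1)) {
    Ct <- sum(s2[1:t])
    val <- abs(Ct - (t / n) * sum(s2)) / sqrt(lam) / sqrt(n)
    if (val > best) {
      best <- val
      t_star <- t
    }
  }
  list(kappa2 = best, t_star = t_star)
}

# O(n^2) sample-entropy pair counting in plain R.
oracle_sampen <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  nm <- n - m
  A <- 0
  B <- 0
  for (i in 1:(nm - 1)) {
    for (j in (i + 1):nm) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# exhaustive one-to-one event matching maximising the number of matches
oracle_match <- function(detected, truth, min_overlap = 0.5) {
  nt <- nrow(truth)
  nd <- nrow(detected)
  ok <- matrix(FALSE, nt, nd)
  for (i in seq_len(nt)) {
    for (j in seq_len(nd)) {
      ov <- min(truth$end[i], detected$end[j]) -
        max(truth$start[i], detected$start[j])
      ok[i, j] <- ov >= min_overlap * (truth$end[i] - truth$start[i])
    }
  }
  best <- 0
  assign_rec <- function(i, used) {
    if (i > nt) return(0)
    most <- assign_rec(i + 1, used)
    for (j in seq_len(nd)) {
      if (ok[i, j] && !used[j]) {
        used2 <- used
        used2[j] <- TRUE
        most <- max(most, 1 + assign_rec(i + 1, used2))
      }
    }
    most
  }
  assign_rec(1, logical(nd))
}

quiet_correct <- function(...) suppressWarnings(correct_rr(...))
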
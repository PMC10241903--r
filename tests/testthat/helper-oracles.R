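# Independent brute-force oracles used to pin down expected values.
# These deliberately re-derive each statistic from its textbook definition
# and never share code with the package implementation.

# classical ApEn by direct template counting (self-matches included)
naive_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nm <- n - mm + 1L
    logc <- numeric(nm)
    for (i in seq_len(nm)) {
      cnt <- 0L
      for (j in seq_len(nm)) {
        if (max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)])) <= r) {
          cnt <- cnt + 1L
        }
      }
      logc[i] <- log(cnt / nm)
    }
    mean(logc)
  }
  phi(m) - phi(m + 1L)
}

# same statistic with the inner loop vectorized (still pure counting); used
# where the quadratic double loop would be slow in R
naive_apen_fast <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nm <- n - mm + 1L
    emb <- sapply(seq_len(mm), function(k) x[k:(k + nm - 1L)])
    logc <- numeric(nm)
    for (i in seq_len(nm)) {
      d <- abs(emb - matrix(emb[i, ], nm, mm, byrow = TRUE))
      dmax <- do.call(pmax, as.data.frame(d))
      logc[i] <- log(sum(dmax <= r) / nm)
    }
    mean(logc)
  }
  phi(m) - phi(m + 1L)
}

# two-pass mean/variance sample SD
naive_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1L))
}

# Welch two-sample t and Satterthwaite df from first principles
naive_welch <- function(a, b) {
  va <- naive_sd(a)^2 / length(a)
  vb <- naive_sd(b)^2 / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1L) + vb^2 / (length(b) - 1L))
  list(t = t, df = df)
}

# Spearman rho via the rank-difference formula (average ranks for ties)
naive_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  if (anyDuplicated(rx) || anyDuplicated(ry)) {
    stats::cor(rx, ry)
  } else {
    1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  }
}

# OLS by explicit normal equations
naive_ols <- function(X, y) {
  X1 <- cbind(1, X)
  solve(crossprod(X1), crossprod(X1, y))[, 1L]
}

# Benjamini-Hochberg step-up by hand
naive_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# build a trial with the same series on every axis
make_trial <- function(x, fs, ...) {
  accel_trial(x, x, x, sampling_rate = fs, ...)
}

# sine series covering whole cycles
sine_series <- function(freq, fs, duration, amp = 1, phase = 0) {
  tt <- (seq_len(round(fs * duration)) - 1) / fs
  amp * sin(2 * pi * freq * tt + phase)
}

# cohort design with a single diagnosis group, for marginal checks
single_group_design <- function(group = "PD", n, decline_mean = NULL,
                                decline_sd = NULL, rho = -0.3) {
  des <- cohort_design(group_sizes = setNames(n, group),
                       change_correlation = rho)
  if (!is.null(decline_mean)) des$decline_means[, group] <- decline_mean
  if (!is.null(decline_sd)) des$decline_sds[, group] <- decline_sd
  des
}
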
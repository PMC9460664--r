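# Independent oracles used across the suite.

# Dominant normalized frequency of a signal by periodogram argmax.
periodogram_peak <- function(x) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  half <- seq_len(floor(n / 2) + 1L)
  f <- (half - 1) / n
  f[which.max(p[half])]
}

# Fraction of spectral power within a normalized frequency band.
power_fraction <- function(x, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) / n
  f <- pmin(f, 1 - f)
  # tolerance guards band-edge bins against 1 - f rounding
  sum(p[f >= lo - 1e-9 & f <= hi + 1e-9]) / sum(p)
}

# Naive O(T^2) double-loop fuzzy entropy (Chebyshev distance, per-vector
# mean removal, exponential membership, off-self averages).
fuzzy_entropy_bruteforce <- function(x, m = 2L, n_grad = 2, r = 0.2,
                                     relative = TRUE) {
  n <- length(x)
  if (relative) r <- r * stats::sd(x)
  phi <- function(mm) {
    nv <- n - m
    total <- 0
    for (i in seq_len(nv)) {
      vi <- x[i:(i + mm - 1L)]
      vi <- vi - mean(vi)
      for (j in seq_len(nv)) {
        if (j == i) next
        vj <- x[j:(j + mm - 1L)]
        vj <- vj - mean(vj)
        d <- max(abs(vi - vj))
        total <- total + exp(-(d / r)^n_grad)
      }
    }
    total / (nv * (nv - 1L))
  }
  log(phi(m)) - log(phi(m + 1L))
}

# Zero-mean AR(1) sources with distinct spectra, mixed by a seeded matrix.
make_ar_mixture <- function(T_ = 5000L, phis = c(0.9, 0.3, -0.5),
                            seed = 1L) {
  set.seed(seed)
  s <- t(vapply(phis, function(ph) {
    as.numeric(stats::arima.sim(list(ar = ph), T_))
  }, numeric(T_)))
  repeat {
    A <- matrix(stats::rnorm(length(phis)^2), length(phis))
    if (abs(det(A)) > 0.1) break
  }
  list(sources = s, mixing = A, x = A %*% s)
}

# Is |M| a permutation matrix (one dominant entry per row/column)?
is_signed_permutation <- function(M, tol = 0.1) {
  B <- abs(M) > 1 - tol
  all(rowSums(B) == 1) && all(colSums(B) == 1)
}

# Fixed point of the power-weighted center-frequency map on a pure
# component's half spectrum under the Wiener window with penalty alpha.
# Serves as the independent center-frequency oracle for band noise.
fixed_point_center <- function(x, alpha, w0) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) / n
  keep <- f <= 0.5
  f <- f[keep]; p <- p[keep]
  w <- w0
  for (i in seq_len(2000L)) {
    wt <- p / (1 + 2 * alpha * (f - w)^2)^2
    w_new <- sum(f * wt) / sum(wt)
    if (abs(w_new - w) < 1e-12) break
    w <- w_new
  }
  w
}

# The three-band synthetic used by the K-selection and consistency tests:
# tone power descending with frequency (slow activity dominates, as in
# contaminated EEG) plus mild broadband noise.
three_band_signal <- function(n = 2000L, seed = 5L) {
  set.seed(seed)
  t <- seq_len(n)
  eeg_signal(2 * cos(2 * pi * 0.02 * t) + 1.2 * cos(2 * pi * 0.12 * t) +
               0.8 * cos(2 * pi * 0.35 * t) + 0.2 * stats::rnorm(n),
             fs = 250)
}
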
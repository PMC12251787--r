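# Independent brute-force oracles, deliberately written with naive loops
# and lm() so they share no code path with the implementation.

# DFA profile by explicit loop
oracle_profile <- function(x) {
  xb <- mean(x)
  y <- numeric(length(x))
  acc <- 0
  for (k in seq_along(x)) {
    acc <- acc + (x[k] - xb)
    y[k] <- acc
  }
  y
}

# F(n) by per-window lm() fits; remainder excluded from sum and count
oracle_fluctuation <- function(y, n) {
  m <- length(y) %/% n
  ss <- 0
  for (w in seq_len(m)) {
    idx <- ((w - 1) * n + 1):(w * n)
    fit <- stats::lm(y[idx] ~ idx)
    ss <- ss + sum(stats::residuals(fit)^2)
  }
  sqrt(ss / (m * n))
}

# one-way ANOVA F by textbook sums of squares
oracle_anova_f <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ss_b <- sum(sapply(groups, function(g) length(g) * (mean(g) - grand)^2))
  ss_w <- sum(sapply(groups, function(g) sum((g - mean(g))^2)))
  (ss_b / (length(groups) - 1)) / (ss_w / (length(all_v) - length(groups)))
}

# amplitude of one frequency bin via FFT (signal length must hold an
# integer number of periods for the bin to be exact)
fft_amplitude <- function(x, freq_hz, fs) {
  n <- length(x)
  2 * Mod(stats::fft(x))[round(freq_hz * n / fs) + 1] / n
}

# strike-detection scoring with a sample tolerance
match_strikes <- function(found, truth, tol) {
  tp <- sum(sapply(truth, function(t) any(abs(found - t) <= tol)))
  list(recall = tp / length(truth),
       precision = if (length(found)) {
         sum(sapply(found, function(f) any(abs(truth - f) <= tol))) /
           length(found)
       } else 0)
}
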
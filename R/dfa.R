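# Detrended fluctuation analysis. The series is mean-centered and
# cumulatively summed into a profile Y(k); the profile is cut into
# non-overlapping windows of length n, an OLS line is removed within each
# window, and F(n) is the RMS residual over all covered samples. The
# scaling exponent alpha is the slope of log10 F(n) against log10 n.
# alpha ~ 0.5 for uncorrelated noise, > 0.5 persistent, < 0.5
# anti-persistent, ~ 1.5 for integrated (Brownian-like) signals.

#' Integrate a series into its DFA profile
#'
#' Computes the cumulative sum of mean-centered values,
#' `Y(k) = sum_{i<=k} (x_i - mean(x))`. By construction `Y(N)` is zero up
#' to floating-point error.
#'
#' @param x Numeric vector or [signal_trace], length >= 2, finite.
#' @return Numeric vector `Y` of the same length, class `dfa_profile`.
#' @export
integrate_profile <- function(x) {
  v <- as.numeric(x)
  if (length(v) < 2L)
    stop("integrate_profile: series too short (length < 2)", call. = FALSE)
  if (!all(is.finite(v)))
    stop("integrate_profile: non-finite values", call. = FALSE)
  structure(cumsum(v - mean(v)), class = "dfa_profile")
}

#' RMS fluctuation of a profile at one window size
#'
#' Splits the profile into `floor(N/n)` non-overlapping windows anchored
#' at the start, subtracts an ordinary-least-squares line within each
#' window, and returns the RMS residual over all covered samples. Samples
#' in the trailing remainder (beyond `floor(N/n) * n`) enter neither the
#' sum nor the normalizing count.
#'
#' @param profile A `dfa_profile` (or numeric vector already integrated).
#' @param n Window size, `4 <= n <= length(profile)`. Sizes below 4 are
#'   rejected: a line fitted to two points has identically zero residual.
#' @return `F(n) >= 0`.
#' @export
fluctuation_at <- function(profile, n) {
  y <- as.numeric(profile)
  N <- length(y)
  n <- as.integer(n)
  if (n < 4L)
    stop("fluctuation_at: window size must be >= 4", call. = FALSE)
  if (n > N)
    stop("fluctuation_at: window size exceeds profile length", call. = FALSE)
  m <- N %/% n
  Y <- matrix(y[seq_len(m * n)], nrow = n, ncol = m)
  # vectorized per-column linear detrend on the centered index; explicit
  # residuals (not the Syy - Sty^2/Stt shortcut) to avoid cancellation
  t0 <- seq_len(n) - (n + 1) / 2
  Stt <- sum(t0 * t0)
  Yc <- sweep(Y, 2L, colMeans(Y))
  slope <- as.numeric(crossprod(t0, Yc)) / Stt
  R <- Yc - outer(t0, slope)
  sqrt(sum(R * R) / (m * n))
}

#' Default log-spaced window-size grid
#'
#' About 20 unique integer sizes log-spaced between 16 and `floor(N/4)`.
#' The lower bound avoids the small-window detrending bias; the upper
#' bound guarantees at least four windows contribute to every `F(n)`.
#'
#' @param N Series length, `N >= 64`.
#' @param n_sizes Target number of sizes (default 20).
#' @param min_size Smallest window (default 16).
#' @return Strictly increasing integer vector.
#' @export
default_window_sizes <- function(N, n_sizes = 20L, min_size = 16L) {
  if (N < 64L)
    stop("default_window_sizes: series too short (need N >= 64)", call. = FALSE)
  hi <- N %/% 4L
  sizes <- unique(as.integer(round(exp(seq(log(min_size), log(hi),
                                           length.out = n_sizes)))))
  sizes[sizes >= 4L & sizes <= hi]
}

#' DFA scaling exponent of a series
#'
#' Integrates the series ([integrate_profile]), evaluates the fluctuation
#' function over a window-size grid ([fluctuation_at]), and fits an
#' unweighted OLS line to `(log10 n, log10 F)`. Sizes with `F == 0` are
#' dropped (their log is undefined) with a warning.
#'
#' @param x Numeric vector or [signal_trace]; non-constant, length >= 64
#'   unless an explicit `sizes` grid is supplied.
#' @param sizes Optional integer window sizes; defaults to
#'   [default_window_sizes()].
#' @param detrend_order Polynomial detrending order; only 1 (linear) is
#'   implemented.
#' @return A `dfa_result` list: `alpha`, `intercept`, `r_squared`,
#'   `n_windows_used`, and `curve` (data.frame of `n`, `F`).
#' @examples
#' set.seed(1)
#' dfa_alpha(rnorm(4096))$alpha   # ~ 0.5 for white noise
#' @export
dfa_alpha <- function(x, sizes = NULL, detrend_order = 1L) {
  if (detrend_order != 1L)
    stop("dfa_alpha: only linear (order-1) detrending is implemented",
         call. = FALSE)
  v <- as.numeric(x)
  if (max(v) == min(v))
    stop("dfa_alpha: degenerate signal (constant input)", call. = FALSE)
  if (is.null(sizes)) sizes <- default_window_sizes(length(v))
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 4L) || any(sizes > length(v)))
    stop("dfa_alpha: window sizes must lie in [4, length(x)]", call. = FALSE)
  prof <- integrate_profile(v)
  Fn <- vapply(sizes, function(n) fluctuation_at(prof, n), numeric(1))
  keep <- Fn > 0
  if (!all(keep))
    warning("dfa_alpha: dropping ", sum(!keep), " size(s) with F(n) = 0")
  if (sum(keep) < 4L)
    stop("dfa_alpha: fewer than 4 usable window sizes", call. = FALSE)
  lx <- log10(sizes[keep]); ly <- log10(Fn[keep])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  res <- fit$residuals
  r2 <- if (stats::var(ly) > 0) 1 - sum(res^2) / sum((ly - mean(ly))^2) else 1
  structure(list(alpha = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 r_squared = r2,
                 n_windows_used = sum(keep),
                 curve = data.frame(n = sizes, F = Fn)),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> alpha = %.4f (R^2 = %.4f, %d window sizes)\n",
              x$alpha, x$r_squared, x$n_windows_used))
  invisible(x)
}

#' Log-log fluctuation plot
#'
#' Plots `F(n)` against `n` on log axes with the fitted scaling line and
#' the exponent in the legend, the conventional DFA diagnostic figure.
#'
#' @param x A `dfa_result`.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dfa_result <- function(x, main = "Detrended fluctuation analysis", ...) {
  keep <- x$curve$F > 0
  graphics::plot(x$curve$n[keep], x$curve$F[keep], log = "xy",
                 xlab = "window size n", ylab = "F(n)", pch = 19,
                 main = main, ...)
  ln <- log10(x$curve$n[keep])
  graphics::lines(10^ln, 10^(x$intercept + x$alpha * ln), col = "red3")
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("alpha = %.3f", x$alpha))
  invisible(x)
}
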
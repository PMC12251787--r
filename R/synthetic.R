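# Synthetic inputs for testing every analysis stage without external
# data: seeded Gaussian white noise, fractional Gaussian noise (fGn) with
# exact autocovariance via circulant embedding (Davies-Harte), fractional
# Brownian motion (fBm) as its cumulative sum, and synthetic gait records
# whose heel-strike times are known by construction. All generators are
# pure functions of their arguments: the global RNG state is saved and
# restored, and the same seed reproduces the output bit for bit.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Seeded Gaussian white noise
#'
#' @param n Length (>= 16).
#' @param seed Integer seed; the same seed reproduces the trace exactly.
#' @param sigma Standard deviation (> 0).
#' @param fs Sampling rate attached to the returned trace (default 1, a
#'   dimensionless index).
#' @return A [signal_trace].
#' @export
generate_white_noise <- function(n, seed, sigma = 1, fs = 1) {
  if (n < 16L) stop("generate_white_noise: n must be >= 16", call. = FALSE)
  if (sigma <= 0) stop("generate_white_noise: sigma must be > 0", call. = FALSE)
  signal_trace(with_seed(seed, stats::rnorm(n, sd = sigma)), fs = fs)
}

#' Specification for fractional Gaussian noise
#'
#' @param hurst Hurst exponent H in (0, 1). `H = 0.5` is white noise;
#'   larger H means persistent long-range correlation.
#' @param n Length (>= 16).
#' @param seed Integer seed.
#' @param sigma Marginal standard deviation (> 0).
#' @return An `fgn_spec` list.
#' @export
fgn_spec <- function(hurst, n, seed, sigma = 1) {
  if (!(hurst > 0 && hurst < 1))
    stop("fgn_spec: hurst must lie in (0, 1)", call. = FALSE)
  if (n < 16L) stop("fgn_spec: n must be >= 16", call. = FALSE)
  if (sigma <= 0) stop("fgn_spec: sigma must be > 0", call. = FALSE)
  structure(list(hurst = hurst, n = as.integer(n), seed = as.integer(seed),
                 sigma = sigma),
            class = "fgn_spec")
}

#' Theoretical fGn autocovariance
#'
#' `gamma(k) = (sigma^2 / 2) * (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})`.
#'
#' @param k Integer lag(s), `k >= 0`.
#' @param hurst Hurst exponent.
#' @param sigma Marginal standard deviation.
#' @return Autocovariance value(s).
#' @export
fgn_autocovariance <- function(k, hurst, sigma = 1) {
  h2 <- 2 * hurst
  (sigma^2 / 2) * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
}

#' Generate fractional Gaussian noise by circulant embedding
#'
#' Exact (Davies-Harte) simulation: the target autocovariance sequence is
#' embedded in a circulant matrix whose eigenvalues come from one FFT;
#' complex Gaussian weights in the frequency domain then yield a
#' stationary series with exactly the fGn covariance. The DFA exponent of
#' the output is asymptotically the Hurst exponent H.
#'
#' @param spec An [fgn_spec()].
#' @param on_negative_eigenvalue `"clamp"` (zero out tiny negative FFT
#'   eigenvalues, with a warning) or `"error"`.
#' @return A [signal_trace] of length `spec$n`.
#' @export
generate_fgn <- function(spec, on_negative_eigenvalue = c("clamp", "error")) {
  on_negative_eigenvalue <- match.arg(on_negative_eigenvalue)
  stopifnot(inherits(spec, "fgn_spec"))
  n <- spec$n
  g <- fgn_autocovariance(0:n, spec$hurst, spec$sigma)
  circ <- c(g, g[n:2])                       # length 2n circulant row
  ev <- Re(stats::fft(circ))
  if (any(ev < 0)) {
    worst <- min(ev)
    if (on_negative_eigenvalue == "error" || worst < -1e-8 * max(ev))
      stop("generate_fgn: circulant embedding produced negative eigenvalues (min ",
           format(worst), ")", call. = FALSE)
    warning("generate_fgn: clamping tiny negative eigenvalues (min ",
            format(worst), ")")
    ev[ev < 0] <- 0
  }
  m <- 2L * n
  z <- with_seed(spec$seed, {
    # hermitian-symmetric complex Gaussian spectrum
    v1 <- stats::rnorm(n - 1L); v2 <- stats::rnorm(n - 1L)
    a0 <- stats::rnorm(1L); an <- stats::rnorm(1L)
    w <- complex(length.out = m)
    w[1L] <- sqrt(ev[1L] / m) * a0
    w[n + 1L] <- sqrt(ev[n + 1L] / m) * an
    w[2:n] <- sqrt(ev[2:n] / (2 * m)) * complex(real = v1, imaginary = v2)
    w[m:(n + 2L)] <- Conj(w[2:n])
    Re(stats::fft(w))[seq_len(n)]
  })
  signal_trace(z, fs = 1)
}

#' Generate fractional Brownian motion
#'
#' The cumulative sum of an fGn draw; its DFA exponent targets `H + 1`,
#' the Brownian-like regime (`alpha ~ 1.5` at `H = 0.5`) typical of
#' integrated signals such as foot-pressure waveforms.
#'
#' @param spec An [fgn_spec()] for the underlying increments.
#' @param ... Passed to [generate_fgn()].
#' @return A [signal_trace]; its `diff()` equals the fGn draw exactly up
#'   to the dropped first sample.
#' @export
generate_fbm <- function(spec, ...) {
  incr <- generate_fgn(spec, ...)
  signal_trace(cumsum(as.numeric(incr)), fs = 1)
}

#' Specification for a synthetic gait recording
#'
#' Emulates the morphology the segmentation stage assumes: an FSR trace
#' with smooth stance plateaus and near-zero swing, and EMG channels of
#' bandlimited noise amplitude-modulated by gait-phase-locked envelopes
#' (tibialis anterior peaking in swing, gastrocnemius in late stance).
#'
#' @param fs Sampling rate in Hz (default 1500).
#' @param n_cycles Number of strides per leg (>= 2).
#' @param stride_s Mean stride duration in seconds (default 1.1, a
#'   typical preferred-pace stride time).
#' @param stride_jitter_s Standard deviation of stride duration
#'   (Gaussian, truncated at +/- 3 sd so the 0.5 s refractory bound
#'   stays satisfiable; default 0.02 s).
#' @param stance_fraction Fraction of the cycle in stance (default 0.6).
#' @param noise_sigma Additive Gaussian noise sd on the FSR channels
#'   (default 0.02; FSR plateau amplitude is 1).
#' @param seed Integer seed.
#' @return A `gait_sim_spec` list.
#' @export
gait_sim_spec <- function(fs = 1500, n_cycles = 10L, stride_s = 1.1,
                          stride_jitter_s = 0.02, stance_fraction = 0.6,
                          noise_sigma = 0.02, seed = 1L) {
  if (n_cycles < 2L) stop("gait_sim_spec: n_cycles must be >= 2", call. = FALSE)
  if (!(stance_fraction > 0 && stance_fraction < 1))
    stop("gait_sim_spec: stance_fraction must lie in (0, 1)", call. = FALSE)
  if (stride_s - 3 * stride_jitter_s <= 0.5)
    stop("gait_sim_spec: stride_s - 3*stride_jitter_s must exceed the 0.5 s ",
         "refractory interval", call. = FALSE)
  structure(list(fs = fs, n_cycles = as.integer(n_cycles), stride_s = stride_s,
                 stride_jitter_s = stride_jitter_s,
                 stance_fraction = stance_fraction,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "gait_sim_spec")
}

# raised-cosine stance pulse. Foot-switch style loading and unloading
# edges are mechanically abrupt (~2 ms): the mid-ramp threshold crossing
# then stays within a couple of samples of the true onset, and the
# steep unloading edge crosses the threshold band too fast for sensor
# noise to manufacture a spurious rising edge.
stance_pulse <- function(len, fs, rise_s = 0.002, fall_s = 0.002) {
  rise <- min(max(2L, round(rise_s * fs)), len %/% 3L)
  fall <- min(max(2L, round(fall_s * fs)), len %/% 3L)
  up <- (1 - cos(pi * seq_len(rise) / rise)) / 2
  down <- (1 + cos(pi * seq_len(fall) / fall)) / 2
  c(up, rep(1, max(0L, len - rise - fall)), down)[seq_len(len)]
}

# band-limited Gaussian sensor noise: white noise smoothed by a ~5 ms
# moving average (FSR front-ends are low-pass), rescaled so the marginal
# standard deviation is exactly sigma
sensor_noise <- function(n, sigma, fs) {
  w <- max(1L, round(0.005 * fs))
  z <- stats::rnorm(n)
  if (w > 1L)
    z <- as.numeric(stats::filter(z, rep(1 / w, w), sides = 2L,
                                  circular = TRUE)) * sqrt(w)
  sigma * z
}

# truncated-normal stride lengths in samples; first strike after a short lead-in
simulate_strikes <- function(spec) {
  strides <- stats::rnorm(spec$n_cycles, spec$stride_s, spec$stride_jitter_s)
  lim <- 3 * spec$stride_jitter_s
  strides <- pmin(pmax(strides, spec$stride_s - lim), spec$stride_s + lim)
  round(cumsum(c(0.25 * spec$fs, strides[-spec$n_cycles] * spec$fs)))
}

#' Generate a synthetic gait record with known heel strikes
#'
#' Builds a six-channel [gait_record] (bilateral tibialis anterior and
#' lateral gastrocnemius EMG, bilateral foot FSR). The left foot is
#' offset by half a stride from the right. Ground-truth heel strikes are
#' the first samples of each stance onset.
#'
#' @param spec A [gait_sim_spec()].
#' @return List with `record` (a `gait_record`) and `strikes` (list of
#'   0-based ground-truth strike indices, `$right` and `$left`).
#' @export
generate_synthetic_gait <- function(spec) {
  stopifnot(inherits(spec, "gait_sim_spec"))
  fs <- spec$fs
  with_seed(spec$seed, {
    strikes_r <- simulate_strikes(spec)
    half <- round(spec$stride_s * fs / 2)
    strikes_l <- strikes_r + half
    total <- max(strikes_l) + round(spec$stride_s * fs) + round(0.25 * fs)

    build_fsr <- function(strikes) {
      x <- numeric(total)
      ends <- c(strikes[-1L], strikes[length(strikes)] +
                  round(spec$stride_s * fs))
      phase <- numeric(total)                # gait phase in [0,1) per sample
      for (j in seq_along(strikes)) {
        s <- strikes[j] + 1L                 # to 1-based
        e <- min(ends[j], total)
        len <- e - s + 1L
        stance_len <- round(len * spec$stance_fraction)
        x[s:(s + stance_len - 1L)] <- stance_pulse(stance_len, fs)
        phase[s:e] <- seq(0, 1, length.out = len + 1L)[seq_len(len)]
      }
      if (spec$noise_sigma > 0)
        x <- x + sensor_noise(total, spec$noise_sigma, fs)
      list(fsr = x, phase = phase)
    }

    build_emg <- function(phase, kind) {
      # phase-locked burst envelope: TA peaks mid-swing, LG in late stance
      peak <- if (kind == "ta") (spec$stance_fraction + 1) / 2
              else 0.85 * spec$stance_fraction
      env <- 0.08 + exp(-((phase - peak)^2) / (2 * 0.06^2))
      carrier <- stats::rnorm(total)
      ba <- butter_bandpass(4L, 20, min(450, 0.45 * fs), fs)
      carrier <- filtfilt_oddpad(ba$b, ba$a, carrier)
      env * carrier
    }

    r <- build_fsr(strikes_r)
    l <- build_fsr(strikes_l)
    channels <- list(
      right_fsr_foot = signal_trace(r$fsr, fs),
      left_fsr_foot = signal_trace(l$fsr, fs),
      right_emg_tibialis_anterior = signal_trace(build_emg(r$phase, "ta"), fs),
      right_emg_lateral_gastrocnemius = signal_trace(build_emg(r$phase, "lg"), fs),
      left_emg_tibialis_anterior = signal_trace(build_emg(l$phase, "ta"), fs),
      left_emg_lateral_gastrocnemius = signal_trace(build_emg(l$phase, "lg"), fs))
    record <- gait_record(sprintf("sim%05d", spec$seed), channels)
    list(record = record, strikes = list(right = strikes_r, left = strikes_l))
  })
}

#' Simulate a labelled cohort of synthetic gait records
#'
#' Convenience wrapper generating `n_records` records per group with
#' seeds derived deterministically from `seed`.
#'
#' @param groups Character vector of group labels (default the three
#'   study groups).
#' @param n_records Records per group.
#' @param seed Root seed.
#' @param ... Passed to [gait_sim_spec()].
#' @return List with `records` (list of `gait_record`) and `manifest`
#'   (data.frame of `record_id`, `group`).
#' @export
simulate_cohort <- function(groups = c("control", "taichi", "master"),
                            n_records = 2L, seed = 1L, ...) {
  records <- list(); ids <- character(0); labs <- character(0)
  k <- 0L
  for (g in groups) for (r in seq_len(n_records)) {
    k <- k + 1L
    spec <- gait_sim_spec(seed = seed * 1000L + k, ...)
    sim <- generate_synthetic_gait(spec)
    rec <- sim$record
    rec$record_id <- sprintf("%s%02d", substr(g, 1, 3), r)
    rec$group_label <- g
    records[[rec$record_id]] <- rec
    ids <- c(ids, rec$record_id); labs <- c(labs, g)
  }
  list(records = records,
       manifest = data.frame(record_id = ids, group = labs,
                             stringsAsFactors = FALSE))
}
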
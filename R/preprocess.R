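# Signal conditioning: EMG bandpass (zero-phase) -> full-wave rectify ->
# normalize to trial maximum; FSR min-max normalization. The EMG chain
# mirrors standard surface-EMG practice: a 20-450 Hz fourth-order
# Butterworth removes motion artefact and high-frequency noise while
# keeping the physiological band, and forward-backward application avoids
# phase distortion of burst timing relative to gait events.

#' Bandpass filter specification
#'
#' @param order Per-pass Butterworth order (default 4; the zero-phase
#'   forward-backward cascade then has an effective 8th-order magnitude
#'   response).
#' @param low_hz,high_hz Cutoffs in Hz (defaults 20 and 450).
#' @param mode Only `"zero_phase"` is supported.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(order = 4L, low_hz = 20, high_hz = 450,
                        mode = "zero_phase") {
  mode <- match.arg(mode, "zero_phase")
  if (!(0 < low_hz && low_hz < high_hz))
    stop("filter_spec: need 0 < low_hz < high_hz", call. = FALSE)
  structure(list(order = as.integer(order), low_hz = low_hz,
                 high_hz = high_hz, mode = mode),
            class = "filter_spec")
}

#' Zero-phase Butterworth bandpass of a trace
#'
#' @param x A [signal_trace].
#' @param spec A [filter_spec]; cutoffs must satisfy `high_hz < fs/2`.
#' @return Filtered `signal_trace` of the same length.
#' @export
bandpass_zero_phase <- function(x, spec = filter_spec()) {
  fs <- trace_fs(x)
  if (spec$high_hz >= fs / 2)
    stop("bandpass_zero_phase: high_hz (", spec$high_hz,
         ") must be below fs/2 (", fs / 2, ")", call. = FALSE)
  ba <- butter_bandpass(spec$order, spec$low_hz, spec$high_hz, fs)
  nfilt <- max(length(ba$a), length(ba$b))
  if (length(x) <= 3L * (nfilt - 1L))
    stop("bandpass_zero_phase: trace too short for edge padding (need > ",
         3L * (nfilt - 1L), " samples)", call. = FALSE)
  # pad generously so zero-state transients die inside the padding; at
  # least three low-cutoff periods when the trace allows it
  padlen <- min(length(x) - 1L,
                max(3L * (nfilt - 1L), ceiling(3 * fs / spec$low_hz)))
  signal_trace(filtfilt_oddpad(ba$b, ba$a, as.numeric(x), padlen), fs = fs)
}

#' Full-wave rectification
#'
#' @param x A [signal_trace].
#' @return `signal_trace` of element-wise absolute values.
#' @export
rectify <- function(x) {
  signal_trace(abs(as.numeric(x)), fs = trace_fs(x))
}

#' Normalize a trace to its maximum
#'
#' Divides by the maximum over the whole trace, so the output lies in
#' `[0, 1]` with maximum exactly 1. For EMG this is applied to the
#' rectified signal with the constant taken over the full trial, never
#' per cycle.
#'
#' @param x A [signal_trace] with a strictly positive maximum.
#' @return Normalized `signal_trace`.
#' @export
normalize_max <- function(x) {
  m <- max(as.numeric(x))
  if (!(m > 0))
    stop("normalize_max: degenerate signal (max <= 0)", call. = FALSE)
  signal_trace(as.numeric(x) / m, fs = trace_fs(x))
}

#' Min-max normalization to [0, 1]
#'
#' `(x - min(x)) / (max(x) - min(x))`; used for FSR traces ahead of
#' dynamic-threshold segmentation so thresholds are comparable across
#' subjects with different pressure magnitudes.
#'
#' @param x A non-constant [signal_trace].
#' @return Normalized `signal_trace` spanning exactly `[0, 1]`.
#' @export
normalize_minmax <- function(x) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (!(hi > lo))
    stop("normalize_minmax: degenerate signal (constant trace)", call. = FALSE)
  signal_trace((v - lo) / (hi - lo), fs = trace_fs(x))
}

#' Full EMG conditioning chain
#'
#' Bandpass (zero-phase) -> full-wave rectify -> normalize to the trial
#' maximum, in that order.
#'
#' @param x A [signal_trace] of raw EMG.
#' @param spec A [filter_spec].
#' @return Conditioned `signal_trace` in `[0, 1]`.
#' @export
condition_emg <- function(x, spec = filter_spec()) {
  normalize_max(rectify(bandpass_zero_phase(x, spec)))
}
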
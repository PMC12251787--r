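# Core containers: signal_trace (one channel), channel roles, gait_record
# (synchronized multichannel recording). Sample indices are 0-based and
# intervals half-open [start, end) throughout the package.

#' Construct a signal trace
#'
#' The atomic time-series container: an ordered numeric vector of samples
#' plus its sampling rate in Hz.
#'
#' @param samples Numeric vector of finite sample values (length >= 1).
#' @param fs Sampling rate in Hz (single positive number).
#' @return An object of class `signal_trace`: a numeric vector with an
#'   `fs` attribute.
#' @examples
#' x <- signal_trace(sin(seq(0, 1, length.out = 1500)), fs = 1500)
#' trace_fs(x)
#' @export
signal_trace <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("signal_trace: 'samples' must have length >= 1", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("signal_trace: all samples must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("signal_trace: 'fs' must be a single positive number", call. = FALSE)
  structure(samples, fs = as.numeric(fs), class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d samples @ %g Hz (%.3f s)\n",
              length(x), trace_fs(x), length(x) / trace_fs(x)))
  invisible(x)
}

#' Sampling rate of a trace
#' @param x A `signal_trace`.
#' @return Sampling rate in Hz.
#' @export
trace_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) stop("not a signal_trace: missing fs attribute", call. = FALSE)
  fs
}

# Keep class/fs through subsetting so sliced cycles remain traces.
#' @export
`[.signal_trace` <- function(x, i, ...) {
  signal_trace(unclass(x)[i], fs = trace_fs(x))
}

#' Channel roles
#'
#' A channel role identifies what a channel records (`kind`) and on which
#' side of the body (`side`). The six valid roles cover bilateral EMG of
#' the tibialis anterior and lateral gastrocnemius plus one consolidated
#' FSR channel per foot.
#'
#' @param side `"left"` or `"right"`.
#' @param kind One of `"emg_tibialis_anterior"`, `"emg_lateral_gastrocnemius"`,
#'   `"fsr_foot"`.
#' @return A canonical role string `"<side>_<kind>"`.
#' @examples
#' channel_role("right", "fsr_foot")
#' @export
channel_role <- function(side, kind) {
  side <- match.arg(side, c("left", "right"))
  kind <- match.arg(kind, c("emg_tibialis_anterior",
                            "emg_lateral_gastrocnemius",
                            "fsr_foot"))
  paste(side, kind, sep = "_")
}

#' All six valid channel roles
#' @return Character vector of the six canonical role strings.
#' @export
all_channel_roles <- function() {
  as.character(outer(c("left", "right"),
                     c("emg_tibialis_anterior", "emg_lateral_gastrocnemius",
                       "fsr_foot"),
                     paste, sep = "_"))
}

role_side <- function(role) sub("_.*$", "", role)
role_kind <- function(role) sub("^(left|right)_", "", role)
is_fsr_role <- function(role) grepl("fsr_foot$", role)

#' Construct a gait record
#'
#' A synchronized multichannel recording: a named list of [signal_trace]
#' objects keyed by channel role, all sharing one sampling rate and one
#' length, with at least one foot FSR channel (segmentation needs it).
#'
#' @param record_id Record identifier string.
#' @param channels Named list of `signal_trace`, names are canonical roles
#'   (see [all_channel_roles()]).
#' @param group_label One of `"control"`, `"taichi"`, `"master"`, `"unknown"`.
#' @return An object of class `gait_record`.
#' @export
gait_record <- function(record_id, channels,
                        group_label = c("unknown", "control", "taichi", "master")) {
  group_label <- match.arg(group_label)
  if (!is.character(record_id) || length(record_id) != 1L)
    stop("gait_record: 'record_id' must be a single string", call. = FALSE)
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("gait_record: 'channels' must be a named list", call. = FALSE)
  bad <- setdiff(names(channels), all_channel_roles())
  if (length(bad))
    stop("gait_record: unknown channel roles: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(names(channels)))
    stop("gait_record: duplicated channel roles", call. = FALSE)
  if (!any(is_fsr_role(names(channels))))
    stop("gait_record: at least one fsr_foot channel is required", call. = FALSE)
  fss <- vapply(channels, trace_fs, numeric(1))
  lens <- vapply(channels, length, integer(1))
  if (length(unique(fss)) != 1L)
    stop("gait_record: all channels must share the same fs", call. = FALSE)
  if (length(unique(lens)) != 1L)
    stop("gait_record: all channels must share the same length", call. = FALSE)
  structure(list(record_id = record_id, channels = channels,
                 group_label = group_label),
            class = "gait_record")
}

#' @export
print.gait_record <- function(x, ...) {
  cat(sprintf("<gait_record> '%s' (%s): %d channels x %d samples @ %g Hz\n",
              x$record_id, x$group_label, length(x$channels),
              record_length(x), record_fs(x)))
  cat("  roles:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Sampling rate of a gait record
#' @param record A `gait_record`.
#' @return Sampling rate in Hz.
#' @export
record_fs <- function(record) trace_fs(record$channels[[1L]])

#' Number of samples per channel of a gait record
#' @param record A `gait_record`.
#' @return Integer sample count.
#' @export
record_length <- function(record) length(record$channels[[1L]])
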
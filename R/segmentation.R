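# Heel-strike detection and gait-cycle slicing. A stride is bounded by
# consecutive heel strikes, detected as rising edges of the normalized
# foot-pressure (FSR) trace through a dynamic threshold, with a 0.5 s
# refractory interval suppressing within-step re-crossings.

#' Segmentation parameters
#'
#' @param refractory_s Minimum inter-strike interval in seconds
#'   (default 0.5).
#' @param source `"per_leg_fsr"` (each leg segmented from its own foot,
#'   the default) or `"right_fsr_for_all"` (right-foot strikes applied to
#'   every channel).
#' @param min_cycle_samples Cycles shorter than this are flagged and
#'   excluded from DFA (default 256; DFA needs enough points per cycle).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(refractory_s = 0.5,
                                source = c("per_leg_fsr", "right_fsr_for_all"),
                                min_cycle_samples = 256L) {
  source <- match.arg(source)
  if (refractory_s <= 0)
    stop("segmentation_params: refractory_s must be > 0", call. = FALSE)
  structure(list(refractory_s = refractory_s, source = source,
                 min_cycle_samples = as.integer(min_cycle_samples)),
            class = "segmentation_params")
}

#' Dynamic detection threshold of a normalized FSR trace
#'
#' The midpoint `(min(x) + max(x)) / 2`. After min-max normalization this
#' is exactly 0.5 but the rule is stated on the raw range so detection is
#' invariant under affine rescaling of the trace.
#'
#' @param x A non-constant [signal_trace].
#' @return The threshold value.
#' @export
dynamic_threshold <- function(x) {
  v <- as.numeric(x)
  if (max(v) == min(v))
    stop("dynamic_threshold: degenerate signal (constant trace)", call. = FALSE)
  (min(v) + max(v)) / 2
}

#' Detect heel strikes as thresholded rising edges
#'
#' Scans left to right for samples with `x[i] >= threshold` and
#' `x[i-1] < threshold` (so a plateau at or above threshold yields exactly
#' one strike at its first sample), keeping a candidate only if it falls
#' at least `refractory_s * fs` samples after the last kept strike; the
#' first candidate is always kept.
#'
#' @param x A [signal_trace].
#' @param threshold Detection threshold, typically [dynamic_threshold()].
#' @param params A [segmentation_params()].
#' @return Integer vector of 0-based strike indices (possibly empty).
#' @export
detect_heel_strikes <- function(x, threshold,
                                params = segmentation_params()) {
  v <- as.numeric(x)
  fs <- trace_fs(x)
  above <- v >= threshold
  # rising edges; sample 0 cannot be one (no predecessor below threshold)
  cand <- which(above[-1L] & !above[-length(v)])   # 1-based index of edge - 1
  cand <- cand + 1L                                 # 1-based edge sample
  gap <- params$refractory_s * fs
  kept <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= gap) {
      kept <- c(kept, i)
      last <- i
    }
  }
  kept - 1L                                         # back to 0-based
}

#' Build gait cycles from an ordered strike list
#'
#' `k` strikes yield `k - 1` half-open cycles
#' `[strike_j, strike_{j+1})`.
#'
#' @param strikes Strictly increasing integer strike indices (0-based).
#' @param side `"left"` or `"right"`.
#' @return A data.frame with columns `side`, `cycle_index` (1-based),
#'   `start`, `end` (0-based, half-open).
#' @export
cycles_from_strikes <- function(strikes, side = c("right", "left")) {
  side <- match.arg(side)
  if (length(strikes) < 2L)
    stop("cycles_from_strikes: need at least 2 strikes to form a cycle",
         call. = FALSE)
  if (any(diff(strikes) <= 0))
    stop("cycles_from_strikes: strikes must be strictly increasing",
         call. = FALSE)
  k <- length(strikes)
  data.frame(side = side, cycle_index = seq_len(k - 1L),
             start = strikes[-k], end = strikes[-1L],
             stringsAsFactors = FALSE)
}

#' Slice every channel of a record by the same cycle boundaries
#'
#' All channels are cut with identical `[start, end)` indices so the EMG
#' and FSR segments of a cycle stay sample-synchronized.
#'
#' @param record A [gait_record].
#' @param cycles A cycle data.frame from [cycles_from_strikes()].
#' @return A list, one element per cycle row, each a named list of
#'   [signal_trace] keyed by channel role.
#' @export
slice_cycles <- function(record, cycles) {
  L <- record_length(record)
  if (nrow(cycles) &&
      (min(cycles$start) < 0L || max(cycles$end) > L))
    stop("slice_cycles: cycle indices out of record bounds [0, ", L, ")",
         call. = FALSE)
  lapply(seq_len(nrow(cycles)), function(j) {
    idx <- (cycles$start[j] + 1L):cycles$end[j]     # 0-based -> 1-based
    lapply(record$channels, function(tr) tr[idx])
  })
}

#' Segment a record into gait cycles
#'
#' Normalizes each foot FSR trace (min-max), computes its dynamic
#' threshold, detects heel strikes and builds cycles. With
#' `source = "per_leg_fsr"` each side's cycles come from its own foot;
#' with `"right_fsr_for_all"` the right-foot cycles are used for both
#' sides.
#'
#' @param record A [gait_record] with at least the needed fsr channels.
#' @param params A [segmentation_params()].
#' @return Data.frame of cycles (`side`, `cycle_index`, `start`, `end`,
#'   `duration_s`, `usable`) where `usable` marks cycles long enough for
#'   DFA (`end - start >= min_cycle_samples`).
#' @export
segment_record <- function(record, params = segmentation_params()) {
  fs <- record_fs(record)
  sides <- if (params$source == "per_leg_fsr") {
    present <- names(record$channels)[is_fsr_role(names(record$channels))]
    sort(vapply(present, role_side, character(1)), decreasing = TRUE)
  } else "right"
  out <- list()
  for (s in sides) {
    role <- paste0(s, "_fsr_foot")
    if (is.null(record$channels[[role]]))
      stop("segment_record: missing channel ", role, call. = FALSE)
    fsr <- normalize_minmax(record$channels[[role]])
    strikes <- detect_heel_strikes(fsr, dynamic_threshold(fsr), params)
    if (length(strikes) < 2L) next
    cyc <- cycles_from_strikes(strikes, side = s)
    out[[s]] <- cyc
  }
  if (!length(out))
    return(data.frame(side = character(0), cycle_index = integer(0),
                      start = integer(0), end = integer(0),
                      duration_s = numeric(0), usable = logical(0)))
  cycles <- do.call(rbind, out)
  rownames(cycles) <- NULL
  if (params$source == "right_fsr_for_all" && length(sides) == 1L) {
    left <- cycles; left$side <- "left"
    cycles <- rbind(cycles, left)
  }
  cycles$duration_s <- (cycles$end - cycles$start) / fs
  cycles$usable <- (cycles$end - cycles$start) >= params$min_cycle_samples
  cycles
}

#' Export a cycle table as TSV
#'
#' @param cycles Cycle data.frame from [segment_record()].
#' @param record_id Record identifier to prepend.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cycle_table <- function(cycles, record_id, path) {
  tab <- cbind(record_id = record_id,
               cycles[, c("side", "cycle_index", "start", "end",
                          "duration_s")])
  names(tab)[names(tab) == "start"] <- "start_sample"
  names(tab)[names(tab) == "end"] <- "end_sample"
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
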
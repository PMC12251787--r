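# segmentation: dynamic thresholding, rising-edge strike detection with
# refractory interval, cycle construction and synchronized slicing.

# square wave starting low so every period contributes one rising edge
square_wave <- function(freq_hz, fs, dur_s) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  signal_trace(as.numeric((t * freq_hz) %% 1 >= 0.5), fs = fs)
}

test_that("dynamic_threshold is the min-max midpoint", {
  expect_equal(dynamic_threshold(signal_trace(c(0, 1, 0.2), 1)), 0.5)
  expect_equal(dynamic_threshold(signal_trace(c(0.2, 0.8, 0.5), 1)), 0.5)
  expect_error(dynamic_threshold(signal_trace(rep(0.3, 10), 1)), "degenerate")
})

test_that("1 Hz square wave yields the five rising edges 100 samples apart", {
  x <- square_wave(1, fs = 100, dur_s = 5)
  st <- detect_heel_strikes(x, 0.5)
  # low on [0, 0.5) of each period: one rising edge per second at t = 0.5
  expect_equal(st, c(50, 150, 250, 350, 450))
  expect_true(all(diff(st) == 100))
})

test_that("refractory interval keeps every second edge of a 4 Hz wave", {
  x <- square_wave(4, fs = 100, dur_s = 3)
  # rising edges every 25 samples; greedy keep-first at >= 50-sample gaps
  all_edges <- detect_heel_strikes(x, 0.5, segmentation_params(refractory_s = 1e-9))
  kept <- detect_heel_strikes(x, 0.5, segmentation_params(refractory_s = 0.5))
  # hand-applied greedy rule on the full edge list
  expected <- Reduce(function(acc, e) {
    if (!length(acc) || e - acc[length(acc)] >= 50) c(acc, e) else acc
  }, all_edges, accumulate = FALSE, init = integer(0))
  expect_equal(kept, expected)
  expect_true(all(diff(kept) >= 50))
})

test_that("a trace below threshold yields no strikes; plateaus yield one", {
  low <- signal_trace(runif(500, 0, 0.3), fs = 100)
  expect_identical(detect_heel_strikes(low, 0.5), integer(0))
  plateau <- signal_trace(c(rep(0, 50), rep(1, 100), rep(0, 50)), fs = 100)
  expect_equal(detect_heel_strikes(plateau, 0.5), 50)
})

test_that("detection co-transforms under affine rescaling", {
  set.seed(31)
  sim <- generate_synthetic_gait(gait_sim_spec(fs = 500, n_cycles = 6,
                                               seed = 31))
  x <- sim$record$channels$right_fsr_foot
  st0 <- detect_heel_strikes(x, dynamic_threshold(x))
  y <- signal_trace(4.2 * as.numeric(x) - 17, fs = trace_fs(x))
  expect_identical(detect_heel_strikes(y, dynamic_threshold(y)), st0)
})

test_that("cycles_from_strikes builds half-open consecutive cycles", {
  cyc <- cycles_from_strikes(c(100, 1700, 3300), side = "right")
  expect_equal(cyc$start, c(100, 1700))
  expect_equal(cyc$end, c(1700, 3300))
  expect_equal(cyc$cycle_index, 1:2)
  expect_error(cycles_from_strikes(5), "at least 2")
  expect_error(cycles_from_strikes(c(10, 10, 20)), "strictly increasing")
})

test_that("slice_cycles keeps channels sample-synchronized", {
  sim <- generate_synthetic_gait(gait_sim_spec(fs = 500, n_cycles = 4,
                                               seed = 7))
  rec <- sim$record
  L <- record_length(rec)
  whole <- slice_cycles(rec, data.frame(side = "right", cycle_index = 1L,
                                        start = 0L, end = L))
  expect_equal(as.numeric(whole[[1]]$right_fsr_foot),
               as.numeric(rec$channels$right_fsr_foot))
  cyc <- data.frame(side = "right", cycle_index = 1:2,
                    start = c(10L, 400L), end = c(110L, 900L))
  segs <- slice_cycles(rec, cyc)
  expect_equal(length(segs[[1]]$left_emg_tibialis_anterior), 100L)
  expect_equal(length(segs[[2]]$left_emg_tibialis_anterior), 500L)
  # contiguous cycles re-concatenate to the original span
  cont <- data.frame(side = "right", cycle_index = 1:2,
                     start = c(0L, 250L), end = c(250L, 600L))
  segs2 <- slice_cycles(rec, cont)
  expect_equal(c(as.numeric(segs2[[1]]$right_fsr_foot),
                 as.numeric(segs2[[2]]$right_fsr_foot)),
               as.numeric(rec$channels$right_fsr_foot)[1:600])
  expect_error(slice_cycles(rec, data.frame(side = "right", cycle_index = 1L,
                                            start = 0L, end = L + 1L)),
               "bounds")
})

test_that("noiseless synthetic gait round-trips strikes within 1 sample", {
  sim <- generate_synthetic_gait(gait_sim_spec(
    fs = 1500, n_cycles = 10, stride_s = 1.2, stride_jitter_s = 0,
    noise_sigma = 0, seed = 1))
  fsr <- normalize_minmax(sim$record$channels$right_fsr_foot)
  st <- detect_heel_strikes(fsr, dynamic_threshold(fsr))
  expect_equal(length(st), 10)
  expect_true(all(abs(st - sim$strikes$right) <= 1))
})

test_that("noisy synthetic gait: perfect recall/precision at +/-5 samples", {
  for (s in 1:15) {
    sim <- generate_synthetic_gait(gait_sim_spec(
      fs = 500, n_cycles = 8, noise_sigma = 0.05, seed = 200 + s))
    for (side in c("right", "left")) {
      fsr <- normalize_minmax(sim$record$channels[[paste0(side, "_fsr_foot")]])
      params <- segmentation_params()
      st <- detect_heel_strikes(fsr, dynamic_threshold(fsr), params)
      sc <- match_strikes(st, sim$strikes[[side]], tol = 5)
      expect_equal(sc$recall, 1.0)
      expect_equal(sc$precision, 1.0)
      expect_true(all(diff(st) >= params$refractory_s * 500))
    }
  }
})

test_that("segment_record produces per-leg cycles with duration bookkeeping", {
  sim <- generate_synthetic_gait(gait_sim_spec(fs = 500, n_cycles = 8,
                                               seed = 44))
  cyc <- segment_record(sim$record)
  expect_setequal(unique(cyc$side), c("left", "right"))
  expect_equal(cyc$duration_s, (cyc$end - cyc$start) / 500)
  expect_true(all(cyc$end - cyc$start >= 0.5 * 500))
  expect_true(all(cyc$usable == (cyc$end - cyc$start >= 256)))
  # right-for-all variant duplicates right-foot boundaries onto the left
  cyc_r <- segment_record(sim$record,
                          segmentation_params(source = "right_fsr_for_all"))
  r <- cyc_r[cyc_r$side == "right", ]
  l <- cyc_r[cyc_r$side == "left", ]
  expect_equal(r$start, l$start)
  expect_equal(r$end, l$end)
})
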
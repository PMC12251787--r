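# synthetic_data: generator determinism, exactness of the fGn covariance,
# fBm construction, synthetic gait morphology.

test_that("generators are pure functions of their seed", {
  expect_identical(as.numeric(generate_white_noise(100, seed = 5)),
                   as.numeric(generate_white_noise(100, seed = 5)))
  sp <- fgn_spec(0.7, 256, seed = 9)
  expect_identical(as.numeric(generate_fgn(sp)), as.numeric(generate_fgn(sp)))
  gs <- gait_sim_spec(fs = 500, n_cycles = 3, seed = 2)
  a <- generate_synthetic_gait(gs); b <- generate_synthetic_gait(gs)
  expect_identical(as.numeric(a$record$channels$right_fsr_foot),
                   as.numeric(b$record$channels$right_fsr_foot))
  expect_identical(a$strikes, b$strikes)
})

test_that("generators restore the global RNG state", {
  set.seed(1234)
  before <- .Random.seed
  invisible(generate_white_noise(100, seed = 5))
  invisible(generate_fgn(fgn_spec(0.6, 64, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("white noise is uncorrelated at lag 1", {
  x <- as.numeric(generate_white_noise(1e4, seed = 3))
  r1 <- stats::cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 0.03)
})

test_that("fGn at H=0.5 reduces to uncorrelated noise", {
  x <- as.numeric(generate_fgn(fgn_spec(0.5, 1e4, seed = 4)))
  r1 <- stats::cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 0.03)
  # closed-form covariance collapses to a delta at H = 0.5
  expect_equal(fgn_autocovariance(1:5, 0.5), rep(0, 5))
  expect_equal(fgn_autocovariance(0, 0.5), 1)
})

test_that("fGn sample autocovariance matches the closed form (H=0.8)", {
  # replicate-based Monte Carlo: the across-seed s.e. of the mean is a
  # valid error bar even under long-range dependence within each draw
  n <- 2^12; reps <- 16
  acov <- sapply(1:reps, function(s) {
    x <- as.numeric(generate_fgn(fgn_spec(0.8, n, seed = 600 + s)))
    c(stats::var(x) * (n - 1) / n,
      sapply(1:10, function(k) mean(x[1:(n - k)] * x[(k + 1):n])))
  })
  theo <- c(1, fgn_autocovariance(1:10, 0.8))
  m <- rowMeans(acov)
  se <- apply(acov, 1, stats::sd) / sqrt(reps)
  expect_true(all(abs(m - theo) < 3 * se + 1e-3))
})

test_that("fBm increments equal the underlying fGn exactly", {
  sp <- fgn_spec(0.7, 512, seed = 8)
  fgn <- as.numeric(generate_fgn(sp))
  fbm <- as.numeric(generate_fbm(sp))
  expect_equal(diff(fbm), fgn[-1], tolerance = 1e-12)
  expect_identical(fbm[1], fgn[1])
})

test_that("fBm alpha targets H + 1", {
  a15 <- sapply(0:19, function(s)
    dfa_alpha(generate_fbm(fgn_spec(0.5, 4096, seed = s)))$alpha)
  expect_lt(abs(mean(a15) - 1.5), 0.1)
  a17 <- sapply(0:19, function(s)
    dfa_alpha(generate_fbm(fgn_spec(0.7, 4096, seed = s)))$alpha)
  expect_lt(abs(mean(a17) - 1.7), 0.1)
})

test_that("spec validation rejects infeasible simulations", {
  expect_error(fgn_spec(1.2, 100, 1), "hurst")
  expect_error(fgn_spec(0.5, 8, 1), "n must be")
  expect_error(gait_sim_spec(stance_fraction = 1.2), "stance_fraction")
  expect_error(gait_sim_spec(stride_s = 0.55, stride_jitter_s = 0.05),
               "refractory")
  expect_error(gait_sim_spec(n_cycles = 1), "n_cycles")
})

test_that("synthetic FSR normalizes to [0,1] with threshold exactly 0.5", {
  sim <- generate_synthetic_gait(gait_sim_spec(fs = 500, n_cycles = 5,
                                               seed = 10))
  fsr <- normalize_minmax(sim$record$channels$left_fsr_foot)
  expect_equal(min(as.numeric(fsr)), 0)
  expect_equal(max(as.numeric(fsr)), 1)
  expect_equal(dynamic_threshold(fsr), 0.5)
})

test_that("left foot is offset half a stride; EMG chain ends at max 1", {
  sp <- gait_sim_spec(fs = 1200, n_cycles = 6, stride_jitter_s = 0, seed = 12)
  sim <- generate_synthetic_gait(sp)
  expect_equal(sim$strikes$left - sim$strikes$right,
               rep(round(sp$stride_s * 1200 / 2), 6))
  emg <- condition_emg(sim$record$channels$right_emg_tibialis_anterior)
  expect_equal(max(as.numeric(emg)), 1)
})

test_that("simulate_cohort labels and ids are consistent", {
  co <- simulate_cohort(n_records = 1L, seed = 2, fs = 500, n_cycles = 3)
  expect_equal(nrow(co$manifest), 3L)
  expect_setequal(co$manifest$group, c("control", "taichi", "master"))
  expect_identical(names(co$records), co$manifest$record_id)
  expect_equal(co$records[["mas01"]]$group_label, "master")
})
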
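# group_stats: cell summaries, one-way ANOVA, Tukey HSD post hoc.

test_that("summarize_alpha computes cell mean/sd/n and flags singletons", {
  s <- data.frame(group = c("control", "control", "control", "master"),
                  channel = "right_fsr_foot",
                  alpha = c(0.9, 1.0, 1.1, 1.3))
  out <- summarize_alpha(s)
  ctrl <- out[out$group == "control", ]
  expect_equal(ctrl$mean, 1.0)
  expect_equal(ctrl$sd, 0.1)
  expect_equal(ctrl$n, 3L)
  mas <- out[out$group == "master", ]
  expect_equal(mas$mean, 1.3)
  expect_true(is.na(mas$sd))
  expect_equal(mas$n, 1L)
})

test_that("large-sample cell mean concentrates at the population mean", {
  set.seed(41)
  s <- data.frame(group = "control", channel = "right_emg_tibialis_anterior",
                  alpha = rnorm(1000, 0.95, 0.10))
  out <- summarize_alpha(s)
  expect_lt(abs(out$mean - 0.95), 0.01)
})

test_that("identical group means give F = 0 and p = 1", {
  an <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(an$f_stat, 0)
  expect_equal(an$p_value, 1)
  expect_equal(an$df_between, 2L)
  expect_equal(an$df_within, 6L)
})

test_that("two-group F equals the squared pooled-variance t statistic", {
  set.seed(42)
  for (i in 1:10) {
    a <- rnorm(sample(5:20, 1)); b <- rnorm(sample(5:20, 1), mean = 0.3)
    an <- one_way_anova(list(a = a, b = b))
    t <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(an$f_stat, unname(t$statistic)^2, tolerance = 1e-10)
    expect_equal(an$p_value, t$p.value, tolerance = 1e-10)
  }
})

test_that("F matches the brute-force sums-of-squares oracle", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  expect_equal(one_way_anova(g)$f_stat, oracle_anova_f(g), tolerance = 1e-12)
  set.seed(43)
  for (i in 1:10) {
    g <- lapply(1:4, function(j) rnorm(sample(3:30, 1), mean = j / 10))
    names(g) <- letters[1:4]
    expect_equal(one_way_anova(g)$f_stat, oracle_anova_f(g),
                 tolerance = 1e-10)
  }
})

test_that("F is invariant under a common affine transform", {
  set.seed(44)
  g <- lapply(1:3, function(j) rnorm(10, mean = j))
  f0 <- one_way_anova(g)$f_stat
  g2 <- lapply(g, function(v) 5.5 * v - 2)
  expect_equal(one_way_anova(g2)$f_stat, f0, tolerance = 1e-9)
})

test_that("degenerate and undersized inputs error", {
  expect_error(one_way_anova(list(a = rep(1, 5), b = rep(1, 5))),
               "degenerate")
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "at least 2 obs")
  expect_error(one_way_anova(list(a = c(1, 2))), "at least 2 groups")
})

test_that("two-group Tukey p equals the unadjusted pairwise p", {
  set.seed(45)
  a <- rnorm(15); b <- rnorm(15, 0.5)
  ph <- posthoc_pairwise(list(a = a, b = b), force = TRUE)
  t <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(ph$p_adjusted, t$p.value, tolerance = 1e-6)
})

test_that("Tukey agrees with stats::TukeyHSD on a 3-group problem", {
  set.seed(46)
  v <- c(rnorm(20, 1), rnorm(25, 1.2), rnorm(15, 1.5))
  f <- factor(rep(c("a", "b", "c"), c(20, 25, 15)))
  ph <- posthoc_pairwise(split(v, f), force = TRUE)
  ref <- stats::TukeyHSD(stats::aov(v ~ f))$f
  # rows: b-a, c-a, c-b; ours: a-b, a-c, b-c (sign flipped)
  expect_equal(ph$difference, -unname(ref[, "diff"]), tolerance = 1e-9)
  expect_equal(ph$p_adjusted, unname(ref[, "p adj"]), tolerance = 1e-6)
})

test_that("a 5-sd shifted group separates; the null pair does not", {
  set.seed(47)
  sdp <- 0.1
  g <- list(a = rnorm(50, 1, sdp), b = rnorm(50, 1, sdp),
            c = rnorm(50, 1 + 5 * sdp, sdp))
  ph <- posthoc_pairwise(g)
  expect_lt(ph$p_adjusted[ph$pair == "a-c"], 0.001)
  expect_lt(ph$p_adjusted[ph$pair == "b-c"], 0.001)
  expect_gt(ph$p_adjusted[ph$pair == "a-b"], 0.05)
})

test_that("near-identical groups give adjusted p ~ 1 and the gate gates", {
  set.seed(48)
  base <- rnorm(20)
  g <- list(a = base, b = base + rnorm(20, 0, 1e-6),
            c = base + rnorm(20, 0, 1e-6))
  ph <- posthoc_pairwise(g, force = TRUE)
  expect_true(all(ph$p_adjusted > 0.99))
  gated <- posthoc_pairwise(g)
  expect_equal(nrow(gated), 0L)
  expect_true(isTRUE(attr(gated, "gated")))
})
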
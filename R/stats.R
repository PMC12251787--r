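# Group-level statistics on per-cycle scaling exponents: cell summaries
# (mean +/- sd per group x channel), one-way ANOVA computed from the
# explicit sum-of-squares decomposition, and Tukey HSD (Tukey-Kramer for
# unbalanced groups) post hoc pairwise comparisons.

#' Summarize per-cycle alpha values by group and channel
#'
#' @param samples Data.frame with at least `group`, `channel`, `alpha`
#'   columns (one row per cycle-level observation).
#' @return Data.frame with one row per (group, channel) cell: `mean`,
#'   `sd` (sample, n-1 denominator; `NA` when n < 2) and `n`.
#' @export
summarize_alpha <- function(samples) {
  stopifnot(all(c("group", "channel", "alpha") %in% names(samples)))
  if (any(!is.finite(samples$alpha)))
    stop("summarize_alpha: non-finite alpha values", call. = FALSE)
  key <- interaction(samples$group, samples$channel, drop = TRUE, sep = "\r")
  cells <- split(samples$alpha, key)
  parts <- strsplit(names(cells), "\r", fixed = TRUE)
  out <- data.frame(
    group = vapply(parts, `[`, character(1), 1L),
    channel = vapply(parts, `[`, character(1), 2L),
    mean = vapply(cells, mean, numeric(1)),
    sd = vapply(cells, function(v) if (length(v) >= 2L) stats::sd(v)
                else NA_real_, numeric(1)),
    n = vapply(cells, length, integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$channel, out$group), ]
  rownames(out) <- NULL
  out
}

#' One-way ANOVA from the sum-of-squares decomposition
#'
#' `F = (SS_between / (k-1)) / (SS_within / (N-k))` with the p-value from
#' the F distribution on `(k-1, N-k)` degrees of freedom.
#'
#' @param groups Named list of k >= 2 numeric vectors (one per group),
#'   each of length >= 2.
#' @return An `anova_result` list: `f_stat`, `df_between`, `df_within`,
#'   `p_value`, `group_means`, `group_sds`, `group_ns`, and `ms_within`
#'   (pooled variance, reused by the post hoc test).
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("one_way_anova: need a list of at least 2 groups", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L))
    stop("one_way_anova: every group needs at least 2 observations",
         call. = FALSE)
  all_v <- unlist(groups, use.names = FALSE)
  if (max(all_v) == min(all_v))
    stop("one_way_anova: degenerate input (all values identical)",
         call. = FALSE)
  k <- length(groups); N <- sum(ns)
  gm <- vapply(groups, mean, numeric(1))
  grand <- mean(all_v)
  ss_b <- sum(ns * (gm - grand)^2)
  ss_w <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df_b <- k - 1L; df_w <- N - k
  ms_w <- ss_w / df_w
  f <- (ss_b / df_b) / ms_w
  structure(list(
    f_stat = f, df_between = df_b, df_within = df_w,
    p_value = stats::pf(f, df_b, df_w, lower.tail = FALSE),
    group_means = gm,
    group_sds = vapply(groups, stats::sd, numeric(1)),
    group_ns = ns,
    ms_within = ms_w), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4f, p = %.4g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  invisible(x)
}

#' Tukey HSD post hoc pairwise comparisons
#'
#' All `k(k-1)/2` pairwise mean differences with studentized-range
#' adjusted p-values (Tukey-Kramer standard error for unequal n). By
#' default comparisons are only run when the omnibus ANOVA is significant
#' at `gate`; `force = TRUE` overrides the gate.
#'
#' @param groups Named list of numeric vectors, as in [one_way_anova()].
#' @param gate Omnibus significance gate (default 0.05).
#' @param force Run the comparisons regardless of the omnibus p-value.
#' @param method `"tukey"` (default) or `"bonferroni"`.
#' @return Data.frame with `pair`, `difference` (first minus second),
#'   `p_adjusted`; empty with attribute `gated = TRUE` when the omnibus
#'   test is not significant and `force` is `FALSE`.
#' @export
posthoc_pairwise <- function(groups, gate = 0.05, force = FALSE,
                             method = c("tukey", "bonferroni")) {
  method <- match.arg(method)
  an <- one_way_anova(groups)
  empty <- data.frame(pair = character(0), difference = numeric(0),
                      p_adjusted = numeric(0))
  if (!force && an$p_value >= gate) {
    attr(empty, "gated") <- TRUE
    return(empty)
  }
  k <- length(groups)
  nm <- names(groups)
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    diff_ <- an$group_means[i] - an$group_means[j]
    se2 <- an$ms_within * (1 / an$group_ns[i] + 1 / an$group_ns[j])
    if (method == "tukey") {
      q <- abs(diff_) / sqrt(se2 / 2)
      p <- stats::ptukey(q, k, an$df_within, lower.tail = FALSE)
    } else {
      t <- abs(diff_) / sqrt(se2)
      p <- min(1, choose(k, 2) *
                 2 * stats::pt(t, an$df_within, lower.tail = FALSE))
    }
    rows[[length(rows) + 1L]] <-
      data.frame(pair = paste(nm[i], nm[j], sep = "-"),
                 difference = unname(diff_), p_adjusted = unname(p),
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group comparison report for one channel
#'
#' Bundles the omnibus ANOVA and (gated) post hoc table.
#'
#' @param groups Named list of per-group alpha vectors.
#' @param gate Post hoc gate (default 0.05).
#' @param method Post hoc method.
#' @return List with `anova` and `posthoc`.
#' @export
compare_groups <- function(groups, gate = 0.05,
                           method = c("tukey", "bonferroni")) {
  method <- match.arg(method)
  list(anova = one_way_anova(groups),
       posthoc = posthoc_pairwise(groups, gate = gate, method = method))
}
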
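# End-to-end orchestration: read records -> condition EMG -> cut 15 s
# analysis windows -> normalize FSR and segment strides per window ->
# per-cycle DFA on every channel of the striding side -> pooled group
# summaries, ANOVA and post hoc comparisons -> TSV/JSON artifacts plus a
# reproducibility manifest. The analysis itself is deterministic; the
# seed in the config only drives simulation.

#' Pipeline configuration
#'
#' Defaults follow the study protocol: 15 s analysis windows, 20-450 Hz
#' fourth-order zero-phase Butterworth EMG conditioning, 0.5 s heel-strike
#' refractory interval with per-leg FSR segmentation, linear-detrend DFA
#' on cycles of at least 256 samples, and cycle-level one-way ANOVA with
#' Tukey HSD post hoc comparisons gated at p < 0.05.
#'
#' @param input Input directory (CSV and/or WFDB records) or a list of
#'   in-memory [gait_record] objects.
#' @param output Output directory for artifacts.
#' @param manifest Optional path to a TSV with columns `record_id`,
#'   `group`; defaults to `<input>/manifest.tsv` when present. Ignored
#'   for in-memory records (their `group_label` is used).
#' @param window_s Analysis window length in seconds.
#' @param filter A [filter_spec()].
#' @param segmentation A [segmentation_params()].
#' @param dfa_min_cycle Minimum cycle length in samples for DFA.
#' @param anova_unit `"cycle"` (each cycle is one observation, the
#'   default) or `"record"` (per-record mean alpha, one observation per
#'   record; sidesteps the within-record dependence of cycles).
#' @param posthoc `"tukey"` or `"bonferroni"`.
#' @param gate Omnibus gate for post hoc comparisons.
#' @param plots Emit per-cycle log-log plots (PNG, can be many files).
#' @param seed Root seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, output, manifest = NULL, window_s = 15,
                            filter = filter_spec(),
                            segmentation = segmentation_params(),
                            dfa_min_cycle = 256L,
                            anova_unit = c("cycle", "record"),
                            posthoc = c("tukey", "bonferroni"),
                            gate = 0.05, plots = FALSE, seed = 1L) {
  anova_unit <- match.arg(anova_unit)
  posthoc <- match.arg(posthoc)
  if (window_s <= 0) stop("pipeline_config: window_s must be > 0", call. = FALSE)
  segmentation$min_cycle_samples <- as.integer(dfa_min_cycle)
  structure(list(input = input, output = output, manifest = manifest,
                 window_s = window_s, filter = filter,
                 segmentation = segmentation,
                 dfa_min_cycle = as.integer(dfa_min_cycle),
                 anova_unit = anova_unit, posthoc = posthoc, gate = gate,
                 plots = plots, seed = as.integer(seed)),
            class = "pipeline_config")
}

load_input_records <- function(config) {
  if (is.list(config$input) && !is.character(config$input))
    return(config$input)
  dir <- config$input
  if (!dir.exists(dir))
    stop("run_pipeline: input directory not found: ", dir, call. = FALSE)
  man_path <- config$manifest
  if (is.null(man_path) && file.exists(file.path(dir, "manifest.tsv")))
    man_path <- file.path(dir, "manifest.tsv")
  groups <- NULL
  if (!is.null(man_path)) {
    man <- utils::read.delim(man_path, stringsAsFactors = FALSE)
    groups <- stats::setNames(man$group, man$record_id)
  }
  csvs <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  heas <- list.files(dir, pattern = "\\.hea$", full.names = TRUE)
  paths <- c(stats::setNames(csvs, rep("csv", length(csvs))),
             stats::setNames(sub("\\.hea$", "", heas),
                             rep("wfdb", length(heas))))
  if (!length(paths))
    stop("run_pipeline: no input records (*.csv or *.hea) in ", dir,
         call. = FALSE)
  records <- list()
  for (i in seq_along(paths)) {
    rec <- read_record(paths[i], format = names(paths)[i])
    if (!is.null(groups) && rec$record_id %in% names(groups))
      rec$group_label <- groups[[rec$record_id]]
    records[[rec$record_id]] <- rec
  }
  records
}

analyze_window <- function(win, config, emg_ready = FALSE) {
  # EMG conditioning may already have been applied record-wide
  rec <- win
  if (!emg_ready) {
    for (role in names(rec$channels)) {
      if (!is_fsr_role(role))
        rec$channels[[role]] <- condition_emg(rec$channels[[role]],
                                              config$filter)
    }
  }
  for (role in names(rec$channels)) {
    if (is_fsr_role(role))
      rec$channels[[role]] <- normalize_minmax(rec$channels[[role]])
  }
  cycles <- segment_record(rec, config$segmentation)
  if (!nrow(cycles)) return(NULL)
  rows <- list()
  for (j in seq_len(nrow(cycles))) {
    side <- cycles$side[j]
    idx <- (cycles$start[j] + 1L):cycles$end[j]
    side_roles <- names(rec$channels)[startsWith(names(rec$channels), side)]
    for (role in side_roles) {
      seg <- as.numeric(rec$channels[[role]])[idx]
      row <- data.frame(record_id = win$record_id, group = win$group_label,
                        side = side, channel = role_kind(role),
                        cycle_index = cycles$cycle_index[j],
                        start_sample = cycles$start[j],
                        end_sample = cycles$end[j],
                        duration_s = cycles$duration_s[j],
                        alpha = NA_real_, r_squared = NA_real_,
                        n_windows_used = NA_integer_,
                        status = "ok", stringsAsFactors = FALSE)
      if (!cycles$usable[j]) {
        row$status <- "excluded_short"
      } else {
        res <- tryCatch(suppressWarnings(dfa_alpha(seg)),
                        error = function(e) e)
        if (inherits(res, "error")) {
          row$status <- paste0("dfa_error: ", conditionMessage(res))
        } else {
          row$alpha <- res$alpha
          row$r_squared <- res$r_squared
          row$n_windows_used <- res$n_windows_used
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Run the full gait DFA pipeline
#'
#' @param config A [pipeline_config()].
#' @param verbose Print per-record progress.
#' @return Invisibly, a list with `alpha_table`, `summary`, `stats`
#'   (per-channel ANOVA + post hoc) and the artifact paths. Artifacts
#'   written to `config$output`: `alpha_table.tsv`, `group_summary.tsv`,
#'   `anova_report.json`, `run_manifest.json`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  records <- load_input_records(config)
  if (!length(records))
    stop("run_pipeline: no input records", call. = FALSE)
  dir.create(config$output, recursive = TRUE, showWarnings = FALSE)

  tables <- list()
  log <- list()
  for (rec in records) {
    res <- tryCatch({
      # condition EMG over the full trial so the normalization constant
      # is the trial-wide maximum, then window
      for (role in names(rec$channels)) {
        if (!is_fsr_role(role))
          rec$channels[[role]] <- condition_emg(rec$channels[[role]],
                                                config$filter)
      }
      wins <- window_record(rec, config$window_s)
      do.call(rbind, Filter(Negate(is.null),
                            lapply(wins, analyze_window, config = config,
                                   emg_ready = TRUE)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log[[rec$record_id]] <- conditionMessage(res)
      if (verbose) message("skipping ", rec$record_id, ": ",
                           conditionMessage(res))
      next
    }
    if (verbose && !is.null(res))
      message(rec$record_id, ": ", sum(res$status == "ok"), " cycles ok, ",
              sum(res$status != "ok"), " excluded/failed")
    tables[[rec$record_id]] <- res
  }
  alpha_table <- do.call(rbind, tables)
  if (is.null(alpha_table) || !nrow(alpha_table))
    stop("run_pipeline: no cycles produced from any input record",
         call. = FALSE)
  rownames(alpha_table) <- NULL

  ok <- alpha_table[alpha_table$status == "ok", ]
  summary_tab <- summarize_alpha(
    data.frame(group = ok$group,
               channel = paste(ok$side, ok$channel, sep = "_"),
               alpha = ok$alpha))
  stats_rep <- channel_group_stats(ok, config)

  tsv <- function(d, f) {
    p <- file.path(config$output, f)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  p_alpha <- tsv(alpha_table, "alpha_table.tsv")
  p_sum <- tsv(summary_tab, "group_summary.tsv")
  p_anova <- file.path(config$output, "anova_report.json")
  jsonlite::write_json(stats_rep, p_anova, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  p_man <- file.path(config$output, "run_manifest.json")
  cfg_echo <- config
  cfg_echo$input <- if (is.character(config$input)) config$input
                    else "<in-memory records>"
  jsonlite::write_json(
    list(package = "gaitdfa",
         version = as.character(utils::packageVersion("gaitdfa")),
         seed = config$seed,
         config = unclass(cfg_echo),
         n_records = length(records),
         skipped = log),
    p_man, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)

  if (isTRUE(config$plots)) write_cycle_plots(ok, records, config)

  invisible(list(alpha_table = alpha_table, summary = summary_tab,
                 stats = stats_rep,
                 paths = c(alpha_table = p_alpha, summary = p_sum,
                           anova = p_anova, manifest = p_man)))
}

channel_group_stats <- function(ok, config) {
  rep <- list()
  if (config$anova_unit == "record") {
    agg <- stats::aggregate(alpha ~ record_id + group + side + channel,
                            data = ok, FUN = mean)
    ok <- agg
  }
  for (side in unique(ok$side)) for (ch in unique(ok$channel)) {
    sub <- ok[ok$side == side & ok$channel == ch, ]
    groups <- split(sub$alpha, sub$group)
    groups <- groups[vapply(groups, length, integer(1)) >= 2L]
    key <- paste(side, ch, sep = "_")
    if (length(groups) < 2L) {
      rep[[key]] <- list(note = "fewer than 2 groups with n >= 2")
      next
    }
    cmp <- tryCatch(compare_groups(groups, gate = config$gate,
                                   method = config$posthoc),
                    error = function(e) list(note = conditionMessage(e)))
    if (!is.null(cmp$anova)) {
      a <- cmp$anova
      rep[[key]] <- list(
        f_stat = a$f_stat, df_between = a$df_between,
        df_within = a$df_within, p_value = a$p_value,
        group_means = as.list(a$group_means),
        group_sds = as.list(a$group_sds),
        group_ns = as.list(a$group_ns),
        posthoc = cmp$posthoc)
    } else rep[[key]] <- cmp
  }
  rep
}

write_cycle_plots <- function(ok, records, config) {
  pdir <- file.path(config$output, "plots")
  dir.create(pdir, showWarnings = FALSE)
  # recompute each cycle's curve from the conditioned window trace; the
  # stored start/end are window-relative
  cond <- list()
  for (i in seq_len(nrow(ok))) {
    row <- ok[i, ]
    base_id <- sub("_w[0-9]+$", "", row$record_id)
    win_i <- as.integer(sub("^.*_w", "", row$record_id))
    rec <- records[[base_id]]
    if (is.null(rec) || is.na(win_i)) next
    if (is.null(cond[[base_id]])) {
      for (role in names(rec$channels)) {
        if (!is_fsr_role(role))
          rec$channels[[role]] <- condition_emg(rec$channels[[role]],
                                                config$filter)
      }
      cond[[base_id]] <- rec
    }
    rec <- cond[[base_id]]
    w <- floor(config$window_s * record_fs(rec))
    off <- (win_i - 1L) * w
    role <- paste(row$side, row$channel, sep = "_")
    tr <- as.numeric(rec$channels[[role]])
    seg <- tr[(off + row$start_sample + 1L):(off + row$end_sample)]
    fn <- file.path(pdir, sprintf("%s_%s_%s_c%03d.png", row$record_id,
                                  row$side, row$channel, row$cycle_index))
    grDevices::png(fn, width = 600, height = 450)
    plot(suppressWarnings(dfa_alpha(seg)),
         main = sprintf("%s %s %s cycle %d", row$record_id, row$side,
                        row$channel, row$cycle_index))
    grDevices::dev.off()
  }
}
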
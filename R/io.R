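# Record I/O. Two on-disk formats: WFDB (the PhysioNet waveform format:
# a .hea text header plus a format-16 binary .dat of interleaved 16-bit
# little-endian ADC counts) and a plain CSV fallback (one header row of
# channel names, optional leading "# fs=<Hz>" comment). Channel names are
# resolved to roles through a configurable substring-match table because
# acquisition systems label channels inconsistently.

#' Default channel-name to role mapping
#'
#' Case-insensitive resolution: the side comes from an `l`/`r` prefix or
#' a `left`/`right` substring; the kind from `ta`/`tib` (tibialis
#' anterior), `lg`/`gastroc` (lateral gastrocnemius) or `fsr`/`foot`.
#'
#' @param name Character vector of channel names.
#' @return Character vector of canonical roles; `NA` where unresolved.
#' @export
default_role_map <- function(name) {
  vapply(name, function(nm) {
    low <- tolower(nm)
    side <- if (grepl("left", low) || grepl("^l", low)) "left"
            else if (grepl("right", low) || grepl("^r", low)) "right"
            else return(NA_character_)
    body <- sub("^(left|right|l|r)[ _-]*", "", low)
    kind <- if (grepl("fsr|foot", body)) "fsr_foot"
            else if (grepl("^ta|tib", body)) "emg_tibialis_anterior"
            else if (grepl("^lg|gastroc", body)) "emg_lateral_gastrocnemius"
            else return(NA_character_)
    paste(side, kind, sep = "_")
  }, character(1), USE.NAMES = FALSE)
}

resolve_roles <- function(names, role_map) {
  roles <- role_map(names)
  if (anyNA(roles))
    stop("read_record: cannot resolve channel role(s) for: ",
         paste(names[is.na(roles)], collapse = ", "), call. = FALSE)
  if (anyDuplicated(roles))
    stop("read_record: duplicate channel roles after mapping: ",
         paste(roles[duplicated(roles)], collapse = ", "), call. = FALSE)
  roles
}

#' Read a multichannel gait record
#'
#' @param path For `format = "wfdb"`, the record path without extension
#'   (reads `<path>.hea` and the signal file it names); for `"csv"`, a
#'   CSV file with one header row of channel names, one column per
#'   channel, and optionally a leading `# fs=<Hz>` comment line.
#' @param format `"wfdb"` or `"csv"`.
#' @param fs Sampling rate in Hz; required for CSV files without a
#'   `# fs=` line, ignored for WFDB (taken from the header).
#' @param role_map Function mapping channel names to roles
#'   (default [default_role_map]).
#' @param group_label Group label to attach (default `"unknown"`).
#' @return A [gait_record].
#' @export
read_record <- function(path, format = c("csv", "wfdb"), fs = NULL,
                        role_map = default_role_map,
                        group_label = "unknown") {
  format <- match.arg(format)
  if (format == "csv") read_record_csv(path, fs, role_map, group_label)
  else read_record_wfdb(path, role_map, group_label)
}

read_record_csv <- function(path, fs, role_map, group_label) {
  if (!file.exists(path))
    stop("read_record: file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("fs\\s*=\\s*([0-9.]+)", first))[[1L]]
    if (length(m) == 2L) fs <- as.numeric(m[2L])
    skip <- 1L
  }
  if (is.null(fs))
    stop("read_record: sampling rate unknown; pass fs= or add a '# fs=' line",
         call. = FALSE)
  dat <- utils::read.csv(path, skip = skip, check.names = FALSE)
  if (!nrow(dat)) stop("read_record: no samples in ", path, call. = FALSE)
  roles <- resolve_roles(names(dat), role_map)
  channels <- stats::setNames(
    lapply(seq_along(dat), function(j) signal_trace(dat[[j]], fs)), roles)
  gait_record(tools::file_path_sans_ext(basename(path)), channels,
              group_label = group_label)
}

#' Write a gait record as CSV
#'
#' Emits a `# fs=<Hz>` comment line, a header row of channel names
#' (canonical role strings), and one row per sample.
#'
#' @param record A [gait_record].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  dat <- as.data.frame(lapply(record$channels, as.numeric),
                       check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", record_fs(record)), con)
  utils::write.csv(dat, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- WFDB (format 16) -------------------------------------------------

read_record_wfdb <- function(path, role_map, group_label) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea))
    stop("read_record: WFDB header not found: ", hea, call. = FALSE)
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rec_name <- top[1L]
  n_sig <- as.integer(top[2L])
  fs <- as.numeric(top[3L])
  n_samp <- as.integer(top[4L])
  sig <- lines[1L + seq_len(n_sig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    gain_field <- f[3L]                    # gain(baseline)/units
    base <- 0
    gb <- sub("/.*$", "", gain_field)
    if (grepl("\\(", gb)) {
      base <- as.numeric(sub(".*\\((-?[0-9.]+)\\).*", "\\1", gb))
      gb <- sub("\\(.*$", "", gb)
    }
    list(file = f[1L], fmt = f[2L], gain = as.numeric(gb), baseline = base,
         desc = if (length(f) >= 9L) paste(f[9L:length(f)], collapse = " ")
                else f[length(f)])
  }
  sigs <- lapply(sig, parse_sig)
  fmts <- unique(vapply(sigs, `[[`, character(1), "fmt"))
  if (!identical(fmts, "16"))
    stop("read_record: only WFDB format 16 is supported (got ",
         paste(fmts, collapse = ","), ")", call. = FALSE)
  dat_files <- unique(vapply(sigs, `[[`, character(1), "file"))
  if (length(dat_files) != 1L)
    stop("read_record: multi-file WFDB records are not supported", call. = FALSE)
  dat_path <- file.path(dirname(hea), dat_files)
  if (!file.exists(dat_path))
    stop("read_record: WFDB signal file not found: ", dat_path, call. = FALSE)
  raw <- readBin(dat_path, "integer", n = n_sig * n_samp, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_sig * n_samp)
    stop("read_record: WFDB signal file shorter than header declares",
         call. = FALSE)
  adc <- matrix(raw, nrow = n_sig)           # interleaved sample-major
  names_ <- vapply(sigs, `[[`, character(1), "desc")
  roles <- resolve_roles(names_, role_map)
  channels <- stats::setNames(lapply(seq_len(n_sig), function(j) {
    g <- sigs[[j]]$gain
    if (is.na(g) || g == 0) g <- 200        # WFDB default gain
    signal_trace((adc[j, ] - sigs[[j]]$baseline) / g, fs)
  }), roles)
  gait_record(rec_name, channels, group_label = group_label)
}

#' Write a gait record in WFDB format 16
#'
#' Writes `<path>.hea` and `<path>.dat` (interleaved 16-bit little-endian
#' ADC counts). Each channel gets a gain spanning the 16-bit range over
#' the channel's observed amplitude, so the quantization error is at most
#' half an ADC count over gain. Channel descriptions are the canonical
#' role strings, which [default_role_map()] resolves back.
#'
#' @param record A [gait_record].
#' @param path Record path without extension.
#' @return `path`, invisibly.
#' @export
write_record_wfdb <- function(record, path) {
  n_sig <- length(record$channels)
  n_samp <- record_length(record)
  dat_name <- paste0(basename(path), ".dat")
  adc <- matrix(0L, nrow = n_sig, ncol = n_samp)
  gains <- numeric(n_sig)
  for (j in seq_len(n_sig)) {
    v <- as.numeric(record$channels[[j]])
    amp <- max(abs(v), 1e-12)
    g <- 30000 / amp                         # fill the int16 range
    gains[j] <- g
    adc[j, ] <- as.integer(round(v * g))
  }
  writeBin(as.integer(adc), paste0(path, ".dat"), size = 2L,
           endian = "little")
  hea <- c(sprintf("%s %d %g %d", basename(path), n_sig,
                   record_fs(record), n_samp),
           vapply(seq_len(n_sig), function(j) {
             ck <- sum(adc[j, ]) %% 65536L
             if (ck >= 32768L) ck <- ck - 65536L
             sprintf("%s 16 %.6f(0)/mV 16 0 %d %d 0 %s",
                     dat_name, gains[j], adc[j, 1L], ck,
                     names(record$channels)[j])
           }, character(1)))
  writeLines(hea, paste0(path, ".hea"))
  invisible(path)
}

#' Cut a record into fixed-length non-overlapping windows
#'
#' Windows are anchored at sample 0 and contiguous; the trailing
#' remainder shorter than one window is discarded. Window `k` inherits
#' the record id with a `_w<k>` suffix.
#'
#' @param record A [gait_record].
#' @param window_s Window duration in seconds (default 15).
#' @return List of [gait_record] windows (length `floor(L / (window_s * fs))`).
#' @export
window_record <- function(record, window_s = 15) {
  if (window_s <= 0)
    stop("window_record: window_s must be > 0", call. = FALSE)
  fs <- record_fs(record)
  w <- floor(window_s * fs)
  L <- record_length(record)
  k <- L %/% w
  if (k < 1L)
    stop("window_record: record shorter than one window (", L, " < ", w,
         " samples)", call. = FALSE)
  lapply(seq_len(k), function(i) {
    idx <- ((i - 1L) * w + 1L):(i * w)
    win <- record
    win$record_id <- sprintf("%s_w%d", record$record_id, i)
    win$channels <- lapply(record$channels, function(tr) tr[idx])
    win
  })
}
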
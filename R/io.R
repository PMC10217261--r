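#' Read a signal from disk
#'
#' Supported formats:
#'
#' * `"csv"`: either a single column of sample values (supply `fs`), or two
#'   columns `time,value` with a uniformly spaced time axis (header row
#'   optional). Non-uniform timestamps are rejected.
#' * `"wfdb"`: a PhysioNet WFDB record (MIT-BIH dialect: `.hea` header plus
#'   format-212 `.dat`); `path` is the record path with or without the
#'   `.hea` extension, `channel` picks the signal, and amplitudes are
#'   converted to physical units using the header gain and baseline.
#'
#' @param path File path (CSV file or WFDB record name).
#' @param format `"auto"` (by extension), `"csv"` or `"wfdb"`.
#' @param channel 1-based channel index for WFDB records.
#' @param fs Sampling rate in Hz, required for single-column CSV.
#' @return A signal tibble.
#' @export
read_signal <- function(path, format = c("auto", "csv", "wfdb"),
                        channel = 1, fs = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  switch(format,
    csv = read_signal_csv(path, fs = fs),
    wfdb = read_wfdb(path, channel = channel)
  )
}

read_signal_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
  df <- utils::read.csv(path, header = has_header)
  if (ncol(df) == 1) {
    if (is.null(fs)) abort("Single-column CSV: supply `fs`.")
    vals <- as.numeric(df[[1]])
    if (anyNA(vals)) abort("CSV contains non-numeric or missing sample values.")
    return(as_signal(vals, fs = fs))
  }
  tm <- as.numeric(df[[1]])
  vals <- as.numeric(df[[2]])
  if (anyNA(tm) || anyNA(vals)) abort("CSV contains non-numeric or missing values.")
  as_signal(tibble(time = tm, value = vals))
}

#' Write a signal to CSV
#'
#' Two columns, `time` and `value`, with full double precision; the
#' round-trip through [read_signal()] is exact to 1e-12.
#'
#' @param signal A signal tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  signal <- validate_signal(signal)
  df <- data.frame(time = format(signal$time, digits = 17, trim = TRUE),
                   value = format(signal$value, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a WFDB record (format 212)
#'
#' Minimal reader for the MIT-BIH dialect of the WFDB format: a text `.hea`
#' header naming one `.dat` file in format 212 (two 12-bit two's-complement
#' samples packed into 3 bytes, channels interleaved). Raw ADC units are
#' converted to physical units as `(adc - baseline) / gain`.
#'
#' @param record Record path with or without the `.hea` extension.
#' @param channel 1-based channel to extract.
#' @return A signal tibble carrying the record's sampling rate.
#' @export
read_wfdb <- function(record, channel = 1) {
  hea_path <- if (grepl("\\.hea$", record)) record else paste0(record, ".hea")
  if (!file.exists(hea_path)) abort(sprintf("Header not found: %s", hea_path))
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(head_tok[2])
  fs <- if (length(head_tok) >= 3) as.numeric(head_tok[3]) else 250
  nsamp <- if (length(head_tok) >= 4) as.integer(head_tok[4]) else NA_integer_
  if (is.na(nsig) || nsig < 1) abort("Malformed WFDB header: bad signal count.")
  if (channel < 1 || channel > nsig) {
    abort(sprintf("Channel %d not present (record has %d).", channel, nsig))
  }
  sig_lines <- lines[2:(1 + nsig)]
  specs <- lapply(sig_lines, parse_wfdb_signal_line)
  fmts <- vapply(specs, `[[`, character(1), "format")
  if (!all(fmts == "212")) {
    abort(sprintf("Only format 212 is supported (got: %s).",
                  paste(unique(fmts), collapse = ", ")))
  }
  dat_file <- specs[[1]]$file
  dat_path <- file.path(dirname(hea_path), dat_file)
  if (!file.exists(dat_path)) abort(sprintf("Data file not found: %s", dat_path))
  raw_bytes <- readBin(dat_path, "raw", n = file.size(dat_path))
  adc <- decode_212(raw_bytes)
  total <- if (is.na(nsamp)) floor(length(adc) / nsig) else nsamp
  if (length(adc) < total * nsig) abort("Data file shorter than the header declares.")
  sp <- specs[[channel]]
  adc_ch <- adc[seq.int(channel, by = nsig, length.out = total)]
  vals <- (adc_ch - sp$baseline) / sp$gain
  as_signal(vals, fs = fs, label = basename(sub("\\.hea$", "", hea_path)))
}

parse_wfdb_signal_line <- function(line) {
  tok <- strsplit(trimws(line), "\\s+")[[1]]
  fmt <- sub("[x:+].*$", "", tok[2])
  gain_tok <- if (length(tok) >= 3) tok[3] else "200"
  gain_main <- sub("/.*$", "", gain_tok)
  baseline <- NA_real_
  if (grepl("\\(", gain_main)) {
    baseline <- as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", gain_main))
    gain_main <- sub("\\(.*$", "", gain_main)
  }
  gain <- as.numeric(gain_main)
  if (is.na(gain) || gain == 0) gain <- 200
  adc_zero <- if (length(tok) >= 5) suppressWarnings(as.numeric(tok[5])) else 0
  if (is.na(adc_zero)) adc_zero <- 0
  if (is.na(baseline)) baseline <- adc_zero
  list(file = tok[1], format = fmt, gain = gain, baseline = baseline)
}

decode_212 <- function(bytes) {
  n3 <- floor(length(bytes) / 3) * 3
  b <- as.integer(bytes[seq_len(n3)])
  b1 <- b[seq(1, n3, by = 3)]
  b2 <- b[seq(2, n3, by = 3)]
  b3 <- b[seq(3, n3, by = 3)]
  s1 <- b1 + 256L * (b2 %% 16L)
  s2 <- b3 + 256L * (b2 %/% 16L)
  out <- numeric(2 * length(s1))
  out[c(TRUE, FALSE)] <- s1
  out[c(FALSE, TRUE)] <- s2
  out - 4096 * (out > 2047)
}

#' Write signals as a WFDB format-212 record
#'
#' Companion to [read_wfdb()], mainly for building test fixtures: converts
#' one or two signal tibbles to 12-bit ADC counts and writes a `.hea`/`.dat`
#' pair readable by any WFDB implementation.
#'
#' @param signals A signal tibble or list of up to two sharing one time axis.
#' @param record Record name (no extension).
#' @param dir Output directory.
#' @param gain ADC units per mV (default 200, the MIT-BIH convention).
#' @param baseline ADC value corresponding to 0 mV (default 1024).
#' @return The record path (without extension), invisibly.
#' @export
write_wfdb <- function(signals, record, dir = ".", gain = 200, baseline = 1024) {
  if (is.data.frame(signals)) signals <- list(signals)
  if (length(signals) < 1 || length(signals) > 2) {
    abort("`signals` must hold one or two channels.")
  }
  signals <- lapply(signals, validate_signal)
  n <- nrow(signals[[1]])
  fs <- signal_fs(signals[[1]])
  for (s in signals) {
    if (nrow(s) != n) abort("All channels must share one length.")
  }
  nsig <- length(signals)
  adc <- matrix(0L, nrow = n, ncol = nsig)
  for (j in seq_len(nsig)) {
    a <- as.integer(round(signals[[j]]$value * gain + baseline))
    if (any(a < -2048 | a > 2047)) abort("Signal overflows the 12-bit ADC range.")
    adc[, j] <- a
  }
  flat <- as.integer(t(adc))  # channel-interleaved
  if (length(flat) %% 2 == 1) flat <- c(flat, 0L)
  u <- flat + 4096L * (flat < 0L)  # 12-bit two's complement
  s1 <- u[c(TRUE, FALSE)]
  s2 <- u[c(FALSE, TRUE)]
  bytes <- raw(3 * length(s1))
  bytes[seq(1, length(bytes), by = 3)] <- as.raw(s1 %% 256L)
  bytes[seq(2, length(bytes), by = 3)] <- as.raw((s1 %/% 256L) + 16L * (s2 %/% 256L))
  bytes[seq(3, length(bytes), by = 3)] <- as.raw(s2 %% 256L)
  dat <- paste0(record, ".dat")
  writeBin(bytes, file.path(dir, dat))
  hea <- c(
    sprintf("%s %d %g %d", record, nsig, fs, n),
    vapply(seq_len(nsig), function(j) {
      sprintf("%s 212 %g(%d)/mV 12 %d 0 0 0 ch%d", dat, gain, as.integer(baseline),
              as.integer(baseline), j)
    }, character(1))
  )
  writeLines(hea, file.path(dir, paste0(record, ".hea")))
  invisible(file.path(dir, record))
}

#' Write a denoising report to a directory
#'
#' Emits `denoised.csv` (the output signal), `selection.json` (mode
#' partition, correlations, threshold), `metrics.json` (parameters and, when
#' a reference was supplied, SNR/MSE) and, if the parameters were tuned,
#' `convergence.csv` (sparrow search best-fitness curve).
#'
#' @param report A `denoise_report` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "denoise_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_signal_csv(report$denoised, file.path(dir, "denoised.csv"))
  sel <- report$selection
  jsonlite::write_json(
    list(
      baseline_idx = sel$baseline_idx,
      effective_idx = sel$effective_idx,
      noise_idx = sel$noise_idx,
      rho = sel$rho,
      mu = sel$mu,
      mean_values = unname(sel$mean_values),
      mean_threshold = sel$mean_threshold
    ),
    file.path(dir, "selection.json"),
    digits = NA, na = "null"
  )
  jsonlite::write_json(
    list(
      k = report$k, alpha = report$alpha,
      snr_db = report$snr_db, input_snr_db = report$input_snr_db,
      mse = report$mse, config = report$config
    ),
    file.path(dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, na = "null", null = "null"
  )
  if (!is.null(report$tuning)) {
    utils::write.csv(tidy(report$tuning), file.path(dir, "convergence.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Write decomposition modes to CSV
#'
#' One column per mode (plus a leading `time` column), for external
#' inspection of a [vmd()] decomposition.
#'
#' @param fit A `vmd` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modes_csv <- function(fit, path) {
  stopifnot(inherits(fit, "vmd"))
  df <- data.frame(time = fit$signal$time, fit$modes, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
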
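#' Read a triaxial recording from CSV or EDF
#'
#' CSV files must carry a header with columns `x`, `y`, `z` (acceleration in
#' g) and either a `timestamp` column (ISO 8601) or a declared
#' `sample_rate_hz` plus optional `start_time`. When a timestamp column is
#' present it is checked for strict monotonicity and for uniformity: the
#' median sampling interval must agree with the declared rate within 1%, and
#' no interval may deviate from the median by more than 1%.
#'
#' EDF files are read with the package's own reader for the subset of the
#' European Data Format that [write_recording()] emits: three acceleration
#' signals (physical range +/-8 g, 16-bit), 1-s data records.
#'
#' @param path File path.
#' @param format `"csv"` or `"edf"`; default guessed from the extension.
#' @param site Wear site of the device, `"wrist"` or `"ankle"`.
#' @param sample_rate_hz Declared sampling rate; required for CSV without a
#'   timestamp column, used for the uniformity check otherwise.
#' @param start_time Absolute start time for CSV without timestamps.
#' @param ... Passed to the format-specific reader.
#' @return A [triax_recording()].
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           site = c("wrist", "ankle"),
                           sample_rate_hz = NULL, start_time = NULL, ...) {
  format <- match.arg(format)
  site <- match.arg(site)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "walkanchor_usage_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", edf = "edf",
                     abort(sprintf("cannot guess format from extension '.%s'", ext),
                           class = "walkanchor_usage_error"))
  }
  switch(format,
         csv = read_recording_csv(path, site, sample_rate_hz, start_time),
         edf = read_recording_edf(path, site))
}

read_recording_csv <- function(path, site, sample_rate_hz, start_time) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("x", "y", "z") %in% names(df))) {
    abort("CSV must have header columns x, y, z", class = "walkanchor_format_error")
  }
  if ("timestamp" %in% names(df)) {
    ts <- df$timestamp
    if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = "UTC")
    if (anyNA(ts)) abort("unparseable timestamps", class = "walkanchor_data_error")
    dt <- diff(as.numeric(ts))
    if (any(dt <= 0)) {
      abort("timestamps must be strictly increasing", class = "walkanchor_data_error")
    }
    med <- median(dt)
    if (!is.null(sample_rate_hz) && abs(med - 1 / sample_rate_hz) > 0.01 / sample_rate_hz) {
      abort("timestamp spacing disagrees with declared sample rate by more than 1%",
            class = "walkanchor_data_error")
    }
    if (length(dt) > 0 && max(abs(dt - med)) > 0.01 * med) {
      abort("timestamps are not uniform within 1% of the sampling interval",
            class = "walkanchor_data_error")
    }
    rate <- sample_rate_hz %||% (1 / med)
    # timestamps carry limited precision; snap near-integer inferred rates
    if (is.null(sample_rate_hz) && abs(rate - round(rate)) < 0.005 * rate) {
      rate <- round(rate)
    }
    start <- ts[1]
  } else {
    if (is.null(sample_rate_hz)) {
      abort("CSV without a timestamp column requires sample_rate_hz",
            class = "walkanchor_usage_error")
    }
    rate <- sample_rate_hz
    start <- start_time %||% as.POSIXct("2000-01-01 00:00:00", tz = "UTC")
  }
  triax_recording(df, sample_rate_hz = rate, site = site, start_time = start)
}

#' Write a triaxial recording to CSV or EDF
#'
#' The CSV writer emits `timestamp,x,y,z` with ISO 8601 timestamps. The EDF
#' writer stores the three axes as EDF signals with physical range +/-8 g
#' (matching both study devices) and 16-bit digital range, in 1-s data
#' records; the true sample count is recorded in the header so that a partial
#' trailing record round-trips exactly. Writing EDF requires an integer
#' sampling rate.
#'
#' @param rec A [triax_recording()].
#' @param path Output path.
#' @param format `"csv"` or `"edf"`; default guessed from the extension.
#' @param timestamps For CSV: include a timestamp column (default TRUE).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf"),
                            timestamps = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)), csv = "csv", edf = "edf",
                     abort("cannot guess format from extension",
                           class = "walkanchor_usage_error"))
  }
  if (format == "csv") {
    df <- tibble::as_tibble(rec)
    if (timestamps) {
      ts <- rec_start(rec) + (seq_len(nrow(rec)) - 1) / rec_rate(rec)
      df <- dplyr::bind_cols(tibble::tibble(
        timestamp = format(ts, "%Y-%m-%dT%H:%M:%OS4", tz = "UTC")), df)
    }
    readr::write_csv(df, path, progress = FALSE)
  } else {
    write_edf(rec, path)
  }
  invisible(path)
}

# --- Minimal EDF subset ------------------------------------------------------
# Standard EDF layout: 256-byte fixed header, 256 bytes per signal header,
# then data records of little-endian int16. We use 1-s records, three signals
# labelled AccX/AccY/AccZ, physical range +/-8 g, digital range +/-32767.
# EDF pads the last record; the true sample count is kept in the 44-byte
# reserved header field ("NSAMP=...") so our reader trims the padding.

edf_pad <- function(s, width) {
  s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  fs <- rec_rate(rec)
  if (abs(fs - round(fs)) > 1e-9) {
    abort("EDF writer requires an integer sampling rate", class = "walkanchor_usage_error")
  }
  fs <- as.integer(round(fs))
  n <- nrow(rec)
  n_rec <- ceiling(n / fs)
  phys_min <- -8; phys_max <- 8; dig_min <- -32768L; dig_max <- 32767L
  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  con <- file(path, "wb")
  on.exit(close(con))
  start <- rec_start(rec)
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(paste0("site=", rec_site(rec), " side=", attr(rec, "body_side")), 80),
    edf_pad(paste0("device=", attr(rec, "device_id")), 80),
    edf_pad(format(start, "%d.%m.%y", tz = "UTC"), 8),
    edf_pad(format(start, "%H.%M.%S", tz = "UTC"), 8),
    edf_pad(as.character(256 * (1 + 3)), 8),
    edf_pad(sprintf("NSAMP=%d", n), 44),
    edf_pad(as.character(n_rec), 8),
    edf_pad("1", 8),
    edf_pad("3", 4))
  labels <- c("AccX", "AccY", "AccZ")
  sig <- paste0(
    paste(vapply(labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("triaxial accelerometer", 80), 3), collapse = ""),
    paste(rep(edf_pad("g", 8), 3), collapse = ""),
    paste(rep(edf_pad(as.character(phys_min), 8), 3), collapse = ""),
    paste(rep(edf_pad(as.character(phys_max), 8), 3), collapse = ""),
    paste(rep(edf_pad(as.character(dig_min), 8), 3), collapse = ""),
    paste(rep(edf_pad(as.character(dig_max), 8), 3), collapse = ""),
    paste(rep(edf_pad("LP:20Hz", 80), 3), collapse = ""),
    paste(rep(edf_pad(as.character(fs), 8), 3), collapse = ""),
    paste(rep(edf_pad("", 32), 3), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  to_dig <- function(v) {
    d <- as.integer(round((pmin(pmax(v, phys_min), phys_max) - phys_min) * gain) + dig_min)
    length(d) <- n_rec * fs   # pad with NA
    d[is.na(d)] <- 0L
    d
  }
  dx <- to_dig(rec$x); dy <- to_dig(rec$y); dz <- to_dig(rec$z)
  # interleave by record: for each record, fs samples of x, then y, then z
  idx <- matrix(seq_len(n_rec * fs), nrow = fs)
  out <- integer(3 * n_rec * fs)
  for (r in seq_len(n_rec)) {
    base <- (r - 1) * 3 * fs
    out[base + seq_len(fs)] <- dx[idx[, r]]
    out[base + fs + seq_len(fs)] <- dy[idx[, r]]
    out[base + 2 * fs + seq_len(fs)] <- dz[idx[, r]]
  }
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

read_recording_edf <- function(path, site) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  fld <- function(from, w) trimws(substr(hdr, from, from + w - 1))
  patient <- fld(9, 80)
  startdate <- fld(169, 8); starttime <- fld(177, 8)
  reserved <- fld(193, 44)
  n_rec <- as.integer(fld(237, 8))
  rec_dur <- as.numeric(fld(245, 8))
  ns <- as.integer(fld(253, 4))
  if (is.na(ns) || ns < 3) {
    abort("EDF file must contain three acceleration signals",
          class = "walkanchor_format_error")
  }
  sig <- readChar(con, 256 * ns, useBytes = TRUE)
  sfld <- function(block_off, w, i) {
    from <- block_off * ns + (i - 1) * w + 1
    trimws(substr(sig, from, from + w - 1))
  }
  # field byte offsets within the signal header block, per EDF spec order
  offs <- c(label = 0, transducer = 16 * ns, dim = 96 * ns)
  phys_min <- as.numeric(vapply(1:ns, function(i) sfld(104, 8, i), ""))
  phys_max <- as.numeric(vapply(1:ns, function(i) sfld(112, 8, i), ""))
  dig_min <- as.numeric(vapply(1:ns, function(i) sfld(120, 8, i), ""))
  dig_max <- as.numeric(vapply(1:ns, function(i) sfld(128, 8, i), ""))
  spr <- as.integer(vapply(1:ns, function(i) sfld(216, 8, i), ""))
  dat <- readBin(con, integer(), n = n_rec * sum(spr), size = 2, endian = "little")
  sig_vals <- vector("list", ns)
  cum <- c(0, cumsum(spr))
  rec_len <- sum(spr)
  for (i in seq_len(ns)) {
    take <- unlist(lapply(seq_len(n_rec) - 1, function(r) r * rec_len + cum[i] + seq_len(spr[i])))
    d <- dat[take]
    sig_vals[[i]] <- phys_min[i] + (d - dig_min[i]) *
      (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
  }
  n_true <- NA_integer_
  m <- regmatches(reserved, regexpr("NSAMP=([0-9]+)", reserved))
  if (length(m) == 1) n_true <- as.integer(sub("NSAMP=", "", m))
  n_keep <- if (is.na(n_true)) n_rec * spr[1] else n_true
  df <- tibble::tibble(x = sig_vals[[1]][seq_len(n_keep)],
                       y = sig_vals[[2]][seq_len(n_keep)],
                       z = sig_vals[[3]][seq_len(n_keep)])
  side <- "unspecified"
  if (grepl("side=", patient)) side <- sub(".*side=([a-z]+).*", "\\1", patient)
  start <- as.POSIXct(paste(startdate, starttime), format = "%d.%m.%y %H.%M.%S", tz = "UTC")
  if (is.na(start)) start <- as.POSIXct("2000-01-01", tz = "UTC")
  triax_recording(df, sample_rate_hz = spr[1] / rec_dur, site = site,
                  start_time = start, body_side = side)
}

#' Synchronize wrist and ankle recordings onto a common time base
#'
#' Crops both recordings to their overlapping absolute time range and places
#' them on a single time base: seconds since the overlap start, on the wrist
#' clock. Alignment is metadata-level — no resampling is performed. An
#' optional linear drift correction maps the ankle clock onto the wrist clock
#' through one or two `(event_time_wrist, event_time_ankle)` anchor pairs
#' (e.g. synchronization events performed during the collection): with two
#' anchors the ankle clock is rescaled linearly, with one it is offset only.
#'
#' @param wrist,ankle [triax_recording()] objects with overlapping time
#'   ranges.
#' @param anchors Optional data frame with columns `wrist_s`, `ankle_s`
#'   giving matched event times (seconds since each device's own start); at
#'   most two rows are used.
#' @return A list with elements `wrist` and `ankle`, both cropped, with
#'   `rec_times()` measured from the common origin (`t = 0` at overlap
#'   start).
#' @export
synchronize <- function(wrist, ankle, anchors = NULL) {
  stopifnot(inherits(wrist, "triax_recording"), inherits(ankle, "triax_recording"))
  w_start <- as.numeric(rec_start(wrist))
  a_start <- as.numeric(rec_start(ankle))
  a_rate <- rec_rate(ankle)
  # An event at wrist-clock absolute time T sits at ankle elapsed time t_a with
  # T = a_start_corr + drift_b * t_a. Anchors (wrist_s, ankle_s) are matched
  # device-elapsed times of shared events; they determine the affine map.
  drift_b <- 1
  a_start_corr <- a_start
  if (!is.null(anchors) && nrow(anchors) >= 1) {
    anchors <- anchors[seq_len(min(2, nrow(anchors))), , drop = FALSE]
    tw <- anchors$wrist_s
    ta <- anchors$ankle_s
    if (nrow(anchors) == 2) drift_b <- (tw[2] - tw[1]) / (ta[2] - ta[1])
    a_start_corr <- w_start + tw[1] - drift_b * ta[1]
  }
  a_end <- a_start_corr + drift_b * rec_duration(ankle)
  w_end <- w_start + rec_duration(wrist)
  ov_start <- max(w_start, a_start_corr)
  ov_end <- min(w_end, a_end)
  if (ov_end <= ov_start) {
    abort("recordings do not overlap in time", class = "walkanchor_data_error")
  }
  w_from <- floor((ov_start - w_start) * rec_rate(wrist)) + 1
  w_to <- floor((ov_end - w_start) * rec_rate(wrist) - 1e-9) + 1
  w_to <- min(w_to, nrow(wrist))
  wrist2 <- rec_slice(wrist, w_from, w_to)
  attr(wrist2, "time_offset_s") <- (as.numeric(rec_start(wrist2)) - ov_start)
  # ankle: elapsed own-clock time of overlap start / end
  a_from_t <- (ov_start - a_start_corr) / drift_b
  a_to_t <- (ov_end - a_start_corr) / drift_b
  a_from <- floor(a_from_t * a_rate) + 1
  a_to <- min(floor(a_to_t * a_rate - 1e-9) + 1, nrow(ankle))
  ankle2 <- rec_slice(ankle, a_from, a_to)
  # effective rate on the wrist clock; offset of first kept sample
  attr(ankle2, "sample_rate_hz") <- a_rate / drift_b
  attr(ankle2, "time_offset_s") <-
    (a_start_corr + drift_b * (a_from - 1) / a_rate) - ov_start
  list(wrist = wrist2, ankle = ankle2,
       overlap_start = as.POSIXct(ov_start, origin = "1970-01-01", tz = "UTC"),
       overlap_s = ov_end - ov_start)
}
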
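#' Construct a triaxial accelerometer recording
#'
#' A recording is a tibble with columns `x`, `y`, `z` (acceleration in units
#' of g) and metadata attributes: wear site, body side, sample rate, absolute
#' start time and device id. Sample `i` occurs at
#' `time_offset_s + (i - 1) / sample_rate_hz` seconds on the common time base
#' (seconds since the start of the aligned pair; zero for a fresh recording).
#'
#' @param data A data frame with numeric columns `x`, `y`, `z` in units of g.
#' @param sample_rate_hz Sampling rate in Hz; must lie in \[10, 1000\]. The
#'   study devices sample at 50 Hz (Axivity AX6) and 75 Hz (GENEActiv).
#' @param site `"wrist"` or `"ankle"`.
#' @param start_time Absolute start time (`POSIXct`).
#' @param body_side `"dominant"`, `"nondominant"` or `"unspecified"`.
#' @param device_id Opaque device identifier string.
#' @param time_offset_s Offset of the first sample on the common time base.
#'
#' @return A `triax_recording` tibble.
#' @export
#' @examples
#' rec <- triax_recording(data.frame(x = 0, y = 0, z = rep(1, 100)),
#'                        sample_rate_hz = 50, site = "wrist")
#' rec_duration(rec)
triax_recording <- function(data, sample_rate_hz, site = c("wrist", "ankle"),
                            start_time = as.POSIXct("2000-01-01 00:00:00", tz = "UTC"),
                            body_side = "unspecified", device_id = "synthetic",
                            time_offset_s = 0) {
  site <- match.arg(site)
  stopifnot(is.data.frame(data))
  if (!all(c("x", "y", "z") %in% names(data))) {
    abort("recording data must have columns x, y, z", class = "walkanchor_format_error")
  }
  if (nrow(data) < 1) abort("recording must contain at least one sample")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz < 10 || sample_rate_hz > 1000) {
    abort("sample_rate_hz must lie in [10, 1000]", class = "walkanchor_data_error")
  }
  out <- tibble::as_tibble(data[, c("x", "y", "z")])
  structure(out,
            class = c("triax_recording", class(out)),
            sample_rate_hz = as.numeric(sample_rate_hz),
            site = site,
            body_side = body_side,
            start_time = start_time,
            device_id = device_id,
            time_offset_s = as.numeric(time_offset_s))
}

#' Recording accessors
#'
#' @param rec A [triax_recording()].
#' @return `rec_rate()` the sampling rate (Hz); `rec_site()` the wear site;
#'   `rec_times()` per-sample times (s) on the common time base;
#'   `rec_duration()` the recording duration in seconds; `rec_start()` the
#'   absolute start time.
#' @export
rec_rate <- function(rec) attr(rec, "sample_rate_hz")

#' @rdname rec_rate
#' @export
rec_site <- function(rec) attr(rec, "site")

#' @rdname rec_rate
#' @export
rec_start <- function(rec) attr(rec, "start_time")

#' @rdname rec_rate
#' @export
rec_times <- function(rec) {
  attr(rec, "time_offset_s") + (seq_len(nrow(rec)) - 1) / rec_rate(rec)
}

#' @rdname rec_rate
#' @export
rec_duration <- function(rec) nrow(rec) / rec_rate(rec)

#' @export
print.triax_recording <- function(x, ...) {
  cat(sprintf("<triax_recording> site=%s side=%s %.6g Hz, %d samples (%.1f s), start %s\n",
              rec_site(x), attr(x, "body_side"), rec_rate(x), nrow(x),
              rec_duration(x), format(rec_start(x), usetz = TRUE)))
  NextMethod()
}

# Subset a recording to a sample index range, keeping metadata and shifting
# the time offset so rec_times() stays on the same base.
rec_slice <- function(rec, from, to) {
  out <- triax_recording(rec[from:to, , drop = FALSE],
                         sample_rate_hz = rec_rate(rec),
                         site = rec_site(rec),
                         start_time = rec_start(rec) + (from - 1) / rec_rate(rec),
                         body_side = attr(rec, "body_side"),
                         device_id = attr(rec, "device_id"),
                         time_offset_s = attr(rec, "time_offset_s") + (from - 1) / rec_rate(rec))
  out
}
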
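#' Detect steps from an ankle recording
#'
#' Step timing is recovered from the step-frequency content of the ankle
#' signal: the anteroposterior-dominant axis is auto-selected as the
#' non-gravity axis with the highest 0.5-3 Hz spectral power, band-pass
#' filtered to 0.5-3 Hz (4th-order zero-phase Butterworth), and local maxima
#' of the filtered signal become steps when they clear an adaptive amplitude
#' threshold and respect a 0.25-s refractory period.
#'
#' The adaptive threshold is computed per 10-s block as
#' `max(min_amplitude_g, k * median(|filtered signal|))`. After band-pass
#' filtering, walking is quasi-sinusoidal, and the median absolute amplitude
#' of a sinusoid is about 0.71 of its peak, so `k` must stay below ~1.4 for
#' peaks to be detectable at all; the default `k = 0.7` puts the threshold at
#' about half the local signal amplitude, and the absolute floor rejects
#' fidgeting and sensor noise during non-walking periods.
#'
#' @param ankle An ankle [triax_recording()].
#' @param calibration Optional [autocalibrate()] parameters.
#' @param band_hz Band-pass edges (Hz); default `c(0.5, 3)`, bracketing
#'   plausible step frequencies (30-180 steps/min).
#' @param k Multiplier on the rolling median absolute amplitude.
#' @param min_amplitude_g Absolute threshold floor (g); default 0.02.
#' @param refractory_s Minimum separation between steps (s); default 0.25.
#' @param block_s Length of the rolling-threshold blocks (s); default 10.
#' @return A `step_events` tibble: `step_time_s` (strictly increasing, on
#'   the common time base), `amplitude_g`, with attribute `axis` naming the
#'   detection axis.
#' @export
detect_steps <- function(ankle, calibration = NULL, band_hz = c(0.5, 3),
                         k = 0.7, min_amplitude_g = 0.02, refractory_s = 0.25,
                         block_s = 10) {
  fs <- rec_rate(ankle)
  ankle <- apply_calibration(ankle, calibration)
  xyz <- cbind(ankle$x, ankle$y, ankle$z)
  xyz <- sweep(xyz, 2, colMeans(xyz))  # remove static gravity per axis
  bf <- signal::butter(4, band_hz / (fs / 2), type = "pass")
  filt <- apply(xyz, 2, function(v) filtfilt_padded(bf, v, pad = 5 * fs))
  band_power <- colMeans(filt^2)
  axis <- which.max(band_power)
  f <- filt[, axis]
  n <- length(f)
  # candidate peaks: local maxima
  d <- diff(f)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  # adaptive per-block threshold
  blk <- as.integer(round(block_s * fs))
  blk_id <- pmin((seq_len(n) - 1) %/% blk + 1, max(1, n %/% blk))
  med_abs <- as.numeric(tapply(abs(f), factor(blk_id, levels = seq_len(max(blk_id))),
                               median))
  thr <- pmax(min_amplitude_g, k * med_abs)
  cand <- cand[f[cand] > thr[blk_id[cand]]]
  if (length(cand) == 0) {
    return(new_step_events(tibble::tibble(step_time_s = numeric(),
                                          amplitude_g = numeric()),
                           axis = c("x", "y", "z")[axis]))
  }
  # enforce refractory, keeping the larger peak of any conflicting pair
  ord <- cand[order(f[cand], decreasing = TRUE)]
  ref <- as.integer(round(refractory_s * fs))
  keep <- logical(n)
  blocked <- logical(n)
  for (i in ord) {
    if (!blocked[i]) {
      keep[i] <- TRUE
      lo <- max(1, i - ref); hi <- min(n, i + ref)
      blocked[lo:hi] <- TRUE
    }
  }
  pk <- which(keep)
  # sub-sample timing: parabolic interpolation through the peak and its
  # neighbours, else cadence medians quantize to the sample grid
  delta <- rep(0, length(pk))
  inner <- pk > 1 & pk < n
  i <- pk[inner]
  denom <- f[i - 1] - 2 * f[i] + f[i + 1]
  ok <- denom < 0
  delta[inner][ok] <- (0.5 * (f[i - 1] - f[i + 1]) / denom)[ok]
  delta <- pmin(pmax(delta, -0.5), 0.5)
  t0 <- attr(ankle, "time_offset_s")
  new_step_events(tibble::tibble(step_time_s = t0 + (pk - 1 + delta) / fs,
                                 amplitude_g = f[pk]),
                  axis = c("x", "y", "z")[axis])
}

new_step_events <- function(df, axis) {
  structure(df, class = c("step_events", class(tibble::tibble())), axis = axis)
}

#' Aggregate steps into walking bouts
#'
#' Consecutive steps separated by at most `max_rest_s` seconds (inclusive)
#' belong to the same bout. Bout boundaries are the first and last step
#' times; bouts with fewer than two steps are discarded.
#'
#' @param steps A `step_events` tibble from [detect_steps()], or any data
#'   frame with a `step_time_s` column.
#' @param max_rest_s Maximum within-bout rest (s); default 5, inclusive.
#' @return A `walking_bouts` tibble: `bout_id`, `start_s`, `end_s`,
#'   `n_steps`, `median_cadence_spm`, plus `is_long`/`is_all_walk` set to
#'   `NA` until [flag_walks()] is applied.
#' @export
build_bouts <- function(steps, max_rest_s = 5) {
  t <- sort(steps$step_time_s)
  empty <- tibble::tibble(bout_id = integer(), start_s = numeric(),
                          end_s = numeric(), n_steps = integer(),
                          median_cadence_spm = numeric(),
                          is_long = logical(), is_all_walk = logical())
  if (length(t) < 2) return(empty)
  newb <- c(TRUE, diff(t) > max_rest_s)
  grp <- cumsum(newb)
  out <- tibble::tibble(step_time_s = t, grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(start_s = min(.data$step_time_s),
                     end_s = max(.data$step_time_s),
                     n_steps = dplyr::n(),
                     median_cadence_spm = if (dplyr::n() >= 2)
                       median(60 / diff(.data$step_time_s)) else NA_real_,
                     .groups = "drop") |>
    dplyr::filter(.data$n_steps >= 2) |>
    dplyr::mutate(bout_id = dplyr::row_number(),
                  is_long = NA, is_all_walk = NA) |>
    dplyr::select("bout_id", "start_s", "end_s", "n_steps",
                  "median_cadence_spm", "is_long", "is_all_walk")
  out
}

#' Median cadence of a bout
#'
#' Instantaneous cadence for each consecutive step pair is 60 divided by the
#' inter-step interval (seconds); the bout cadence is the median over all
#' pairs.
#'
#' @param step_times Step times (s) belonging to one bout; at least two.
#' @return Median cadence in steps per minute.
#' @export
#' @examples
#' median_cadence(c(0, 0.6, 1.2, 1.8))  # 100 spm
median_cadence <- function(step_times) {
  if (length(step_times) < 2) {
    abort("median cadence requires at least 2 steps", class = "walkanchor_usage_error")
  }
  median(60 / diff(sort(step_times)))
}

#' Flag LONG walks and ALL walks
#'
#' A LONG walk lasts at least `long_walk_min_s` seconds (last step minus
#' first step) with median cadence strictly above
#' `long_walk_min_cadence_spm`; an ALL walk has at least
#' `all_walk_min_steps` steps.
#'
#' @param bouts A `walking_bouts` tibble from [build_bouts()].
#' @param config A [walk_config()].
#' @return The bouts with `is_long` and `is_all_walk` filled in.
#' @export
flag_walks <- function(bouts, config = walk_config()) {
  dplyr::mutate(bouts,
                is_long = (.data$end_s - .data$start_s) >= config$long_walk_min_s &
                  .data$median_cadence_spm > config$long_walk_min_cadence_spm,
                is_all_walk = .data$n_steps >= config$all_walk_min_steps)
}

#' Daily step totals over ALL walks
#'
#' Sums `n_steps` over bouts flagged `is_all_walk`, grouped by the calendar
#' day (UTC) on which each bout starts.
#'
#' @param bouts Flagged bouts from [flag_walks()].
#' @param start_time Absolute time of `t = 0` on the common time base.
#' @return A tibble `date`, `steps`.
#' @export
daily_steps <- function(bouts, start_time = as.POSIXct("2000-01-01", tz = "UTC")) {
  bouts |>
    dplyr::filter(.data$is_all_walk) |>
    dplyr::mutate(date = as.Date(start_time + .data$start_s, tz = "UTC")) |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(steps = sum(.data$n_steps), .groups = "drop")
}
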
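#' Classify AVM epochs into intensity classes
#'
#' Applies the cut points to AVM values: below the light threshold is
#' sedentary; at or above the light threshold but below the moderate
#' threshold is light; at or above the moderate threshold is MVPA (moderate
#' and vigorous are merged). Boundaries are lower-inclusive for the upper
#' class.
#'
#' @param avm_mg Numeric vector of AVM values (mg, >= 0).
#' @param cuts An [intensity_cut_points()] object.
#' @return A factor with levels `sedentary < light < MVPA`.
#' @export
classify_epoch <- function(avm_mg, cuts = intensity_cut_points()) {
  validate_cut_points(cuts)
  if (any(avm_mg < 0, na.rm = TRUE)) {
    abort("AVM values must be non-negative", class = "walkanchor_usage_error")
  }
  lab <- ifelse(avm_mg >= cuts$moderate_threshold_mg, "MVPA",
                ifelse(avm_mg >= cuts$light_threshold_mg, "light", "sedentary"))
  factor(lab, levels = c("sedentary", "light", "MVPA"), ordered = TRUE)
}

#' Label 15-s epochs inside LONG walks
#'
#' Intersects the global epoch grid with LONG-walk intervals. An epoch
#' belongs to a walk iff it starts at or after the walk start *and* ends at
#' or before the walk end: epochs that would end after the end of their walk
#' are excluded from the analysis, and the first candidate epoch of a walk
#' is the first grid epoch starting at or after the walk start (the grid is
#' anchored at the recording start, not per walk).
#'
#' @param epochs15 An `avm_epochs` series (normally 15-s epochs from
#'   [reepoch()]).
#' @param bouts Flagged bouts from [flag_walks()]; only rows with
#'   `is_long == TRUE` are used.
#' @param cuts An [intensity_cut_points()] object.
#' @return A `labeled_epochs` tibble restricted to LONG walks:
#'   `epoch_start_s`, `avm_mg`, `label`, `in_long_walk`, `bout_id`.
#' @export
label_walk_epochs <- function(epochs15, bouts, cuts = intensity_cut_points()) {
  len <- attr(epochs15, "epoch_length_s")
  long <- dplyr::filter(bouts, .data$is_long)
  out <- purrr::map_dfr(seq_len(nrow(long)), function(i) {
    inside <- epochs15$epoch_start_s >= long$start_s[i] &
      epochs15$epoch_start_s + len <= long$end_s[i]
    if (!any(inside)) return(NULL)
    tibble::tibble(epoch_start_s = epochs15$epoch_start_s[inside],
                   avm_mg = epochs15$avm_mg[inside],
                   bout_id = long$bout_id[i])
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(epoch_start_s = numeric(), avm_mg = numeric(),
                          bout_id = integer())
  }
  out$label <- classify_epoch(out$avm_mg, cuts)
  out$in_long_walk <- rep(TRUE, nrow(out))
  structure(out[, c("epoch_start_s", "avm_mg", "label", "in_long_walk", "bout_id")],
            class = c("labeled_epochs", class(tibble::tibble())),
            epoch_length_s = len)
}

#' Detect nightly sleep windows
#'
#' When explicit annotations are supplied they are passed through unchanged.
#' Otherwise a simple heuristic stands in for a full sleep-detection
#' algorithm (deliberately out of this package's scope): within each
#' night-time search window (20:00 to 12:00 the next day), the longest run
#' of at least `min_sleep_h` hours in which the 5-minute rolling median of
#' 1-s wrist AVM stays below `quiet_mg` is reported as sleep. Recordings
#' with no such run contribute no sleep and the whole day is treated as
#' waking.
#'
#' @param epochs1 A 1-s `avm_epochs` series from the wrist.
#' @param annotations Optional tibble `start_s`, `end_s` of known sleep.
#' @param quiet_mg AVM threshold (mg) under which the wrist is "quiet";
#'   default 5.
#' @param min_sleep_h Minimum sleep duration (h); default 5.
#' @return A tibble of sleep intervals `start_s`, `end_s`.
#' @export
detect_sleep_windows <- function(epochs1, annotations = NULL, quiet_mg = 5,
                                 min_sleep_h = 5) {
  if (!is.null(annotations)) return(tibble::as_tibble(annotations))
  len <- attr(epochs1, "epoch_length_s")
  start_time <- attr(epochs1, "start_time")
  roll_n <- as.integer(round(300 / len))
  if (roll_n %% 2 == 0) roll_n <- roll_n + 1
  quiet <- stats::runmed(epochs1$avm_mg, roll_n, endrule = "median") < quiet_mg
  # clock hour of each epoch
  secs_of_day <- (as.numeric(start_time) + epochs1$epoch_start_s) %% 86400
  # search windows run 20:00 -> 12:00; index nights by noon-to-noon blocks
  in_window <- secs_of_day >= 20 * 3600 | secs_of_day < 12 * 3600
  night_id <- floor((as.numeric(start_time) + epochs1$epoch_start_s - 12 * 3600) / 86400)
  eligible <- quiet & in_window
  res <- tibble::tibble(start_s = numeric(), end_s = numeric())
  for (nid in unique(night_id)) {
    sel <- which(night_id == nid)
    r <- rle(eligible[sel])
    if (!any(r$values)) next
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    runs <- which(r$values & r$lengths * len >= min_sleep_h * 3600)
    if (length(runs) == 0) next
    best <- runs[which.max(r$lengths[runs])]
    i0 <- sel[starts[best]]; i1 <- sel[ends[best]]
    res <- dplyr::bind_rows(res, tibble::tibble(
      start_s = epochs1$epoch_start_s[i0],
      end_s = epochs1$epoch_start_s[i1] + len))
  }
  res
}

#' Daily activity summaries over valid days
#'
#' For each full calendar day covered by the recording, waking wear time is
#' 24 h minus detected sleep and nonwear (resolved at the 15-s epoch grid).
#' Minutes per intensity class count 15-s waking-wear epochs times 0.25. A
#' day is valid when it is a full calendar day with at least
#' `valid_day_min_wear_h` hours of waking wear.
#'
#' @param epochs15 A 15-s `avm_epochs` series (wrist).
#' @param nonwear Nonwear intervals ([detect_nonwear()]).
#' @param sleep Sleep intervals ([detect_sleep_windows()]).
#' @param bouts Flagged bouts ([flag_walks()]), for daily step counts.
#' @param config A [walk_config()].
#' @return A `daily_summary` tibble: `date`, `wear_h_waking`, `valid`,
#'   `sedentary_min`, `light_min`, `mvpa_min`, `pct_sedentary`, `pct_light`,
#'   `pct_mvpa`, `steps`.
#' @export
summarize_days <- function(epochs15, nonwear = NULL, sleep = NULL,
                           bouts = NULL, config = walk_config()) {
  len <- attr(epochs15, "epoch_length_s")
  start_time <- attr(epochs15, "start_time")
  abs_start <- as.numeric(start_time) + epochs15$epoch_start_s
  date <- as.Date(as.POSIXct(abs_start, origin = "1970-01-01", tz = "UTC"), tz = "UTC")
  covered <- function(iv, t) {
    if (is.null(iv) || nrow(iv) == 0) return(rep(FALSE, length(t)))
    out <- rep(FALSE, length(t))
    for (i in seq_len(nrow(iv))) {
      out <- out | (t >= iv$start_s[i] & t + len <= iv$end_s[i] + 1e-9)
    }
    out
  }
  asleep <- covered(sleep, epochs15$epoch_start_s)
  nw <- covered(nonwear, epochs15$epoch_start_s)
  label <- classify_epoch(epochs15$avm_mg, config$cut_points)
  waking_wear <- !asleep & !nw
  df <- tibble::tibble(date = date, waking_wear = waking_wear, label = label)
  day_tab <- df |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(
      n_epochs = dplyr::n(),
      wear_h_waking = sum(.data$waking_wear) * len / 3600,
      sedentary_min = sum(.data$waking_wear & .data$label == "sedentary") * len / 60,
      light_min = sum(.data$waking_wear & .data$label == "light") * len / 60,
      mvpa_min = sum(.data$waking_wear & .data$label == "MVPA") * len / 60,
      .groups = "drop")
  epochs_per_day <- 86400 / len
  day_tab <- day_tab |>
    dplyr::mutate(
      full_day = .data$n_epochs == epochs_per_day,
      valid = .data$full_day & .data$wear_h_waking >= config$valid_day_min_wear_h,
      pct_sedentary = ifelse(.data$wear_h_waking > 0,
                             .data$sedentary_min / (.data$wear_h_waking * 60) * 100, NA),
      pct_light = ifelse(.data$wear_h_waking > 0,
                         .data$light_min / (.data$wear_h_waking * 60) * 100, NA),
      pct_mvpa = ifelse(.data$wear_h_waking > 0,
                        .data$mvpa_min / (.data$wear_h_waking * 60) * 100, NA))
  if (!is.null(bouts)) {
    st <- daily_steps(bouts, start_time)
    day_tab <- dplyr::left_join(day_tab, st, by = "date") |>
      dplyr::mutate(steps = dplyr::coalesce(.data$steps, 0L))
  } else {
    day_tab$steps <- NA_integer_
  }
  dplyr::select(day_tab, "date", "wear_h_waking", "valid", "sedentary_min",
                "light_min", "mvpa_min", "pct_sedentary", "pct_light",
                "pct_mvpa", "steps")
}
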
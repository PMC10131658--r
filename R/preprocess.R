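#' Find stationary windows in a recording
#'
#' Splits the recording into non-overlapping windows and keeps those in which
#' the per-axis standard deviation is below `sd_threshold_g` on all three
#' axes. Stationary windows are the raw material for gravity-based
#' autocalibration: while the device rests, the measured vector should have
#' magnitude exactly 1 g.
#'
#' @param rec A [triax_recording()].
#' @param window_s Window length in seconds (>= 1); default 10 s.
#' @param sd_threshold_g Per-axis standard-deviation threshold in g;
#'   default 0.013 g, the conventional stillness criterion for
#'   autocalibration.
#' @return A tibble with one row per stationary window: `start_s`, `end_s`,
#'   and the window mean of each axis (`mean_x`, `mean_y`, `mean_z`).
#' @export
find_stationary_windows <- function(rec, window_s = 10, sd_threshold_g = 0.013) {
  stopifnot(window_s >= 1)
  fs <- rec_rate(rec)
  w <- as.integer(round(window_s * fs))
  n_win <- nrow(rec) %/% w
  if (n_win == 0) return(tibble::tibble(start_s = numeric(), end_s = numeric(),
                                        mean_x = numeric(), mean_y = numeric(),
                                        mean_z = numeric()))
  grp <- rep(seq_len(n_win), each = w)
  idx <- seq_len(n_win * w)
  stats_axis <- function(v) {
    m <- matrix(v[idx], nrow = w)
    list(mean = colMeans(m), sd = matrixStats_colSds(m))
  }
  sx <- stats_axis(rec$x); sy <- stats_axis(rec$y); sz <- stats_axis(rec$z)
  still <- sx$sd < sd_threshold_g & sy$sd < sd_threshold_g & sz$sd < sd_threshold_g
  t0 <- attr(rec, "time_offset_s")
  tibble::tibble(start_s = t0 + (which(still) - 1) * window_s,
                 end_s = t0 + which(still) * window_s,
                 mean_x = sx$mean[still], mean_y = sy$mean[still],
                 mean_z = sz$mean[still])
}

# zero-phase filtering with odd-reflection end padding; bare filtfilt leaves
# edge transients even on constant input
filtfilt_padded <- function(bf, x, pad) {
  n <- length(x)
  p <- min(pad, n - 1)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  signal::filtfilt(bf, xp)[(p + 1):(p + n)]
}

# column sds without an extra dependency
matrixStats_colSds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt(pmax(0, (colMeans(m * m) - mu * mu) * n / (n - 1)))
}

#' Gravity-based autocalibration
#'
#' Estimates per-axis offset and gain so that the vector magnitudes of
#' stationary windows are as close as possible to 1 g (the known constant
#' acceleration available in free-living data). The fit is the standard
#' iterative sphere fit: each window mean is projected onto the unit sphere
#' and per-axis weighted linear regressions of the projection on the
#' measurement are alternated until convergence.
#'
#' Calibration is attempted only when at least `min_windows` stationary
#' windows are available and their orientations are diverse (not all mean
#' unit vectors within 30 degrees of each other); otherwise, and whenever the
#' fitted parameters leave the plausible range (gains in \[0.8, 1.2\],
#' offsets in \[-0.25, 0.25\] g), identity parameters are returned with
#' `calibrated = FALSE`. A degraded result is never an error.
#'
#' @param rec A [triax_recording()] (used only when `windows` is missing).
#' @param windows Stationary windows from [find_stationary_windows()].
#' @param min_windows Minimum number of stationary windows; default 5.
#' @param max_iter,tol Iteration controls for the sphere fit.
#' @return A `calibration_params` list: `offset` (length-3, g), `gain`
#'   (length-3), `calibrated`, `n_stationary_windows`.
#' @export
autocalibrate <- function(rec, windows = NULL, min_windows = 5,
                          max_iter = 100, tol = 1e-10) {
  if (is.null(windows)) windows <- find_stationary_windows(rec)
  identity_cal <- function(n) structure(
    list(offset = c(0, 0, 0), gain = c(1, 1, 1), calibrated = FALSE,
         n_stationary_windows = n), class = "calibration_params")
  n <- nrow(windows)
  if (n < min_windows) return(identity_cal(n))
  M <- as.matrix(windows[, c("mean_x", "mean_y", "mean_z")])
  norms <- sqrt(rowSums(M^2))
  if (any(norms == 0)) return(identity_cal(n))
  U <- M / norms
  # orientation diversity: reject if every pair of unit vectors is within 30 deg
  gram <- U %*% t(U)
  if (min(gram) > cos(30 * pi / 180)) return(identity_cal(n))
  offset <- c(0, 0, 0); gain <- c(1, 1, 1)
  for (iter in seq_len(max_iter)) {
    C <- sweep(sweep(M, 2, gain, `*`), 2, offset, `+`)
    r <- sqrt(rowSums(C^2))
    target <- C / r
    delta <- 0
    for (j in 1:3) {
      fit <- stats::lm.fit(cbind(1, M[, j]), target[, j])
      off_j <- fit$coefficients[1]; gain_j <- fit$coefficients[2]
      delta <- max(delta, abs(off_j - offset[j]), abs(gain_j - gain[j]))
      offset[j] <- off_j; gain[j] <- gain_j
    }
    if (delta < tol) break
  }
  bad <- any(gain < 0.8 | gain > 1.2) || any(abs(offset) > 0.25)
  if (bad) return(identity_cal(n))
  structure(list(offset = unname(offset), gain = unname(gain),
                 calibrated = TRUE, n_stationary_windows = n),
            class = "calibration_params")
}

#' @export
print.calibration_params <- function(x, ...) {
  cat(sprintf("<calibration_params> calibrated=%s (%d stationary windows)\n",
              x$calibrated, x$n_stationary_windows))
  cat(sprintf("  offset (g): %s\n  gain     : %s\n",
              paste(signif(x$offset, 4), collapse = ", "),
              paste(signif(x$gain, 4), collapse = ", ")))
  invisible(x)
}

# apply calibration to the raw axes; calibrated value = raw * gain + offset
apply_calibration <- function(rec, calibration = NULL) {
  if (is.null(calibration) || !calibration$calibrated) return(rec)
  rec$x <- rec$x * calibration$gain[1] + calibration$offset[1]
  rec$y <- rec$y * calibration$gain[2] + calibration$offset[2]
  rec$z <- rec$z * calibration$gain[3] + calibration$offset[3]
  rec
}

#' Detect nonwear intervals
#'
#' Flags 60-s windows in which at least 2 of the 3 axes are both nearly
#' constant (standard deviation below `sd_threshold_g`) and nearly
#' range-free (peak-to-peak below `range_threshold_g`). Maximal runs of
#' flagged windows lasting at least `min_duration_min` become candidate
#' nonwear intervals; candidates separated by gaps shorter than 5 minutes
#' are merged.
#'
#' @param rec A [triax_recording()].
#' @param window_s Window length (s); default 60.
#' @param sd_threshold_g Per-axis sd threshold (g); default 0.013.
#' @param range_threshold_g Per-axis range threshold (g); default 0.05.
#' @param min_duration_min Minimum candidate duration (min); default 60.
#' @param merge_gap_min Merge candidates closer than this (min); default 5.
#' @return A tibble of half-open intervals `start_s`, `end_s` on the
#'   recording time base; zero rows when no nonwear is found.
#' @export
detect_nonwear <- function(rec, window_s = 60, sd_threshold_g = 0.013,
                           range_threshold_g = 0.05, min_duration_min = 60,
                           merge_gap_min = 5) {
  fs <- rec_rate(rec)
  w <- as.integer(round(window_s * fs))
  n_win <- nrow(rec) %/% w
  empty <- tibble::tibble(start_s = numeric(), end_s = numeric())
  if (n_win == 0) return(empty)
  idx <- seq_len(n_win * w)
  flag_axis <- function(v) {
    m <- matrix(v[idx], nrow = w)
    sds <- matrixStats_colSds(m)
    rng <- matrixStats_colMaxs(m) - matrixStats_colMins(m)
    sds < sd_threshold_g & rng < range_threshold_g
  }
  n_quiet <- flag_axis(rec$x) + flag_axis(rec$y) + flag_axis(rec$z)
  flagged <- n_quiet >= 2
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths * window_s >= min_duration_min * 60
  if (!any(keep)) return(empty)
  t0 <- attr(rec, "time_offset_s")
  iv <- tibble::tibble(start_s = t0 + (starts[keep] - 1) * window_s,
                       end_s = t0 + ends[keep] * window_s)
  merge_intervals(iv, gap_s = merge_gap_min * 60)
}

matrixStats_colMaxs <- function(m) apply(m, 2, max)
matrixStats_colMins <- function(m) apply(m, 2, min)

# merge sorted intervals whose gap is strictly below gap_s
merge_intervals <- function(iv, gap_s = 0) {
  if (nrow(iv) <= 1) return(iv)
  iv <- dplyr::arrange(iv, .data$start_s)
  out_s <- iv$start_s[1]; out_e <- iv$end_s[1]
  res_s <- numeric(); res_e <- numeric()
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start_s[i] - out_e < gap_s) {
      out_e <- max(out_e, iv$end_s[i])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- iv$start_s[i]; out_e <- iv$end_s[i]
    }
  }
  tibble::tibble(start_s = c(res_s, out_s), end_s = c(res_e, out_e))
}

#' Compute average vector magnitude (AVM) epochs
#'
#' Applies the calibration, low-pass filters each axis (4th-order zero-phase
#' Butterworth, 20 Hz cutoff; skipped when the Nyquist frequency does not
#' exceed the cutoff), computes the per-sample Euclidean norm minus 1 g
#' floored at zero (the ENMO realization of gravity subtraction), and
#' averages within consecutive epochs. Values are reported in milli-g. The
#' trailing partial epoch is dropped, never padded.
#'
#' @param rec A [triax_recording()].
#' @param calibration Optional `calibration_params` from [autocalibrate()].
#' @param epoch_length_s Epoch length (s); default 1.
#' @param lowpass_hz Low-pass cutoff (Hz); default 20. `NA` disables
#'   filtering.
#' @param nonwear Optional nonwear intervals (from [detect_nonwear()]) used
#'   to fill the per-epoch `wear_fraction`.
#' @return An `avm_epochs` tibble: `epoch_start_s`, `avm_mg`,
#'   `wear_fraction`, with attribute `epoch_length_s`.
#' @export
compute_avm <- function(rec, calibration = NULL, epoch_length_s = 1,
                        lowpass_hz = 20, nonwear = NULL) {
  fs <- rec_rate(rec)
  spe <- epoch_length_s * fs
  if (abs(spe - round(spe)) > 1e-6) {
    abort("epoch_length_s times the sampling rate must be an integer",
          class = "walkanchor_usage_error")
  }
  spe <- as.integer(round(spe))
  n_ep <- nrow(rec) %/% spe
  if (n_ep < 1) {
    abort("epoch is longer than the recording", class = "walkanchor_usage_error")
  }
  rec <- apply_calibration(rec, calibration)
  xyz <- cbind(rec$x, rec$y, rec$z)
  if (!is.na(lowpass_hz) && fs / 2 > lowpass_hz) {
    bf <- signal::butter(4, lowpass_hz / (fs / 2), type = "low")
    for (j in 1:3) xyz[, j] <- filtfilt_padded(bf, xyz[, j], pad = 3 * fs)
  }
  enmo <- pmax(0, sqrt(rowSums(xyz^2)) - 1)
  idx <- seq_len(n_ep * spe)
  avm <- colMeans(matrix(enmo[idx], nrow = spe)) * 1000
  t0 <- attr(rec, "time_offset_s")
  out <- tibble::tibble(epoch_start_s = t0 + (seq_len(n_ep) - 1) * epoch_length_s,
                        avm_mg = avm, wear_fraction = 1)
  out <- new_avm_epochs(out, epoch_length_s, rec_start(rec) - t0)
  if (!is.null(nonwear)) out <- apply_nonwear(out, nonwear)
  out
}

new_avm_epochs <- function(df, epoch_length_s, start_time) {
  structure(df, class = c("avm_epochs", class(tibble::tibble())),
            epoch_length_s = epoch_length_s, start_time = start_time)
}

#' @export
print.avm_epochs <- function(x, ...) {
  cat(sprintf("<avm_epochs> %d epochs of %g s\n", nrow(x), attr(x, "epoch_length_s")))
  NextMethod()
}

#' Set per-epoch wear fractions from nonwear intervals
#'
#' @param epochs An `avm_epochs` series.
#' @param nonwear Intervals from [detect_nonwear()].
#' @return The series with `wear_fraction` equal to the fraction of each
#'   epoch not covered by nonwear.
#' @export
apply_nonwear <- function(epochs, nonwear) {
  len <- attr(epochs, "epoch_length_s")
  wf <- rep(1, nrow(epochs))
  for (i in seq_len(nrow(nonwear))) {
    ov <- pmin(epochs$epoch_start_s + len, nonwear$end_s[i]) -
      pmax(epochs$epoch_start_s, nonwear$start_s[i])
    wf <- wf - pmax(0, ov) / len
  }
  epochs$wear_fraction <- pmax(0, wf)
  epochs
}

#' Reaverage an epoch series to a longer epoch length
#'
#' Each output value is the arithmetic mean of its constituent source
#' epochs; the trailing incomplete block is dropped. Wear fractions are
#' averaged the same way, so the total of `value * epoch_length` over the
#' retained span is conserved exactly.
#'
#' @param epochs An `avm_epochs` series.
#' @param target_length_s Target epoch length (s); must be an integer
#'   multiple of the source epoch length. Default 15.
#' @return An `avm_epochs` series at the target length.
#' @export
#' @examples
#' rec <- triax_recording(data.frame(x = 0, y = 0, z = rep(1, 50 * 45)),
#'                        sample_rate_hz = 50, site = "wrist")
#' e1 <- compute_avm(rec, epoch_length_s = 1)
#' e15 <- reepoch(e1, 15)
#' nrow(e15)  # 3
reepoch <- function(epochs, target_length_s = 15) {
  src <- attr(epochs, "epoch_length_s")
  k <- target_length_s / src
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    abort("target epoch length must be an integer multiple of the source length",
          class = "walkanchor_usage_error")
  }
  k <- as.integer(round(k))
  n_out <- nrow(epochs) %/% k
  if (n_out == 0) {
    return(new_avm_epochs(tibble::tibble(epoch_start_s = numeric(),
                                         avm_mg = numeric(),
                                         wear_fraction = numeric()),
                          target_length_s, attr(epochs, "start_time")))
  }
  idx <- seq_len(n_out * k)
  out <- tibble::tibble(
    epoch_start_s = epochs$epoch_start_s[seq(1, n_out * k, by = k)],
    avm_mg = colMeans(matrix(epochs$avm_mg[idx], nrow = k)),
    wear_fraction = colMeans(matrix(epochs$wear_fraction[idx], nrow = k)))
  new_avm_epochs(out, target_length_s, attr(epochs, "start_time"))
}
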
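#' Define a synthetic participant profile
#'
#' A profile fully determines one participant's dual-site recording: walking
#' segments (with cadence, arm-swing amplitude and arm condition), sleep and
#' nonwear blocks, tremor parameters, sensor noise and the random seed. The
#' generator renders the behavioural phenomena that dissociate wrist- from
#' ankle-derived activity: normal arm swing at stride frequency, arm-swing
#' suppression (gait-aid use), a reoriented static forearm posture
#' (activities of daily living such as pushing a cart, palm down), and a
#' 4.5 Hz pronation-supination tremor.
#'
#' @param duration_h Recording length (hours).
#' @param sample_rate_hz 50 or 75 Hz (the two study device rates).
#' @param walk_segments Tibble with columns `start_s`, `duration_s`,
#'   `cadence_spm` (40-200), optional `cadence_end_spm` (linear ramp),
#'   `arm_swing_amplitude_g` (>= 0) and `arm_condition` (one of `normal`,
#'   `suppressed`, `adl_posture`, `tremor`). Segments must not overlap.
#' @param sleep Optional tibble `start_s`, `end_s` of one or more sleep
#'   blocks.
#' @param nonwear Optional tibble `start_s`, `end_s` of nonwear blocks.
#' @param tremor_frequency_hz Tremor frequency; default 4.5 Hz.
#' @param tremor_amplitude_g Tremor acceleration amplitude; default 0.35 g.
#' @param noise_sd_g White sensor noise sd; default 0.01 g.
#' @param fidget_amplitude_g Amplitude of the slow non-walking wrist/ankle
#'   wobble; default 0.03 g.
#' @param seed Integer seed; all randomness in the rendered participant
#'   derives from it.
#' @param start_time Absolute start time of the recording.
#' @param participant_id Identifier carried into the ledger.
#' @return A `participant_profile` list.
#' @export
participant_profile <- function(duration_h = 2, sample_rate_hz = 50,
                                walk_segments = tibble::tibble(),
                                sleep = NULL, nonwear = NULL,
                                tremor_frequency_hz = 4.5,
                                tremor_amplitude_g = 0.35,
                                noise_sd_g = 0.01,
                                fidget_amplitude_g = 0.03,
                                seed = 1L,
                                start_time = as.POSIXct("2000-01-01 12:00:00", tz = "UTC"),
                                participant_id = "P1") {
  if (!sample_rate_hz %in% c(50, 75)) {
    abort("sample_rate_hz must be 50 or 75", class = "walkanchor_config_error")
  }
  ws <- tibble::as_tibble(walk_segments)
  if (nrow(ws) > 0) {
    if (!all(c("start_s", "duration_s", "cadence_spm") %in% names(ws))) {
      abort("walk_segments needs start_s, duration_s, cadence_spm",
            class = "walkanchor_profile_error")
    }
    if (!"cadence_end_spm" %in% names(ws)) ws$cadence_end_spm <- ws$cadence_spm
    if (!"arm_swing_amplitude_g" %in% names(ws)) ws$arm_swing_amplitude_g <- 0.4
    if (!"arm_condition" %in% names(ws)) ws$arm_condition <- "normal"
    ok_cond <- ws$arm_condition %in% c("normal", "suppressed", "adl_posture", "tremor")
    if (!all(ok_cond)) abort("unknown arm_condition", class = "walkanchor_profile_error")
    if (any(c(ws$cadence_spm, ws$cadence_end_spm) < 40 |
            c(ws$cadence_spm, ws$cadence_end_spm) > 200)) {
      abort("cadence_spm must lie in [40, 200]", class = "walkanchor_profile_error")
    }
    if (any(ws$arm_swing_amplitude_g < 0)) {
      abort("arm swing amplitudes must be >= 0", class = "walkanchor_profile_error")
    }
    ws <- dplyr::arrange(ws, .data$start_s)
    if (nrow(ws) > 1 &&
        any(ws$start_s[-1] < (ws$start_s + ws$duration_s)[-nrow(ws)])) {
      abort("walk segments overlap", class = "walkanchor_profile_error")
    }
    if (any(ws$start_s < 0 | ws$start_s + ws$duration_s > duration_h * 3600)) {
      abort("walk segments exceed the recording", class = "walkanchor_profile_error")
    }
  }
  structure(list(duration_h = duration_h, sample_rate_hz = sample_rate_hz,
                 walk_segments = ws, sleep = sleep, nonwear = nonwear,
                 tremor_frequency_hz = tremor_frequency_hz,
                 tremor_amplitude_g = tremor_amplitude_g,
                 noise_sd_g = noise_sd_g,
                 fidget_amplitude_g = fidget_amplitude_g,
                 seed = as.integer(seed), start_time = start_time,
                 participant_id = participant_id),
            class = "participant_profile")
}

# predicted steady-state AVM (mg) of the wrist model for one walking
# condition, by numerical integration over one cycle of the rendered signal
predicted_wrist_avm <- function(condition, amplitude_g, tremor_amplitude_g = 0.35) {
  th <- seq(0, 2 * pi, length.out = 2001)[-1]
  enmo <- switch(condition,
    normal = pmax(0, sqrt((1 + amplitude_g * sin(th))^2 +
                            (0.5 * amplitude_g * cos(th))^2) - 1),
    suppressed = 0,
    adl_posture = 0,
    tremor = pmax(0, abs(1 + tremor_amplitude_g * sin(th)) - 1))
  mean(enmo) * 1000
}

#' Simulate one participant's wrist and ankle recordings
#'
#' Renders the profile into two synchronized [triax_recording()]s plus a
#' ground-truth ledger. The ankle carries gravity on one axis and a per-step
#' impact transient on the anteroposterior axis: a damped 8 Hz ringing with
#' a unidirectional foot-strike component, ~0.8 g, at cadence-defined step
#' times with 2% timing jitter. The wrist carries gravity plus, per walking
#' segment, the arm-condition signal: a sinusoid at stride frequency
#' (cadence / 120 Hz) for normal swing; nothing for suppressed swing;
#' reoriented static gravity for the ADL posture; a tremor sinusoid for the
#' tremor condition. Non-walking waking time is low-amplitude fidgeting,
#' sleep is near-zero motion with brief position turns, and nonwear is an
#' exactly constant orientation with zero noise.
#'
#' @param profile A [participant_profile()].
#' @return A list `wrist`, `ankle` (recordings) and `ledger`, itself a list
#'   with `steps`, `bouts` (including each bout's expected LONG flag and
#'   expected intensity label), `epochs` (per-15-s expected condition),
#'   `sleep`, `nonwear` and `expected_sedentary_fraction` (of expected
#'   LONG-walk epochs).
#' @export
simulate_participant <- function(profile) {
  stopifnot(inherits(profile, "participant_profile"))
  set.seed(profile$seed)
  fs <- profile$sample_rate_hz
  n <- as.integer(round(profile$duration_h * 3600 * fs))
  t <- (seq_len(n) - 1) / fs
  dur_s <- profile$duration_h * 3600

  wrist <- matrix(0, n, 3); wrist[, 3] <- 1
  ankle <- matrix(0, n, 3); ankle[, 3] <- 1

  in_interval <- function(iv) {
    m <- rep(FALSE, n)
    if (is.null(iv) || nrow(iv) == 0) return(m)
    for (i in seq_len(nrow(iv))) m[t >= iv$start_s[i] & t < iv$end_s[i]] <- TRUE
    m
  }
  sleep_mask <- in_interval(profile$sleep)
  nonwear_mask <- in_interval(profile$nonwear)
  walk_mask <- rep(FALSE, n)

  # ankle impact kernel: damped 8 Hz ringing + unidirectional strike pulse
  kt <- seq(0, 0.3, by = 1 / fs)
  kernel <- 0.8 * exp(-kt / 0.05) * sin(2 * pi * 8 * kt) +
    0.4 * sin(pi * kt / 0.08) * (kt < 0.08)

  ws <- profile$walk_segments
  steps_all <- list(); bouts <- list()
  for (si in seq_len(nrow(ws))) {
    seg <- ws[si, ]
    # step times: intervals 60/cadence with a linear cadence ramp and 2% jitter
    st <- numeric(0); cur <- seg$start_s
    repeat {
      frac <- (cur - seg$start_s) / seg$duration_s
      cad <- seg$cadence_spm + frac * (seg$cadence_end_spm - seg$cadence_spm)
      step <- (60 / cad) * (1 + rnorm(1, 0, 0.02))
      nxt <- cur + step
      if (nxt > seg$start_s + seg$duration_s) break
      st <- c(st, nxt)
      cur <- nxt
    }
    if (length(st) < 2) next
    idx0 <- as.integer(round(st * fs)) + 1
    for (ii in idx0) {
      span <- ii:min(ii + length(kernel) - 1, n)
      ankle[span, 1] <- ankle[span, 1] + kernel[seq_along(span)]
    }
    seg_idx <- t >= seg$start_s & t < seg$start_s + seg$duration_s
    walk_mask <- walk_mask | seg_idx
    # wrist per condition
    A <- seg$arm_swing_amplitude_g
    cad_mid <- (seg$cadence_spm + seg$cadence_end_spm) / 2
    f_stride <- cad_mid / 120   # arms swing once per stride = half step rate
    tt <- t[seg_idx] - seg$start_s
    cond <- seg$arm_condition
    if (cond == "normal" && A > 0) {
      wrist[seg_idx, 3] <- wrist[seg_idx, 3] + A * sin(2 * pi * f_stride * tt)
      wrist[seg_idx, 1] <- wrist[seg_idx, 1] + 0.5 * A * cos(2 * pi * f_stride * tt)
    } else if (cond == "adl_posture") {
      # horizontal forearm, palm down: gravity moves onto the x axis
      wrist[seg_idx, 3] <- 0
      wrist[seg_idx, 1] <- 1
    } else if (cond == "tremor") {
      wrist[seg_idx, 3] <- wrist[seg_idx, 3] +
        profile$tremor_amplitude_g * sin(2 * pi * profile$tremor_frequency_hz * tt)
    }
    med_cad <- median(60 / diff(st))
    bout_dur <- st[length(st)] - st[1]
    exp_avm <- predicted_wrist_avm(cond, A, profile$tremor_amplitude_g)
    bouts[[length(bouts) + 1]] <- tibble::tibble(
      segment_id = si, start_s = st[1], end_s = st[length(st)],
      n_steps = length(st), median_cadence_spm = med_cad,
      condition = cond,
      expected_long = bout_dur >= 60 & med_cad > 80,
      expected_all = length(st) >= 5,
      expected_avm_mg = exp_avm)
    steps_all[[length(steps_all) + 1]] <- tibble::tibble(step_time_s = st,
                                                         segment_id = si)
  }
  steps <- if (length(steps_all)) dplyr::bind_rows(steps_all) else
    tibble::tibble(step_time_s = numeric(), segment_id = integer())
  bouts <- if (length(bouts)) dplyr::bind_rows(bouts) else
    tibble::tibble(segment_id = integer(), start_s = numeric(), end_s = numeric(),
                   n_steps = integer(), median_cadence_spm = numeric(),
                   condition = character(), expected_long = logical(),
                   expected_all = logical(), expected_avm_mg = numeric())

  # fidgeting during waking non-walk wear time. The wrist gets a rectified
  # slow oscillation (norm excursions above 1 g) so sedentary waking epochs
  # sit clearly between the sleep-quiet level and the light cut point; the
  # ankle gets only a sub-band postural wobble that must not trip the step
  # detector.
  fidget_mask <- !walk_mask & !sleep_mask & !nonwear_mask
  Af <- profile$fidget_amplitude_g
  f_fid <- runif(1, 0.6, 0.9)
  f1 <- runif(1, 0.05, 0.15)
  ph <- runif(3, 0, 2 * pi)
  wob_w <- Af * abs(sin(pi * f_fid * t + ph[1]))
  wob_a <- Af * sin(2 * pi * f1 * t + ph[2]) +
    0.5 * Af * sin(2 * pi * 2 * f1 * t + ph[3])
  wrist[fidget_mask, 3] <- wrist[fidget_mask, 3] + wob_w[fidget_mask]
  ankle[fidget_mask, 1] <- ankle[fidget_mask, 1] + wob_a[fidget_mask]

  # sleep: near-zero motion with brief position turns every 15-25 min
  if (any(sleep_mask) && !is.null(profile$sleep)) {
    for (i in seq_len(nrow(profile$sleep))) {
      s0 <- profile$sleep$start_s[i]; s1 <- profile$sleep$end_s[i]
      turn <- s0 + runif(1, 900, 1500)
      while (turn < s1 - 10) {
        sel <- t >= turn & t < turn + 5
        # a turn reorients the limb: at least two axes move, so brief posture
        # shifts break up would-be nonwear runs the way real sleep does
        wrist[sel, 1] <- wrist[sel, 1] + 0.2 * sin(pi * (t[sel] - turn) / 5)
        wrist[sel, 3] <- wrist[sel, 3] - 0.15 * sin(pi * (t[sel] - turn) / 5)
        ankle[sel, 1] <- ankle[sel, 1] + 0.2 * sin(pi * (t[sel] - turn) / 5)
        ankle[sel, 3] <- ankle[sel, 3] - 0.15 * sin(pi * (t[sel] - turn) / 5)
        turn <- turn + runif(1, 900, 1500)
      }
    }
  }

  # sensor noise: full during wear, reduced during sleep, none during nonwear
  noise_scale <- rep(profile$noise_sd_g, n)
  noise_scale[sleep_mask] <- profile$noise_sd_g * 0.2
  noise_scale[nonwear_mask] <- 0
  for (j in 1:3) {
    wrist[, j] <- wrist[, j] + rnorm(n) * noise_scale
    ankle[, j] <- ankle[, j] + rnorm(n) * noise_scale
  }
  # nonwear: exactly constant resting orientation
  if (any(nonwear_mask)) {
    wrist[nonwear_mask, 1] <- 0.6; wrist[nonwear_mask, 2] <- 0
    wrist[nonwear_mask, 3] <- 0.8
    ankle[nonwear_mask, 1] <- 0.6; ankle[nonwear_mask, 2] <- 0
    ankle[nonwear_mask, 3] <- 0.8
  }

  wrist_rec <- triax_recording(
    data.frame(x = wrist[, 1], y = wrist[, 2], z = wrist[, 3]),
    sample_rate_hz = fs, site = "wrist", start_time = profile$start_time,
    body_side = "dominant", device_id = paste0("sim-", profile$participant_id, "-W"))
  ankle_rec <- triax_recording(
    data.frame(x = ankle[, 1], y = ankle[, 2], z = ankle[, 3]),
    sample_rate_hz = fs, site = "ankle", start_time = profile$start_time,
    body_side = "dominant", device_id = paste0("sim-", profile$participant_id, "-A"))

  ledger <- build_ledger(profile, steps, bouts, dur_s)
  list(wrist = wrist_rec, ankle = ankle_rec, ledger = ledger)
}

# expected per-epoch conditions and sedentary fraction, on the global 15-s grid
build_ledger <- function(profile, steps, bouts, dur_s, epoch_s = 15,
                         cuts = intensity_cut_points()) {
  n_ep <- floor(dur_s / epoch_s)
  ep_start <- (seq_len(n_ep) - 1) * epoch_s
  cond <- rep("nonwalk", n_ep)
  exp_label <- rep(NA_character_, n_ep)
  in_long <- rep(FALSE, n_ep)
  for (i in seq_len(nrow(bouts))) {
    inside <- ep_start >= bouts$start_s[i] & ep_start + epoch_s <= bouts$end_s[i]
    cond[inside] <- bouts$condition[i]
    if (isTRUE(bouts$expected_long[i])) {
      in_long[inside] <- TRUE
      exp_label[inside] <- as.character(classify_epoch(bouts$expected_avm_mg[i], cuts))
    }
  }
  mark <- function(iv, what) {
    if (is.null(iv) || nrow(iv) == 0) return()
    for (i in seq_len(nrow(iv))) {
      cond[ep_start >= iv$start_s[i] & ep_start + epoch_s <= iv$end_s[i]] <<- what
    }
  }
  mark(profile$sleep, "sleep")
  mark(profile$nonwear, "nonwear")
  n_long <- sum(in_long)
  sed_frac <- if (n_long > 0) sum(exp_label[in_long] == "sedentary") / n_long else NA_real_
  list(participant_id = profile$participant_id,
       steps = steps, bouts = bouts,
       epochs = tibble::tibble(epoch_start_s = ep_start, condition = cond,
                               in_long_walk = in_long, expected_label = exp_label),
       sleep = profile$sleep %||% tibble::tibble(start_s = numeric(), end_s = numeric()),
       nonwear = profile$nonwear %||% tibble::tibble(start_s = numeric(), end_s = numeric()),
       expected_sedentary_fraction = sed_frac)
}

#' Scenario presets and cohort simulation
#'
#' Draws participant profiles from named behavioural scenarios and renders
#' them. Presets: `"active_oa"` (mostly normal arm swing, brisk cadence),
#' `"gait_aid"` (mostly suppressed swing, slower cadence), `"tremor_pd"`
#' (fast cadence, tremor and suppressed swing), `"mixed_adl"` (normal swing
#' mixed with ADL arm postures), and `"graded"` (target sedentary fraction
#' set explicitly via `target_sedentary_fraction`). Everything is
#' deterministic under `seed`.
#'
#' @param n Number of participants.
#' @param scenario_mix Character vector of scenario names, recycled to
#'   length `n`.
#' @param seed Cohort seed; participant `i` uses `seed * 1000 + i`.
#' @param duration_h Per-participant duration (hours); default 2.
#' @param sample_rate_hz Device rate; default 50.
#' @param target_sedentary_fraction Optional numeric vector (length `n`)
#'   used by the `"graded"` scenario: the fraction of walking time rendered
#'   with suppressed arm swing.
#' @return A list of `simulate_participant()` results plus a `cohort_ledger`
#'   tibble (`participant_id`, `scenario`,
#'   `expected_sedentary_fraction`, step and LONG-walk totals).
#' @export
simulate_cohort <- function(n, scenario_mix = "active_oa", seed = 1L,
                            duration_h = 2, sample_rate_hz = 50,
                            target_sedentary_fraction = NULL) {
  stopifnot(n >= 1)
  known <- c("active_oa", "gait_aid", "tremor_pd", "mixed_adl", "graded")
  if (!all(scenario_mix %in% known)) {
    abort(sprintf("unknown scenario: %s",
                  paste(setdiff(scenario_mix, known), collapse = ", ")),
          class = "walkanchor_config_error")
  }
  scenarios <- rep(scenario_mix, length.out = n)
  participants <- vector("list", n)
  ledger_rows <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("S%02d", i)
    prof <- scenario_profile(scenarios[i], seed = seed * 1000 + i,
                             duration_h = duration_h,
                             sample_rate_hz = sample_rate_hz,
                             participant_id = pid,
                             target_sed = target_sedentary_fraction[i] %||% NULL)
    participants[[i]] <- simulate_participant(prof)
    led <- participants[[i]]$ledger
    ledger_rows[[i]] <- tibble::tibble(
      participant_id = pid, scenario = scenarios[i],
      n_steps = nrow(led$steps),
      n_long_bouts = sum(led$bouts$expected_long),
      expected_sedentary_fraction = led$expected_sedentary_fraction)
  }
  list(participants = participants,
       cohort_ledger = dplyr::bind_rows(ledger_rows))
}

# draw one profile for a scenario; deterministic under seed
scenario_profile <- function(scenario, seed, duration_h, sample_rate_hz,
                             participant_id, target_sed = NULL) {
  set.seed(seed)
  total_s <- duration_h * 3600
  # walk placement: alternating walk/gap until the time is used up
  segs <- list(); cur <- 120
  while (cur < total_s - 200) {
    dur <- runif(1, 70, 170)           # comfortably past the 60-s LONG floor
    if (runif(1) < 0.25) dur <- runif(1, 15, 40)  # short, non-LONG walk
    par <- switch(scenario,
      active_oa = list(cad = rnorm(1, 112, 7),
                       cond = sample(c("normal", "adl_posture"), 1, prob = c(0.9, 0.1)),
                       amp = runif(1, 0.3, 0.5)),
      gait_aid = list(cad = rnorm(1, 95, 5),
                      cond = sample(c("suppressed", "normal"), 1, prob = c(0.9, 0.1)),
                      amp = runif(1, 0.3, 0.4)),
      tremor_pd = list(cad = rnorm(1, 128, 8),
                       cond = sample(c("tremor", "suppressed", "normal"), 1,
                                     prob = c(0.5, 0.25, 0.25)),
                       amp = runif(1, 0.25, 0.4)),
      mixed_adl = list(cad = rnorm(1, 107, 7),
                       cond = sample(c("normal", "adl_posture"), 1, prob = c(0.5, 0.5)),
                       amp = runif(1, 0.3, 0.5)),
      graded = list(cad = rnorm(1, 110, 7),
                    cond = sample(c("suppressed", "normal"), 1,
                                  prob = c(target_sed %||% 0.2,
                                           1 - (target_sed %||% 0.2))),
                    amp = runif(1, 0.35, 0.5)))
    cad <- min(max(par$cad, 85), 160)
    segs[[length(segs) + 1]] <- tibble::tibble(
      start_s = cur, duration_s = dur, cadence_spm = cad,
      cadence_end_spm = cad, arm_swing_amplitude_g = par$amp,
      arm_condition = par$cond)
    cur <- cur + dur + runif(1, 40, 120)
  }
  participant_profile(duration_h = duration_h, sample_rate_hz = sample_rate_hz,
                      walk_segments = dplyr::bind_rows(segs),
                      seed = seed, participant_id = participant_id)
}

#' Dominant frequency of a recording axis
#'
#' Locates the spectral peak of one axis (mean removed) within a frequency
#' band, via the FFT periodogram. Useful for verifying the synthetic
#' generator: an ankle recording of walking at cadence `c` spm peaks at
#' `c / 60` Hz; a tremor-condition wrist peaks at the tremor frequency.
#'
#' @param rec A [triax_recording()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param band Frequency band (Hz) to search.
#' @return Peak frequency in Hz.
#' @export
dominant_frequency <- function(rec, axis = "x", band = c(0.5, 10)) {
  v <- rec[[axis]] - mean(rec[[axis]])
  n <- length(v)
  sp <- Mod(stats::fft(v))[seq_len(floor(n / 2))]^2
  freq <- (seq_len(floor(n / 2)) - 1) * rec_rate(rec) / n
  sel <- freq >= band[1] & freq <= band[2]
  freq[sel][which.max(sp[sel])]
}
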
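test_that("epoch classification respects lower-inclusive upper-class boundaries", {
  cuts <- intensity_cut_points(30, 100)
  expect_equal(as.character(classify_epoch(0, cuts)), "sedentary")
  expect_equal(as.character(classify_epoch(29.999, cuts)), "sedentary")
  expect_equal(as.character(classify_epoch(30, cuts)), "light")
  expect_equal(as.character(classify_epoch(100, cuts)), "MVPA")  # boundary -> MVPA
  expect_error(classify_epoch(-1, cuts), class = "walkanchor_usage_error")

  # sweep: labels non-decreasing in AVM
  sweep_labels <- classify_epoch(seq(0, 500, by = 0.25), cuts)
  expect_true(all(diff(as.integer(sweep_labels)) >= 0))
})

test_that("classification is monotone in the cut points themselves", {
  set.seed(30)
  avm <- runif(500, 0, 300)
  base <- classify_epoch(avm, intensity_cut_points(30, 100))
  raised_light <- classify_epoch(avm, intensity_cut_points(45, 100))
  expect_gte(sum(raised_light == "sedentary"), sum(base == "sedentary"))
  raised_mod <- classify_epoch(avm, intensity_cut_points(30, 150))
  expect_lte(sum(raised_mod == "MVPA"), sum(base == "MVPA"))
})

test_that("walk-epoch selection matches the end-exclusion examples", {
  mk_epochs <- function(n, len = 15) walkanchor:::new_avm_epochs(
    tibble::tibble(epoch_start_s = (seq_len(n) - 1) * len, avm_mg = 50,
                   wear_fraction = 1), len, as.POSIXct("2000-01-01", tz = "UTC"))
  mk_bout <- function(s, e) tibble::tibble(
    bout_id = 1L, start_s = s, end_s = e, n_steps = 100L,
    median_cadence_spm = 100, is_long = TRUE, is_all_walk = TRUE)
  ep <- mk_epochs(100)
  expect_equal(nrow(label_walk_epochs(ep, mk_bout(0, 70))), 4)   # 5th ends at 75
  expect_equal(nrow(label_walk_epochs(ep, mk_bout(0, 60))), 4)
  expect_equal(nrow(label_walk_epochs(ep, mk_bout(0, 59.9))), 3)
})

test_that("walk-epoch selection equals the brute-force containment oracle", {
  set.seed(31)
  ep <- walkanchor:::new_avm_epochs(
    tibble::tibble(epoch_start_s = (0:199) * 15, avm_mg = 50, wear_fraction = 1),
    15, as.POSIXct("2000-01-01", tz = "UTC"))
  for (i in 1:200) {
    ws <- runif(1, 0, 2000)
    we <- ws + runif(1, 20, 400)
    got <- label_walk_epochs(ep, tibble::tibble(
      bout_id = 1L, start_s = ws, end_s = we, n_steps = 10L,
      median_cadence_spm = 100, is_long = TRUE, is_all_walk = TRUE))
    expect_equal(got$epoch_start_s, containment_oracle(ws, we, 15, 199 * 15))
  }
})

test_that("sleep detection recovers a synthetic night and passes annotations through", {
  ann <- tibble::tibble(start_s = 100, end_s = 200)
  e_dummy <- walkanchor:::new_avm_epochs(
    tibble::tibble(epoch_start_s = 0:10, avm_mg = 1, wear_fraction = 1), 1,
    as.POSIXct("2000-01-01", tz = "UTC"))
  expect_equal(detect_sleep_windows(e_dummy, ann), ann)

  # synthetic 24-h day with an 8-h quiet night: recovered within 15 min
  prof <- participant_profile(duration_h = 24, sample_rate_hz = 50,
    walk_segments = tibble::tibble(start_s = 10000, duration_s = 120,
                                   cadence_spm = 110,
                                   arm_swing_amplitude_g = 0.4,
                                   arm_condition = "normal"),
    sleep = tibble::tibble(start_s = 39600, end_s = 68400),  # 23:00-07:00
    seed = 32, start_time = as.POSIXct("2000-01-01 12:00:00", tz = "UTC"))
  sim <- simulate_participant(prof)
  e1 <- compute_avm(sim$wrist, epoch_length_s = 1)
  sl <- detect_sleep_windows(e1)
  expect_equal(nrow(sl), 1)
  expect_lt(abs(sl$start_s - 39600), 900)
  expect_lt(abs(sl$end_s - 68400), 900)

  # daytime-only recording: no sleep
  prof2 <- participant_profile(duration_h = 2, seed = 33,
    start_time = as.POSIXct("2000-01-01 13:00:00", tz = "UTC"))
  sim2 <- simulate_participant(prof2)
  expect_equal(nrow(detect_sleep_windows(compute_avm(sim2$wrist, epoch_length_s = 1))), 0)
})

test_that("daily summaries apply the valid-day rule and count label minutes exactly", {
  len <- 15
  n <- 2 * 86400 / len  # two full days
  start <- as.POSIXct("2000-01-03 00:00:00", tz = "UTC")
  set.seed(34)
  avm <- rep(10, n)
  # day 1: 200 light epochs, 100 MVPA epochs among waking wear (after 06:00,
  # i.e. epoch 1440 onwards)
  avm[2400:2599] <- 50
  avm[3000:3099] <- 150
  ep <- walkanchor:::new_avm_epochs(
    tibble::tibble(epoch_start_s = (seq_len(n) - 1) * len, avm_mg = avm,
                   wear_fraction = 1), len, start)
  sleep <- tibble::tibble(start_s = c(0, 84600, 84600 + 86400),
                          end_s = c(6 * 3600, 86400 + 6 * 3600, 2 * 86400))
  d <- summarize_days(ep, nonwear = NULL, sleep = sleep, config = walk_config())
  expect_equal(nrow(d), 2)
  expect_true(all(d$valid))  # ~17.5 h waking wear
  expect_equal(d$light_min[1], 200 * 0.25)
  expect_equal(d$mvpa_min[1], 100 * 0.25)

  # 9.9 h of waking wear: invalid under the strict >= 10 h rule
  sleep_long <- tibble::tibble(start_s = 0, end_s = (24 - 9.9) * 3600)
  d2 <- summarize_days(walkanchor:::new_avm_epochs(
    tibble::tibble(epoch_start_s = (seq_len(86400 / len) - 1) * len,
                   avm_mg = 10, wear_fraction = 1), len, start),
    sleep = sleep_long, config = walk_config())
  expect_false(d2$valid[1])
  expect_equal(d2$wear_h_waking[1], 9.9, tolerance = 0.01)

  # partial first day is never valid
  ep_partial <- walkanchor:::new_avm_epochs(
    tibble::tibble(epoch_start_s = (seq_len(6000) - 1) * len, avm_mg = 10,
                   wear_fraction = 1), len, start + 3600)
  d3 <- summarize_days(ep_partial, config = walk_config())
  expect_false(any(d3$valid))
})

test_that("intensity class counts within LONG walks are conserved", {
  sim <- simulate_participant(one_walk_profile(seed = 35, dur = 150))
  st <- detect_steps(sim$ankle)
  bouts <- flag_walks(build_bouts(st))
  lab <- label_walk_epochs(reepoch(compute_avm(sim$wrist, epoch_length_s = 1), 15), bouts)
  expect_equal(sum(lab$label == "sedentary") + sum(lab$label == "light") +
                 sum(lab$label == "MVPA"), nrow(lab))
  expect_true(all(lab$in_long_walk))
})
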
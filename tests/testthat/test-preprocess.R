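test_that("stationary windows are found where and only where the device rests", {
  set.seed(10)
  still <- gravity_rec(60, noise = 0.002)
  w <- find_stationary_windows(still)
  expect_equal(nrow(w), 6)
  expect_equal(sqrt(w$mean_x^2 + w$mean_y^2 + w$mean_z^2), rep(1, 6),
               tolerance = 1e-3)

  # continuous 0.1 g sinusoid: nothing is stationary at the 0.013 g threshold
  fs <- 50; t <- (0:(60 * fs - 1)) / fs
  mov <- triax_recording(data.frame(x = 0.1 * sin(2 * pi * 1 * t), y = 0, z = 1),
                         fs, "wrist")
  expect_equal(nrow(find_stationary_windows(mov)), 0)

  # mixed signal: quiet block at 20-40 s found within one window of truth
  xq <- 0.1 * sin(2 * pi * 1 * t)
  xq[t >= 20 & t < 40] <- 0
  mix <- triax_recording(data.frame(x = xq + rnorm(length(t), 0, 0.002),
                                    y = 0, z = 1), fs, "wrist")
  wm <- find_stationary_windows(mix)
  expect_gte(min(wm$start_s), 10)
  expect_lte(max(wm$end_s), 50)
  expect_gte(nrow(wm), 1)
})

test_that("autocalibration recovers injected offsets and gains", {
  set.seed(11)
  clean <- six_orientation_rec()
  cal0 <- autocalibrate(clean)
  expect_true(cal0$calibrated)
  expect_lt(max(abs(cal0$offset)), 1e-3)
  expect_lt(max(abs(cal0$gain - 1)), 1e-3)

  off <- c(0.05, -0.02, 0); gn <- c(1.03, 0.98, 1.00)
  set.seed(12)
  distorted <- six_orientation_rec(offset = off, gain = gn)
  cal <- autocalibrate(distorted)
  expect_true(cal$calibrated)
  expect_lt(max(abs(cal$offset - off)), 0.005)
  expect_lt(max(abs(cal$gain - gn)), 0.005)

  # single orientation: under-determined, identity with calibrated = FALSE
  set.seed(13)
  single <- gravity_rec(120, noise = 0.002)
  cal1 <- autocalibrate(single)
  expect_false(cal1$calibrated)
  expect_equal(cal1$offset, c(0, 0, 0))
  expect_equal(cal1$gain, c(1, 1, 1))
})

test_that("calibration application is idempotent within tolerance", {
  off <- c(0.05, -0.02, 0); gn <- c(1.03, 0.98, 1.00)
  set.seed(14)
  distorted <- six_orientation_rec(offset = off, gain = gn)
  cal <- autocalibrate(distorted)
  once <- walkanchor:::apply_calibration(distorted, cal)
  cal2 <- autocalibrate(once)
  # a second fit on already-calibrated data finds (nearly) identity
  if (cal2$calibrated) {
    twice <- walkanchor:::apply_calibration(once, cal2)
    expect_lt(max(abs(twice$x - once$x)), 1e-3)
  }
  expect_lt(max(abs(cal2$offset)), 1e-3)
  expect_lt(max(abs(cal2$gain - 1)), 1e-3)
})

test_that("nonwear detection finds still blocks and applies the merge rule", {
  fs <- 25  # coarser rate keeps the 8-h fixture light
  set.seed(15)
  n_h <- 8; n <- n_h * 3600 * fs
  t <- (0:(n - 1)) / fs
  x <- 0.2 * sin(2 * pi * 0.8 * t) + rnorm(n, 0, 0.01)
  z <- 1 + 0.1 * sin(2 * pi * 0.5 * t) + rnorm(n, 0, 0.01)
  blk <- t >= 2 * 3600 & t < 5 * 3600   # 3-h still block
  x[blk] <- 0.6; z[blk] <- 0.8
  rec <- triax_recording(data.frame(x = x, y = rnorm(n, 0, 0.005), z = z), fs, "wrist")
  nw <- detect_nonwear(rec)
  expect_equal(nrow(nw), 1)
  expect_lt(abs(nw$start_s - 2 * 3600), 120)
  expect_lt(abs(nw$end_s - 5 * 3600), 120)

  # fully active: empty
  ta <- t[1:(2 * 3600 * fs)]
  act <- triax_recording(data.frame(x = 0.2 * sin(2 * pi * 0.8 * ta),
                                    y = 0.1 * sin(2 * pi * 0.5 * ta),
                                    z = 1 + 0.15 * cos(2 * pi * 0.8 * ta)), fs, "wrist")
  expect_equal(nrow(detect_nonwear(act)), 0)

  # two 90-min still blocks separated by 3 min of movement merge into one
  x2 <- rep(0.6, n); z2 <- rep(0.8, n)
  gap <- t >= 90 * 60 & t < 93 * 60
  x2[gap] <- 0.3 * sin(2 * pi * 1 * t[gap]); z2[gap] <- 1 + 0.3 * cos(2 * pi * 1 * t[gap])
  rec2 <- triax_recording(data.frame(x = x2[1:(183 * 60 * fs)], y = 0,
                                     z = z2[1:(183 * 60 * fs)]), fs, "wrist")
  nw2 <- detect_nonwear(rec2)
  expect_equal(nrow(nw2), 1)
  expect_lte(nw2$start_s, 60)
  expect_gte(nw2$end_s, 182 * 60)
})

test_that("AVM matches the per-sample oracle and is zero at rest", {
  still <- gravity_rec(30, noise = 0)
  e <- compute_avm(still, epoch_length_s = 1)
  expect_equal(e$avm_mg, rep(0, 30))

  # single-axis sinusoid on orthogonal gravity, unfiltered: oracle to 1e-9
  fs <- 50; t <- (0:(30 * fs - 1)) / fs
  rec <- triax_recording(data.frame(x = 0.1 * sin(2 * pi * 1 * t), y = 0, z = 1),
                         fs, "wrist")
  e2 <- compute_avm(rec, epoch_length_s = 1, lowpass_hz = NA)
  expect_equal(e2$avm_mg, avm_oracle(rec), tolerance = 1e-9)

  # with the default 20 Hz filter, sub-cutoff motion agrees closely
  e3 <- compute_avm(rec, epoch_length_s = 1)
  expect_equal(e3$avm_mg, avm_oracle(rec), tolerance = 0.02)

  # doubling amplitude raises every epoch
  rec2 <- triax_recording(data.frame(x = 0.2 * sin(2 * pi * 1 * t), y = 0, z = 1),
                          fs, "wrist")
  e4 <- compute_avm(rec2, epoch_length_s = 1, lowpass_hz = NA)
  expect_true(all(e4$avm_mg > e2$avm_mg))

  expect_error(compute_avm(gravity_rec(5), epoch_length_s = 10),
               class = "walkanchor_usage_error")
})

test_that("AVM is invariant to fixed rotations of the device frame", {
  set.seed(16)
  fs <- 50; t <- (0:(20 * fs - 1)) / fs
  base <- cbind(0.15 * sin(2 * pi * 1.2 * t), 0.05 * cos(2 * pi * 0.7 * t), 1 + 0.1 * sin(2 * pi * 2 * t))
  ref <- compute_avm(triax_recording(as.data.frame(`colnames<-`(base, c("x", "y", "z"))),
                                     fs, "wrist"), epoch_length_s = 1)
  for (i in 1:5) {
    m <- matrix(rnorm(9), 3)
    q <- qr.Q(qr(m))  # random orthogonal matrix
    rot <- base %*% q
    er <- compute_avm(triax_recording(as.data.frame(`colnames<-`(rot, c("x", "y", "z"))),
                                      fs, "wrist"), epoch_length_s = 1)
    expect_equal(er$avm_mg, ref$avm_mg, tolerance = 1e-6)
  }
})

test_that("reepoch averages exactly, drops partial blocks and conserves totals", {
  mk <- function(v) walkanchor:::new_avm_epochs(
    tibble::tibble(epoch_start_s = seq_along(v) - 1, avm_mg = v,
                   wear_fraction = 1), 1, as.POSIXct("2000-01-01", tz = "UTC"))
  expect_equal(reepoch(mk(rep(30, 15)), 15)$avm_mg, 30)
  expect_equal(reepoch(mk(1:15), 15)$avm_mg, 8)
  e47 <- reepoch(mk(seq_len(47)), 15)
  expect_equal(nrow(e47), 3)
  expect_equal(sum(e47$avm_mg) * 15, sum(1:45) * 1)  # conservation on retained span
  expect_error(reepoch(mk(1:30), 10.5), class = "walkanchor_usage_error")
})
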
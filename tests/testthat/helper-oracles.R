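# Independent oracles and small fixture builders used across the suite.

# gravity-only recording: z = 1 g
gravity_rec <- function(n_s = 60, fs = 50, site = "wrist", noise = 0) {
  n <- n_s * fs
  triax_recording(data.frame(x = rnorm(n, 0, noise), y = rnorm(n, 0, noise),
                             z = 1 + rnorm(n, 0, noise)),
                  sample_rate_hz = fs, site = site)
}

# recording cycling through the six +/- axis orientations, optionally
# distorted by known calibration errors (raw = (true - offset) / gain)
six_orientation_rec <- function(per_s = 30, fs = 50, offset = c(0, 0, 0),
                                gain = c(1, 1, 1), noise = 0.002) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  blocks <- lapply(seq_len(6), function(i) {
    n <- per_s * fs
    true <- matrix(rep(dirs[i, ], each = n), n, 3)
    true <- true + matrix(rnorm(3 * n, 0, noise), n, 3)
    sweep(sweep(true, 2, offset, `-`), 2, gain, `/`)
  })
  m <- do.call(rbind, blocks)
  triax_recording(data.frame(x = m[, 1], y = m[, 2], z = m[, 3]),
                  sample_rate_hz = fs, site = "wrist")
}

# brute-force per-sample AVM oracle: no filtering, ENMO floored at zero,
# epoch means in mg, trailing partial epoch dropped
avm_oracle <- function(rec, epoch_s = 1) {
  fs <- rec_rate(rec)
  enmo <- pmax(0, sqrt(rec$x^2 + rec$y^2 + rec$z^2) - 1)
  spe <- epoch_s * fs
  n_ep <- floor(length(enmo) / spe)
  vapply(seq_len(n_ep), function(i) {
    mean(enmo[((i - 1) * spe + 1):(i * spe)]) * 1000
  }, 0)
}

# full hypergeometric enumeration of the two-sided Fisher exact p for a 2x2
# table with fixed margins
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force epoch/walk containment oracle over a global epoch grid
containment_oracle <- function(walk_start, walk_end, epoch_len, grid_max) {
  starts <- seq(0, grid_max, by = epoch_len)
  starts[starts >= walk_start & starts + epoch_len <= walk_end]
}

# minimal one-walk profile used by several suites
one_walk_profile <- function(cadence = 107, dur = 120, cond = "normal",
                             amp = 0.4, seed = 7, duration_h = 0.2,
                             fs = 50, ...) {
  participant_profile(
    duration_h = duration_h, sample_rate_hz = fs,
    walk_segments = tibble::tibble(start_s = 120, duration_s = dur,
                                   cadence_spm = cadence,
                                   arm_swing_amplitude_g = amp,
                                   arm_condition = cond),
    seed = seed, ...)
}
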
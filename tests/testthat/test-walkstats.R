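test_that("intensity distributions reproduce printed-count percentages", {
  d <- intensity_distribution(253, 700, 1101)  # total 2054
  expect_equal(round(d$pct[d$class == "sedentary"], 1), 12.3)
  pooled <- intensity_distribution(7446, 8861, 19941)
  expect_equal(round(pooled$pct[c(1, 3)], 2), c(20.54, 55.01))
  expect_equal(pooled$pct[2], 24.44, tolerance = 1e-3)  # published value truncated
  z <- intensity_distribution(0, 0, 10)
  expect_equal(z$pct, c(0, 0, 100))
  expect_warning(intensity_distribution(0, 0, 0))
})

test_that("the Fisher test equals full hypergeometric enumeration", {
  # small worked case: (3 active, 1 sedentary) vs all-active has p = 1
  expect_equal(fisher_active_test(3, 1)$p_value, 1.0)
  expect_equal(fisher_active_test(10, 0)$p_value, 1.0)

  # oracle equivalence for all totals <= 50
  for (total in c(5, 12, 27, 50)) {
    for (sed in unique(c(0, 1, 3, total %/% 2, total))) {
      got <- fisher_active_test(total - sed, sed)
      expect_equal(got$p_value, fisher_enum_oracle(got$table), tolerance = 1e-12,
                   label = sprintf("total %d sed %d", total, sed))
    }
  }
  expect_error(fisher_active_test(-1, 3), class = "walkanchor_usage_error")
})

test_that("Fisher p decreases as misclassification grows at fixed total", {
  p <- vapply(0:30, function(s) fisher_active_test(60 - s, s)$p_value, 0)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("Bonferroni adjustment is capped, order-preserving and dominates raw p", {
  expect_equal(bonferroni(0.01, 35), 0.35)
  expect_equal(bonferroni(0.5, 35), 1.0)
  set.seed(40)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    adj <- bonferroni(p, length(p) + sample(0:5, 1))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= 0))  # monotone map (ties at the cap)
    expect_true(all(adj <= 1))
  }
  expect_error(bonferroni(1.2, 5), class = "walkanchor_usage_error")
  expect_error(bonferroni(c(0.1, 0.2), 1), class = "walkanchor_usage_error")
})

test_that("the clinical threshold converts epochs to minutes, inclusive at 20", {
  expect_equal(clinical_threshold(80), list(minutes = 20.0, exceeds = TRUE))
  expect_equal(clinical_threshold(79), list(minutes = 19.75, exceeds = FALSE))
  c867 <- clinical_threshold(867)
  expect_equal(c867$minutes, 216.75)
  expect_true(c867$exceeds)
})

test_that("AVM CoV matches the two-pass formula", {
  expect_equal(avm_cov(c(10, 10, 10)), 0)
  expect_equal(avm_cov(c(10, 20, 30)), 50)
  set.seed(41)
  v <- runif(500, 5, 200)
  expect_equal(avm_cov(v), sd(v) / mean(v) * 100, tolerance = 1e-9)
  expect_error(avm_cov(5), class = "walkanchor_usage_error")
  expect_warning(expect_true(is.na(avm_cov(c(0, 0, 0)))))
})

test_that("quartile groups have size ceiling(n/4) with deterministic ties", {
  set.seed(42)
  d35 <- tibble::tibble(participant_id = sprintf("P%02d", 1:35),
                        pct_sedentary = sample(seq(1, 70, by = 2), 35))
  q <- quartile_groups(d35)
  expect_equal(q$k, 9)
  expect_length(q$q1, 9)
  expect_length(q$q4, 9)
  expect_length(intersect(q$q1, q$q4), 0)
  expect_true(max(d35$pct_sedentary[d35$participant_id %in% q$q1]) <=
                min(d35$pct_sedentary[d35$participant_id %in% q$q4]))

  d8 <- tibble::tibble(participant_id = letters[1:8], pct_sedentary = 8:1)
  expect_equal(quartile_groups(d8)$k, 2)

  # ties at the boundary resolve by id, stably
  dt <- tibble::tibble(participant_id = c("b", "a", "d", "c", "e", "f"),
                       pct_sedentary = c(50, 50, 50, 10, 10, 10))
  q1 <- quartile_groups(dt)
  q2 <- quartile_groups(dt[sample(1:6), ])
  expect_equal(sort(q1$q4), sort(q2$q4))
  expect_equal(q1$q4, c("b", "d"))
})

test_that("pooled t reproduces the published group-comparison statistics", {
  avm <- pooled_t(37.5, 16.9, 9, 51.2, 9.4, 9)
  expect_equal(round(abs(avm$t), 2), 2.13)
  expect_equal(avm$df, 16)
  expect_lt(avm$p_value, 0.05)

  cad <- pooled_t(112.8, 10.7, 9, 105.8, 12.7, 9)
  expect_equal(round(abs(cad$t), 2), 1.26)

  time <- pooled_t(338.5, 156.1, 9, 218.9, 86.0, 9)
  expect_equal(round(abs(time$t), 2), 2.01)

  same <- pooled_t(5, 2, 6, 5, 2, 6)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  zero <- pooled_t(1, 0, 3, 1, 0, 3)
  expect_equal(zero$t, 0)
  expect_warning(pooled_t(1, 0, 3, 2, 0, 3))
})

test_that("cohort reports assemble Bonferroni-adjusted summaries and comparisons", {
  set.seed(43)
  mk_summary <- function(id, sed, total = 400) {
    lab <- factor(c(rep("sedentary", sed), rep("MVPA", total - sed)),
                  levels = c("sedentary", "light", "MVPA"), ordered = TRUE)
    labeled <- tibble::tibble(epoch_start_s = seq_len(total) * 15,
                              avm_mg = ifelse(lab == "sedentary", 5, 130),
                              label = lab, in_long_walk = TRUE, bout_id = 1L)
    bouts <- tibble::tibble(bout_id = 1L, start_s = 0, end_s = total * 15,
                            n_steps = 2L * total, median_cadence_spm = 105,
                            is_long = TRUE, is_all_walk = TRUE)
    participant_walk_summary(labeled, bouts, id)
  }
  # 10 of 12 participants exceed the 20-min (80-epoch) threshold
  sed_counts <- c(100, 150, 90, 200, 120, 85, 300, 250, 110, 95, 20, 10)
  summaries <- purrr::map_dfr(seq_along(sed_counts),
                              function(i) mk_summary(sprintf("P%02d", i), sed_counts[i]))
  rep <- cohort_report(summaries)
  expect_equal(nrow(rep$participants), 12)
  expect_equal(rep$n_exceeding, 10)
  expect_equal(round(rep$fraction_exceeding_pct, 1), 83.3)
  expect_equal(rep$participants$fisher_p_bonferroni,
               pmin(1, rep$participants$fisher_p * 12))
  expect_length(intersect(rep$quartiles$q1, rep$quartiles$q4), 0)
  expect_s3_class(rep$comparisons, "quartile_comparison")
  expect_true(all(rep$comparisons$df == 4))  # 3 + 3 - 2

  td <- tidy(rep)
  expect_equal(nrow(td), 12)
  gl <- glance(rep)
  expect_equal(gl$n_participants, 12)
})

test_that("per-participant summaries keep internal consistency", {
  sim <- simulate_participant(one_walk_profile(seed = 44, dur = 150))
  st <- detect_steps(sim$ankle)
  bouts <- flag_walks(build_bouts(st))
  lab <- label_walk_epochs(reepoch(compute_avm(sim$wrist, epoch_length_s = 1), 15), bouts)
  s <- participant_walk_summary(lab, bouts, "X")
  expect_equal(s$n_sedentary + s$n_light + s$n_mvpa, s$n_epochs)
  expect_equal(s$pct_sedentary + s$pct_light + s$pct_mvpa, 100, tolerance = 0.1)
  expect_equal(s$sedentary_misclassified_min, s$n_sedentary * 0.25)
})
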
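#' Intensity distribution as percentages
#'
#' Expresses per-class epoch counts within LONG walks as percentages of the
#' total.
#'
#' @param sedentary,light,mvpa Epoch counts per class.
#' @return A tibble with `class`, `n`, `pct`; `pct` is `NA` (with a warning)
#'   when the total is zero.
#' @export
#' @examples
#' intensity_distribution(253, 700, 1101)  # OA6-style counts
intensity_distribution <- function(sedentary, light, mvpa) {
  n <- c(sedentary = sedentary, light = light, mvpa = mvpa)
  if (any(n < 0)) abort("counts must be non-negative", class = "walkanchor_usage_error")
  total <- sum(n)
  if (total == 0) {
    warn("total epoch count is zero; percentages undefined")
    pct <- rep(NA_real_, 3)
  } else {
    pct <- as.numeric(n) / total * 100
  }
  tibble::tibble(class = factor(c("sedentary", "light", "MVPA"),
                                levels = c("sedentary", "light", "MVPA")),
                 n = as.numeric(n), pct = pct)
}

#' Fisher exact test against the all-active expectation
#'
#' Walking epochs are dichotomized into active (light or MVPA) versus
#' sedentary, and the observed split is compared with the expectation that
#' every epoch inside an ankle-defined walking bout should be active. The
#' 2x2 table pits the observed row `(n_active, n_sedentary)` against an
#' expected row of the same size with zero sedentary epochs; the two-sided
#' p value sums hypergeometric probabilities of tables no more probable than
#' the observed one.
#'
#' @param n_active Observed active (light + MVPA) epoch count.
#' @param n_sedentary Observed sedentary epoch count.
#' @return A list with `p_value`, `table`, `n`.
#' @export
#' @examples
#' fisher_active_test(1774, 31)$p_value  # < .001
fisher_active_test <- function(n_active, n_sedentary) {
  if (n_active < 0 || n_sedentary < 0) {
    abort("counts must be non-negative", class = "walkanchor_usage_error")
  }
  total <- n_active + n_sedentary
  if (total == 0) abort("at least one epoch required", class = "walkanchor_usage_error")
  tab <- matrix(c(n_active, n_sedentary, total, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("observed", "expected"), c("active", "sedentary")))
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  list(p_value = p, table = tab, n = total)
}

#' Bonferroni correction
#'
#' @param p Vector of raw p values in \[0, 1\].
#' @param m Number of tests in the family; must be at least `length(p)`.
#'   Defaults to `length(p)`.
#' @return Adjusted p values `pmin(1, p * m)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p values must lie in [0, 1]", class = "walkanchor_usage_error")
  }
  if (m < length(p)) {
    abort("m must be at least the number of p values", class = "walkanchor_usage_error")
  }
  pmin(1, p * m)
}

#' Clinically important sedentary-misclassification threshold
#'
#' Converts a count of sedentary-labelled 15-s epochs within LONG walks to
#' minutes and compares against the clinical threshold: 20 minutes of
#' misclassified walking corresponds to roughly one day's worth of the
#' recommended 150 weekly MVPA minutes over a week-long collection. The
#' threshold is inclusive at exactly 20 minutes.
#'
#' @param n_sedentary_epochs Count of sedentary 15-s epochs.
#' @param threshold_min Threshold in minutes; default 20.
#' @return A list with `minutes` and `exceeds`.
#' @export
#' @examples
#' clinical_threshold(80)   # 20.0 min, exceeds
#' clinical_threshold(867)  # 216.75 min, exceeds
clinical_threshold <- function(n_sedentary_epochs, threshold_min = 20) {
  stopifnot(n_sedentary_epochs >= 0)
  minutes <- n_sedentary_epochs * 0.25
  list(minutes = minutes, exceeds = minutes >= threshold_min)
}

#' AVM coefficient of variation
#'
#' Sample standard deviation divided by the mean, times 100, over a
#' participant's 15-s LONG-walk AVM epochs — an index of how variable the
#' wrist moved across walking.
#'
#' @param avm_mg AVM values (mg); at least two, with positive mean.
#' @return CoV in percent; `NA` with a warning when the mean is zero.
#' @export
#' @examples
#' avm_cov(c(10, 20, 30))  # 50
avm_cov <- function(avm_mg) {
  if (length(avm_mg) < 2) {
    abort("CoV requires at least two epochs", class = "walkanchor_usage_error")
  }
  m <- mean(avm_mg)
  if (m <= 0) {
    warn("mean AVM is zero; CoV undefined")
    return(NA_real_)
  }
  sd(avm_mg) / m * 100
}

#' Quartile groups of percent-sedentary
#'
#' Stratifies participants by the percent of LONG-walk epochs classified
#' sedentary and returns the extreme quartile groups: SED_Q1 (lowest) and
#' SED_Q4 (highest), each of size `ceiling(n / 4)` (9 of 35 in the study
#' design). Ties at a boundary are broken by participant id so membership is
#' deterministic.
#'
#' @param data A data frame with columns `participant_id` and
#'   `pct_sedentary`.
#' @return A list with character vectors `q1` and `q4` of participant ids,
#'   and `k` the group size.
#' @export
quartile_groups <- function(data) {
  n <- nrow(data)
  if (n < 4) abort("need at least 4 participants", class = "walkanchor_usage_error")
  k <- ceiling(n / 4)
  ord <- order(data$pct_sedentary, data$participant_id)
  ids <- data$participant_id[ord]
  list(q1 = ids[seq_len(k)], q4 = ids[seq(n - k + 1, n)], k = k)
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Student's t with pooled variance, computed from group means, standard
#' deviations and sizes; two-sided p on `n1 + n2 - 2` degrees of freedom.
#' When the pooled variance is zero, equal means give `t = 0`, unequal means
#' give an infinite statistic (flagged by a warning).
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A one-row tibble: `t`, `df`, `p_value`.
#' @export
#' @examples
#' pooled_t(37.5, 16.9, 9, 51.2, 9.4, 9)  # |t| = 2.13, df = 16
pooled_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2) {
      return(tibble::tibble(t = 0, df = df, p_value = 1))
    }
    warn("zero pooled variance with unequal means; t is infinite")
    return(tibble::tibble(t = sign(mean1 - mean2) * Inf, df = df, p_value = 0))
  }
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble::tibble(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Summarize one participant's LONG-walk misclassification
#'
#' Combines labelled LONG-walk epochs and flagged bouts into the
#' per-participant record used throughout the group analysis: epoch counts
#' and percentages per intensity class, sedentary-misclassified minutes and
#' the clinical-threshold flag, the AVM coefficient of variation, and the
#' Fisher exact test against the all-active expectation (unadjusted; see
#' [cohort_report()] for the Bonferroni family correction).
#'
#' @param labeled A `labeled_epochs` tibble from [label_walk_epochs()].
#' @param bouts Flagged bouts from [flag_walks()].
#' @param participant_id Identifier string.
#' @param config A [walk_config()].
#' @return A one-row `participant_walk_summary` tibble.
#' @export
participant_walk_summary <- function(labeled, bouts, participant_id = "P1",
                                     config = walk_config()) {
  long <- dplyr::filter(bouts, .data$is_long)
  n_sed <- sum(labeled$label == "sedentary")
  n_light <- sum(labeled$label == "light")
  n_mvpa <- sum(labeled$label == "MVPA")
  total <- nrow(labeled)
  clin <- clinical_threshold(n_sed, config$clinical_threshold_min)
  fisher_p <- if (total > 0) fisher_active_test(n_light + n_mvpa, n_sed)$p_value else NA_real_
  tibble::tibble(
    participant_id = participant_id,
    n_long_walks = nrow(long),
    long_walk_minutes = sum(long$end_s - long$start_s) / 60,
    median_cadence_spm = median(long$median_cadence_spm),
    n_epochs = total,
    n_sedentary = n_sed, n_light = n_light, n_mvpa = n_mvpa,
    pct_sedentary = if (total > 0) n_sed / total * 100 else NA_real_,
    pct_light = if (total > 0) n_light / total * 100 else NA_real_,
    pct_mvpa = if (total > 0) n_mvpa / total * 100 else NA_real_,
    sedentary_misclassified_min = clin$minutes,
    exceeds_clinical_threshold = clin$exceeds,
    avm_cov_pct = if (total >= 2) avm_cov(labeled$avm_mg) else NA_real_,
    fisher_p = fisher_p)
}

#' Cohort-level report: Fisher family, clinical-threshold fraction and
#' quartile comparison
#'
#' Applies the Bonferroni correction across the per-participant Fisher
#' tests (one test per participant is the family), records the count and
#' fraction of participants whose sedentary-misclassified walking time
#' reaches the clinical threshold, forms SED_Q1/SED_Q4 quartile groups on
#' percent-sedentary, and runs pooled two-sample t tests between the groups
#' for the requested variables.
#'
#' @param summaries A row-bound tibble of [participant_walk_summary()]
#'   results.
#' @param compare_vars Columns of `summaries` to compare between SED_Q1 and
#'   SED_Q4.
#' @param config A [walk_config()].
#' @return A `walk_cohort_report` list: `participants` (with
#'   `fisher_p_bonferroni` added), `n_exceeding`, `fraction_exceeding_pct`,
#'   `quartiles`, and `comparisons` (class `quartile_comparison`).
#' @export
cohort_report <- function(summaries,
                          compare_vars = c("n_long_walks", "long_walk_minutes",
                                           "median_cadence_spm", "avm_cov_pct"),
                          config = walk_config()) {
  m <- nrow(summaries)
  summaries$fisher_p_bonferroni <- bonferroni(summaries$fisher_p, m)
  n_exceed <- sum(summaries$exceeds_clinical_threshold)
  qt <- if (m >= 4) quartile_groups(summaries) else NULL
  comparisons <- NULL
  if (!is.null(qt)) {
    g1 <- dplyr::filter(summaries, .data$participant_id %in% qt$q1)
    g4 <- dplyr::filter(summaries, .data$participant_id %in% qt$q4)
    comparisons <- purrr::map_dfr(compare_vars, function(v) {
      x1 <- g1[[v]]; x4 <- g4[[v]]
      tt <- pooled_t(mean(x1), sd(x1), length(x1), mean(x4), sd(x4), length(x4))
      tibble::tibble(variable = v,
                     mean_q1 = mean(x1), sd_q1 = sd(x1), n_q1 = length(x1),
                     mean_q4 = mean(x4), sd_q4 = sd(x4), n_q4 = length(x4),
                     t = tt$t, df = tt$df, p_value = tt$p_value)
    })
    class(comparisons) <- c("quartile_comparison", class(comparisons))
  }
  structure(list(participants = summaries,
                 n_exceeding = n_exceed,
                 fraction_exceeding_pct = n_exceed / m * 100,
                 quartiles = qt,
                 comparisons = comparisons),
            class = "walk_cohort_report")
}

#' @export
print.walk_cohort_report <- function(x, ...) {
  cat(sprintf("<walk_cohort_report> %d participants; %d (%.1f%%) at/above the clinical threshold\n",
              nrow(x$participants), x$n_exceeding, x$fraction_exceeding_pct))
  if (!is.null(x$comparisons)) {
    cat("SED_Q1 vs SED_Q4 comparisons:\n")
    print(tibble::as_tibble(x$comparisons))
  }
  invisible(x)
}

#' @rdname tidy-walkanchor
#' @export
tidy.walk_cohort_report <- function(x, ...) tibble::as_tibble(x$participants)

#' Tidiers for walkanchor result objects
#'
#' `tidy()` returns the per-participant table of a cohort report or the
#' per-variable rows of a quartile comparison; `glance()` returns one-row
#' cohort-level summaries.
#'
#' @param x A `walk_cohort_report` or `quartile_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy-walkanchor
NULL

#' @rdname tidy-walkanchor
#' @export
glance.walk_cohort_report <- function(x, ...) {
  p <- x$participants
  tibble::tibble(n_participants = nrow(p),
                 n_exceeding = x$n_exceeding,
                 fraction_exceeding_pct = x$fraction_exceeding_pct,
                 mean_pct_sedentary = mean(p$pct_sedentary, na.rm = TRUE),
                 mean_pct_mvpa = mean(p$pct_mvpa, na.rm = TRUE),
                 all_fisher_significant = all(p$fisher_p_bonferroni < 0.05, na.rm = TRUE))
}

#' @rdname tidy-walkanchor
#' @export
tidy.quartile_comparison <- function(x, ...) tibble::as_tibble(unclass(x))
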
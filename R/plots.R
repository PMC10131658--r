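#' Plot an AVM epoch series
#'
#' @param object An `avm_epochs` series.
#' @param cuts Optional [intensity_cut_points()] drawn as horizontal lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.avm_epochs <- function(object, cuts = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$epoch_start_s / 3600,
                                    y = .data$avm_mg)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (h)", y = "AVM (mg)",
                  title = sprintf("%g-s AVM epochs", attr(object, "epoch_length_s"))) +
    ggplot2::theme_minimal()
  if (!is.null(cuts)) {
    p <- p + ggplot2::geom_hline(yintercept = c(cuts$light_threshold_mg,
                                                cuts$moderate_threshold_mg),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a raw triaxial recording
#'
#' @param object A [triax_recording()].
#' @param from_s,to_s Optional time window (s) to display.
#' @param ... Unused.
#' @return A ggplot with one facet per axis.
#' @export
autoplot.triax_recording <- function(object, from_s = NULL, to_s = NULL, ...) {
  df <- tibble::as_tibble(object)
  df$time_s <- rec_times(object)
  if (!is.null(from_s)) df <- dplyr::filter(df, .data$time_s >= from_s)
  if (!is.null(to_s)) df <- dplyr::filter(df, .data$time_s <= to_s)
  df <- tidyr::pivot_longer(df, c("x", "y", "z"), names_to = "axis",
                            values_to = "acceleration_g")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$acceleration_g)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    ggplot2::labs(x = "Time (s)", y = "Acceleration (g)",
                  title = sprintf("%s recording", rec_site(object))) +
    ggplot2::theme_minimal()
}

#' Stacked per-participant intensity distribution within LONG walks
#'
#' The cohort analogue of a per-participant stacked bar chart: percent of
#' LONG-walk epochs per intensity class, one bar per participant, ordered by
#' percent sedentary.
#'
#' @param object A `walk_cohort_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.walk_cohort_report <- function(object, ...) {
  df <- tibble::as_tibble(object$participants) |>
    dplyr::select("participant_id", "pct_sedentary", "pct_light", "pct_mvpa") |>
    tidyr::pivot_longer(-"participant_id", names_to = "class",
                        names_prefix = "pct_", values_to = "pct") |>
    dplyr::mutate(class = factor(.data$class,
                                 levels = c("mvpa", "light", "sedentary"),
                                 labels = c("MVPA", "light", "sedentary")))
  ord <- object$participants$participant_id[order(object$participants$pct_sedentary)]
  df$participant_id <- factor(df$participant_id, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$participant_id, y = .data$pct,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(MVPA = "#1b9e77", light = "#7570b3",
                                          sedentary = "#d95f02")) +
    ggplot2::labs(x = NULL, y = "% of LONG-walk epochs", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot walking bouts over time
#'
#' @param bouts A bout table from [build_bouts()] / [flag_walks()].
#' @return A ggplot of bout spans coloured by LONG status.
#' @export
plot_bouts <- function(bouts) {
  df <- tibble::as_tibble(bouts)
  df$kind <- ifelse(df$is_long %in% TRUE, "LONG", "other")
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start_s / 3600,
                                       xend = .data$end_s / 3600,
                                       y = .data$median_cadence_spm,
                                       yend = .data$median_cadence_spm,
                                       colour = .data$kind),
                          linewidth = 2) +
    ggplot2::labs(x = "Time (h)", y = "Median cadence (spm)", colour = NULL) +
    ggplot2::theme_minimal()
}
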
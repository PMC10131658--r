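#' Pipeline configuration
#'
#' Assembles the full set of tunable parameters used by the pipeline: epoch
#' lengths, walking-bout criteria, valid-day and clinical thresholds, and the
#' intensity cut points. Defaults follow the study protocol the package
#' implements: 1-s base epochs reaveraged to 15 s, bouts broken by rests
#' longer than 5 s, LONG walks of at least 60 s with median cadence above
#' 80 steps/min, ALL walks of at least 5 steps, valid days with at least 10 h
#' of waking wear, and a clinically important threshold of 20 sedentary
#' minutes during walking.
#'
#' The cut points shipped here are package defaults chosen for the synthetic
#' simulations; deployments analysing real data must transcribe the published
#' older-adult wrist AVM cut points into the configuration (see
#' [intensity_cut_points()]).
#'
#' @param epoch_short_s Base epoch length (s).
#' @param epoch_long_s Analysis epoch length (s); must be an integer multiple
#'   of `epoch_short_s`.
#' @param bout_max_rest_s Maximum within-bout rest between steps (s),
#'   inclusive.
#' @param long_walk_min_s Minimum LONG-walk duration (s).
#' @param long_walk_min_cadence_spm LONG walks require median cadence strictly
#'   above this (steps/min).
#' @param all_walk_min_steps Minimum steps for an ALL walk.
#' @param valid_day_min_wear_h Minimum waking wear (h) for a valid day.
#' @param clinical_threshold_min Sedentary walking minutes considered
#'   clinically important (inclusive).
#' @param cut_points An [intensity_cut_points()] object.
#' @param seed Integer seed for any stochastic stage.
#'
#' @return A `walk_config` list.
#' @export
walk_config <- function(epoch_short_s = 1,
                        epoch_long_s = 15,
                        bout_max_rest_s = 5,
                        long_walk_min_s = 60,
                        long_walk_min_cadence_spm = 80,
                        all_walk_min_steps = 5,
                        valid_day_min_wear_h = 10,
                        clinical_threshold_min = 20,
                        cut_points = intensity_cut_points(),
                        seed = 1L) {
  cfg <- list(epoch_short_s = epoch_short_s,
              epoch_long_s = epoch_long_s,
              bout_max_rest_s = bout_max_rest_s,
              long_walk_min_s = long_walk_min_s,
              long_walk_min_cadence_spm = long_walk_min_cadence_spm,
              all_walk_min_steps = all_walk_min_steps,
              valid_day_min_wear_h = valid_day_min_wear_h,
              clinical_threshold_min = clinical_threshold_min,
              cut_points = cut_points,
              seed = as.integer(seed))
  validate_walk_config(cfg)
  structure(cfg, class = "walk_config")
}

validate_walk_config <- function(cfg) {
  num <- c("epoch_short_s", "epoch_long_s", "bout_max_rest_s", "long_walk_min_s",
           "long_walk_min_cadence_spm", "all_walk_min_steps",
           "valid_day_min_wear_h", "clinical_threshold_min")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(sprintf("config field '%s' must be a single positive number", f),
            class = "walkanchor_config_error")
    }
  }
  ratio <- cfg$epoch_long_s / cfg$epoch_short_s
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort("epoch_long_s must be an integer multiple of epoch_short_s",
          class = "walkanchor_config_error")
  }
  validate_cut_points(cfg$cut_points)
  invisible(cfg)
}

#' Intensity cut points on the AVM scale
#'
#' Thresholds (in milli-g) separating sedentary from light and light from
#' moderate activity, applied to 15-s wrist AVM epochs. The upper class is
#' lower-inclusive: an epoch exactly at a threshold takes the higher label.
#'
#' The defaults (light at 30 mg, moderate at 100 mg) are placeholder values
#' calibrated to the package's synthetic signal generator. They are *not* the
#' published older-adult cut points, which must be transcribed from their
#' source into the configuration when analysing real data; the `provenance`
#' field exists to record where the deployed values came from.
#'
#' @param light_threshold_mg AVM (mg) at/above which an epoch is at least
#'   light.
#' @param moderate_threshold_mg AVM (mg) at/above which an epoch is MVPA.
#' @param provenance Free-text note on where the values came from.
#' @return An `intensity_cut_points` list.
#' @export
#' @examples
#' cuts <- intensity_cut_points(30, 100)
#' classify_epoch(c(0, 30, 99, 100), cuts)
intensity_cut_points <- function(light_threshold_mg = 30,
                                 moderate_threshold_mg = 100,
                                 provenance = paste(
                                   "walkanchor synthetic defaults;",
                                   "replace with published older-adult wrist AVM cut points",
                                   "for real-data analyses")) {
  cp <- structure(list(light_threshold_mg = light_threshold_mg,
                       moderate_threshold_mg = moderate_threshold_mg,
                       provenance = provenance),
                  class = "intensity_cut_points")
  validate_cut_points(cp)
  cp
}

validate_cut_points <- function(cp) {
  ok <- is.numeric(cp$light_threshold_mg) && is.numeric(cp$moderate_threshold_mg) &&
    length(cp$light_threshold_mg) == 1 && length(cp$moderate_threshold_mg) == 1 &&
    cp$light_threshold_mg > 0 && cp$light_threshold_mg < cp$moderate_threshold_mg
  if (!ok) {
    abort("cut points must satisfy 0 < light_threshold_mg < moderate_threshold_mg",
          class = "walkanchor_config_error")
  }
  invisible(cp)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path File path.
#' @param config A [walk_config()].
#' @return `read_walk_config()` returns a `walk_config`;
#'   `write_walk_config()` returns `path` invisibly.
#' @export
read_walk_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cp <- raw$cut_points
  raw$cut_points <- NULL
  args <- raw
  if (!is.null(cp)) {
    args$cut_points <- intensity_cut_points(
      light_threshold_mg = cp$light_mg,
      moderate_threshold_mg = cp$moderate_mg,
      provenance = cp$provenance %||% "unspecified")
  }
  do.call(walk_config, args)
}

#' @rdname read_walk_config
#' @export
write_walk_config <- function(config, path) {
  validate_walk_config(config)
  lst <- unclass(config)
  cp <- lst$cut_points
  lst$cut_points <- list(light_mg = cp$light_threshold_mg,
                         moderate_mg = cp$moderate_threshold_mg,
                         provenance = cp$provenance)
  yaml::write_yaml(lst, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
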
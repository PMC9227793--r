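#' Scoring-engine configuration
#'
#' Collects every tunable threshold of the scoring pipeline in one validated
#' list. Defaults follow the monitoring protocol's standard constants
#' where one exists (30-minute replacement window, 30/60-minute meal window
#' around a levodopa intake, 14-day summary window, >70 / 30-70 / <30 bands);
#' the remaining values are the package's own documented choices.
#'
#' @param replacement_window_min minutes around a planned intake within which
#'   an extra dose counts as a replacement of that intake. Default 30.
#' @param deviation_max_min deviation (minutes) at which the per-occasion
#'   medication score reaches 0 under the linear decay mapping. Default 120.
#' @param replacement_counts how a replacement extra dose enters the daily
#'   medication mean: `"deviation"` (scored by its own timing deviation,
#'   default) or `"omit"` (excluded from the daily mean entirely).
#' @param min_interruption_gap_min shortest out-of-bed gap (minutes) counted
#'   as a sleep interruption; shorter gaps are treated as sensor jitter and
#'   merged. Default 1.
#' @param night_chain_gap_h bed intervals separated by less than this many
#'   hours are chained into one sleep episode. Default 4.
#' @param night_start_after_h,night_start_before_h an episode is treated as a
#'   night only if it starts after `night_start_after_h` o'clock or before
#'   `night_start_before_h` o'clock (defaults 18 and 12); episodes starting in
#'   the early afternoon are naps and are not scored.
#' @param meal_window_before_min,meal_window_after_min the protected window
#'   around each levodopa intake: `before` minutes before to `after` minutes
#'   after. Defaults 30 and 60.
#' @param meal_window_mode `"avoid"` (default): a meal complies when it falls
#'   inside no intake's protected window (levodopa competes with dietary
#'   protein, so meals should keep clear of intakes). `"require"`: the reading
#'   in which a meal must fall inside such a window to comply.
#' @param rolling_window_days window for [rolling_summary()]. Default 14.
#'
#' @return A named list of class `parkscore_config`.
#' @seealso [read_engine_config()] to load the same keys from a YAML file.
#' @export
#' @examples
#' cfg <- engine_config(deviation_max_min = 90)
#' cfg$deviation_max_min
engine_config <- function(replacement_window_min = 30,
                          deviation_max_min = 120,
                          replacement_counts = c("deviation", "omit"),
                          min_interruption_gap_min = 1,
                          night_chain_gap_h = 4,
                          night_start_after_h = 18,
                          night_start_before_h = 12,
                          meal_window_before_min = 30,
                          meal_window_after_min = 60,
                          meal_window_mode = c("avoid", "require"),
                          rolling_window_days = 14) {
  replacement_counts <- match.arg(replacement_counts)
  meal_window_mode <- match.arg(meal_window_mode)
  cfg <- list(
    replacement_window_min = replacement_window_min,
    deviation_max_min = deviation_max_min,
    replacement_counts = replacement_counts,
    min_interruption_gap_min = min_interruption_gap_min,
    night_chain_gap_h = night_chain_gap_h,
    night_start_after_h = night_start_after_h,
    night_start_before_h = night_start_before_h,
    meal_window_before_min = meal_window_before_min,
    meal_window_after_min = meal_window_after_min,
    meal_window_mode = meal_window_mode,
    rolling_window_days = rolling_window_days
  )
  validate_engine_config(cfg)
}

validate_engine_config <- function(cfg) {
  chk_pos <- function(key, allow_zero = FALSE) {
    v <- cfg[[key]]
    ok <- is.numeric(v) && length(v) == 1 && is.finite(v) &&
      (v > 0 || (allow_zero && v >= 0))
    if (!ok) {
      abort(sprintf("config key '%s' must be a single %s number, got %s",
                    key, if (allow_zero) "non-negative" else "positive",
                    paste(format(v), collapse = ",")),
            class = "parkscore_config_error")
    }
  }
  chk_pos("replacement_window_min", allow_zero = TRUE)
  chk_pos("deviation_max_min")
  chk_pos("min_interruption_gap_min", allow_zero = TRUE)
  chk_pos("night_chain_gap_h")
  chk_pos("meal_window_before_min", allow_zero = TRUE)
  chk_pos("meal_window_after_min", allow_zero = TRUE)
  chk_pos("rolling_window_days")
  if (cfg$rolling_window_days != round(cfg$rolling_window_days)) {
    abort("config key 'rolling_window_days' must be a whole number",
          class = "parkscore_config_error")
  }
  for (key in c("night_start_after_h", "night_start_before_h")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 24) {
      abort(sprintf("config key '%s' must be an hour in [0, 24]", key),
            class = "parkscore_config_error")
    }
  }
  if (!cfg$replacement_counts %in% c("deviation", "omit")) {
    abort("config key 'replacement_counts' must be 'deviation' or 'omit'",
          class = "parkscore_config_error")
  }
  if (!cfg$meal_window_mode %in% c("avoid", "require")) {
    abort("config key 'meal_window_mode' must be 'avoid' or 'require'",
          class = "parkscore_config_error")
  }
  structure(cfg, class = "parkscore_config")
}

#' Load an engine configuration from YAML
#'
#' Reads a YAML mapping whose keys are the arguments of [engine_config()];
#' unknown keys are an error, missing keys take their defaults, and every
#' value is validated against its documented range.
#'
#' @param path path to a YAML file.
#' @return A `parkscore_config` list.
#' @export
read_engine_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(engine_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s (valid keys: %s)",
                  paste(unknown, collapse = ", "),
                  paste(known, collapse = ", ")),
          class = "parkscore_config_error")
  }
  do.call(engine_config, raw)
}

#' @export
print.parkscore_config <- function(x, ...) {
  cat("<parkscore engine config>\n")
  for (key in names(x)) cat(sprintf("  %-26s %s\n", key, format(x[[key]])))
  invisible(x)
}
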
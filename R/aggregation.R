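# Per-day score assembly, rolling summaries, traffic-light bands and lagged
# cross-score correlation.

SCORE_COLUMNS <- c("medication", "sleep", "bradykinesia", "dyskinesia",
                   "meal", "exercise", "overall_day")

#' Assemble one day's stream results into a daily-summary row
#'
#' Joins the per-stream one-row results for a single calendar day into one
#' row of the daily score table. Absent streams stay missing — a score is
#' never imputed from other streams.
#'
#' @param date the calendar date.
#' @param medication output of [daily_medication_score()] (or `NULL`).
#' @param sleep a one-row tibble with a `sleep` column (or `NULL`).
#' @param motor output of [daily_motor_scores()] (or `NULL`).
#' @param meal output of [meal_timing_score()] (or `NULL`).
#' @param exercise output of [physical_activity_score()] (or `NULL`).
#' @param qol output of [qol_daily()] (or `NULL`).
#' @return One row with columns `date, medication, sleep, bradykinesia,
#'   dyskinesia, meal, exercise, overall_day, qol_q1..qol_q8`.
#' @export
assemble_daily_summary <- function(date, medication = NULL, sleep = NULL,
                                   motor = NULL, meal = NULL, exercise = NULL,
                                   qol = NULL) {
  row <- tibble::tibble(date = as.Date(date))
  row$medication <- if (is.null(medication)) NA_real_ else medication$medication
  row$sleep <- if (is.null(sleep)) NA_real_ else sleep$sleep
  row$bradykinesia <- if (is.null(motor)) NA_real_ else motor$bradykinesia
  row$dyskinesia <- if (is.null(motor)) NA_real_ else motor$dyskinesia
  row$meal <- if (is.null(meal)) NA_real_ else meal$meal
  row$exercise <- if (is.null(exercise)) NA_real_ else exercise$exercise
  if (is.null(qol)) {
    row$overall_day <- NA_real_
    for (i in 1:8) row[[paste0("qol_q", i)]] <- NA_integer_
  } else {
    row$overall_day <- qol$overall_day
    for (i in 1:8) row[[paste0("qol_q", i)]] <- qol[[paste0("qol_q", i)]]
  }
  row[c("date", SCORE_COLUMNS[1:6], "overall_day", paste0("qol_q", 1:8))]
}

#' Score a full scenario per calendar day
#'
#' Runs the complete pipeline: partitions the streams by day (nights to their
#' wake day), scores each stream, and assembles one row per date between the
#' first and last event. Every score lies in \[0, 100\] or is `NA` when its
#' stream is absent that day; empty days are retained so the time axis stays
#' contiguous.
#'
#' @param scenario a [scenario()].
#' @param config an [engine_config()].
#' @return A tibble of daily scores, columns `date, medication, sleep,
#'   bradykinesia, dyskinesia, meal, exercise, overall_day, qol_q1..qol_q8`.
#' @export
#' @examples
#' sim <- simulate_scenario(sim_config(seed = 1, days = 3))
#' score_scenario(sim$scenario)
score_scenario <- function(scenario, config = engine_config()) {
  stopifnot(inherits(scenario, "parkscore_scenario"))
  days <- partition_by_day(scenario, config)
  if (length(days) == 0) {
    return(assemble_daily_summary(as.Date(character()))[0, ])
  }
  rows <- lapply(days, function(day) {
    med <- if (nrow(day$planned_doses) + nrow(day$taken_doses) > 0) {
      score_medication_day(day$planned_doses, day$taken_doses, config)
    }
    slp <- if (nrow(day$nights) > 0) score_sleep_day(day$nights)
    mot <- if (nrow(day$motor_samples) > 0) {
      daily_motor_scores(day$motor_samples, day$date)
    }
    ml <- if (nrow(day$meals) > 0) {
      meal_timing_score(day$meals, day$taken_doses, config)
    }
    ex <- if (nrow(day$exercise) > 0) {
      physical_activity_score(day$exercise, scenario$patient_target)
    }
    q <- if (nrow(day$qol) > 0) qol_daily(day$qol)
    assemble_daily_summary(day$date, medication = med, sleep = slp,
                           motor = mot, meal = ml, exercise = ex, qol = q)
  })
  dplyr::bind_rows(rows)
}

#' Rolling per-score means
#'
#' Mean of each score over the last `window_days` calendar days (the
#' patient start page shows the 14-day means), excluding missing days
#' score-by-score; a score missing on every day of the window stays missing.
#'
#' @param rows daily score table from [score_scenario()].
#' @param window_days number of trailing days. Default from `config`.
#' @param config an [engine_config()].
#' @return One-row tibble of per-score means over the window, plus
#'   `window_start` and `window_end` dates.
#' @export
rolling_summary <- function(rows, window_days = NULL,
                            config = engine_config()) {
  window_days <- window_days %||% config$rolling_window_days
  if (!is.numeric(window_days) || window_days < 1) {
    abort("window_days must be at least 1",
          class = "parkscore_validation_error")
  }
  rows <- rows[order(rows$date), , drop = FALSE]
  if (nrow(rows) == 0) {
    abort("no daily rows to summarise", class = "parkscore_validation_error")
  }
  window_end <- max(rows$date)
  window_start <- window_end - window_days + 1
  win <- rows[rows$date >= window_start, , drop = FALSE]
  out <- tibble::tibble(window_start = window_start, window_end = window_end)
  for (col in SCORE_COLUMNS) {
    v <- win[[col]]
    out[[col]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out
}

#' Traffic-light band of a score
#'
#' Scores above 70 are good (green), scores from 30 to 70 inclusive are
#' average (gray), scores below 30 are bad (orange). Missing scores get a
#' missing band.
#'
#' @param value numeric vector of scores in \[0, 100\] (`NA` allowed).
#' @return A tibble with `value`, `band` (factor good/average/bad) and
#'   `color` (factor green/gray/orange).
#' @export
#' @examples
#' classify_score(c(85, 70, 12, NA))
classify_score <- function(value) {
  if (any(!is.na(value) & (value < 0 | value > 100))) {
    abort("scores must lie in [0, 100]", class = "parkscore_validation_error")
  }
  band <- dplyr::case_when(
    is.na(value) ~ NA_character_,
    value > 70 ~ "good",
    value >= 30 ~ "average",
    TRUE ~ "bad"
  )
  color <- c(good = "green", average = "gray", bad = "orange")[band]
  tibble::tibble(
    value = value,
    band = factor(band, levels = c("good", "average", "bad")),
    color = factor(unname(color), levels = c("green", "gray", "orange"))
  )
}

#' Correlate two daily scores, optionally at a lag
#'
#' Pairs score `x` on day `d` with score `y` on day `d + lag_days` over all
#' pairwise-complete days and reports the correlation coefficient (Pearson by
#' default, Spearman by flag) together with the number of pairs and the day
#' range used. Supports questions such as whether medication compliance on
#' one day tracks the motor scores of the same or a later day.
#'
#' @param rows daily score table from [score_scenario()].
#' @param x,y score column names (one of `medication, sleep, bradykinesia,
#'   dyskinesia, meal, exercise, overall_day`).
#' @param lag_days integer lag applied to `y` (0 = same day).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list of class `parkscore_correlation`: `coefficient`, `n_pairs`,
#'   `x`, `y`, `lag_days`, `method`, `window_start`, `window_end`.
#' @export
#' @examples
#' sim <- simulate_scenario(sim_config(seed = 7, days = 21))
#' rows <- score_scenario(sim$scenario)
#' correlate_scores(rows, "medication", "bradykinesia")
correlate_scores <- function(rows, x, y, lag_days = 0L,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  valid <- c(SCORE_COLUMNS, paste0("qol_q", 1:8))
  for (name in c(x, y)) {
    if (!name %in% valid) {
      abort(sprintf("unknown score name '%s'; valid names: %s", name,
                    paste(valid, collapse = ", ")),
            class = "parkscore_validation_error")
    }
  }
  if (lag_days != round(lag_days)) {
    abort("lag_days must be a whole number of days",
          class = "parkscore_validation_error")
  }
  rows <- rows[order(rows$date), , drop = FALSE]
  shifted <- rows[, c("date", y)]
  shifted$date <- shifted$date - lag_days  # y of day d+lag aligned to day d
  names(shifted)[2] <- ".y"
  aligned <- dplyr::inner_join(rows[, c("date", x)], shifted, by = "date")
  names(aligned)[2] <- ".x"
  complete <- aligned[!is.na(aligned$.x) & !is.na(aligned$.y), , drop = FALSE]
  if (nrow(complete) < 3) {
    abort(sprintf(
      "insufficient data: %d complete (%s, %s) pairs at lag %d; need at least 3",
      nrow(complete), x, y, lag_days),
      class = "parkscore_insufficient_data")
  }
  structure(list(
    coefficient = cor(complete$.x, complete$.y, method = method),
    n_pairs = nrow(complete),
    x = x, y = y, lag_days = as.integer(lag_days), method = method,
    window_start = min(complete$date), window_end = max(complete$date)
  ), class = "parkscore_correlation")
}

#' @export
print.parkscore_correlation <- function(x, ...) {
  cat(sprintf("<correlation %s vs %s (lag %d d): %s r = %.3f, n = %d, %s..%s>\n",
              x$x, x$y, x$lag_days, x$method, x$coefficient, x$n_pairs,
              format(x$window_start), format(x$window_end)))
  invisible(x)
}

#' Write the daily score table as CSV
#'
#' Columns exactly `date, medication, sleep, bradykinesia, dyskinesia, meal,
#' exercise, overall_day, qol_q1..qol_q8`; missing scores become empty cells.
#'
#' @param rows daily score table from [score_scenario()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(rows, path) {
  out <- as.data.frame(rows)
  out$date <- format(out$date)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a daily score table written by [write_scores_csv()]
#'
#' @param path CSV file path.
#' @return A daily score tibble.
#' @export
read_scores_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", SCORE_COLUMNS[1:6], "overall_day", paste0("qol_q", 1:8))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("scores file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "parkscore_parse_error")
  }
  df$date <- parse_date(df$date, "date")
  tibble::as_tibble(df[need])
}
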
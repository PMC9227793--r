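# Typed in-memory model of the six raw input streams. Each stream is a tibble
# with a fixed column contract; a scenario bundles all six for one patient.

STREAM_NAMES <- c("planned_doses", "taken_doses", "bed_intervals",
                  "motor_samples", "meals", "exercise", "qol")

stream_columns <- list(
  planned_doses = c("time", "dose"),
  taken_doses   = c("time", "dose", "source"),
  bed_intervals = c("enter", "leave"),
  motor_samples = c("time", "bradykinesia", "dyskinesia"),
  meals         = c("time"),
  exercise      = c("time", "mode", "duration"),
  qol           = c("date", paste0("q", 1:8), "vas")
)

empty_stream <- function(name) {
  switch(name,
    planned_doses = tibble::tibble(time = as.POSIXct(character(), tz = .TZ),
                                   dose = numeric()),
    taken_doses   = tibble::tibble(time = as.POSIXct(character(), tz = .TZ),
                                   dose = numeric(), source = character()),
    bed_intervals = tibble::tibble(enter = as.POSIXct(character(), tz = .TZ),
                                   leave = as.POSIXct(character(), tz = .TZ)),
    motor_samples = tibble::tibble(time = as.POSIXct(character(), tz = .TZ),
                                   bradykinesia = numeric(),
                                   dyskinesia = numeric()),
    meals         = tibble::tibble(time = as.POSIXct(character(), tz = .TZ)),
    exercise      = tibble::tibble(time = as.POSIXct(character(), tz = .TZ),
                                   mode = integer(), duration = numeric()),
    qol           = {
      q <- tibble::tibble(date = as.Date(character()))
      for (i in 1:8) q[[paste0("q", i)]] <- integer()
      q$vas <- numeric()
      q
    }
  )
}

stream_error <- function(stream, row, msg) {
  abort(sprintf("invalid %s record %d: %s", stream, row, msg),
        class = "parkscore_validation_error")
}

validate_stream <- function(df, name) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(stream_columns[[name]], names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("stream '%s' is missing column(s): %s", name,
                  paste(missing_cols, collapse = ", ")),
          class = "parkscore_validation_error")
  }
  df <- df[stream_columns[[name]]]
  if (nrow(df) == 0) return(empty_stream(name))

  if (name == "qol") {
    df$date <- parse_date(df$date, "qol date")
    for (i in 1:8) {
      col <- paste0("q", i)
      v <- df[[col]]
      bad <- which(!v %in% c(1L, 2L, 3L))
      if (length(bad) > 0) {
        stream_error("qol", bad[1],
                     sprintf("item %s level must be 1, 2 or 3 (got %s)",
                             col, format(v[bad[1]])))
      }
      df[[col]] <- as.integer(v)
    }
    bad <- which(!is.finite(df$vas) | df$vas < 0 | df$vas > 100)
    if (length(bad) > 0) {
      stream_error("qol", bad[1], sprintf("vas must lie in [0, 100] (got %s)",
                                          format(df$vas[bad[1]])))
    }
    dup <- which(duplicated(df$date))
    if (length(dup) > 0) {
      stream_error("qol", dup[1],
                   sprintf("duplicate response for %s", df$date[dup[1]]))
    }
    return(df[order(df$date), ])
  }

  if (name == "bed_intervals") {
    df$enter <- parse_ts(df$enter, "bed_intervals enter")
    df$leave <- parse_ts(df$leave, "bed_intervals leave")
    bad <- which(df$leave <= df$enter)
    if (length(bad) > 0) {
      stream_error("bed_intervals", bad[1],
                   sprintf("leave (%s) must be after enter (%s)",
                           fmt_ts(df$leave[bad[1]]), fmt_ts(df$enter[bad[1]])))
    }
    df <- df[order(df$enter), ]
    if (nrow(df) > 1) {
      overlap <- which(df$enter[-1] < df$leave[-nrow(df)])
      if (length(overlap) > 0) {
        stream_error("bed_intervals", overlap[1] + 1,
                     "bed intervals must not overlap")
      }
    }
    return(df)
  }

  df$time <- parse_ts(df$time, paste(name, "time"))
  if (name %in% c("planned_doses", "taken_doses")) {
    bad <- which(!is.finite(df$dose) | df$dose <= 0)
    if (length(bad) > 0) {
      stream_error(name, bad[1], sprintf("dose must be > 0 (got %s)",
                                         format(df$dose[bad[1]])))
    }
  }
  if (name == "taken_doses") {
    bad <- which(!df$source %in% c("scheduled-delivery", "extra"))
    if (length(bad) > 0) {
      stream_error("taken_doses", bad[1],
                   sprintf("source must be 'scheduled-delivery' or 'extra' (got '%s')",
                           df$source[bad[1]]))
    }
  }
  if (name == "motor_samples") {
    for (col in c("bradykinesia", "dyskinesia")) {
      v <- df[[col]]
      bad <- which(!is.finite(v) | v < 0 | v > 100)
      if (length(bad) > 0) {
        stream_error("motor_samples", bad[1],
                     sprintf("%s must lie in [0, 100] (got %s)",
                             col, format(v[bad[1]])))
      }
    }
  }
  if (name == "exercise") {
    bad <- which(!df$mode %in% c(1L, 2L, 3L))
    if (length(bad) > 0) {
      stream_error("exercise", bad[1],
                   sprintf("mode must be 1, 2 or 3 (got %s)",
                           format(df$mode[bad[1]])))
    }
    df$mode <- as.integer(df$mode)
    bad <- which(!is.finite(df$duration) | df$duration <= 0)
    if (length(bad) > 0) {
      stream_error("exercise", bad[1],
                   sprintf("duration must be > 0 minutes (got %s)",
                           format(df$duration[bad[1]])))
    }
  }
  df <- df[order(df$time), ]
  if (name == "planned_doses" && nrow(df) > 1) {
    close <- which(mins_between(df$time[-nrow(df)], df$time[-1]) < 1)
    if (length(close) > 0) {
      stream_error("planned_doses", close[1] + 1,
                   "planned intake times must be at least 1 minute apart")
    }
  }
  df
}

#' Build a patient scenario from its raw streams
#'
#' A scenario bundles the six per-patient input streams, each a tibble with a
#' fixed column contract (see Details), plus the patient identifier and the
#' individual physical-activity target. All timestamps are minute-resolution
#' local time; every stream is validated and sorted chronologically.
#'
#' @details Stream column contracts:
#' * `planned_doses`: `time`, `dose` (> 0, levodopa units).
#' * `taken_doses`: `time`, `dose`, `source` (`"scheduled-delivery"` or
#'   `"extra"`).
#' * `bed_intervals`: `enter`, `leave` (non-overlapping, `leave > enter`).
#' * `motor_samples`: `time`, `bradykinesia`, `dyskinesia` (both 0-100,
#'   higher = better, nominal 2-minute cadence).
#' * `meals`: `time`.
#' * `exercise`: `time`, `mode` (1 = boxing/dancing/running/swimming,
#'   2 = bicycling/gym, 3 = walking), `duration` (minutes, > 0).
#' * `qol`: `date`, `q1`..`q8` (levels 1-3, 1 = no problems), `vas` (0-100).
#'
#' @param patient_id patient identifier string.
#' @param patient_target individual daily physical-activity target in
#'   (0, 100]; the exercise score normalises mode-weighted minutes by it.
#' @param planned_doses,taken_doses,bed_intervals,motor_samples,meals,exercise,qol
#'   data frames following the contracts above; missing streams default to
#'   empty.
#' @return An object of class `parkscore_scenario`.
#' @export
#' @examples
#' sc <- scenario("p1", 80,
#'   planned_doses = data.frame(time = "2021-03-01 08:00", dose = 100),
#'   taken_doses = data.frame(time = "2021-03-01 08:05", dose = 100,
#'                            source = "scheduled-delivery"))
#' sc
scenario <- function(patient_id = "patient",
                     patient_target = 80,
                     planned_doses = NULL, taken_doses = NULL,
                     bed_intervals = NULL, motor_samples = NULL,
                     meals = NULL, exercise = NULL, qol = NULL) {
  if (!is.numeric(patient_target) || length(patient_target) != 1 ||
      !is.finite(patient_target) ||
      patient_target <= 0 || patient_target > 100) {
    abort("patient_target must be a single number in (0, 100]",
          class = "parkscore_validation_error")
  }
  supplied <- list(planned_doses = planned_doses, taken_doses = taken_doses,
                   bed_intervals = bed_intervals, motor_samples = motor_samples,
                   meals = meals, exercise = exercise, qol = qol)
  streams <- lapply(STREAM_NAMES, function(name) {
    df <- supplied[[name]]
    if (is.null(df)) empty_stream(name) else validate_stream(df, name)
  })
  names(streams) <- STREAM_NAMES
  structure(
    list(patient_id = as.character(patient_id),
         patient_target = as.numeric(patient_target),
         streams = streams),
    class = "parkscore_scenario"
  )
}

#' @export
print.parkscore_scenario <- function(x, ...) {
  cat(sprintf("<parkscore scenario: %s, activity target %g>\n",
              x$patient_id, x$patient_target))
  counts <- vapply(x$streams, nrow, integer(1))
  for (name in names(counts)) cat(sprintf("  %-14s %d records\n", name, counts[name]))
  invisible(x)
}

#' Summarise record counts per stream
#'
#' @param scenario a [scenario()].
#' @return Named integer vector of record counts, one per stream.
#' @export
stream_counts <- function(scenario) {
  stopifnot(inherits(scenario, "parkscore_scenario"))
  vapply(scenario$streams, nrow, integer(1))
}

#' Read a scenario from disk
#'
#' Two on-disk layouts are supported. `"csv-bundle"`: a directory holding one
#' UTF-8 CSV per stream (`planned_doses.csv`, `taken_doses.csv`,
#' `bed_intervals.csv`, `motor_samples.csv`, `meals.csv`, `exercise.csv`,
#' `qol.csv`; header row mandatory, ISO 8601 timestamps) plus a small
#' `patient.json` with `patient_id` and `patient_target`. A missing stream
#' file is read as an empty stream with a warning. `"json-document"`: one JSON
#' file with `patient_id`, `patient_target` and one array per stream.
#'
#' @param path directory (csv-bundle) or file (json-document).
#' @param format `"csv-bundle"` or `"json-document"`.
#' @return A validated [scenario()] with a parse report attached as attribute
#'   `"parse_report"` (record count per stream).
#' @export
load_scenario <- function(path, format = c("csv-bundle", "json-document")) {
  format <- match.arg(format)
  if (format == "csv-bundle") {
    if (!dir.exists(path)) {
      abort(sprintf("scenario bundle directory not found: %s", path),
            class = "parkscore_parse_error")
    }
    meta_path <- file.path(path, "patient.json")
    meta <- if (file.exists(meta_path)) {
      jsonlite::read_json(meta_path, simplifyVector = TRUE)
    } else {
      list(patient_id = basename(path), patient_target = 80)
    }
    streams <- lapply(STREAM_NAMES, function(name) {
      f <- file.path(path, paste0(name, ".csv"))
      if (!file.exists(f)) {
        warn(sprintf("stream file missing, treated as empty: %s", basename(f)))
        return(NULL)
      }
      df <- read.csv(f, stringsAsFactors = FALSE, colClasses = "character")
      for (col in setdiff(names(df), c("time", "enter", "leave", "date", "source"))) {
        df[[col]] <- as.numeric(df[[col]])
      }
      df
    })
    names(streams) <- STREAM_NAMES
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    meta <- list(patient_id = doc$patient_id %||% basename(path),
                 patient_target = doc$patient_target %||% 80)
    streams <- lapply(STREAM_NAMES, function(name) {
      df <- doc$streams[[name]]
      if (is.null(df) || length(df) == 0 || NROW(df) == 0) NULL
      else tibble::as_tibble(df)
    })
    names(streams) <- STREAM_NAMES
  }
  sc <- scenario(patient_id = meta$patient_id,
                 patient_target = meta$patient_target,
                 planned_doses = streams$planned_doses,
                 taken_doses = streams$taken_doses,
                 bed_intervals = streams$bed_intervals,
                 motor_samples = streams$motor_samples,
                 meals = streams$meals,
                 exercise = streams$exercise,
                 qol = streams$qol)
  attr(sc, "parse_report") <- stream_counts(sc)
  sc
}

#' Write a scenario to disk
#'
#' Inverse of [load_scenario()]: writes either the CSV bundle (one file per
#' stream plus `patient.json`) or the single JSON document. Round-trips
#' record-for-record at minute resolution.
#'
#' @param scenario a [scenario()].
#' @param path output directory (csv-bundle) or file (json-document).
#' @param format `"csv-bundle"` or `"json-document"`.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path,
                           format = c("csv-bundle", "json-document")) {
  stopifnot(inherits(scenario, "parkscore_scenario"))
  format <- match.arg(format)
  serial <- lapply(scenario$streams, function(df) {
    out <- as.data.frame(df)
    for (col in names(out)) {
      if (inherits(out[[col]], "POSIXct")) out[[col]] <- fmt_ts(out[[col]])
      if (inherits(out[[col]], "Date")) out[[col]] <- format(out[[col]])
    }
    out
  })
  if (format == "csv-bundle") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (name in STREAM_NAMES) {
      write.csv(serial[[name]], file.path(path, paste0(name, ".csv")),
                row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(
      list(patient_id = scenario$patient_id,
           patient_target = scenario$patient_target),
      file.path(path, "patient.json"), auto_unbox = TRUE)
  } else {
    jsonlite::write_json(
      list(patient_id = scenario$patient_id,
           patient_target = scenario$patient_target,
           streams = serial),
      path, auto_unbox = TRUE, dataframe = "rows", na = "null", digits = NA)
  }
  invisible(path)
}

#' Split a scenario into calendar-day slices
#'
#' Every point event (doses, motor samples, meals, exercise, QoL responses)
#' is assigned to the calendar date containing its local timestamp. Bed
#' intervals are first chained into sleep episodes (see [build_nights()]) and
#' each episode is attributed to its wake day — the date on which the patient
#' finally left the bed — so a night spanning midnight is scored on the
#' morning it ends.
#'
#' @param scenario a [scenario()].
#' @param config an [engine_config()] (night-chaining thresholds).
#' @return A named list keyed by `"YYYY-MM-DD"`, covering every date between
#'   the first and last event. Each element holds the six stream slices for
#'   that day plus `nights`, the [build_nights()] rows waking on that date.
#' @export
partition_by_day <- function(scenario, config = engine_config()) {
  stopifnot(inherits(scenario, "parkscore_scenario"))
  s <- scenario$streams
  nights <- build_nights(s$bed_intervals, config)

  all_dates <- c(
    ts_date(s$planned_doses$time), ts_date(s$taken_doses$time),
    ts_date(s$motor_samples$time), ts_date(s$meals$time),
    ts_date(s$exercise$time), s$qol$date, nights$wake_date
  )
  if (length(all_dates) == 0) return(structure(list(), names = character()))
  dates <- seq(min(all_dates), max(all_dates), by = "day")

  slice_by <- function(df, keys) lapply(dates, function(d) df[keys == d, , drop = FALSE])
  slices <- list(
    planned_doses = slice_by(s$planned_doses, ts_date(s$planned_doses$time)),
    taken_doses   = slice_by(s$taken_doses, ts_date(s$taken_doses$time)),
    motor_samples = slice_by(s$motor_samples, ts_date(s$motor_samples$time)),
    meals         = slice_by(s$meals, ts_date(s$meals$time)),
    exercise      = slice_by(s$exercise, ts_date(s$exercise$time)),
    qol           = slice_by(s$qol, s$qol$date),
    nights        = slice_by(nights, nights$wake_date)
  )
  out <- lapply(seq_along(dates), function(i) {
    day <- lapply(slices, function(x) x[[i]])
    day$date <- dates[i]
    day
  })
  names(out) <- format(dates)
  out
}
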
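# Sleep scoring from bed-sensor occupancy intervals. Three components adapted
# from the Pittsburgh Sleep Quality Index — sleep duration, habitual sleep
# efficiency, sleep disturbances — each graded 0 (best) to 3 (worst) by rule
# tables, then combined into a 0-100 daily sleep score.

#' Chain bed intervals into nightly records
#'
#' Consecutive bed intervals separated by less than `night_chain_gap_h` hours
#' form one sleep episode. An episode counts as a night when it starts in the
#' evening (after `night_start_after_h` o'clock) or in the early morning
#' (before `night_start_before_h` o'clock); early-afternoon episodes are naps
#' and are dropped. Each night is attributed to its wake day — the calendar
#' date of the final leave. Gaps of at least `min_interruption_gap_min`
#' minutes count as interruptions; shorter gaps are merged as sensor jitter.
#'
#' @param intervals bed-interval tibble (`enter`, `leave`), non-overlapping.
#' @param config an [engine_config()].
#' @return A tibble with one row per night: `wake_date`, `min_time` (first
#'   time in bed), `max_time` (final leave), `cumulative_hours` (total time
#'   in bed), `interruptions`, `n_intervals` and an `intervals` list-column.
#' @export
#' @examples
#' iv <- data.frame(enter = c("2021-03-01 23:00", "2021-03-02 01:30"),
#'                  leave = c("2021-03-02 01:00", "2021-03-02 06:30"))
#' build_nights(iv)
build_nights <- function(intervals, config = engine_config()) {
  intervals <- validate_stream(intervals, "bed_intervals")
  empty <- tibble::tibble(
    wake_date = as.Date(character()), min_time = as.POSIXct(character(), tz = .TZ),
    max_time = as.POSIXct(character(), tz = .TZ), cumulative_hours = numeric(),
    interruptions = integer(), n_intervals = integer(), intervals = list()
  )
  if (nrow(intervals) == 0) return(empty)

  gap_h <- c(Inf, hours_between(intervals$leave[-nrow(intervals)],
                                intervals$enter[-1]))
  episode <- cumsum(gap_h >= config$night_chain_gap_h)

  nights <- lapply(split(seq_len(nrow(intervals)), episode), function(rows) {
    iv <- intervals[rows, , drop = FALSE]
    # merge sub-threshold gaps: they are jitter, not interruptions
    if (nrow(iv) > 1) {
      gaps <- mins_between(iv$leave[-nrow(iv)], iv$enter[-1])
      keep_gap <- gaps >= config$min_interruption_gap_min
      grp <- cumsum(c(TRUE, keep_gap))
      iv <- dplyr::summarise(dplyr::group_by(tibble::tibble(
        enter = iv$enter, leave = iv$leave, grp = grp), .data$grp),
        enter = min(.data$enter), leave = max(.data$leave), .groups = "drop")
      iv <- iv[order(iv$enter), c("enter", "leave")]
    }
    start_min <- time_of_day_min(iv$enter[1])
    is_night <- start_min >= config$night_start_after_h * 60 ||
      start_min < config$night_start_before_h * 60
    if (!is_night) return(NULL)
    tibble::tibble(
      wake_date = ts_date(iv$leave[nrow(iv)]),
      min_time = iv$enter[1],
      max_time = iv$leave[nrow(iv)],
      cumulative_hours = sum(hours_between(iv$enter, iv$leave)),
      interruptions = nrow(iv) - 1L,
      n_intervals = nrow(iv),
      intervals = list(iv)
    )
  })
  nights <- dplyr::bind_rows(nights)
  if (nrow(nights) == 0) return(empty)
  nights[order(nights$wake_date, nights$min_time), , drop = FALSE]
}

# rule tables; boundary values fall into the less-severe bucket
duration_component <- function(cumulative_hours) {
  dplyr::case_when(
    cumulative_hours >= 7 ~ 0L,
    cumulative_hours >= 6 ~ 1L,
    cumulative_hours >= 5 ~ 2L,
    TRUE ~ 3L
  )
}

efficiency_component <- function(ratio) {
  dplyr::case_when(
    ratio >= 85 ~ 0L,
    ratio >= 75 ~ 1L,
    ratio >= 65 ~ 2L,
    TRUE ~ 3L
  )
}

disturbance_component <- function(interruptions) {
  pmin(as.integer(interruptions), 3L)
}

#' Grade the three sleep components of a night
#'
#' Sleep duration is graded from the cumulative hours in bed (more than 7 h
#' grades 0, under 5 h grades 3). Habitual sleep efficiency is the ratio, in
#' percent, of cumulative time in bed to the full in-bed window from first
#' entry (`min_time`) to final leave (`max_time`); 85% or better grades 0,
#' under 65% grades 3. Sleep disturbances grade equals the interruption count
#' capped at 3. Rule-table boundary values join the less-severe bucket.
#'
#' @param nights one or more rows from [build_nights()].
#' @return The input with `efficiency_ratio` (percent) and integer columns
#'   `duration_component`, `efficiency_component`, `disturbance_component`
#'   (each 0-3) appended; `sleep_score` is added by [daily_sleep_score()].
#' @export
sleep_components <- function(nights) {
  window_h <- hours_between(nights$min_time, nights$max_time)
  if (any(window_h <= 0)) {
    abort("degenerate night: max_time must be after min_time",
          class = "parkscore_validation_error")
  }
  nights$efficiency_ratio <- 100 * nights$cumulative_hours / window_h
  nights$duration_component <- duration_component(nights$cumulative_hours)
  nights$efficiency_component <- efficiency_component(nights$efficiency_ratio)
  nights$disturbance_component <- disturbance_component(nights$interruptions)
  nights
}

#' Daily sleep score from graded components
#'
#' The three 0-3 components are summed (0 best, 9 worst) and mapped linearly
#' onto the common 0-100 scale: `100 * (1 - sum / 9)`, so an uninterrupted,
#' efficient night of more than 7 hours scores 100.
#'
#' @param components output of [sleep_components()].
#' @return The input with a `sleep_score` column in \[0, 100\] appended.
#' @export
daily_sleep_score <- function(components) {
  total <- components$duration_component + components$efficiency_component +
    components$disturbance_component
  components$sleep_score <- 100 * (1 - total / 9)
  components
}

# one-day convenience wrapper: nights waking on one date -> one-row tibble.
# Multiple qualifying episodes on a wake day are merged by scoring the longest
# (principal) night.
score_sleep_day <- function(nights) {
  if (nrow(nights) == 0) {
    return(tibble::tibble(sleep = NA_real_))
  }
  principal <- nights[which.max(nights$cumulative_hours), , drop = FALSE]
  scored <- daily_sleep_score(sleep_components(principal))
  tibble::tibble(sleep = scored$sleep_score)
}
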
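# Self-report scores: meal timing relative to levodopa intakes, physical
# activity against an individual target, and the daily quality-of-life items.

#' Daily meal timing compliance score
#'
#' Each levodopa intake defines a protected window from
#' `meal_window_before_min` minutes before to `meal_window_after_min` minutes
#' after the intake (defaults 30 and 60). Under the default `"avoid"` reading
#' a meal complies when it falls inside no intake's window — levodopa
#' absorption competes with dietary protein, so meals should keep clear of
#' intakes; `meal_window_mode = "require"` flips the reading so a meal must
#' fall inside a window. The daily score is `100 * NWI / n`, where `NWI`
#' counts compliant meals and `n` the reported meals.
#'
#' @param meals meal tibble (`time`) for one day.
#' @param med_intakes taken-dose tibble for the same day; every delivered
#'   dose (scheduled or extra) anchors a window.
#' @param config an [engine_config()].
#' @return One-row tibble with `nwi`, `n` and `meal` (score, `NA` when no
#'   meals were reported).
#' @export
#' @examples
#' meals <- data.frame(time = c("2021-03-01 08:10", "2021-03-01 13:30"))
#' intakes <- data.frame(time = "2021-03-01 12:00", dose = 100,
#'                       source = "scheduled-delivery")
#' meal_timing_score(meals, intakes)
meal_timing_score <- function(meals, med_intakes, config = engine_config()) {
  meals <- validate_stream(meals, "meals")
  med_intakes <- validate_stream(med_intakes, "taken_doses")
  n <- nrow(meals)
  if (n == 0) {
    return(tibble::tibble(nwi = 0L, n = 0L, meal = NA_real_))
  }
  in_any_window <- vapply(meals$time, function(m) {
    if (nrow(med_intakes) == 0) return(FALSE)
    offset <- mins_between(med_intakes$time, m)  # meal - intake, minutes
    any(offset >= -config$meal_window_before_min &
        offset <= config$meal_window_after_min)
  }, logical(1))
  compliant <- if (config$meal_window_mode == "avoid") !in_any_window else in_any_window
  nwi <- sum(compliant)
  tibble::tibble(nwi = as.integer(nwi), n = as.integer(n),
                 meal = 100 * nwi / n)
}

#' Daily physical activity score
#'
#' Each reported occasion contributes its duration in minutes weighted by the
#' exercise mode (1 = boxing, dancing, running, swimming; 2 = bicycling,
#' gym; 3 = walking); the weighted minutes are summed over the day,
#' normalised by the individual patient target and expressed on the 0-100
#' scale, capped at 100. With the worked defaults — mode 1 for 10 minutes
#' plus mode 2 for 25 minutes against a target of 80 — the day scores
#' `100 * (10 + 2 * 25) / 80 = 75`.
#'
#' @param occasions exercise tibble (`time`, `mode`, `duration`) for one day.
#' @param patient_target individual daily target in (0, 100].
#' @return One-row tibble with `exercise` (score, `NA` when no occasion was
#'   reported).
#' @export
#' @examples
#' occ <- data.frame(time = c("2021-03-01 10:00", "2021-03-01 17:00"),
#'                   mode = c(1, 2), duration = c(10, 25))
#' physical_activity_score(occ, patient_target = 80)
physical_activity_score <- function(occasions, patient_target) {
  occasions <- validate_stream(occasions, "exercise")
  if (!is.numeric(patient_target) || length(patient_target) != 1 ||
      !is.finite(patient_target) ||
      patient_target <= 0 || patient_target > 100) {
    abort("patient_target must be a single number in (0, 100]",
          class = "parkscore_validation_error")
  }
  if (nrow(occasions) == 0) {
    return(tibble::tibble(exercise = NA_real_))
  }
  raw <- 100 * sum(occasions$mode * occasions$duration) / patient_target
  tibble::tibble(exercise = min(100, raw))
}

#' The daily quality-of-life questionnaire items
#'
#' The nine items answered each day: eight three-level items drawn from the
#' EQ-5D-3L (European Quality of Life 5 Dimensions 3 Level) and the PDQ-8
#' (8-item Parkinson Disease Questionnaire), plus the EQ-5D-3L visual
#' analogue overall-health rating.
#'
#' @return A tibble with `item` (1-9), `label`, `questionnaire` and `kind`
#'   (`"level"` for the 3-level items, `"vas"` for the 0-100 rating).
#' @export
qol_items <- function() {
  tibble::tibble(
    item = 1:9,
    label = c("Mobility", "Personal care", "Daily activities",
              "Pain or discomfort", "Worry or depression",
              "Concentration difficulties", "Communication difficulties",
              "Painful cramps or spasms in the muscles", "Overall health"),
    questionnaire = c(rep("EQ-5D-3L", 5), rep("PDQ-8", 3), "EQ-5D-3L"),
    kind = c(rep("level", 8), "vas")
  )
}

#' Daily quality-of-life scores
#'
#' The eight three-level items (1 = no problems, 2 = some problems,
#' 3 = extreme problems) are recoded to the clinician tile scale 0-2 with 0
#' the worst result (`item_score = 3 - level`). The 0-100 visual analogue
#' overall-health rating is taken as the overall day score.
#'
#' @param response one row of the `qol` stream (`date`, `q1`..`q8`, `vas`).
#' @return One-row tibble with `qol_q1`..`qol_q8` (each 0-2) and
#'   `overall_day` (the VAS value).
#' @export
qol_daily <- function(response) {
  response <- validate_stream(response, "qol")
  if (nrow(response) != 1) {
    abort("qol_daily expects exactly one response row",
          class = "parkscore_validation_error")
  }
  out <- tibble::tibble(.rows = 1)
  for (i in 1:8) {
    out[[paste0("qol_q", i)]] <- 3L - response[[paste0("q", i)]]
  }
  out$overall_day <- response$vas
  out
}
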
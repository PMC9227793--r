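# Medication timing compliance: match delivered doses to the planned schedule,
# classify extra doses, score each occasion 0-100 by its timing deviation and
# average over the day.

# Minimum-total-deviation assignment between two sorted time vectors. All of
# the shorter side is matched, at most one partner each; for absolute-time
# costs an optimal assignment is non-crossing, so a sorted-lists DP suffices.
# Ties are broken toward matching the earlier element of the longer side.
# Returns, for each element of `short`, the index it matches in `long`.
assign_min_deviation <- function(short, long) {
  m <- length(short); k <- length(long)
  if (m == 0) return(integer(0))
  cost <- abs(outer(short, long, "-"))
  f <- matrix(Inf, nrow = m + 1, ncol = k + 1)
  f[1, ] <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(k)) {
      if (j < i) next
      f[i + 1, j + 1] <- min(f[i + 1, j], f[i, j] + cost[i, j])
    }
  }
  match_idx <- integer(m)
  i <- m; j <- k
  while (i >= 1) {
    # prefer dropping long[j] on ties: pushes matches toward earlier partners
    if (j > i && f[i + 1, j + 1] == f[i + 1, j]) {
      j <- j - 1
    } else {
      match_idx[i] <- j
      i <- i - 1; j <- j - 1
    }
  }
  match_idx
}

#' Match delivered doses to the planned schedule and classify extras
#'
#' Scheduled deliveries are paired with planned intakes by the assignment that
#' minimises the total timing deviation (at most one delivery per planned
#' intake). Extra doses within `replacement_window_min` minutes of a planned
#' time stand in for that intake: if the intake is otherwise unmatched the
#' extra becomes its delivery with status `"replaced"`, otherwise the extra is
#' omitted from all calculations. Extra doses outside every window become
#' `"extra-credited"` occasions (later scored 100). Planned intakes with no
#' delivery are `"missed"`.
#'
#' @param planned,taken planned-dose and taken-dose tibbles (see [scenario()])
#'   for one calendar day, sorted by time.
#' @param config an [engine_config()].
#' @return A tibble of occasions with columns `planned_time`, `planned_dose`,
#'   `taken_time`, `taken_dose`, `deviation_min` (`NA` when unmatched) and
#'   `status` (`on-schedule`, `replaced`, `missed`, `extra-credited`);
#'   `occasion_score` is filled in by [occasion_score()].
#' @export
#' @examples
#' planned <- data.frame(time = "2021-03-01 08:00", dose = 100)
#' taken <- data.frame(time = c("2021-03-01 08:05", "2021-03-01 12:00"),
#'                     dose = 100, source = c("scheduled-delivery", "extra"))
#' match_and_classify(planned, taken)
match_and_classify <- function(planned, taken, config = engine_config()) {
  planned <- validate_stream(planned, "planned_doses")
  taken <- validate_stream(taken, "taken_doses")
  p_min <- as.numeric(planned$time) / 60
  scheduled <- taken[taken$source == "scheduled-delivery", , drop = FALSE]
  extras <- taken[taken$source == "extra", , drop = FALSE]
  s_min <- as.numeric(scheduled$time) / 60

  matched_taken_row <- rep(NA_integer_, nrow(planned))
  surplus_sched <- integer(0)
  if (nrow(scheduled) > 0 && nrow(planned) > 0) {
    if (length(s_min) <= length(p_min)) {
      idx <- assign_min_deviation(s_min, p_min)
      matched_taken_row[idx] <- seq_along(s_min)
    } else {
      idx <- assign_min_deviation(p_min, s_min)
      matched_taken_row <- idx
      surplus_sched <- setdiff(seq_along(s_min), idx)
    }
  } else if (nrow(scheduled) > 0) {
    surplus_sched <- seq_len(nrow(scheduled))
  }

  occ <- tibble::tibble(
    planned_time = planned$time,
    planned_dose = planned$dose,
    taken_time = as.POSIXct(rep(NA_real_, nrow(planned)),
                            origin = "1970-01-01", tz = .TZ),
    taken_dose = NA_real_,
    deviation_min = NA_real_,
    status = as.character(ifelse(is.na(matched_taken_row), "missed",
                                 "on-schedule"))
  )
  hit <- which(!is.na(matched_taken_row))
  occ$taken_time[hit] <- scheduled$time[matched_taken_row[hit]]
  occ$taken_dose[hit] <- scheduled$dose[matched_taken_row[hit]]
  occ$deviation_min[hit] <- abs(mins_between(occ$planned_time[hit],
                                             occ$taken_time[hit]))

  # scheduled deliveries beyond the planned schedule behave like extra doses
  extras <- dplyr::bind_rows(extras, scheduled[surplus_sched, , drop = FALSE])
  if (nrow(extras) > 0) extras <- extras[order(extras$time), , drop = FALSE]

  credited <- empty_stream("taken_doses")
  window <- config$replacement_window_min
  for (r in seq_len(nrow(extras))) {
    e_time <- extras$time[r]
    if (nrow(planned) > 0) {
      dev <- abs(mins_between(planned$time, e_time))
      in_window <- which(dev <= window)
    } else {
      in_window <- integer(0)
    }
    if (length(in_window) > 0) {
      open <- in_window[occ$status[in_window] == "missed"]
      if (length(open) > 0) {
        tgt <- open[which.min(dev[open])]
        occ$status[tgt] <- "replaced"
        occ$taken_time[tgt] <- e_time
        occ$taken_dose[tgt] <- extras$dose[r]
        occ$deviation_min[tgt] <- dev[tgt]
      }
      # otherwise: a replacement for an already-delivered intake, omitted
    } else {
      credited <- dplyr::bind_rows(credited, extras[r, , drop = FALSE])
    }
  }
  if (nrow(credited) > 0) {
    occ <- dplyr::bind_rows(occ, tibble::tibble(
      planned_time = as.POSIXct(rep(NA_real_, nrow(credited)),
                                origin = "1970-01-01", tz = .TZ),
      planned_dose = NA_real_,
      taken_time = credited$time,
      taken_dose = credited$dose,
      deviation_min = NA_real_,
      status = "extra-credited"
    ))
  }
  occ$occasion_score <- NA_real_
  event_time <- dplyr::coalesce(occ$planned_time, occ$taken_time)
  occ[order(event_time), , drop = FALSE]
}

#' Score medication occasions by timing deviation
#'
#' Maps each classified occasion to a 0-100 score: extra doses outside every
#' replacement window are credited the highest score, 100; missed intakes
#' score 0; delivered intakes (including replacements) decay linearly from
#' 100 at zero deviation to 0 at `deviation_max_min` minutes, clamped.
#'
#' @param occasions output of [match_and_classify()].
#' @param config an [engine_config()].
#' @return The same tibble with `occasion_score` filled in.
#' @export
occasion_score <- function(occasions, config = engine_config()) {
  d_max <- config$deviation_max_min
  decay <- pmax(0, 100 * (1 - occasions$deviation_min / d_max))
  occasions$occasion_score <- dplyr::case_when(
    occasions$status == "extra-credited" ~ 100,
    occasions$status == "missed" ~ 0,
    TRUE ~ pmin(100, decay)
  )
  occasions
}

#' Daily medication compliance score
#'
#' The arithmetic mean of the occasion scores over the day's medication
#' intake occasions. With `replacement_counts = "omit"` replaced occasions
#' are left out of the mean (the reading in which replacements are omitted
#' from calculations entirely); by default they contribute their own timing
#' deviation. A day with no occasions has a missing score.
#'
#' @param occasions scored occasions from [occasion_score()].
#' @param config an [engine_config()].
#' @return One-row tibble with `n` (occasions entering the mean) and
#'   `medication` (daily score, `NA` if `n` is 0).
#' @export
daily_medication_score <- function(occasions, config = engine_config()) {
  if (any(is.na(occasions$occasion_score) &
          occasions$status != "replaced")) {
    abort("occasions must be scored with occasion_score() first",
          class = "parkscore_validation_error")
  }
  keep <- occasions
  if (config$replacement_counts == "omit") {
    keep <- keep[keep$status != "replaced", , drop = FALSE]
  }
  n <- nrow(keep)
  tibble::tibble(
    n = n,
    medication = if (n == 0) NA_real_ else mean(keep$occasion_score)
  )
}

# one-day convenience wrapper used by the pipeline
score_medication_day <- function(planned, taken, config = engine_config()) {
  occ <- match_and_classify(planned, taken, config)
  occ <- occasion_score(occ, config)
  daily_medication_score(occ, config)
}
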
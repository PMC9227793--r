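# Small builders for stream tibbles used across the tests.

pd <- function(times, dose = 100) {
  data.frame(time = times, dose = rep_len(dose, length(times)))
}

td <- function(times, source = "scheduled-delivery", dose = 100) {
  data.frame(time = times, dose = rep_len(dose, length(times)),
             source = rep_len(source, length(times)))
}

bi <- function(enter, leave) {
  data.frame(enter = enter, leave = leave)
}

ms <- function(times, brady, dysk = brady) {
  data.frame(time = times, bradykinesia = brady, dyskinesia = dysk)
}

meal_df <- function(times) data.frame(time = times)

ex_df <- function(times, mode, duration) {
  data.frame(time = times, mode = mode, duration = duration)
}

qol_df <- function(dates, levels = rep(1L, 8), vas = 80) {
  q <- data.frame(date = dates)
  for (i in 1:8) q[[paste0("q", i)]] <- levels[i]
  q$vas <- vas
  q
}

# a synthetic night record row bypassing build_nights, for rule-table tests
night_row <- function(cumulative_hours, window_hours = cumulative_hours,
                      interruptions = 0L, wake_date = as.Date("2021-03-02")) {
  min_time <- as.POSIXct("2021-03-01 23:00", tz = "UTC")
  tibble::tibble(
    wake_date = wake_date,
    min_time = min_time,
    max_time = min_time + window_hours * 3600,
    cumulative_hours = cumulative_hours,
    interruptions = as.integer(interruptions),
    n_intervals = as.integer(interruptions) + 1L,
    intervals = list(NULL)
  )
}

# exhaustive minimum-total-deviation matching for small instances: every
# injective assignment of the shorter side into the longer side
brute_force_min_deviation <- function(short, long) {
  m <- length(short); k <- length(long)
  stopifnot(m <= k)
  if (m == 0) return(0)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (subset in asplit(utils::combn(k, m), 2)) {
    for (p in perms(subset)) {
      best <- min(best, sum(abs(short - long[p])))
    }
  }
  best
}
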
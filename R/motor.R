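# Motor function: the wrist sensor emits bradykinesia and dyskinesia scores
# every 2 minutes on a 0-100 scale (higher = better). The daily summary is the
# per-channel arithmetic mean; the two channels are reported separately.

#' Daily motor scores from wrist-sensor samples
#'
#' @param samples motor-sample tibble (`time`, `bradykinesia`, `dyskinesia`)
#'   for one calendar day.
#' @param date the calendar date the samples belong to (`Date` or string);
#'   samples on other dates raise an error.
#' @return One-row tibble with `bradykinesia`, `dyskinesia` (channel means,
#'   `NA` when there are no samples — never 0) and `n_samples`.
#' @export
#' @examples
#' s <- data.frame(time = c("2021-03-01 10:00", "2021-03-01 10:02"),
#'                 bradykinesia = c(40, 60), dyskinesia = c(70, 80))
#' daily_motor_scores(s, "2021-03-01")
daily_motor_scores <- function(samples, date) {
  samples <- validate_stream(samples, "motor_samples")
  date <- as.Date(date)
  if (nrow(samples) > 0 && any(ts_date(samples$time) != date)) {
    abort(sprintf("motor samples outside %s supplied to daily_motor_scores",
                  format(date)),
          class = "parkscore_validation_error")
  }
  n <- nrow(samples)
  tibble::tibble(
    bradykinesia = if (n == 0) NA_real_ else mean(samples$bradykinesia),
    dyskinesia = if (n == 0) NA_real_ else mean(samples$dyskinesia),
    n_samples = n
  )
}
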
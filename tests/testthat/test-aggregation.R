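daily_fixture <- function(dates, values) {
  rows <- lapply(seq_along(dates), function(i) {
    assemble_daily_summary(dates[i],
      medication = tibble::tibble(n = 1L, medication = values[i]),
      motor = tibble::tibble(bradykinesia = values[i], dyskinesia = values[i],
                             n_samples = 1L))
  })
  dplyr::bind_rows(rows)
}

test_that("daily rows assemble stream results and keep absent streams missing", {
  row <- assemble_daily_summary("2021-03-01",
    medication = tibble::tibble(n = 3L, medication = 90),
    sleep = tibble::tibble(sleep = 88.9),
    motor = tibble::tibble(bradykinesia = 60, dyskinesia = 70, n_samples = 10L),
    meal = tibble::tibble(nwi = 2L, n = 3L, meal = 66.7),
    exercise = tibble::tibble(exercise = 75),
    qol = qol_daily(qol_df("2021-03-01", vas = 80)))
  expect_equal(names(row)[1:9],
               c("date", "medication", "sleep", "bradykinesia", "dyskinesia",
                 "meal", "exercise", "overall_day", "qol_q1"))
  expect_equal(row$medication, 90)
  expect_equal(row$overall_day, 80)

  partial <- assemble_daily_summary("2021-03-01",
    medication = tibble::tibble(n = 1L, medication = 100))
  expect_true(is.na(partial$sleep))
  expect_true(is.na(partial$overall_day))
})

test_that("days without any events keep a fully-missing row for axis continuity", {
  sc <- scenario(meals = meal_df(c("2021-03-01 12:00", "2021-03-03 12:00")))
  rows <- score_scenario(sc)
  expect_equal(rows$date, as.Date(c("2021-03-01", "2021-03-02", "2021-03-03")))
  gap <- rows[rows$date == as.Date("2021-03-02"), ]
  expect_true(all(is.na(unlist(gap[, -1]))))
})

test_that("rolling means cover the trailing window and skip missing days", {
  d <- as.Date("2021-03-01") + 0:13
  rows <- daily_fixture(d, rep(100, 14))
  s <- rolling_summary(rows, 14)
  expect_equal(s$medication, 100)
  expect_true(is.na(s$sleep))  # never observed in the window

  # 7 present days of 80 inside a 14-day window
  rows <- daily_fixture(d, c(rep(NA, 7), rep(80, 7)))
  expect_equal(rolling_summary(rows, 14)$medication, 80)

  rows <- daily_fixture(d, 0:13)
  expect_equal(rolling_summary(rows, 14)$medication, 6.5)

  # window 1 is just the last day
  expect_equal(rolling_summary(rows, 1)$medication, 13)
  expect_error(rolling_summary(rows, 0), class = "parkscore_validation_error")
})

test_that("scores classify into good/average/bad with the stated boundaries", {
  got <- classify_score(c(71, 70.001, 100, 70, 30, 50, 29.9, 0, NA))
  expect_equal(as.character(got$band),
               c("good", "good", "good", "average", "average", "average",
                 "bad", "bad", NA))
  expect_equal(as.character(got$color),
               c("green", "green", "green", "gray", "gray", "gray",
                 "orange", "orange", NA))
  expect_error(classify_score(120), class = "parkscore_validation_error")

  # brute-force re-check of the band function over a value sweep
  v <- seq(0, 100, by = 0.25)
  got <- classify_score(v)
  oracle <- ifelse(v > 70, "good", ifelse(v >= 30, "average", "bad"))
  expect_equal(as.character(got$band), oracle)
})

test_that("correlation is exact on constructed pairs and symmetric at lag 0", {
  d <- as.Date("2021-03-01") + 0:9
  x <- c(10, 30, 50, 20, 80, 60, 40, 90, 70, 55)
  rows <- daily_fixture(d, x)
  rows$sleep <- 100 - x

  self <- correlate_scores(rows, "medication", "bradykinesia")
  expect_equal(self$coefficient, 1)
  expect_equal(self$n_pairs, 10L)

  anti <- correlate_scores(rows, "medication", "sleep")
  expect_equal(anti$coefficient, -1)

  ab <- correlate_scores(rows, "medication", "sleep")
  ba <- correlate_scores(rows, "sleep", "medication")
  expect_equal(ab$coefficient, ba$coefficient)

  # lag alignment: y tomorrow equals x today -> perfect correlation at lag 1
  rows$sleep <- c(NA, x[-10])
  lag1 <- correlate_scores(rows, "medication", "sleep", lag_days = 1)
  expect_equal(lag1$coefficient, 1)
  expect_equal(lag1$n_pairs, 9L)

  expect_error(correlate_scores(rows[1:2, ], "medication", "sleep"),
               class = "parkscore_insufficient_data")
  expect_error(correlate_scores(rows, "medication", "banana"),
               "valid names", class = "parkscore_validation_error")
})

test_that("a simulated dose-locked motor response yields a positive correlation", {
  # strong medication->motor coupling, long window
  ok <- 0L
  n_runs <- 25L
  for (s in seq_len(n_runs)) {
    cfg <- sim_config(seed = 1000 + s, days = 28, adherence_sd_min = 60,
                      miss_prob = 0.3, dose_response_amplitude = 25,
                      motor_noise_sd = 2)
    rows <- score_scenario(simulate_scenario(cfg)$scenario)
    r <- correlate_scores(rows, "medication", "bradykinesia")
    if (r$coefficient > 0) ok <- ok + 1L
  }
  expect_gte(ok / n_runs, 0.95)
})

test_that("the daily score table round-trips through scores.csv", {
  sim <- simulate_scenario(sim_config(seed = 3, days = 4))
  rows <- score_scenario(sim$scenario)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scores_csv(rows, path)
  header <- readLines(path, n = 1)
  expect_equal(header, paste(c("date", "medication", "sleep", "bradykinesia",
                               "dyskinesia", "meal", "exercise", "overall_day",
                               paste0("qol_q", 1:8)), collapse = ","))
  back <- read_scores_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(rows), tolerance = 1e-10)
})
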
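test_that("bed intervals chain into nights with cumulative hours and interruptions", {
  n <- build_nights(bi("2021-03-01 23:00", "2021-03-02 07:00"))
  expect_equal(nrow(n), 1L)
  expect_equal(n$cumulative_hours, 8)
  expect_equal(n$interruptions, 0L)
  expect_equal(n$wake_date, as.Date("2021-03-02"))

  n <- build_nights(bi(c("2021-03-01 23:00", "2021-03-02 01:30"),
                       c("2021-03-02 01:00", "2021-03-02 06:30")))
  expect_equal(n$cumulative_hours, 7)
  expect_equal(n$interruptions, 1L)
  expect_equal(n$min_time, as.POSIXct("2021-03-01 23:00", tz = "UTC"))
  expect_equal(n$max_time, as.POSIXct("2021-03-02 06:30", tz = "UTC"))

  expect_equal(nrow(build_nights(bi(character(0), character(0)))), 0L)
})

test_that("afternoon naps are not nights and long gaps split episodes", {
  # early-afternoon episode: excluded from sleep scoring
  expect_equal(nrow(build_nights(bi("2021-03-01 13:00", "2021-03-01 14:00"))), 0L)
  # a 5 h gap splits two episodes; the evening one is the night
  n <- build_nights(bi(c("2021-03-01 13:00", "2021-03-01 23:00"),
                       c("2021-03-01 14:00", "2021-03-02 06:00")))
  expect_equal(nrow(n), 1L)
  expect_equal(n$cumulative_hours, 7)
})

test_that("sub-threshold gaps are merged as jitter, configurable", {
  iv <- bi(c("2021-03-01 23:00", "2021-03-02 03:00:30"),
           c("2021-03-02 03:00", "2021-03-02 07:00"))
  # timestamps are floored to the minute, so this gap vanishes entirely
  n <- build_nights(iv)
  expect_equal(n$interruptions, 0L)

  iv2 <- bi(c("2021-03-01 23:00", "2021-03-02 03:05"),
            c("2021-03-02 03:00", "2021-03-02 07:00"))
  expect_equal(build_nights(iv2)$interruptions, 1L)
  cfg <- engine_config(min_interruption_gap_min = 10)
  merged <- build_nights(iv2, cfg)
  expect_equal(merged$interruptions, 0L)
  expect_equal(merged$cumulative_hours, 8)
})

test_that("the duration, efficiency and disturbance rule tables grade as printed", {
  # duration from cumulative hours in bed
  for (case in list(c(4.5, 3), c(5.5, 2), c(6.5, 1), c(7.5, 0))) {
    n <- sleep_components(night_row(case[1], window_hours = 9))
    expect_equal(n$duration_component, as.integer(case[2]),
                 info = paste("cumulative", case[1]))
  }
  # efficiency from the in-bed ratio (cumulative / window, percent)
  for (case in list(c(60, 3), c(70, 2), c(80, 1), c(90, 0))) {
    n <- sleep_components(night_row(cumulative_hours = 8 * case[1] / 100,
                                    window_hours = 8))
    expect_equal(n$efficiency_ratio, case[1])
    expect_equal(n$efficiency_component, as.integer(case[2]),
                 info = paste("ratio", case[1]))
  }
  # disturbances from the interruption count
  for (case in list(c(0, 0), c(1, 1), c(2, 2), c(5, 3))) {
    n <- sleep_components(night_row(7.5, window_hours = 9,
                                    interruptions = case[1]))
    expect_equal(n$disturbance_component, as.integer(case[2]),
                 info = paste("interruptions", case[1]))
  }
})

test_that("rule-table boundary values join the less-severe bucket", {
  expect_equal(sleep_components(night_row(7, window_hours = 9))$duration_component, 0L)
  expect_equal(sleep_components(night_row(6, window_hours = 9))$duration_component, 1L)
  expect_equal(sleep_components(night_row(5, window_hours = 9))$duration_component, 2L)
  for (ratio in c(85, 75, 65)) {
    n <- sleep_components(night_row(10 * ratio / 100, window_hours = 10))
    expect_equal(n$efficiency_component,
                 c(`85` = 0L, `75` = 1L, `65` = 2L)[[as.character(ratio)]])
  }
})

test_that("the daily sleep score maps the component sum onto 0-100", {
  grid <- expand.grid(d = 0:3, e = 0:3, i = 0:3)
  for (r in seq_len(nrow(grid))) {
    n <- night_row(7.5, window_hours = 9)
    n$duration_component <- grid$d[r]
    n$efficiency_component <- grid$e[r]
    n$disturbance_component <- grid$i[r]
    n$efficiency_ratio <- NA_real_
    s <- daily_sleep_score(n)$sleep_score
    expect_equal(s, 100 * (1 - sum(grid[r, ]) / 9))
    expect_gte(s, 0); expect_lte(s, 100)
  }
  best <- daily_sleep_score(sleep_components(night_row(8, window_hours = 8)))
  expect_equal(best$sleep_score, 100)
  # worst case: short, inefficient, heavily interrupted
  worst <- daily_sleep_score(sleep_components(
    night_row(4, window_hours = 10, interruptions = 5)))
  expect_equal(worst$sleep_score, 0)
  # intermediate hand-computed case: components 3, 0, 2 -> 44.4 to 1 dp
  mid <- night_row(4.5, window_hours = 5, interruptions = 2)
  expect_equal(round(daily_sleep_score(sleep_components(mid))$sleep_score, 1), 44.4)
})

test_that("sleep score is non-increasing in each component separately", {
  base <- night_row(7.5, window_hours = 8)
  for (col in c("duration_component", "efficiency_component",
                "disturbance_component")) {
    prev <- Inf
    for (v in 0:3) {
      n <- sleep_components(base)
      n[[col]] <- v
      s <- daily_sleep_score(n)$sleep_score
      expect_lt(s, prev)
      prev <- s
    }
  }
})

test_that("components stay in 0..3 for arbitrary random nights", {
  set.seed(99)
  for (rep in 1:200) {
    cum <- runif(1, 0.1, 14)
    window <- cum + runif(1, 0, 6)
    n <- sleep_components(night_row(cum, window_hours = window,
                                    interruptions = sample(0:10, 1)))
    comps <- c(n$duration_component, n$efficiency_component,
               n$disturbance_component)
    expect_true(all(comps %in% 0:3))
    s <- daily_sleep_score(n)$sleep_score
    expect_gte(s, 0); expect_lte(s, 100)
  }
})

test_that("a zero-length in-bed window is a degenerate-night error", {
  n <- night_row(0.5, window_hours = 0)
  expect_error(sleep_components(n), "degenerate",
               class = "parkscore_validation_error")
})
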
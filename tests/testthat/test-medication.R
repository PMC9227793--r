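one_day_score <- function(planned, taken, config = engine_config()) {
  occ <- occasion_score(match_and_classify(planned, taken, config), config)
  daily_medication_score(occ, config)$medication
}

test_that("delivered doses are matched and classified as stated by the rules", {
  # exact delivery
  occ <- match_and_classify(pd("2021-03-01 08:00"), td("2021-03-01 08:00"))
  expect_equal(occ$status, "on-schedule")
  expect_equal(occ$deviation_min, 0)

  # extra within 30 min of an unmatched planned time replaces it
  occ <- match_and_classify(pd("2021-03-01 08:00"),
                            td("2021-03-01 08:20", source = "extra"))
  expect_equal(occ$status, "replaced")
  expect_equal(occ$deviation_min, 20)

  # extra far from any planned time is credited as its own occasion
  occ <- match_and_classify(
    pd("2021-03-01 08:00"),
    td(c("2021-03-01 08:05", "2021-03-01 12:00"),
       source = c("scheduled-delivery", "extra")))
  expect_equal(occ$status, c("on-schedule", "extra-credited"))
  expect_equal(occ$deviation_min, c(5, NA))

  # unmatched planned dose is missed
  occ <- match_and_classify(pd(c("2021-03-01 08:00", "2021-03-01 14:00")),
                            td("2021-03-01 08:00"))
  expect_equal(occ$status, c("on-schedule", "missed"))

  expect_error(
    match_and_classify(pd(c("2021-03-01 08:00", "2021-03-01 08:00")),
                       td("2021-03-01 08:00")),
    class = "parkscore_validation_error")
})

test_that("occasion scores follow the deviation decay with its fixed points", {
  occ <- match_and_classify(
    pd(c("2021-03-01 08:00", "2021-03-01 12:00", "2021-03-01 16:00")),
    td(c("2021-03-01 08:00", "2021-03-01 13:00", "2021-03-01 23:00"),
       source = c("scheduled-delivery", "scheduled-delivery", "extra")))
  occ <- occasion_score(occ)
  scores <- setNames(occ$occasion_score, occ$status)
  expect_equal(unname(scores[occ$deviation_min %in% 0]), 100)  # zero deviation
  expect_equal(unname(scores[occ$deviation_min %in% 60]), 50)  # 60 of 120 max
  expect_equal(unname(scores[occ$status == "extra-credited"]), 100)
  expect_equal(unname(scores[occ$status == "missed"]), 0)

  # deviation beyond the maximum clamps at 0, never negative
  far <- occasion_score(match_and_classify(pd("2021-03-01 08:00"),
                                           td("2021-03-01 12:00")))
  expect_equal(far$occasion_score, 0)
})

test_that("the daily score is the mean over occasions and missing when none", {
  expect_equal(one_day_score(pd(c("2021-03-01 08:00", "2021-03-01 14:00")),
                             td(c("2021-03-01 08:00", "2021-03-01 14:00"))),
               100)
  # one perfect, one missed -> mean of 100 and 0
  expect_equal(one_day_score(pd(c("2021-03-01 08:00", "2021-03-01 14:00")),
                             td("2021-03-01 08:00")), 50)
  empty <- occasion_score(match_and_classify(pd(character(0)), td(character(0))))
  expect_true(is.na(daily_medication_score(empty)$medication))
  expect_equal(daily_medication_score(empty)$n, 0L)
})

test_that("increasing a matched deviation never increases the daily score", {
  planned <- pd(c("2021-03-01 08:00", "2021-03-01 14:00", "2021-03-01 20:00"))
  base_taken <- c("2021-03-01 08:05", "2021-03-01 14:00", "2021-03-01 20:10")
  prev <- Inf
  for (shift in c(0, 10, 25, 45, 90, 180)) {
    taken_times <- as.POSIXct(base_taken, tz = "UTC")
    taken_times[1] <- taken_times[1] + shift * 60
    s <- one_day_score(planned, td(taken_times))
    expect_lte(s, prev)
    prev <- s
  }
})

test_that("a replacement for an already-delivered intake is omitted entirely", {
  planned <- pd(c("2021-03-01 08:00", "2021-03-01 14:00"))
  taken <- td(c("2021-03-01 08:05", "2021-03-01 14:10"))
  with_extra <- rbind(taken, td("2021-03-01 08:15", source = "extra"))
  expect_equal(one_day_score(planned, with_extra), one_day_score(planned, taken))
})

test_that("with replacement_counts = 'omit' a replaced occasion leaves the mean", {
  planned <- pd(c("2021-03-01 08:00", "2021-03-01 14:00"))
  taken <- td(c("2021-03-01 08:29", "2021-03-01 14:00"),
              source = c("extra", "scheduled-delivery"))
  cfg_dev <- engine_config(replacement_counts = "deviation")
  cfg_omit <- engine_config(replacement_counts = "omit")
  expect_equal(one_day_score(planned, taken, cfg_dev),
               mean(c(100 * (1 - 29 / 120), 100)))
  expect_equal(one_day_score(planned, taken, cfg_omit), 100)
})

test_that("matching minimises total deviation (exhaustive oracle, small instances)", {
  set.seed(404)
  for (rep in 1:60) {
    m <- sample(1:5, 1)
    k <- sample(1:5, 1)
    short_n <- min(m, k); long_n <- max(m, k)
    short <- sort(sample(0:1440, short_n)) / 1
    long <- sort(sample(0:1440, long_n)) / 1
    got <- parkscore:::assign_min_deviation(short, long)
    expect_equal(length(got), short_n)
    expect_false(any(duplicated(got)))
    expect_equal(sum(abs(short - long[got])),
                 brute_force_min_deviation(short, long))
  }
})

test_that("matching through match_and_classify agrees with the assignment oracle", {
  set.seed(505)
  day0 <- as.POSIXct("2021-03-01 00:00", tz = "UTC")
  for (rep in 1:25) {
    n_p <- sample(2:5, 1)
    n_t <- sample(1:n_p, 1)
    p_min <- sort(sample(seq(360, 1380, by = 7), n_p))
    t_min <- sort(sample(seq(360, 1380, by = 3), n_t))
    occ <- match_and_classify(pd(day0 + p_min * 60), td(day0 + t_min * 60))
    matched <- occ[occ$status == "on-schedule", ]
    expect_equal(sum(matched$deviation_min),
                 brute_force_min_deviation(t_min, p_min))
  }
})
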
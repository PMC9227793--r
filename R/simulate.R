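# Seeded multi-stream scenario simulator. Generates all six raw streams for a
# synthetic patient together with the ground truth the recovery tests check
# against. The target is statistical structure sufficient to exercise the
# scoring engine (adherence noise, interrupted nights, dose-locked motor
# fluctuation, missing data) — not a clinically faithful disease model.

#' Simulator configuration
#'
#' All randomness flows from `seed`; per-stream sub-seeds are derived from it
#' deterministically, so changing one stream's parameters never perturbs the
#' draws of another.
#'
#' @param seed integer master seed.
#' @param days number of monitored days.
#' @param start_date first calendar day.
#' @param doses_per_day planned levodopa intakes per day, evenly spaced over
#'   the waking window 08:00-20:00.
#' @param dose_value,extra_dose_value dispensed dose sizes (levodopa units).
#' @param adherence_sd_min SD (minutes) of the Gaussian timing deviation of a
#'   delivered dose around its planned time, truncated at 3 SD.
#' @param miss_prob probability that a planned intake is never delivered.
#' @param extra_rate_per_day Poisson rate of extra doses, uniform over the
#'   waking window.
#' @param bedtime_h nominal hour of going to bed (jittered by
#'   `bed_jitter_min` minutes); `bed_duration_h` hours in bed follow. Set
#'   `bed_duration_h = 0` to disable the bed stream.
#' @param bed_jitter_min SD (minutes) of the bedtime jitter.
#' @param bed_duration_h nominal hours in bed per night.
#' @param interruption_rate_per_night Poisson rate of out-of-bed
#'   interruptions per night (5-20 minutes each).
#' @param motor_baseline baseline of both wrist-sensor channels (0-100,
#'   higher = better).
#' @param dose_response_amplitude peak improvement of the bradykinesia
#'   channel after each delivered dose; the dyskinesia channel dips by half
#'   this amplitude (dyskinesia worsens on medication). The response is a
#'   raised-cosine bump of width `dose_response_width_min` minutes.
#' @param dose_response_width_min width of the post-dose response bump.
#' @param motor_noise_sd SD of the Gaussian sample noise on both channels.
#' @param meal_count_per_day self-reported meals per day (0-6), at typical
#'   mealtimes jittered by 20 minutes SD.
#' @param exercise_prob_per_day probability of one reported exercise occasion
#'   (random mode, 20-60 minutes) on a day.
#' @param patient_target individual physical-activity target in (0, 100].
#' @param qol_vas_mean,qol_vas_sd mean and SD of the daily 0-100
#'   overall-health rating (clamped); item levels are drawn with
#'   probabilities 0.6 / 0.3 / 0.1 for levels 1 / 2 / 3.
#' @return A validated list of class `parkscore_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       days = 14L,
                       start_date = as.Date("2021-03-01"),
                       doses_per_day = 3L,
                       dose_value = 100,
                       extra_dose_value = 50,
                       adherence_sd_min = 15,
                       miss_prob = 0.05,
                       extra_rate_per_day = 0.2,
                       bedtime_h = 23,
                       bed_jitter_min = 20,
                       bed_duration_h = 8,
                       interruption_rate_per_night = 1,
                       motor_baseline = 70,
                       dose_response_amplitude = 15,
                       dose_response_width_min = 120,
                       motor_noise_sd = 5,
                       meal_count_per_day = 3L,
                       exercise_prob_per_day = 0.7,
                       patient_target = 80,
                       qol_vas_mean = 70,
                       qol_vas_sd = 10) {
  cfg <- as.list(environment())
  cfg$start_date <- as.Date(start_date)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(cond, msg) {
    if (!isTRUE(cond)) abort(paste("invalid simulator config:", msg),
                             class = "parkscore_config_error")
  }
  num1 <- function(key) is.numeric(cfg[[key]]) && length(cfg[[key]]) == 1 &&
    is.finite(cfg[[key]])
  chk(num1("seed") && cfg$seed == round(cfg$seed), "seed must be an integer")
  chk(num1("days") && cfg$days >= 1 && cfg$days == round(cfg$days),
      "days must be a positive integer")
  chk(num1("doses_per_day") && cfg$doses_per_day >= 0 &&
        cfg$doses_per_day == round(cfg$doses_per_day),
      "doses_per_day must be a non-negative integer")
  for (key in c("dose_value", "extra_dose_value")) {
    chk(num1(key) && cfg[[key]] > 0, paste(key, "must be > 0"))
  }
  for (key in c("adherence_sd_min", "extra_rate_per_day", "bed_jitter_min",
                "interruption_rate_per_night", "dose_response_width_min",
                "motor_noise_sd", "qol_vas_sd")) {
    chk(num1(key) && cfg[[key]] >= 0, paste(key, "must be >= 0"))
  }
  for (key in c("miss_prob", "exercise_prob_per_day")) {
    chk(num1(key) && cfg[[key]] >= 0 && cfg[[key]] <= 1,
        paste(key, "must be a probability in [0, 1]"))
  }
  chk(num1("bedtime_h") && cfg$bedtime_h >= 0 && cfg$bedtime_h < 24,
      "bedtime_h must be in [0, 24)")
  chk(num1("bed_duration_h") && cfg$bed_duration_h >= 0 &&
        cfg$bed_duration_h <= 20,
      "bed_duration_h must be in [0, 20]")
  chk(num1("motor_baseline") && cfg$motor_baseline >= 0 &&
        cfg$motor_baseline <= 100, "motor_baseline must be in [0, 100]")
  chk(num1("dose_response_amplitude"), "dose_response_amplitude must be a number")
  chk(num1("meal_count_per_day") && cfg$meal_count_per_day >= 0 &&
        cfg$meal_count_per_day <= 6 &&
        cfg$meal_count_per_day == round(cfg$meal_count_per_day),
      "meal_count_per_day must be an integer in 0..6")
  chk(num1("patient_target") && cfg$patient_target > 0 &&
        cfg$patient_target <= 100, "patient_target must be in (0, 100]")
  chk(num1("qol_vas_mean") && cfg$qol_vas_mean >= 0 && cfg$qol_vas_mean <= 100,
      "qol_vas_mean must be in [0, 100]")
  chk(inherits(cfg$start_date, "Date") && !is.na(cfg$start_date),
      "start_date must be a Date")
  structure(cfg, class = "parkscore_sim_config")
}

# run expr under a private RNG state seeded with `seed`
with_sub_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

day_ts <- function(date, minute_of_day) {
  as.POSIXct(as.numeric(as.POSIXct(format(date), tz = .TZ)) +
               round(minute_of_day) * 60, origin = "1970-01-01", tz = .TZ)
}

#' Simulate a patient scenario with known ground truth
#'
#' Generates all six streams under `config`, deterministically given the
#' seed. Planned intakes are evenly spaced over the waking hours; delivered
#' times add truncated Gaussian deviations with occasional misses and
#' Poisson extra doses; nights have the configured duration with Poisson
#' interruptions; motor samples every 2 minutes follow baseline plus a
#' raised-cosine dose-locked response plus noise, clamped to 0-100; meals,
#' exercise and QoL responses are drawn per configuration.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return A list with `scenario` (a [scenario()]) and `ground_truth`, a list
#'   holding the realised per-day truth: `medication` (mean absolute
#'   deviation, miss/extra counts), `nights` (cumulative hours, interruption
#'   counts, efficiency ratio), `motor` (noise-free channel means) and
#'   `meals` (within-window compliant fraction), plus the config.
#' @export
#' @examples
#' sim <- simulate_scenario(sim_config(seed = 42, days = 5))
#' sim$scenario
#' sim$ground_truth$medication
simulate_scenario <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "parkscore_sim_config"))
  if (!is.null(seed)) {
    config$seed <- seed
    config <- validate_sim_config(config)
  }
  sub_seeds <- with_sub_seed(config$seed, sample.int(2^31 - 2, 8))
  dates <- config$start_date + seq_len(config$days) - 1

  ## planned + delivered medication -----------------------------------------
  k <- config$doses_per_day
  dose_minutes <- if (k == 0) numeric(0)
    else if (k == 1) 8 * 60
    else seq(8 * 60, 20 * 60, length.out = k)
  planned <- tibble::tibble(
    time = do.call(c, lapply(dates, day_ts, minute_of_day = dose_minutes)),
    dose = rep(config$dose_value, length(dates) * k)
  )
  if (k == 0) planned <- empty_stream("planned_doses")

  med <- with_sub_seed(sub_seeds[1], {
    n <- nrow(planned)
    dev <- rnorm(n, 0, config$adherence_sd_min)
    lim <- 3 * config$adherence_sd_min
    dev <- round(pmin(pmax(dev, -lim), lim))
    missed <- runif(n) < config$miss_prob
    list(dev = dev, missed = missed)
  })
  taken <- tibble::tibble(
    time = planned$time + med$dev * 60,
    dose = planned$dose,
    source = "scheduled-delivery"
  )[!med$missed, , drop = FALSE]

  extras <- with_sub_seed(sub_seeds[2], {
    n_extra <- rpois(length(dates), config$extra_rate_per_day)
    times <- lapply(seq_along(dates), function(i) {
      if (n_extra[i] == 0) return(NULL)
      day_ts(dates[i], sort(runif(n_extra[i], 8 * 60, 22 * 60)))
    })
    times <- times[!vapply(times, is.null, logical(1))]
    if (length(times) == 0) empty_stream("taken_doses")
    else tibble::tibble(time = do.call(c, times),
                        dose = config$extra_dose_value, source = "extra")
  })
  taken_all <- dplyr::bind_rows(taken, extras)
  taken_all <- taken_all[order(taken_all$time), , drop = FALSE]

  gt_med <- tibble::tibble(
    date = dates,
    mean_abs_deviation_min = vapply(dates, function(d) {
      idx <- which(ts_date(planned$time) == d & !med$missed)
      if (length(idx) == 0) NA_real_ else mean(abs(med$dev[idx]))
    }, numeric(1)),
    n_planned = vapply(dates, function(d) sum(ts_date(planned$time) == d),
                       numeric(1)),
    n_missed = vapply(dates, function(d) {
      sum(ts_date(planned$time) == d & med$missed)
    }, numeric(1)),
    n_extra = vapply(dates, function(d) sum(ts_date(extras$time) == d),
                     numeric(1))
  )

  ## bed intervals ----------------------------------------------------------
  beds <- with_sub_seed(sub_seeds[3], {
    if (config$bed_duration_h == 0) {
      list(intervals = empty_stream("bed_intervals"), nights = NULL)
    } else {
      per_night <- lapply(seq_along(dates), function(i) {
        enter_min <- config$bedtime_h * 60 +
          round(rnorm(1, 0, config$bed_jitter_min))
        enter <- day_ts(dates[i] - 1, enter_min)
        leave <- enter + max(1, round(config$bed_duration_h * 60)) * 60
        night_len <- mins_between(enter, leave)
        n_int <- rpois(1, config$interruption_rate_per_night)
        gaps <- NULL
        if (n_int > 0 && night_len > 90) {
          g_dur <- round(runif(n_int, 5, 20))
          g_start <- round(runif(n_int, 15, night_len - 40))
          o <- order(g_start)
          g_start <- g_start[o]
          g_dur <- g_dur[o]
          # colliding draws are dropped; realised counts are recorded as truth
          keep <- logical(n_int)
          last_end <- -Inf
          for (g in seq_len(n_int)) {
            if (g_start[g] > last_end + 2) {
              keep[g] <- TRUE
              last_end <- g_start[g] + g_dur[g]
            }
          }
          gaps <- cbind(start = g_start[keep], dur = g_dur[keep])
        }
        if (is.null(gaps) || nrow(gaps) == 0) {
          iv <- tibble::tibble(enter = enter, leave = leave)
        } else {
          cuts <- c(0, as.vector(t(cbind(gaps[, "start"],
                                         gaps[, "start"] + gaps[, "dur"]))),
                    night_len)
          starts <- cuts[seq(1, length(cuts) - 1, by = 2)]
          ends <- cuts[seq(2, length(cuts), by = 2)]
          iv_enter <- enter + starts * 60
          iv_leave <- enter + ends * 60
          iv <- tibble::tibble(enter = iv_enter, leave = iv_leave)
        }
        list(intervals = iv,
             truth = tibble::tibble(
               wake_date = ts_date(iv$leave[nrow(iv)]),
               cumulative_hours = sum(hours_between(iv$enter, iv$leave)),
               window_hours = hours_between(iv$enter[1], iv$leave[nrow(iv)]),
               interruptions = nrow(iv) - 1L
             ))
      })
      list(intervals = dplyr::bind_rows(lapply(per_night, `[[`, "intervals")),
           nights = dplyr::bind_rows(lapply(per_night, `[[`, "truth")))
    }
  })
  gt_nights <- beds$nights
  if (!is.null(gt_nights)) {
    gt_nights$efficiency_ratio <-
      100 * gt_nights$cumulative_hours / gt_nights$window_hours
  }

  ## motor samples ----------------------------------------------------------
  sample_min <- seq(0, 24 * 60 - 2, by = 2)
  bump_width <- config$dose_response_width_min
  motor <- with_sub_seed(sub_seeds[4], {
    per_day <- lapply(seq_along(dates), function(i) {
      t_abs <- as.numeric(day_ts(dates[i], sample_min)) / 60  # minutes
      response <- rep(0, length(t_abs))
      if (nrow(taken_all) > 0 && bump_width > 0) {
        dose_min <- as.numeric(taken_all$time) / 60
        near <- dose_min[dose_min > min(t_abs) - bump_width &
                           dose_min < max(t_abs) + bump_width]
        for (dm in near) {
          x <- (t_abs - dm) / bump_width
          inside <- x > 0 & x < 1
          response[inside] <- response[inside] +
            0.5 * (1 - cos(2 * pi * x[inside]))
        }
      }
      brady_clean <- pmin(100, pmax(0, config$motor_baseline +
                                      config$dose_response_amplitude * response))
      dysk_clean <- pmin(100, pmax(0, config$motor_baseline -
                                     0.5 * config$dose_response_amplitude * response))
      noise_b <- rnorm(length(t_abs), 0, config$motor_noise_sd)
      noise_d <- rnorm(length(t_abs), 0, config$motor_noise_sd)
      list(samples = tibble::tibble(
             time = day_ts(dates[i], sample_min),
             bradykinesia = round(pmin(100, pmax(0, brady_clean + noise_b)), 4),
             dyskinesia = round(pmin(100, pmax(0, dysk_clean + noise_d)), 4)),
           truth = tibble::tibble(date = dates[i],
                                  bradykinesia_mean = mean(brady_clean),
                                  dyskinesia_mean = mean(dysk_clean)))
    })
    list(samples = dplyr::bind_rows(lapply(per_day, `[[`, "samples")),
         truth = dplyr::bind_rows(lapply(per_day, `[[`, "truth")))
  })

  ## meals ------------------------------------------------------------------
  typical_meals <- c(8.5, 13, 19, 10.5, 16, 21) * 60
  meals <- with_sub_seed(sub_seeds[5], {
    m <- config$meal_count_per_day
    if (m == 0) empty_stream("meals")
    else tibble::tibble(time = do.call(c, lapply(dates, function(d) {
      day_ts(d, sort(typical_meals[seq_len(m)] + rnorm(m, 0, 20)))
    })))
  })

  ## exercise ---------------------------------------------------------------
  exercise <- with_sub_seed(sub_seeds[6], {
    rows <- lapply(dates, function(d) {
      if (runif(1) >= config$exercise_prob_per_day) return(NULL)
      tibble::tibble(time = day_ts(d, 17 * 60 + round(rnorm(1, 0, 30))),
                     mode = sample(1:3, 1),
                     duration = round(runif(1, 20, 60), 1))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0) empty_stream("exercise") else dplyr::bind_rows(rows)
  })

  ## quality of life --------------------------------------------------------
  qol <- with_sub_seed(sub_seeds[7], {
    q <- tibble::tibble(date = dates)
    for (i in 1:8) {
      q[[paste0("q", i)]] <- sample(1:3, length(dates), replace = TRUE,
                                    prob = c(0.6, 0.3, 0.1))
    }
    q$vas <- round(pmin(100, pmax(0, rnorm(length(dates), config$qol_vas_mean,
                                           config$qol_vas_sd))), 1)
    q
  })

  sc <- scenario(
    patient_id = sprintf("sim-%d", config$seed),
    patient_target = config$patient_target,
    planned_doses = planned, taken_doses = taken_all,
    bed_intervals = beds$intervals, motor_samples = motor$samples,
    meals = meals, exercise = exercise, qol = qol
  )

  # realised within-window meal compliance, counted directly per day
  ecfg <- engine_config()
  gt_meals <- tibble::tibble(
    date = dates,
    compliant_fraction = vapply(dates, function(d) {
      m <- sc$streams$meals$time[ts_date(sc$streams$meals$time) == d]
      if (length(m) == 0) return(NA_real_)
      intakes <- sc$streams$taken_doses$time[
        ts_date(sc$streams$taken_doses$time) == d]
      ok <- vapply(m, function(t) {
        if (length(intakes) == 0) return(TRUE)
        off <- mins_between(intakes, t)
        !any(off >= -ecfg$meal_window_before_min &
               off <= ecfg$meal_window_after_min)
      }, logical(1))
      mean(ok)
    }, numeric(1))
  )

  list(
    scenario = sc,
    ground_truth = list(
      config = config,
      medication = gt_med,
      nights = gt_nights,
      motor = motor$truth,
      meals = gt_meals
    )
  )
}
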
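# Timestamps are minute-resolution, timezone-naive local time. Internally they
# are POSIXct pinned to UTC so arithmetic never crosses a DST boundary; the UTC
# label is a storage convention, not a claim about the patient's clock.

.TZ <- "UTC"

#' Parse minute-resolution local timestamps
#'
#' Accepts `POSIXct`, or ISO 8601 character strings (`"2021-03-01 08:00"`,
#' `"2021-03-01T08:00:00"`); seconds are truncated to whole minutes.
#'
#' @param x vector of timestamps.
#' @param what label used in error messages (e.g. a stream/column name).
#' @return `POSIXct` vector (UTC-pinned local time), floored to the minute.
#' @keywords internal
parse_ts <- function(x, what = "timestamp") {
  if (inherits(x, "POSIXct")) {
    out <- as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = .TZ)
  } else {
    chr <- gsub("T", " ", as.character(x), fixed = TRUE)
    out <- as.POSIXct(rep(NA_real_, length(chr)), origin = "1970-01-01",
                      tz = .TZ)
    for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
      idx <- which(is.na(out) & !is.na(chr))
      if (length(idx) == 0) break
      out[idx] <- as.POSIXct(strptime(chr[idx], fmt, tz = .TZ), tz = .TZ)
    }
  }
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    abort(sprintf("malformed %s at row %d: '%s'", what, bad[1],
                  as.character(x[bad[1]])),
          class = "parkscore_parse_error")
  }
  floor_minute(out)
}

floor_minute <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 60) * 60, origin = "1970-01-01", tz = .TZ)
}

parse_date <- function(x, what = "date") {
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    abort(sprintf("malformed %s at row %d: '%s'", what, bad[1],
                  as.character(x[bad[1]])),
          class = "parkscore_parse_error")
  }
  out
}

#' @keywords internal
ts_date <- function(t) as.Date(t, tz = .TZ)

# minutes between two POSIXct vectors (b - a)
mins_between <- function(a, b) as.numeric(difftime(b, a, units = "mins"))

hours_between <- function(a, b) as.numeric(difftime(b, a, units = "hours"))

# minute-of-day, fractional days allowed
time_of_day_min <- function(t) {
  as.numeric(t) %% 86400 / 60
}

fmt_ts <- function(t) format(t, "%Y-%m-%d %H:%M", tz = .TZ)
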
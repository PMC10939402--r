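#' Read a daily weather table
#'
#' Reads a CSV of daily minimum/maximum air temperatures, validates it and
#' returns a date-sorted `daily_weather` data frame. Column names in the file
#' are mapped through `dialect`, so arbitrary source schemas can be read.
#'
#' @param path Path to a CSV file.
#' @param dialect Named character vector mapping the canonical columns
#'   `date`, `tmin`, `tmax` (and optionally `latitude`) to the column names
#'   used in the file.
#' @param gaps How to treat missing calendar days between the first and last
#'   date: `"strict"` raises an error; `"permissive"` linearly imputes runs of
#'   up to 3 missing days (longer runs still error) and records the imputed
#'   dates in the `"imputed_dates"` attribute.
#' @return A `daily_weather` data frame with columns `date` (Date), `tmin`,
#'   `tmax` (numeric, degrees C) and optionally `latitude`, sorted by date.
#' @export
read_daily_weather <- function(path,
                               dialect = c(date = "date", tmin = "tmin",
                                           tmax = "tmax"),
                               gaps = c("strict", "permissive")) {
  gaps <- match.arg(gaps)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("date", "tmin", "tmax")
  for (canon in needed) {
    src <- dialect_col(dialect, canon)
    if (!src %in% names(raw))
      stop_schema("weather file '%s' lacks required column '%s' (mapped from '%s')",
                  path, src, canon)
  }
  df <- data.frame(
    date = as.Date(raw[[dialect_col(dialect, "date")]]),
    tmin = as.numeric(raw[[dialect_col(dialect, "tmin")]]),
    tmax = as.numeric(raw[[dialect_col(dialect, "tmax")]])
  )
  lat_src <- dialect_col(dialect, "latitude")
  if (lat_src %in% names(raw))
    df$latitude <- as.numeric(raw[[lat_src]])
  daily_weather(df, gaps = gaps)
}

#' Construct and validate a daily weather table
#'
#' @param df Data frame with `date`, `tmin`, `tmax` columns.
#' @inheritParams read_daily_weather
#' @return A validated, sorted `daily_weather` data frame.
#' @export
daily_weather <- function(df, gaps = c("strict", "permissive")) {
  gaps <- match.arg(gaps)
  if (!all(c("date", "tmin", "tmax") %in% names(df)))
    stop_schema("daily weather needs columns date, tmin, tmax")
  df$date <- as.Date(df$date)
  if (anyNA(df$date))
    stop_validation("unparseable dates in daily weather")
  df <- df[order(df$date), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df$date))
    stop_validation("duplicated dates in daily weather: %s",
                    paste(unique(df$date[duplicated(df$date)]), collapse = ", "))
  if (anyNA(df$tmin) || anyNA(df$tmax))
    stop_validation("missing tmin/tmax values in daily weather")
  bad <- df$tmin > df$tmax
  if (any(bad))
    stop_validation("tmin exceeds tmax on: %s",
                    paste(df$date[bad], collapse = ", "))

  all_days <- seq(min(df$date), max(df$date), by = "day")
  missing <- setdiff(as.character(all_days), as.character(df$date))
  if (length(missing)) {
    if (gaps == "strict")
      stop_validation("missing daily records for: %s",
                      paste(missing, collapse = ", "))
    df <- impute_daily_gaps(df, all_days)
  }
  class(df) <- c("daily_weather", "data.frame")
  df
}

# Linear imputation of short gaps (<= 3 consecutive missing days).
impute_daily_gaps <- function(df, all_days) {
  full <- data.frame(date = all_days)
  full <- merge(full, df, by = "date", all.x = TRUE, sort = TRUE)
  miss <- is.na(full$tmin)
  runs <- rle(miss)
  if (any(runs$lengths[runs$values] > 3L)) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    long <- which(runs$values & runs$lengths > 3L)
    stop_validation("weather gap longer than 3 days starting %s",
                    paste(full$date[starts[long]], collapse = ", "))
  }
  for (col in intersect(c("tmin", "tmax", "latitude"), names(full))) {
    full[[col]] <- stats::approx(x = as.numeric(full$date[!miss]),
                                 y = full[[col]][!miss],
                                 xout = as.numeric(full$date))$y
  }
  attr(full, "imputed_dates") <- full$date[miss]
  full
}

#' Estimate hourly temperatures from daily minima and maxima
#'
#' Expands daily tmin/tmax into an hourly series using an idealized diurnal
#' curve: temperature follows a sine from the morning minimum (at sunrise) to
#' the afternoon maximum, and a logarithmic decay through the night toward
#' the next morning's minimum. With the fixed default day geometry (sunrise
#' 06:00, sunset 18:00) the sine peaks at 14:00, so each day's hourly maximum
#' equals its `tmax` and the sunrise hour equals its `tmin`.
#'
#' @param daily A `daily_weather` data frame (or coercible data frame).
#' @param site_id Site identifier stored with the series.
#' @param sunrise_hour,sunset_hour Day-period boundaries, local standard time
#'   (no daylight-saving shifts; the series is a strict 24-hour grid).
#' @return A `temperature_series` data frame with columns `datetime`
#'   (POSIXct, UTC-anchored local standard time), `date`, `hour`, `temp`,
#'   `site_id`; exactly 24 rows per input day.
#' @export
interpolate_hourly <- function(daily, site_id = "site",
                               sunrise_hour = 6, sunset_hour = 18) {
  if (!inherits(daily, "daily_weather")) daily <- daily_weather(daily)
  n <- nrow(daily)
  if (n < 1L) stop_validation("interpolate_hourly needs at least one day")
  daylen <- sunset_hour - sunrise_hour
  night_len <- 24 - daylen
  # temperature at sunset on the daytime sine
  sunset_frac <- sin(pi * daylen / (daylen + 4))

  tmin <- daily$tmin
  tmax <- daily$tmax
  t_sunset <- tmin + (tmax - tmin) * sunset_frac
  # boundary convention: first day reuses itself as "previous day", last day
  # reuses itself as "next day" (keeps identical consecutive days identical)
  tmin_next <- c(tmin[-1], tmin[n])
  t_sunset_prev <- c(t_sunset[1], t_sunset[-n])
  tmin_today <- tmin

  hours <- 0:23
  temp <- matrix(NA_real_, nrow = 24, ncol = n)
  for (h in hours) {
    if (h >= sunrise_hour && h <= sunset_hour) {
      temp[h + 1, ] <- tmin + (tmax - tmin) *
        sin(pi * (h - sunrise_hour) / (daylen + 4))
    } else if (h < sunrise_hour) {
      tau <- h + 24 - sunset_hour          # hours since previous sunset
      temp[h + 1, ] <- t_sunset_prev - (t_sunset_prev - tmin_today) *
        log(1 + tau) / log(1 + night_len)
    } else {
      tau <- h - sunset_hour
      temp[h + 1, ] <- t_sunset - (t_sunset - tmin_next) *
        log(1 + tau) / log(1 + night_len)
    }
  }

  datetime <- as.POSIXct(paste(rep(daily$date, each = 24),
                               sprintf("%02d:00:00", rep(hours, n))),
                         tz = "UTC")
  out <- data.frame(
    datetime = datetime,
    date = rep(daily$date, each = 24),
    hour = rep(hours, n),
    temp = as.vector(temp),
    site_id = site_id,
    stringsAsFactors = FALSE
  )
  class(out) <- c("temperature_series", "data.frame")
  out
}

#' Read LT50 observations
#'
#' Reads a CSV of bud LT50 measurements (date, site, cultivar, lt50).
#' Rows whose cultivar is not in `roster` are kept but reported through the
#' `"flagged"` attribute; unparseable LT50 values are row-level errors.
#'
#' @param path Path to a CSV file with columns `date`, `site`, `cultivar`,
#'   `lt50` (remappable through `dialect`).
#' @param roster Character vector of known cultivar names.
#' @param dialect Named character vector remapping canonical column names.
#' @return Data frame of validated records sorted by date; attribute
#'   `"flagged"` holds row indices with cultivars outside the roster.
#' @export
read_lt50 <- function(path, roster = default_roster(),
                      dialect = c(date = "date", site = "site",
                                  cultivar = "cultivar", lt50 = "lt50")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (canon in c("date", "site", "cultivar", "lt50")) {
    src <- dialect_col(dialect, canon)
    if (!src %in% names(raw))
      stop_schema("LT50 file '%s' lacks required column '%s'", path, src)
  }
  if (nrow(raw) == 0L) {
    warning("LT50 file '", path, "' contains no rows")
    out <- data.frame(date = as.Date(character()), site = character(),
                      cultivar = character(), lt50 = numeric())
    attr(out, "flagged") <- integer()
    return(out)
  }
  lt50_raw <- raw[[dialect_col(dialect, "lt50")]]
  lt50 <- suppressWarnings(as.numeric(lt50_raw))
  bad <- which(!is.finite(lt50))
  if (length(bad))
    stop_validation("unparseable lt50 value(s) at row(s) %s: %s",
                    paste(bad, collapse = ", "),
                    paste(lt50_raw[bad], collapse = ", "))
  out <- data.frame(
    date = as.Date(raw[[dialect_col(dialect, "date")]]),
    site = as.character(raw[[dialect_col(dialect, "site")]]),
    cultivar = as.character(raw[[dialect_col(dialect, "cultivar")]]),
    lt50 = lt50,
    stringsAsFactors = FALSE
  )
  if (anyNA(out$date)) stop_validation("unparseable dates in LT50 file")
  if (any(out$lt50 > 0))
    warning("positive LT50 values present (expected <= 0 degrees C)")
  ord <- order(out$date)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flagged") <- which(!out$cultivar %in% roster)
  out
}
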
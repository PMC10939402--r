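#' One-hot encode a cultivar name
#'
#' @param name Cultivar name; must be present in `roster`.
#' @param roster Character vector of cultivar names with fixed order.
#' @return Integer 0/1 vector of length `length(roster)`, named
#'   `cultivar_<name>`, with exactly one 1 at the roster position of `name`.
#' @export
#' @examples
#' one_hot_cultivar("Riesling", default_roster())
one_hot_cultivar <- function(name, roster = default_roster()) {
  validate_roster(roster)
  idx <- match(name, roster)
  if (is.na(idx)) {
    near <- roster[utils::adist(name, roster, ignore.case = TRUE) <= 2]
    hint <- if (length(near)) paste0("; did you mean: ",
                                     paste(near, collapse = ", "), "?") else ""
    stop_validation("unknown cultivar '%s'%s", name, hint)
  }
  v <- integer(length(roster))
  v[idx] <- 1L
  names(v) <- cultivar_feature_names(roster)
  v
}

cultivar_feature_names <- function(roster) {
  paste0("cultivar_", gsub("[^A-Za-z0-9]+", "_", roster))
}

#' Days elapsed in the dormancy season
#'
#' The dormancy season is keyed to 1 September: 1 September itself is day 0,
#' and dates in January through August count from the previous year's
#' 1 September.
#'
#' @param date A `Date` vector (or coercible).
#' @return Integer vector of days since the season's 1 September.
#' @export
#' @examples
#' days_in_season(as.Date("2021-09-01"))  # 0
#' days_in_season(as.Date("2022-01-01"))  # 122
days_in_season <- function(date) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  mo <- as.integer(format(date, "%m"))
  start_year <- ifelse(mo >= 9L, yr, yr - 1L)
  start <- as.Date(sprintf("%d-09-01", start_year))
  as.integer(date - start)
}

#' Season start date for a given date
#'
#' @inheritParams days_in_season
#' @return `Date` vector: the 1 September opening the dormancy season each
#'   date belongs to.
#' @export
season_start <- function(date) {
  as.Date(date) - days_in_season(date)
}

# Normalized exponential weights over a trailing window of n days, oldest
# first. alpha = 2/(n+1) (span convention); newest day gets the largest
# weight.
ewma_weights <- function(n, alpha = 2 / (n + 1)) {
  if (!is_scalar_number(n) || n < 1) stop_validation("window size must be >= 1")
  w <- (1 - alpha)^((n - 1):0)
  w / sum(w)
}

#' Exponentially weighted moving-average temperature
#'
#' Computes the EWMA of a daily temperature statistic over a hard trailing
#' window of `n` days ending at the last element of `x`: weights ascend
#' exponentially from the oldest to the newest day (ratio `1 - alpha` per
#' day, `alpha = 2/(n+1)`), renormalized to sum to one. The result is a
#' convex combination, so it always lies within the range of the window.
#'
#' @param x Numeric vector of daily values, oldest first; the last `n`
#'   entries form the window. If fewer than `n` values are supplied the
#'   available window is used with renormalized weights (`partial = TRUE`);
#'   with `partial = FALSE` this is an error.
#' @param n Window size in days.
#' @param partial Allow windows shorter than `n` (renormalized weights).
#' @return Scalar weighted mean (degrees C).
#' @export
#' @examples
#' ewma(c(10, 20), 2)   # 0.75*20 + 0.25*10 = 17.5
ewma <- function(x, n, partial = TRUE) {
  if (!length(x)) stop_validation("ewma: empty series")
  m <- min(n, length(x))
  if (length(x) < n && !partial)
    stop_compute("ewma: window of %d days requested but only %d available",
                 n, length(x))
  # alpha stays anchored to the requested span; short early-season windows
  # keep the newest-m weights, renormalized
  alpha <- 2 / (n + 1)
  w <- (1 - alpha)^((m - 1):0)
  w <- w / sum(w)
  win <- x[(length(x) - m + 1):length(x)]
  sum(w * win)
}

#' Reverse exponentially weighted moving-average temperature
#'
#' REWMA reverses the trailing window before applying the EWMA, so the
#' weight descends exponentially from the oldest day of the window to the
#' newest: early temperatures dominate. Encodes cold-priming / cold-shock
#' memory of the preceding window.
#'
#' @inheritParams ewma
#' @return Scalar weighted mean (degrees C).
#' @export
#' @examples
#' rewma(c(10, 20), 2)  # 0.75*10 + 0.25*20 = 12.5
rewma <- function(x, n, partial = TRUE) {
  if (!length(x)) stop_validation("rewma: empty series")
  m <- min(n, length(x))
  if (length(x) < n && !partial)
    stop_compute("rewma: window of %d days requested but only %d available",
                 n, length(x))
  win <- x[(length(x) - m + 1):length(x)]
  ewma(rev(win), n)
}

# Rolling EWMA/REWMA over a whole daily series; returns one value per day.
rolling_ewma <- function(x, n, reverse = FALSE) {
  fn <- if (reverse) rewma else ewma
  vapply(seq_along(x), function(i) fn(x[seq_len(i)], n), numeric(1))
}

# --- chilling accumulation weight tables ------------------------------------

# Richardson et al. (Utah model) hourly chill-unit weights, degrees C bands.
.utah_breaks <- c(-Inf, 1.4, 2.4, 9.1, 12.4, 15.9, 18, Inf)
.utah_weights <- c(0, 0.5, 1, 0.5, 0, -0.5, -1)

# Shaltout & Unrath (North Carolina model) hourly chill-unit weights.
.nc_breaks <- c(-Inf, -1.1, 1.6, 7.2, 13, 16.5, 19, 20.7, 22.1, Inf)
.nc_weights <- c(0, 0.5, 1, 0.5, 0, -0.5, -1, -1.5, -2)

chill_weight <- function(temp, breaks, weights) {
  weights[findInterval(temp, breaks, left.open = TRUE)]
}

extract_temps <- function(hourly, through = NULL, from = NULL) {
  if (inherits(hourly, "temperature_series")) {
    keep <- rep(TRUE, nrow(hourly))
    if (!is.null(from)) keep <- keep & hourly$date >= as.Date(from)
    if (!is.null(through)) keep <- keep & hourly$date <= as.Date(through)
    temps <- hourly$temp[keep]
  } else {
    temps <- as.numeric(hourly)
  }
  if (anyNA(temps)) stop_validation("non-finite hourly temperatures")
  temps
}

#' Utah-model chilling accumulation
#'
#' Sums the Richardson (Utah) per-hour chill-unit weights over an hourly
#' temperature series. The weight table is piecewise over temperature bands
#' and carries negative weights above 16 degrees C, so accumulation can
#' decrease during warm spells.
#'
#' @param hourly A `temperature_series` or a plain numeric vector of hourly
#'   temperatures (degrees C).
#' @param through Optional last date (inclusive) when `hourly` is a series.
#' @param from Optional first date; defaults to the full series (callers
#'   normally pass a series already clipped to the season).
#' @return Scalar chill units.
#' @export
#' @examples
#' utah_chill(rep(5, 10))   # 10
#' utah_chill(rep(20, 5))   # -5
utah_chill <- function(hourly, through = NULL, from = NULL) {
  temps <- extract_temps(hourly, through, from)
  sum(chill_weight(temps, .utah_breaks, .utah_weights))
}

#' North Carolina model chilling accumulation
#'
#' As [utah_chill()], but with the Shaltout-Unrath (North Carolina) weight
#' curve, whose negative weights extend to -2 above 22.1 degrees C.
#'
#' @inheritParams utah_chill
#' @return Scalar chill units.
#' @export
nc_chill <- function(hourly, through = NULL, from = NULL) {
  temps <- extract_temps(hourly, through, from)
  sum(chill_weight(temps, .nc_breaks, .nc_weights))
}

#' Chilling hours (0-7.2 degrees C)
#'
#' Count of hours with temperature in (0, 7.2] degrees C.
#'
#' @inheritParams utah_chill
#' @return Scalar hour count.
#' @export
chill_hours <- function(hourly, through = NULL, from = NULL) {
  temps <- extract_temps(hourly, through, from)
  sum(temps > 0 & temps <= 7.2)
}

#' Growing degree hours
#'
#' Accumulated heat above a base temperature:
#' `sum over hours of max(0, T - base)`.
#'
#' @inheritParams utah_chill
#' @param base Base temperature, degrees C.
#' @return Scalar degree-hours.
#' @export
#' @examples
#' gdh(rep(12, 10), base = 10)  # 20
gdh <- function(hourly, through = NULL, from = NULL, base = 10) {
  temps <- extract_temps(hourly, through, from)
  sum(pmax(0, temps - base))
}

#' Freezing degree hours
#'
#' Accumulated sub-zero cold magnitude: `sum over hours of max(0, -T)`.
#'
#' @inheritParams utah_chill
#' @return Scalar degree-hours below 0 degrees C (nonnegative).
#' @export
freezing_degree_hours <- function(hourly, through = NULL, from = NULL) {
  temps <- extract_temps(hourly, through, from)
  sum(pmax(0, -temps))
}
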
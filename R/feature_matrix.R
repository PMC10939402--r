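#' Feature configuration
#'
#' Describes the feature set assembled for each (site, date, cultivar)
#' sample. The default configuration reproduces the 117-column study layout:
#' 45 cultivar indicators + days in season + 3 daily descriptors (that day's
#' mean/max/min) + 3 chilling accumulations (Utah, North Carolina, chilling
#' hours) + 4 growing-degree-hour accumulations (bases 0/4/7/10 degrees C) +
#' 1 freezing-degree-hour accumulation + 60 EWMA/REWMA temperatures
#' (window sizes 2-20 days in steps of 2, over daily mean/max/min, forward
#' and reversed).
#'
#' @param roster Cultivar roster (fixed order; serialized with models).
#' @param windows EWMA/REWMA window sizes in days.
#' @param stats Daily statistics smoothed by EWMA/REWMA.
#' @param gdh_bases Base temperatures for growing degree hours.
#' @return A `feature_config` list with a stable `hash`.
#' @export
#' @examples
#' length(feature_names(feature_config()))  # 117
feature_config <- function(roster = default_roster(),
                           windows = seq(2, 20, by = 2),
                           stats = c("mean", "max", "min"),
                           gdh_bases = c(0, 4, 7, 10)) {
  validate_roster(roster)
  if (!all(windows >= 1)) stop_validation("window sizes must be >= 1 day")
  stats <- match.arg(stats, several.ok = TRUE)
  cfg <- list(roster = as.character(roster), windows = as.integer(windows),
              stats = stats, gdh_bases = as.numeric(gdh_bases))
  cfg$hash <- rlang::hash(cfg[c("roster", "windows", "stats", "gdh_bases")])
  class(cfg) <- "feature_config"
  cfg
}

#' Ordered feature names for a configuration
#'
#' @param config A [feature_config()].
#' @return Character vector of feature (column) names in their fixed order.
#' @export
feature_names <- function(config = feature_config()) {
  ew <- unlist(lapply(c("ewma", "rewma"), function(dir)
    unlist(lapply(config$stats, function(st)
      paste0(dir, "_", st, "_", config$windows)))))
  c(cultivar_feature_names(config$roster),
    "days_in_season",
    c("t_mean", "t_max", "t_min"),
    c("chill_utah", "chill_nc", "chill_hours"),
    paste0("gdh_base", config$gdh_bases),
    "fdh",
    ew)
}

# Names of the EWMA/REWMA block only.
ewma_feature_names <- function(config = feature_config()) {
  grep("^r?ewma_", feature_names(config), value = TRUE)
}

# Per-day summary of an hourly series: daily stats plus per-day sums of each
# cumulative accumulator's hourly weights. One row per covered day.
daily_summary <- function(hourly, config) {
  if (!inherits(hourly, "temperature_series"))
    stop_schema("expected a temperature_series (see interpolate_hourly)")
  counts <- table(hourly$date)
  if (any(counts != 24L))
    stop_validation("hourly series must hold 24 values per day; offending: %s",
                    paste(names(counts)[counts != 24L], collapse = ", "))
  dates <- as.Date(names(counts))
  if (any(diff(dates) != 1L))
    stop_validation("hourly series has day gaps at: %s",
                    paste(dates[which(diff(dates) != 1L) + 1L], collapse = ", "))
  temp <- hourly$temp
  if (any(!is.finite(temp))) stop_validation("non-finite hourly temperatures")
  g <- match(hourly$date, dates)
  day <- data.frame(
    date = dates,
    t_mean = as.numeric(tapply(temp, g, mean)),
    t_max = as.numeric(tapply(temp, g, max)),
    t_min = as.numeric(tapply(temp, g, min)),
    chill_utah = as.numeric(tapply(chill_weight(temp, .utah_breaks, .utah_weights), g, sum)),
    chill_nc = as.numeric(tapply(chill_weight(temp, .nc_breaks, .nc_weights), g, sum)),
    chill_hours = as.numeric(tapply(temp > 0 & temp <= 7.2, g, sum)),
    fdh = as.numeric(tapply(pmax(0, -temp), g, sum))
  )
  for (b in config$gdh_bases)
    day[[paste0("gdh_base", b)]] <- as.numeric(tapply(pmax(0, temp - b), g, sum))
  day
}

# Cumulative (since season start) and EWMA feature table, one row per day.
# Accumulators reset on 1 September.
season_feature_table <- function(day, config) {
  season <- format(season_start(day$date))
  acc_cols <- c("chill_utah", "chill_nc", "chill_hours", "fdh",
                paste0("gdh_base", config$gdh_bases))
  out <- day
  out$days_in_season <- days_in_season(day$date)
  for (s in unique(season)) {
    idx <- which(season == s)
    for (col in acc_cols)
      out[[col]][idx] <- cumsum(day[[col]][idx])
    for (st in config$stats) {
      x <- day[[paste0("t_", st)]][idx]
      for (n in config$windows) {
        out[[paste0("ewma_", st, "_", n)]][idx] <- rolling_ewma(x, n)
        out[[paste0("rewma_", st, "_", n)]][idx] <- rolling_ewma(x, n, reverse = TRUE)
      }
    }
  }
  out
}

#' Assemble the feature vector for one sample
#'
#' Builds the full feature representation (117 columns under the default
#' configuration) of a single (hourly series, cultivar, date) sample. The
#' hourly series must cover every day from the season's 1 September through
#' `date`; cumulative accumulators run from the season start, and EWMA/REWMA
#' windows early in the season fall back to the available (renormalized)
#' window.
#'
#' @param hourly A `temperature_series` covering the season up to `date`.
#' @param cultivar Cultivar name (must be in the configuration's roster).
#' @param date Sample date.
#' @param config A [feature_config()].
#' @return Named numeric vector with `length(feature_names(config))` entries.
#' @export
assemble_features <- function(hourly, cultivar, date,
                              config = feature_config()) {
  m <- build_feature_matrix(hourly,
                            data.frame(date = as.Date(date),
                                       cultivar = cultivar),
                            config)
  stats::setNames(as.numeric(m[1, ]), colnames(m))
}

#' Build a feature matrix for many samples over one hourly series
#'
#' Vectorized companion to [assemble_features()]: the per-day descriptor
#' table is computed once for the series and shared across samples.
#'
#' @inheritParams assemble_features
#' @param samples Data frame with columns `date` and `cultivar`.
#' @return Numeric matrix, one row per sample, columns
#'   `feature_names(config)` in fixed order.
#' @export
build_feature_matrix <- function(hourly, samples, config = feature_config()) {
  if (!all(c("date", "cultivar") %in% names(samples)))
    stop_schema("samples need columns date, cultivar")
  samples$date <- as.Date(samples$date)
  day <- daily_summary(hourly, config)
  tab <- season_feature_table(day, config)

  # every sample's season must be covered from its 1 September
  need_start <- season_start(samples$date)
  covered_from <- min(tab$date)
  if (any(need_start < covered_from & samples$date >= covered_from)) {
    bad <- unique(samples$date[need_start < covered_from])
    stop_validation(
      "hourly series starts %s; season coverage from %s required for sample date(s) %s (cumulative and window features unavailable)",
      covered_from, min(need_start), paste(bad, collapse = ", "))
  }
  idx <- match(samples$date, tab$date)
  if (anyNA(idx))
    stop_validation("sample date(s) outside hourly coverage: %s",
                    paste(unique(samples$date[is.na(idx)]), collapse = ", "))

  fn <- feature_names(config)
  temp_cols <- setdiff(fn, cultivar_feature_names(config$roster))
  onehot <- t(vapply(samples$cultivar, one_hot_cultivar,
                     integer(length(config$roster)), roster = config$roster))
  mat <- cbind(onehot, as.matrix(tab[idx, temp_cols, drop = FALSE]))
  colnames(mat) <- fn
  rownames(mat) <- NULL
  if (any(!is.finite(mat)))
    stop_compute("non-finite feature values produced")
  # flag samples whose largest EWMA window was truncated by the season start
  attr(mat, "partial_window") <- tab$days_in_season[idx] + 1L < max(config$windows)
  mat
}
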
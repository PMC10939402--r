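#' Synthetic climate specification
#'
#' Parameters of the synthetic daily weather generator: a seasonal sinusoid
#' in the daily minimum temperature (coldest around mid-January) plus AR(1)
#' day-to-day deviations, with tmax offset by a diurnal range. Defaults
#' emulate a continental cool-climate viticultural site.
#'
#' @param mean_winter_min Seasonal-curve daily minimum at the mid-January
#'   trough, degrees C.
#' @param seasonal_amplitude Half-range scale of the seasonal curve; summer
#'   minima sit `2 * seasonal_amplitude` above the winter trough.
#' @param diurnal_range Mean tmax - tmin gap, degrees C.
#' @param ar1 AR(1) coefficient of daily deviations, in [0, 1).
#' @param noise_sd Stationary standard deviation of the deviations,
#'   degrees C (>= 0; the tmax jitter scales with it too).
#' @param season_start,season_end Month-day strings bounding each dormant
#'   season (default 1 September - 30 April).
#' @return A `climate_spec` list.
#' @export
climate_spec <- function(mean_winter_min = -12, seasonal_amplitude = 14,
                         diurnal_range = 9, ar1 = 0.65, noise_sd = 3.5,
                         season_start = "09-01", season_end = "04-30") {
  if (ar1 < 0 || ar1 >= 1) stop_validation("ar1 must lie in [0, 1)")
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  if (diurnal_range < 0) stop_validation("diurnal_range must be >= 0")
  structure(list(mean_winter_min = mean_winter_min,
                 seasonal_amplitude = seasonal_amplitude,
                 diurnal_range = diurnal_range, ar1 = ar1,
                 noise_sd = noise_sd, season_start = season_start,
                 season_end = season_end),
            class = "climate_spec")
}

#' Simulate multi-season daily weather
#'
#' Daily minima follow the seasonal sinusoid of `spec` (phase anchored to
#' days-in-season, so every season repeats the same curve) plus an AR(1)
#' deviation restarted each season; maxima add the diurnal range with a
#' jitter proportional to `noise_sd`, clamped so `tmax >= tmin`.
#'
#' @param spec A [climate_spec()].
#' @param n_seasons Number of dormant seasons.
#' @param seed Integer seed; fixed seed gives a bit-identical series.
#' @param start_year Calendar year of the first season's 1 September.
#' @param site_id Site label stored in the output.
#' @return A `daily_weather` data frame (columns `date`, `tmin`, `tmax`,
#'   `site`, `season`); seasons are internally gap-free but separated by
#'   the off-season months.
#' @export
simulate_weather <- function(spec = climate_spec(), n_seasons = 1L, seed = 1L,
                             start_year = 2015L, site_id = "site") {
  stopifnot(inherits(spec, "climate_spec"))
  out <- withr::with_seed(derive_seed(seed, "weather", site_id), {
    seasons <- lapply(seq_len(n_seasons) - 1L, function(s) {
      yr <- start_year + s
      dates <- seq(as.Date(sprintf("%d-%s", yr, spec$season_start)),
                   as.Date(sprintf("%d-%s", yr + 1L, spec$season_end)),
                   by = "day")
      dis <- days_in_season(dates)
      # trough at mid-January (day 136 of the season)
      base <- spec$mean_winter_min + spec$seasonal_amplitude *
        (1 - cos(2 * pi * (dis - 136) / 365.25))
      n <- length(dates)
      e <- numeric(n)
      if (spec$noise_sd > 0) {
        e[1] <- stats::rnorm(1, 0, spec$noise_sd)
        innov_sd <- spec$noise_sd * sqrt(1 - spec$ar1^2)
        for (t in seq_len(n)[-1])
          e[t] <- spec$ar1 * e[t - 1] + stats::rnorm(1, 0, innov_sd)
      }
      tmin <- base + e
      jitter <- if (spec$noise_sd > 0)
        stats::rnorm(n, 0, 0.3 * spec$noise_sd) else 0
      tmax <- pmax(tmin, tmin + spec$diurnal_range + jitter)
      data.frame(date = dates, tmin = tmin, tmax = tmax,
                 site = site_id,
                 season = sprintf("%d-%d", yr, yr + 1L))
    })
    do.call(rbind, seasons)
  })
  rownames(out) <- NULL
  class(out) <- c("daily_weather", "data.frame")
  out
}

#' Cultivar hardiness dynamics
#'
#' Parameters of the discrete daily LT50 update used by the generator:
#' below the temperature threshold buds acclimate (LT50 drops)
#' proportionally to the cold exposure; above it they deacclimate
#' proportionally to the warmth, gated by a logistic function of
#' accumulated chill (little deacclimation before the chilling requirement
#' is met, full responsiveness in ecodormancy).
#'
#' @param initial_lt50 Early-autumn LT50, degrees C (< 0).
#' @param max_hardiness Deepest attainable LT50, degrees C
#'   (< `initial_lt50`).
#' @param acclim_rate Hardiness gained per day per degree below the
#'   threshold (degrees C per day per degree C).
#' @param deacclim_rate Hardiness lost per day per degree above the
#'   threshold, at full chill.
#' @param chill_requirement Accumulated chill (proxy hours) at which
#'   deacclimation responsiveness reaches half of its maximum.
#' @param threshold Temperature separating acclimating from deacclimating
#'   days, degrees C.
#' @return A `cultivar_dynamics` list.
#' @export
cultivar_dynamics <- function(initial_lt50 = -9, max_hardiness = -26,
                              acclim_rate = 0.10, deacclim_rate = 0.08,
                              chill_requirement = 900, threshold = 10) {
  if (!(max_hardiness < initial_lt50 && initial_lt50 < 0))
    stop_validation("need max_hardiness < initial_lt50 < 0")
  if (acclim_rate <= 0 || deacclim_rate <= 0)
    stop_validation("acclimation/deacclimation rates must be > 0")
  structure(list(initial_lt50 = initial_lt50, max_hardiness = max_hardiness,
                 acclim_rate = acclim_rate, deacclim_rate = deacclim_rate,
                 chill_requirement = chill_requirement, threshold = threshold),
            class = "cultivar_dynamics")
}

#' Simulate a latent LT50 trajectory with noisy observations
#'
#' Runs the [cultivar_dynamics()] update over a daily weather table (one
#' trajectory per season, restarting at `initial_lt50` each 1 September)
#' and samples noisy observations on `sampling_dates`. The update is
#' deliberately a threshold model, not an EWMA, so learning tests against
#' the EWMA-based feature set are honest.
#'
#' @param weather A `daily_weather` data frame (may span several seasons;
#'   a `season` column is honoured, otherwise seasons are inferred).
#' @param dynamics A [cultivar_dynamics()].
#' @param obs_noise_sd Observation noise SD, degrees C (0 for noiseless).
#' @param sampling_dates Dates observed; default every 7th day of each
#'   season from 1 October through 15 April.
#' @param seed Integer seed for the observation noise.
#' @return A `synthetic_lt50` list: `latent` (per-day data frame with
#'   `lt50_latent`, chill proxy and deacclimation gate), `observations`
#'   (`date`, `lt50`), the dynamics and seed.
#' @export
simulate_lt50 <- function(weather, dynamics = cultivar_dynamics(),
                          obs_noise_sd = 1.0, sampling_dates = NULL,
                          seed = 1L) {
  stopifnot(inherits(dynamics, "cultivar_dynamics"))
  if (!all(c("date", "tmin", "tmax") %in% names(weather)))
    stop_schema("weather needs columns date, tmin, tmax")
  weather <- weather[order(as.Date(weather$date)), , drop = FALSE]
  dates <- as.Date(weather$date)
  season <- if ("season" %in% names(weather)) weather$season
            else format(season_start(dates))
  tmean <- (weather$tmin + weather$tmax) / 2

  lt50 <- numeric(length(dates))
  chill <- numeric(length(dates))
  gate <- numeric(length(dates))
  for (s in unique(season)) {
    idx <- which(season == s)
    h <- dynamics$initial_lt50
    c_acc <- 0
    for (k in seq_along(idx)) {
      i <- idx[k]
      # chill proxy: a day counts fully when its mean sits in the chilling band
      c_acc <- c_acc + 24 * (tmean[i] > 0 && tmean[i] <= 7.2)
      gt <- stats::plogis((c_acc - dynamics$chill_requirement) /
                            (dynamics$chill_requirement / 8))
      if (tmean[i] < dynamics$threshold) {
        h <- h - dynamics$acclim_rate * (dynamics$threshold - tmean[i])
      } else {
        h <- h + dynamics$deacclim_rate * (tmean[i] - dynamics$threshold) * gt
      }
      h <- min(max(h, dynamics$max_hardiness), dynamics$initial_lt50)
      lt50[i] <- h
      chill[i] <- c_acc
      gate[i] <- gt
    }
  }
  latent <- data.frame(date = dates, season = season, lt50_latent = lt50,
                       chill = chill, gate = gate)

  if (is.null(sampling_dates)) {
    dis <- days_in_season(dates)
    sampling_dates <- dates[dis >= 30 & dis <= 226 & dis %% 7L == 2L]
  }
  sampling_dates <- as.Date(sampling_dates)
  miss <- setdiff(as.character(sampling_dates), as.character(dates))
  if (length(miss))
    stop_validation("sampling dates outside weather coverage: %s",
                    paste(miss, collapse = ", "))
  ix <- match(as.character(sampling_dates), as.character(dates))
  noise <- if (obs_noise_sd > 0)
    withr::with_seed(derive_seed(seed, "obs"),
                     stats::rnorm(length(ix), 0, obs_noise_sd)) else 0
  observations <- data.frame(date = sampling_dates,
                             lt50 = lt50[ix] + noise,
                             lt50_latent = lt50[ix])
  structure(list(latent = latent, observations = observations,
                 dynamics = dynamics, obs_noise_sd = obs_noise_sd,
                 seed = seed),
            class = "synthetic_lt50")
}

# Dynamics presets for the two cultivar archetypes: cold-hardy hybrids
# reach deeper LT50 and move faster; V. vinifera cultivars are tenderer
# and slower. A small deterministic per-cultivar offset separates cultivars
# within a group.
archetype_dynamics <- function(group, index, cultivar_effects = TRUE) {
  if (!cultivar_effects)
    return(cultivar_dynamics(initial_lt50 = -9, max_hardiness = -28,
                             acclim_rate = 0.10, deacclim_rate = 0.08,
                             chill_requirement = 900))
  jit <- ((index - 1L) %% 3L - 1L) * 0.6
  if (group == "hybrid") {
    cultivar_dynamics(initial_lt50 = -9.5, max_hardiness = -32 + jit,
                      acclim_rate = 0.13, deacclim_rate = 0.11,
                      chill_requirement = 800)
  } else {
    cultivar_dynamics(initial_lt50 = -8.5, max_hardiness = -24 + jit,
                      acclim_rate = 0.08, deacclim_rate = 0.06,
                      chill_requirement = 1000)
  }
}

#' Generate a crossed synthetic benchmark dataset
#'
#' Builds a site x cultivar x season benchmark with known structure:
#' per-site climates of varying winter severity, a mixed roster of
#' hardy-hybrid-like and vinifera-like cultivars, weekly LT50 observations
#' with Gaussian noise, and the full feature matrix assembled per sample.
#' The latent (noise-free) trajectory is kept alongside the observations,
#' so parameter-recovery tests know the truth.
#'
#' @param n_sites,n_cultivars,n_seasons Design size.
#' @param obs_noise_sd Observation noise SD, degrees C.
#' @param seed Integer master seed.
#' @param config A [feature_config()]; its roster must contain the chosen
#'   cultivars (the default 45-cultivar roster is used as-is, so the
#'   feature matrix keeps the study's 117-column shape).
#' @param cultivar_effects If `FALSE`, all cultivars share one dynamics
#'   (null control: no between-cultivar hardiness differences).
#' @return A `synthetic_benchmark` list: `data` (a [hardiness_dataset()]
#'   with metadata date/site/cultivar/season), `truth` (latent LT50 per
#'   row), `weather` (per-site daily tables), `params`, `seed`.
#' @export
make_benchmark <- function(n_sites = 4L, n_cultivars = 6L, n_seasons = 3L,
                           obs_noise_sd = 1.0, seed = 1L,
                           config = feature_config(),
                           cultivar_effects = TRUE) {
  roster <- config$roster
  group <- attr(default_roster(), "group")
  full <- default_roster()
  n_hyb <- ceiling(n_cultivars / 2)
  picks <- c(full[group == "hybrid"][seq_len(n_hyb)],
             full[group == "vinifera"][seq_len(n_cultivars - n_hyb)])
  if (!all(picks %in% roster))
    stop_validation("configured roster lacks benchmark cultivars: %s",
                    paste(setdiff(picks, roster), collapse = ", "))
  pick_group <- c(rep("hybrid", n_hyb),
                  rep("vinifera", n_cultivars - n_hyb))

  site_mwm <- seq(-16, -8, length.out = n_sites)
  feats <- list(); labs <- list(); metas <- list(); truths <- list()
  weather_all <- list()
  for (s in seq_len(n_sites)) {
    site <- sprintf("site%02d", s)
    spec <- climate_spec(mean_winter_min = site_mwm[s])
    wx <- simulate_weather(spec, n_seasons = n_seasons,
                           seed = derive_seed(seed, "site", s),
                           site_id = site)
    weather_all[[site]] <- wx
    for (season in unique(wx$season)) {
      wx_s <- wx[wx$season == season, , drop = FALSE]
      hourly <- interpolate_hourly(wx_s, site_id = site)
      for (ci in seq_len(n_cultivars)) {
        dyn <- archetype_dynamics(pick_group[ci], ci, cultivar_effects)
        sim <- simulate_lt50(wx_s, dyn, obs_noise_sd = obs_noise_sd,
                             seed = derive_seed(seed, "lt50", s, season, ci))
        obs <- sim$observations
        if (!nrow(obs)) next
        samples <- data.frame(date = obs$date, cultivar = picks[ci])
        fm <- build_feature_matrix(hourly, samples, config)
        feats[[length(feats) + 1L]] <- fm
        labs[[length(labs) + 1L]] <- obs$lt50
        truths[[length(truths) + 1L]] <- obs$lt50_latent
        metas[[length(metas) + 1L]] <- data.frame(
          date = obs$date, site = site, cultivar = picks[ci],
          season = season, stringsAsFactors = FALSE)
      }
    }
  }
  features <- do.call(rbind, feats)
  attr(features, "config_hash") <- config$hash
  data <- hardiness_dataset(features, unlist(labs), do.call(rbind, metas))
  structure(list(data = data, truth = unlist(truths),
                 weather = weather_all,
                 params = list(n_sites = n_sites, n_cultivars = n_cultivars,
                               n_seasons = n_seasons,
                               obs_noise_sd = obs_noise_sd,
                               cultivars = picks, site_mwm = site_mwm,
                               cultivar_effects = cultivar_effects,
                               config_hash = config$hash),
                 seed = seed),
            class = "synthetic_benchmark")
}
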
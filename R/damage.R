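#' Freezing-damage potential
#'
#' Sigmoid transform of the gap between the daily minimum temperature and
#' the predicted bud LT50:
#' \deqn{P = \frac{100}{1 + e^{-(\ln(1-P_h) - \ln P_h)\, g^{-1} (T - LT50_{pred})}}}
#' With the defaults `p_h = 0.9` and `g = 2`, the damage potential is 10%
#' when the minimum temperature sits 2 degrees C above the predicted LT50,
#' 90% when 2 degrees C below it, and 50% exactly at the predicted LT50.
#' `P` decreases strictly as `T - LT50` grows and is point-symmetric about
#' (LT50, 50).
#'
#' @param temp Daily minimum temperature, degrees C (vectorized).
#' @param lt50_pred Predicted LT50, degrees C (vectorized).
#' @param p_h Damage potential (as a proportion, in (0.5, 1)) reached when
#'   the temperature is `g` degrees below the predicted LT50.
#' @param g Temperature gap (degrees C, > 0) at which `p_h` is reached.
#' @return Damage potential in percent, `[0, 100]`.
#' @export
#' @examples
#' damage_potential(-22, -24)  # 10
#' damage_potential(-26, -24)  # 90
damage_potential <- function(temp, lt50_pred, p_h = 0.9, g = 2) {
  if (!is_scalar_number(p_h) || p_h <= 0.5 || p_h >= 1)
    stop_validation("p_h must lie in (0.5, 1)")
  if (!is_scalar_number(g) || g <= 0)
    stop_validation("g must be a positive temperature gap")
  slope <- (log(1 - p_h) - log(p_h)) / g
  100 / (1 + exp(-slope * (temp - lt50_pred)))
}

#' Daily freezing-damage table
#'
#' @param dates Date vector.
#' @param tmin Daily minimum temperatures, degrees C.
#' @param lt50_pred Predicted LT50 per day, degrees C.
#' @param p_h,g Sigmoid constants, see [damage_potential()].
#' @return Data frame `date`, `tmin`, `lt50_pred`, `damage_potential`.
#' @export
damage_table <- function(dates, tmin, lt50_pred, p_h = 0.9, g = 2) {
  if (length(tmin) != length(dates) || length(lt50_pred) != length(dates))
    stop_schema("dates, tmin and lt50_pred must have equal length")
  data.frame(date = as.Date(dates), tmin = tmin, lt50_pred = lt50_pred,
             damage_potential = damage_potential(tmin, lt50_pred,
                                                 p_h = p_h, g = g))
}

#' Seasonal damage summary
#'
#' @param estimates A data frame as returned by [damage_table()].
#' @return List with `max_damage_potential` (percent), `min_predicted_lt50`
#'   (degrees C, the season's maximum hardiness) and the dates on which
#'   each occurs.
#' @export
season_summary <- function(estimates) {
  if (!all(c("date", "damage_potential", "lt50_pred") %in% names(estimates)))
    stop_schema("estimates need columns date, lt50_pred, damage_potential")
  if (!nrow(estimates)) stop_validation("empty damage table")
  i_max <- which.max(estimates$damage_potential)
  i_min <- which.min(estimates$lt50_pred)
  list(max_damage_potential = estimates$damage_potential[i_max],
       max_damage_date = estimates$date[i_max],
       min_predicted_lt50 = estimates$lt50_pred[i_min],
       min_predicted_lt50_date = estimates$date[i_min])
}
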
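#' Daily growing degree days
#'
#' Capped-average thermal time contribution of one day:
#' \code{max(0, (min(tmax, tcap) + min(tmin, tcap))/2 - tbase)}.
#' Defaults are the conventional soybean cardinal temperatures (base 10,
#' cap 30 degrees C); all thermal-time outputs downstream are relative to the
#' same configuration.
#'
#' @param tmin,tmax daily minimum and maximum air temperature (degrees C),
#'   vectors of equal length.
#' @param tbase base temperature (degrees C).
#' @param tcap upper cap temperature (degrees C).
#' @return daily GDD (degree C day), non-negative.
#' @export
gdd_daily <- function(tmin, tmax, tbase = 10, tcap = 30) {
  if (any(tmax < tmin)) stopf("gdd_daily: tmax < tmin for %d record(s)", sum(tmax < tmin))
  pmax(0, (pmin(tmax, tcap) + pmin(tmin, tcap)) / 2 - tbase)
}

#' Cumulative thermal time from a sowing date
#'
#' @param weather data.frame with columns \code{date}, \code{tmin},
#'   \code{tmax}.
#' @param sowing_date a \code{Date}; accumulation starts the day after
#'   sowing, and dates before sowing contribute 0.
#' @param tbase,tcap passed to [gdd_daily()].
#' @return numeric vector of cumulative GDD aligned with \code{weather$date}.
#' @export
thermal_time <- function(weather, sowing_date, tbase = 10, tcap = 30) {
  g <- gdd_daily(weather$tmin, weather$tmax, tbase, tcap)
  g[weather$date <= as.Date(sowing_date)] <- 0
  cumsum(g)
}

# saturation vapour pressure (kPa) at temperature T (deg C), FAO-56 eq. 11
svp <- function(temp) 0.6108 * exp(17.27 * temp / (temp + 237.3))

# extraterrestrial radiation (MJ m-2 d-1), FAO-56 eqs. 21-24
extraterrestrial_radiation <- function(doy, latitude) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- clamp(-tan(phi) * tan(delta), -1, 1)
  ws <- acos(x)
  24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' FAO-56 Penman-Monteith reference evapotranspiration (daily)
#'
#' Standard daily reference crop evapotranspiration
#' \deqn{ET_0 = \frac{0.408\,\Delta(R_n - G) +
#'   \gamma \frac{900}{T+273} u_2 (e_s - e_a)}{\Delta + \gamma(1 + 0.34 u_2)}}
#' with soil heat flux G = 0 at the daily step, net radiation derived from
#' measured solar radiation (albedo 0.23, clear-sky envelope from
#' extraterrestrial radiation), saturation vapour pressure averaged over
#' Tmin/Tmax, and actual vapour pressure from daily mean relative humidity.
#'
#' @param weather data.frame with columns \code{date}, \code{tmin},
#'   \code{tmax} (deg C), \code{rh_mean} (\%), \code{radiation}
#'   (MJ m-2 d-1), \code{wind2m} (m s-1).
#' @param latitude degrees (north positive).
#' @param elevation metres above sea level.
#' @return ET0 in mm d-1 (non-negative), aligned with \code{weather$date}.
#' @export
et0_penman_monteith <- function(weather, latitude, elevation = 0) {
  for (f in c("date", "tmin", "tmax", "rh_mean", "radiation", "wind2m")) {
    if (is.null(weather[[f]]) || anyNA(weather[[f]]))
      stopf("et0_penman_monteith: missing values in weather field '%s'", f)
  }
  if (any(weather$tmax < weather$tmin)) stopf("et0_penman_monteith: tmax < tmin")
  tmean <- (weather$tmax + weather$tmin) / 2
  delta <- 4098 * svp(tmean) / (tmean + 237.3)^2
  pres <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
  gamma <- 0.000665 * pres
  es <- (svp(weather$tmax) + svp(weather$tmin)) / 2
  ea <- weather$rh_mean / 100 * es
  doy <- as.integer(format(as.Date(weather$date), "%j"))
  ra <- extraterrestrial_radiation(doy, latitude)
  rso <- (0.75 + 2e-5 * elevation) * ra
  rns <- (1 - 0.23) * weather$radiation
  rel <- ifelse(rso > 0, clamp(weather$radiation / rso, 0, 1), 0)
  sigma <- 4.903e-9
  rnl <- sigma * ((weather$tmax + 273.16)^4 + (weather$tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(pmax(ea, 0))) * (1.35 * rel - 0.35)
  rnl <- pmax(rnl, 0)   # net longwave is an outgoing loss; overcast floor at 0
  rn <- rns - rnl
  u2 <- weather$wind2m
  et0 <- (0.408 * delta * rn + gamma * 900 / (tmean + 273) * u2 * (es - ea)) /
    (delta + gamma * (1 + 0.34 * u2))
  pmax(et0, 0)
}

#' Cumulative water deficit
#'
#' Running sum of daily reference evapotranspiration minus precipitation
#' from a fixed start date (April 1 by convention for the trial site); days
#' before the start date carry \code{NA}. May go negative in wet spells.
#'
#' @param dates Date vector aligned with the series.
#' @param et0 daily ET0 (mm).
#' @param precip daily precipitation (mm).
#' @param start_date accumulation start (Date or "MM-DD" applied to the
#'   first year in \code{dates}); default April 1.
#' @return cumulative water deficit (mm) aligned with \code{dates}.
#' @export
cumulative_water_deficit <- function(dates, et0, precip, start_date = NULL) {
  if (length(dates) != length(et0) || length(et0) != length(precip))
    stopf("cumulative_water_deficit: series lengths differ")
  dates <- as.Date(dates)
  if (is.unsorted(dates)) stopf("cumulative_water_deficit: dates must be sorted")
  if (is.null(start_date))
    start_date <- as.Date(sprintf("%s-04-01", format(min(dates), "%Y")))
  start_date <- as.Date(start_date)
  cwd <- rep(NA_real_, length(dates))
  on <- dates >= start_date
  cwd[on] <- cumsum(et0[on] - precip[on])
  cwd
}

#' Crop water stress index
#'
#' Canopy-minus-air temperature scaled between the non-stressed (lower) and
#' non-transpiring (upper) baselines, clamped to [0, 1]:
#' \code{((tc - ta) - dT_ll) / (dT_ul - dT_ll)}.
#'
#' @param tc canopy temperature (deg C).
#' @param ta air temperature (deg C), mean over the midday window.
#' @param dT_ll,dT_ul lower and upper baseline temperature differentials
#'   (deg C); \code{dT_ul > dT_ll} required.
#' @return CWSI in [0, 1].
#' @export
cwsi <- function(tc, ta, dT_ll, dT_ul) {
  if (!(dT_ul > dT_ll)) stopf("cwsi: dT_ul must exceed dT_ll")
  clamp(((tc - ta) - dT_ll) / (dT_ul - dT_ll), 0, 1)
}

#' Empirical CWSI baselines for one flight
#'
#' Quantile-based baselines when purpose-flown baseline surfaces are not
#' available: the lower baseline is a low quantile of the canopy-air
#' differential among well-watered plots, the upper baseline a high quantile
#' over all plots plus a margin. Intended per flight; override with manual
#' baselines where available.
#'
#' @param dT canopy-minus-air temperature differential (deg C), one value
#'   per plot on the flight.
#' @param well_watered logical vector marking the well-watered plots.
#' @param q_low,q_high quantiles for the lower/upper baseline.
#' @param margin additive margin (deg C) on the upper baseline.
#' @return list with \code{dT_ll} and \code{dT_ul}.
#' @export
estimate_baselines <- function(dT, well_watered, q_low = 0.05, q_high = 0.95,
                               margin = 0) {
  if (sum(well_watered) < 5L) stopf("estimate_baselines: need >= 5 well-watered plots")
  dT_ll <- unname(stats::quantile(dT[well_watered], q_low, na.rm = TRUE))
  dT_ul <- unname(stats::quantile(dT, q_high, na.rm = TRUE)) + margin
  if (!(dT_ul > dT_ll))
    stopf("estimate_baselines: degenerate spread (dT_ul <= dT_ll); supply manual baselines")
  list(dT_ll = dT_ll, dT_ul = dT_ul)
}

#' Environment series for a sowing cohort
#'
#' Combines daily GDD, cumulative GDD from sowing, ET0 and cumulative water
#' deficit into one table.
#'
#' @inheritParams et0_penman_monteith
#' @param sowing_date Date of sowing for the cohort.
#' @param tbase,tcap GDD parameters.
#' @param cwd_start accumulation start for the water deficit.
#' @return data.frame: date, gdd_daily, gdd_cum, et0, precip, cwd.
#' @export
env_series <- function(weather, sowing_date, latitude, elevation = 0,
                       tbase = 10, tcap = 30, cwd_start = NULL) {
  et0 <- et0_penman_monteith(weather, latitude, elevation)
  data.frame(
    date = as.Date(weather$date),
    gdd_daily = gdd_daily(weather$tmin, weather$tmax, tbase, tcap),
    gdd_cum = thermal_time(weather, sowing_date, tbase, tcap),
    et0 = et0,
    precip = weather$precip,
    cwd = cumulative_water_deficit(weather$date, et0, weather$precip, cwd_start)
  )
}
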
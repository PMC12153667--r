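# Solar ephemeris, noon-to-noon night windows, and night-window weather
# averaging. All pipeline timestamps live on a single fixed-offset clock
# (default UTC): deployments are short (days to ~2 weeks) within one season,
# so no DST arithmetic is performed inside the pipeline.

# Core NOAA solar-position quantities for a given Julian century.
solar_geometry <- function(julian_century) {
  t <- julian_century
  deg2rad <- pi / 180
  gmls <- (280.46646 + t * (36000.76983 + t * 0.0003032)) %% 360
  gmas <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  ecc <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  eqctr <- sin(gmas * deg2rad) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(2 * gmas * deg2rad) * (0.019993 - 0.000101 * t) +
    sin(3 * gmas * deg2rad) * 0.000289
  truelong <- gmls + eqctr
  app_long <- truelong - 0.00569 -
    0.00478 * sin((125.04 - 1934.136 * t) * deg2rad)
  mean_obliq <- 23 + (26 + (21.448 - t * (46.815 + t *
    (0.00059 - t * 0.001813))) / 60) / 60
  obliq_corr <- mean_obliq + 0.00256 * cos((125.04 - 1934.136 * t) * deg2rad)
  declin <- asin(sin(obliq_corr * deg2rad) * sin(app_long * deg2rad)) /
    deg2rad
  vary <- tan(obliq_corr / 2 * deg2rad)^2
  # equation of time, minutes
  eqtime <- 4 / deg2rad * (vary * sin(2 * gmls * deg2rad) -
    2 * ecc * sin(gmas * deg2rad) +
    4 * ecc * vary * sin(gmas * deg2rad) * cos(2 * gmls * deg2rad) -
    0.5 * vary^2 * sin(4 * gmls * deg2rad) -
    1.25 * ecc^2 * sin(2 * gmas * deg2rad))
  list(declination = declin, eqtime = eqtime)
}

# sunrise/sunset of one calendar date as minutes after local midnight on the
# configured fixed-offset clock. Standard -0.833 deg altitude (refraction +
# solar semidiameter).
sun_rise_set_minutes <- function(date, latitude, longitude, tz_offset) {
  deg2rad <- pi / 180
  jd <- as.numeric(as.Date(date)) + 2440587.5 # Julian day at 00:00 UTC
  t <- (jd + 0.5 - 2451545) / 36525           # century at local-ish noon
  geom <- solar_geometry(t)
  cos_ha <- cos(90.833 * deg2rad) /
    (cos(latitude * deg2rad) * cos(geom$declination * deg2rad)) -
    tan(latitude * deg2rad) * tan(geom$declination * deg2rad)
  if (cos_ha < -1 || cos_ha > 1) {
    stop("sun does not rise/set on ", date, " at latitude ", latitude)
  }
  ha <- acos(cos_ha) / deg2rad
  solar_noon <- 720 - 4 * longitude - geom$eqtime + 60 * tz_offset
  list(sunrise = solar_noon - 4 * ha, sunset = solar_noon + 4 * ha)
}

#' Sunset and next-morning sunrise for a date
#'
#' Standard NOAA solar-position calculation (accuracy well within +/- 5 min
#' of almanac values at temperate latitudes). Returns the evening sunset of
#' `date` and the sunrise of the following morning, as POSIXct on a fixed
#' UTC-offset clock.
#'
#' @param date Date (or coercible).
#' @param latitude degrees north; must satisfy |latitude| <= 66.5 (polar
#'   day/night are not handled).
#' @param longitude degrees east (west negative).
#' @param tz_offset fixed clock offset from UTC in hours (default 0).
#' @return list with POSIXct elements `sunset` and `sunrise`
#'   (sunset < sunrise).
#' @examples
#' solar_events(as.Date("2018-06-15"), 51.77, -1.33)
#' @export
solar_events <- function(date, latitude, longitude, tz_offset = 0) {
  if (abs(latitude) > 66.5) {
    stop("polar latitudes (|lat| > 66.5) are not supported")
  }
  date <- as.Date(date)
  today <- sun_rise_set_minutes(date, latitude, longitude, tz_offset)
  tomorrow <- sun_rise_set_minutes(date + 1, latitude, longitude, tz_offset)
  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  list(sunset = midnight + today$sunset * 60,
       sunrise = midnight + 86400 + tomorrow$sunrise * 60)
}

#' Noon-to-noon night windows
#'
#' Defines the 24-h analysis unit for a nocturnal animal: each night starts
#' at local noon of `night_id` and ends at the next local noon, containing
#' one sunset and one sunrise.
#'
#' @param night_ids vector of Dates, one per night (date of the starting
#'   noon).
#' @param latitude,longitude,tz_offset site location and fixed clock offset,
#'   as in [solar_events()].
#' @return tibble: `night_id`, `start`, `end`, `sunset`, `sunrise`; always
#'   `start < sunset < sunrise < end`.
#' @export
night_windows <- function(night_ids, latitude, longitude, tz_offset = 0) {
  night_ids <- as.Date(night_ids)
  rows <- lapply(night_ids, function(d) {
    ev <- solar_events(d, latitude, longitude, tz_offset)
    start <- as.POSIXct(paste(d, "12:00:00"), tz = "UTC")
    tibble::tibble(night_id = d, start = start, end = start + 86400,
                   sunset = ev$sunset, sunrise = ev$sunrise)
  })
  out <- dplyr::bind_rows(rows)
  bad <- out$start >= out$sunset | out$sunset >= out$sunrise |
    out$sunrise >= out$end
  if (any(bad)) {
    stop("night window ordering violated for night_id ",
         paste(out$night_id[bad], collapse = ", "))
  }
  out
}

#' Average weather between sunset and sunrise
#'
#' For each night window, aggregates the hourly records whose hour-start
#' falls in `[sunset, sunrise)` (half-open, hour-start convention):
#' rainfall is summed (total overnight precipitation), every other covariate
#' is arithmetically averaged. Windows missing any expected hour are flagged
#' `incomplete` rather than imputed.
#'
#' @param weather a [weather_series()].
#' @param windows night-window tibble from [night_windows()].
#' @return tibble with one row per night: `night_id`, night means of temp,
#'   wind, rh, soilm, soilt10, soilt30, summed `rain`, `n_hours`, and
#'   `incomplete`.
#' @export
night_weather_average <- function(weather, windows) {
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    inside <- weather$hour_start >= w$sunset & weather$hour_start < w$sunrise
    sub <- weather[inside, ]
    first_hour <- trunc(w$sunset, "hours")
    if (first_hour < w$sunset) first_hour <- first_hour + 3600
    expected <- length(seq(from = first_hour, to = w$sunrise - 1, by = 3600))
    means <- vapply(setdiff(WEATHER_COVARIATES, "rain"),
                    function(v) mean(sub[[v]]), numeric(1))
    tibble::tibble(night_id = w$night_id, !!!as.list(means),
                   rain = sum(sub$rain), n_hours = nrow(sub),
                   incomplete = nrow(sub) < expected)
  })
  dplyr::bind_rows(rows)
}
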
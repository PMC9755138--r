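# Solar ephemeris and the suntime transformation.
#
# The solar position uses the NOAA fractional-year / equation-of-time
# formulation (accurate to well under a minute for event times in the
# study latitude band). Sunrise/sunset are taken at solar altitude
# -0.833 deg (refraction + upper-limb convention used by civil almanacs);
# astronomical twilight bounds at -18 deg. All timestamps are UTC; the
# local solar day is derived from longitude alone.

DEG <- pi / 180

# Fractional year (radians) and its derived quantities.
.sun_gamma <- function(time) {
  lt <- as.POSIXlt(as_utc(time), tz = "UTC")
  yr <- lt$year + 1900L
  leap <- (yr %% 4 == 0 & yr %% 100 != 0) | (yr %% 400 == 0)
  ydays <- ifelse(leap, 366, 365)
  frac_hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  2 * pi / ydays * (lt$yday + (frac_hour - 12) / 24)
}

# Equation of time (minutes) and solar declination (radians).
.sun_eqtime_decl <- function(gamma) {
  eqtime <- 229.18 * (0.000075 +
    0.001868 * cos(gamma) - 0.032077 * sin(gamma) -
    0.014615 * cos(2 * gamma) - 0.040849 * sin(2 * gamma))
  decl <- 0.006918 -
    0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  list(eqtime = eqtime, decl = decl)
}

#' Geometric solar altitude
#'
#' Altitude of the centre of the solar disc above the horizon, without
#' refraction, continuous in time.
#'
#' @param time POSIXct timestamps (UTC).
#' @param lon,lat Site coordinates, WGS84 degrees.
#' @return Altitude in degrees (vectorised over `time`).
#' @export
solar_altitude <- function(time, lon, lat) {
  time <- as_utc(time)
  sd <- .sun_eqtime_decl(.sun_gamma(time))
  lt <- as.POSIXlt(time, tz = "UTC")
  min_utc <- lt$hour * 60 + lt$min + lt$sec / 60
  tst <- (min_utc + sd$eqtime + 4 * lon) %% 1440
  ha <- (tst / 4 - 180) * DEG
  sin_alt <- sin(lat * DEG) * sin(sd$decl) +
    cos(lat * DEG) * cos(sd$decl) * cos(ha)
  asin(pmin(1, pmax(-1, sin_alt))) / DEG
}

# Event time (minutes UTC from midnight of `date`) for a given zenith,
# refined by re-evaluating the solar terms at the event estimate.
.event_minutes <- function(date, lon, lat, zenith_deg, rising) {
  day0 <- as_utc(date)
  guess <- rep(720 - 4 * lon, length.out = length(day0)) # solar noon rough
  for (it in 1:3) {
    sd <- .sun_eqtime_decl(.sun_gamma(day0 + guess * 60))
    cos_ha <- (cos(zenith_deg * DEG) -
                 sin(lat * DEG) * sin(sd$decl)) /
      (cos(lat * DEG) * cos(sd$decl))
    ha_deg <- ifelse(abs(cos_ha) <= 1, acos(pmin(1, pmax(-1, cos_ha))) / DEG, NA_real_)
    guess <- 720 - 4 * (lon + (if (rising) ha_deg else -ha_deg)) -
      sd$eqtime
  }
  guess
}

#' Daily solar events
#'
#' Sunrise, solar noon, sunset and the bounds of astronomical twilight for
#' each calendar date at a site. Sunrise/sunset are at altitude -0.833
#' degrees; astronomical twilight begins/ends at -18 degrees. Under polar
#' conditions (no event at the requested altitude) the event is `NA` with
#' a warning; the study band (|lat| < 60) always has all five events.
#'
#' @param date `Date` vector (local solar date).
#' @param lon,lat Site coordinates, WGS84 degrees.
#' @return A data.frame with columns `date`, `astro_dawn_start`, `sunrise`,
#'   `solar_noon`, `sunset`, `astro_dusk_end` (POSIXct, UTC).
#' @export
solar_events <- function(date, lon, lat) {
  date <- as.Date(date)
  if (any(abs(lat) >= 60))
    warning("solar_events is intended for |lat| < 60; events may be undefined")
  day0 <- as_utc(date)
  sd_noon <- .sun_eqtime_decl(.sun_gamma(day0 + (720 - 4 * lon) * 60))
  noon_min <- 720 - 4 * lon - sd_noon$eqtime
  sunrise <- .event_minutes(date, lon, lat, 90.833, TRUE)
  sunset <- .event_minutes(date, lon, lat, 90.833, FALSE)
  dawn18 <- .event_minutes(date, lon, lat, 108, TRUE)
  dusk18 <- .event_minutes(date, lon, lat, 108, FALSE)
  if (anyNA(c(sunrise, sunset, dawn18, dusk18)))
    warning("no solar event at requested altitude for some dates (polar conditions)")
  out <- data.frame(
    date = date,
    astro_dawn_start = day0 + dawn18 * 60,
    sunrise = day0 + sunrise * 60,
    solar_noon = day0 + noon_min * 60,
    sunset = day0 + sunset * 60,
    astro_dusk_end = day0 + dusk18 * 60
  )
  out
}

# Internal: events for times, keyed by the local solar date + offset days.
.events_for <- function(time, lon, lat, day_offset = 0L) {
  solar_events(local_solar_date(time, lon) + day_offset, lon, lat)
}

#' Suntime transformation
#'
#' Map clock time to a circular "suntime" coordinate calibrated so that on
#' every day of the year sunrise falls at `pi/2`, solar noon at `pi` and
#' sunset at `3*pi/2`. The map is piecewise linear between anchors;
#' night runs from sunset (`3*pi/2`) through the midpoint of the night
#' (`0 = 2*pi`) to the next sunrise (`pi/2`).
#'
#' @param time POSIXct timestamps (UTC).
#' @param lon,lat Site coordinates, WGS84 degrees.
#' @return Suntime in radians, `[0, 2*pi)`, vectorised over `time`.
#' @export
to_suntime <- function(time, lon, lat) {
  time <- as_utc(time)
  ev0 <- .events_for(time, lon, lat, -1L)
  ev1 <- .events_for(time, lon, lat, 0L)
  ev2 <- .events_for(time, lon, lat, 1L)
  t <- as.numeric(time)
  sr <- as.numeric(ev1$sunrise); ss <- as.numeric(ev1$sunset)
  noon <- as.numeric(ev1$solar_noon)
  theta <- numeric(length(t))

  day_am <- t >= sr & t < noon
  day_pm <- t >= noon & t < ss
  theta[day_am] <- pi / 2 + (t[day_am] - sr[day_am]) /
    (noon[day_am] - sr[day_am]) * (pi / 2)
  theta[day_pm] <- pi + (t[day_pm] - noon[day_pm]) /
    (ss[day_pm] - noon[day_pm]) * (pi / 2)

  # Night after sunset: sunset(d) -> sunrise(d+1)
  late <- t >= ss
  if (any(late)) {
    s0 <- ss[late]; s1 <- as.numeric(ev2$sunrise)[late]
    theta[late] <- .night_theta(t[late], s0, s1)
  }
  # Night before sunrise: sunset(d-1) -> sunrise(d)
  early <- t < sr
  if (any(early)) {
    s0 <- as.numeric(ev0$sunset)[early]; s1 <- sr[early]
    theta[early] <- .night_theta(t[early], s0, s1)
  }
  wrap_2pi(theta)
}

# Piecewise-linear night map: sunset -> 3pi/2, night midpoint -> 2pi,
# next sunrise -> 5pi/2.
.night_theta <- function(t, sunset, sunrise_next) {
  mid <- (sunset + sunrise_next) / 2
  first <- t < mid
  th <- numeric(length(t))
  th[first] <- 3 * pi / 2 + (t[first] - sunset[first]) /
    (mid[first] - sunset[first]) * (pi / 2)
  th[!first] <- 2 * pi + (t[!first] - mid[!first]) /
    (sunrise_next[!first] - mid[!first]) * (pi / 2)
  th
}

#' Classify timestamps into dawn, day, dusk and night
#'
#' Dawn is the beginning of astronomical twilight (solar altitude -18
#' degrees) to sunrise, day is sunrise to sunset, dusk is sunset to the end
#' of astronomical twilight, and night is the period between twilights.
#' Intervals are half-open: a boundary instant belongs to the later period.
#'
#' @param time POSIXct timestamps (UTC).
#' @param lon,lat Site coordinates, WGS84 degrees.
#' @return Factor with levels `dawn`, `day`, `dusk`, `night`.
#' @export
classify_period <- function(time, lon, lat) {
  time <- as_utc(time)
  ev <- .events_for(time, lon, lat, 0L)
  t <- as.numeric(time)
  lab <- rep("night", length(t))
  lab[t >= as.numeric(ev$astro_dawn_start) & t < as.numeric(ev$sunrise)] <- "dawn"
  lab[t >= as.numeric(ev$sunrise) & t < as.numeric(ev$sunset)] <- "day"
  lab[t >= as.numeric(ev$sunset) & t < as.numeric(ev$astro_dusk_end)] <- "dusk"
  factor(lab, levels = c("dawn", "day", "dusk", "night"))
}
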
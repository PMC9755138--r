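# Independent solar-position oracle (Meeus low-accuracy formulation:
# Julian centuries, equation of centre, obliquity, iterated hour angle).
# Used only to cross-validate the package's ephemeris; shares no code
# with it.

oracle_julian_day <- function(time) as.numeric(time) / 86400 + 2440587.5

oracle_sun <- function(jd) {
  T <- (jd - 2451545) / 36525
  L0 <- (280.46646 + 36000.76983 * T + 0.0003032 * T^2) %% 360
  M <- (357.52911 + 35999.05029 * T - 0.0001537 * T^2) %% 360
  C <- (1.914602 - 0.004817 * T - 0.000014 * T^2) * sin(M * pi / 180) +
    (0.019993 - 0.000101 * T) * sin(2 * M * pi / 180) +
    0.000289 * sin(3 * M * pi / 180)
  lam <- (L0 + C) %% 360
  eps <- 23.439291 - 0.0130042 * T
  dec <- asin(sin(eps * pi / 180) * sin(lam * pi / 180)) * 180 / pi
  ra <- (atan2(cos(eps * pi / 180) * sin(lam * pi / 180),
               cos(lam * pi / 180)) * 180 / pi) %% 360
  # equation of time, minutes (Meeus 28.3 without nutation)
  E <- 4 * (L0 - 0.0057183 - ra)
  E <- ((E + 720) %% 1440) - 720
  list(dec = dec, eqtime_min = E)
}

# Sunrise/sunset (altitude -0.833 deg) by iterated hour angle; returns
# POSIXct UTC.
oracle_sun_events <- function(date, lon, lat, altitude = -0.833) {
  day0 <- as.POSIXct(as.character(date), tz = "UTC")
  ev <- function(rising) {
    t_min <- 720 - 4 * lon # first guess: local solar noon
    for (i in 1:4) {
      s <- oracle_sun(oracle_julian_day(day0 + t_min * 60))
      transit <- 720 - 4 * lon - s$eqtime_min
      cosH <- (sin(altitude * pi / 180) -
                 sin(lat * pi / 180) * sin(s$dec * pi / 180)) /
        (cos(lat * pi / 180) * cos(s$dec * pi / 180))
      if (abs(cosH) > 1) return(NA)
      H <- acos(cosH) * 180 / pi
      t_min <- transit + (if (rising) -4 * H else 4 * H)
    }
    day0 + t_min * 60
  }
  list(sunrise = ev(TRUE), sunset = ev(FALSE))
}
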
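# Low-precision lunar ephemeris.
#
# Truncated-series geocentric lunar position (good to ~0.3 deg), adequate
# because lunar illumination enters the analysis only as a smooth
# covariate. Illuminated fraction comes from the Sun-Moon elongation;
# altitude is topocentric via a parallax-in-altitude correction.

.julian_day <- function(time) as.numeric(as_utc(time)) / 86400 + 2440587.5

# Geocentric ecliptic longitude of the Sun (degrees), Meeus-style
# equation of centre; shared by the lunar elongation computation.
.sun_ecliptic_lon <- function(T) {
  L0 <- (280.46646 + 36000.76983 * T + 0.0003032 * T^2) %% 360
  M <- (357.52911 + 35999.05029 * T - 0.0001537 * T^2) %% 360
  C <- (1.914602 - 0.004817 * T) * sin(M * DEG) +
    (0.019993 - 0.000101 * T) * sin(2 * M * DEG) +
    0.000289 * sin(3 * M * DEG)
  (L0 + C) %% 360
}

#' Lunar state: illuminated fraction and altitude
#'
#' Illuminated fraction of the lunar disc (0 at conjunction/new moon, 1 at
#' opposition/full moon) and the moon's topocentric altitude. The fraction
#' is `(1 - cos(psi)) / 2` for Sun-Moon elongation `psi`, equivalent to
#' `(1 + cos(i)) / 2` for phase angle `i` when the solar distance is
#' treated as infinite (error < 1%).
#'
#' @param time POSIXct timestamps (UTC).
#' @param lon,lat Site coordinates, WGS84 degrees.
#' @return data.frame with `illuminated_fraction` in `[0, 1]`,
#'   `altitude` (degrees, topocentric) and logical `above_horizon`.
#' @export
lunar_state <- function(time, lon, lat) {
  time <- as_utc(time)
  jd <- .julian_day(time)
  T <- (jd - 2451545) / 36525

  # Truncated lunar series (degrees): longitude, latitude, horizontal parallax.
  lam <- (218.32 + 481267.8813 * T +
    6.29 * sin((134.9 + 477198.85 * T) * DEG) -
    1.27 * sin((259.2 - 413335.38 * T) * DEG) +
    0.66 * sin((235.7 + 890534.23 * T) * DEG) +
    0.21 * sin((269.9 + 954397.70 * T) * DEG) -
    0.19 * sin((357.5 + 35999.05 * T) * DEG) -
    0.11 * sin((186.6 + 966404.05 * T) * DEG)) %% 360
  beta <- 5.13 * sin((93.3 + 483202.03 * T) * DEG) +
    0.28 * sin((228.2 + 960400.87 * T) * DEG) -
    0.28 * sin((318.3 + 6003.18 * T) * DEG) -
    0.17 * sin((217.6 - 407332.20 * T) * DEG)
  plx <- 0.9508 +
    0.0518 * cos((134.9 + 477198.85 * T) * DEG) +
    0.0095 * cos((259.2 - 413335.38 * T) * DEG) +
    0.0078 * cos((235.7 + 890534.23 * T) * DEG) +
    0.0028 * cos((269.9 + 954397.70 * T) * DEG)

  sun_lam <- .sun_ecliptic_lon(T)
  cos_psi <- cos(beta * DEG) * cos((lam - sun_lam) * DEG)
  frac <- (1 - cos_psi) / 2

  # Equatorial coordinates.
  eps <- (23.439291 - 0.0130042 * T) * DEG
  sl <- sin(lam * DEG); cl <- cos(lam * DEG)
  sb <- sin(beta * DEG); cb <- cos(beta * DEG)
  ra <- atan2(sl * cb * cos(eps) - sb * sin(eps), cl * cb) / DEG
  dec <- asin(sb * cos(eps) + cb * sin(eps) * sl) / DEG

  gmst <- (280.46061837 + 360.98564736629 * (jd - 2451545)) %% 360
  ha <- ((gmst + lon - ra) %% 360) * DEG
  alt <- asin(pmin(1, pmax(-1,
    sin(lat * DEG) * sin(dec * DEG) +
      cos(lat * DEG) * cos(dec * DEG) * cos(ha)))) / DEG
  alt_topo <- alt - plx * cos(alt * DEG) # parallax in altitude

  data.frame(
    illuminated_fraction = pmin(1, pmax(0, frac)),
    altitude = alt_topo,
    above_horizon = alt_topo > 0
  )
}
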
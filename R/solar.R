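# Sunset/sunrise from the NOAA solar-calculator equations (the Meeus-based
# formulation used by the NOAA spreadsheet): apparent solar longitude,
# corrected obliquity, equation of time, and the hour angle at which the sun
# centre crosses -0.833 deg (standard refraction + semidiameter).

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# declination (deg) and equation of time (minutes) at a given instant,
# expressed as a Julian century from J2000
noaa_sun <- function(jc) {
  l0 <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  m <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  c <- sin(deg2rad(m)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(deg2rad(2 * m)) * (0.019993 - 0.000101 * jc) +
    sin(deg2rad(3 * m)) * 0.000289
  true_long <- l0 + c
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))
  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(deg2rad(omega))
  decl <- rad2deg(asin(sin(deg2rad(eps)) * sin(deg2rad(app_long))))
  y <- tan(deg2rad(eps / 2))^2
  eqtime <- 4 * rad2deg(
    y * sin(2 * deg2rad(l0)) - 2 * e * sin(deg2rad(m)) +
      4 * e * y * sin(deg2rad(m)) * cos(2 * deg2rad(l0)) -
      0.5 * y^2 * sin(4 * deg2rad(l0)) - 1.25 * e^2 * sin(2 * deg2rad(m)))
  list(decl = decl, eqtime = eqtime)
}

# one sunrise or sunset (UTC POSIXct) for a calendar date, iterating the
# solar position once at the provisional event time
noaa_event <- function(date, lon, lat, rising) {
  jd <- as.numeric(as.Date(date)) + 2440587.5  # midnight UTC
  minutes <- 720  # start at noon UTC
  for (i in 1:3) {
    jc <- (jd + minutes / 1440 - 2451545) / 36525
    s <- noaa_sun(jc)
    cos_ha <- (cos(deg2rad(90.833)) / (cos(deg2rad(lat)) * cos(deg2rad(s$decl)))) -
      tan(deg2rad(lat)) * tan(deg2rad(s$decl))
    if (cos_ha < -1 || cos_ha > 1)
      stop("sun does not cross the horizon at this latitude/date (polar day or night)")
    ha <- rad2deg(acos(cos_ha))
    noon <- 720 - 4 * lon - s$eqtime
    minutes <- if (rising) noon - 4 * ha else noon + 4 * ha
  }
  as.POSIXct(as.Date(date), tz = "UTC") + minutes * 60
}

#' Sunset and next-morning sunrise for a tracking night
#'
#' Standard-refraction solar events (sun centre at -0.833 degrees) from the
#' NOAA solar-calculator equations. A tracking "night" is keyed by the
#' calendar date of its evening: the returned sunset falls on `date` and the
#' returned sunrise on the following morning.
#'
#' @param date a `Date` (or string coercible to one), the evening's calendar
#'   date in UTC.
#' @param lon,lat site coordinates, WGS84 degrees. Latitudes at or beyond
#'   66.5 degrees are rejected (polar day/night would make the events
#'   undefined for part of the year).
#' @return list with POSIXct (UTC) elements `sunset` and `sunrise`, with
#'   `sunset < sunrise` guaranteed.
#' @export
#' @examples
#' solar_events("2014-07-01", lon = 14.048, lat = 53.373)
solar_events <- function(date, lon, lat) {
  stopifnot(length(lon) == 1, length(lat) == 1)
  if (abs(lat) >= 66.5)
    stop("unsupported latitude: |lat| must be below 66.5 degrees")
  date <- as.Date(date)
  sunset <- noaa_event(date, lon, lat, rising = FALSE)
  sunrise <- noaa_event(date + 1, lon, lat, rising = TRUE)
  stopifnot(sunset < sunrise)
  list(sunset = sunset, sunrise = sunrise)
}
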
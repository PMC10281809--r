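# Low-precision lunar ephemeris: truncated series for the geocentric ecliptic
# longitudes of the sun and moon, good to a few tenths of a degree, which
# bounds the illuminated-fraction error well below 0.01 — sufficient for
# closure-window work anchored to whole new-moon dates.

deg2rad <- function(d) d * pi / 180

julian_day <- function(instant) {
  # instant: POSIXct (any tz); JD of the corresponding UTC instant
  as.numeric(instant) / 86400 + 2440587.5
}

# Solar geocentric apparent longitude (degrees), low precision.
sun_longitude <- function(T) {
  L0 <- 280.46646 + 36000.76983 * T + 0.0003032 * T^2
  M <- deg2rad(357.52911 + 35999.05029 * T - 0.0001537 * T^2)
  C <- (1.914602 - 0.004817 * T - 0.000014 * T^2) * sin(M) +
    (0.019993 - 0.000101 * T) * sin(2 * M) +
    0.000289 * sin(3 * M)
  (L0 + C) %% 360
}

# Lunar geocentric longitude and latitude (degrees), principal terms only.
moon_position <- function(T) {
  Lp <- 218.3164477 + 481267.88123421 * T - 0.0015786 * T^2
  D <- deg2rad(297.8501921 + 445267.1114034 * T - 0.0018819 * T^2)
  M <- deg2rad(357.5291092 + 35999.0502909 * T - 0.0001536 * T^2)
  Mp <- deg2rad(134.9633964 + 477198.8675055 * T + 0.0087414 * T^2)
  F <- deg2rad(93.2720950 + 483202.0175233 * T - 0.0036539 * T^2)
  dL <- 6.288774 * sin(Mp) +
    1.274027 * sin(2 * D - Mp) +
    0.658314 * sin(2 * D) +
    0.213618 * sin(2 * Mp) -
    0.185116 * sin(M) -
    0.114332 * sin(2 * F) +
    0.058793 * sin(2 * D - 2 * Mp) +
    0.057066 * sin(2 * D - M - Mp) +
    0.053322 * sin(2 * D + Mp) +
    0.045758 * sin(2 * D - M) -
    0.040923 * sin(M - Mp) -
    0.034720 * sin(D) -
    0.030383 * sin(M + Mp) +
    0.015327 * sin(2 * D - 2 * F) -
    0.012528 * sin(Mp + 2 * F) +
    0.010980 * sin(Mp - 2 * F) +
    0.010675 * sin(4 * D - Mp) +
    0.010034 * sin(3 * Mp) +
    0.008548 * sin(4 * D - 2 * Mp) -
    0.007888 * sin(2 * D + M - Mp) -
    0.006766 * sin(2 * D + M) -
    0.005163 * sin(D - Mp)
  beta <- 5.128122 * sin(F) +
    0.280602 * sin(Mp + F) +
    0.277693 * sin(Mp - F) +
    0.173237 * sin(2 * D - F) +
    0.055413 * sin(2 * D - Mp + F) +
    0.046271 * sin(2 * D - Mp - F) +
    0.032573 * sin(2 * D + F) +
    0.017198 * sin(2 * Mp + F)
  list(longitude = (Lp + dL) %% 360, latitude = beta)
}

# Phase angle proxy: the selenocentric elongation psi with
# cos psi = cos(beta) cos(lambda_moon - lambda_sun). At lunar distance the
# phase angle is 180 - psi to within ~0.2 deg, negligible for illumination.
moon_phase_angle <- function(instant) {
  T <- (julian_day(instant) - 2451545) / 36525
  ls <- sun_longitude(T)
  m <- moon_position(T)
  cospsi <- cos(deg2rad(m$latitude)) * cos(deg2rad(m$longitude - ls))
  cospsi <- pmin(1, pmax(-1, cospsi))
  acos(cospsi) * 180 / pi
}

#' Illuminated fraction of the lunar disc
#'
#' Computes the fraction of the moon's disc that is illuminated at a given
#' instant, as `(1 - cos(phi)) / 2` where `phi` is the sun-moon elongation
#' from a low-precision analytic ephemeris. The instant is shifted by
#' `shift_hours` before evaluation; the default `+10` converts a date-time
#' interpreted as UTC into Australian Eastern Standard Time so that daily
#' averages align with local nights on the Great Barrier Reef.
#'
#' @param instant a `POSIXct` vector, or a `Date` (taken at local midnight).
#' @param shift_hours hours added to the instant before evaluating the
#'   ephemeris (default `10`, AEST).
#' @return numeric vector of illuminated fractions in `[0, 1]`.
#' @export
#' @examples
#' lunar_illumination(as.POSIXct("2021-10-06 11:05:00", tz = "UTC"),
#'                    shift_hours = 0) # new moon, ~0
lunar_illumination <- function(instant, shift_hours = 10) {
  if (inherits(instant, "Date")) {
    instant <- as.POSIXct(as.numeric(instant) * 86400,
                          origin = "1970-01-01", tz = "UTC")
  }
  # The +10 h shift re-expresses a local AEST clock reading as the UTC
  # instant the ephemeris needs: local = UTC + 10 h, so UTC = local - 10 h.
  shifted <- instant - shift_hours * 3600
  phi <- moon_phase_angle(shifted)
  (1 - cos(deg2rad(phi))) / 2
}

#' Dates of new moons within a date range
#'
#' Locates instants of minimal illuminated fraction (sun-moon conjunction)
#' and reports them as local calendar dates under the `+shift_hours`
#' convention used throughout the closure analysis.
#'
#' @param start_date,end_date closed `Date` range to search.
#' @param shift_hours local-time shift in hours (default `10`, AEST).
#' @return a `Date` vector of new-moon dates (local), ordered.
#' @export
#' @examples
#' new_moons(as.Date("2021-10-01"), as.Date("2021-12-31"))
new_moons <- function(start_date, end_date, shift_hours = 10) {
  start_date <- as_date(start_date)
  end_date <- as_date(end_date)
  stopifnot(start_date <= end_date)
  # Coarse 6-hourly UTC grid padded a synodic month either side, then refine
  # each bracketed minimum of the elongation.
  t0 <- as.POSIXct(as.numeric(start_date - 31) * 86400,
                   origin = "1970-01-01", tz = "UTC")
  t1 <- as.POSIXct(as.numeric(end_date + 31) * 86400,
                   origin = "1970-01-01", tz = "UTC")
  grid <- seq(t0, t1, by = 6 * 3600)
  phi <- moon_phase_angle(grid)
  interior <- which(diff(sign(diff(phi))) > 0) + 1L
  locals <- vapply(interior, function(i) {
    lo <- as.numeric(grid[max(1L, i - 2L)])
    hi <- as.numeric(grid[min(length(grid), i + 2L)])
    opt <- stats::optimize(function(s) {
      moon_phase_angle(as.POSIXct(s, origin = "1970-01-01", tz = "UTC"))
    }, interval = c(lo, hi))
    opt$minimum
  }, numeric(1))
  local_dates <- as.Date(floor((locals + shift_hours * 3600) / 86400),
                         origin = "1970-01-01")
  local_dates <- sort(unique(local_dates))
  local_dates[local_dates >= start_date & local_dates <= end_date]
}
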
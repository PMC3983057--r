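## Solar and lunar almanac, wind alignment, and season covariates.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

julian_day <- function(time) {
  # days since J2000.0 (2000-01-01 12:00 UTC), fractional
  as.numeric(difftime(as.POSIXct(time, tz = "UTC"),
                      as.POSIXct("2000-01-01 12:00:00", tz = "UTC"),
                      units = "days"))
}

#' Solar elevation angle
#'
#' Geometric solar elevation (no refraction) from the NOAA solar-calculator
#' equations: Julian-century polynomial mean elements, equation of center,
#' apparent longitude with nutation correction, mean obliquity, declination
#' and the equation of time.
#'
#' @param lat,lon position in degrees (longitude east-positive).
#' @param time POSIXct, UTC.
#' @return elevation above the horizon, degrees. Vectorised over `time`.
#' @export
solar_elevation <- function(lat, lon, time) {
  jd <- julian_day(time)
  T <- jd / 36525
  L0 <- (280.46646 + 36000.76983 * T + 0.0003032 * T^2) %% 360
  M <- 357.52911 + 35999.05029 * T - 0.0001537 * T^2
  e <- 0.016708634 - 0.000042037 * T - 0.0000001267 * T^2
  Mr <- deg2rad(M)
  C <- sin(Mr) * (1.914602 - 0.004817 * T - 0.000014 * T^2) +
    sin(2 * Mr) * (0.019993 - 0.000101 * T) + sin(3 * Mr) * 0.000289
  true_long <- L0 + C
  omega <- deg2rad(125.04 - 1934.136 * T)
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega)
  eps0 <- 23 + 26 / 60 + 21.448 / 3600 -
    (46.815 * T + 0.00059 * T^2 - 0.001813 * T^3) / 3600
  eps <- deg2rad(eps0 + 0.00256 * cos(omega))
  decl <- asin(sin(eps) * sin(deg2rad(app_long)))
  y <- tan(eps / 2)^2
  L0r <- deg2rad(L0)
  eqtime <- 4 * rad2deg(y * sin(2 * L0r) - 2 * e * sin(Mr) +
                          4 * e * y * sin(Mr) * cos(2 * L0r) -
                          0.5 * y^2 * sin(4 * L0r) -
                          1.25 * e^2 * sin(2 * Mr))
  utc_min <- (jd + 0.5) %% 1 * 1440  # minutes past 00:00 UTC
  tst <- (utc_min + eqtime + 4 * lon) %% 1440
  ha <- deg2rad(tst / 4 - 180)
  latr <- deg2rad(lat)
  rad2deg(asin(sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)))
}

#' Proportion of a 6-h block in nautical daylight
#'
#' "Daylight" means solar elevation at or above -12 degrees (nautical dawn
#' to nautical dusk), evaluated at a fixed location — the animal's estimated
#' position at the block midpoint. The fraction is computed by sampling
#' solar elevation at one-minute resolution across the block, which remains
#' well defined at high latitudes where dawn/dusk crossings may not exist.
#'
#' @param lat,lon position at the block midpoint, degrees.
#' @param block_start POSIXct UTC start of the block.
#' @param block_hours block length in hours. Default 6.
#' @param threshold solar elevation defining daylight, degrees. Default -12.
#' @return fraction in `[0, 1]`.
#' @export
proportion_daylight <- function(lat, lon, block_start, block_hours = 6,
                                threshold = -12) {
  block_start <- as.POSIXct(block_start, tz = "UTC")
  nmin <- round(block_hours * 60)
  tt <- block_start + (seq_len(nmin) - 0.5) * 60
  mean(solar_elevation(lat, lon, tt) >= threshold)
}

#' Illuminated fraction of the lunar disk
#'
#' Geocentric, location-independent fraction
#' \eqn{M = (1 - \cos\psi) / 2}, where \eqn{\psi} is the Moon-Sun elongation
#' computed from a truncated-series lunar ephemeris (mean longitude plus the
#' principal anomalistic, evection, variation and annual terms) and the same
#' solar longitude used by [solar_elevation()]. Accuracy is a few thousandths
#' of the disk fraction — ample for a behavioural covariate. 0 at new moon,
#' 1 at full moon.
#'
#' @param time POSIXct, UTC. Vectorised.
#' @return fraction in `[0, 1]`.
#' @export
lunar_fraction <- function(time) {
  T <- julian_day(time) / 36525
  Lp <- 218.3164477 + 481267.88123421 * T    # lunar mean longitude
  D <- deg2rad(297.8501921 + 445267.1114034 * T)   # mean elongation
  M <- deg2rad(357.5291092 + 35999.0502909 * T)    # solar mean anomaly
  Mp <- deg2rad(134.9633964 + 477198.8675055 * T)  # lunar mean anomaly
  F <- deg2rad(93.2720950 + 483202.0175233 * T)    # argument of latitude
  lam_moon <- Lp + 6.288774 * sin(Mp) + 1.274027 * sin(2 * D - Mp) +
    0.658314 * sin(2 * D) + 0.213618 * sin(2 * Mp) -
    0.185116 * sin(M) - 0.114332 * sin(2 * F) +
    0.058793 * sin(2 * D - 2 * Mp) + 0.057066 * sin(2 * D - M - Mp) +
    0.053322 * sin(2 * D + Mp) + 0.045758 * sin(2 * D - M)
  beta <- deg2rad(5.128122 * sin(F) + 0.280602 * sin(Mp + F) +
                    0.277693 * sin(Mp - F))
  # solar true longitude (same elements as solar_elevation)
  L0 <- 280.46646 + 36000.76983 * T + 0.0003032 * T^2
  C <- sin(M) * (1.914602 - 0.004817 * T) + sin(2 * M) * 0.019993 +
    sin(3 * M) * 0.000289
  lam_sun <- L0 + C
  psi <- acos(pmin(1, pmax(-1,
    cos(beta) * cos(deg2rad(lam_moon - lam_sun)))))
  (1 - cos(psi)) / 2
}

#' Nearest-cell wind speed and direction for a block
#'
#' Looks up the u/v components at the grid cell nearest the given position
#' and at the exact synoptic time of the block start (6-h blocks coincide
#' with the synoptic hours of the wind product, so no temporal interpolation
#' is performed). Wind speed is \eqn{\sqrt{u^2 + v^2}}; direction is the
#' direction the wind blows toward, degrees clockwise from north.
#'
#' @param wind a [wind_grid()] object.
#' @param lat,lon position, degrees.
#' @param time POSIXct UTC; must match a grid time exactly.
#' @return list with `ws` (m s^-1), `dir` (degrees, `NA` for calm), `u`, `v`.
#' @export
wind_at <- function(wind, lat, lon, time) {
  stopifnot(inherits(wind, "wind_grid"))
  time <- as.POSIXct(time, tz = "UTC")
  ti <- match(as.numeric(time), as.numeric(wind$time))
  if (is.na(ti))
    stop(sprintf("wind_at: time %s not in grid (%s .. %s)",
                 format(time), format(min(wind$time)),
                 format(max(wind$time))), call. = FALSE)
  if (lat < min(wind$lat) - 1.25 || lat > max(wind$lat) + 1.25 ||
      lon < min(wind$lon) - 1.25 || lon > max(wind$lon) + 1.25)
    stop(sprintf(
      "wind_at: point (%.2f, %.2f) outside grid lat [%g, %g], lon [%g, %g]",
      lat, lon, min(wind$lat), max(wind$lat), min(wind$lon), max(wind$lon)),
      call. = FALSE)
  li <- which.min(abs(wind$lat - lat))
  oi <- which.min(abs(wind$lon - lon))
  u <- wind$u[ti, li, oi]
  v <- wind$v[ti, li, oi]
  ws <- sqrt(u^2 + v^2)
  dir <- if (ws == 0) NA_real_ else (rad2deg(atan2(u, v)) + 360) %% 360
  list(ws = ws, dir = dir, u = u, v = v)
}

#' Days since 1 October
#'
#' The seasonal covariate: fractional days elapsed since 00:00 UTC on
#' 1 October of the deployment season. When `year` is omitted, the most
#' recent 1 October at or before the timestamp is used.
#'
#' @param time POSIXct UTC (vectorised).
#' @param year season start year; optional.
#' @return fractional days, `>= 0`.
#' @export
season_days <- function(time, year = NULL) {
  time <- as.POSIXct(time, tz = "UTC")
  if (is.null(year)) {
    y <- as.integer(format(time, "%Y"))
    m <- as.integer(format(time, "%m"))
    year <- ifelse(m >= 10, y, y - 1)
  }
  start <- as.POSIXct(paste0(year, "-10-01 00:00:00"), tz = "UTC")
  s <- as.numeric(difftime(time, start, units = "days"))
  if (any(s < 0)) stop("season_days: timestamp precedes 1 October of season",
                       call. = FALSE)
  s
}

#' Build the per-block covariate table for a regularised track
#'
#' Combines proportion daylight, lunar fraction (at the block midpoint),
#' wind speed/direction, days since 1 October, habitat label and (optionally)
#' aligned mixed-layer depth into one row per 6-h block.
#'
#' @param track a `RegularTrack`-style data.frame with `id`, `block` (POSIXct
#'   UTC), `lat`, `lon` (and typically `b`).
#' @param wind optional [wind_grid()].
#' @param regions optional LME region set from [read_lme_regions()].
#' @param mld optional per-block MLD data.frame from [align_mld_to_blocks()].
#' @return data.frame with one `CovariateRow` per block.
#' @export
build_covariates <- function(track, wind = NULL, regions = NULL, mld = NULL) {
  mid <- track$block + 3 * 3600
  n <- nrow(track)
  D <- vapply(seq_len(n), function(i)
    proportion_daylight(track$lat[i], track$lon[i], track$block[i]), 0)
  M <- lunar_fraction(mid)
  S <- season_days(track$block)
  out <- data.frame(id = track$id, block = track$block,
                    D = D, M = M, S = S,
                    WS = NA_real_, wind_dir = NA_real_,
                    lme = NA_character_, mld = NA_real_)
  if (!is.null(wind)) {
    for (i in seq_len(n)) {
      w <- wind_at(wind, track$lat[i], track$lon[i], track$block[i])
      out$WS[i] <- w$ws
      out$wind_dir[i] <- w$dir
    }
  }
  if (!is.null(regions))
    out$lme <- vapply(seq_len(n), function(i)
      assign_lme(track$lat[i], track$lon[i], regions), "")
  if (!is.null(mld))
    out$mld <- mld$mld[match(as.numeric(track$block),
                             as.numeric(mld$block))]
  if ("b" %in% names(track)) out$b <- track$b
  out
}
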
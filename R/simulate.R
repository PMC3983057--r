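## Synthetic-data generators: movement track with Argos observation,
## dive blocks, CTD casts, winds and eddy catalogs, all with planted truth.

# von Mises sampler (Best & Fisher 1979 rejection); kappa = Inf -> 0,
# kappa = 0 -> uniform on (-pi, pi].
rvonmises <- function(n, kappa) {
  if (!is.finite(kappa)) return(rep(0, n))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
        break
      }
    }
  }
  out
}

km_per_deg_lat <- pi * 6371 / 180

plane_to_lonlat <- function(x, y, lat0, lon0) {
  lat <- lat0 + y / km_per_deg_lat
  lon <- lon0 + x / (km_per_deg_lat * cos(lat0 * pi / 180))
  lon <- ((lon + 180) %% 360) - 180
  list(lat = lat, lon = lon)
}

lonlat_to_plane <- function(lat, lon, lat0, lon0) {
  dlon <- ((lon - lon0 + 180) %% 360) - 180
  list(x = dlon * km_per_deg_lat * cos(lat0 * pi / 180),
       y = (lat - lat0) * km_per_deg_lat)
}

#' Simulate a two-state movement track with Argos observation
#'
#' Generates one animal's true 6-h positions from a first-difference
#' correlated random walk whose persistence and turn concentration switch
#' with a two-state Markov chain (state 1 = transient travel, state 2 =
#' area-restricted residency), then observes it as irregularly timed Argos
#' fixes with class-specific isotropic Gaussian error.
#'
#' @param config a [sim_config()].
#' @param id animal identifier.
#' @param seed overrides `config$seed` when given (used for multi-animal
#'   replicates).
#' @param fix_times optional POSIXct vector of fix times (within the track
#'   span) overriding the random irregular schedule; useful for placing
#'   fixes exactly on block boundaries.
#' @return list with `truth` (class `sim_truth`: blocks, true lat/lon and
#'   planar positions, binary state per block, generating parameters) and
#'   `fixes` (data.frame `id`, `time`, `class`, `lat`, `lon`).
#' @export
simulate_track <- function(config, id = "seal1", seed = NULL,
                           fix_times = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  T <- config$n_blocks
  A <- config$transition
  # stationary initial state of the 2-state chain
  p1 <- A[2, 1] / (A[1, 2] + A[2, 1])
  s <- integer(T)
  s[1] <- if (stats::runif(1) < p1) 1L else 2L
  for (t in 2:T) s[t] <- if (stats::runif(1) < A[s[t - 1], 1]) 1L else 2L

  x <- matrix(0, T, 2)
  d <- c(config$step_sd, 0) * c(cos(th0 <- stats::runif(1, -pi, pi)),
                                sin(th0))
  d <- d + config$step_sd * stats::rnorm(2)
  x[2, ] <- x[1, ] + d
  if (T > 2) {
    for (t in 3:T) {
      st <- s[t - 1]                      # state governs the step into t
      th <- rvonmises(1, config$turn_kappa[st])
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      d <- config$gamma[st] * as.numeric(rot %*% d) +
        config$step_sd * stats::rnorm(2)
      x[t, ] <- x[t - 1, ] + d
    }
  }
  blocks <- config$start_time + (seq_len(T) - 1) * 6 * 3600
  ll <- plane_to_lonlat(x[, 1], x[, 2], config$start_lat, config$start_lon)

  span_days <- (T - 1) / 4
  if (is.null(fix_times)) {
    n_fix <- max(8L, stats::rpois(1, config$fix_rate * span_days))
    ft <- sort(stats::runif(n_fix, 0, (T - 1) * 6 * 3600))
  } else {
    ft <- sort(as.numeric(as.POSIXct(fix_times, tz = "UTC")) -
                 as.numeric(config$start_time))
    if (any(ft < 0) || any(ft > (T - 1) * 6 * 3600))
      stop("simulate_track: fix_times outside the track span", call. = FALSE)
    n_fix <- length(ft)
  }
  cls <- sample(names(config$class_probs), n_fix, replace = TRUE,
                prob = config$class_probs)
  # true position at fix time: linear interpolation between block positions
  fx <- stats::approx(seq(0, (T - 1) * 6 * 3600, by = 6 * 3600), x[, 1],
                      xout = ft)$y
  fy <- stats::approx(seq(0, (T - 1) * 6 * 3600, by = 6 * 3600), x[, 2],
                      xout = ft)$y
  err_sd <- config$argos_sd[cls]
  fx <- fx + stats::rnorm(n_fix, 0, err_sd)
  fy <- fy + stats::rnorm(n_fix, 0, err_sd)
  fll <- plane_to_lonlat(fx, fy, config$start_lat, config$start_lon)
  fixes <- data.frame(id = id, time = config$start_time + ft, class = cls,
                      lat = fll$lat, lon = fll$lon,
                      stringsAsFactors = FALSE)
  rownames(fixes) <- NULL

  truth <- structure(list(id = id, blocks = blocks, lat = ll$lat,
                          lon = ll$lon, x = x[, 1], y = x[, 2], state = s,
                          gamma = config$gamma,
                          transition = config$transition,
                          step_sd = config$step_sd,
                          dive_coefs = config$dive_coefs),
                     class = "sim_truth")
  list(truth = truth, fixes = fixes)
}

#' Simulate 6-h dive blocks from planted truth
#'
#' Per block, draws a Poisson number of dives with log-normal maximum depths
#' around the planted log-linear predictor
#' `b0 + bD*D + bM*M + bMLD*MLD`, censors them into the SPLASH histogram
#' bins, and computes SRDL-style summaries (mean/SD/max depth and duration,
#' n) from the dives deeper than 6 m. Raw per-block depths are kept in the
#' `"raw_depths"` attribute for closed-loop coefficient-recovery checks.
#'
#' @param truth a `sim_truth` from [simulate_track()].
#' @param covariates data.frame aligned to `truth$blocks` with columns `D`,
#'   `M` and `mld` (NA mld contributes 0 to the predictor).
#' @param config a [sim_config()].
#' @param source `"SPLASH"`, `"SRDL"`, or `"both"` (histograms and
#'   summaries on the same rows).
#' @return data.frame of dive blocks in the layout [clean_records()] accepts.
#' @export
simulate_dive_blocks <- function(truth, covariates, config,
                                 source = "both") {
  stopifnot(inherits(truth, "sim_truth"))
  T <- length(truth$blocks)
  if (nrow(covariates) != T)
    stop("simulate_dive_blocks: covariates not aligned to blocks",
         call. = FALSE)
  set.seed(config$seed + 1L)
  cf <- config$dive_coefs
  dl <- config$depth_limits
  tl <- config$duration_limits
  nb <- length(dl)
  out <- data.frame(id = truth$id, block = truth$blocks,
                    source = if (source == "SRDL") "SRDL" else "SPLASH")
  hmat <- matrix(0, T, nb)
  tmat <- matrix(0, T, length(tl))
  srdl <- matrix(NA_real_, T, 7)
  raw <- vector("list", T)
  mld <- ifelse(is.na(covariates$mld), 0, covariates$mld)
  for (t in seq_len(T)) {
    n <- stats::rpois(1, config$dives_per_block)
    if (n == 0) { raw[[t]] <- numeric(0); next }
    mu <- cf[1] + cf[2] * covariates$D[t] + cf[3] * covariates$M[t] +
      cf[4] * mld[t]
    depths <- stats::rlnorm(n, mu, config$dive_sdlog)
    depths <- pmax(depths, 2)           # tags only record dives >= 2 m
    durs <- pmax(exp(log(90) + 0.6 * (log(depths) - mu) +
                       stats::rnorm(n, 0, 0.3)), 8)
    raw[[t]] <- depths
    hmat[t, ] <- tabulate(findInterval(depths, c(0, dl), left.open = TRUE,
                                       rightmost.closed = FALSE), nb)
    tmat[t, ] <- tabulate(findInterval(durs, c(0, tl), left.open = TRUE),
                          length(tl))
    deep <- depths > 6
    if (any(deep)) {
      srdl[t, ] <- c(mean(depths[deep]), stats::sd(depths[deep]),
                     max(depths[deep]), mean(durs[deep]),
                     stats::sd(durs[deep]), max(durs[deep]), sum(deep))
    } else srdl[t, 7] <- 0
  }
  if (source != "SRDL") {
    colnames(hmat) <- paste0("d", seq_len(nb))
    colnames(tmat) <- paste0("t", seq_along(tl))
    out <- cbind(out, hmat, tmat)
  }
  if (source != "SPLASH") {
    srdl[is.na(srdl[, 7]), 7] <- 0
    colnames(srdl) <- c("mean_depth", "sd_depth", "max_depth",
                        "mean_dur", "sd_dur", "max_dur", "n_dives")
    out <- cbind(out, srdl)
  } else {
    out$n_dives <- rowSums(hmat)
  }
  attr(out, "raw_depths") <- raw
  out
}

#' Simulate sparse CTD casts with a planted mixed layer
#'
#' Builds two-layer casts: uniform temperature and salinity above the
#' planted mixed-layer depth, then a pycnocline in which temperature drops
#' and salinity rises over `pycnocline_m` metres. Up to 17 sample depths
#' mix fixed near-surface levels with levels spread to the cast bottom.
#'
#' @param mld_truth numeric vector of planted MLDs (m), one per cast;
#'   values must be >= 10 (shallower layers are not resolvable by a
#'   criterion that starts at 10 m).
#' @param times POSIXct cast timestamps, same length.
#' @param id animal identifier.
#' @param noise_sd Gaussian noise SD added to temperature (C) and, scaled by
#'   0.1, to salinity (PSU).
#' @param max_depth cast bottom, m.
#' @param surface_T,surface_S mixed-layer temperature and salinity.
#' @param dT_deep,dS_deep property change across the pycnocline.
#' @param pycnocline_m pycnocline thickness, m.
#' @param spike_at optional depth (m) at which to inject a gross density
#'   spike (for QC tests), applied to every cast.
#' @param seed RNG seed.
#' @return list of [ctd_profile()] objects.
#' @export
simulate_ctd_profiles <- function(mld_truth, times, id = "seal1",
                                  noise_sd = 0, max_depth = 180,
                                  surface_T = 8, surface_S = 33,
                                  dT_deep = 3, dS_deep = 0.3,
                                  pycnocline_m = 30, spike_at = NULL,
                                  seed = 1L) {
  stopifnot(length(mld_truth) == length(times))
  if (any(mld_truth < 10))
    stop("simulate_ctd_profiles: planted MLD must be >= 10 m", call. = FALSE)
  set.seed(as.integer(seed))
  times <- as.POSIXct(times, tz = "UTC")
  lapply(seq_along(mld_truth), function(i) {
    mld <- mld_truth[i]
    z <- sort(unique(round(c(2, 4, 6, 8, 10,
                             seq(12, max_depth, length.out = 12)), 1)))
    z <- utils::head(z, 17)
    frac <- pmin(pmax((z - mld) / pycnocline_m, 0), 1)
    temp <- surface_T - dT_deep * frac + stats::rnorm(length(z), 0, noise_sd)
    sal <- surface_S + dS_deep * frac +
      stats::rnorm(length(z), 0, 0.1 * noise_sd)
    if (!is.null(spike_at)) {
      k <- which.min(abs(z - spike_at))
      sal[k] <- sal[k] + 6.5   # ~5 kg m^-3 density spike
    }
    ctd_profile(id, times[i], z, temp, sal)
  })
}

#' Simulate a gridded 6-hourly wind field
#'
#' Mean flow plus AR(1) synoptic variability per cell, with whole days
#' upgraded to storms (extra speed in a random direction) at frequency
#' `storm_freq`. The grid covers the given bounding box at 2.5-degree
#' spacing.
#'
#' @param config a [sim_config()].
#' @param times POSIXct synoptic times (00/06/12/18 UTC).
#' @param lat_range,lon_range grid extent, degrees.
#' @return a [wind_grid()].
#' @export
simulate_wind_field <- function(config, times,
                                lat_range = c(35, 62.5),
                                lon_range = c(-180, -125)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  times <- as.POSIXct(times, tz = "UTC")
  lat <- seq(lat_range[1], lat_range[2], by = 2.5)
  lon <- seq(lon_range[1], lon_range[2], by = 2.5)
  nt <- length(times)
  day <- as.Date(times, tz = "UTC")
  udays <- unique(day)
  u <- array(0, c(nt, length(lat), length(lon)))
  v <- u
  for (li in seq_along(lat)) {
    for (oi in seq_along(lon)) {
      eu <- stats::filter(stats::rnorm(nt, 0, config$wind_sd * sqrt(1 - 0.6^2)),
                          0.6, method = "recursive")
      ev <- stats::filter(stats::rnorm(nt, 0, config$wind_sd * sqrt(1 - 0.6^2)),
                          0.6, method = "recursive")
      storm_day <- udays[stats::runif(length(udays)) < config$storm_freq]
      boost <- day %in% storm_day
      ang <- stats::runif(1, 0, 2 * pi)
      u[, li, oi] <- config$wind_mean[1] + as.numeric(eu) +
        ifelse(boost, config$storm_amp * cos(ang), 0)
      v[, li, oi] <- config$wind_mean[2] + as.numeric(ev) +
        ifelse(boost, config$storm_amp * sin(ang), 0)
    }
  }
  wind_grid(times, lat, lon, u, v)
}

#' Simulate weekly eddy catalogs
#'
#' Uniform random eddy centres in the bounding box with radii drawn from
#' `config$eddy_radius_range` and random polarity, one catalog per week.
#'
#' @param config a [sim_config()].
#' @param week_starts Date vector of catalog weeks.
#' @inheritParams simulate_wind_field
#' @return data.frame `week`, `lat`, `lon`, `radius_km`, `polarity`.
#' @export
simulate_eddies <- function(config, week_starts,
                            lat_range = c(35, 62.5),
                            lon_range = c(-180, -125)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  week_starts <- as.Date(week_starts)
  do.call(rbind, lapply(week_starts, function(w) {
    n <- config$n_eddies
    data.frame(week = w,
               lat = stats::runif(n, lat_range[1], lat_range[2]),
               lon = stats::runif(n, lon_range[1], lon_range[2]),
               radius_km = stats::runif(n, config$eddy_radius_range[1],
                                        config$eddy_radius_range[2]),
               polarity = sample(c(-1, 1), n, replace = TRUE))
  }))
}
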
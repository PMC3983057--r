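#' Configuration for the synthetic biologging generator
#'
#' Bundles every knob of the synthetic-data module. The defaults emulate the
#' study conditions: winter deployments from St. Paul Island (57.2 N,
#' 172.2 W) starting late October, ~100 days of 6-h blocks per animal, a
#' two-state movement process (transient travel vs. area-restricted
#' residency), Argos error magnitudes growing from the best to the worst
#' location class, dive depths log-linear in daylight, moonlight and
#' mixed-layer depth with magnitudes comparable to the fitted study models,
#' and a storm-modulated wind climate.
#'
#' @param n_seals number of animals.
#' @param n_blocks number of 6-h blocks per animal.
#' @param transition 2x2 state transition matrix, rows = from-state
#'   (1 = transient, 2 = resident), rows summing to 1.
#' @param gamma per-state move persistence in `[0, 1]`; element 1 (transient)
#'   must exceed element 2 (resident).
#' @param turn_kappa per-state von Mises turn concentration; `Inf` means no
#'   turning (straight-line persistence).
#' @param step_sd process step standard deviation, km per 6 h.
#' @param argos_sd named per-class isotropic error SD, km, classes 3,2,1,0,A,B.
#' @param class_probs sampling probabilities of the location classes.
#' @param fix_rate Argos fixes per day.
#' @param depth_limits,duration_limits histogram bin limits (SPLASH layout).
#' @param dive_coefs planted log-depth model `c(b0, bD, bM, bMLD)`:
#'   log depth = b0 + bD*D + bM*M + bMLD*MLD.
#' @param dive_sdlog log-scale dive-depth SD.
#' @param dives_per_block mean dives per 6-h block (Poisson).
#' @param mld_mean,mld_amp mixed-layer truth: mean depth (m) and seasonal
#'   amplitude; truth deepens linearly by `mld_amp` over the track.
#' @param wind_mean mean wind components `c(u, v)`, m s^-1.
#' @param wind_sd synoptic wind component SD, m s^-1.
#' @param storm_freq probability a given day is a storm day.
#' @param storm_amp extra wind speed on storm days, m s^-1.
#' @param n_eddies eddies per weekly catalog.
#' @param eddy_radius_range eddy radius range, km.
#' @param start_lat,start_lon deployment site, degrees.
#' @param start_time first block start (snapped to a 6-h UTC boundary).
#' @param seed integer seed fixing all randomness.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_seals = 5,
                       n_blocks = 400,
                       transition = matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2,
                                           byrow = TRUE),
                       gamma = c(0.85, 0.20),
                       turn_kappa = c(Inf, Inf),
                       step_sd = 3,
                       argos_sd = c("3" = 0.25, "2" = 0.5, "1" = 1.5,
                                    "0" = 4, "A" = 6, "B" = 10),
                       class_probs = c("3" = 0.08, "2" = 0.15, "1" = 0.20,
                                       "0" = 0.15, "A" = 0.22, "B" = 0.20),
                       fix_rate = 8,
                       depth_limits = splash_depth_limits(),
                       duration_limits = splash_duration_limits(),
                       dive_coefs = c(b0 = 3.0, bD = 0.3, bM = 0.2,
                                      bMLD = 0.01),
                       dive_sdlog = 0.5,
                       dives_per_block = 25,
                       mld_mean = 45,
                       mld_amp = 30,
                       wind_mean = c(u = 3, v = -2),
                       wind_sd = 4,
                       storm_freq = 0.15,
                       storm_amp = 14,
                       n_eddies = 20,
                       eddy_radius_range = c(40, 150),
                       start_lat = 57.2,
                       start_lon = -172.2,
                       start_time = as.POSIXct("2009-11-01 00:00:00",
                                               tz = "UTC"),
                       seed = 1L) {
  cfg <- as.list(environment())
  if (!is.matrix(cfg$transition) || any(dim(cfg$transition) != 2) ||
      any(cfg$transition < 0) ||
      any(abs(rowSums(cfg$transition) - 1) > 1e-8))
    stop("sim_config: transition must be a 2x2 matrix with rows summing to 1",
         call. = FALSE)
  if (any(cfg$gamma < 0 | cfg$gamma > 1))
    stop("sim_config: gamma must lie in [0, 1]", call. = FALSE)
  if (cfg$step_sd <= 0 || any(cfg$argos_sd < 0))
    stop("sim_config: step_sd must be > 0 and argos_sd >= 0", call. = FALSE)
  if (cfg$n_blocks < 2) stop("sim_config: n_blocks must be >= 2",
                             call. = FALSE)
  cfg$start_time <- as.POSIXct(
    floor(as.numeric(cfg$start_time) / (6 * 3600)) * 6 * 3600,
    origin = "1970-01-01", tz = "UTC")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d seal(s) x %d blocks from %s; gamma = (%.2f, %.2f), step sd %.1f km, seed %d\n",
    x$n_seals, x$n_blocks, format(x$start_time, "%Y-%m-%d %H:%M UTC"),
    x$gamma[1], x$gamma[2], x$step_sd, x$seed))
  invisible(x)
}
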
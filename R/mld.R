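#' Seawater density anomaly at surface pressure (EOS-80)
#'
#' Computes \eqn{\sigma_t = \rho(T, S, p = 0) - 1000} from the UNESCO 1983
#' one-atmosphere International Equation of State of seawater (EOS-80,
#' Millero & Poisson coefficients). Telemetry CTD casts are shallow, so the
#' surface form (\eqn{\sigma_t}, not potential density) is used throughout.
#'
#' @param temperature in-situ temperature, degrees C. Vectorised.
#' @param salinity practical salinity, PSU. Vectorised (recycled against
#'   `temperature`).
#' @return density anomaly in kg m^-3.
#' @examples
#' sigma_t(10, 35)
#' @export
sigma_t <- function(temperature, salinity) {
  if (any(!is.finite(temperature)) || any(!is.finite(salinity)))
    stop("sigma_t: non-finite temperature or salinity", call. = FALSE)
  t <- temperature
  s <- salinity
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  a <- 8.24493e-1 - 4.0899e-3 * t + 7.6438e-5 * t^2 -
    8.2467e-7 * t^3 + 5.3875e-9 * t^4
  b <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  c0 <- 4.8314e-4
  rho_w + a * s + b * s^1.5 + c0 * s^2 - 1000
}

#' Season-specific temperature decrement for the mixed-layer criterion
#'
#' The density increment that defines the mixed-layer base is the density
#' increase caused by cooling the reference sample by a season-specific
#' \eqn{\Delta T}: 1.0 C in winter (Jan-Mar), 0.8 C in spring (Apr-Jun),
#' 0.2 C in summer (Jul-Sep), 0.8 C in fall (Oct-Dec). These values were
#' calibrated for the northeast Pacific, the wintering region of the study
#' animals.
#'
#' @param date a `Date`, `POSIXt`, or string coercible to `Date`.
#' @return \eqn{\Delta T} in degrees C.
#' @export
seasonal_dT <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  c(1.0, 1.0, 1.0, 0.8, 0.8, 0.8, 0.2, 0.2, 0.2, 0.8, 0.8, 0.8)[m]
}

#' Construct a CTD profile object
#'
#' @param id animal identifier.
#' @param time cast timestamp (POSIXct, UTC).
#' @param depth,temperature,salinity numeric vectors of equal length;
#'   depths must be strictly increasing (m, degrees C, PSU).
#' @return an object of class `ctd_profile`.
#' @export
ctd_profile <- function(id, time, depth, temperature, salinity) {
  n <- length(depth)
  if (length(temperature) != n || length(salinity) != n)
    stop("ctd_profile: depth/temperature/salinity lengths differ", call. = FALSE)
  if (n >= 2 && any(diff(depth) <= 0))
    stop("ctd_profile: depths must be strictly increasing", call. = FALSE)
  structure(list(id = id, time = as.POSIXct(time, tz = "UTC"),
                 depth = as.numeric(depth),
                 temperature = as.numeric(temperature),
                 salinity = as.numeric(salinity)),
            class = "ctd_profile")
}

#' @export
print.ctd_profile <- function(x, ...) {
  cat(sprintf("CTD cast %s at %s: %d samples, %.1f-%.1f m\n",
              x$id, format(x$time, "%Y-%m-%d %H:%M UTC"),
              length(x$depth),
              if (length(x$depth)) min(x$depth) else NA,
              if (length(x$depth)) max(x$depth) else NA))
  invisible(x)
}

#' Quality control for a sparse CTD cast
#'
#' Removes samples that produce erroneous density spikes: a sample is flagged
#' when the point-to-point \eqn{\sigma_t} jumps on both sides exceed
#' `spike_mult` times the cast's median absolute jump and the two jumps have
#' opposite sign (an up-down excursion); an end sample is flagged when its
#' single adjacent jump exceeds the same threshold. Casts reduced below two
#' usable samples are rejected. Also drops samples with unphysical
#' temperatures (outside (-3, 35) C).
#'
#' @param profile a [ctd_profile()].
#' @param spike_mult multiple of the median absolute density jump that
#'   defines a spike. Default 10.
#' @param spike_abs absolute density jump (kg m^-3) that always counts as a
#'   spike, regardless of the cast's own noise level; also the sole
#'   criterion at the cast end points, where a genuine gradient cannot be
#'   told apart from noise by sign reversal. Default 1.
#' @param reject_abs casts still containing a point-to-point jump above
#'   this (kg m^-3) after cleaning are rejected outright. Default 5.
#' @return a list with elements `profile` (the cleaned cast) and `flags`
#'   (character vector describing every removal; `"rejected"` present when
#'   fewer than two samples survive or gross jumps remain).
#' @export
quality_control <- function(profile, spike_mult = 10, spike_abs = 1,
                            reject_abs = 5) {
  stopifnot(inherits(profile, "ctd_profile"))
  flags <- character(0)

  keep <- profile$temperature > -3 & profile$temperature < 35 &
    is.finite(profile$temperature) & is.finite(profile$salinity)
  if (any(!keep)) {
    flags <- c(flags, sprintf("unphysical sample at %.1f m removed",
                              profile$depth[!keep]))
    profile <- subset_cast(profile, keep)
  }

  repeat {
    n <- length(profile$depth)
    if (n < 3) break
    sg <- sigma_t(profile$temperature, profile$salinity)
    jump <- diff(sg)
    med <- stats::median(abs(jump))
    # a spike is extreme relative to the cast's own jumps OR in absolute
    # terms; a real pycnocline is a monotone increase, so the sign-reversal
    # requirement protects it
    thr <- min(spike_mult * max(med, 1e-4), spike_abs)
    spike <- rep(FALSE, n)
    for (i in 2:(n - 1)) {
      if (abs(jump[i - 1]) > thr && abs(jump[i]) > thr &&
          sign(jump[i - 1]) != sign(jump[i])) spike[i] <- TRUE
    }
    if (!any(spike)) {
      if (abs(jump[1]) > spike_abs) spike[1] <- TRUE
      if (abs(jump[n - 1]) > spike_abs && !spike[n - 1]) spike[n] <- TRUE
    }
    if (!any(spike)) break
    flags <- c(flags, sprintf("density spike at %.1f m removed",
                              profile$depth[spike]))
    profile <- subset_cast(profile, !spike)
  }

  if (length(profile$depth) >= 2) {
    sg <- sigma_t(profile$temperature, profile$salinity)
    if (any(abs(diff(sg)) > reject_abs)) flags <- c(flags, "rejected")
  }
  if (length(profile$depth) < 2) flags <- c(flags, "rejected")
  list(profile = profile, flags = flags)
}

subset_cast <- function(p, keep) {
  p$depth <- p$depth[keep]
  p$temperature <- p$temperature[keep]
  p$salinity <- p$salinity[keep]
  p
}

# Linear interpolation of a cast variable at a target depth; NA outside range.
interp_at_depth <- function(depth, value, z) {
  if (z < depth[1] || z > depth[length(depth)]) return(NA_real_)
  stats::approx(depth, value, xout = z, ties = "ordered")$y
}

#' Detect the mixed-layer depth from a sparse CTD cast
#'
#' Implements a seasonal density-difference criterion with a secondary
#' 10-m-referenced method and explicit fallbacks. The primary method scans
#' sample pairs from 10 m for the first interval over which \eqn{\sigma_t}
#' increases by more than 10\% of the density increment
#' \eqn{\Delta\sigma_t = \sigma_t(T_n - \Delta T, S_n) - \sigma_t(T_n, S_n)};
#' the upper sample of that pair becomes the reference and the MLD is the
#' (linearly interpolated) depth at which \eqn{\sigma_t} first exceeds the
#' reference density plus \eqn{\Delta\sigma_t}. The secondary method uses the
#' 10-m density as reference instead; it is used when the top of the water
#' column is unstable (a density decrease with depth above 10 m exceeding
#' `instability_tol`), or when the primary scan finds no qualifying pair
#' before density has risen \eqn{2\Delta\sigma_t} above the 10-m reference,
#' or when the primary reference yields no exceedance. Casts not reaching
#' 10 m, and casts on which neither method finds an exceedance, are reported
#' as `shallower_than_max_dive` (the dive is presumed not to have reached
#' the mixed-layer base).
#'
#' @param profile a [ctd_profile()] (ideally after [quality_control()]).
#' @param date date of the cast, used for the seasonal \eqn{\Delta T};
#'   defaults to the cast timestamp.
#' @param instability_tol density decrease (kg m^-3) above 10 m that
#'   triggers the secondary method. Default 0.02.
#' @param qc apply [quality_control()] first. Default TRUE.
#' @return an object of class `mld_result`: a list with `status` in
#'   `found_primary`, `found_secondary`, `shallower_than_max_dive`,
#'   `undetermined`; `mld` (m, NA unless found); `sigma_ref`, `dsigma`
#'   (kg m^-3); `dT` (C); `season`; and `flags` from QC.
#' @export
detect_mld <- function(profile, date = profile$time,
                       instability_tol = 0.02, qc = TRUE) {
  stopifnot(inherits(profile, "ctd_profile"))
  dT <- seasonal_dT(date)
  season <- c("winter", "winter", "winter", "spring", "spring", "spring",
              "summer", "summer", "summer", "fall", "fall",
              "fall")[as.integer(format(as.Date(date), "%m"))]
  flags <- character(0)
  if (qc) {
    qcr <- quality_control(profile)
    profile <- qcr$profile
    flags <- qcr$flags
  }
  out <- function(status, mld = NA_real_, sigma_ref = NA_real_,
                  dsigma = NA_real_) {
    structure(list(id = profile$id, time = profile$time, status = status,
                   mld = mld, sigma_ref = sigma_ref, dsigma = dsigma,
                   dT = dT, season = season, flags = flags),
              class = "mld_result")
  }

  z <- profile$depth
  if ("rejected" %in% flags || length(z) < 2)
    return(out("undetermined"))
  if (max(z) <= 10)
    return(out("shallower_than_max_dive"))

  sg <- sigma_t(profile$temperature, profile$salinity)

  # 10-m reference: interpolated when the cast brackets 10 m, else the
  # shallowest sample (casts starting below 10 m).
  if (z[1] <= 10) {
    sig10 <- interp_at_depth(z, sg, 10)
    t10 <- interp_at_depth(z, profile$temperature, 10)
    s10 <- interp_at_depth(z, profile$salinity, 10)
  } else {
    sig10 <- sg[1]; t10 <- profile$temperature[1]; s10 <- profile$salinity[1]
  }
  dsig10 <- sigma_t(t10 - dT, s10) - sigma_t(t10, s10)

  # unstable top of the water column above 10 m -> secondary method
  above <- which(z <= 10)
  unstable <- length(above) >= 2 &&
    any(diff(sg[above]) < -instability_tol)

  idx <- which(z >= 10)
  if (length(idx) < 2)
    return(out("undetermined"))

  # first depth >= z0 at which the piecewise-linear density profile
  # exceeds `target`
  exceed_depth <- function(target, z0) {
    s0 <- interp_at_depth(z, sg, z0)
    if (!is.na(s0) && s0 > target) return(z0)
    for (m in seq(2, length(z))) {
      if (z[m] <= z0) next
      a <- max(z[m - 1], z0)
      sa <- interp_at_depth(z, sg, a)
      if (sg[m] > target) {
        if (sa >= target) return(a)
        return(a + (target - sa) / (sg[m] - sa) * (z[m] - a))
      }
    }
    NA_real_
  }

  secondary <- function() {
    mld <- exceed_depth(sig10 + dsig10, max(10, z[1]))
    if (is.na(mld)) return(out("shallower_than_max_dive"))
    out("found_secondary", mld = max(mld, 10),
        sigma_ref = sig10, dsigma = dsig10)
  }

  if (unstable) return(secondary())

  # primary: scan sample pairs (n, n+1) from 10 m
  for (k in idx[-length(idx)]) {
    # fallback: density already 2*dsigma above the 10-m reference
    if (sg[k] - sig10 > 2 * dsig10) return(secondary())
    dsn <- sigma_t(profile$temperature[k] - dT, profile$salinity[k]) -
      sigma_t(profile$temperature[k], profile$salinity[k])
    if (sg[k + 1] - sg[k] > 0.1 * dsn) {
      mld <- exceed_depth(sg[k] + dsn, z[k])
      if (is.na(mld)) return(secondary())
      return(out("found_primary", mld = max(mld, 10),
                 sigma_ref = sg[k], dsigma = dsn))
    }
  }
  secondary()
}

#' @export
print.mld_result <- function(x, ...) {
  cat(sprintf("MLD result [%s]: %s%s (dT = %.1f C, %s)\n",
              x$id, x$status,
              if (is.finite(x$mld)) sprintf(", %.1f m", x$mld) else "",
              x$dT, x$season))
  invisible(x)
}

#' Align cast-level MLD determinations to 6-h dive blocks
#'
#' Found MLDs falling in the same 6-h block are averaged. Interior gaps may
#' then be filled by linear interpolation, but only under two explicit
#' thresholds replacing the original subjective judgement: the gap must not
#' exceed `max_gap` blocks and the two flanking block MLDs must not differ by
#' more than `max_range` metres. Blocks failing either rule stay missing.
#'
#' @param results list of `mld_result` objects (non-found statuses ignored).
#' @param blocks POSIXct vector of 6-h block start times (UTC).
#' @param interpolate fill qualifying gaps. Default TRUE.
#' @param max_gap maximum gap length, in blocks, eligible for interpolation.
#' @param max_range maximum |difference| (m) between flanking MLDs.
#' @return data.frame with columns `block`, `mld`, `n_casts`, `interpolated`.
#' @export
align_mld_to_blocks <- function(results, blocks, interpolate = TRUE,
                                max_gap = 2, max_range = 15) {
  blocks <- as.POSIXct(blocks, tz = "UTC")
  vals <- rep(NA_real_, length(blocks))
  nc <- integer(length(blocks))
  interp <- rep(FALSE, length(blocks))
  found <- Filter(function(r) r$status %in% c("found_primary",
                                              "found_secondary"), results)
  if (length(found)) {
    ct <- as.POSIXct(vapply(found, function(r) as.numeric(r$time), 0),
                     origin = "1970-01-01", tz = "UTC")
    mld <- vapply(found, function(r) r$mld, 0)
    bi <- findInterval(as.numeric(ct), as.numeric(blocks))
    for (b in unique(bi[bi >= 1])) {
      sel <- bi == b & as.numeric(ct) - as.numeric(blocks[b]) < 6 * 3600
      if (any(sel)) {
        vals[b] <- mean(mld[sel])
        nc[b] <- sum(sel)
      }
    }
  }
  if (interpolate) {
    obs <- which(!is.na(vals))
    if (length(obs) >= 2) {
      for (j in seq_len(length(obs) - 1)) {
        l <- obs[j]; r <- obs[j + 1]
        gap <- r - l - 1
        if (gap >= 1 && gap <= max_gap &&
            abs(vals[r] - vals[l]) <= max_range) {
          k <- seq(l + 1, r - 1)
          vals[k] <- vals[l] + (vals[r] - vals[l]) * (k - l) / (r - l)
          interp[k] <- TRUE
        }
      }
    }
  }
  data.frame(block = blocks, mld = vals, n_casts = nc, interpolated = interp)
}
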
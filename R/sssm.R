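#' Default Argos location-class error magnitudes
#'
#' One isotropic standard deviation (km) per Argos location class, used as
#' the fixed measurement-error scale of the movement model. The source
#' telemetry literature does not pin these down for this deployment, so the
#' defaults are conventional magnitudes growing from the best class (3) to
#' the unvalidated classes (A, B); all are configurable.
#'
#' @return named numeric vector over classes 3, 2, 1, 0, A, B (km).
#' @export
argos_error_sd <- function() {
  c("3" = 0.25, "2" = 0.5, "1" = 1.5, "0" = 4, "A" = 6, "B" = 10)
}

validate_fixes <- function(fixes) {
  need <- c("id", "time", "class", "lat", "lon")
  if (!all(need %in% names(fixes)))
    stop("fixes must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  fixes$time <- as.POSIXct(fixes$time, tz = "UTC")
  bad <- !is.finite(fixes$lat) | !is.finite(fixes$lon) |
    abs(fixes$lat) > 90 | is.na(fixes$time)
  if (any(bad)) {
    warning(sprintf("fit_sssm: rejecting %d fix(es) with non-finite or invalid coordinates (rows %s)",
                    sum(bad), paste(which(bad), collapse = ", ")))
    fixes <- fixes[!bad, , drop = FALSE]
  }
  fixes$lon <- ((fixes$lon + 180) %% 360) - 180
  # deterministic order regardless of input row order, then de-duplicate
  # identical timestamps keeping the first
  o <- order(fixes$time, fixes$lat, fixes$lon, fixes$class)
  fixes <- fixes[o, , drop = FALSE]
  fixes <- fixes[!duplicated(fixes$time), , drop = FALSE]
  rownames(fixes) <- NULL
  fixes
}

#' Fit the switching state-space movement model
#'
#' Regularises one animal's irregular, error-prone Argos fixes onto a 6-h
#' UTC grid (00/06/12/18 block starts) and estimates a continuous
#' behavioural-state index. The model is a first-difference correlated
#' random walk whose move persistence switches between a transient state
#' (1, high persistence: fast, directed travel) and a resident state (2,
#' low persistence: area-restricted movements), with a Markov chain on the
#' state sequence; fixes observe the linearly interpolated path with known
#' Gaussian error per Argos class. Estimation is Metropolis-within-Gibbs on
#' a local tangent-plane projection (km), with conjugate updates for the
#' states, persistence parameters (order-constrained for identifiability),
#' process variance and transition matrix, and adaptive random-walk updates
#' for the positions (adaptation frozen after burn-in). The behavioural
#' index is the posterior mean of the resident-state indicator: b = 0 pure
#' transient, b = 1 pure resident.
#'
#' @param fixes data.frame with columns `id`, `time` (POSIXct UTC), `class`
#'   (one of 3, 2, 1, 0, A, B), `lat`, `lon`. Rows with non-finite
#'   coordinates are rejected with a report; input row order is irrelevant.
#' @param iters MCMC iterations per chain (default 10000).
#' @param burn burn-in iterations (default `iters/2`).
#' @param thin thinning interval (default 5).
#' @param chains independent chains (default 2); results pool all chains.
#' @param seed integer seed; the fit is deterministic given the seed.
#' @param err_sd named per-class error SD, km; see [argos_error_sd()].
#' @param d1_sd diffuse SD (km) for the first displacement. Default 50.
#' @param gamma_split identifiability boundary separating the two
#'   persistence regimes: the transient gamma is restricted to
#'   `(gamma_split, 1]` and the resident gamma to `[0, gamma_split)`.
#'   Default 0.5.
#' @return an object of class `sssm` with components `track` (data.frame:
#'   `id`, `block`, `lat`, `lon`, `b`, `lat_se`, `lon_se`, `b_lo`, `b_hi`),
#'   `pars` (posterior summary of gamma1, gamma2, sigma_proc, a11, a22),
#'   `samples`, `accept`, `rhat`, and the call configuration.
#' @export
fit_sssm <- function(fixes, iters = 10000, burn = floor(iters / 2),
                     thin = 5, chains = 2, seed = 1,
                     err_sd = argos_error_sd(), d1_sd = 50,
                     gamma_split = 0.5) {
  fixes <- validate_fixes(fixes)
  if (nrow(fixes) < 8)
    stop("fit_sssm: need at least 8 usable fixes", call. = FALSE)

  t0 <- floor(min(as.numeric(fixes$time)) / 21600) * 21600
  t1 <- ceiling(max(as.numeric(fixes$time)) / 21600) * 21600
  blocks <- as.POSIXct(seq(t0, t1, by = 21600), origin = "1970-01-01",
                       tz = "UTC")
  T <- length(blocks)
  if (T < 2) stop("fit_sssm: fixes must span at least 2 blocks",
                  call. = FALSE)

  lat0 <- mean(fixes$lat)
  lon0 <- atan2(mean(sin(fixes$lon * pi / 180)),
                mean(cos(fixes$lon * pi / 180))) * 180 / pi
  pl <- lonlat_to_plane(fixes$lat, fixes$lon, lat0, lon0)
  y <- cbind(pl$x, pl$y)

  ft <- as.numeric(fixes$time)
  bidx <- findInterval(ft, as.numeric(blocks))
  w <- (ft - as.numeric(blocks)[bidx]) / 21600
  at_end <- bidx >= T
  bidx[at_end] <- T - 1
  w[at_end] <- 1

  obs_sd <- pmax(unname(err_sd[as.character(fixes$class)]), 0.01)
  if (any(is.na(obs_sd)))
    stop("fit_sssm: unknown Argos class in fixes", call. = FALSE)

  xi <- cbind(stats::approx(ft, y[, 1], xout = as.numeric(blocks),
                            rule = 2)$y,
              stats::approx(ft, y[, 2], xout = as.numeric(blocks),
                            rule = 2)$y)

  runs <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + ch - 1L)
    runs[[ch]] <- sssm_mcmc(y, obs_sd, bidx - 1L, w, T, xi,
                            as.integer(iters), as.integer(burn),
                            as.integer(thin), d1_sd,
                            prop_sd_init = max(mean(obs_sd) / 2, 0.1),
                            prior_a0 = 2, prior_b0 = 1,
                            gamma_split = gamma_split)
  }

  pool <- function(field) do.call(c, lapply(runs, `[[`, field))
  samples <- list(gamma1 = pool("gamma1"), gamma2 = pool("gamma2"),
                  sigma_proc = pool("sigma"), a11 = pool("a11"),
                  a22 = pool("a22"))
  n_kept <- sum(vapply(runs, `[[`, 0, "n_kept"))
  wts <- vapply(runs, `[[`, 0, "n_kept") / n_kept

  x_mean <- Reduce(`+`, Map(function(r, wt) r$x_mean * wt, runs, wts))
  x_var <- Reduce(`+`, Map(function(r, wt)
    (r$x_sd^2 + r$x_mean^2) * wt, runs, wts)) - x_mean^2
  x_sd <- sqrt(pmax(x_var, 0))
  b_core <- Reduce(`+`, Map(function(r, wt) r$b * wt, runs, wts))
  b <- c(b_core, b_core[length(b_core)])  # last block inherits final state

  ll <- plane_to_lonlat(x_mean[, 1], x_mean[, 2], lat0, lon0)
  # posterior SD in km converted to degrees at the local scale
  lat_se <- x_sd[, 2] / km_per_deg_lat
  lon_se <- x_sd[, 1] / (km_per_deg_lat * cos(lat0 * pi / 180))

  # per-block binomial-style uncertainty of the state indicator
  b_se <- sqrt(pmax(b * (1 - b), 0) / max(n_kept, 1))

  pars <- do.call(rbind, lapply(names(samples), function(p) {
    v <- samples[[p]]
    data.frame(parameter = p, mean = mean(v), sd = stats::sd(v),
               q025 = unname(stats::quantile(v, 0.025)),
               q975 = unname(stats::quantile(v, 0.975)))
  }))

  rhat <- vapply(c("gamma1", "gamma2", "sigma"), function(f) {
    if (chains < 2) return(NA_real_)
    m <- vapply(runs, function(r) mean(r[[f]]), 0)
    v <- vapply(runs, function(r) stats::var(r[[f]]), 0)
    W <- mean(v)
    B <- stats::var(m) * runs[[1]]$n_kept
    if (W <= 0) return(1)
    sqrt((W * (runs[[1]]$n_kept - 1) / runs[[1]]$n_kept +
            B / runs[[1]]$n_kept) / W)
  }, 0)

  structure(list(
    track = data.frame(id = fixes$id[1], block = blocks,
                       lat = ll$lat, lon = ll$lon, b = b,
                       lat_se = lat_se, lon_se = lon_se,
                       b_lo = pmax(b - 1.96 * b_se, 0),
                       b_hi = pmin(b + 1.96 * b_se, 1)),
    pars = pars, samples = samples,
    accept = mean(vapply(runs, `[[`, 0, "accept")),
    rhat = rhat, n_fixes = nrow(fixes),
    config = list(iters = iters, burn = burn, thin = thin,
                  chains = chains, seed = seed, err_sd = err_sd),
    projection = list(lat0 = lat0, lon0 = lon0)),
    class = "sssm")
}

#' @export
print.sssm <- function(x, ...) {
  cat(sprintf("Switching state-space model fit: %s\n", x$track$id[1]))
  cat(sprintf("  %d fixes -> %d six-hour blocks (%s .. %s)\n", x$n_fixes,
              nrow(x$track), format(min(x$track$block), "%Y-%m-%d"),
              format(max(x$track$block), "%Y-%m-%d")))
  cat(sprintf("  mean behavioural index b = %.2f (0 transient, 1 resident)\n",
              mean(x$track$b)))
  cat(sprintf("  gamma: transient %.2f, resident %.2f; process SD %.2f km/6h\n",
              x$pars$mean[x$pars$parameter == "gamma1"],
              x$pars$mean[x$pars$parameter == "gamma2"],
              x$pars$mean[x$pars$parameter == "sigma_proc"]))
  invisible(x)
}

#' @export
summary.sssm <- function(object, ...) {
  cat("Posterior parameter summary (pooled chains):\n")
  print(object$pars, row.names = FALSE, digits = 3)
  cat(sprintf("\nPosition-update acceptance rate: %.2f\n", object$accept))
  if (!all(is.na(object$rhat))) {
    cat("Split-chain R-hat: ")
    cat(paste(names(object$rhat), sprintf("%.3f", object$rhat),
              collapse = ", "), "\n")
  }
  invisible(object$pars)
}

#' @export
coef.sssm <- function(object, ...) {
  stats::setNames(object$pars$mean, object$pars$parameter)
}

#' @export
as.data.frame.sssm <- function(x, ...) x$track

#' @export
plot.sssm <- function(x, which = c("track", "state"), ...) {
  which <- match.arg(which)
  if (which == "track") {
    plot(x$track$lon, x$track$lat, type = "l", col = "grey50",
         xlab = "Longitude", ylab = "Latitude",
         main = paste("Regularised track", x$track$id[1]), ...)
    cols <- grDevices::hcl.colors(100, "Blue-Red")
    points(x$track$lon, x$track$lat, pch = 16, cex = 0.6,
           col = cols[pmax(1, ceiling(x$track$b * 100))])
  } else {
    plot(x$track$block, x$track$b, type = "l", ylim = c(0, 1),
         xlab = "Block start (UTC)", ylab = "Behavioural index b", ...)
    graphics::abline(h = 0.5, lty = 3)
  }
  invisible(x)
}

#' Logit-transform a behavioural-state index
#'
#' Clamps values exactly at 0 or 1 inward by 0.0001 (only the exact
#' endpoints are altered) and returns `log(b / (1 - b))`, the transform
#' applied to the state index before linear mixed-effects modelling.
#'
#' @param b numeric vector in `[0, 1]`.
#' @return logit values.
#' @examples
#' transform_state(c(0, 0.5, 1))
#' @export
transform_state <- function(b) {
  if (any(!is.finite(b)) || any(b < 0 | b > 1))
    stop("transform_state: b must lie in [0, 1]", call. = FALSE)
  b[b == 0] <- 1e-4
  b[b == 1] <- 1 - 1e-4
  log(b / (1 - b))
}
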
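# Independent oracles and small data builders used across the test suite.
# These deliberately re-derive quantities along different code paths from
# the package implementation.

# --- solar position: PSA algorithm (Blanco-Muriel et al. 2001), an
# independent formulation of the solar ephemeris.
psa_elevation <- function(lat, lon, time) {
  time <- as.POSIXct(time, tz = "UTC")
  elapsed <- as.numeric(difftime(time,
                                 as.POSIXct("2000-01-01 12:00:00",
                                            tz = "UTC"), units = "days"))
  hour <- as.numeric(difftime(time, trunc(time, "days"), units = "hours"))
  omega <- 2.1429 - 0.0010394594 * elapsed
  ml <- 4.8950630 + 0.017202791698 * elapsed
  ma <- 6.2400600 + 0.0172019699 * elapsed
  el <- ml + 0.03341607 * sin(ma) + 0.00034894 * sin(2 * ma) -
    0.0001134 - 0.0000203 * sin(omega)
  ob <- 0.4090928 - 6.2140e-9 * elapsed + 0.0000396 * cos(omega)
  ra <- atan2(cos(ob) * sin(el), cos(el)) %% (2 * pi)
  dec <- asin(sin(ob) * sin(el))
  gmst <- 6.6974243242 + 0.0657098283 * elapsed + hour
  lmst <- (gmst * 15 + lon) * pi / 180
  ha <- lmst - ra
  latr <- lat * pi / 180
  asin(cos(latr) * cos(ha) * cos(dec) + sin(dec) * sin(latr)) * 180 / pi
}

psa_daylight_fraction <- function(lat, lon, block_start, step_s = 30) {
  tt <- as.POSIXct(block_start, tz = "UTC") +
    seq(step_s / 2, 6 * 3600 - step_s / 2, by = step_s)
  mean(psa_elevation(lat, lon, tt) >= -12)
}

# --- mixed-layer depth: literal dense-scan re-implementation of the
# seasonal density-difference criterion on the piecewise-linear density
# profile (grid resolution `dz`).
oracle_mld <- function(profile, date = profile$time, dz = 0.02,
                       instability_tol = 0.02) {
  z <- profile$depth
  if (length(z) < 2) return(list(status = "undetermined", mld = NA_real_))
  if (max(z) <= 10)
    return(list(status = "shallower_than_max_dive", mld = NA_real_))
  dT <- sealwinter::seasonal_dT(date)
  sg <- sealwinter::sigma_t(profile$temperature, profile$salinity)

  zf <- seq(z[1], z[length(z)], by = dz)
  sf <- approx(z, sg, xout = zf)$y

  at10 <- function(v) if (z[1] <= 10) approx(z, v, xout = 10)$y else v[1]
  sig10 <- at10(sg)
  t10 <- at10(profile$temperature)
  s10 <- at10(profile$salinity)
  dsig10 <- sealwinter::sigma_t(t10 - dT, s10) -
    sealwinter::sigma_t(t10, s10)

  above <- which(z <= 10)
  unstable <- length(above) >= 2 && any(diff(sg[above]) < -instability_tol)

  scan_from <- max(10, z[1])
  secondary <- function() {
    hit <- which(zf >= scan_from & sf > sig10 + dsig10)
    if (!length(hit))
      return(list(status = "shallower_than_max_dive", mld = NA_real_))
    list(status = "found_secondary", mld = max(zf[hit[1]], 10))
  }
  if (unstable) return(secondary())

  idx <- which(z >= 10)
  if (length(idx) < 2) return(list(status = "undetermined", mld = NA_real_))
  for (k in idx[-length(idx)]) {
    if (sg[k] - sig10 > 2 * dsig10) return(secondary())
    dsn <- sealwinter::sigma_t(profile$temperature[k] - dT,
                               profile$salinity[k]) -
      sealwinter::sigma_t(profile$temperature[k], profile$salinity[k])
    if (sg[k + 1] - sg[k] > 0.1 * dsn) {
      hit <- which(zf >= z[k] & sf > sg[k] + dsn)
      if (!length(hit)) return(secondary())
      return(list(status = "found_primary", mld = max(zf[hit[1]], 10)))
    }
  }
  secondary()
}

# random synthetic casts spanning mixed, layered, unstable and noisy shapes
random_cast <- function(seed) {
  set.seed(seed)
  n <- sample(5:17, 1)
  z <- sort(runif(n, 1, 200))
  z <- z[c(TRUE, diff(z) > 0.5)]
  n <- length(z)
  shape <- sample(c("twolayer", "gradient", "mixed", "wiggly"), 1)
  mldz <- runif(1, 12, 150)
  temp <- switch(shape,
    twolayer = 8 - 3 * pmin(pmax((z - mldz) / 25, 0), 1),
    gradient = 10 - 0.02 * z,
    mixed = rep(7, n),
    wiggly = 8 - 0.015 * z + rnorm(n, 0, 0.15))
  sal <- switch(shape,
    twolayer = 33 + 0.3 * pmin(pmax((z - mldz) / 25, 0), 1),
    gradient = 32.8 + 0.002 * z,
    mixed = rep(33, n),
    wiggly = 33 + rnorm(n, 0, 0.02))
  sealwinter::ctd_profile("oracle", as.POSIXct("2010-01-15", tz = "UTC") +
                            sample(0:300, 1) * 86400, z, temp, sal)
}

# --- dense multivariate-normal log-likelihood of the marginal LMM
# (random intercept + AR(1) residual correlation indexed by block lag)
dense_lmm_loglik <- function(fit, data, group = "id",
                             index = "block_index") {
  X <- model.matrix(fit$formula, data)
  yname <- all.vars(fit$formula)[1]
  r <- data[[yname]] - as.numeric(X %*% fit$coefficients$Estimate)
  ll <- 0
  for (g in unique(data[[group]])) {
    sel <- data[[group]] == g
    idx <- data[[index]][sel]
    R <- fit$phi^abs(outer(idx, idx, "-"))
    V <- fit$sigma_id^2 + fit$sigma^2 * R
    ch <- chol(V)
    zz <- backsolve(ch, r[sel], transpose = TRUE)
    ll <- ll - 0.5 * sum(zz^2) - sum(log(diag(ch))) -
      0.5 * sum(sel) * log(2 * pi)
  }
  ll
}

# grouped AR(1) data with a random intercept; beta = c(intercept, slope)
sim_lmm_data <- function(n_groups, n_blocks, beta = c(1, 0.5),
                         sigma_id = 0.5, phi = 0.6, sigma = 1,
                         drop_frac = 0) {
  out <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    ws <- rnorm(n_blocks, 8, 3)
    # innovations scaled so the marginal residual SD is `sigma`
    e <- if (phi != 0)
      as.numeric(stats::arima.sim(list(ar = phi), n_blocks,
                                  sd = sigma * sqrt(1 - phi^2)))
    else rnorm(n_blocks, 0, sigma)
    data.frame(id = sprintf("g%02d", g), block_index = seq_len(n_blocks),
               WS = ws,
               y = beta[1] + beta[2] * ws + rnorm(1, 0, sigma_id) + e)
  }))
  if (drop_frac > 0) out <- out[runif(nrow(out)) > drop_frac, ]
  rownames(out) <- NULL
  out
}
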
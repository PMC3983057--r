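test_that("every generator is deterministic given the seed", {
  cfg <- sim_config(n_blocks = 40, seed = 12)
  s1 <- simulate_track(cfg, "a")
  s2 <- simulate_track(cfg, "a")
  expect_identical(s1, s2)

  cov <- data.frame(D = runif(40), M = runif(40), mld = rep(30, 40))
  expect_identical(simulate_dive_blocks(s1$truth, cov, cfg),
                   simulate_dive_blocks(s1$truth, cov, cfg))
  tt <- s1$truth$blocks[1:5]
  expect_identical(simulate_ctd_profiles(rep(40, 5), tt, seed = 4),
                   simulate_ctd_profiles(rep(40, 5), tt, seed = 4))
  expect_identical(simulate_wind_field(cfg, tt, c(50, 55), c(-175, -170)),
                   simulate_wind_field(cfg, tt, c(50, 55), c(-175, -170)))
  wk <- as.Date("2009-11-02") + 7 * (0:3)
  expect_identical(simulate_eddies(cfg, wk), simulate_eddies(cfg, wk))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(transition = matrix(c(0.5, 0.4, 0.1, 0.9), 2, 2)),
               "summing to 1")
  expect_error(sim_config(gamma = c(1.2, 0.1)), "\\[0, 1\\]")
  expect_error(sim_config(step_sd = 0), "step_sd")
  expect_error(sim_config(n_blocks = 1), "n_blocks")
  tr <- simulate_track(sim_config(n_blocks = 50, seed = 2), "x")$truth
  expect_true(all(tr$state %in% 1:2))
  expect_length(tr$state, 50)
  expect_length(tr$lat, 50)
})

test_that("zero observation noise with boundary fix times recovers truth", {
  cfg <- sim_config(n_blocks = 30, seed = 7,
                    argos_sd = setNames(rep(0, 6),
                                        c("3", "2", "1", "0", "A", "B")))
  ft <- cfg$start_time + (0:29) * 21600
  sim <- simulate_track(cfg, "a", fix_times = ft)
  expect_equal(sim$fixes$lat, sim$truth$lat)
  expect_equal(sim$fixes$lon, sim$truth$lon)
  expect_error(simulate_track(cfg, "a", fix_times = ft + 1e7), "span")
})

test_that("zero persistence leaves step headings uncorrelated", {
  cfg <- sim_config(n_blocks = 3000, seed = 19, gamma = c(0, 0))
  tr <- simulate_track(cfg, "a")$truth
  dx <- diff(tr$x); dy <- diff(tr$y)
  head_ang <- atan2(dy, dx)
  turn <- diff(head_ang)
  # brute-force circular autocorrelation of successive headings
  rho <- mean(cos(turn))
  expect_lt(abs(rho), 3 / sqrt(length(turn)))
})

test_that("planted dive-depth coefficients are recoverable by OLS on truth", {
  cfg <- sim_config(n_blocks = 400, seed = 23, dives_per_block = 30)
  tr <- simulate_track(cfg, "a")$truth
  set.seed(31)
  cov <- data.frame(D = runif(400), M = runif(400),
                    mld = runif(400, 15, 90))
  dv <- simulate_dive_blocks(tr, cov, cfg)
  raw <- attr(dv, "raw_depths")
  n <- vapply(raw, length, 0L)
  dat <- data.frame(logd = log(unlist(raw)),
                    D = rep(cov$D, n), M = rep(cov$M, n),
                    mld = rep(cov$mld, n))
  # censoring at 2 m affects a negligible share of depths at these settings
  ols <- summary(lm(logd ~ D + M + mld, dat))$coefficients
  truthv <- cfg$dive_coefs
  for (k in 1:4) {
    expect_lt(abs(ols[k, "Estimate"] - truthv[k]), 2.5 * ols[k, "Std. Error"])
  }
})

test_that("synthetic casts resolve the planted layer and flag shallow casts", {
  t0 <- as.POSIXct("2010-01-05 00:00", tz = "UTC")
  cast <- simulate_ctd_profiles(40, t0, noise_sd = 0, seed = 1)[[1]]
  r <- detect_mld(cast)
  expect_true(r$status %in% c("found_primary", "found_secondary"))
  expect_lt(abs(r$mld - 40), max(diff(cast$depth)))
  expect_error(simulate_ctd_profiles(5, t0), ">= 10")

  shallow <- simulate_ctd_profiles(40, t0, max_depth = 8, seed = 1)[[1]]
  expect_identical(detect_mld(shallow)$status, "shallower_than_max_dive")

  flat <- simulate_ctd_profiles(500, t0, dT_deep = 0, dS_deep = 0,
                                noise_sd = 0, seed = 1)[[1]]
  expect_identical(detect_mld(flat)$status, "shallower_than_max_dive")
})

test_that("text round-trips preserve every simulated artefact", {
  cfg <- sim_config(n_blocks = 12, seed = 3)
  sim <- simulate_track(cfg, "rt")
  tdir <- withr::local_tempdir()
  f <- file.path(tdir, "fixes.csv")
  write_fixes(sim$fixes, f)
  rt0 <- read_fixes(f)
  expect_identical(rt0$class, sim$fixes$class)
  expect_equal(rt0$lat, sim$fixes$lat, tolerance = 1e-12)
  expect_equal(rt0$lon, sim$fixes$lon, tolerance = 1e-12)
  # ISO-8601 serialisation keeps whole seconds
  expect_true(all(abs(as.numeric(rt0$time) -
                        as.numeric(sim$fixes$time)) < 1))

  cov <- data.frame(D = runif(12), M = runif(12), mld = rep(25, 12))
  dv <- simulate_dive_blocks(sim$truth, cov, cfg)
  g <- file.path(tdir, "dives.csv")
  write_dive_blocks(dv, g)
  rt <- read_dive_blocks(g)
  attr(dv, "raw_depths") <- NULL
  expect_equal(rt, dv, tolerance = 1e-12)

  casts <- simulate_ctd_profiles(c(30, 60), sim$truth$blocks[1:2],
                                 noise_sd = 0.05, seed = 2)
  h <- file.path(tdir, "casts.csv")
  write_ctd_casts(casts, h)
  rt2 <- read_ctd_casts(h)
  expect_equal(rt2[[1]]$depth, casts[[1]]$depth)
  expect_equal(rt2[[2]]$temperature, casts[[2]]$temperature,
               tolerance = 1e-6)

  wg <- simulate_wind_field(cfg, sim$truth$blocks[1:4], c(50, 55),
                            c(-175, -170))
  wf <- file.path(tdir, "wind.txt")
  write_wind_grid(wg, wf)
  rt3 <- read_wind_grid(wf)
  expect_equal(rt3$u, wg$u, tolerance = 1e-6)
  expect_identical(rt3$time, wg$time)

  ed <- simulate_eddies(cfg, as.Date("2009-11-02"))
  ef <- file.path(tdir, "eddies.csv")
  write_eddies(ed, ef)
  expect_equal(read_eddies(ef), ed, tolerance = 1e-12)

  tf <- file.path(tdir, "truth.json")
  write_truth(sim$truth, tf)
  rt4 <- read_truth(tf)
  expect_equal(rt4$lat, sim$truth$lat, tolerance = 1e-12)
  expect_equal(rt4$state, sim$truth$state)
  expect_identical(rt4$blocks, sim$truth$blocks)
})
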
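test_that("haversine distance is symmetric, definite, and near-geodesic", {
  set.seed(21)
  lat1 <- runif(60, 30, 65); lon1 <- runif(60, -165, -130)
  # second points within ~2000 km
  lat2 <- lat1 + runif(60, -8, 8); lon2 <- lon1 + runif(60, -12, 12)
  d12 <- haversine_km(lat1, lon1, lat2, lon2)
  d21 <- haversine_km(lat2, lon2, lat1, lon1)
  expect_equal(d12, d21)
  expect_equal(haversine_km(55, -170, 55, -170), 0)
  expect_true(all(d12[lat1 != lat2 | lon1 != lon2] > 0))
  geo <- geosphere::distGeo(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
  keep <- geo < 2000 & geo > 1
  expect_true(all(abs(d12[keep] - geo[keep]) / geo[keep] < 0.005))
})

test_that("LME assignment uses the shipped polygons and boundary rule", {
  regions <- read_lme_regions()
  expect_s3_class(regions, "lme_regions")
  expect_identical(names(regions), c("BS", "BB", "AS", "NP", "GA", "CC"))
  expect_identical(assign_lme(57.2, -172.2, regions), "BS")   # St. Paul Is.
  expect_identical(assign_lme(45, -160, regions), "NP")
  expect_identical(assign_lme(57, -145, regions), "GA")
  expect_identical(assign_lme(40, -125, regions), "CC")
  expect_identical(assign_lme(53.5, -174, regions), "BB")
  expect_identical(assign_lme(52, -170, regions), "AS")
  expect_identical(assign_lme(10, -150, regions), "outside")
  # a shared vertex resolves to the first-listed region
  expect_identical(assign_lme(54.5, -166.5, regions), "BS")
})

test_that("interior containment agrees with an independent point-in-polygon",
{
  skip_if_not_installed("mgcv")
  regions <- read_lme_regions()
  set.seed(3)
  pts <- cbind(lon = runif(150, -179, -120), lat = runif(150, 32, 64))
  for (label in names(regions)) {
    ring <- regions[[label]][[1]]
    io <- mgcv::in.out(ring, pts)
    mine <- vapply(seq_len(nrow(pts)), function(i)
      sealwinter:::point_in_ring(pts[i, "lat"], pts[i, "lon"], ring), TRUE)
    # exclude points within a whisker of an edge, where conventions differ
    near_edge <- vapply(seq_len(nrow(pts)), function(i)
      min(abs(ring[, "lon"] - pts[i, "lon"])) < 0.05 ||
        min(abs(ring[, "lat"] - pts[i, "lat"])) < 0.05, TRUE)
    expect_identical(mine[!near_edge], io[!near_edge])
  }
})

test_that("stormy-day proportions count any-synoptic exceedances per day", {
  window <- as.Date(c("2009-11-01", "2010-03-31"))
  days <- seq(window[1], window[2], by = "day")
  times <- rep(as.POSIXct(paste(days, "00:00"), tz = "UTC"), each = 4) +
    rep(c(0, 6, 12, 18) * 3600, length(days))
  lat <- c(50, 52.5); lon <- c(-170, -167.5)
  mk <- function(ws_by_time) {
    u <- array(rep(ws_by_time, 4), c(length(times), 2, 2))
    wind_grid(times, lat, lon, u, array(0, dim(u)))
  }
  expect_true(all(stormy_proportion(mk(rep(15, length(times))),
                                    window) == 1))
  expect_true(all(stormy_proportion(mk(rep(5, length(times))),
                                    window) == 0))
  # exactly 30 stormy days out of 151: one synoptic hit on each of 30 days
  ws <- rep(5, length(times))
  stormy_days <- sort(sample(length(days), 30))
  ws[(stormy_days - 1) * 4 + 2] <- 12
  sp <- stormy_proportion(mk(ws), window)
  expect_true(all(abs(sp - 30 / 151) < 1e-12))
  # monotone non-increasing in threshold, bounded in [0, 1]
  sp_hi <- stormy_proportion(mk(ws), window, threshold = 13)
  expect_true(all(sp_hi <= sp))
  expect_true(all(sp >= 0 & sp <= 1))
  # incomplete coverage flags the cell as missing
  short <- mk(ws)
  short$time <- short$time[-(1:4)]
  short$u <- short$u[-(1:4), , , drop = FALSE]
  short$v <- short$v[-(1:4), , , drop = FALSE]
  expect_true(all(is.na(stormy_proportion(short, window))))
})

test_that("zero storm frequency yields no stormy days anywhere", {
  cfg <- sim_config(seed = 5, storm_freq = 0, wind_mean = c(u = 3, v = 1),
                    wind_sd = 1.5)
  window <- as.Date(c("2009-11-01", "2010-03-31"))
  days <- seq(window[1], window[2], by = "day")
  times <- rep(as.POSIXct(paste(days, "00:00"), tz = "UTC"), each = 4) +
    rep(c(0, 6, 12, 18) * 3600, length(days))
  g <- simulate_wind_field(cfg, times, lat_range = c(50, 55),
                           lon_range = c(-175, -170))
  expect_true(all(stormy_proportion(g, window) == 0))
})

test_that("eddy edge distance honours the signed convention and min rule", {
  e1 <- data.frame(lat = 50, lon = -150, radius_km = 50, polarity = 1)
  expect_equal(eddy_edge_distance(50, -150, e1), -50)
  # a point ~100 km due north of a 40 km eddy sits ~60 km outside it
  north <- 50 + 100 / (pi * 6371 / 180)
  e2 <- data.frame(lat = 50, lon = -150, radius_km = 40, polarity = 1)
  expect_equal(eddy_edge_distance(north, -150, e2), 60, tolerance = 0.01)

  set.seed(8)
  for (i in 1:20) {
    edd <- data.frame(lat = runif(6, 40, 60), lon = runif(6, -170, -130),
                      radius_km = runif(6, 30, 120), polarity = 1)
    p <- c(runif(1, 40, 60), runif(1, -170, -130))
    brute <- min(haversine_km(p[1], p[2], edd$lat, edd$lon) - edd$radius_km)
    expect_equal(eddy_edge_distance(p[1], p[2], edd), brute)
    perm <- edd[sample(6), ]
    expect_equal(eddy_edge_distance(p[1], p[2], perm),
                 eddy_edge_distance(p[1], p[2], edd))
  }
  expect_true(is.na(eddy_edge_distance(50, -150, e1[0, ])))
  expect_error(eddy_edge_distance(50, -150,
                                  data.frame(lat = 50, lon = -150,
                                             radius_km = -2, polarity = 1)),
               "positive")
})
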
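test_that("sigma_t reproduces EOS-80 check values and monotonicities", {
  # UNESCO one-atmosphere check values (rho, kg m^-3)
  expect_equal(sigma_t(5, 0) + 1000, 999.96675, tolerance = 1e-6)
  expect_equal(sigma_t(5, 35) + 1000, 1027.67547, tolerance = 1e-6)
  expect_equal(sigma_t(25, 35) + 1000, 1023.34306, tolerance = 1e-6)
  tt <- seq(0.5, 24.5, by = 0.5)
  expect_true(all(diff(sigma_t(tt, 33)) < 0))        # thermal expansion
  ss <- seq(30, 36, by = 0.25)
  expect_true(all(diff(sigma_t(8, ss)) > 0))          # haline contraction
  expect_error(sigma_t(NA, 33), "non-finite")
})

test_that("seasonal temperature decrement follows the month mapping", {
  expect_identical(seasonal_dT(as.Date("2010-02-15")), 1.0)
  expect_identical(seasonal_dT(as.Date("2009-08-01")), 0.2)
  expect_identical(seasonal_dT(as.Date("2009-12-31")), 0.8)
  expect_identical(seasonal_dT(as.Date("2010-01-01")), 1.0)
  expect_identical(seasonal_dT(as.Date("2010-05-10")), 0.8)
  expect_identical(seasonal_dT(as.Date("2009-10-01")), 0.8)
})

two_layer_cast <- function(top_T = 8, bot_T = 5, sal = 33,
                           depths = c(2, 6, 10, 20, 30, 40, 50, 60, 80,
                                      100, 130, 160, 190)) {
  temp <- ifelse(depths <= 50, top_T, bot_T)
  ctd_profile("t", as.POSIXct("2010-01-15 06:00", tz = "UTC"),
              depths, temp, rep(sal, length(depths)))
}

test_that("two-layer winter cast yields the interpolated primary MLD", {
  p <- two_layer_cast()
  r <- detect_mld(p)
  expect_identical(r$status, "found_primary")
  o <- oracle_mld(p)
  expect_identical(o$status, "found_primary")
  expect_equal(r$mld, o$mld, tolerance = 0.05)
  # the layer base is at 50 m: exceedance must fall inside the 50-60 m gap
  expect_gt(r$mld, 50)
  expect_lt(r$mld, 60)
  # reference density is the uniform upper-layer density
  expect_equal(r$sigma_ref, sigma_t(8, 33), tolerance = 1e-8)
  expect_equal(r$dsigma, sigma_t(7, 33) - sigma_t(8, 33), tolerance = 1e-10)
})

test_that("degenerate casts produce the documented statuses", {
  z <- seq(10, 200, by = 10)
  uniform <- ctd_profile("u", as.POSIXct("2010-01-15", tz = "UTC"),
                         z, rep(7, length(z)), rep(33, length(z)))
  r <- detect_mld(uniform)
  expect_identical(r$status, "shallower_than_max_dive")
  expect_true(is.na(r$mld))

  shallow <- ctd_profile("s", as.POSIXct("2010-01-15", tz = "UTC"),
                         c(2, 5, 8), c(8, 8, 8), c(33, 33, 33))
  expect_identical(detect_mld(shallow)$status, "shallower_than_max_dive")

  two <- ctd_profile("2", as.POSIXct("2010-01-15", tz = "UTC"),
                     c(5, 9), c(8, 8), c(33, 33))
  expect_identical(detect_mld(two)$status, "shallower_than_max_dive")
})

test_that("quality control removes spikes and rejects degenerate casts", {
  p <- two_layer_cast()
  qc <- quality_control(p)
  expect_length(qc$flags, 0)
  expect_identical(qc$profile$depth, p$depth)

  spiked <- p
  spiked$salinity[6] <- spiked$salinity[6] + 6.5  # ~5 kg m^-3 spike
  qc2 <- quality_control(spiked)
  expect_true(any(grepl("spike", qc2$flags)))
  expect_false(40 %in% qc2$profile$depth)
  expect_identical(detect_mld(spiked)$status, "found_primary")

  allspike <- ctd_profile("a", as.POSIXct("2010-01-15", tz = "UTC"),
                          c(5, 15, 25, 35),
                          c(8, 8, 8, 8), c(33, 40, 28, 40))
  expect_true("rejected" %in% quality_control(allspike)$flags)
  expect_identical(detect_mld(allspike)$status, "undetermined")
})

test_that("planted mixed layers are recovered within one sample spacing", {
  when <- as.POSIXct(c("2010-01-15", "2010-05-15", "2009-08-15",
                       "2009-11-15"), tz = "UTC")
  for (d in when) {
    for (mld in c(15, 40, 80, 120, 150)) {
      cast <- simulate_ctd_profiles(mld, as.POSIXct(d, origin = "1970-01-01",
                                                    tz = "UTC"),
                                    noise_sd = 0, seed = 1)[[1]]
      r <- detect_mld(cast)
      expect_true(r$status %in% c("found_primary", "found_secondary"))
      spacing <- max(diff(cast$depth))
      expect_lt(abs(r$mld - mld), spacing + 1e-9)
      expect_gte(r$mld, 10)
      expect_lte(r$mld, max(cast$depth))
    }
  }
})

test_that("detector agrees with the dense-scan oracle on random casts", {
  mismatch <- 0
  for (i in 1:300) {
    p <- random_cast(i)
    r <- detect_mld(p, qc = FALSE)
    o <- oracle_mld(p)
    ok <- identical(r$status, o$status) &&
      (is.na(r$mld) == is.na(o$mld)) &&
      (is.na(r$mld) || abs(r$mld - o$mld) <= 0.05)
    if (!ok) mismatch <- mismatch + 1
    if (!is.na(r$mld)) {
      expect_gte(r$mld, 10)
      expect_lte(r$mld, max(p$depth))
    }
  }
  expect_identical(mismatch, 0)
})

test_that("block alignment averages, interpolates and respects thresholds", {
  blocks <- as.POSIXct("2010-01-01 00:00", tz = "UTC") + (0:11) * 21600
  mk <- function(t, mld) structure(list(id = "x", time = t,
                                        status = "found_primary", mld = mld),
                                   class = "mld_result")
  res <- list(mk(blocks[1] + 3600, 40), mk(blocks[1] + 7200, 60),
              mk(blocks[3] + 100, 44))
  al <- align_mld_to_blocks(res, blocks)
  expect_equal(al$mld[1], 50)             # two casts in one block -> mean
  expect_equal(al$n_casts[1], 2L)
  expect_equal(al$mld[2], 47)             # one-block gap midpoint of 50, 44
  expect_true(al$interpolated[2])
  al_mid <- align_mld_to_blocks(list(mk(blocks[5], 40), mk(blocks[7], 44)),
                                blocks)
  expect_equal(al_mid$mld[6], 42)         # linear midpoint of 40 and 44

  # a long gap stays missing under the max-gap threshold
  res2 <- list(mk(blocks[1], 40), mk(blocks[12], 44))
  al2 <- align_mld_to_blocks(res2, blocks, max_gap = 2)
  expect_true(all(is.na(al2$mld[2:11])))

  # steep MLD change across the gap also blocks interpolation
  res3 <- list(mk(blocks[1], 40), mk(blocks[3], 80))
  al3 <- align_mld_to_blocks(res3, blocks, max_range = 15)
  expect_true(is.na(al3$mld[2]))
  # non-found results are ignored entirely
  res4 <- list(structure(list(id = "x", time = blocks[5],
                              status = "undetermined", mld = NA_real_),
                         class = "mld_result"))
  expect_true(all(is.na(align_mld_to_blocks(res4, blocks)$mld)))
})
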
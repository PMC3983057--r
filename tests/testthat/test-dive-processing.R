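test_that("histogram means follow the midpoint convention", {
  dl <- splash_depth_limits()
  cnt <- numeric(14)
  cnt[6] <- 5                      # the (20, 34] bin
  expect_equal(histogram_mean(cnt, dl), 27)
  cnt2 <- numeric(14)
  cnt2[6] <- 1; cnt2[7] <- 1       # (20,34] and (34,50] -> (27 + 42)/2
  expect_equal(histogram_mean(cnt2, dl), 34.5)
  # uniform weights over the closed bins = unweighted mean of midpoints
  cnt3 <- c(rep(1, 13), 0)
  lower <- c(0, head(dl, -1))
  expect_equal(histogram_mean(cnt3, dl),
               mean(((lower + dl) / 2)[1:13]))
  # open-ended bin representative = 200 + open_end_width / 2
  cnt4 <- numeric(14); cnt4[14] <- 2
  expect_equal(histogram_mean(cnt4, dl), 213)          # default 174-200 width
  expect_equal(histogram_mean(cnt4, dl, open_end_width = 50), 225)
})

test_that("an all-zero histogram signals an undefined mean", {
  expect_warning(m <- histogram_mean(numeric(14), splash_depth_limits()),
                 "undefined")
  expect_true(is.na(m))
  expect_error(histogram_mean(c(-1, rep(0, 13)), splash_depth_limits()),
               "negative")
  expect_error(histogram_mean(numeric(3), splash_depth_limits()), "lengths")
})

test_that("histogram mean is bounded by occupied representative values", {
  dl <- splash_depth_limits()
  reps <- c((c(0, head(dl, -1)) + dl) / 2)
  reps[14] <- 213
  set.seed(1)
  for (i in 1:50) {
    cnt <- rpois(14, 2)
    if (sum(cnt) == 0) next
    m <- histogram_mean(cnt, dl)
    expect_gte(m, min(reps[cnt > 0]))
    expect_lte(m, max(reps[cnt > 0]))
  }
})

make_blocks <- function() {
  b0 <- as.POSIXct("2009-11-01 00:00", tz = "UTC")
  h <- matrix(0, 3, 14, dimnames = list(NULL, paste0("d", 1:14)))
  h[1, 6] <- 10
  h[2, 1:3] <- c(2, 3, 4)          # only bins at or below 6 m
  h[3, 6:8] <- 1
  tmat <- matrix(0, 3, 14, dimnames = list(NULL, paste0("t", 1:14)))
  tmat[, 4] <- rowSums(h)
  cbind(data.frame(id = "f1", block = b0 + c(0, 21600, 43200),
                   source = "SPLASH"), h, tmat)
}

test_that("record cleaning de-duplicates, filters shallow bins, is idempotent", {
  blocks <- make_blocks()
  dup <- rbind(blocks, blocks[1, ])
  cl <- clean_records(dup)
  expect_identical(nrow(cl), 3L)                       # duplicate dropped
  expect_identical(cl$n_dives[2], 0)                   # <= 6 m bins zeroed
  expect_identical(cl$n_dives[1], 10)
  expect_true(all(cl[, c("d1", "d2", "d3")] == 0))
  expect_true(all(cl$t1 == 0))                         # 15 s bin zeroed
  cl2 <- clean_records(cl)
  attr(cl, "rejected") <- NULL; attr(cl2, "rejected") <- NULL
  expect_identical(cl, cl2)                            # idempotent
})

test_that("malformed block starts are rejected with a report", {
  blocks <- make_blocks()
  blocks$block[2] <- blocks$block[2] + 3600            # 01:00, not a boundary
  expect_warning(cl <- clean_records(blocks), "boundary")
  expect_identical(nrow(cl), 2L)
  expect_identical(nrow(attr(cl, "rejected")), 1L)
  empty <- clean_records(blocks[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("constant-depth dives land in the bracketing histogram bin", {
  cfg <- sim_config(n_seals = 1, n_blocks = 8, seed = 2,
                    dive_coefs = c(b0 = log(30), bD = 0, bM = 0, bMLD = 0),
                    dive_sdlog = 1e-8)
  tr <- simulate_track(cfg, "c")
  cov <- data.frame(D = rep(0.5, 8), M = rep(0.5, 8), mld = rep(NA_real_, 8))
  dv <- simulate_dive_blocks(tr$truth, cov, cfg)
  h <- as.matrix(dv[, paste0("d", 1:14)])
  expect_true(all(h[, -6] == 0))                       # all mass in (20, 34]
  expect_identical(sum(h[, 6]), sum(dv$n_dives))
})

test_that("histogram counts conserve the generated dive count", {
  cfg <- sim_config(n_seals = 1, n_blocks = 30, seed = 6)
  tr <- simulate_track(cfg, "c")
  cov <- data.frame(D = runif(30), M = runif(30), mld = runif(30, 20, 80))
  dv <- simulate_dive_blocks(tr$truth, cov, cfg)
  raw <- attr(dv, "raw_depths")
  h <- as.matrix(dv[, paste0("d", 1:14)])
  expect_equal(rowSums(h), vapply(raw, length, 0L))
  # zero-dive block contract: empty histogram, n = 0
  cfg0 <- sim_config(n_seals = 1, n_blocks = 5, seed = 3,
                     dives_per_block = 1e-9)
  dv0 <- simulate_dive_blocks(simulate_track(cfg0, "z")$truth,
                              cov[1:5, ], cfg0)
  expect_true(all(dv0$n_dives == 0))
  expect_true(all(as.matrix(dv0[, paste0("d", 1:14)]) == 0))
})

test_that("SRDL and SPLASH summaries of the same dives agree to binning error", {
  cfg <- sim_config(n_seals = 1, n_blocks = 40, seed = 9,
                    dives_per_block = 40)
  tr <- simulate_track(cfg, "c")
  cov <- data.frame(D = runif(40), M = runif(40), mld = runif(40, 20, 60))
  dv <- simulate_dive_blocks(tr$truth, cov, cfg, source = "both")
  cl <- clean_records(dv)
  sm <- summarize_dive_blocks(cl)
  dl <- splash_depth_limits()
  for (i in seq_len(nrow(sm))) {
    if (is.na(sm$mean_depth[i]) || cl$n_dives[i] < 5) next
    cnt <- as.numeric(cl[i, paste0("d", 1:14)])
    occupied <- which(cnt > 0)
    widths <- diff(c(0, dl))[occupied]
    widths[!is.finite(widths)] <- 26
    srdl_mean <- dv$mean_depth[i]       # onboard summary of dives > 6 m
    expect_lt(abs(sm$mean_depth[i] - srdl_mean), max(widths) / 2 + 1e-9)
  }
})
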
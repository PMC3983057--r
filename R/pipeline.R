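#' Read the packaged deployment table
#'
#' Loads the capture/deployment summary packaged with `sealwinter`
#' (capture, migration-departure and last-transmission dates, masses and
#' tracked migrating days for the ten females and five males), validating
#' the date ordering invariant on every row.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return data.frame of deployment records.
#' @export
read_deployments <- function(path = system.file("extdata",
                                                "table1_deployments.csv",
                                                package = "sealwinter")) {
  tab <- utils::read.csv(path, colClasses = c(id = "character"))
  for (col in c("capture_date", "departure_date", "last_transmission_date"))
    tab[[col]] <- as.Date(tab[[col]])
  bad <- tab$capture_date > tab$departure_date |
    tab$departure_date > tab$last_transmission_date
  if (any(bad))
    stop("read_deployments: capture <= departure <= last transmission violated for id(s) ",
         paste(tab$id[bad], collapse = ", "), call. = FALSE)
  if (any(tab$mass_kg <= 0))
    stop("read_deployments: non-positive mass", call. = FALSE)
  tab
}

#' Read the packaged per-ecosystem dive summary
#'
#' Mean dive depth (with SD) and dive counts per Large Marine Ecosystem,
#' sex and daylight category (day, >50% day, >50% night, night).
#'
#' @param path CSV path; defaults to the packaged table.
#' @return data.frame.
#' @export
read_dive_summary <- function(path = system.file("extdata",
                                                 "table4_dive_summary.csv",
                                                 package = "sealwinter")) {
  utils::read.csv(path)
}

#' Cohort tracking-duration summary
#'
#' Per animal: days from capture to migration departure, tracked migrating
#' days, and the percentage of the estimated total migration that was
#' recorded, where the total migration runs from the departure date to a
#' sex-specific assumed return date to the rookery. Cohort aggregates: the
#' maximum number of departures in any window of 10 consecutive calendar
#' days (both endpoint days inclusive), minimum/maximum tracked migrating
#' days by sex, the minimum transmitter span (capture to last transmission)
#' and the largest-male to smallest-female mass ratio.
#'
#' @param records data.frame from [read_deployments()] (columns `id`, `sex`,
#'   `mass_kg`, `capture_date`, `departure_date`,
#'   `last_transmission_date`, `migrating_days`).
#' @param return_dates named list/vector with `male` and `female` assumed
#'   return dates. Defaults to 1 June and 10 July of the year after the
#'   October deployments.
#' @param window_days departure-window length in calendar days. Default 10.
#' @return list with `per_seal` (data.frame adding `days_to_departure`,
#'   `migration_days_total`, `pct_recorded`, `pct_recorded_rounded`,
#'   `transmission_span`) and `cohort` (named list of aggregates).
#' @export
tracking_summary <- function(records,
                             return_dates = list(male = "2010-06-01",
                                                 female = "2010-07-10"),
                             window_days = 10) {
  ret <- as.Date(unlist(return_dates))[match(tolower(records$sex),
                                             c("m", "f"))]
  ret[is.na(ret)] <- as.Date(unlist(return_dates))[
    match(tolower(records$sex), c("male", "female"))][is.na(ret)]
  if (any(is.na(ret)))
    stop("tracking_summary: sex must be M/F (or male/female)",
         call. = FALSE)
  total <- as.numeric(ret - records$departure_date)
  if (any(total <= 0))
    stop("tracking_summary: departure on or after the assumed return date for id(s) ",
         paste(records$id[total <= 0], collapse = ", "), call. = FALSE)
  per <- data.frame(
    id = records$id, sex = records$sex,
    days_to_departure = as.numeric(records$departure_date -
                                     records$capture_date),
    migrating_days = records$migrating_days,
    migration_days_total = total,
    pct_recorded = 100 * records$migrating_days / total,
    transmission_span = as.numeric(records$last_transmission_date -
                                     records$capture_date))
  per$pct_recorded_rounded <- round(per$pct_recorded)
  per <- per[order(per$id), ]
  rownames(per) <- NULL

  dep <- records$departure_date
  starts <- sort(unique(dep))
  max_window <- max(vapply(starts, function(d)
    sum(dep >= d & dep <= d + window_days - 1), 0L))

  is_m <- tolower(substr(per$sex, 1, 1)) == "m"
  rec_m <- tolower(substr(records$sex, 1, 1)) == "m"
  cohort <- list(
    max_departures_in_window = max_window,
    longest_migration_female = max(per$migrating_days[!is_m]),
    longest_migration_male = max(per$migrating_days[is_m]),
    min_transmission_span = min(per$transmission_span),
    female_pct_range = range(per$pct_recorded_rounded[!is_m]),
    male_pct_range = range(per$pct_recorded_rounded[is_m]),
    mass_ratio_max_male_min_female =
      max(records$mass_kg[rec_m]) / min(records$mass_kg[!rec_m]))
  list(per_seal = per, cohort = cohort)
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates an end-to-end run on synthetic data with planted ground
#' truth: track simulation and Argos observation, state-space
#' regularisation, dive-record generation and cleaning, CTD simulation with
#' mixed-layer detection and block alignment, covariate construction
#' (daylight, moon, wind, season, habitat), and linear mixed-effects fits
#' ranked by AIC. Every intermediate table can be persisted as delimited
#' text.
#'
#' @param config either a path to a YAML configuration file (sections
#'   mirroring the list form; `sim` entries are passed to [sim_config()])
#'   or a list with (all optional): `sim` (a [sim_config()]),
#'   `mcmc` (list `iters`, `burn`, `thin`, `chains`), `formulas` (named
#'   character vector of fixed-effect formulas on the assembled block
#'   table; available columns include `logit_b`, `log_depth`, `log_ndives`,
#'   `D`, `M`, `S`, `WS`, `lme`, `mld`), `out_dir` (persist intermediates
#'   when non-NULL), `seed`.
#' @return a list bundle of class `seal_pipeline`: per-seal fits, the
#'   assembled block table, model fits, the AIC ranking and the run log.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- config
  if (is.character(cfg) && length(cfg) == 1) {
    if (!file.exists(cfg))
      stop("run_pipeline: config file not found: ", cfg, call. = FALSE)
    cfg <- yaml::read_yaml(cfg)
  }
  if (!is.null(cfg$sim) && !inherits(cfg$sim, "sim_config")) {
    if (!is.null(cfg$sim$transition) && !is.matrix(cfg$sim$transition))
      cfg$sim$transition <- matrix(unlist(cfg$sim$transition), 2, 2,
                                   byrow = TRUE)
    cfg$sim <- do.call(sim_config, cfg$sim)
  }
  if (is.null(cfg$sim)) cfg$sim <- sim_config(n_seals = 2, n_blocks = 120)
  if (is.null(cfg$seed)) cfg$seed <- cfg$sim$seed
  if (is.null(cfg$mcmc)) cfg$mcmc <- list(iters = 2000, burn = 1000,
                                          thin = 2, chains = 2)
  if (is.null(cfg$formulas))
    cfg$formulas <- c(full = "log_depth ~ D + M + mld",
                      light = "log_depth ~ D + M",
                      day = "log_depth ~ D")

  # fail-fast validation before any computation
  uses_mld <- any(vapply(cfg$formulas, function(f)
    "mld" %in% all.vars(stats::as.formula(f)), TRUE))
  if (uses_mld && isTRUE(cfg$no_ctd))
    stop("run_pipeline: formulas use 'mld' but the configuration disables CTD casts",
         call. = FALSE)

  log <- c(sprintf("run_pipeline seed=%d n_seals=%d n_blocks=%d",
                   cfg$seed, cfg$sim$n_seals, cfg$sim$n_blocks))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("run_pipeline: stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  regions <- stage("habitat", read_lme_regions())
  sims <- fits <- vector("list", cfg$sim$n_seals)
  rows <- list()
  for (i in seq_len(cfg$sim$n_seals)) {
    id <- sprintf("sim%02d", i)
    sims[[i]] <- stage("movement",
                       simulate_track(cfg$sim, id = id,
                                      seed = cfg$seed + 17 * i))
    fits[[i]] <- stage("movement",
                       fit_sssm(sims[[i]]$fixes, iters = cfg$mcmc$iters,
                                burn = cfg$mcmc$burn, thin = cfg$mcmc$thin,
                                chains = cfg$mcmc$chains,
                                seed = cfg$seed + i))
    truth <- sims[[i]]$truth

    # covariates on the true blocks (planted values drive the dive model)
    blocks <- truth$blocks
    cov <- data.frame(id = id, block = blocks,
                      D = vapply(seq_along(blocks), function(k)
                        proportion_daylight(truth$lat[k], truth$lon[k],
                                            blocks[k]), 0),
                      M = lunar_fraction(blocks + 3 * 3600),
                      S = season_days(blocks))
    mldt <- cfg$sim$mld_mean +
      cfg$sim$mld_amp * (seq_along(blocks) - 1) / max(length(blocks) - 1, 1)
    cast_sel <- stage("mld", {
      set.seed(cfg$seed + 101 * i)
      which(stats::runif(length(blocks)) < 0.75)
    })
    casts <- stage("mld",
                   simulate_ctd_profiles(mldt[cast_sel],
                                         blocks[cast_sel] + 3600,
                                         id = id, noise_sd = 0.01,
                                         seed = cfg$seed + 7 * i))
    mres <- stage("mld", lapply(casts, detect_mld))
    mal <- stage("mld", align_mld_to_blocks(mres, blocks))
    cov$mld <- mal$mld

    dives <- stage("dive_processing",
                   simulate_dive_blocks(truth, cov,
                                        within_seed(cfg$sim, cfg$seed + 31 * i)))
    dives <- stage("dive_processing", clean_records(dives))
    dsum <- stage("dive_processing", summarize_dive_blocks(dives))

    b <- fits[[i]]$track$b[match(as.numeric(blocks),
                                 as.numeric(fits[[i]]$track$block))]
    tab <- data.frame(id = id, block = blocks, block_index = seq_along(blocks),
                      D = cov$D, M = cov$M, S = cov$S, mld = cov$mld,
                      lme = vapply(seq_along(blocks), function(k)
                        assign_lme(truth$lat[k], truth$lon[k], regions), ""),
                      b = b,
                      n_dives = dsum$n_dives[match(as.numeric(blocks),
                                                   as.numeric(dsum$block))],
                      mean_depth = dsum$mean_depth[
                        match(as.numeric(blocks), as.numeric(dsum$block))])
    rows[[i]] <- tab
    log <- c(log, sprintf("seal %s: %d fixes, %d casts, mean b %.2f", id,
                          nrow(sims[[i]]$fixes), length(casts),
                          mean(b, na.rm = TRUE)))
  }
  blocks_tab <- do.call(rbind, rows)
  blocks_tab$logit_b <- NA_real_
  hasb <- !is.na(blocks_tab$b)
  blocks_tab$logit_b[hasb] <-
    transform_state(pmin(pmax(blocks_tab$b[hasb], 0), 1))
  keep <- !is.na(blocks_tab$mean_depth) & blocks_tab$n_dives > 0
  blocks_tab$log_depth <- ifelse(keep, log(blocks_tab$mean_depth), NA)
  blocks_tab$log_ndives <- ifelse(keep, log(blocks_tab$n_dives), NA)

  model_data <- blocks_tab[stats::complete.cases(
    blocks_tab[, unique(c("id", "block_index",
                          unlist(lapply(cfg$formulas, function(f)
                            all.vars(stats::as.formula(f))))))]), ]
  lmm_fits <- stage("stats_models",
                    lapply(cfg$formulas, fit_lmm, data = model_data))
  ranking <- stage("stats_models", aic_rank(lmm_fits))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(sims)) {
      write_fixes(sims[[i]]$fixes,
                  file.path(cfg$out_dir, sprintf("fixes_%02d.csv", i)))
      write_truth(sims[[i]]$truth,
                  file.path(cfg$out_dir, sprintf("truth_%02d.json", i)))
      utils::write.csv(fits[[i]]$track,
                       file.path(cfg$out_dir, sprintf("track_%02d.csv", i)),
                       row.names = FALSE)
    }
    utils::write.csv(blocks_tab, file.path(cfg$out_dir, "blocks.csv"),
                     row.names = FALSE)
    utils::write.csv(ranking, file.path(cfg$out_dir, "aic_ranking.csv"),
                     row.names = FALSE)
    writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
  }

  structure(list(sims = sims, tracks = fits, blocks = blocks_tab,
                 models = lmm_fits, ranking = ranking, log = log,
                 config = cfg),
            class = "seal_pipeline")
}

# clone a sim_config with a different seed (generators derive their own
# sub-seeds from it)
within_seed <- function(config, seed) {
  config$seed <- as.integer(seed)
  config
}

#' @export
print.seal_pipeline <- function(x, ...) {
  cat(sprintf("seal_pipeline: %d animals, %d block rows, %d model(s)\n",
              length(x$sims), nrow(x$blocks), length(x$models)))
  print(x$ranking, row.names = FALSE, digits = 5)
  invisible(x)
}
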
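## Delimited-text readers/writers for the pipeline's table formats. All
## timestamps are ISO-8601 UTC.

fmt_time <- function(x) format(as.POSIXct(x, tz = "UTC"),
                               "%Y-%m-%dT%H:%M:%SZ")
parse_time <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ",
                                     tz = "UTC")

#' Read and write Argos fix tables
#'
#' Delimited text with columns `id`, `time` (ISO-8601 UTC), `class`
#' (3/2/1/0/A/B), `lat`, `lon`.
#'
#' @param fixes data.frame of fixes.
#' @param path file path.
#' @return `read_fixes` returns the data.frame with parsed times.
#' @export
write_fixes <- function(fixes, path) {
  out <- fixes
  out$time <- fmt_time(out$time)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixes
#' @export
read_fixes <- function(path) {
  tab <- utils::read.csv(path, colClasses = c(class = "character"))
  tab$time <- parse_time(tab$time)
  tab
}

#' Read and write 6-h dive block tables
#'
#' @param blocks data.frame in the [clean_records()] layout.
#' @param path file path.
#' @export
write_dive_blocks <- function(blocks, path) {
  out <- blocks
  out$block <- fmt_time(out$block)
  attr(out, "raw_depths") <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dive_blocks
#' @export
read_dive_blocks <- function(path) {
  tab <- utils::read.csv(path)
  tab$block <- parse_time(tab$block)
  tab
}

#' Read and write CTD cast tables
#'
#' Long-format delimited text: `id`, `time`, `depth`, `temperature`,
#' `salinity`, one row per sample, grouped into casts by (`id`, `time`).
#'
#' @param casts list of [ctd_profile()] objects.
#' @param path file path.
#' @return `read_ctd_casts` returns a list of [ctd_profile()] objects.
#' @export
write_ctd_casts <- function(casts, path) {
  rows <- do.call(rbind, lapply(casts, function(p)
    data.frame(id = p$id, time = fmt_time(p$time), depth = p$depth,
               temperature = p$temperature, salinity = p$salinity)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ctd_casts
#' @export
read_ctd_casts <- function(path) {
  tab <- utils::read.csv(path)
  keys <- unique(tab[, c("id", "time")])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- tab$id == keys$id[i] & tab$time == keys$time[i]
    sub <- tab[sel, , drop = FALSE]
    o <- order(sub$depth)
    ctd_profile(keys$id[i], parse_time(keys$time[i]), sub$depth[o],
                sub$temperature[o], sub$salinity[o])
  })
}

#' Read and write weekly eddy catalogs
#'
#' @param eddies data.frame `week`, `lat`, `lon`, `radius_km`, `polarity`.
#' @param path file path.
#' @export
write_eddies <- function(eddies, path) {
  utils::write.csv(eddies, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eddies
#' @export
read_eddies <- function(path) {
  tab <- utils::read.csv(path)
  tab$week <- as.Date(tab$week)
  tab
}

#' Write the ground-truth sidecar of a synthetic run
#'
#' JSON serialisation of the planted truth (block times, positions, states,
#' generating parameters) so downstream recovery checks can run without the
#' in-memory object.
#'
#' @param truth a `sim_truth` from [simulate_track()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  obj <- list(id = truth$id, blocks = fmt_time(truth$blocks),
              lat = truth$lat, lon = truth$lon, state = truth$state,
              gamma = truth$gamma,
              transition = as.vector(truth$transition),
              step_sd = truth$step_sd, dive_coefs = truth$dive_coefs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(id = obj$id, blocks = parse_time(obj$blocks),
                 lat = obj$lat, lon = obj$lon, state = obj$state,
                 gamma = obj$gamma,
                 transition = matrix(obj$transition, 2, 2),
                 step_sd = obj$step_sd, dive_coefs = obj$dive_coefs),
            class = "sim_truth")
}
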
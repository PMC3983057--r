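#' Gridded 6-hourly 10-m wind container
#'
#' Holds u (eastward) and v (northward) 10-m wind components on a regular
#' latitude/longitude grid at synoptic times (00/06/12/18 UTC), mirroring
#' the layout of reanalysis surface-wind products.
#'
#' @param time POSIXct UTC vector of synoptic times.
#' @param lat,lon grid-cell centre coordinates, degrees (typically 2.5
#'   degree spacing).
#' @param u,v arrays dimensioned `[time, lat, lon]`, m s^-1.
#' @return an object of class `wind_grid`.
#' @export
wind_grid <- function(time, lat, lon, u, v) {
  time <- as.POSIXct(time, tz = "UTC")
  dims <- c(length(time), length(lat), length(lon))
  if (!identical(dim(u), dims) || !identical(dim(v), dims))
    stop("wind_grid: u/v must be [time, lat, lon] arrays", call. = FALSE)
  structure(list(time = time, lat = as.numeric(lat), lon = as.numeric(lon),
                 u = u, v = v), class = "wind_grid")
}

#' @export
print.wind_grid <- function(x, ...) {
  cat(sprintf("wind_grid: %d times (%s .. %s), %d x %d cells\n",
              length(x$time), format(min(x$time), "%Y-%m-%d %H:%M"),
              format(max(x$time), "%Y-%m-%d %H:%M"),
              length(x$lat), length(x$lon)))
  invisible(x)
}

#' Read and write wind grids as self-describing text
#'
#' A plain-text serialisation of a [wind_grid()]: `#`-prefixed header lines
#' declare the dimensions (times as ISO-8601 UTC, then latitude and
#' longitude vectors) followed by a delimited table of `time_index, lat,
#' lon, u10, v10` rows.
#'
#' @param wind a [wind_grid()].
#' @param path file path.
#' @return `read_wind_grid` returns a [wind_grid()]; `write_wind_grid`
#'   returns `path` invisibly.
#' @export
write_wind_grid <- function(wind, path) {
  stopifnot(inherits(wind, "wind_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# sealwinter wind grid v1",
    paste0("# time: ", paste(format(wind$time, "%Y-%m-%dT%H:%M:%SZ"),
                             collapse = ",")),
    paste0("# lat: ", paste(wind$lat, collapse = ",")),
    paste0("# lon: ", paste(wind$lon, collapse = ",")),
    "time_index,lat,lon,u10,v10"), con)
  idx <- expand.grid(ti = seq_along(wind$time), li = seq_along(wind$lat),
                     oi = seq_along(wind$lon))
  rows <- sprintf("%d,%g,%g,%g,%g", idx$ti, wind$lat[idx$li],
                  wind$lon[idx$oi],
                  wind$u[cbind(idx$ti, idx$li, idx$oi)],
                  wind$v[cbind(idx$ti, idx$li, idx$oi)])
  writeLines(rows, con)
  invisible(path)
}

#' @rdname write_wind_grid
#' @export
read_wind_grid <- function(path) {
  hdr <- readLines(path, n = 5)
  get <- function(key) {
    line <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    strsplit(sub(paste0("^# ", key, ": *"), "", line), ",")[[1]]
  }
  time <- as.POSIXct(get("time"), format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  lat <- as.numeric(get("lat"))
  lon <- as.numeric(get("lon"))
  tab <- utils::read.csv(path, comment.char = "#")
  u <- array(NA_real_, c(length(time), length(lat), length(lon)))
  v <- u
  li <- match(tab$lat, lat)
  oi <- match(tab$lon, lon)
  u[cbind(tab$time_index, li, oi)] <- tab$u10
  v[cbind(tab$time_index, li, oi)] <- tab$v10
  wind_grid(time, lat, lon, u, v)
}
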
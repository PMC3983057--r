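#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Positional precision of
#' the inputs (Argos fixes, weekly eddy centres with approximate radii) does
#' not warrant ellipsoidal geodesics.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees; vectorised.
#' @return distance in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371) # km
}

#' Load Large Marine Ecosystem polygons
#'
#' Reads a GeoJSON FeatureCollection of (multi)polygons with a `label`
#' property. The packaged region set
#' (`lme_regions_synthetic.geojson`) contains simplified, synthetic
#' approximations of the six study regions — Bering Sea Shelf (BS), Bering
#' Sea Basin (BB), Alaska Stream (AS), North Pacific Ocean (NP), Gulf of
#' Alaska (GA) and California Current (CC) — with the shelf/basin split
#' along an approximate 1000-m isobath line; they are qualitative
#' stand-ins, not the original analysis polygons.
#'
#' @param path GeoJSON file; defaults to the packaged synthetic region set.
#' @return an object of class `lme_regions`: a named list of polygons, each
#'   a matrix with columns `lon`, `lat` (closed rings).
#' @export
read_lme_regions <- function(path = system.file("extdata",
                                                "lme_regions_synthetic.geojson",
                                                package = "sealwinter")) {
  gj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                 error = function(e)
                   stop("read_lme_regions: cannot parse ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  if (is.null(gj$features))
    stop("read_lme_regions: not a GeoJSON FeatureCollection", call. = FALSE)
  regions <- list()
  for (f in gj$features) {
    label <- f$properties$label
    geom <- f$geometry
    rings <- switch(geom$type,
                    Polygon = list(geom$coordinates[[1]]),
                    MultiPolygon = lapply(geom$coordinates,
                                          function(p) p[[1]]),
                    stop("read_lme_regions: unsupported geometry ",
                         geom$type, call. = FALSE))
    mats <- lapply(rings, function(r) {
      m <- do.call(rbind, lapply(r, function(pt)
        c(lon = as.numeric(pt[[1]]), lat = as.numeric(pt[[2]]))))
      colnames(m) <- c("lon", "lat")
      m
    })
    if (label %in% names(regions))
      stop("read_lme_regions: duplicate label ", label, call. = FALSE)
    regions[[label]] <- mats
  }
  structure(regions, class = "lme_regions")
}

# Ray-casting point-in-polygon with an explicit boundary rule: points on an
# edge or vertex count as inside.
point_in_ring <- function(lat, lon, ring) {
  x <- ring[, "lon"]; y <- ring[, "lat"]
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
    # boundary test: point on segment (i, j)
    cross <- (lon - xi) * (yj - yi) - (lat - yi) * (xj - xi)
    if (abs(cross) < 1e-9 &&
        lon >= min(xi, xj) - 1e-9 && lon <= max(xi, xj) + 1e-9 &&
        lat >= min(yi, yj) - 1e-9 && lat <= max(yi, yj) + 1e-9)
      return(TRUE)
    if ((yi > lat) != (yj > lat)) {
      xint <- xi + (lat - yi) / (yj - yi) * (xj - xi)
      if (lon < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Assign a position to a Large Marine Ecosystem
#'
#' Returns the label of the first listed region whose polygon contains the
#' point; boundary points count as inside, and listing order breaks ties.
#' Points in no region get `"outside"`.
#'
#' @param lat,lon position, degrees.
#' @param regions an `lme_regions` object from [read_lme_regions()].
#' @return a region label, or `"outside"`.
#' @export
assign_lme <- function(lat, lon, regions) {
  stopifnot(inherits(regions, "lme_regions"))
  for (label in names(regions)) {
    for (ring in regions[[label]]) {
      if (point_in_ring(lat, lon, ring)) return(label)
    }
  }
  "outside"
}

#' Per-cell proportion of stormy days
#'
#' A UTC calendar day is stormy when any of its four synoptic wind speeds
#' exceeds `threshold` (default 11 m s^-1). The proportion is computed per
#' grid cell over the given window (default 1 November - 31 March, the storm
#' season assessed in the study). Cells whose series does not cover every
#' day of the window are set to `NA`.
#'
#' @param wind a [wind_grid()].
#' @param window length-2 Date vector, inclusive.
#' @param threshold wind speed threshold, m s^-1.
#' @return matrix `[lat, lon]` of fractions in `[0, 1]`.
#' @export
stormy_proportion <- function(wind,
                              window = as.Date(c("2009-11-01", "2010-03-31")),
                              threshold = 11) {
  stopifnot(inherits(wind, "wind_grid"))
  day <- as.Date(wind$time, tz = "UTC")
  sel <- day >= window[1] & day <= window[2]
  ndays <- as.integer(window[2] - window[1]) + 1
  out <- matrix(NA_real_, length(wind$lat), length(wind$lon),
                dimnames = list(wind$lat, wind$lon))
  if (!any(sel)) return(out)
  dsel <- day[sel]
  covered <- length(unique(dsel)) == ndays
  ws <- sqrt(wind$u[sel, , , drop = FALSE]^2 +
               wind$v[sel, , , drop = FALSE]^2)
  for (li in seq_along(wind$lat)) {
    for (oi in seq_along(wind$lon)) {
      cell <- ws[, li, oi]
      if (!covered || any(!is.finite(cell))) next
      stormy <- tapply(cell, dsel, function(z) any(z > threshold))
      out[li, oi] <- sum(stormy) / ndays
    }
  }
  out
}

#' Signed distance to the nearest eddy edge
#'
#' Great-circle distance from a position to the nearest eddy centre minus
#' that eddy's radius: negative inside an eddy. Returns `NA` when the
#' week's catalog is empty.
#'
#' @param lat,lon position, degrees.
#' @param eddies data.frame with columns `lat`, `lon`, `radius_km` (one
#'   week's catalog).
#' @return signed distance, km.
#' @export
eddy_edge_distance <- function(lat, lon, eddies) {
  if (is.null(eddies) || nrow(eddies) == 0) return(NA_real_)
  if (any(eddies$radius_km <= 0))
    stop("eddy_edge_distance: eddy radii must be positive", call. = FALSE)
  d <- haversine_km(lat, lon, eddies$lat, eddies$lon) - eddies$radius_km
  min(d)
}
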
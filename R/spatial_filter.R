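# Search areas (circle/square), geodesic distance, containment filtering.

# meters per degree of latitude used for the small-area planar square spans;
# at 200 m scale the planar error is far below positional tolerance
METERS_PER_DEG_LAT <- 111320
EARTH_RADIUS_M <- 6371008.8  # mean Earth radius

#' Define a circular or quadratic search area
#'
#' Google-style query regions are circular, OSM-style regions quadratic.
#' The field default for urban areas is a 200 m circle diameter or square
#' edge, i.e. `search_area("circle", ..., size_m = 100)` (radius) and
#' `search_area("square", ..., size_m = 200)` (edge length).
#'
#' @param kind "circle" or "square".
#' @param center_latitude,center_longitude Center, WGS84 decimal degrees.
#' @param size_m Radius (circle) or edge length (square), meters, > 0.
#' @param area_id Text identifier.
#' @return An object of class `search_area`.
#' @export
#' @examples
#' search_area("circle", 48.137, 11.575, size_m = 100, area_id = "C")
search_area <- function(kind = c("circle", "square"), center_latitude,
                        center_longitude, size_m, area_id = "area") {
  kind <- match.arg(kind)
  if (!is.numeric(size_m) || size_m <= 0) {
    stop_obesopoi("size_m must be a positive number of meters",
                  "area_domain_error")
  }
  if (abs(center_latitude) > 90 || abs(center_longitude) > 180) {
    stop_obesopoi("area center out of WGS84 coordinate range",
                  "area_domain_error")
  }
  structure(
    list(kind = kind, center_latitude = center_latitude,
         center_longitude = center_longitude, size_m = size_m,
         area_id = area_id),
    class = "search_area"
  )
}

#' @export
print.search_area <- function(x, ...) {
  cat(sprintf("<search_area '%s'> %s, center (%.5f, %.5f), size %g m\n",
              x$area_id, x$kind, x$center_latitude, x$center_longitude,
              x$size_m))
  invisible(x)
}

#' Great-circle (haversine) distance in meters
#'
#' Vectorized haversine distance on a sphere of mean Earth radius
#' 6 371 008.8 m.
#'
#' @param lat1,lon1,lat2,lon2 WGS84 decimal degrees.
#' @return Distance(s) in meters.
#' @export
#' @examples
#' haversine_distance_m(0, 0, 0, 180)  # half circumference
haversine_distance_m <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop_obesopoi("coordinates out of WGS84 range", "area_domain_error")
  }
  if (length(lat1) == 0 || length(lat2) == 0) return(numeric(0))
  unname(geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                  r = EARTH_RADIUS_M))
}

#' Test whether points fall inside a search area
#'
#' Circles use haversine distance to the center; squares are axis-aligned
#' geodesic boxes with north-south and east-west extents of `size_m`, their
#' half-spans converted to degrees with 111 320 m/degree (scaled by
#' cos(latitude) east-west). The boundary counts as inside.
#'
#' @param area A [search_area()].
#' @param latitude,longitude Point coordinates (vectorized).
#' @return Logical vector.
#' @export
area_contains <- function(area, latitude, longitude) {
  stopifnot(inherits(area, "search_area"))
  if (area$kind == "circle") {
    d <- haversine_distance_m(latitude, longitude,
                              area$center_latitude, area$center_longitude)
    d <= area$size_m
  } else {
    half_lat <- (area$size_m / 2) / METERS_PER_DEG_LAT
    half_lon <- (area$size_m / 2) /
      (METERS_PER_DEG_LAT * cos(area$center_latitude * pi / 180))
    eps <- 1e-12  # float guard so exact boundary points test inside
    abs(latitude - area$center_latitude) <= half_lat + eps &
      abs(longitude - area$center_longitude) <= half_lon + eps
  }
}

#' Restrict a POI set to a search area
#'
#' Keeps exactly the records whose coordinates lie inside the area
#' (boundary inclusive), preserving input order; the number of dropped
#' records is logged.
#'
#' @param pois A [poi_tbl()].
#' @param area A [search_area()].
#' @return The filtered [poi_tbl()].
#' @export
filter_to_area <- function(pois, area) {
  pois <- validate_poi_tbl(pois)
  if (nrow(pois) == 0) return(pois)
  inside <- area_contains(area, pois$latitude, pois$longitude)
  n_drop <- sum(!inside)
  if (n_drop > 0) {
    poi_log(sprintf("area '%s': dropped %d of %d record(s) outside",
                    area$area_id, n_drop, nrow(pois)))
  }
  validate_poi_tbl(pois[inside, , drop = FALSE])
}

#' Area outline as a GeoJSON Polygon string
#'
#' For map overlays; circle outlines are discretized with `n` vertices.
#' Coordinates are written (lon, lat) per the GeoJSON standard.
#'
#' @param area A [search_area()].
#' @param n Number of vertices for circle outlines.
#' @return A single GeoJSON character string.
#' @export
area_outline_geojson <- function(area, n = 90) {
  xy <- area_outline_coords(area, n)
  ring <- cbind(xy$longitude, xy$latitude)
  ring <- rbind(ring, ring[1, ])
  jsonlite::toJSON(
    list(type = "Polygon", coordinates = list(ring)),
    auto_unbox = TRUE, digits = 10
  )
}

# internal: outline vertices as a data frame (latitude, longitude)
area_outline_coords <- function(area, n = 90) {
  lat0 <- area$center_latitude
  lon0 <- area$center_longitude
  m_lat <- METERS_PER_DEG_LAT
  m_lon <- METERS_PER_DEG_LAT * cos(lat0 * pi / 180)
  if (area$kind == "circle") {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    data.frame(latitude = lat0 + area$size_m * sin(th) / m_lat,
               longitude = lon0 + area$size_m * cos(th) / m_lon)
  } else {
    h <- area$size_m / 2
    data.frame(
      latitude = lat0 + c(-h, -h, h, h) / m_lat,
      longitude = lon0 + c(-h, h, h, -h) / m_lon
    )
  }
}

# internal: displace a (lat, lon) point by (east_m, north_m) meters using the
# same planar approximation as the square containment test
offset_point <- function(latitude, longitude, east_m, north_m) {
  list(
    latitude = latitude + north_m / METERS_PER_DEG_LAT,
    longitude = longitude +
      east_m / (METERS_PER_DEG_LAT * cos(latitude * pi / 180))
  )
}
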
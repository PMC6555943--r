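# Fixture builders and independent oracles shared across test files.

# --- JSON builders ---------------------------------------------------------

google_places_json <- function(entries) {
  jsonlite::toJSON(list(results = entries, status = "OK"),
                   auto_unbox = TRUE, digits = 10)
}

google_entry <- function(id, lat, lng, types, name = NULL) {
  e <- list(place_id = id,
            geometry = list(location = list(lat = lat, lng = lng)),
            types = as.list(types))
  if (!is.null(name)) e$name <- name
  e
}

overpass_json <- function(elements) {
  jsonlite::toJSON(list(version = 0.6, elements = elements),
                   auto_unbox = TRUE, digits = 10)
}

overpass_node <- function(id, lat, lon, tags) {
  list(type = "node", id = id, lat = lat, lon = lon, tags = tags)
}

overpass_way <- function(id, center_lat, center_lon, tags) {
  list(type = "way", id = id,
       center = list(lat = center_lat, lon = center_lon), tags = tags)
}

geojson_points <- function(features) {
  jsonlite::toJSON(list(type = "FeatureCollection", features = features),
                   auto_unbox = TRUE, digits = 10)
}

geojson_point <- function(id, lat, lon, props) {
  list(type = "Feature",
       geometry = list(type = "Point", coordinates = list(lon, lat)),
       properties = c(list(id = id), props))
}

# --- independent distance oracle ------------------------------------------

# spherical law of cosines; independent of the haversine implementation
slc_distance_m <- function(lat1, lon1, lat2, lon2, r = 6371008.8) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  c <- pmin(1, pmax(-1, sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)))
  r * acos(c)
}

# --- printed field-validation reference values -----------------------------

# (tp, fp, fn) triples with the printed PPV, FP share and sensitivity
# percentages, for all POIs and for the recomputation without "doctor"
printed_validation <- function(which = c("all", "no_doctor")) {
  which <- match.arg(which)
  if (which == "all") {
    tibble::tribble(
      ~area, ~source,  ~tp, ~fp, ~fn, ~ppv,   ~fp_pct, ~sens,
      "A",   "google",  19,  11,  13, 63.33,  36.67,   59.38,
      "A",   "osm",     15,   2,  17, 88.24,  11.76,   46.88,
      "B",   "google",  58,   7,   1, 89.23,  10.77,   98.31,
      "B",   "osm",     12,   0,  47, 100,     0,      20.34,
      "C",   "google", 144,  57,  63, 71.64,  28.36,   69.57,
      "C",   "osm",     41,   6, 166, 87.23,  12.77,   19.81,
      "D",   "google",  22,  12,  11, 64.71,  35.29,   66.67,
      "D",   "osm",     21,   5,  12, 80.77,  19.23,   63.64)
  } else {
    tibble::tribble(
      ~area, ~source,  ~tp, ~fp, ~fn, ~ppv,   ~fp_pct, ~sens,
      "A",   "google",  18,  11,  13, 62.07,  37.93,   58.06,
      "A",   "osm",     15,   2,  16, 88.24,  11.76,   48.39,
      "B",   "google",  29,   3,   1, 90.63,   9.38,   96.67,
      "B",   "osm",     10,   0,  20, 100,     0,      33.33,
      "C",   "google",  48,  21,  30, 69.57,  30.43,   61.54,
      "C",   "osm",     36,   6,  42, 85.71,  14.29,   46.15,
      "D",   "google",  19,   9,   6, 67.86,  32.14,   76.00,
      "D",   "osm",     21,   5,   4, 80.77,  19.23,   84.00)
  }
}

# build a metrics_result whose doctor stratum is the difference between the
# with-doctor and without-doctor printed rows, and whose remainder is lumped
# into one other category
printed_metrics_result <- function(area, source) {
  t3 <- printed_validation("all")
  t4 <- printed_validation("no_doctor")
  r3 <- t3[t3$area == area & t3$source == source, ]
  r4 <- t4[t4$area == area & t4$source == source, ]
  metrics_result(area, source, tibble::tibble(
    category = c("doctor", "food"),
    tp = c(r3$tp - r4$tp, r4$tp),
    fp = c(r3$fp - r4$fp, r4$fp),
    fn = c(r3$fn - r4$fn, r4$fn)))
}

# small helper: a poi_tbl at fixed offsets (east/north meters) from a center
poi_at_offsets <- function(area, east_m, north_m, source = "google",
                           ids = NULL, labels = "gym") {
  p <- obesopoi:::offset_point(area$center_latitude, area$center_longitude,
                               east_m, north_m)
  n <- length(east_m)
  poi_tbl(source_id = ids %||% sprintf("p%d", seq_len(n)),
          source = source, name = NA_character_,
          latitude = p$latitude, longitude = p$longitude,
          raw_labels = rep(list(labels), n), provenance = "fixture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
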
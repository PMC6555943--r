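# Ingest: parse POI exports from the two geocoding-service dialects into a
# common record form (one row per POI) and remove duplicate listings.

#' Construct a POI record table
#'
#' The common record form flowing through the whole pipeline: one row per
#' geocoded point, with the source-native labels kept as a list-column.
#'
#' @param source_id Character, identifier unique within the source.
#' @param source "google" or "osm".
#' @param name Optional character name (NA allowed).
#' @param latitude,longitude WGS84 decimal degrees.
#' @param raw_labels List of character vectors (Google place types such as
#'   "gym"; OSM "key=value" tag pairs such as "amenity=fast_food"). May be
#'   empty vectors.
#' @param provenance Character: file or query of origin, one line per record.
#' @return A tibble of class `poi_tbl` with the columns above.
#' @export
poi_tbl <- function(source_id = character(), source = character(),
                    name = NA_character_, latitude = numeric(),
                    longitude = numeric(), raw_labels = list(),
                    provenance = NA_character_) {
  out <- tibble::tibble(
    source_id = as.character(source_id),
    source = as.character(source),
    name = as.character(name),
    latitude = as.numeric(latitude),
    longitude = as.numeric(longitude),
    raw_labels = as.list(raw_labels),
    provenance = as.character(provenance)
  )
  validate_poi_tbl(out)
}

validate_poi_tbl <- function(x) {
  need <- c("source_id", "source", "name", "latitude", "longitude",
            "raw_labels", "provenance")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop_obesopoi(paste0("POI table is missing columns: ",
                         paste(miss, collapse = ", ")), "poi_schema_error")
  }
  if (nrow(x) > 0) {
    if (any(!x$source %in% c("google", "osm"))) {
      stop_obesopoi("source must be 'google' or 'osm'", "poi_schema_error")
    }
    if (any(is.na(x$source_id)) || any(!nzchar(x$source_id))) {
      stop_obesopoi("source_id must be non-empty", "poi_schema_error")
    }
    bad <- is.na(x$latitude) | is.na(x$longitude) |
      abs(x$latitude) > 90 | abs(x$longitude) > 180
    if (any(bad)) {
      stop_obesopoi(
        paste0("coordinates out of WGS84 range for source_id: ",
               paste(x$source_id[bad], collapse = ", ")),
        "poi_coordinate_error")
    }
  }
  class(x) <- unique(c("poi_tbl", class(x)))
  x
}

#' Read a Google-Places-style JSON export
#'
#' Parses the Places response dialect: a top-level `results` array whose
#' entries carry an identifier (`place_id` or `id`), a point geometry at
#' `geometry.location.lat/lng`, optional `name` and a `types` string array.
#'
#' @param path Path to a JSON file, or a literal JSON string.
#' @param provenance Provenance string stored per record; defaults to the
#'   file path.
#' @return A [poi_tbl()] with `source = "google"`, input order preserved and
#'   `raw_labels` holding the entry's type strings.
#' @export
#' @examples
#' txt <- '{"results":[{"place_id":"g1","name":"Gym One",
#'   "geometry":{"location":{"lat":48.1,"lng":11.5}},"types":["gym"]}]}'
#' read_google_places_json(txt, provenance = "inline")
read_google_places_json <- function(path, provenance = NULL) {
  doc <- parse_json_input(path)
  if (is.null(provenance)) {
    provenance <- if (file.exists(path)) path else "google_places_json"
  }
  results <- doc$results
  if (is.null(results)) {
    stop_obesopoi("document has no 'results' array (not the Places dialect)",
                  "poi_parse_error")
  }
  if (length(results) == 0) return(poi_tbl())
  rows <- purrr::imap(results, function(entry, i) {
    id <- entry$place_id %||% entry$id
    loc <- entry$geometry$location
    if (is.null(id) || !nzchar(as.character(id))) {
      stop_obesopoi(sprintf("entry %d lacks an identifier", i),
                    "poi_record_error")
    }
    if (is.null(loc$lat) || is.null(loc$lng)) {
      stop_obesopoi(sprintf("entry %d ('%s') lacks a point geometry",
                            i, as.character(id)), "poi_record_error")
    }
    tibble::tibble(
      source_id = as.character(id),
      source = "google",
      name = as.character(entry$name %||% NA_character_),
      latitude = as.numeric(loc$lat),
      longitude = as.numeric(loc$lng),
      raw_labels = list(as.character(unlist(entry$types))),
      provenance = provenance
    )
  })
  validate_poi_tbl(dplyr::bind_rows(rows))
}

#' Read an OSM element export (Overpass JSON or GeoJSON)
#'
#' Overpass dialect: an `elements` array; nodes carry `lat`/`lon`,
#' ways/relations a representative `center` point. GeoJSON dialect: a
#' FeatureCollection of Point features, coordinates in (lon, lat) axis
#' order, tags under `properties`. Elements without any tag cannot be
#' crosswalked and are dropped (counted in a log line).
#'
#' @param path Path to a JSON file, or a literal JSON string.
#' @param dialect "overpass_json" or "geojson".
#' @param provenance Provenance string stored per record.
#' @return A [poi_tbl()] with `source = "osm"` and `raw_labels` as
#'   "key=value" strings for all tags.
#' @export
read_osm_elements <- function(path, dialect = c("overpass_json", "geojson"),
                              provenance = NULL) {
  dialect <- match.arg(dialect)
  doc <- parse_json_input(path)
  if (is.null(provenance)) {
    provenance <- if (file.exists(path)) path else dialect
  }
  if (dialect == "overpass_json") {
    els <- doc$elements
    if (is.null(els)) {
      stop_obesopoi("document has no 'elements' array (not Overpass JSON)",
                    "poi_parse_error")
    }
    rows <- purrr::imap(els, function(el, i) {
      tags <- el$tags
      if (is.null(tags) || length(tags) == 0) return(NULL)
      lat <- el$lat %||% el$center$lat
      lon <- el$lon %||% el$center$lon
      if (is.null(lat) || is.null(lon)) {
        stop_obesopoi(sprintf("element %d (id %s) has no resolvable coordinate",
                              i, as.character(el$id %||% "?")),
                      "poi_record_error")
      }
      tibble::tibble(
        source_id = as.character(el$id %||% paste0("el", i)),
        source = "osm",
        name = as.character(tags$name %||% NA_character_),
        latitude = as.numeric(lat),
        longitude = as.numeric(lon),
        raw_labels = list(paste0(names(tags), "=",
                                 vapply(tags, as.character, character(1)))),
        provenance = provenance
      )
    })
    n_in <- length(els)
  } else {
    feats <- doc$features
    if (is.null(feats)) {
      stop_obesopoi("document has no 'features' array (not GeoJSON)",
                    "poi_parse_error")
    }
    rows <- purrr::imap(feats, function(ft, i) {
      props <- ft$properties
      tags <- props[setdiff(names(props), c("name", "id"))]
      if (length(tags) == 0) return(NULL)
      geom <- ft$geometry
      if (is.null(geom) || !identical(geom$type, "Point") ||
          length(geom$coordinates) < 2) {
        stop_obesopoi(sprintf("feature %d has no Point geometry", i),
                      "poi_record_error")
      }
      # GeoJSON (RFC 7946) is (lon, lat); internal order is (lat, lon)
      tibble::tibble(
        source_id = as.character(props$id %||% ft$id %||% paste0("ft", i)),
        source = "osm",
        name = as.character(props$name %||% NA_character_),
        latitude = as.numeric(geom$coordinates[[2]]),
        longitude = as.numeric(geom$coordinates[[1]]),
        raw_labels = list(paste0(names(tags), "=",
                                 vapply(tags, as.character, character(1)))),
        provenance = provenance
      )
    })
    n_in <- length(feats)
  }
  rows <- purrr::compact(rows)
  n_dropped <- n_in - length(rows)
  if (n_dropped > 0) {
    poi_log(sprintf("dropped %d untagged element(s) of %d", n_dropped, n_in))
  }
  if (length(rows) == 0) return(poi_tbl())
  validate_poi_tbl(dplyr::bind_rows(rows))
}

parse_json_input <- function(path) {
  txt <- if (length(path) == 1 && !grepl("[{\\[]", substr(path, 1, 1)) &&
             file.exists(path)) {
    paste(readLines(path, warn = FALSE), collapse = "\n")
  } else {
    path
  }
  tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) {
      stop_obesopoi(paste0("malformed JSON: ", conditionMessage(e)),
                    "poi_parse_error")
    }
  )
}

#' Remove duplicate POI listings within one source
#'
#' Records sharing a `source_id` (the same place listed under several
#' service categories) are merged into one record carrying the union of
#' raw labels. Optionally, records whose normalized names are equal
#' (case-folded, trimmed, internal whitespace collapsed) and that lie
#' within `distance_tol_m` of each other are merged too. Output keeps the
#' first-occurrence order and the operation is idempotent.
#'
#' @param pois A [poi_tbl()], all rows from a single source.
#' @param distance_tol_m Merge radius in meters for equal-name merging.
#'   Default 25 m: the typical positional scatter between services, small
#'   relative to 200 m search areas.
#' @param merge_names Also merge equal-normalized-name records within
#'   `distance_tol_m`? Default TRUE.
#' @return A deduplicated [poi_tbl()].
#' @export
deduplicate_pois <- function(pois, distance_tol_m = 25, merge_names = TRUE) {
  pois <- validate_poi_tbl(pois)
  if (nrow(pois) == 0) return(pois)
  if (length(unique(pois$source)) > 1) {
    stop_obesopoi("deduplicate_pois expects records from a single source",
                  "poi_usage_error")
  }
  stopifnot(distance_tol_m >= 0)

  # pass 1: merge identical source_id
  group <- match(pois$source_id, unique(pois$source_id))

  # pass 2: equal normalized name within distance tolerance
  if (isTRUE(merge_names)) {
    norm <- normalize_poi_name(pois$name)
    reps <- tapply(seq_len(nrow(pois)), group, `[`, 1)  # group representative
    g_of <- function(i) group[i]
    for (i in seq_len(nrow(pois))) {
      if (is.na(norm[i]) || !nzchar(norm[i])) next
      for (j in seq_len(i - 1L)) {
        if (g_of(i) == g_of(j)) next
        if (is.na(norm[j]) || norm[i] != norm[j]) next
        d <- haversine_distance_m(pois$latitude[i], pois$longitude[i],
                                  pois$latitude[j], pois$longitude[j])
        if (d <= distance_tol_m) {
          group[group == g_of(i)] <- g_of(j)
          break
        }
      }
    }
  }

  keep <- !duplicated(group)
  out <- pois[keep, , drop = FALSE]
  out$raw_labels <- lapply(group[keep], function(g) {
    unique(unlist(pois$raw_labels[group == g], use.names = FALSE))
  })
  n_merged <- nrow(pois) - nrow(out)
  if (n_merged > 0) poi_log(sprintf("merged %d duplicate listing(s)", n_merged))
  validate_poi_tbl(out)
}

normalize_poi_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Read/write the common POI record CSV
#'
#' Columns: source_id, source, name, latitude, longitude, raw_labels
#' (pipe-delimited), provenance. The written file round-trips through
#' [read_poi_csv()] field-identically.
#'
#' @param pois A [poi_tbl()].
#' @param path File path.
#' @return `write_poi_csv` returns `path` invisibly; `read_poi_csv` a
#'   [poi_tbl()].
#' @export
write_poi_csv <- function(pois, path) {
  pois <- validate_poi_tbl(pois)
  flat <- pois
  flat$raw_labels <- vapply(pois$raw_labels, paste, character(1),
                            collapse = "|")
  readr::write_csv(flat, path, na = "")
  invisible(path)
}

#' @rdname write_poi_csv
#' @export
read_poi_csv <- function(path) {
  flat <- readr::read_csv(
    path, na = character(),
    col_types = readr::cols(
      source_id = readr::col_character(), source = readr::col_character(),
      name = readr::col_character(), latitude = readr::col_double(),
      longitude = readr::col_double(), raw_labels = readr::col_character(),
      provenance = readr::col_character()
    )
  )
  flat$name[!nzchar(flat$name)] <- NA_character_
  flat$provenance[!nzchar(flat$provenance)] <- NA_character_
  flat$raw_labels <- lapply(flat$raw_labels, function(s) {
    if (!nzchar(s)) character() else strsplit(s, "|", fixed = TRUE)[[1]]
  })
  validate_poi_tbl(tibble::as_tibble(flat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
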
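# Parsing the two service dialects into the common record form, and
# duplicate-listing removal.

test_that("Google Places JSON parses to records matching a manual parse", {
  txt <- google_places_json(list(
    google_entry("g1", 48.1374, 11.5755, c("gym"), name = "Gym One"),
    google_entry("g2", 48.1386, 11.5736, c("bakery"), name = "Backstube")))
  pois <- read_google_places_json(txt, provenance = "fixture")

  # oracle: manual parse of the literal fixture values
  expect_equal(nrow(pois), 2)
  expect_equal(pois$source_id, c("g1", "g2"))
  expect_equal(pois$source, c("google", "google"))
  expect_equal(pois$name, c("Gym One", "Backstube"))
  expect_equal(pois$latitude, c(48.1374, 48.1386))
  expect_equal(pois$longitude, c(11.5755, 11.5736))
  expect_equal(pois$raw_labels, list("gym", "bakery"))

  expect_equal(nrow(read_google_places_json(google_places_json(list()))), 0)
})

test_that("Google entries without geometry or identifier are record-level errors", {
  no_geom <- google_places_json(list(list(place_id = "g1",
                                          types = list("gym"))))
  expect_error(read_google_places_json(no_geom), class = "obesopoi_error")
  expect_error(read_google_places_json(no_geom), "entry 1")
  no_id <- google_places_json(list(
    list(geometry = list(location = list(lat = 48, lng = 11)),
         types = list("gym"))))
  expect_error(read_google_places_json(no_id), "identifier")
  expect_error(read_google_places_json("{not json"), class = "obesopoi_error")
})

test_that("Overpass nodes and ways parse with key=value labels", {
  txt <- overpass_json(list(
    overpass_node(101, 48.2, 11.6, list(amenity = "cafe", name = "Cafe Alt")),
    overpass_way(202, 48.21, 11.61, list(amenity = "school"))))
  pois <- read_osm_elements(txt, "overpass_json")
  expect_equal(nrow(pois), 2)
  expect_equal(pois$source, c("osm", "osm"))
  expect_setequal(pois$raw_labels[[1]], c("amenity=cafe", "name=Cafe Alt"))
  # way located at its representative center
  expect_equal(pois$latitude[2], 48.21)
  expect_equal(pois$longitude[2], 11.61)

  expect_equal(nrow(read_osm_elements(overpass_json(list()),
                                      "overpass_json")), 0)
  expect_error(read_osm_elements(txt, "osmar"))
})

test_that("untagged OSM elements are dropped; missing coordinates error", {
  txt <- overpass_json(list(
    overpass_node(1, 48.2, 11.6, list(amenity = "cafe")),
    list(type = "node", id = 2, lat = 48.2, lon = 11.6)))  # no tags
  expect_equal(nrow(suppressMessages(read_osm_elements(txt, "overpass_json"))), 1)

  bad <- overpass_json(list(list(type = "way", id = 3,
                                 tags = list(amenity = "pub"))))
  expect_error(read_osm_elements(bad, "overpass_json"),
               class = "obesopoi_error")
})

test_that("GeoJSON points parse with (lon, lat) axis order converted", {
  txt <- geojson_points(list(
    geojson_point("n1", lat = 48.25, lon = 11.65,
                  props = list(amenity = "fast_food", name = "Imbiss"))))
  pois <- read_osm_elements(txt, "geojson")
  expect_equal(pois$latitude, 48.25)
  expect_equal(pois$longitude, 11.65)
  expect_true("amenity=fast_food" %in% pois$raw_labels[[1]])
})

test_that("same-id listings merge with the union of labels", {
  pois <- poi_tbl(source_id = c("g1", "g1"), source = "google",
                  name = c("Laden", "Laden"),
                  latitude = c(48.1, 48.1), longitude = c(11.5, 11.5),
                  raw_labels = list("food", "bakery"),
                  provenance = "fixture")
  out <- suppressMessages(deduplicate_pois(pois))
  expect_equal(nrow(out), 1)
  expect_setequal(out$raw_labels[[1]], c("food", "bakery"))
})

test_that("equal-name records merge only within the distance tolerance", {
  area <- search_area("circle", 48.137, 11.575, 100, "t")
  near <- poi_at_offsets(area, east_m = c(0, 5), north_m = c(0, 0),
                         ids = c("a", "b"))
  near$name <- c("Cafe  Alt", "cafe alt")  # differs only by case/whitespace
  # haversine oracle: the two points really are ~5 m apart
  d <- slc_distance_m(near$latitude[1], near$longitude[1],
                      near$latitude[2], near$longitude[2])
  expect_lt(d, 25)
  merged <- suppressMessages(deduplicate_pois(near, distance_tol_m = 25,
                                              merge_names = TRUE))
  expect_equal(nrow(merged), 1)

  diff_names <- near
  diff_names$name <- c("Cafe Alt", "Cafe Neu")
  expect_equal(nrow(deduplicate_pois(diff_names, 25, TRUE)), 2)

  far <- poi_at_offsets(area, east_m = c(0, 60), north_m = c(0, 0),
                        ids = c("a", "b"))
  far$name <- c("Cafe Alt", "Cafe Alt")
  expect_equal(nrow(deduplicate_pois(far, 25, TRUE)), 2)
})

test_that("deduplication is idempotent, never grows, and keeps all labels", {
  set.seed(42)
  area <- search_area("square", 48.137, 11.575, 200, "t")
  for (rep in 1:5) {
    n <- 20
    pois <- poi_at_offsets(area, stats::runif(n, -90, 90),
                           stats::runif(n, -90, 90), source = "osm",
                           ids = sample(sprintf("id%d", 1:10), n,
                                        replace = TRUE))
    pois$name <- sample(c("Alpha", "Beta", NA), n, replace = TRUE)
    pois$raw_labels <- replicate(n, sample(letters[1:5],
                                           sample(1:3, 1)), simplify = FALSE)
    once <- suppressMessages(deduplicate_pois(pois))
    twice <- suppressMessages(deduplicate_pois(once))
    expect_equal(twice, once)
    expect_lte(nrow(once), nrow(pois))
    expect_setequal(unique(unlist(once$raw_labels)),
                    unique(unlist(pois$raw_labels)))
  }
  mixed <- poi_tbl(source_id = c("a", "b"), source = c("google", "osm"),
                   name = NA, latitude = c(48, 48), longitude = c(11, 11),
                   raw_labels = list("x", "y"), provenance = "f")
  expect_error(deduplicate_pois(mixed), class = "obesopoi_error")
})

test_that("common-record CSV round-trips field-identically", {
  pois <- poi_tbl(source_id = c("g1", "g2"), source = "google",
                  name = c("Gym One", NA),
                  latitude = c(48.1374, 48.1386),
                  longitude = c(11.5755, 11.5736),
                  raw_labels = list(c("gym", "health"), character()),
                  provenance = "fixture.json")
  path <- withr::local_tempfile(fileext = ".csv")
  write_poi_csv(pois, path)
  back <- read_poi_csv(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(pois))
})
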
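# Seeded synthetic truth sets, per-service databases with controlled
# completeness/commission errors, and auto-derived audit files.

#' Describe a synthetic validation scenario
#'
#' A scenario fixes everything the generator needs: the search area, how
#' many real amenities of each category exist in it, each service's
#' per-category detection probability (database completeness), each
#' service's expected number of spurious entries (commission errors), and
#' the positional jitter applied to detected entries.
#'
#' @param area A [search_area()].
#' @param truth_counts Named integer vector over (a subset of)
#'   [poi_categories()]: real POIs per category.
#' @param detection_prob Either a single probability, a named-by-source
#'   list of single probabilities, or a named-by-source list of named
#'   per-category probability vectors. Sources default to c("google",
#'   "osm").
#' @param commission_mean Named-by-source expected count of spurious
#'   database entries (Poisson mean), or a single number for all sources.
#' @param jitter_sd_m Standard deviation (meters) of isotropic positional
#'   noise on detected entries.
#' @param seed Integer seed; identical scenarios and seeds give identical
#'   bundles.
#' @param sources Character vector of service names.
#' @return An object of class `poi_scenario`.
#' @export
#' @examples
#' sc <- poi_scenario(
#'   search_area("circle", 48.137, 11.575, 100, "demo"),
#'   truth_counts = c(food = 30, doctor = 10),
#'   detection_prob = 0.7, commission_mean = 5, seed = 1)
poi_scenario <- function(area, truth_counts, detection_prob = 0.7,
                         commission_mean = 0, jitter_sd_m = 5, seed = 1,
                         sources = c("google", "osm")) {
  stopifnot(inherits(area, "search_area"))
  if (is.null(names(truth_counts)) ||
      !all(names(truth_counts) %in% poi_categories())) {
    stop_obesopoi("truth_counts must be named by the six categories",
                  "scenario_error")
  }
  if (any(truth_counts < 0) || any(truth_counts != floor(truth_counts))) {
    stop_obesopoi("truth_counts must be non-negative integers",
                  "scenario_error")
  }
  dp <- expand_by_source_category(detection_prob, sources,
                                  names(truth_counts))
  if (any(unlist(dp) < 0) || any(unlist(dp) > 1)) {
    stop_obesopoi("detection probabilities must lie in [0, 1]",
                  "scenario_error")
  }
  cm <- expand_by_source(commission_mean, sources)
  if (any(unlist(cm) < 0)) {
    stop_obesopoi("commission_mean must be non-negative", "scenario_error")
  }
  stopifnot(jitter_sd_m >= 0)
  structure(
    list(area = area, truth_counts = truth_counts, detection_prob = dp,
         commission_mean = cm, jitter_sd_m = jitter_sd_m,
         seed = as.integer(seed), sources = sources),
    class = "poi_scenario")
}

expand_by_source <- function(x, sources) {
  if (is.list(x) || !is.null(names(x))) {
    miss <- setdiff(sources, names(x))
    if (length(miss) > 0) {
      stop_obesopoi(paste0("missing value for source(s): ",
                           paste(miss, collapse = ", ")), "scenario_error")
    }
    as.list(x)[sources]
  } else {
    stats::setNames(rep(list(x), length(sources)), sources)
  }
}

expand_by_source_category <- function(x, sources, cats) {
  per_source <- expand_by_source(x, sources)
  lapply(per_source, function(p) {
    if (is.null(names(p))) {
      stats::setNames(rep(as.numeric(p), length(cats)), cats)
    } else {
      miss <- setdiff(cats, names(p))
      if (length(miss) > 0) {
        stop_obesopoi(paste0("missing detection prob for category: ",
                             paste(miss, collapse = ", ")), "scenario_error")
      }
      p[cats]
    }
  })
}

# internal: uniform points inside an area, as a data frame (latitude, longitude)
sample_points_in_area <- function(area, n) {
  if (n == 0) {
    return(data.frame(latitude = numeric(), longitude = numeric()))
  }
  if (area$kind == "circle") {
    r <- area$size_m * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    east <- r * cos(th); north <- r * sin(th)
  } else {
    h <- area$size_m / 2
    east <- stats::runif(n, -h, h); north <- stats::runif(n, -h, h)
  }
  p <- offset_point(area$center_latitude, area$center_longitude, east, north)
  data.frame(latitude = p$latitude, longitude = p$longitude)
}

# internal: clamp a jittered point back onto the area boundary when the
# jitter pushed it outside (logged by the caller)
clamp_to_area <- function(area, latitude, longitude) {
  if (area$kind == "circle") {
    d <- haversine_distance_m(latitude, longitude,
                              area$center_latitude, area$center_longitude)
    out <- d > area$size_m
    n_out <- sum(out)
    # radial pull-back, iterated with a 1 mm margin: scaling degree offsets
    # is only first-order linear in great-circle distance
    while (any(out)) {
      f <- (area$size_m - 1e-3) / d[out]
      latitude[out] <- area$center_latitude +
        (latitude[out] - area$center_latitude) * f
      longitude[out] <- area$center_longitude +
        (longitude[out] - area$center_longitude) * f
      d <- haversine_distance_m(latitude, longitude,
                                area$center_latitude, area$center_longitude)
      out <- d > area$size_m
    }
    list(latitude = latitude, longitude = longitude, n_clamped = n_out)
  } else {
    half_lat <- (area$size_m / 2) / METERS_PER_DEG_LAT
    half_lon <- (area$size_m / 2) /
      (METERS_PER_DEG_LAT * cos(area$center_latitude * pi / 180))
    out <- abs(latitude - area$center_latitude) > half_lat |
      abs(longitude - area$center_longitude) > half_lon
    latitude <- pmin(pmax(latitude, area$center_latitude - half_lat),
                     area$center_latitude + half_lat)
    longitude <- pmin(pmax(longitude, area$center_longitude - half_lon),
                      area$center_longitude + half_lon)
  }
  list(latitude = latitude, longitude = longitude, n_clamped = sum(out))
}

# internal: one crosswalkable raw label per (source, category)
label_for_category <- function(source, category, crosswalk) {
  sub <- crosswalk[crosswalk$source == source &
                     crosswalk$category == category &
                     !endsWith(crosswalk$raw_label, "*"), , drop = FALSE]
  if (nrow(sub) == 0) {
    stop_obesopoi(sprintf("crosswalk has no %s label for category '%s'",
                          source, category), "scenario_error")
  }
  sub$raw_label[1]
}

#' Generate a synthetic validation bundle
#'
#' Places `truth_counts` real POIs uniformly in the scenario area, then
#' builds each service's database: every truth POI is detected
#' independently with the service's per-category detection probability and,
#' when detected, its recorded position is jittered by isotropic Gaussian
#' noise (sd `jitter_sd_m`; points pushed outside the area are clamped to
#' the boundary and logged). Each service additionally receives a
#' Poisson(`commission_mean`) number of spurious entries placed uniformly
#' and labeled with crosswalkable labels. Audit files are derived exactly
#' from the construction: detected truth = confirmed hit, spurious entry =
#' rejected hit, undetected truth = field observation missing from that
#' service.
#'
#' @param scenario A [poi_scenario()].
#' @param crosswalk Crosswalk used to label synthetic records; default the
#'   bundled one.
#' @return A list of class `poi_bundle`: `truth` (categorized POI tibble),
#'   `databases` (named list of [poi_tbl()] per source), `audits` (named
#'   list per source with elements `hits` and `observations`), and the
#'   scenario.
#' @export
generate_bundle <- function(scenario, crosswalk = load_crosswalk()) {
  stopifnot(inherits(scenario, "poi_scenario"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(scenario$seed)

  area <- scenario$area
  cats <- names(scenario$truth_counts)
  n_total <- sum(scenario$truth_counts)

  # ground truth, uniform per category
  pts <- sample_points_in_area(area, n_total)
  truth <- tibble::tibble(
    truth_id = sprintf("t%04d", seq_len(n_total)),
    name = sprintf("Synthetic %s %04d",
                   rep(cats, scenario$truth_counts), seq_len(n_total)),
    latitude = pts$latitude, longitude = pts$longitude,
    category = factor(rep(cats, scenario$truth_counts),
                      levels = poi_categories())
  )

  databases <- list()
  audits <- list()
  detected <- matrix(FALSE, nrow = n_total,
                     ncol = length(scenario$sources),
                     dimnames = list(NULL, scenario$sources))
  n_clamped <- 0L

  for (src in scenario$sources) {
    p_cat <- scenario$detection_prob[[src]]
    p <- unname(p_cat[as.character(truth$category)])
    hit <- stats::runif(n_total) < p
    detected[, src] <- hit

    # detected truth entries, jittered
    lat <- truth$latitude[hit] +
      stats::rnorm(sum(hit), 0, scenario$jitter_sd_m) / METERS_PER_DEG_LAT
    lon <- truth$longitude[hit] +
      stats::rnorm(sum(hit), 0, scenario$jitter_sd_m) /
      (METERS_PER_DEG_LAT * cos(area$center_latitude * pi / 180))
    cl <- clamp_to_area(area, lat, lon)
    n_clamped <- n_clamped + cl$n_clamped
    labels <- vapply(as.character(truth$category[hit]), label_for_category,
                     character(1), source = src, crosswalk = crosswalk)

    # spurious (commission) entries
    n_spur <- stats::rpois(1, scenario$commission_mean[[src]])
    spur_pts <- sample_points_in_area(area, n_spur)
    spur_cat <- sample(cats, n_spur, replace = TRUE)
    spur_labels <- vapply(spur_cat, label_for_category, character(1),
                          source = src, crosswalk = crosswalk)

    db <- poi_tbl(
      source_id = c(paste0(src, "_", truth$truth_id[hit]),
                    sprintf("%s_spur%03d", src, seq_len(n_spur))),
      source = src,
      name = c(truth$name[hit], sprintf("Phantom %s %03d", spur_cat,
                                        seq_len(n_spur))),
      latitude = c(cl$latitude, spur_pts$latitude),
      longitude = c(cl$longitude, spur_pts$longitude),
      raw_labels = as.list(c(labels, spur_labels)),
      provenance = sprintf("synthetic:%s:%s:seed=%d", area$area_id, src,
                           scenario$seed)
    )
    databases[[src]] <- db

    audits[[src]] <- list(
      hits = tibble::tibble(
        hit_id = db$source_id,
        area_id = area$area_id,
        source = src,
        status = c(rep("confirmed", sum(hit)), rep("rejected", n_spur)),
        category = factor(c(as.character(truth$category[hit]), spur_cat),
                          levels = poi_categories()),
        audit_date = as.Date("2026-01-01"),
        note = NA_character_
      )
    )
  }

  # field observations shared across sources: one per truth POI missed by
  # at least one service, listing exactly the services that missed it
  missed_any <- rowSums(!detected) > 0
  observations <- tibble::tibble(
    name = truth$name[missed_any],
    latitude = truth$latitude[missed_any],
    longitude = truth$longitude[missed_any],
    category = truth$category[missed_any],
    missing_from = apply(!detected[missed_any, , drop = FALSE], 1,
                         function(m) scenario$sources[m], simplify = FALSE)
  )
  for (src in scenario$sources) audits[[src]]$observations <- observations

  if (n_clamped > 0) {
    poi_log(sprintf("clamped %d jittered point(s) to the area boundary",
                    n_clamped))
  }
  structure(list(truth = truth, databases = databases, audits = audits,
                 scenario = scenario),
            class = "poi_bundle")
}

#' Closed-form expected metrics for a scenario
#'
#' The Monte-Carlo-free companion to [generate_bundle()]: expected
#' sensitivity is the truth-weighted mean detection probability,
#' 100 * sum(p_cat * N_cat) / sum(N_cat); expected PPV is
#' 100 * D / (D + C) with D the expected number of detected truth POIs and
#' C the commission mean.
#'
#' @param scenario A [poi_scenario()].
#' @return Tibble with one row per source: expected_sensitivity_pct,
#'   expected_ppv_pct (NA where undefined).
#' @export
#' @examples
#' sc <- poi_scenario(search_area("circle", 48, 11, 100),
#'                    truth_counts = c(food = 100),
#'                    detection_prob = 0.7, commission_mean = 30)
#' expected_metrics(sc)  # sensitivity 70, ppv 70
expected_metrics <- function(scenario) {
  stopifnot(inherits(scenario, "poi_scenario"))
  N <- scenario$truth_counts
  purrr::map_dfr(scenario$sources, function(src) {
    p <- scenario$detection_prob[[src]][names(N)]
    D <- sum(p * N)
    C <- scenario$commission_mean[[src]]
    tibble::tibble(
      source = src,
      expected_sensitivity_pct =
        if (sum(N) > 0) 100 * D / sum(N) else NA_real_,
      expected_ppv_pct =
        if (D + C > 0) 100 * D / (D + C) else NA_real_
    )
  })
}

#' Run the validation pipeline on a synthetic bundle
#'
#' Tallies each source's audit against the shared observations and returns
#' one [metrics_result()] per source.
#'
#' @param bundle A [generate_bundle()] result.
#' @return Named list of `metrics_result` objects.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "poi_bundle"))
  lapply(stats::setNames(nm = bundle$scenario$sources), function(src) {
    a <- bundle$audits[[src]]
    validate_area(a$hits, a$observations,
                  area_id = bundle$scenario$area$area_id, source = src)
  })
}

#' Write a bundle to disk as the same files real runs consume
#'
#' Databases as common-record CSVs, audits and observations as CSVs, so
#' synthetic and real data are interchangeable downstream.
#'
#' @param bundle A [generate_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (src in names(bundle$databases)) {
    write_poi_csv(bundle$databases[[src]],
                  file.path(dir, paste0("database_", src, ".csv")))
    hits <- bundle$audits[[src]]$hits
    hits$category <- as.character(hits$category)
    readr::write_csv(hits, file.path(dir, paste0("audit_", src, ".csv")),
                     na = "")
  }
  obs <- bundle$audits[[1]]$observations
  flat <- obs
  flat$category <- as.character(flat$category)
  flat$missing_from <- vapply(obs$missing_from, paste, character(1),
                              collapse = "|")
  readr::write_csv(flat, file.path(dir, "observations.csv"), na = "")
  truth <- bundle$truth
  truth$category <- as.character(truth$category)
  readr::write_csv(truth, file.path(dir, "truth.csv"), na = "")
  invisible(dir)
}
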
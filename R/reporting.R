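# Maps, category bar charts and validation tables.

# fixed plotting order for categories in bar charts
BAR_ORDER <- c("doctor", "education", "food", "sport", "transport", "other")

CATEGORY_COLORS <- c(
  food = "#E41A1C", doctor = "#377EB8", sport = "#4DAF4A",
  education = "#984EA3", transport = "#FF7F00", other = "#999999")

#' Render a POI map for one search area
#'
#' One marker per POI, colored by category, with the search-area outline
#' overlaid. Maps draw on a blank canvas with coordinate axes (no basemap
#' tiles, so rendering is fully offline and byte-deterministic).
#'
#' @param pois A categorized POI tibble (see [categorize_pois()]); may be
#'   empty.
#' @param area A [search_area()].
#' @param out_path Output image path (.png).
#' @param width,height,dpi Device size in inches and resolution.
#' @return `out_path`, invisibly.
#' @export
render_poi_map <- function(pois, area, out_path, width = 6, height = 6,
                           dpi = 96) {
  outline <- area_outline_coords(area, n = 180)
  outline <- rbind(outline, outline[1, ])
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(
      data = outline,
      ggplot2::aes(x = .data$longitude, y = .data$latitude),
      linetype = "dashed", color = "grey30")
  if (nrow(pois) > 0) {
    dat <- tibble::tibble(
      longitude = pois$longitude, latitude = pois$latitude,
      category = factor(as.character(pois$category), levels = BAR_ORDER))
    p <- p + ggplot2::geom_point(
      data = dat,
      ggplot2::aes(x = .data$longitude, y = .data$latitude,
                   color = .data$category),
      size = 2) +
      ggplot2::scale_color_manual(values = CATEGORY_COLORS, drop = TRUE)
  } else {
    p <- p + ggplot2::labs(subtitle = "no POIs in this area")
  }
  p <- p +
    ggplot2::coord_quickmap() +
    ggplot2::labs(title = paste("Area", area$area_id),
                  x = "Longitude", y = "Latitude", color = "Category") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(out_path, p, width = width, height = height, dpi = dpi)
  invisible(out_path)
}

#' Render the category distribution of database hits
#'
#' Bar chart of hit counts over the six categories, bars ordered doctor,
#' education, food, sport, transport, other.
#'
#' @param counts Named counts over (a subset of) [poi_categories()], e.g.
#'   from [summarize_hits_by_category()].
#' @param out_path Output image path (.png).
#' @param width,height,dpi Device size in inches and resolution.
#' @return `out_path`, invisibly.
#' @export
render_category_bars <- function(counts, out_path, width = 6, height = 4,
                                 dpi = 96) {
  full <- stats::setNames(rep(0L, length(BAR_ORDER)), BAR_ORDER)
  full[names(counts)] <- as.integer(counts)
  dat <- tibble::tibble(
    category = factor(BAR_ORDER, levels = BAR_ORDER),
    n = unname(full))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$category, y = .data$n,
                                         fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = CATEGORY_COLORS) +
    ggplot2::labs(x = "Category", y = "Database hits") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(out_path, p, width = width, height = height, dpi = dpi)
  invisible(out_path)
}

#' Write a validation results table
#'
#' One row per (area, source): true positives with PPV, false positives
#' with their share of hits, false negatives, and sensitivity. Percentages
#' are printed with 2 decimals ("." decimal separator); undefined metrics
#' print as "NA". The written file round-trips through
#' [read_validation_table()] with numeric fields intact.
#'
#' @param results List of [metrics_result()] objects, non-conflicting on
#'   (area, source).
#' @param out_path Output CSV path.
#' @return `out_path`, invisibly.
#' @export
write_validation_table <- function(results, out_path) {
  stopifnot(all(vapply(results, inherits, logical(1), "metrics_result")))
  keys <- vapply(results, function(r) paste(r$area_id, r$source), character(1))
  if (anyDuplicated(keys)) {
    stop_obesopoi(paste0("duplicate (area, source) rows: ",
                         paste(unique(keys[duplicated(keys)]), collapse = "; ")),
                  "report_validation_error")
  }
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
  rows <- purrr::map_dfr(results, function(r) {
    fp_pct <- if (r$overall$tp + r$overall$fp > 0) {
      round_half_up(100 * r$overall$fp / (r$overall$tp + r$overall$fp), 2)
    } else NA_real_
    tibble::tibble(
      area = r$area_id, source = r$source,
      tp = r$overall$tp, ppv_pct = fmt(r$ppv_pct),
      fp = r$overall$fp, fp_pct = fmt(fp_pct),
      fn = r$overall$fn, sensitivity_pct = fmt(r$sensitivity_pct))
  })
  if (length(results) == 0) {
    rows <- tibble::tibble(
      area = character(), source = character(), tp = integer(),
      ppv_pct = character(), fp = integer(), fp_pct = character(),
      fn = integer(), sensitivity_pct = character())
  }
  readr::write_csv(rows, out_path, na = "NA")
  invisible(out_path)
}

#' @rdname write_validation_table
#' @param path CSV written by [write_validation_table()].
#' @export
read_validation_table <- function(path) {
  readr::read_csv(
    path, na = "NA",
    col_types = readr::cols(
      area = readr::col_character(), source = readr::col_character(),
      tp = readr::col_integer(), ppv_pct = readr::col_double(),
      fp = readr::col_integer(), fp_pct = readr::col_double(),
      fn = readr::col_integer(), sensitivity_pct = readr::col_double()))
}

#' Bundled field-validation confusion counts
#'
#' Confusion counts (tp, fp, fn) from a published two-service, four-area
#' field validation of geocoding-service POIs in Bavaria, Germany: once for
#' all POIs (`table = "all"`) and once recomputed without the category
#' "doctor" (`table = "no_doctor"`). Useful as reference input for the
#' metric engine and for reproducing the corresponding validation tables.
#'
#' @param table "all" or "no_doctor".
#' @return Tibble with columns area, source, tp, fp, fn.
#' @export
#' @examples
#' counts <- field_validation_counts()
#' compute_metrics(counts$tp, counts$fp, counts$fn)
field_validation_counts <- function(table = c("all", "no_doctor")) {
  table <- match.arg(table)
  path <- system.file("extdata", "field_validation_counts.csv",
                      package = "obesopoi", mustWork = TRUE)
  all <- readr::read_csv(
    path,
    col_types = readr::cols(
      table = readr::col_character(), area = readr::col_character(),
      source = readr::col_character(), tp = readr::col_integer(),
      fp = readr::col_integer(), fn = readr::col_integer()))
  out <- all[all$table == table, , drop = FALSE]
  out$table <- NULL
  out
}
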
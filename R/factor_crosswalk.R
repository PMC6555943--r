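# Crosswalk: map source-native labels to environmental factors, one of six
# categories and an obesogenic direction.

#' Load and validate a label crosswalk
#'
#' A crosswalk maps a source-native label (a Google place type or an OSM
#' "key=value" tag) to an environmental factor, one of the six categories
#' and an obesogenic direction. OSM entries may end in a trailing asterisk
#' ("shop=*") to match any value of a key; wildcard entries are consulted
#' only after exact entries.
#'
#' @param path CSV with columns source, raw_label, factor_name, category,
#'   direction. If `NULL`, the bundled default crosswalk is loaded: the 25
#'   Google place-type labels and the 42 OSM amenity labels used in the
#'   field validation (the wider OSM variable pool can be supplied by the
#'   user as additional rows).
#' @return A validated crosswalk tibble (class `poi_crosswalk`).
#' @export
#' @examples
#' xw <- load_crosswalk()
#' table(xw$source)
load_crosswalk <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "crosswalk_default.csv",
                        package = "obesopoi", mustWork = TRUE)
  }
  xw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        na = character())
  need <- c("source", "raw_label", "factor_name", "category", "direction")
  miss <- setdiff(need, names(xw))
  if (length(miss) > 0) {
    stop_obesopoi(paste0("crosswalk is missing columns: ",
                         paste(miss, collapse = ", ")),
                  "crosswalk_validation_error")
  }
  dup <- duplicated(xw[, c("source", "raw_label")])
  if (any(dup)) {
    stop_obesopoi(
      paste0("duplicate (source, raw_label) entries: ",
             paste(unique(paste(xw$source[dup], xw$raw_label[dup])),
                   collapse = "; ")),
      "crosswalk_validation_error")
  }
  bad_cat <- !xw$category %in% poi_categories()
  if (any(bad_cat)) {
    stop_obesopoi(
      paste0("unknown category value(s): ",
             paste(unique(xw$category[bad_cat]), collapse = ", ")),
      "crosswalk_validation_error")
  }
  bad_dir <- !xw$direction %in% c("obesogenic", "protective", "unclassified")
  if (any(bad_dir)) {
    stop_obesopoi(
      paste0("unknown direction value(s): ",
             paste(unique(xw$direction[bad_dir]), collapse = ", ")),
      "crosswalk_validation_error")
  }
  if (any(!xw$source %in% c("google", "osm"))) {
    stop_obesopoi("crosswalk source must be 'google' or 'osm'",
                  "crosswalk_validation_error")
  }
  xw$row_order <- seq_len(nrow(xw))
  class(xw) <- unique(c("poi_crosswalk", class(xw)))
  xw
}

# internal: match one label against the crosswalk for a source.
# Exact entries first, then trailing-asterisk wildcards ("shop=*").
match_label <- function(label, source, xw) {
  sub <- xw[xw$source == source, , drop = FALSE]
  hit <- sub[sub$raw_label == label, , drop = FALSE]
  if (nrow(hit) > 0) return(hit[1, , drop = FALSE])
  wild <- sub[endsWith(sub$raw_label, "*"), , drop = FALSE]
  if (nrow(wild) > 0) {
    pref <- sub("\\*$", "", wild$raw_label)
    ok <- startsWith(label, pref)
    if (any(ok)) return(wild[which(ok)[1], , drop = FALSE])
  }
  NULL
}

#' Assign each POI a factor, category and direction
#'
#' Each record's raw labels are looked up in the crosswalk; among the
#' matching entries, the one whose category ranks highest in `priority`
#' wins (ties within a category broken by crosswalk row order). Records
#' with no matching label fall back to category "other" with direction
#' "unclassified"; their label sets are logged.
#'
#' @param pois A [poi_tbl()].
#' @param crosswalk A [load_crosswalk()] result; default the bundled one.
#' @param priority Permutation of [poi_categories()] ranking categories for
#'   multi-label POIs; default [default_category_priority()].
#' @return The input tibble with added columns `factor_name`, `category`
#'   (factor over the six levels) and `direction`.
#' @export
#' @examples
#' pois <- poi_tbl("n1", "osm", "Imbiss", 48.1, 11.5,
#'                 list("amenity=fast_food"), "demo")
#' categorize_pois(pois)$category
categorize_pois <- function(pois, crosswalk = load_crosswalk(),
                            priority = default_category_priority()) {
  pois <- validate_poi_tbl(pois)
  if (!setequal(priority, poi_categories()) ||
      length(priority) != length(poi_categories())) {
    stop_obesopoi("priority must be a permutation of the six categories",
                  "crosswalk_validation_error")
  }
  n <- nrow(pois)
  factor_name <- rep(NA_character_, n)
  category <- rep("other", n)
  direction <- rep("unclassified", n)
  unmatched <- character()
  for (i in seq_len(n)) {
    hits <- purrr::compact(lapply(pois$raw_labels[[i]], match_label,
                                  source = pois$source[i], xw = crosswalk))
    if (length(hits) == 0) {
      if (length(pois$raw_labels[[i]]) > 0) {
        unmatched <- c(unmatched,
                       paste(pois$raw_labels[[i]], collapse = "|"))
      }
      next
    }
    hits <- dplyr::bind_rows(hits)
    rank <- match(hits$category, priority)
    best <- hits[order(rank, hits$row_order), , drop = FALSE][1, ]
    factor_name[i] <- best$factor_name
    category[i] <- best$category
    direction[i] <- best$direction
  }
  if (length(unmatched) > 0) {
    poi_log(sprintf("%d record(s) with no crosswalk match (labels: %s)",
                    length(unmatched),
                    paste(utils::head(unique(unmatched), 5), collapse = "; ")))
  }
  out <- pois
  out$factor_name <- factor_name
  out$category <- factor(category, levels = poi_categories())
  out$direction <- direction
  out
}

#' Fill crosswalk directions from literature verdicts
#'
#' Where a crosswalk factor appears in a verdict table (see
#' [classify_evidence_table()]), its direction is set from the verdict:
#' overall positive correlation with obesity = "obesogenic", negative =
#' "protective", otherwise "unclassified". Factors absent from the verdict
#' table keep their current direction.
#'
#' @param crosswalk A [load_crosswalk()] result.
#' @param verdicts Output of [classify_evidence_table()].
#' @return The crosswalk with updated `direction`.
#' @export
apply_verdict_directions <- function(crosswalk, verdicts) {
  idx <- match(crosswalk$factor_name, verdicts$factor_name)
  has <- !is.na(idx)
  map <- c(positive = "obesogenic", negative = "protective",
           none = "unclassified", insufficient = "unclassified")
  crosswalk$direction[has] <- unname(map[as.character(verdicts$direction[idx[has]])])
  crosswalk
}
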
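# Confusion tallies from audited hits and field observations; sensitivity
# and positive predictive value per area x source, stratified by category.

#' Tally confusion counts from audited hits and field observations
#'
#' A "hit" is a POI returned by a database for a search area. Field audits
#' mark each hit confirmed (true positive) or rejected (false positive);
#' amenities discovered in the field but absent from a service's hits are
#' false negatives for that service. One walk-through audit serves every
#' service: each observation lists the sources it was missing from, so the
#' shared field-truth total (tp + fn) is identical across sources by
#' construction.
#'
#' @param hits Tibble of audited hits with columns `hit_id`, `status`
#'   ("confirmed", "rejected" or "unresolved") and `category`. Unresolved
#'   hits block tallying: uncertainties must be resolved (e.g. via online
#'   search engines) before metrics are computed.
#' @param observations Tibble of field observations with columns `category`
#'   and `missing_from` (list-column of source names, or pipe-delimited
#'   strings). An observation counts as a false negative for `source` only
#'   when `source` is in its `missing_from` set.
#' @param source Source the tally is for ("google" or "osm").
#' @return A tibble with one row per category (all six, zero-filled) and
#'   columns category, tp, fp, fn.
#' @export
tally_confusion <- function(hits, observations, source) {
  hits <- tibble::as_tibble(hits)
  observations <- tibble::as_tibble(observations)
  if (nrow(hits) > 0) {
    bad <- !hits$status %in% c("confirmed", "rejected", "unresolved")
    if (any(bad)) {
      stop_obesopoi(paste0("unknown audit status for hit(s): ",
                           paste(hits$hit_id[bad], collapse = ", ")),
                    "audit_status_error")
    }
    unres <- hits$status == "unresolved"
    if (any(unres)) {
      stop_obesopoi(
        paste0("unresolved audit status for hit(s): ",
               paste(hits$hit_id[unres], collapse = ", "),
               "; resolve before tallying"),
        "audit_unresolved_error")
    }
  }
  if (nrow(observations) > 0) {
    mf <- observations$missing_from
    if (!is.list(mf)) mf <- strsplit(as.character(mf), "|", fixed = TRUE)
    if (any(lengths(mf) == 0)) {
      stop_obesopoi("every field observation must be missing from at least one source",
                    "audit_status_error")
    }
    qual <- vapply(mf, function(s) source %in% s, logical(1))
    observations <- observations[qual, , drop = FALSE]
  }
  cats <- poi_categories()
  cat_of <- function(x) factor(as.character(x), levels = cats)
  tp <- table(cat_of(hits$category[hits$status == "confirmed"]))
  fp <- table(cat_of(hits$category[hits$status == "rejected"]))
  fn <- table(cat_of(observations$category))
  tibble::tibble(
    category = factor(cats, levels = cats),
    tp = as.integer(tp[cats]),
    fp = as.integer(fp[cats]),
    fn = as.integer(fn[cats])
  )
}

#' Sensitivity and positive predictive value from confusion counts
#'
#' Sensitivity = 100 * tp / (tp + fn), the database's completeness against
#' field truth; PPV = 100 * tp / (tp + fp), the correctness of its entries.
#' Percentages are rounded half-away-from-zero to 2 decimals. When a
#' denominator is 0 the metric is undefined and reported as `NA` (never 0
#' or 100).
#'
#' @param tp,fp,fn Non-negative counts (vectorized).
#' @return A tibble with columns `sensitivity_pct` and `ppv_pct`.
#' @export
#' @examples
#' compute_metrics(19, 11, 13)  # ppv 63.33, sensitivity 59.38
compute_metrics <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) {
    stop_obesopoi("confusion counts must be non-negative", "metrics_domain_error")
  }
  sens <- ifelse(tp + fn > 0, round_half_up(100 * tp / (tp + fn), 2), NA_real_)
  ppv <- ifelse(tp + fp > 0, round_half_up(100 * tp / (tp + fp), 2), NA_real_)
  tibble::tibble(sensitivity_pct = sens, ppv_pct = ppv)
}

#' Build a per-area, per-source metrics result
#'
#' Wraps a by-category confusion breakdown into a `metrics_result`: overall
#' counts are the category sums, overall and per-category sensitivity/PPV
#' are computed with [compute_metrics()].
#'
#' @param area_id,source Identifiers.
#' @param by_category Tibble with columns category, tp, fp, fn; missing
#'   categories are zero-filled.
#' @return An object of class `metrics_result` with fields `area_id`,
#'   `source`, `overall` (tp, fp, fn), `sensitivity_pct`, `ppv_pct` and
#'   `by_category`.
#' @export
metrics_result <- function(area_id, source, by_category) {
  by_category <- tibble::as_tibble(by_category)
  cats <- poi_categories()
  by_category$category <- factor(as.character(by_category$category),
                                 levels = cats)
  if (anyNA(by_category$category)) {
    stop_obesopoi("by_category contains a category outside the six levels",
                  "metrics_domain_error")
  }
  full <- dplyr::left_join(
    tibble::tibble(category = factor(cats, levels = cats)),
    by_category, by = "category")
  full[is.na(full)] <- 0L
  full <- dplyr::bind_cols(
    full, compute_metrics(full$tp, full$fp, full$fn))
  overall <- list(tp = sum(full$tp), fp = sum(full$fp), fn = sum(full$fn))
  m <- compute_metrics(overall$tp, overall$fp, overall$fn)
  structure(
    list(area_id = area_id, source = source, overall = overall,
         sensitivity_pct = m$sensitivity_pct, ppv_pct = m$ppv_pct,
         by_category = full),
    class = "metrics_result")
}

#' @export
print.metrics_result <- function(x, ...) {
  cat(sprintf(
    "<metrics_result> area %s, %s: tp=%d fp=%d fn=%d | PPV %s%% sens %s%%\n",
    x$area_id, x$source, x$overall$tp, x$overall$fp, x$overall$fn,
    format(x$ppv_pct), format(x$sensitivity_pct)))
  invisible(x)
}

#' Validate one area x source from audit inputs
#'
#' Convenience wrapper: [tally_confusion()] then [metrics_result()].
#'
#' @inheritParams tally_confusion
#' @param area_id Area identifier.
#' @return A `metrics_result`.
#' @export
validate_area <- function(hits, observations, area_id, source) {
  metrics_result(area_id, source,
                 tally_confusion(hits, observations, source))
}

#' Recompute metrics with one category excluded
#'
#' Reproduces the category-exclusion analysis: the excluded category's
#' stratum counts are subtracted from the overall counts, metrics are
#' recomputed, and the stratum is dropped from the breakdown. Excluding a
#' category absent from the breakdown (or with an all-zero stratum) leaves
#' the result unchanged.
#'
#' @param result A [metrics_result()].
#' @param category One of [poi_categories()].
#' @return A new `metrics_result`.
#' @export
exclude_category <- function(result, category) {
  stopifnot(inherits(result, "metrics_result"))
  bc <- result$by_category
  if (!category %in% as.character(bc$category)) {
    rlang::warn(sprintf("category '%s' absent from breakdown; no-op", category))
    return(result)
  }
  keep <- bc[as.character(bc$category) != category,
             c("category", "tp", "fp", "fn"), drop = FALSE]
  out <- metrics_result(result$area_id, result$source, keep)
  # record the exclusion; the dropped stratum no longer reports counts
  out$excluded <- unique(c(result$excluded, category))
  out$by_category <- out$by_category[
    !as.character(out$by_category$category) %in% out$excluded, , drop = FALSE]
  out
}

#' Check the shared field-truth total across sources
#'
#' For one area validated against a single field-truth universe, tp + fn
#' (true positives plus false negatives) is the number of real amenities
#' and must be equal for every source. Flags any pair of results where it
#' is not.
#'
#' @param results List of [metrics_result()] objects for one area.
#' @return A tibble report with one row per source pair and a `consistent`
#'   flag; attribute `pass` is TRUE when all pairs agree.
#' @export
cross_source_consistency_check <- function(results) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "metrics_result")))
  ids <- unique(vapply(results, `[[`, character(1), "area_id"))
  if (length(ids) != 1) {
    stop_obesopoi("results span multiple areas; check one area at a time",
                  "metrics_domain_error")
  }
  src <- vapply(results, `[[`, character(1), "source")
  tot <- vapply(results, function(r) r$overall$tp + r$overall$fn, numeric(1))
  pairs <- utils::combn(seq_along(results), 2)
  rep <- tibble::tibble(
    area_id = ids,
    source_a = src[pairs[1, ]], source_b = src[pairs[2, ]],
    total_a = tot[pairs[1, ]], total_b = tot[pairs[2, ]],
    consistent = tot[pairs[1, ]] == tot[pairs[2, ]]
  )
  if (any(!rep$consistent)) {
    poi_log(sprintf("area %s: tp+fn differs across sources (%s)",
                    ids, paste(unique(tot), collapse = " vs ")))
  }
  attr(rep, "pass") <- all(rep$consistent)
  rep
}

#' Count database hits per category
#'
#' Distribution of hits across the six categories (the bar-chart summary);
#' absent categories report 0 and counts sum to the input size.
#'
#' @param pois A categorized POI tibble (see [categorize_pois()]).
#' @return Named integer vector over [poi_categories()].
#' @export
summarize_hits_by_category <- function(pois) {
  cats <- poi_categories()
  if (nrow(pois) == 0) {
    return(stats::setNames(integer(length(cats)), cats))
  }
  tab <- table(factor(as.character(pois$category), levels = cats))
  stats::setNames(as.integer(tab[cats]), cats)
}

#' Read audit and observation CSV files
#'
#' Audit CSV columns: hit_id, area_id, source, status, audit_date, note
#' (and optionally category, when not joined from categorized POIs).
#' Observation CSV columns: name, latitude, longitude, category,
#' missing_from (pipe-delimited source names).
#'
#' @param path File path.
#' @return A tibble; `read_observations_csv` parses `missing_from` into a
#'   list-column.
#' @export
read_audit_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = "c"),
                  na = character())
}

#' @rdname read_audit_csv
#' @export
read_observations_csv <- function(path) {
  obs <- readr::read_csv(
    path, na = character(),
    col_types = readr::cols(
      name = readr::col_character(), latitude = readr::col_double(),
      longitude = readr::col_double(), category = readr::col_character(),
      missing_from = readr::col_character()))
  obs$missing_from <- strsplit(obs$missing_from, "|", fixed = TRUE)
  obs
}
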
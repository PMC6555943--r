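# Evidence-ratio rule: classify each environmental factor's overall
# correlation with obesity from per-factor study counts.

#' Classify a factor's overall correlation from study counts
#'
#' For one environmental factor, `n_positive` counts studies reporting a
#' significant positive correlation with weight status, `n_negative`
#' significant negative ones, and `n_null` studies with no significant
#' association. The rule: with fewer than three significant publications
#' (positive + negative) the evidence is "insufficient"; otherwise the
#' factor is "positive" if n_positive / n_negative >= 2, "negative" if
#' n_negative / n_positive >= 2 (division by zero counts as infinity), and
#' "none" otherwise. Null studies never enter the verdict. The worked
#' reference case: 5 positive vs 12 negative classifies negative, since
#' 12/5 >= 2.
#'
#' @param n_positive,n_negative,n_null Non-negative integer counts
#'   (vectorized).
#' @return A tibble with `direction` (factor: positive, negative, none,
#'   insufficient), `ratio_pos` = n_positive/n_negative and `ratio_neg` =
#'   n_negative/n_positive (Inf allowed).
#' @export
#' @examples
#' classify_correlation(5, 12)   # negative: 12/5 >= 2
#' classify_correlation(3, 0)    # positive with ratio_pos = Inf
classify_correlation <- function(n_positive, n_negative, n_null = 0) {
  counts <- cbind(n_positive, n_negative, n_null)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_obesopoi("study counts must be non-negative integers",
                  "evidence_domain_error")
  }
  n_pos <- unname(counts[, 1])
  n_neg <- unname(counts[, 2])
  ratio_pos <- ifelse(n_neg == 0, ifelse(n_pos == 0, NaN, Inf), n_pos / n_neg)
  ratio_neg <- ifelse(n_pos == 0, ifelse(n_neg == 0, NaN, Inf), n_neg / n_pos)
  direction <- dplyr::case_when(
    n_pos + n_neg < 3 ~ "insufficient",
    !is.nan(ratio_pos) & ratio_pos >= 2 ~ "positive",
    !is.nan(ratio_neg) & ratio_neg >= 2 ~ "negative",
    TRUE ~ "none"
  )
  tibble::tibble(
    direction = factor(direction,
                       levels = c("positive", "negative", "none",
                                  "insufficient")),
    ratio_pos = ratio_pos,
    ratio_neg = ratio_neg
  )
}

#' Classify a whole evidence table
#'
#' Row-wise application of [classify_correlation()] to a per-factor
#' evidence table.
#'
#' @param evidence A data frame (or CSV path) with columns factor_name,
#'   n_positive, n_negative, n_null.
#' @return A tibble with factor_name, the counts, direction and both
#'   ratios.
#' @export
classify_evidence_table <- function(evidence) {
  if (is.character(evidence) && length(evidence) == 1) {
    evidence <- readr::read_csv(
      evidence,
      col_types = readr::cols(
        factor_name = readr::col_character(),
        .default = readr::col_double()
      ))
  }
  need <- c("factor_name", "n_positive", "n_negative", "n_null")
  miss <- setdiff(need, names(evidence))
  if (length(miss) > 0) {
    stop_obesopoi(paste0("evidence table is missing columns: ",
                         paste(miss, collapse = ", ")),
                  "evidence_schema_error")
  }
  if (nrow(evidence) == 0) {
    return(tibble::tibble(
      factor_name = character(), n_positive = numeric(),
      n_negative = numeric(), n_null = numeric(),
      direction = factor(character(),
                         levels = c("positive", "negative", "none",
                                    "insufficient")),
      ratio_pos = numeric(), ratio_neg = numeric()
    ))
  }
  verdict <- classify_correlation(evidence$n_positive, evidence$n_negative,
                                  evidence$n_null)
  dplyr::bind_cols(tibble::as_tibble(evidence)[, need], verdict)
}
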
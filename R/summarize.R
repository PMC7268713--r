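#' Summarize sample demographics as counts and integer percentages
#'
#' For each metadata column, tabulates category counts and the percentage
#' of the full sample, rounded to the nearest integer with halves rounded
#' away from zero (the convention used in the study's demographic table).
#' The denominator is the total number of participants, including those
#' with a missing value in the column, so percentages within a block with
#' missingness sum to slightly under 100.
#'
#' @param meta Data frame of participant metadata; a `participant_id`
#'   column, if present, is ignored.
#' @param levels Optional named list mapping column names to their allowed
#'   category values; observed values outside the set are collected into
#'   `"Other"`. By default all observed values are kept as-is.
#' @param total Denominator for percentages; defaults to `nrow(meta)`.
#' @return A tibble with columns `variable`, `category`, `n`, `pct`.
#' @examples
#' summarize_sample(study_meta())
#' @export
summarize_sample <- function(meta, levels = NULL, total = nrow(meta)) {
  meta <- tibble::as_tibble(meta)
  if (nrow(meta) == 0) stop("metadata is empty.", call. = FALSE)
  vars <- setdiff(names(meta), "participant_id")
  purrr::map_dfr(vars, function(v) {
    x <- as.character(meta[[v]])
    if (!is.null(levels[[v]])) {
      x[!is.na(x) & !(x %in% levels[[v]])] <- "Other"
    }
    x <- x[!is.na(x)]
    tab <- table(x)
    tibble::tibble(
      variable = v,
      category = names(tab),
      n = as.integer(tab),
      pct = round_half_away(100 * as.integer(tab) / total)
    )
  })
}

# round to nearest integer, halves away from zero (0.5 -> 1, -0.5 -> -1)
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}
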
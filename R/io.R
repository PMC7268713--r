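#' Write a solution to a directory of plain-text files
#'
#' Produces `loadings.csv` (participants x factors with flag columns),
#' `arrays.csv` (statements x factors, the factor-array table layout),
#' `eigen.csv` (eigenvalue, percentage of variance, cumulative) and
#' `solution.json` (configuration echo, retention decisions, warnings).
#' Factor arrays are integers, so re-reading `arrays.csv` reproduces them
#' exactly.
#'
#' @param solution A `q_solution`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_solution <- function(solution, out_dir) {
  stopifnot(inherits(solution, "q_solution"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)

  L <- solution$rotation$loadings
  loadings <- tibble::tibble(participant_id = rownames(L))
  for (j in colnames(L)) loadings[[j]] <- unname(L[, j])
  loadings <- dplyr::left_join(
    loadings,
    dplyr::select(solution$flags, "participant_id",
                  flagged_factor = "factor", "sign", "status"),
    by = "participant_id"
  )
  readr::write_csv(loadings, fp("loadings.csv"), progress = FALSE)
  readr::write_csv(solution$arrays, fp("arrays.csv"), progress = FALSE)
  readr::write_csv(
    scree_table(solution$extraction$values, solution$n_sorts),
    fp("eigen.csv"), progress = FALSE
  )
  jsonlite::write_json(
    list(
      config = solution$config,
      k = solution$k,
      n_sorts = solution$n_sorts,
      n_statements = solution$n_statements,
      n_exemplars = as.list(solution$scores$n_exemplars),
      retention = solution$retention_rationale,
      warnings = solution$warnings
    ),
    fp("solution.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}

#' Read a factor-array CSV back in
#'
#' Inverse of the `arrays.csv` written by [write_solution()]; also reads
#' the packaged factor-array fixture layout.
#'
#' @param path CSV with `statement_id` plus integer factor columns.
#' @return A tibble of integer ranks.
#' @export
read_factor_arrays <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_integer()),
                  progress = FALSE)
}
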
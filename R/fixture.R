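#' The packaged health-perception Q-study instrument and results
#'
#' Loads the study materials shipped with the package: the 42-statement
#' Q-sample on aspects of health, the 11-rank forced grid, the five
#' published factor arrays (one ideal sort per viewpoint), the published
#' sample demographics, and the per-factor exemplar demographics. These are
#' read from plain-text files under `inst/extdata/` and re-validated on
#' every load.
#'
#' The raw 110 individual Q-sorts of the study are not publicly deposited;
#' the factor arrays and count tables are the machine-readable record of
#' the results and serve as ground-truth fixtures for this package's tests.
#'
#' @return A list of class `q_study` with elements:
#' \describe{
#'   \item{statements}{tibble `statement_id`, `text` (42 rows).}
#'   \item{grid}{the [study_grid()].}
#'   \item{factor_arrays}{tibble `statement_id`, `F1`..`F5` of integer ranks.}
#'   \item{table1}{tibble `block`, `category`, `count` — whole-sample
#'     demographics (n = 110; the EQ-5D, VAS and education blocks sum to 109
#'     as printed in the source table, reflecting missing responses).}
#'   \item{table3}{tibble `block`, `category`, `F1`..`F5` — exemplar
#'     demographics per factor (block `mean_age` holds means, not counts).}
#'   \item{exemplar_n}{integer vector: exemplars per factor (19, 25, 16, 6, 4).}
#'   \item{n_participants}{110.}
#'   \item{condition_of_instruction}{the sorting prompt shown to participants.}
#' }
#' @examples
#' fx <- q_study()
#' fx$factor_arrays[fx$factor_arrays$statement_id == 25, "F1"]  # +5
#' @export
q_study <- function() {
  path <- function(f) system.file("extdata", f, package = "qsortr", mustWork = TRUE)
  ct <- readr::cols(.default = readr::col_integer())
  statements <- readr::read_csv(
    path("statements.csv"),
    col_types = readr::cols(statement_id = readr::col_integer(),
                            text = readr::col_character()),
    progress = FALSE
  )
  arrays <- readr::read_csv(path("factor_arrays.csv"), col_types = ct,
                            progress = FALSE)
  table1 <- readr::read_csv(
    path("table1_counts.csv"),
    col_types = readr::cols(block = readr::col_character(),
                            category = readr::col_character(),
                            count = readr::col_integer()),
    progress = FALSE
  )
  table3 <- readr::read_csv(
    path("table3_counts.csv"),
    col_types = readr::cols(block = readr::col_character(),
                            category = readr::col_character(),
                            .default = readr::col_integer()),
    progress = FALSE
  )
  grid <- read_grid_json(path("grid.json"))

  stopifnot(
    nrow(statements) == 42L,
    identical(statements$statement_id, 1:42),
    all(nzchar(statements$text)),
    grid$n_statements == 42L
  )
  # every published array column must itself be a valid sort on the grid
  rep <- validate_panel(as_q_panel(arrays, grid = grid, validate = FALSE))
  stopifnot(attr(rep, "ok"))

  structure(
    list(
      statements = statements,
      grid = grid,
      factor_arrays = arrays,
      table1 = table1,
      table3 = table3,
      exemplar_n = stats::setNames(c(19L, 25L, 16L, 6L, 4L), paste0("F", 1:5)),
      n_participants = 110L,
      condition_of_instruction = paste(
        "When judging a person's health,",
        "how important is it to know about their ___?"
      )
    ),
    class = "q_study"
  )
}

#' @export
print.q_study <- function(x, ...) {
  cat("<q_study> ", nrow(x$statements), " statements, ",
      ncol(x$factor_arrays) - 1L, " factor arrays, n = ",
      x$n_participants, " participants\n", sep = "")
  cat("Condition of instruction: ", x$condition_of_instruction, "\n", sep = "")
  invisible(x)
}

#' Synthetic per-participant metadata matching the published marginals
#'
#' The study does not deposit a per-participant table, only marginal counts
#' per demographic block. This helper expands each block independently into
#' a column of length 110, so every marginal distribution matches the
#' published one exactly while the joint structure across columns is
#' arbitrary (participants are not real). Blocks that sum to 109 get one
#' `NA` (missing response). Intended for exercising [summarize_sample()]
#' and report crosstabs, not for inference about real participants.
#'
#' @return A 110-row tibble with columns `participant_id`, `gender`, `age`,
#'   `education`, `eq5d_profile`, `vas_band`, `residence`, `region`.
#' @export
study_meta <- function() {
  fx <- q_study()
  n <- fx$n_participants
  expand_block <- function(block) {
    b <- dplyr::filter(fx$table1, .data$block == !!block)
    v <- rep(b$category, times = b$count)
    c(v, rep(NA_character_, n - length(v)))
  }
  tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    gender = expand_block("gender"),
    age = expand_block("age"),
    education = expand_block("education"),
    eq5d_profile = expand_block("eq5d_profile"),
    vas_band = expand_block("vas_band"),
    residence = expand_block("residence"),
    region = expand_block("region")
  )
}
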
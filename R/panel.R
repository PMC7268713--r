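#' Build a Q-sort panel from a data frame
#'
#' A panel is a wide tibble with a `statement_id` column followed by one
#' integer column of ranks per participant, carrying the grid it must obey
#' as an attribute. This is the raw input to every analysis function.
#'
#' @param df Data frame: `statement_id` plus one column per participant.
#' @param grid A [q_grid()]; when `NULL` it is derived from the first
#'   participant column via [derive_grid()].
#' @param validate If `TRUE` (default), stop when [validate_panel()] reports
#'   violations.
#' @return A tibble of class `q_panel` with attribute `grid`.
#' @export
as_q_panel <- function(df, grid = NULL, validate = TRUE) {
  df <- tibble::as_tibble(df)
  if (!"statement_id" %in% names(df)) {
    stop("panel needs a `statement_id` column.", call. = FALSE)
  }
  df <- dplyr::relocate(df, "statement_id")
  if (ncol(df) < 2) stop("panel has no participant columns.", call. = FALSE)
  df$statement_id <- as.integer(df$statement_id)
  for (p in names(df)[-1]) df[[p]] <- as.integer(df[[p]])
  if (is.null(grid)) grid <- derive_grid(df[[2]])
  panel <- structure(df, grid = grid, class = c("q_panel", class(df)))
  if (validate) {
    rep <- validate_panel(panel)
    if (!attr(rep, "ok")) {
      stop("panel violates its grid; see validate_panel() (",
           nrow(rep), " violation(s), first: ",
           format_violation(rep[1, ]), ")", call. = FALSE)
    }
  }
  panel
}

#' @export
print.q_panel <- function(x, ...) {
  g <- attr(x, "grid")
  cat("<q_panel> ", nrow(x), " statements x ", ncol(x) - 1L,
      " participants, ranks ", min(g$ranks), "..", max(g$ranks), "\n", sep = "")
  NextMethod()
}

#' Grid attached to a panel
#' @param panel A `q_panel`.
#' @return The panel's [q_grid()].
#' @export
panel_grid <- function(panel) {
  g <- attr(panel, "grid")
  if (is.null(g)) stop("panel carries no grid attribute.", call. = FALSE)
  g
}

# statements x participants integer matrix, dimnames set
sort_matrix <- function(panel) {
  m <- as.matrix(panel[, -1, drop = FALSE])
  rownames(m) <- panel$statement_id
  storage.mode(m) <- "integer"
  m
}

#' Read Q-sorts from CSV
#'
#' Wide layout: first column `statement_id`, one column per participant.
#' Long layout: columns `participant_id`, `statement_id`, `rank`.
#' Typographic minus signs (Unicode U+2212) and stray spaces are normalized
#' before integer conversion, since published tables often use them.
#'
#' @param path CSV file (UTF-8, comma-separated, header row).
#' @param layout `"wide"` or `"long"`.
#' @param grid Optional [q_grid()]; derived from the data when `NULL`.
#' @param validate Passed to [as_q_panel()].
#' @return A `q_panel`.
#' @export
read_qsorts <- function(path, layout = c("wide", "long"), grid = NULL,
                        validate = TRUE) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (layout == "wide") {
    if (!"statement_id" %in% names(raw)) names(raw)[1] <- "statement_id"
    for (j in seq_along(raw)) raw[[j]] <- parse_rank_column(raw[[j]], names(raw)[j])
    panel <- raw
  } else {
    need <- c("participant_id", "statement_id", "rank")
    if (!all(need %in% names(raw))) {
      stop("long layout needs columns participant_id, statement_id, rank.",
           call. = FALSE)
    }
    raw$statement_id <- parse_rank_column(raw$statement_id, "statement_id")
    raw$rank <- parse_rank_column(raw$rank, "rank")
    dup <- duplicated(raw[, c("participant_id", "statement_id")])
    if (any(dup)) {
      i <- which(dup)[1]
      stop("duplicate (participant, statement) pair at data row ", i, ": (",
           raw$participant_id[i], ", ", raw$statement_id[i], ")", call. = FALSE)
    }
    panel <- tidyr::pivot_wider(raw, names_from = "participant_id",
                                values_from = "rank")
    panel <- dplyr::arrange(panel, .data$statement_id)
    if (anyNA(panel)) {
      miss <- which(is.na(as.matrix(panel[, -1])), arr.ind = TRUE)[1, ]
      stop("missing rank for statement ", panel$statement_id[miss[1]],
           ", participant ", names(panel)[-1][miss[2]], call. = FALSE)
    }
  }
  as_q_panel(panel, grid = grid, validate = validate)
}

parse_rank_column <- function(x, col) {
  x <- gsub("−", "-", trimws(x))
  bad <- !grepl("^-?[0-9]+$", x)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("non-integer value ", dQuote(x[i]), " in column ", dQuote(col),
         ", data row ", i, call. = FALSE)
  }
  as.integer(x)
}

#' Write a panel to wide CSV
#' @param panel A `q_panel`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_qsorts <- function(panel, path) {
  readr::write_csv(tibble::as_tibble(panel), path, progress = FALSE)
  invisible(path)
}

#' Validate a panel against its grid
#'
#' Checks, per participant, that every statement id appears exactly once
#' with a non-missing integer rank and that the frequency of each rank
#' matches the grid capacity. Violations are returned as data rather than
#' raised as errors.
#'
#' @param panel A `q_panel` (or plain data frame with `statement_id`).
#' @param grid Optional [q_grid()] override.
#' @return A tibble of class `q_validation` with columns `participant_id`,
#'   `kind` (`"capacity"`, `"missing_statement"`, `"duplicate_statement"`,
#'   `"missing_rank"`, `"out_of_range"`), `statement_id`, `rank`,
#'   `expected`, `observed`, and attribute `ok` (TRUE iff no rows).
#' @export
validate_panel <- function(panel, grid = NULL) {
  if (is.null(grid)) grid <- attr(panel, "grid")
  if (is.null(grid)) stop("no grid supplied or attached.", call. = FALSE)
  df <- tibble::as_tibble(panel)
  sids <- df$statement_id
  out <- list()
  add <- function(pid, kind, statement_id = NA_integer_, rank = NA_integer_,
                  expected = NA_integer_, observed = NA_integer_) {
    out[[length(out) + 1]] <<- tibble::tibble(
      participant_id = pid, kind = kind,
      statement_id = as.integer(statement_id), rank = as.integer(rank),
      expected = as.integer(expected), observed = as.integer(observed)
    )
  }
  dup <- sids[duplicated(sids)]
  for (pid in names(df)[-1]) {
    r <- df[[pid]]
    for (s in unique(dup)) add(pid, "duplicate_statement", statement_id = s)
    if (anyNA(r)) {
      for (s in sids[is.na(r)]) add(pid, "missing_rank", statement_id = s)
    }
    expected_ids <- seq_len(grid$n_statements)
    for (s in setdiff(expected_ids, sids)) add(pid, "missing_statement", statement_id = s)
    rr <- r[!is.na(r)]
    oor <- setdiff(unique(rr), grid$ranks)
    for (v in oor) add(pid, "out_of_range", rank = v, observed = sum(rr == v))
    obs <- table(factor(rr[rr %in% grid$ranks], levels = grid$ranks))
    for (k in seq_along(grid$ranks)) {
      if (as.integer(obs[k]) != grid$capacity[k]) {
        add(pid, "capacity", rank = grid$ranks[k],
            expected = grid$capacity[k], observed = as.integer(obs[k]))
      }
    }
  }
  rep <- if (length(out)) dplyr::bind_rows(out) else tibble::tibble(
    participant_id = character(), kind = character(),
    statement_id = integer(), rank = integer(),
    expected = integer(), observed = integer()
  )
  structure(rep, ok = nrow(rep) == 0L,
            class = c("q_validation", class(rep)))
}

#' @export
print.q_validation <- function(x, ...) {
  if (attr(x, "ok")) {
    cat("<q_validation> ok: all sorts conform to the grid\n")
  } else {
    cat("<q_validation> ", nrow(x), " violation(s)\n", sep = "")
    NextMethod()
  }
  invisible(x)
}

#' Is a validation report (or panel) clean?
#' @param x A `q_validation` report or a `q_panel`.
#' @return Logical scalar.
#' @export
is_valid <- function(x) {
  if (inherits(x, "q_validation")) return(isTRUE(attr(x, "ok")))
  isTRUE(attr(validate_panel(x), "ok"))
}

format_violation <- function(v) {
  paste0(v$participant_id, ": ", v$kind,
         if (!is.na(v$rank)) paste0(" at rank ", v$rank) else "",
         if (!is.na(v$statement_id)) paste0(" statement ", v$statement_id) else "",
         if (!is.na(v$expected)) paste0(" (expected ", v$expected,
                                        ", observed ", v$observed, ")") else "")
}
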
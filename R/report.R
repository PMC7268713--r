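#' Render a human-readable Markdown report of a solution
#'
#' Writes `report.md` with the scree/eigenvalue table, the rotated
#' loadings with exemplar flags, the factor arrays laid out like the
#' published results table (statement text plus one column per factor),
#' the distinguishing/consensus classification, and — when participant
#' metadata is supplied — a per-factor demographics crosstab of the
#' flagged exemplars.
#'
#' @param solution A `q_solution`.
#' @param path Output file (e.g. `file.path(dir, "report.md")`).
#' @param statements Optional tibble `statement_id`, `text` for labels.
#' @param meta Optional participant metadata (keyed by `participant_id`).
#' @param title Report title; when the packaged instrument's statements
#'   are used, the study's condition of instruction makes a self-
#'   describing header.
#' @return `path`, invisibly.
#' @export
write_report <- function(solution, path, statements = NULL, meta = NULL,
                         title = "Q-methodology analysis report") {
  lines <- c(paste("#", title), "")
  g <- glance(solution)
  lines <- c(lines, sprintf(
    "%d sorts on %d statements; %d factor(s) retained explaining %.1f%% of study variance; flagging threshold %.4f (|loading| at p < %s, reported rounded as %.1f).",
    g$n_sorts, g$n_statements, g$k, g$pct_variance_explained,
    solution$threshold, format(solution$config$alpha),
    solution$config$threshold_rounded), "")
  if (length(solution$warnings)) {
    lines <- c(lines, paste("**Warning:**", solution$warnings), "")
  }

  lines <- c(lines, "## Eigenvalues and scree table", "",
             md_table(head_scree(solution)), "")

  lines <- c(lines, "## Rotated loadings and flags", "",
             md_table(loading_table(solution)), "")

  lines <- c(lines, "## Factor arrays", "", md_table(array_table(solution, statements)), "")

  if (!is.null(solution$distinguishing)) {
    dd <- dplyr::filter(solution$distinguishing, .data$distinguishes_05)
    cons <- unique(solution$distinguishing$statement_id[
      solution$distinguishing$consensus])
    lines <- c(lines, "## Distinguishing and consensus statements", "",
               sprintf("Consensus statements (distinguish no factor at 0.05): %s",
                       if (length(cons)) paste(cons, collapse = ", ") else "none"),
               "")
    if (nrow(dd)) {
      dd$z <- round(dd$z, 3)
      lines <- c(lines, md_table(
        dplyr::select(dd, "statement_id", "factor", "z", "distinguishes_01")), "")
    }
  }

  if (!is.null(meta)) {
    lines <- c(lines, "## Exemplar demographics by factor", "",
               md_table(exemplar_crosstab(solution, meta)), "")
  }
  writeLines(lines, path)
  invisible(path)
}

head_scree <- function(solution) {
  st <- scree_table(solution$extraction$values, solution$n_sorts)
  st <- utils::head(st, max(solution$extraction$m, solution$k))
  st$eigenvalue <- round(st$eigenvalue, 3)
  st$pct_variance <- round(st$pct_variance, 1)
  st$cumulative_pct <- round(st$cumulative_pct, 1)
  st
}

loading_table <- function(solution) {
  L <- solution$rotation$loadings
  out <- tibble::tibble(participant_id = rownames(L))
  for (j in colnames(L)) out[[j]] <- round(unname(L[, j]), 3)
  fl <- solution$flags
  out$flag <- ifelse(
    fl$status == "flagged",
    paste0("F", fl$factor, ifelse(fl$sign < 0, " (-)", "")),
    fl$status
  )
  out
}

array_table <- function(solution, statements = NULL) {
  arr <- solution$arrays
  if (!is.null(statements)) {
    arr <- dplyr::left_join(statements, arr, by = "statement_id")
  }
  arr
}

# crosstab of flagged exemplars' metadata per factor, one row per
# (variable, category), one column per factor
exemplar_crosstab <- function(solution, meta) {
  fl <- dplyr::filter(solution$flags, .data$status == "flagged")
  mm <- dplyr::inner_join(fl, tibble::as_tibble(meta), by = "participant_id")
  vars <- setdiff(names(meta), "participant_id")
  long <- tidyr::pivot_longer(
    dplyr::select(mm, "factor", dplyr::all_of(vars)),
    -"factor", names_to = "variable", values_to = "category",
    values_transform = as.character
  )
  counts <- dplyr::count(dplyr::filter(long, !is.na(.data$category)),
                         .data$variable, .data$category, .data$factor)
  wide <- tidyr::pivot_wider(counts, names_from = "factor",
                             values_from = "n", values_fill = 0L,
                             names_prefix = "F", names_sort = TRUE)
  dplyr::arrange(wide, .data$variable, .data$category)
}

md_table <- function(df) {
  df <- tibble::as_tibble(df)
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
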
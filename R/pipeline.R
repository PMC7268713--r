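#' Run the full Q-methodology pipeline
#'
#' Executes, in order: inter-sort correlation, principal-component
#' extraction, rule-based retention (or a fixed k), Varimax rotation,
#' exemplar flagging, weighted factor z-score estimation, quantization of
#' scores into grid-conforming factor arrays and, for k >= 2,
#' distinguishing/consensus statement classification. Every intermediate
#' decision and the full configuration are recorded on the returned
#' solution.
#'
#' @param panel A `q_panel`.
#' @param method Correlation method, `"pearson"` (default) or `"spearman"`.
#' @param n_extract Components to extract before retention; default
#'   `min(8, P - 1)`.
#' @param k `"auto"` (rule-based retention, default) or a fixed integer.
#' @param alpha Significance level for the loading threshold (0.01 or 0.05).
#' @param bipolar Handling of negative exemplars in scoring
#'   (`"exclude"`/`"include"`, see [factor_zscores()]).
#' @param kaiser Kaiser normalization in rotation (default TRUE).
#' @param flag_rule `"pure"` (default) or `"pqmethod"`.
#' @param min_exemplars Minimum pure loaders per retained factor.
#' @return An object of class `q_solution`; see [tidy.q_solution()],
#'   [glance.q_solution()], [write_solution()].
#' @examples
#' sim <- simulate_qsorts(K = 3, n_per_factor = 6, noise_sd = 0,
#'                        confounded_frac = 0, negative_frac = 0, seed = 7)
#' sol <- q_analyze(sim$panel)
#' glance(sol)
#' @export
q_analyze <- function(panel, method = c("pearson", "spearman"),
                      n_extract = NULL, k = "auto", alpha = 0.01,
                      bipolar = c("exclude", "include"), kaiser = TRUE,
                      flag_rule = c("pure", "pqmethod"),
                      min_exemplars = 2L) {
  method <- match.arg(method)
  bipolar <- match.arg(bipolar)
  flag_rule <- match.arg(flag_rule)
  grid <- panel_grid(panel)
  S <- grid$n_statements
  threshold <- loading_threshold(S, alpha)

  corr <- with_stage("correlate", q_correlate(panel, method = method))
  extraction <- with_stage("extract", q_extract(corr, m = n_extract))

  if (identical(k, "auto")) {
    retention <- with_stage("retain", retain_factors(
      extraction, threshold, min_exemplars = min_exemplars,
      kaiser = kaiser, flag_rule = flag_rule
    ))
    k_used <- retention$k
    rotation <- retention$rotation
    flags <- retention$flags
    rationale <- retention$rationale
  } else {
    k_used <- as.integer(k)
    if (is.na(k_used) || k_used < 1 || k_used > extraction$m) {
      stop("fixed k must be an integer in 1..", extraction$m, call. = FALSE)
    }
    rotation <- with_stage("rotate", q_varimax(
      extraction$loadings[, seq_len(k_used), drop = FALSE], kaiser = kaiser
    ))
    flags <- with_stage("flag", flag_exemplars(rotation, threshold,
                                               rule = flag_rule))
    rationale <- tibble::tibble(
      k_tried = k_used, factor = seq_len(k_used),
      eigenvalue = extraction$values[seq_len(k_used)],
      n_pure = vapply(seq_len(k_used), function(j) {
        sum(flags$status == "flagged" & flags$factor == j, na.rm = TRUE)
      }, 1L),
      ok = TRUE, reason = "fixed by user"
    )
    missing_ex <- rationale$factor[rationale$n_pure < 1]
    if (length(missing_ex)) {
      stop("fixed k = ", k_used, " but factor(s) ",
           paste(missing_ex, collapse = ", "),
           " have no flagged exemplar.", call. = FALSE)
    }
  }

  scores <- with_stage("score", factor_zscores(panel, flags, bipolar = bipolar))
  arrays <- with_stage("quantize", quantize_to_array(scores, grid))
  distinguishing <- if (k_used >= 2) {
    with_stage("distinguish", distinguish_statements(scores))
  } else NULL

  warnings <- character(0)
  if (!rotation$converged) {
    warnings <- c(warnings, sprintf(
      "varimax did not converge within %d sweeps", rotation$iterations))
  }

  structure(
    list(
      grid = grid,
      n_statements = S,
      n_sorts = extraction$n_sorts,
      participant_ids = colnames(corr),
      corr = corr,
      extraction = extraction,
      k = k_used,
      rotation = rotation,
      flags = flags,
      retention_rationale = rationale,
      scores = scores,
      arrays = arrays,
      distinguishing = distinguishing,
      threshold = threshold,
      warnings = warnings,
      config = list(
        method = method, n_extract = extraction$m, k = k,
        alpha = alpha, threshold = threshold,
        threshold_rounded = round(threshold, 1),
        bipolar = bipolar, kaiser = kaiser, flag_rule = flag_rule,
        min_exemplars = min_exemplars
      )
    ),
    class = "q_solution"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("in stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' @export
print.q_solution <- function(x, ...) {
  cat("<q_solution> ", x$k, " factor(s) from ", x$n_sorts, " sorts on ",
      x$n_statements, " statements\n", sep = "")
  st <- scree_table(x$extraction$values[seq_len(x$k)], x$n_sorts)
  cat("Variance explained: ",
      paste(sprintf("%s %.1f%%", paste0("F", st$factor), st$pct_variance),
            collapse = ", "),
      " (cumulative ", sprintf("%.1f%%", max(st$cumulative_pct)), ")\n", sep = "")
  cat("Flagged exemplars: ",
      paste(names(x$scores$n_exemplars), x$scores$n_exemplars,
            sep = "=", collapse = ", "), "\n", sep = "")
  if (length(x$warnings)) cat("Warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Tidy a Q solution into a long loading table
#'
#' One row per participant x factor with the rotated loading, plus the
#' participant's flag status.
#'
#' @param x A `q_solution`.
#' @param ... Unused.
#' @return A tibble: `participant_id`, `factor`, `loading`, `flagged`,
#'   `status`, `sign`.
#' @export
tidy.q_solution <- function(x, ...) {
  L <- x$rotation$loadings
  out <- tibble::as_tibble(L)
  out$participant_id <- rownames(L) %||% x$participant_ids
  out <- tidyr::pivot_longer(out, -"participant_id", names_to = "factor",
                             values_to = "loading")
  fl <- dplyr::select(x$flags, "participant_id",
                      flag_factor = "factor", "status", "sign")
  out <- dplyr::left_join(out, fl, by = "participant_id")
  out$flagged <- out$status == "flagged" &
    out$factor == paste0("F", out$flag_factor)
  dplyr::select(out, "participant_id", "factor", "loading", "flagged",
                "status", "sign")
}

#' One-row summary of a Q solution
#'
#' @param x A `q_solution`.
#' @param ... Unused.
#' @return A tibble with `n_sorts`, `n_statements`, `k`,
#'   `pct_variance_explained` (cumulative over retained factors),
#'   `n_flagged`, `n_confounded`, `n_nonsignificant`, `threshold`.
#' @export
glance.q_solution <- function(x, ...) {
  tibble::tibble(
    n_sorts = x$n_sorts,
    n_statements = x$n_statements,
    k = x$k,
    pct_variance_explained = sum(x$extraction$pct_variance[seq_len(x$k)]),
    n_flagged = sum(x$flags$status == "flagged"),
    n_confounded = sum(x$flags$status == "confounded"),
    n_nonsignificant = sum(x$flags$status == "nonsignificant"),
    threshold = x$threshold
  )
}
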
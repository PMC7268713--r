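#' Rule-based factor retention
#'
#' Applies the two published retention rules jointly: a retained factor
#' must have an eigenvalue greater than 1.00 **and**, after Varimax
#' rotation of the leading candidates, at least `min_exemplars` (default
#' two) pure significant loaders. The procedure starts from the number of
#' eigenvalue-passing components (capped at the extraction size and
#' `max_k`) and steps k down, re-rotating each time, until every one of
#' the k leading factors carries enough exemplars. The scree table is
#' advisory only and never drives the decision.
#'
#' @param extraction A `q_extraction`.
#' @param threshold Loading significance threshold ([loading_threshold()]).
#' @param max_k Upper bound on retained factors; defaults to the
#'   extraction size.
#' @param min_exemplars Minimum pure loaders per factor (default 2).
#' @param kaiser,flag_rule Passed to [q_varimax()] and [flag_exemplars()].
#' @return A list of class `q_retention`: `k` (chosen), `rotation` (the
#'   `q_rotation` at k), `flags` (the `q_flags` at k), and `rationale`, a
#'   tibble recording for every candidate k tried which rule bound which
#'   factor.
#' @export
retain_factors <- function(extraction, threshold, max_k = NULL,
                           min_exemplars = 2L, kaiser = TRUE,
                           flag_rule = "pure") {
  stopifnot(inherits(extraction, "q_extraction"))
  ev <- extraction$values
  n_pass <- sum(ev > 1.00)
  k0 <- min(n_pass, extraction$m, max_k %||% extraction$m)
  rationale <- list()
  note <- function(k_tried, factor, eigenvalue, n_pure, ok, reason) {
    rationale[[length(rationale) + 1]] <<- tibble::tibble(
      k_tried = k_tried, factor = factor, eigenvalue = eigenvalue,
      n_pure = n_pure, ok = ok, reason = reason
    )
  }
  if (n_pass > k0) {
    for (j in seq(k0 + 1, n_pass)) {
      note(k0, j, ev[j], NA_integer_, FALSE, "beyond extraction/max_k cap")
    }
  }
  if (n_pass < length(ev)) {
    # record only the first failing eigenvalue; the rest follow by ordering
    j <- n_pass + 1L
    note(k0, j, ev[j], NA_integer_, FALSE, "eigenvalue <= 1.00")
  }
  if (k0 < 1) {
    stop("no factor passes the eigenvalue rule; inspect the scree table.",
         call. = FALSE)
  }
  for (k in seq(k0, 1)) {
    rot <- q_varimax(extraction$loadings[, seq_len(k), drop = FALSE],
                     kaiser = kaiser)
    flags <- flag_exemplars(rot, threshold, rule = flag_rule)
    flagged <- dplyr::filter(flags, .data$status == "flagged")
    n_pure <- vapply(seq_len(k), function(j) sum(flagged$factor == j), 1L)
    ok <- n_pure >= min_exemplars
    for (j in seq_len(k)) {
      note(k, j, ev[j], n_pure[j], ok[j],
           if (ok[j]) "retained" else
             sprintf("only %d pure loader(s), need %d", n_pure[j], min_exemplars))
    }
    if (all(ok)) {
      return(structure(
        list(k = k, rotation = rot, flags = flags,
             rationale = dplyr::bind_rows(rationale)),
        class = "q_retention"
      ))
    }
  }
  stop("no candidate k satisfies both retention rules ",
       "(eigenvalue > 1 and >= ", min_exemplars, " pure loaders); ",
       "inspect loadings or fix k manually.", call. = FALSE)
}

#' @export
print.q_retention <- function(x, ...) {
  cat("<q_retention> k = ", x$k, "\n", sep = "")
  print(x$rationale)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
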
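#' Weighted factor z-scores per statement
#'
#' For each retained factor, the flagged exemplar sorts are merged into a
#' single score per statement: each exemplar contributes its ranks weighted
#' by `w = f / (1 - f^2)` (see [factor_weights()]), and the weighted sums
#' are standardized across statements to mean 0 and sd 1.
#'
#' Negative exemplars (sign -1) are excluded by default: the published
#' analysis this package follows interprets its single negative loader
#' narratively rather than folding the mirrored sort into the factor
#' estimate. With `bipolar = "include"` a negative exemplar's ranks are
#' negated (its mirror image on a symmetric grid) and included with the
#' magnitude of its weight.
#'
#' @param panel A `q_panel`.
#' @param flags A `q_flags` tibble from [flag_exemplars()].
#' @param bipolar `"exclude"` (default) or `"include"`.
#' @return An object of class `q_scores`: list with `z` (tibble
#'   `statement_id` + one column per factor, each mean 0 / sd 1),
#'   `n_exemplars` (integer per factor, included exemplars),
#'   `weights` (list of per-exemplar weight tibbles), `bipolar`.
#' @export
factor_zscores <- function(panel, flags, bipolar = c("exclude", "include")) {
  bipolar <- match.arg(bipolar)
  m <- sort_matrix(panel)
  flagged <- dplyr::filter(flags, .data$status == "flagged")
  if (nrow(flagged) == 0) stop("no flagged exemplars.", call. = FALSE)
  factors <- sort(unique(flagged$factor))
  zcols <- list()
  n_ex <- integer(0)
  wts <- list()
  for (f in factors) {
    ex <- dplyr::filter(flagged, .data$factor == !!f)
    if (bipolar == "exclude") ex <- dplyr::filter(ex, .data$sign > 0)
    if (nrow(ex) == 0) {
      stop("factor ", f, " has no included exemplars (all negative and ",
           "bipolar = \"exclude\").", call. = FALSE)
    }
    w <- factor_weights(ex$loading)
    # under "include", a mirror sort enters as its rank-negation with
    # positive weight; negating the weight is the same linear operation
    if (bipolar == "include") w <- abs(w) * ex$sign
    ranks <- m[, ex$participant_id, drop = FALSE]
    raw <- as.numeric(ranks %*% w)
    z <- (raw - mean(raw)) / stats::sd(raw)
    zcols[[paste0("F", f)]] <- z
    n_ex[paste0("F", f)] <- nrow(ex)
    wts[[paste0("F", f)]] <- tibble::tibble(
      participant_id = ex$participant_id, loading = ex$loading,
      sign = ex$sign, weight = w
    )
  }
  z <- tibble::tibble(statement_id = as.integer(rownames(m)), !!!zcols)
  structure(
    list(z = z, n_exemplars = n_ex, weights = wts, bipolar = bipolar),
    class = "q_scores"
  )
}

#' @export
print.q_scores <- function(x, ...) {
  cat("<q_scores> ", ncol(x$z) - 1L, " factor(s), exemplars: ",
      paste(names(x$n_exemplars), x$n_exemplars, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Quantize factor z-scores onto the grid
#'
#' Converts each factor's continuous z-scores back into an "ideal" Q-sort
#' (the factor array) by ranking statements by z, descending, and filling
#' grid slots from the highest rank down, respecting capacities. Ties in z
#' are broken by ascending statement id (the lower id takes the higher
#' rank) so quantization is deterministic.
#'
#' @param scores A `q_scores`, or a tibble `statement_id` + z columns.
#' @param grid A [q_grid()].
#' @return A tibble `statement_id` + one integer rank column per factor;
#'   every column conforms to `grid`.
#' @export
quantize_to_array <- function(scores, grid) {
  z <- if (inherits(scores, "q_scores")) scores$z else tibble::as_tibble(scores)
  out <- tibble::tibble(statement_id = as.integer(z$statement_id))
  for (col in setdiff(names(z), "statement_id")) {
    out[[col]] <- quantize_ranks(z[[col]], out$statement_id, grid)
  }
  out
}

# core fill: order by z desc, statement id asc on ties; assign ranks
# r_max..r_min with multiplicities = capacities
quantize_ranks <- function(z, statement_id, grid) {
  if (length(z) != grid$n_statements) {
    stop("scores length (", length(z), ") does not match grid size (",
         grid$n_statements, ").", call. = FALSE)
  }
  ord <- order(-z, statement_id)
  slots <- rep(rev(grid$ranks), times = rev(grid$capacity))
  ranks <- integer(length(z))
  ranks[ord] <- slots
  ranks
}

#' Distinguishing and consensus statements
#'
#' Compares each statement's z-scores across factors. The composite
#' reliability of a factor estimated from p exemplars is
#' `r = 0.80 p / (1 + (p - 1) 0.80)` (0.80 is the conventional assumed
#' test-retest reliability of a single sort), its standard error is
#' `SE = sqrt(1 - r)`, and the standard error of the difference between
#' factors f and g is `SED = sqrt(SE_f^2 + SE_g^2)`. A statement
#' *distinguishes* factor f at a given alpha when `|z_f - z_g|` exceeds
#' `z_alpha * SED_fg` for **every** other factor g; a *consensus*
#' statement distinguishes no factor at the 0.05 level.
#'
#' @param scores A `q_scores` with at least two factors.
#' @param reliability Assumed single-sort reliability (default 0.80).
#' @return A tibble: `statement_id`, `factor`, `z`, `distinguishes_05`,
#'   `distinguishes_01`, `consensus` (per statement, repeated across its
#'   factor rows). Attribute `se` holds the per-factor standard errors.
#' @export
distinguish_statements <- function(scores, reliability = 0.80) {
  stopifnot(inherits(scores, "q_scores"))
  zt <- scores$z
  fac <- setdiff(names(zt), "statement_id")
  k <- length(fac)
  if (k < 2) stop("need at least two factors to compare.", call. = FALSE)
  p <- scores$n_exemplars[fac]
  if (any(is.na(p) | p < 1)) stop("every factor needs >= 1 exemplar.", call. = FALSE)
  r <- reliability * p / (1 + (p - 1) * reliability)
  se <- sqrt(1 - r)
  zmat <- as.matrix(zt[, fac])
  zcrit <- c(`05` = 1.96, `01` = 2.58)
  dist_at <- function(zc) {
    res <- matrix(FALSE, nrow(zmat), k)
    for (f in seq_len(k)) {
      others <- setdiff(seq_len(k), f)
      ok <- rep(TRUE, nrow(zmat))
      for (g in others) {
        sed <- sqrt(se[f]^2 + se[g]^2)
        ok <- ok & (abs(zmat[, f] - zmat[, g]) > zc * sed)
      }
      res[, f] <- ok
    }
    res
  }
  d05 <- dist_at(zcrit["05"])
  d01 <- dist_at(zcrit["01"])
  consensus <- rowSums(d05) == 0
  out <- tidyr::pivot_longer(zt, -"statement_id", names_to = "factor",
                             values_to = "z")
  out$distinguishes_05 <- as.vector(t(d05))
  out$distinguishes_01 <- as.vector(t(d01))
  out$consensus <- rep(consensus, each = k)
  structure(out, se = stats::setNames(se, fac),
            class = c("q_distinguish", class(out)))
}
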
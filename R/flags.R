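#' Significance threshold for factor loadings
#'
#' The conventional standard error of a zero-order Q-sort loading is
#' `1 / sqrt(S)` where S is the number of statements, so a loading is
#' significant at alpha when it exceeds `z_alpha / sqrt(S)` in magnitude
#' (z = 1.96 at 0.05, 2.58 at 0.01). For a 42-statement sample at
#' p < 0.01 this gives 0.398, the familiar "0.4" flagging criterion. The
#' raw, unrounded value is returned and used in computations.
#'
#' @param S Number of statements (>= 2).
#' @param alpha Significance level, `0.01` (default) or `0.05`.
#' @return Numeric scalar threshold.
#' @examples
#' loading_threshold(42, 0.01) # 0.398...
#' @export
loading_threshold <- function(S, alpha = 0.01) {
  if (S < 2) stop("need at least two statements.", call. = FALSE)
  z <- c("0.05" = 1.96, "0.01" = 2.58)[format(alpha)]
  if (is.na(z)) stop("alpha must be 0.05 or 0.01.", call. = FALSE)
  unname(z) / sqrt(S)
}

#' Flag exemplar sorts on rotated loadings
#'
#' A participant is flagged as an exemplar of factor j when their loading
#' magnitude reaches the threshold on factor j **only** (the pure-loader
#' rule used for interpretation: loading at least the criterion, p < 0.01,
#' on one factor only). Participants reaching the threshold on two or more
#' factors are "confounded"; those reaching it nowhere are
#' "nonsignificant"; neither is flagged. Negative loaders are flagged with
#' sign -1: they hold the mirrored viewpoint of a (potentially bipolar)
#' factor.
#'
#' The alternative `"pqmethod"` rule additionally requires the squared
#' loading to exceed half the communality (the automatic pre-flagging rule
#' of classic Q software).
#'
#' @param rotated A `q_rotation`, or a P x k loading matrix.
#' @param threshold Positive loading threshold (see [loading_threshold()]).
#' @param rule `"pure"` (default) or `"pqmethod"`.
#' @return A tibble of class `q_flags`: `participant_id`, `factor`
#'   (integer or NA), `sign` (+1/-1 or NA), `loading`, `status`
#'   (`"flagged"`, `"confounded"`, `"nonsignificant"`), with attributes
#'   `threshold` and `rule`.
#' @export
flag_exemplars <- function(rotated, threshold, rule = c("pure", "pqmethod")) {
  rule <- match.arg(rule)
  if (inherits(rotated, "q_rotation")) rotated <- rotated$loadings
  L <- as.matrix(rotated)
  if (threshold <= 0) stop("threshold must be positive.", call. = FALSE)
  ids <- rownames(L)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(nrow(L)))
  rows <- lapply(seq_len(nrow(L)), function(i) {
    l <- L[i, ]
    sig <- which(abs(l) >= threshold)
    if (rule == "pqmethod" && length(sig)) {
      h2 <- sum(l^2)
      sig <- sig[l[sig]^2 > h2 / 2]
    }
    if (length(sig) == 1) {
      tibble::tibble(participant_id = ids[i], factor = as.integer(sig),
                     sign = as.integer(sign(l[sig])), loading = unname(l[sig]),
                     status = "flagged")
    } else if (length(sig) >= 2) {
      j <- sig[which.max(abs(l[sig]))]
      tibble::tibble(participant_id = ids[i], factor = NA_integer_,
                     sign = NA_integer_, loading = unname(l[j]),
                     status = "confounded")
    } else {
      j <- which.max(abs(l))
      tibble::tibble(participant_id = ids[i], factor = NA_integer_,
                     sign = NA_integer_, loading = unname(l[j]),
                     status = "nonsignificant")
    }
  })
  out <- dplyr::bind_rows(rows)
  structure(out, threshold = threshold, rule = rule,
            class = c("q_flags", class(out)))
}

#' Exemplar weight from a factor loading
#'
#' When exemplar sorts are merged into a factor estimate, each sort is
#' weighted by `w = f / (1 - f^2)`, giving higher-loading sorts more
#' influence. Loadings with magnitude at or above 0.999 are clamped to
#' 0.999 (with a warning) so weights stay finite; the sign of the weight
#' follows the sign of the loading.
#'
#' @param f Numeric vector of loadings in (-1, 1) (clamped beyond 0.999).
#' @return Numeric vector of weights.
#' @examples
#' factor_weights(c(0, 0.5, -0.5))
#' @export
factor_weights <- function(f) {
  if (any(abs(f) >= 0.999)) {
    warning("loading(s) with |f| >= 0.999 clamped to 0.999 before weighting.",
            call. = FALSE)
    f <- sign(f) * pmin(abs(f), 0.999)
  }
  f / (1 - f^2)
}
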
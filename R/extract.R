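#' Principal-component extraction from an inter-sort correlation matrix
#'
#' Eigendecomposition of the P x P correlation matrix. Unrotated loadings
#' for component j are the j-th eigenvector scaled by the square root of
#' its eigenvalue, with each column's sign fixed so that the entry of
#' largest magnitude is positive (reproducible across linear-algebra
#' backends). Because the matrix has unit diagonal, the eigenvalues sum to
#' P and the percentage of study variance accounted for by component j is
#' `100 * eigenvalue_j / P`.
#'
#' @param corr Symmetric correlation matrix (e.g. from [q_correlate()]).
#' @param m Number of components for which loadings are kept; defaults to
#'   `min(8, P - 1)`, the usual Q-methodology practice of extracting up to
#'   eight candidates before retention.
#' @return An object of class `q_extraction`: list with `values` (all P
#'   eigenvalues, descending), `loadings` (P x m matrix), `pct_variance`
#'   (length m), `m`, `n_sorts`.
#' @export
q_extract <- function(corr, m = NULL) {
  p <- nrow(corr)
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8))) {
    stop("correlation matrix is not symmetric.", call. = FALSE)
  }
  if (is.null(m)) m <- min(8L, p - 1L)
  if (m < 1 || m > p) stop("`m` must be between 1 and P.", call. = FALSE)
  e <- eigen((corr + t(corr)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-6 * p) {
    stop("correlation matrix is not positive semi-definite.", call. = FALSE)
  }
  values <- pmax(e$values, 0)
  vecs <- e$vectors[, seq_len(m), drop = FALSE]
  load <- sweep(vecs, 2, sqrt(values[seq_len(m)]), `*`)
  load <- fix_column_signs(load)
  rownames(load) <- rownames(corr)
  colnames(load) <- paste0("F", seq_len(m))
  structure(
    list(
      values = values,
      loadings = load,
      pct_variance = 100 * values[seq_len(m)] / p,
      m = as.integer(m),
      n_sorts = as.integer(p)
    ),
    class = "q_extraction"
  )
}

# flip column signs so the largest-magnitude entry of each column is positive
fix_column_signs <- function(x) {
  s <- apply(x, 2, function(col) {
    v <- col[which.max(abs(col))]
    if (v < 0) -1 else 1
  })
  sweep(x, 2, s, `*`)
}

#' @export
print.q_extraction <- function(x, ...) {
  cat("<q_extraction> ", x$n_sorts, " sorts, ", x$m,
      " components kept\n", sep = "")
  print(utils::head(scree_table(x$values, x$n_sorts), x$m))
  invisible(x)
}

#' Convert between eigenvalues and percentage of study variance
#'
#' In Q-methodology the eigenvalue of a factor equals the percentage of
#' study variance it accounts for times the number of participants over
#' 100; these two helpers are exact inverses.
#'
#' @param pct Percentage of study variance (0..100).
#' @param eigenvalue Eigenvalue (0..n_sorts).
#' @param n_sorts Number of participants P.
#' @return A numeric scalar (vectorized over the first argument).
#' @examples
#' eigenvalue_from_pct(10, 110) # 11
#' pct_from_eigenvalue(11, 110) # 10
#' @export
eigenvalue_from_pct <- function(pct, n_sorts) {
  stopifnot(n_sorts >= 1)
  if (any(pct < 0 | pct > 100)) stop("pct must lie in [0, 100].", call. = FALSE)
  pct * n_sorts / 100
}

#' @rdname eigenvalue_from_pct
#' @export
pct_from_eigenvalue <- function(eigenvalue, n_sorts) {
  stopifnot(n_sorts >= 1)
  if (any(eigenvalue < 0)) stop("eigenvalue must be non-negative.", call. = FALSE)
  100 * eigenvalue / n_sorts
}

#' Scree table of eigenvalues
#'
#' Advisory table for the scree test: eigenvalues with per-factor and
#' cumulative percentages of study variance. No automatic elbow detection
#' is performed; retention is decided by [retain_factors()].
#'
#' @param eigenvalues Numeric vector, descending.
#' @param n_sorts Number of participants P (denominator for percentages).
#' @return A tibble with columns `factor`, `eigenvalue`, `pct_variance`,
#'   `cumulative_pct` (non-decreasing).
#' @export
scree_table <- function(eigenvalues, n_sorts) {
  if (is.unsorted(rev(eigenvalues), strictly = FALSE)) {
    stop("eigenvalues must be in descending order.", call. = FALSE)
  }
  pct <- pct_from_eigenvalue(eigenvalues, n_sorts)
  tibble::tibble(
    factor = seq_along(eigenvalues),
    eigenvalue = as.numeric(eigenvalues),
    pct_variance = pct,
    cumulative_pct = cumsum(pct)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.q_extraction <- function(x, ...) {
  scree_table(x$values, x$n_sorts)
}

#' Scree plot
#' @param object A `q_extraction`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.q_extraction <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Component", y = "Eigenvalue",
                  title = "Scree plot (dashed line: eigenvalue = 1)") +
    ggplot2::theme_minimal()
}
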
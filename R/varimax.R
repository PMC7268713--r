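#' Varimax rotation by pairwise planar sweeps
#'
#' Orthogonal rotation maximizing the varimax simple-structure criterion:
#' the sum over factors of the variance of squared loadings. The classic
#' algorithm rotates each pair of columns in turn through the closed-form
#' optimal plane angle and sweeps until the criterion gain falls below
#' `tol`. With Kaiser normalization (the default, matching common Q
#' software), rows are scaled to unit communality before rotation and
#' rescaled afterwards; rows with zero communality are passed through
#' unscaled.
#'
#' After convergence, column signs are fixed so each column's
#' largest-magnitude loading is positive and columns are reordered by
#' explained variance (sum of squared loadings), descending; the returned
#' rotation matrix incorporates both adjustments, so
#' `loadings == input %*% rotmat` always holds.
#'
#' @param loadings P x k numeric matrix of unrotated loadings (or a
#'   `q_extraction`, whose loadings are used).
#' @param kaiser Apply Kaiser row normalization (default TRUE).
#' @param tol Convergence tolerance on the criterion gain per sweep.
#' @param max_iter Maximum number of sweeps; exceeding it records a
#'   convergence warning in the result instead of failing.
#' @return An object of class `q_rotation`: list with `loadings` (rotated,
#'   signed, reordered), `rotmat` (k x k orthonormal), `criterion`,
#'   `iterations`, `converged`, `kaiser`.
#' @export
q_varimax <- function(loadings, kaiser = TRUE, tol = 1e-8, max_iter = 1000L) {
  if (inherits(loadings, "q_extraction")) loadings <- loadings$loadings
  L <- as.matrix(loadings)
  k <- ncol(L)
  p <- nrow(L)
  if (k < 1) stop("need at least one factor.", call. = FALSE)
  if (k == 1) {
    return(structure(
      list(loadings = L, rotmat = matrix(1, 1, 1), criterion = varimax_criterion(L),
           iterations = 0L, converged = TRUE, kaiser = kaiser),
      class = "q_rotation"
    ))
  }
  h <- sqrt(rowSums(L^2))
  scale_rows <- if (kaiser) ifelse(h > 0, h, 1) else rep(1, p)
  X <- L / scale_rows
  R <- diag(k)
  crit <- varimax_criterion(X)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    for (a in seq_len(k - 1)) {
      for (b in seq((a + 1), k)) {
        x <- X[, a]; y <- X[, b]
        u <- x^2 - y^2
        v <- 2 * x * y
        num <- 2 * (p * sum(u * v) - sum(u) * sum(v))
        den <- p * (sum(u^2) - sum(v^2)) - (sum(u)^2 - sum(v)^2)
        if (num == 0 && den == 0) next
        phi <- atan2(num, den) / 4
        if (abs(phi) < 1e-14) next
        cs <- cos(phi); sn <- sin(phi)
        rot <- matrix(c(cs, -sn, sn, cs), 2, 2, byrow = TRUE)
        X[, c(a, b)] <- X[, c(a, b)] %*% rot
        R[, c(a, b)] <- R[, c(a, b)] %*% rot
      }
    }
    new_crit <- varimax_criterion(X)
    gain <- new_crit - crit
    crit <- new_crit
    if (gain < tol) { converged <- TRUE; break }
  }
  Lr <- X * scale_rows
  # sign convention then explained-variance ordering, folded into R
  sgn <- apply(Lr, 2, function(col) if (col[which.max(abs(col))] < 0) -1 else 1)
  Lr <- sweep(Lr, 2, sgn, `*`)
  R <- sweep(R, 2, sgn, `*`)
  ord <- order(colSums(Lr^2), decreasing = TRUE)
  Lr <- Lr[, ord, drop = FALSE]
  R <- R[, ord, drop = FALSE]
  dimnames(Lr) <- list(rownames(L), paste0("F", seq_len(k)))
  structure(
    list(loadings = Lr, rotmat = R, criterion = varimax_criterion(Lr / scale_rows),
         iterations = iter, converged = converged, kaiser = kaiser),
    class = "q_rotation"
  )
}

#' The varimax simple-structure criterion
#'
#' `sum_j [ sum_i L_ij^4 - (sum_i L_ij^2)^2 / P ]` — P times the summed
#' column variances of squared loadings. Exposed so rotation quality can be
#' compared against independent optimizers.
#'
#' @param loadings P x k numeric matrix.
#' @return Numeric scalar.
#' @export
varimax_criterion <- function(loadings) {
  L2 <- as.matrix(loadings)^2
  sum(colSums(L2^2) - colSums(L2)^2 / nrow(L2))
}

#' @export
print.q_rotation <- function(x, ...) {
  cat("<q_rotation> ", ncol(x$loadings), " factors, criterion ",
      format(x$criterion, digits = 6), ", ", x$iterations, " sweep(s)",
      if (!x$converged) " [NOT converged]" else "", "\n", sep = "")
  invisible(x)
}
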
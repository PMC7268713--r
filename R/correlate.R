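#' Inter-sort correlation matrix
#'
#' Correlates participants' sorts with each other (by-person correlation:
#' persons are the variables, statements the observations). Under a shared
#' forced grid every sort has the same mean and variance, so Pearson
#' correlation reduces to a scaled inner product of ranks; Spearman is
#' offered for consistency with rank-based reporting.
#'
#' @param panel A `q_panel`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A P x P symmetric numeric matrix with unit diagonal and
#'   attribute `method`; dimnames are participant ids.
#' @export
q_correlate <- function(panel, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- sort_matrix(panel)
  if (ncol(m) < 2) stop("need at least two sorts to correlate.", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sort(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(m, method = method)
  diag(r) <- 1
  r <- (r + t(r)) / 2
  attr(r, "method") <- method
  r
}
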
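#' Forced-distribution grid specification
#'
#' A Q-grid fixes, for every rank value, how many statements a participant
#' must place at that rank. Ranks must form a contiguous integer range
#' (e.g. -5 to +5) and the capacities must sum to the number of statements
#' in the Q-sample. A completed Q-sort is valid only if its rank frequencies
#' match the grid exactly.
#'
#' @param capacity Named integer vector: names are rank values (as strings
#'   or integers), values are the number of statements allowed at that rank.
#'   Ranks must be contiguous integers.
#' @return An object of class `q_grid` with fields `ranks` (integer vector,
#'   ascending), `capacity` (integer vector aligned with `ranks`),
#'   `n_statements` (sum of capacities) and `symmetric` (TRUE when
#'   `capacity(r) == capacity(-r)` for every rank).
#' @examples
#' q_grid(c(`-1` = 1, `0` = 2, `1` = 1))
#' study_grid()
#' @export
q_grid <- function(capacity) {
  if (is.null(names(capacity)) || any(!nzchar(names(capacity)))) {
    stop("`capacity` must be a named vector; names are rank values.", call. = FALSE)
  }
  ranks <- suppressWarnings(as.integer(names(capacity)))
  if (anyNA(ranks)) stop("grid rank names must be integers.", call. = FALSE)
  ord <- order(ranks)
  ranks <- ranks[ord]
  cap <- as.integer(capacity[ord])
  if (anyNA(cap) || any(cap <= 0)) {
    stop("grid capacities must be positive integers.", call. = FALSE)
  }
  if (anyDuplicated(ranks)) stop("duplicate rank in grid.", call. = FALSE)
  if (!identical(ranks, seq(min(ranks), max(ranks)))) {
    stop("grid ranks must be contiguous integers (no gaps).", call. = FALSE)
  }
  symmetric <- setequal(ranks, -ranks) &&
    all(cap == cap[match(-ranks, ranks)])
  structure(
    list(
      ranks = ranks,
      capacity = stats::setNames(cap, ranks),
      n_statements = sum(cap),
      symmetric = symmetric
    ),
    class = "q_grid"
  )
}

#' @export
print.q_grid <- function(x, ...) {
  cat("<q_grid> ", x$n_statements, " statements, ranks ",
      min(x$ranks), "..", max(x$ranks),
      if (x$symmetric) " (symmetric)" else "", "\n", sep = "")
  print(x$capacity)
  invisible(x)
}

#' Derive a grid from an observed Q-sort
#'
#' Counts the frequency of each rank value in a completed sort and returns
#' the implied forced distribution. Useful when the grid is not documented
#' but a known-valid sort (e.g. a published factor array) is.
#'
#' @param ranks Integer vector of ranks (one complete sort), or a data frame
#'   whose first numeric column after `statement_id` is used.
#' @return A [q_grid()].
#' @examples
#' derive_grid(c(-1, 0, 1))
#' @export
derive_grid <- function(ranks) {
  if (is.data.frame(ranks)) {
    cols <- setdiff(names(ranks), "statement_id")
    if (length(cols) == 0) stop("no rank column found.", call. = FALSE)
    ranks <- ranks[[cols[1]]]
  }
  ranks <- as.integer(ranks)
  if (anyNA(ranks)) stop("ranks contain missing values.", call. = FALSE)
  tab <- table(ranks)
  q_grid(stats::setNames(as.integer(tab), names(tab)))
}

#' The grid used by the packaged health-perception study
#'
#' Eleven ranks from -5 (least important) to +5 (most important) with
#' capacities 1, 2, 3, 5, 6, 8, 6, 5, 3, 2, 1 — a symmetric quasi-normal
#' distribution over 42 statements. The capacities are those implied by the
#' published factor arrays (every array column has exactly this rank
#' frequency profile).
#'
#' @return A [q_grid()] for 42 statements.
#' @export
study_grid <- function() {
  q_grid(stats::setNames(
    c(1L, 2L, 3L, 5L, 6L, 8L, 6L, 5L, 3L, 2L, 1L),
    -5:5
  ))
}

#' Read / write a grid as JSON
#'
#' The JSON layout is `{"ranks": {"-5": 1, "-4": 2, ...}}`.
#'
#' @param path File path.
#' @return `read_grid_json()` returns a [q_grid()]; `write_grid_json()`
#'   returns `path` invisibly.
#' @export
read_grid_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$ranks)) stop("grid JSON must contain a `ranks` object.", call. = FALSE)
  q_grid(unlist(obj$ranks))
}

#' @rdname read_grid_json
#' @param grid A [q_grid()].
#' @export
write_grid_json <- function(grid, path) {
  stopifnot(inherits(grid, "q_grid"))
  jsonlite::write_json(
    list(ranks = as.list(grid$capacity)),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

# Expanded multiset of ranks implied by a grid (ascending), e.g. for the
# minimal grid {-1:1, 0:2, 1:1} this is c(-1, 0, 0, 1).
grid_rank_multiset <- function(grid) {
  rep(grid$ranks, times = grid$capacity)
}

# Theoretical per-sort moments under a forced grid: every valid sort shares
# mean sum(c_r * r)/S and variance sum(c_r * r^2)/S - mean^2.
grid_moments <- function(grid) {
  x <- grid_rank_multiset(grid)
  c(mean = mean(x), var = mean(x^2) - mean(x)^2)
}
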
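# shared fixtures and independent oracles, built in code at test time

mini_grid <- function() q_grid(c(`-1` = 1, `0` = 2, `1` = 1))

# a tiny symmetric 9-statement grid: -2..2 with capacities 1,2,3,2,1
grid9 <- function() q_grid(stats::setNames(c(1, 2, 3, 2, 1), -2:2))

# one random valid sort on a grid
random_sort <- function(grid) sample(rep(grid$ranks, grid$capacity))

# panel of n random valid sorts
random_panel <- function(grid, n, seed = NULL) {
  f <- function() {
    cols <- replicate(n, random_sort(grid), simplify = FALSE)
    names(cols) <- sprintf("P%03d", seq_len(n))
    as_q_panel(
      tibble::tibble(statement_id = seq_len(grid$n_statements), !!!cols),
      grid = grid
    )
  }
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}

# independent varimax oracle for k = 2: exhaustive grid search over the
# rotation angle at 0.001 degree steps; returns the best criterion value
varimax_grid_oracle <- function(L, step_deg = 0.001) {
  th <- seq(0, pi / 2 - 1e-12, by = step_deg * pi / 180)
  x1 <- L[, 1]; x2 <- L[, 2]
  y1 <- outer(x1, cos(th)) + outer(x2, sin(th))
  y2 <- -outer(x1, sin(th)) + outer(x2, cos(th))
  p <- nrow(L)
  crit <- (colSums(y1^4) - colSums(y1^2)^2 / p) +
    (colSums(y2^4) - colSums(y2^2)^2 / p)
  max(crit)
}

# spreadsheet-style weighted z-score oracle: explicit per-statement loops
zscore_oracle <- function(ranks_mat, weights) {
  raw <- numeric(nrow(ranks_mat))
  for (s in seq_len(nrow(ranks_mat))) {
    acc <- 0
    for (j in seq_along(weights)) acc <- acc + weights[j] * ranks_mat[s, j]
    raw[s] <- acc
  }
  (raw - mean(raw)) / stats::sd(raw)
}

expect_valid_panel <- function(panel) {
  expect_true(isTRUE(attr(validate_panel(panel), "ok")))
}
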
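make_flags <- function(ids, factors, signs, loadings) {
  structure(
    tibble::tibble(participant_id = ids, factor = as.integer(factors),
                   sign = as.integer(signs), loading = loadings,
                   status = "flagged"),
    threshold = 0.4, rule = "pure",
    class = c("q_flags", "tbl_df", "tbl", "data.frame")
  )
}

test_that("a single exemplar factor reproduces that exemplar's sort", {
  g <- grid9()
  s <- withr::with_seed(8, random_sort(g))
  panel <- as_q_panel(tibble::tibble(statement_id = 1:9, solo = s), grid = g,
                      validate = TRUE)
  flags <- make_flags("solo", 1, 1, 0.8)
  sc <- factor_zscores(panel, flags)
  expect_equal(sc$z$F1, as.numeric(scale(s)), tolerance = 1e-12)
  expect_equal(mean(sc$z$F1), 0, tolerance = 1e-8)
  expect_equal(stats::sd(sc$z$F1), 1, tolerance = 1e-8)
  arr <- quantize_to_array(sc, g)
  expect_equal(arr$F1, s)
})

test_that("duplicated exemplars with any positive weights change nothing", {
  g <- grid9()
  s <- withr::with_seed(9, random_sort(g))
  panel <- as_q_panel(tibble::tibble(statement_id = 1:9, a = s, b = s),
                      grid = g)
  one <- factor_zscores(panel, make_flags("a", 1, 1, 0.9))
  two <- factor_zscores(panel, make_flags(c("a", "b"), c(1, 1), c(1, 1),
                                          c(0.9, 0.5)))
  expect_equal(two$z$F1, one$z$F1, tolerance = 1e-12)
  expect_equal(two$n_exemplars[["F1"]], 2L)
})

test_that("weighted merging matches the brute-force oracle", {
  g <- grid9()
  sorts <- withr::with_seed(10, replicate(3, random_sort(g)))
  colnames(sorts) <- c("a", "b", "c")
  panel <- as_q_panel(tibble::tibble(statement_id = 1:9,
                                     a = sorts[, 1], b = sorts[, 2],
                                     c = sorts[, 3]), grid = g)
  # loadings chosen so the weights f/(1-f^2) are the simple ladder 1, .5, .25
  f_for_w <- function(w) (sqrt(1 + 4 * w^2) - 1) / (2 * w)
  loads <- vapply(c(1, 0.5, 0.25), f_for_w, 1)
  expect_equal(factor_weights(loads), c(1, 0.5, 0.25), tolerance = 1e-12)
  sc <- factor_zscores(panel, make_flags(c("a", "b", "c"), c(1, 1, 1),
                                         c(1, 1, 1), loads))
  expect_equal(sc$z$F1, zscore_oracle(sorts, c(1, 0.5, 0.25)),
               tolerance = 1e-10)
})

test_that("negative exemplars are excluded by default and mirrored on request", {
  g <- grid9()
  s <- withr::with_seed(11, random_sort(g))
  panel <- as_q_panel(tibble::tibble(statement_id = 1:9, pos = s,
                                     neg = -s), grid = g)
  flags <- make_flags(c("pos", "neg"), c(1, 1), c(1, -1), c(0.8, -0.8))
  excl <- factor_zscores(panel, flags, bipolar = "exclude")
  expect_equal(excl$n_exemplars[["F1"]], 1L)
  incl <- factor_zscores(panel, flags, bipolar = "include")
  expect_equal(incl$n_exemplars[["F1"]], 2L)
  # the mirror of a mirrored sort is the sort: scores agree either way
  expect_equal(incl$z$F1, excl$z$F1, tolerance = 1e-10)
  only_neg <- make_flags("neg", 1, -1, -0.8)
  expect_error(factor_zscores(panel, only_neg), "no included exemplars")
})

test_that("quantization fills the grid respecting capacities and tie-breaks", {
  g <- q_grid(c(`-1` = 1, `0` = 2, `1` = 1))
  z <- tibble::tibble(statement_id = 1:4, F1 = c(0.9, 0.1, -0.2, -1.3))
  arr <- quantize_to_array(z, g)
  expect_equal(arr$F1, c(1L, 0L, 0L, -1L))
  # extremes on a strictly ordered 42-vector
  g42 <- study_grid()
  z42 <- tibble::tibble(statement_id = 1:42,
                        F1 = seq(2, -2, length.out = 42))
  a42 <- quantize_to_array(z42, g42)
  expect_equal(a42$F1[1], 5L)
  expect_equal(a42$F1[42], -5L)
  expect_true(is_valid(as_q_panel(a42, grid = g42)))
})

test_that("exact z ties at a capacity boundary favour the lower statement id", {
  g <- q_grid(c(`0` = 3, `1` = 1))
  z <- tibble::tibble(statement_id = c(3L, 7L, 9L, 12L),
                      F1 = c(-1, 0.5, 0.5, -0.2))
  arr <- quantize_to_array(z, g)
  expect_equal(arr$F1[arr$statement_id == 7], 1L)
  expect_equal(arr$F1[arr$statement_id == 9], 0L)
})

test_that("quantized arrays always validate against the panel grid", {
  g <- study_grid()
  for (seed in 1:5) {
    z <- tibble::tibble(statement_id = 1:42,
                        F1 = withr::with_seed(seed, rnorm(42)))
    arr <- quantize_to_array(z, g)
    expect_true(is_valid(as_q_panel(arr, grid = g)))
  }
})
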
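test_that("wide CSV round-trips through read_qsorts", {
  g <- mini_grid()
  panel <- random_panel(g, 3, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_qsorts(panel, path)
  back <- read_qsorts(path, layout = "wide", grid = g)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(panel))
})

test_that("a published factor-array column reads as a valid one-sort panel", {
  fx <- q_study()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(fx$factor_arrays[, c("statement_id", "F1")], path)
  panel <- read_qsorts(path, grid = fx$grid)
  expect_equal(ncol(panel), 2L)
  expect_true(is_valid(panel))
})

test_that("long CSV with two identical sorts yields equal columns", {
  g <- mini_grid()
  s <- withr::with_seed(3, random_sort(g))
  long <- tibble::tibble(
    participant_id = rep(c("a", "b"), each = 4),
    statement_id = rep(1:4, 2),
    rank = rep(s, 2)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(long, path)
  panel <- read_qsorts(path, layout = "long", grid = g)
  expect_equal(ncol(panel), 3L)
  expect_equal(panel$a, panel$b)
})

test_that("parse errors name the offending row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("statement_id,p1", "1,-1", "2,zero", "3,0", "4,1"), path)
  expect_error(read_qsorts(path), "non-integer.*row 2")
  long <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,statement_id,rank",
               "a,1,-1", "a,1,0", "a,2,0", "a,3,1"), long)
  expect_error(read_qsorts(long, layout = "long"), "duplicate")
})

test_that("typographic minus is normalized on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("statement_id,p1", "1,−1", "2,0", "3,0", "4,1"), path)
  panel <- read_qsorts(path, grid = mini_grid())
  expect_equal(panel$p1, c(-1L, 0L, 0L, 1L))
})

test_that("capacity violations are reported as paired under/over records", {
  g <- mini_grid()
  df <- tibble::tibble(statement_id = 1:4, p1 = c(-1L, 0L, 0L, 1L))
  ok <- validate_panel(as_q_panel(df, grid = g))
  expect_true(attr(ok, "ok"))
  # move a 0 to +1: rank 0 undersubscribed, +1 oversubscribed
  bad <- tibble::tibble(statement_id = 1:4, p1 = c(-1L, 0L, 1L, 1L))
  rep <- validate_panel(as_q_panel(bad, grid = g, validate = FALSE))
  expect_false(attr(rep, "ok"))
  expect_equal(nrow(rep), 2L)
  expect_setequal(rep$rank, c(0L, 1L))
  expect_equal(rep$observed[rep$rank == 1], 2L)
  # assigning the top rank twice on the study grid is a capacity violation
  s <- withr::with_seed(4, random_sort(study_grid()))
  s[which(s == 4)[1]] <- 5L
  rep2 <- validate_panel(
    as_q_panel(tibble::tibble(statement_id = 1:42, p1 = s),
               grid = study_grid(), validate = FALSE))
  expect_true(any(rep2$kind == "capacity" & rep2$rank == 5 & rep2$observed == 2))
})

test_that("missing statements and missing ranks are detected", {
  g <- mini_grid()
  df <- tibble::tibble(statement_id = c(1:3), p1 = c(-1L, 0L, 0L))
  rep <- validate_panel(as_q_panel(df, grid = g, validate = FALSE))
  expect_true(any(rep$kind == "missing_statement" & rep$statement_id == 4))
  df2 <- tibble::tibble(statement_id = 1:4, p1 = c(-1L, 0L, NA, 1L))
  rep2 <- suppressWarnings(
    validate_panel(structure(df2, grid = g, class = c("q_panel", class(df2)))))
  expect_true(any(rep2$kind == "missing_rank" & rep2$statement_id == 3))
})

test_that("validation verdict is invariant under column permutation", {
  g <- grid9()
  panel <- random_panel(g, 5, seed = 21)
  perm <- panel[, c(1, 4, 2, 6, 3, 5)]
  expect_true(is_valid(as_q_panel(perm, grid = g)))
  expect_equal(attr(validate_panel(panel), "ok"),
               attr(validate_panel(as_q_panel(perm, grid = g)), "ok"))
})

test_that("all five published arrays validate as a five-sort panel", {
  fx <- q_study()
  panel <- as_q_panel(fx$factor_arrays, grid = fx$grid)
  expect_valid_panel(panel)
})
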
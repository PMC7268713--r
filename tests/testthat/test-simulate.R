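test_that("prototypes are grid-valid, separated and seed-deterministic", {
  g <- study_grid()
  p1 <- withr::with_seed(91, make_prototypes(g, 3))
  p2 <- withr::with_seed(91, make_prototypes(g, 3))
  expect_identical(p1, p2)
  expect_true(is_valid(as_q_panel(p1, grid = g)))
  rho <- stats::cor(as.matrix(p1[, -1]), method = "spearman")
  expect_true(all(abs(rho[upper.tri(rho)]) <= 0.3))
  single <- withr::with_seed(92, make_prototypes(g, 1))
  expect_true(is_valid(as_q_panel(single, grid = g)))
  expect_error(
    withr::with_seed(93, make_prototypes(g, 6, max_pairwise_corr = -1,
                                         max_draws = 50)),
    "budget")
})

test_that("simulated panels validate and reproduce under one seed", {
  s1 <- simulate_qsorts(K = 3, n_per_factor = 5, noise_sd = 1,
                        confounded_frac = 0.2, negative_frac = 0.1,
                        seed = 94)
  s2 <- simulate_qsorts(K = 3, n_per_factor = 5, noise_sd = 1,
                        confounded_frac = 0.2, negative_frac = 0.1,
                        seed = 94)
  expect_identical(tibble::as_tibble(s1$panel), tibble::as_tibble(s2$panel))
  expect_identical(s1$truth$assignment, s2$truth$assignment)
  expect_valid_panel(s1$panel)
  roles <- table(s1$truth$assignment$role)
  expect_equal(unname(roles["pure"]), 15L)
  expect_equal(unname(roles["confounded"]), 3L)  # round(0.2 * 15)
  expect_equal(unname(roles["negative"]), 2L)    # round(0.1 * 15)
})

test_that("noiseless sorts coincide with their prototypes, mirrors negate", {
  sim <- simulate_qsorts(K = 2, n_per_factor = 3, noise_sd = 0,
                         confounded_frac = 0, negative_frac = 0.4,
                         seed = 95)
  pm <- as.matrix(sim$truth$prototypes[, -1])
  a <- sim$truth$assignment
  m <- as.matrix(tibble::as_tibble(sim$panel)[, -1])
  for (i in seq_len(nrow(a))) {
    expected <- pm[, a$factor[i]] * a$sign[i]
    expect_equal(unname(m[, a$participant_id[i]]), unname(expected))
  }
  neg <- a$participant_id[a$role == "negative"][1]
  rho <- stats::cor(m[, neg], pm[, a$factor[a$participant_id == neg]])
  expect_equal(rho, -1)
})

test_that("factor matching recovers permutations, signs, and partial overlaps", {
  g <- study_grid()
  protos <- withr::with_seed(96, make_prototypes(g, 3))
  shuffled <- protos[, c("statement_id", "F3", "F1", "F2")]
  names(shuffled) <- c("statement_id", "F1", "F2", "F3")
  m <- match_factors(shuffled, protos)
  expect_equal(m$rho, rep(1, 3))
  expect_equal(m$true_factor[m$est_factor == 1], 3L)
  # sign-flipped column matches with |rho| = 1 and sign -1
  flipped <- protos
  flipped$F2 <- -flipped$F2
  m2 <- match_factors(flipped, protos)
  expect_equal(m2$rho, rep(1, 3))
  expect_equal(m2$sign[m2$est_factor == 2], -1L)
  # fewer estimated than true factors: matched pairs only
  m3 <- match_factors(protos[, c("statement_id", "F1")], protos)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$true_factor, 1L)
  expect_error(match_factors(matrix(0, 4, 8), matrix(0, 4, 8)), "at most 7")
})

test_that("matching totals equal an independent exhaustive enumeration", {
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (seed in 1:5) {
    est <- withr::with_seed(seed, matrix(rnorm(24), 8, 3))
    tru <- withr::with_seed(seed + 100, matrix(rnorm(24), 8, 3))
    rho <- stats::cor(est, tru, method = "spearman")
    oracle <- max(vapply(perms3, function(p) {
      sum(abs(rho[cbind(1:3, p)]))
    }, 0))
    m <- match_factors(est, tru)
    expect_equal(attr(m, "total"), oracle, tolerance = 1e-12)
  }
})

test_that("recovery metrics are perfect in the noiseless limit", {
  sim <- simulate_qsorts(K = 4, n_per_factor = 4, noise_sd = 0,
                         confounded_frac = 0, negative_frac = 0, seed = 97)
  sol <- suppressWarnings(q_analyze(sim$panel))
  rec <- recovery_report(sol, sim$truth)
  expect_equal(rec$k_est, 4L)
  expect_equal(rec$mean_abs_rho, 1)
  expect_equal(rec$flag_accuracy, 1)
})

test_that("recovery degrades monotonically with noise on average", {
  noise_grid <- c(0, 0.5, 1, 2)
  mean_rho <- vapply(noise_grid, function(ns) {
    rhos <- vapply(1:20, function(seed) {
      sim <- simulate_qsorts(grid = study_grid(), K = 3, n_per_factor = 8,
                             noise_sd = ns, confounded_frac = 0,
                             negative_frac = 0, seed = 1000 + seed)
      sol <- suppressWarnings(q_analyze(sim$panel, k = 3))
      recovery_report(sol, sim$truth)$mean_abs_rho
    }, 0)
    mean(rhos)
  }, 0)
  expect_true(all(diff(mean_rho) <= 0))
})
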
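#' Generate well-separated prototype factor arrays
#'
#' Draws grid-conforming arrays by randomly permuting the grid's rank
#' multiset and rejecting draws until all pairwise absolute Spearman
#' correlations are at or below `max_pairwise_corr`. Deterministic given
#' the RNG state (seed it with [withr::with_seed()] or via
#' [simulate_qsorts()]).
#'
#' @param grid A [q_grid()].
#' @param K Number of prototypes (>= 1).
#' @param max_pairwise_corr Separation bound on |Spearman| (default 0.3).
#' @param max_draws Rejection budget (default 10000 draws).
#' @return A tibble `statement_id` + `F1`..`FK` of integer ranks.
#' @export
make_prototypes <- function(grid, K, max_pairwise_corr = 0.3,
                            max_draws = 10000L) {
  stopifnot(K >= 1)
  multiset <- grid_rank_multiset(grid)
  S <- grid$n_statements
  protos <- matrix(NA_integer_, S, 0)
  draws <- 0L
  while (ncol(protos) < K) {
    draws <- draws + 1L
    if (draws > max_draws) {
      stop("rejection budget (", max_draws, " draws) exhausted; ",
           "loosen `max_pairwise_corr` or reduce K.", call. = FALSE)
    }
    cand <- sample(multiset)
    if (ncol(protos) > 0) {
      rho <- suppressWarnings(
        stats::cor(cand, protos, method = "spearman"))
      if (any(abs(rho) > max_pairwise_corr)) next
    }
    protos <- cbind(protos, cand)
  }
  colnames(protos) <- paste0("F", seq_len(K))
  tibble::tibble(statement_id = seq_len(S), !!!as.data.frame(protos))
}

#' Simulate a Q-sort panel with known ground truth
#'
#' Emulates the statistical structure of a forced-distribution Q study: K
#' latent viewpoints (prototype arrays), pure participants as noisy
#' realizations of one prototype, plus optional confounded participants
#' (50/50 mixtures of two prototypes) and negative loaders (realizations
#' of a negated prototype). Each participant's latent score vector is the
#' standardized prototype ranks plus iid Gaussian noise, re-quantized onto
#' the grid with the same deterministic tie-break used by
#' [quantize_to_array()], so every simulated panel is grid-valid by
#' construction.
#'
#' Defaults mirror the structure of the packaged study: the 42-statement
#' grid, five viewpoints with the published exemplar group sizes, about
#' one negative loader per hundred sorts, a fifth of sorts confounded, and
#' unit noise on standardized scores.
#'
#' @param grid A [q_grid()]; default [study_grid()].
#' @param K Number of latent viewpoints (default 5).
#' @param n_per_factor Pure sorts per viewpoint; scalar or length-K vector
#'   (default the study exemplar counts 19, 25, 16, 6, 4).
#' @param noise_sd Noise sd on standardized latent scores (default 1).
#' @param confounded_frac Confounded sorts as a fraction of the pure count
#'   (default 0.2).
#' @param negative_frac Negative loaders as a fraction of the pure count
#'   (default 0.01).
#' @param seed Integer seed; all randomness flows from it. `NULL` uses the
#'   current RNG state.
#' @param prototypes Optional pre-made prototype tibble
#'   (from [make_prototypes()]); generated when `NULL`.
#' @param max_pairwise_corr Separation bound passed to [make_prototypes()].
#' @return A list of class `q_sim`: `panel` (a valid `q_panel`) and
#'   `truth` (list: `prototypes`, `assignment` tibble with
#'   `participant_id`, `role` in pure/confounded/negative, `factor`,
#'   `factor2` for mixtures, `sign`).
#' @export
simulate_qsorts <- function(grid = study_grid(), K = 5,
                            n_per_factor = c(19, 25, 16, 6, 4),
                            noise_sd = 1, confounded_frac = 0.2,
                            negative_frac = 0.01, seed = NULL,
                            prototypes = NULL, max_pairwise_corr = 0.3) {
  stopifnot(K >= 1, noise_sd >= 0,
            confounded_frac >= 0, confounded_frac <= 1,
            negative_frac >= 0, negative_frac <= 1)
  n_per_factor <- rep_len(as.integer(n_per_factor), K)
  run <- function() {
    if (is.null(prototypes)) {
      prototypes <- make_prototypes(grid, K, max_pairwise_corr)
    }
    pm <- as.matrix(prototypes[, paste0("F", seq_len(K)), drop = FALSE])
    zproto <- scale(pm) # standardized prototype ranks, one column per factor
    S <- grid$n_statements
    n_pure <- sum(n_per_factor)
    n_conf <- if (K >= 2) round_half_away(confounded_frac * n_pure) else 0L
    n_neg <- round_half_away(negative_frac * n_pure)

    draw_sort <- function(latent) {
      noisy <- latent + stats::rnorm(S, 0, noise_sd)
      quantize_ranks(noisy, seq_len(S), grid)
    }
    cols <- list()
    assign_rows <- list()
    idx <- 0L
    add <- function(ranks, role, f1, f2, sgn) {
      idx <<- idx + 1L
      pid <- sprintf("P%03d", idx)
      cols[[pid]] <<- ranks
      assign_rows[[idx]] <<- tibble::tibble(
        participant_id = pid, role = role, factor = f1,
        factor2 = f2, sign = sgn
      )
    }
    for (f in seq_len(K)) {
      for (i in seq_len(n_per_factor[f])) {
        add(draw_sort(zproto[, f]), "pure", f, NA_integer_, 1L)
      }
    }
    for (i in seq_len(n_conf)) {
      pair <- sample(K, 2)
      latent <- 0.5 * zproto[, pair[1]] + 0.5 * zproto[, pair[2]]
      add(draw_sort(latent), "confounded", pair[1], pair[2], 1L)
    }
    for (i in seq_len(n_neg)) {
      f <- sample(K, 1)
      add(draw_sort(-zproto[, f]), "negative", f, NA_integer_, -1L)
    }
    panel <- as_q_panel(
      tibble::tibble(statement_id = seq_len(S), !!!cols),
      grid = grid, validate = TRUE
    )
    structure(
      list(panel = panel,
           truth = list(prototypes = prototypes,
                        assignment = dplyr::bind_rows(assign_rows))),
      class = "q_sim"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.q_sim <- function(x, ...) {
  a <- x$truth$assignment
  cat("<q_sim> ", ncol(x$panel) - 1L, " sorts (",
      sum(a$role == "pure"), " pure, ", sum(a$role == "confounded"),
      " confounded, ", sum(a$role == "negative"), " negative), ",
      ncol(x$truth$prototypes) - 1L, " prototypes\n", sep = "")
  invisible(x)
}

#' Match estimated factor arrays to prototypes
#'
#' Exhaustively searches injective assignments of estimated factors to
#' prototypes (supported up to 7 factors) maximizing the total absolute
#' Spearman correlation, and reports the per-pair correlation and sign.
#'
#' @param estimated Tibble or matrix of estimated arrays (columns =
#'   factors; a `statement_id` column is dropped).
#' @param prototypes Same layout, the ground-truth arrays.
#' @return A tibble of class `q_match`: `est_factor`, `true_factor`,
#'   `rho` (absolute Spearman), `sign`; attribute `total` is the summed
#'   absolute correlation.
#' @export
match_factors <- function(estimated, prototypes) {
  em <- drop_sid(estimated)
  pm <- drop_sid(prototypes)
  ke <- ncol(em); kp <- ncol(pm)
  if (max(ke, kp) > 7) stop("matching supports at most 7 factors.", call. = FALSE)
  rho <- suppressWarnings(stats::cor(em, pm, method = "spearman"))
  # search over injective maps from the smaller side into the larger
  if (ke <= kp) {
    perms <- all_injections(ke, kp)
    score <- vapply(perms, function(p) sum(abs(rho[cbind(seq_len(ke), p)])), 0)
    best <- perms[[which.max(score)]]
    est_idx <- seq_len(ke); true_idx <- best
  } else {
    perms <- all_injections(kp, ke)
    score <- vapply(perms, function(p) sum(abs(rho[cbind(p, seq_len(kp))])), 0)
    best <- perms[[which.max(score)]]
    est_idx <- best; true_idx <- seq_len(kp)
  }
  pair_rho <- rho[cbind(est_idx, true_idx)]
  out <- tibble::tibble(
    est_factor = est_idx,
    true_factor = true_idx,
    rho = abs(pair_rho),
    sign = ifelse(pair_rho >= 0, 1L, -1L)
  )
  out <- dplyr::arrange(out, .data$est_factor)
  structure(out, total = sum(abs(pair_rho)),
            class = c("q_match", class(out)))
}

drop_sid <- function(x) {
  x <- tibble::as_tibble(as.data.frame(x))
  as.matrix(x[, setdiff(names(x), "statement_id"), drop = FALSE])
}

# all injective maps seq_len(n) -> subsets of seq_len(m), n <= m
all_injections <- function(n, m) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  recurse <- function(chosen, remaining) {
    if (length(chosen) == n) {
      out[[length(out) + 1]] <<- chosen
      return(invisible())
    }
    for (x in remaining) recurse(c(chosen, x), setdiff(remaining, x))
  }
  recurse(integer(0), seq_len(m))
  out
}

#' Recovery metrics of a solution against simulation ground truth
#'
#' @param solution A `q_solution` fitted on a simulated panel.
#' @param truth The `truth` element of a [simulate_qsorts()] result (or
#'   the whole `q_sim`).
#' @return A list of class `q_recovery`: `k_est`, `k_true`,
#'   `mean_abs_rho` (mean matched absolute Spearman over matched pairs),
#'   `n_matched`, `flag_accuracy` (fraction of pure participants flagged
#'   on their true factor), `matches` (the [match_factors()] table).
#' @export
recovery_report <- function(solution, truth) {
  if (inherits(truth, "q_sim")) truth <- truth$truth
  matches <- match_factors(solution$arrays, truth$prototypes)
  assignment <- truth$assignment
  pure <- dplyr::filter(assignment, .data$role == "pure")
  est_to_true <- stats::setNames(matches$true_factor, matches$est_factor)
  fl <- dplyr::filter(solution$flags, .data$status == "flagged")
  fl <- dplyr::inner_join(fl, pure, by = "participant_id",
                          suffix = c("_est", "_true"))
  mapped <- unname(est_to_true[as.character(fl$factor_est)])
  hits <- sum(!is.na(mapped) & mapped == fl$factor_true)
  structure(
    list(
      k_est = solution$k,
      k_true = ncol(truth$prototypes) - 1L,
      mean_abs_rho = mean(matches$rho),
      n_matched = nrow(matches),
      flag_accuracy = hits / nrow(pure),
      matches = matches
    ),
    class = "q_recovery"
  )
}

#' @export
print.q_recovery <- function(x, ...) {
  cat("<q_recovery> k_est = ", x$k_est, " (true ", x$k_true,
      "), mean |rho| = ", sprintf("%.3f", x$mean_abs_rho),
      ", flag accuracy = ", sprintf("%.3f", x$flag_accuracy), "\n", sep = "")
  invisible(x)
}
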
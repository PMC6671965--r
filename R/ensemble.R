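#' Random initial relation matrix
#'
#' Each off-diagonal relation is drawn independently from the uniform
#' distribution on (-1, 1), the homogeneous density `rho(x) = 1/2`.
#'
#' @param n number of actors (>= 3).
#' @param seed optional integer seed; when given, the draw is
#'   reproducible and the caller's RNG state is left untouched.
#' @return a [relation_matrix()].
#' @examples
#' random_initial(7, seed = 1)
#' @export
random_initial <- function(n, seed = NULL) {
  stopifnot(n >= 3)
  draw <- function() {
    m <- matrix(stats::runif(n * n, -1, 1), n, n)
    diag(m) <- 0
    relation_matrix(m)
  }
  if (is.null(seed)) return(draw())
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  draw()
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Monte-Carlo ensemble of relation-dynamics runs
#'
#' Runs the full pipeline `random_initial -> evolve -> discretize ->
#' refine_classes -> class_graph -> identify_template` for `k_runs`
#' independent networks of `n` actors and tallies the terminal class
#' graphs.  Per-run seeds are drawn once from the master `seed`, so the
#' result is reproducible and individual runs can be replayed.
#' Non-converged runs (model time `t_max` exhausted or solver failure)
#' are recorded but not classified.
#'
#' @param n number of actors.
#' @param k_runs number of networks in the sample.
#' @param seed master seed.
#' @param tol corner stop criterion passed to [evolve()].
#' @param t_max maximum model time per run.
#' @param init optional function `(run_index, seed) -> relation_matrix`
#'   replacing [random_initial()] (used for controlled experiments).
#' @param progress print a progress line every 1000 runs.
#' @return an `ensemble_result`: list with `n`, `k_runs`, `seed`,
#'   `records` (one tibble row per run: `run`, `seed`, `converged`,
#'   `stationary`, `degenerate`, `t_end`, `asymmetric`, `kind`,
#'   `N1`..`N4`, `c`, `key`) and `tallies` (per canonical key: `key`,
#'   `kind`, `N1`..`N4`, `count`).  Frozen states that violate the
#'   sign condition (first corner visits of heteroclinically cycling
#'   trajectories) are recorded as `kind = "other"` with
#'   `stationary = FALSE` and are excluded from `tallies`, so every
#'   tallied class graph is a genuine stationary state.
#' @examples
#' run_ensemble(7, k_runs = 5, seed = 1)
#' @export
run_ensemble <- function(n, k_runs = 10000L, seed = 1L, tol = 1e-8,
                         t_max = 1000, init = NULL, progress = FALSE) {
  stopifnot(n >= 3, k_runs >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, k_runs)
  restore_rng(old)

  rows <- vector("list", k_runs)
  for (r in seq_len(k_runs)) {
    x0 <- if (is.null(init)) {
      random_initial(n, seed = run_seeds[r])
    } else {
      init(r, run_seeds[r])
    }
    ev <- tryCatch(
      suppressWarnings(evolve(x0, tol = tol, t_max = t_max)),
      error = function(e) NULL)
    if (is.null(ev) || !ev$converged) {
      rows[[r]] <- tibble::tibble(
        run = r, seed = run_seeds[r], converged = FALSE,
        stationary = NA, degenerate = NA,
        t_end = if (is.null(ev)) NA_real_ else ev$t_end,
        asymmetric = NA, kind = NA_character_,
        N1 = NA_integer_, N2 = NA_integer_, N3 = NA_integer_,
        N4 = NA_integer_, c = NA_integer_, key = NA_character_)
    } else {
      s <- ev$sign
      st <- is_stationary(s)
      if (st$stationary) {
        cl <- classify_state(s)
      } else {
        # a first corner visit of a heteroclinically cycling trajectory
        # (or, for even n, a zero triad sum): frozen but not a genuine
        # fixed-point class graph — reported as "other", never tallied
        cl <- tibble::tibble(kind = "other", N1 = NA_integer_,
                             N2 = NA_integer_, N3 = NA_integer_,
                             N4 = NA_integer_, c = NA_integer_,
                             key = NA_character_)
      }
      rows[[r]] <- tibble::tibble(
        run = r, seed = run_seeds[r], converged = TRUE,
        stationary = st$stationary,
        degenerate = nrow(st$zero_sum_links) > 0L,
        t_end = ev$t_end,
        asymmetric = any(unclass(s) != t(unclass(s))),
        kind = cl$kind, N1 = cl$N1, N2 = cl$N2, N3 = cl$N3, N4 = cl$N4,
        c = cl$c, key = cl$key)
    }
    if (progress && r %% 1000L == 0L) {
      message(sprintf("run %d / %d", r, k_runs))
    }
  }
  records <- dplyr::bind_rows(rows)
  tallies <- records |>
    dplyr::filter(.data$converged, .data$stationary) |>
    dplyr::count(.data$key, .data$kind, .data$N1, .data$N2, .data$N3,
                 .data$N4, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count))
  structure(list(n = n, k_runs = as.integer(k_runs), seed = seed,
                 tol = tol, t_max = t_max,
                 records = records, tallies = tallies),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "<ensemble_result> n = %d, %d runs (seed %s): %.1f%% converged\n",
    x$n, x$k_runs, format(x$seed), 100 * mean(x$records$converged)))
  invisible(x)
}

#' Per-run records of an ensemble
#' @param x an `ensemble_result`.
#' @param ... unused.
#' @export
tidy.ensemble_result <- function(x, ...) x$records

#' One-row ensemble summary
#'
#' @param x an `ensemble_result`.
#' @param ... unused.
#' @return a tibble with the converged fraction, the asymmetric fraction
#'   among converged runs, and the CIII/CIV share of the whole sample.
#' @export
glance.ensemble_result <- function(x, ...) {
  rec <- x$records
  conv <- rec[rec$converged, ]
  tibble::tibble(
    n = x$n, k_runs = x$k_runs,
    converged_frac = nrow(conv) / x$k_runs,
    asymmetric_frac = mean(conv$asymmetric),
    ciii_civ_frac = sum(conv$kind %in% c("CIII", "CIV")) / x$k_runs)
}

#' Fraction of asymmetric terminal states
#'
#' A terminal state is asymmetric when its sign matrix differs from its
#' transpose; symmetric terminal states are the classical balanced ones.
#'
#' @param r an `ensemble_result`.
#' @param denominator `"converged"` (default) or `"all"` runs.
#' @return a single fraction in `[0, 1]`.
#' @export
asymmetric_fraction <- function(r, denominator = c("converged", "all")) {
  denominator <- match.arg(denominator)
  conv <- r$records[r$records$converged, ]
  den <- if (denominator == "converged") nrow(conv) else r$k_runs
  sum(conv$asymmetric) / den
}

#' Frequency table of terminal class graphs
#'
#' One row per distinct archetype size configuration, in the layout of
#' the published tables: columns `N1`..`N4` (three-class rows carry
#' `N4 = 0`) and the count, sorted by archetype and then by decreasing
#' count.
#'
#' @param r an `ensemble_result`.
#' @param kinds archetypes to include.
#' @return a tibble with `kind`, `N1`..`N4`, `count`.
#' @export
frequency_table <- function(r, kinds = c("HB", "CII", "CIII", "CIV")) {
  r$tallies |>
    dplyr::filter(.data$kind %in% kinds) |>
    dplyr::group_by(.data$kind, .data$N1, .data$N2, .data$N3, .data$N4) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(kind = factor(.data$kind, levels = kinds)) |>
    dplyr::arrange(.data$kind, dplyr::desc(.data$count)) |>
    dplyr::mutate(kind = as.character(.data$kind))
}

#' Rank-frequency spectrum of terminal class graphs
#'
#' Distinct terminal class graphs ordered by increasing frequency, higher
#' rank for the more frequent.
#'
#' @param r an `ensemble_result`.
#' @return a tibble with `rank`, `count`, `key` (counts non-decreasing in
#'   rank).
#' @export
rank_frequency <- function(r) {
  if (nrow(r$tallies) == 0L) {
    stop("no converged runs to rank", call. = FALSE)
  }
  r$tallies |>
    dplyr::arrange(.data$count, .data$key) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "count", "key")
}

#' Rank-scaling exponent across ensembles
#'
#' Least-squares estimate of the exponent `alpha` for which the
#' rank-frequency curves of several network sizes collapse when the rank
#' is multiplied by `n^-alpha`: fits
#' `log(rank) ~ log(count) + alpha * log(n)` over the pooled spectra.
#'
#' @param results list of `ensemble_result` objects of at least two
#'   different network sizes.
#' @return the fitted exponent (a single number).
#' @export
rank_scaling_exponent <- function(results) {
  sizes <- vapply(results, function(r) r$n, numeric(1))
  if (length(unique(sizes)) < 2L) {
    stop("need ensembles of at least two different sizes", call. = FALSE)
  }
  df <- purrr::map_dfr(results, function(r) {
    dplyr::mutate(rank_frequency(r), n = r$n)
  })
  fit <- stats::lm(log(rank) ~ log(count) + log(n), data = df)
  unname(stats::coef(fit)[["log(n)"]])
}

#' Rank-frequency plot
#' @param object an `ensemble_result`.
#' @param ... unused.
#' @return a log-log ggplot of frequency against rank.
#' @export
autoplot.ensemble_result <- function(object, ...) {
  df <- rank_frequency(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$count)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank (increasing frequency)", y = "frequency",
                  title = sprintf("n = %d, %d runs", object$n,
                                  object$k_runs)) +
    ggplot2::theme_minimal()
}

#' Stirling numbers of the second kind
#'
#' `stirling2(n, k)` counts the partitions of `n` labeled elements into
#' `k` nonempty unlabeled sets, via the recurrence
#' `S(n, k) = k S(n-1, k) + S(n-1, k-1)`.  Values are exact while they
#' stay below 2^53.
#'
#' @param n,k non-negative integers, `k <= n`.
#' @return the Stirling number as a numeric scalar.
#' @examples
#' stirling2(7, 3)
#' @export
stirling2 <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (is.na(n) || is.na(k) || k < 0L || n < 0L || k > n) {
    stop("need 0 <= k <= n", call. = FALSE)
  }
  if (n == 0L) return(as.numeric(k == 0L))
  if (k == 0L) return(0)
  # row-wise recurrence over S(m, .)
  row <- c(1, rep(0, k - 1))  # S(1, 1..k)
  if (n == 1L) return(row[k])
  for (m in 2:n) {
    new <- numeric(k)
    new[1] <- 1  # S(m, 1) = 1
    for (j in seq_len(min(m, k))[-1]) {
      new[j] <- j * row[j] + row[j - 1]
    }
    row <- new
  }
  row[k]
}

#' Ratio of four- to three-set partition counts
#'
#' `S(n, 4) / S(n, 3)`: how many more ways there are to split `n` actors
#' into four groups than into three.  The rapid growth of this ratio with
#' `n` explains why four-class terminal graphs crowd out three-class ones
#' in large networks.
#'
#' @param n number of actors (>= 4).
#' @return the ratio as a numeric scalar.
#' @examples
#' partition_ratio(7)
#' @export
partition_ratio <- function(n) {
  stopifnot(n >= 4)
  stirling2(n, 4) / stirling2(n, 3)
}
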
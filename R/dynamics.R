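#' Right-hand side of the relation dynamics
#'
#' Evaluates the time derivative of every directed relation:
#' `dx_ij/dt = (1 - x_ij^2) * sum_{k != i, j} x_ik * x_kj`.
#' A third actor `k` that is a common friend or a common enemy of `i` and
#' `j` pushes `x_ij` up; a mixed pair pushes it down.  The factor
#' `1 - x_ij^2` confines every relation to `[-1, 1]` and makes the
#' hypercube corners `x_ij = +/-1` fixed points.
#'
#' @param x a [relation_matrix()].
#' @return an `n x n` numeric matrix of derivatives with zero diagonal.
#' @examples
#' heider_rhs(relation_matrix(matrix(0.5, 3, 3)))
#' @export
heider_rhs <- function(x) {
  if (!inherits(x, "relation_matrix")) x <- relation_matrix(x)
  m <- unclass(x)
  # with a zero diagonal the k = i and k = j terms of the matrix product
  # vanish, so m %*% m is exactly the sum over the remaining n - 2 actors
  d <- (1 - m^2) * (m %*% m)
  diag(d) <- 0
  d
}

corner_gap <- function(m) {
  max(abs(1 - abs(offdiag(m))))
}

#' Integrate the relation dynamics to a corner state
#'
#' Integrates the coupled relation equations from `x0` with an adaptive
#' solver (`deSolve::lsodar` driving the compiled right-hand side) until
#' either every relation is within `tol` of +/-1 (a corner of the
#' hypercube, detected by the solver's root finder) or model time `t_max`
#' is exhausted.  Solver tolerances default to two orders of magnitude
#' tighter than the corner criterion.
#'
#' @param x0 a [relation_matrix()] (or coercible matrix) of initial
#'   relations, `|x_ij| <= 1`.
#' @param tol corner stop criterion: converged when
#'   `max |1 - |x_ij|| <= tol`.
#' @param t_max maximum model time.
#' @param rtol,atol relative/absolute solver tolerances.
#' @param trace if `TRUE`, keep the trajectory (a tibble in long format)
#'   for plotting.
#' @return an `evolution_result`: list with elements `final` (the
#'   [relation_matrix()] at the stop time), `converged`, `t_end` (the
#'   first checkpoint at which the corner criterion held), `sign` (the
#'   [sign_matrix()] of the corner, or `NULL` when not converged), `tol`,
#'   and optionally `trace`.
#' @examples
#' ev <- evolve(make_template(template_spec("HB", c(4, 3))))
#' ev$converged
#' @export
evolve <- function(x0, tol = 1e-8, t_max = 1000, rtol = 1e-10, atol = 1e-10,
                   trace = FALSE) {
  if (!inherits(x0, "relation_matrix")) x0 <- relation_matrix(x0)
  n <- n_actors(x0)
  if (n %% 2L == 0L) {
    warning("even number of actors: stationarity can be ambiguous ",
            "(a corner triad sum can be exactly zero)", call. = FALSE)
  }
  m0 <- unclass(x0)
  res <- list(final = x0, converged = FALSE, t_end = 0, sign = NULL,
              tol = tol)
  class(res) <- "evolution_result"

  if (corner_gap(m0) <= tol) {
    res$converged <- TRUE
    res$sign <- discretize(x0, tol)
    if (trace) res$trace <- trace_tibble(matrix(as.vector(m0), 1), 0, n)
    return(res)
  }

  # chunked adaptive integration with root-triggered stopping: the
  # solver halts as soon as every |x_ij| enters the corner band (the
  # root fires marginally inside the band so the criterion holds
  # strictly at the reported state).  Note that a trajectory on a
  # heteroclinic excursion can graze a *saddle* corner; the stop rule
  # deliberately accepts such first visits too, so a converged state is
  # guaranteed frozen only in the +/-1 sense — stationarity is a
  # separate question answered by is_stationary().
  y <- as.vector(m0)
  t_now <- 0
  converged <- FALSE
  tr_states <- NULL
  tr_times <- NULL
  iter <- 0L
  while (t_now < t_max && iter < 200L) {
    iter <- iter + 1L
    t_chunk <- min(t_now + 250, t_max)
    times <- if (trace) {
      seq(t_now, t_chunk, length.out = 251L)
    } else {
      c(t_now, t_chunk)
    }
    out <- tryCatch(
      deSolve::lsodar(
        y = y, times = times, func = "heider_deriv",
        parms = c(n, 1 - 0.999 * tol), dllname = "heiderdyn",
        initfunc = "heider_init", rootfunc = "heider_root", nroot = 1L,
        rtol = rtol, atol = atol, maxsteps = 100000L),
      error = function(e) NULL,
      warning = function(w) NULL)
    if (is.null(out) || nrow(out) < 2L || anyNA(out)) {
      break  # solver failure: report the last healthy state
    }
    if (max(abs(out[, -1])) > 1 + 1e-6) {
      stop("trajectory drifted beyond |x| = 1 + 1e-6; ",
           "solver tolerances are misconfigured", call. = FALSE)
    }
    if (trace) {
      tr_states <- rbind(tr_states, out[-1, -1, drop = FALSE])
      tr_times <- c(tr_times, out[-1, 1])
    }
    t_prev <- t_now
    t_now <- out[nrow(out), 1]
    y <- pmin(pmax(out[nrow(out), -1], -1), 1)
    mat <- matrix(y, n, n)
    diag(mat) <- 0
    if (corner_gap(mat) <= tol) {
      converged <- TRUE
      break
    }
    if (t_now <= t_prev + 1e-10) break  # no progress: give up
  }
  mat <- matrix(y, n, n)
  diag(mat) <- 0
  res$final <- relation_matrix(mat)
  res$t_end <- t_now
  res$converged <- converged
  if (converged) res$sign <- discretize(res$final, tol)
  if (trace && !is.null(tr_states)) {
    res$trace <- trace_tibble(tr_states, tr_times, n)
  }
  res
}


trace_tibble <- function(states, times, n) {
  states <- matrix(states, ncol = n * n)
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  keep <- ij$i != ij$j
  purrr::map_dfr(seq_along(times), function(r) {
    tibble::tibble(t = times[r], i = ij$i[keep], j = ij$j[keep],
                   x = states[r, keep])
  })
}

#' @export
print.evolution_result <- function(x, ...) {
  cat(sprintf("<evolution_result> n = %d, %s at t = %.4g (tol = %g)\n",
              n_actors(x$final),
              if (x$converged) "converged to a corner" else "not converged",
              x$t_end, x$tol))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of an evolution run
#' @param x an `evolution_result`.
#' @param ... unused.
#' @return a tibble with `n`, `converged`, `t_end`, `tol`.
#' @export
glance.evolution_result <- function(x, ...) {
  tibble::tibble(n = n_actors(x$final), converged = x$converged,
                 t_end = x$t_end, tol = x$tol)
}

#' Trajectory plot of an evolution run
#'
#' Requires `evolve(..., trace = TRUE)`.
#' @param object an `evolution_result` with a stored trace.
#' @param ... unused.
#' @return a ggplot: one line per directed relation over model time.
#' @export
autoplot.evolution_result <- function(object, ...) {
  if (is.null(object$trace)) {
    stop("no trajectory stored; rerun evolve() with trace = TRUE",
         call. = FALSE)
  }
  df <- dplyr::mutate(object$trace,
                      link = paste0(.data$i, "→", .data$j))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$x, group = .data$link)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = "dotted") +
    ggplot2::labs(x = "model time", y = expression(x[ij])) +
    ggplot2::theme_minimal()
}

#' Extract the sign matrix of a corner state
#'
#' @param x a [relation_matrix()] whose entries are all within `tol` of
#'   +/-1.
#' @param tol corner tolerance.
#' @return the [sign_matrix()] of entrywise signs.
#' @examples
#' discretize(relation_matrix(matrix(1 - 1e-9, 3, 3)))
#' @export
discretize <- function(x, tol = 1e-8) {
  if (!inherits(x, "relation_matrix")) x <- relation_matrix(x)
  if (corner_gap(x) > tol) {
    stop(sprintf(
      "state is not a corner at tolerance %g (max |1 - |x|| = %g)",
      tol, corner_gap(x)), call. = FALSE)
  }
  s <- sign(unclass(x))
  diag(s) <- 0
  sign_matrix(s)
}
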
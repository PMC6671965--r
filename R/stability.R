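#' Sign-condition stationarity of a corner state
#'
#' A corner state is a fixed point of the relation dynamics that attracts
#' its neighbourhood iff every directed link agrees with the sign of its
#' triad sum: `s_ij = sign(T_ij)` with `T_ij = sum_{k != i, j} s_ik s_kj`.
#' A link with `T_ij = 0` (possible only for an even number of actors)
#' leaves the stationarity undecided and is reported separately, never
#' silently resolved.
#'
#' @param s a [sign_matrix()].
#' @return a `stability_report`: list with `stationary` (`TRUE` iff no
#'   violating and no zero-sum links), `violating_links` and
#'   `zero_sum_links` (tibbles with columns `i`, `j`, `t_sum`).
#' @examples
#' is_stationary(make_template(template_spec("CII", c(5, 2))))
#' @export
is_stationary <- function(s) {
  if (!is_sign_matrix(s)) s <- sign_matrix(s)
  m <- unclass(s)
  t_sum <- m %*% m  # zero diagonal removes the k = i, j terms
  off <- row(m) != col(m)
  zero <- off & t_sum == 0
  viol <- off & t_sum != 0 & sign(t_sum) != m
  as_links <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    tibble::tibble(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                   t_sum = t_sum[idx])
  }
  structure(list(stationary = !any(viol) && !any(zero),
                 violating_links = as_links(viol),
                 zero_sum_links = as_links(zero)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s (%d violating, %d zero-sum links)\n",
              if (x$stationary) "stationary" else "not stationary",
              nrow(x$violating_links), nrow(x$zero_sum_links)))
  invisible(x)
}

#' Offending links of a stability report
#' @param x a `stability_report`.
#' @param ... unused.
#' @return a tibble with `i`, `j`, `t_sum`, `problem`.
#' @export
tidy.stability_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$violating_links, problem = "sign violation"),
    dplyr::mutate(x$zero_sum_links, problem = "zero triad sum"))
}

#' One-row summary of a stability report
#' @param x a `stability_report`.
#' @param ... unused.
#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(stationary = x$stationary,
                 n_violating = nrow(x$violating_links),
                 n_zero_sum = nrow(x$zero_sum_links))
}

# Drop trailing zero classes, delegating degenerate archetypes to the
# lower one they reduce to.
reduce_template <- function(spec) {
  sizes <- spec$sizes
  kind <- spec$kind
  while (length(sizes) > 1L && sizes[length(sizes)] == 0L) {
    sizes <- sizes[-length(sizes)]
    if (kind == "CII") {
      kind <- "HB"          # hostile class empty: one friendly clique
    } else if (kind == "CIII") {
      kind <- "HB"          # aspirant class empty: two hostile cliques
    } else if (kind == "CIV") {
      kind <- "CIII"        # fourth class empty; roles 1 and 2 swap
      sizes <- sizes[c(2, 1, 3)]
    }
  }
  list(kind = kind, sizes = sizes)
}

#' Closed-form stability of an archetype
#'
#' Evaluates the binding sign-condition inequality of each archetype:
#' HB is always stable; CII requires `N1 > N2 + 2`; CIII requires
#' `N1 + N2 > N3 + 2`; CIV requires `N1 + N2 > N3 + N4 + 2`.  Trailing
#' empty classes delegate to the archetype the template degenerates to.
#'
#' @param spec a [template_spec()].
#' @return `TRUE` iff the constructed corner state is stationary.
#' @examples
#' template_stable(template_spec("CIII", c(3, 3, 1)))
#' @export
template_stable <- function(spec) {
  stopifnot(inherits(spec, "template_spec"))
  red <- reduce_template(spec)
  sz <- red$sizes
  switch(red$kind,
    HB = TRUE,
    CII = sz[1] > sz[2] + 2L,
    CIII = sz[1] + sz[2] > sz[3] + 2L,
    CIV = sz[1] + sz[2] > sz[3] + sz[4] + 2L)
}

#' Closed-form per-class self-evaluation of an archetype
#'
#' The self-evaluation index is constant within a class.  Closed forms:
#' HB `(N1 - 1, N2 - 1)`; CII `(N1 - 1, -N1)`; CIII
#' `(N1 - 1, N2 - N3 - 1, -N1)`; CIV
#' `(N1 - N3 - 1, N2 - N4 - 1, N4 - N2, N3 - N1)`.
#'
#' @param spec a [template_spec()].
#' @return a tibble with `class`, `size` and `f` for each nonempty class
#'   (in the archetype's role order).
#' @examples
#' template_self_evaluations(template_spec("CIV", c(4, 3, 2, 1)))
#' @export
template_self_evaluations <- function(spec) {
  stopifnot(inherits(spec, "template_spec"))
  sz <- spec$sizes
  f <- switch(spec$kind,
    HB = c(sz[1] - 1L, sz[2] - 1L),
    CII = c(sz[1] - 1L, -sz[1]),
    CIII = c(sz[1] - 1L, sz[2] - sz[3] - 1L, -sz[1]),
    CIV = c(sz[1] - sz[3] - 1L, sz[2] - sz[4] - 1L,
            sz[4] - sz[2], sz[3] - sz[1]))
  keep <- sz > 0L
  tibble::tibble(class = which(keep), size = sz[keep],
                 f = as.integer(f[keep]))
}
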
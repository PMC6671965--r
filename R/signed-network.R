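#' Continuous relation matrix
#'
#' A `relation_matrix` holds the state of a fully connected directed signed
#' network of `n >= 3` actors: one real relation `x[i, j]` in `[-1, 1]` for
#' every ordered pair of distinct actors.  Self-relations are not dynamical
#' variables; the diagonal is stored as 0 and ignored everywhere.
#'
#' @param x a square numeric matrix with `|x[i, j]| <= 1` off the diagonal.
#'   Diagonal values are discarded.
#' @return `x` as a `relation_matrix` (a classed numeric matrix with zero
#'   diagonal).
#' @examples
#' relation_matrix(matrix(0.5, 3, 3))
#' @export
relation_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || nrow(x) != ncol(x)) {
    stop("`x` must be a square numeric matrix", call. = FALSE)
  }
  n <- nrow(x)
  if (n < 3L) {
    stop("a relation network needs at least 3 actors (no triads otherwise)",
         call. = FALSE)
  }
  diag(x) <- 0
  if (anyNA(x)) stop("relations must not be NA", call. = FALSE)
  if (max(abs(x)) > 1) {
    stop("all relations must satisfy |x_ij| <= 1", call. = FALSE)
  }
  structure(x, class = c("relation_matrix", "matrix", "array"))
}

#' Discrete sign matrix
#'
#' A `sign_matrix` is a corner state of the relation dynamics: every
#' off-diagonal entry is exactly +1 (friendly) or -1 (hostile).  The
#' diagonal carries no information and is stored as 0.
#'
#' @param s a square matrix whose off-diagonal entries are all +1 or -1.
#' @return `s` as a `sign_matrix`.
#' @examples
#' sign_matrix(matrix(1, 3, 3))
#' @export
sign_matrix <- function(s) {
  s <- as.matrix(s)
  if (!is.numeric(s) || nrow(s) != ncol(s)) {
    stop("`s` must be a square numeric matrix", call. = FALSE)
  }
  n <- nrow(s)
  if (n < 3L) {
    stop("a sign network needs at least 3 actors", call. = FALSE)
  }
  off <- s[row(s) != col(s)]
  if (anyNA(off) || !all(off %in% c(-1, 1))) {
    stop("all off-diagonal entries must be exactly +1 or -1", call. = FALSE)
  }
  diag(s) <- 0
  structure(s, class = c("sign_matrix", "matrix", "array"))
}

#' Test for a sign matrix
#' @param x an object.
#' @return `TRUE` if `x` is a `sign_matrix`.
#' @export
is_sign_matrix <- function(x) inherits(x, "sign_matrix")

n_actors <- function(m) nrow(m)

offdiag <- function(m) m[row(m) != col(m)]

#' Archetype specification
#'
#' The recurring terminal class graphs of the dynamics come in four
#' archetypes: the symmetric two-clique Heider balance (`"HB"`), the
#' two-class asymmetric graph (`"CII"`), and the generic three- and
#' four-class asymmetric graphs (`"CIII"`, `"CIV"`).  A `template_spec`
#' names the archetype together with its class sizes `N1, N2[, N3[, N4]]`.
#'
#' Trailing zero sizes are allowed and denote degenerate cases (e.g.
#' `HB` with `N2 = 0` is a single all-friendly clique); a zero size before
#' a nonzero one is rejected.
#'
#' @param kind one of `"HB"`, `"CII"`, `"CIII"`, `"CIV"`.
#' @param sizes integer vector of class sizes; length 2 for HB/CII, 3 for
#'   CIII, 4 for CIV.
#' @return a `template_spec` object.
#' @examples
#' template_spec("CIII", c(3, 3, 1))
#' @export
template_spec <- function(kind, sizes) {
  kind <- match.arg(kind, c("HB", "CII", "CIII", "CIV"))
  want <- c(HB = 2L, CII = 2L, CIII = 3L, CIV = 4L)[[kind]]
  sizes <- as.integer(sizes)
  if (length(sizes) != want) {
    stop(sprintf("archetype %s takes %d class sizes, got %d",
                 kind, want, length(sizes)), call. = FALSE)
  }
  if (anyNA(sizes) || any(sizes < 0L)) {
    stop("class sizes must be non-negative integers", call. = FALSE)
  }
  nz <- which(sizes > 0L)
  if (length(nz) == 0L || max(nz) != length(nz)) {
    stop("empty classes are only allowed as trailing degenerate cases",
         call. = FALSE)
  }
  if (sum(sizes) < 3L) {
    stop("class sizes must sum to at least 3", call. = FALSE)
  }
  structure(list(kind = kind, sizes = sizes), class = "template_spec")
}

#' @export
print.template_spec <- function(x, ...) {
  cat(sprintf("<template_spec> %s (%s), n = %d\n",
              x$kind, paste(x$sizes, collapse = ", "), sum(x$sizes)))
  invisible(x)
}

# Block sign pattern of each archetype: entry [a, b] is the sign of the
# relations from class a towards class b (diagonal = within-class sign).
template_pattern <- function(kind) {
  switch(kind,
    HB = matrix(c(
      1, -1,
      -1, 1), 2, 2, byrow = TRUE),
    CII = matrix(c(
      1, -1,
      1, -1), 2, 2, byrow = TRUE),
    CIII = matrix(c(
      1, -1, -1,
      -1, 1, 1,
      1, -1, -1), 3, 3, byrow = TRUE),
    CIV = matrix(c(
      1, -1, 1, -1,
      -1, 1, -1, 1,
      -1, 1, -1, 1,
      1, -1, 1, -1), 4, 4, byrow = TRUE)
  )
}

#' Construct the sign matrix of an archetype
#'
#' Builds the block sign matrix of a class-graph archetype with the given
#' class sizes, actors ordered class-contiguously (class 1 first).  Within
#' each archetype, `pattern[a, b]` gives the sign of every relation from a
#' class-`a` actor towards a class-`b` actor; see [template_spec()] for the
#' archetypes.
#'
#' @param spec a [template_spec()].
#' @return a [sign_matrix()] of size `sum(spec$sizes)`.
#' @examples
#' make_template(template_spec("CII", c(5, 2)))
#' @export
make_template <- function(spec) {
  stopifnot(inherits(spec, "template_spec"))
  pat <- template_pattern(spec$kind)
  sizes <- spec$sizes
  n <- sum(sizes)
  cls <- rep.int(seq_along(sizes), sizes)
  s <- pat[cls, cls, drop = FALSE]
  diag(s) <- 0
  sign_matrix(s)
}

#' Self-evaluation index of each actor
#'
#' The self-evaluation ("looking-glass self") index of actor `i` sums the
#' reciprocal relations of all actors that `i` likes:
#' `F_i = (1/2) * sum_k (1 + s_ik) * s_ki`, i.e. each `k` with
#' `s_ik = +1` contributes `s_ki`, while disliked actors contribute
#' nothing.  `F_i` is an integer in `[-(n-1), n-1]`; a negative value
#' marks an actor whose liking is mostly unreciprocated.
#'
#' @param s a [sign_matrix()].
#' @return a tibble with columns `actor` and `f`.
#' @examples
#' self_evaluation(make_template(template_spec("CII", c(5, 2))))
#' @export
self_evaluation <- function(s) {
  if (!is_sign_matrix(s)) s <- sign_matrix(s)
  n <- n_actors(s)
  f <- vapply(seq_len(n), function(i) {
    liked <- which(s[i, ] == 1)
    sum(s[liked, i])
  }, numeric(1))
  tibble::tibble(actor = seq_len(n), f = as.integer(f))
}

#' Convert a network matrix to an edge-list tibble
#'
#' @param m a [relation_matrix()] or [sign_matrix()].
#' @return a tibble with columns `i`, `j` (1-based actor indices, `i != j`)
#'   and `value`.
#' @export
as_edge_list <- function(m) {
  n <- n_actors(m)
  idx <- which(row(m) != col(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tibble::tibble(i = idx[, 1], j = idx[, 2],
                 value = m[idx])
}

#' Rebuild a network matrix from an edge list
#'
#' @param edges a data frame with columns `i`, `j`, `value` covering every
#'   ordered pair of distinct actors `1..n`.
#' @param type `"relation"` or `"sign"`.
#' @return a [relation_matrix()] or [sign_matrix()].
#' @export
from_edge_list <- function(edges, type = c("relation", "sign")) {
  type <- match.arg(type)
  n <- max(edges$i, edges$j)
  m <- matrix(0, n, n)
  m[cbind(edges$i, edges$j)] <- edges$value
  if (nrow(edges) != n * (n - 1)) {
    stop("edge list must cover every ordered pair of distinct actors",
         call. = FALSE)
  }
  if (type == "sign") sign_matrix(m) else relation_matrix(m)
}

#' Read / write network matrices as CSV
#'
#' Plain `n x n` numeric CSV without header; the diagonal is written as 0
#' and ignored on read.
#'
#' @param m a [relation_matrix()] or [sign_matrix()].
#' @param path file path.
#' @param type on read, `"relation"` or `"sign"`.
#' @return `write_matrix_csv()` returns `path` invisibly;
#'   `read_matrix_csv()` returns the matrix.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.table(unclass(m), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path, type = c("relation", "sign")) {
  type <- match.arg(type)
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  if (type == "sign") sign_matrix(m) else relation_matrix(m)
}
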
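#' Node classes of a frozen sign matrix
#'
#' Reduces a corner sign matrix to its classes of structurally equivalent
#' actors: the coarsest partition in which every within-class and
#' between-class block of relations carries a single sign.  On a fully
#' connected network such a partition is automatically equitable (all
#' members of a class have the same numbers of friendly out- and in-links
#' into every class), so it coincides with the signed equitable
#' ("color-refinement") partition the classification algorithm targets,
#' seeded by the per-node counts of friendly out-links `M(i)` and
#' friendly in-links `L(i)`.
#'
#' Refinement starts from a single block and repeatedly splits any block
#' that is not sign-uniform towards some block, grouping its members by
#' their sign pattern; a standard lattice argument shows the fixed point
#' is the unique coarsest sign-uniform partition, independent of node
#' labeling and of the split order.
#'
#' @param s a [sign_matrix()].
#' @return a `node_partition`: list with `membership` (integer class id
#'   per node, classes in canonical order) and `blocks` (list of integer
#'   node-index vectors).
#' @examples
#' refine_classes(make_template(template_spec("CIII", c(3, 3, 1))))
#' @export
refine_classes <- function(s) {
  if (!is_sign_matrix(s)) s <- sign_matrix(s)
  n <- n_actors(s)
  cls <- rep(1L, n)
  repeat {
    new_cls <- count_split(s, cls)
    if (is.null(new_cls)) new_cls <- sign_split(s, cls)
    if (is.null(new_cls)) break
    cls <- new_cls
  }
  canonical_partition(cls, s)
}

# Equitable (count) refinement step: split any block whose members differ
# in their numbers of friendly out- or in-links into some block.  Returns
# the refined membership vector, or NULL at a fixed point.
count_split <- function(s, cls) {
  ids <- sort(unique(cls))
  for (b in ids) {
    mb <- which(cls == b)
    if (length(mb) < 2L) next
    key <- vapply(mb, function(i) {
      paste(vapply(ids, function(a) {
        ma <- setdiff(which(cls == a), i)
        sprintf("%d.%d", sum(s[i, ma] == 1), sum(s[ma, i] == 1))
      }, character(1)), collapse = ";")
    }, character(1))
    if (length(unique(key)) > 1L) {
      cls[mb] <- max(cls) + as.integer(factor(key))
      return(cls)
    }
  }
  NULL
}

# Sign-uniformity step: split a block involved in a mixed-sign block pair.
# All split keys compare entries at identical third-node positions, which
# guarantees that two nodes lying in a common block of any coarser
# sign-uniform partition are never separated; within-block splits take the
# coarsest common coarsening of the "liked set including self" and "liked
# set excluding self" groupings for the same reason (the internal sign of
# the hidden coarser block may be either + or -).
sign_split <- function(s, cls) {
  ids <- sort(unique(cls))
  for (a in ids) {
    for (b in ids) {
      ma <- which(cls == a)
      mb <- which(cls == b)
      vals <- s[ma, mb]
      vals <- vals[vals != 0]
      if (length(unique(vals)) <= 1L) next
      if (a != b) {
        # rows of a towards b, aligned by member identity
        key <- vapply(ma, function(i) paste(s[i, mb], collapse = ","),
                      character(1))
        if (length(unique(key)) > 1L) {
          cls[ma] <- max(cls) + as.integer(factor(key))
          return(cls)
        }
        # rows all equal, so the columns must differ: split b instead
        key <- vapply(mb, function(j) paste(s[ma, j], collapse = ","),
                      character(1))
        cls[mb] <- max(cls) + as.integer(factor(key))
        return(cls)
      }
      grp <- within_block_split(s, ma)
      if (!is.null(grp)) {
        cls[ma] <- max(cls) + grp
        return(cls)
      }
    }
  }
  NULL
}

within_block_split <- function(s, ma) {
  out_incl <- lapply(ma, function(i) sort(c(i, ma[s[i, ma] == 1])))
  out_excl <- lapply(ma, function(i) ma[s[i, ma] == 1])
  in_incl <- lapply(ma, function(i) sort(c(i, ma[s[ma, i] == 1])))
  in_excl <- lapply(ma, function(i) ma[s[ma, i] == 1])
  for (keys in list(list(out_incl, out_excl), list(in_incl, in_excl))) {
    grp <- partition_join(set_groups(keys[[1]]), set_groups(keys[[2]]))
    if (max(grp) > 1L) return(grp)
  }
  # unreachable for the states this dynamics produces; last resort that
  # guarantees termination (may overshoot the coarsest partition)
  grp <- set_groups(out_excl)
  if (max(grp) > 1L) return(grp)
  NULL
}

set_groups <- function(sets) {
  key <- vapply(sets, function(x) paste(x, collapse = ","), character(1))
  as.integer(factor(key))
}

# Finest common coarsening of two group-id vectors over the same members:
# connected components of "same group in either".
partition_join <- function(g1, g2) {
  m <- length(g1)
  comp <- seq_len(m)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (g in list(g1, g2)) {
    for (v in unique(g)) {
      members <- which(g == v)
      r <- find(members[1])
      for (i in members[-1]) comp[find(i)] <- r
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  as.integer(factor(roots))
}

# Relabel classes into a canonical order: internal sign (+ first), size
# descending, then lexicographic block-sign row towards the other classes
# (with ties broken by the ordering that minimizes the key string).
canonical_partition <- function(cls, s) {
  ids <- unique(cls)
  c_n <- length(ids)
  sizes <- vapply(ids, function(a) sum(cls == a), integer(1))
  rel <- block_rel(s, cls, ids)
  ord <- order_classes(rel, sizes)
  ids <- ids[ord]
  membership <- match(cls, ids)
  blocks <- lapply(seq_len(c_n), function(a) which(membership == a))
  structure(list(membership = membership, blocks = blocks),
            class = "node_partition")
}

block_rel <- function(s, cls, ids) {
  c_n <- length(ids)
  rel <- matrix(NA_real_, c_n, c_n)
  for (a in seq_len(c_n)) {
    for (b in seq_len(c_n)) {
      ma <- which(cls == ids[a])
      mb <- which(cls == ids[b])
      vals <- s[ma, mb, drop = FALSE]
      vals <- vals[!outer(ma, mb, "==")]
      if (length(vals) == 0L) next  # size-1 class towards itself
      u <- unique(vals)
      rel[a, b] <- if (length(u) == 1L) u else NaN  # NaN marks mixed signs
    }
  }
  rel
}

order_classes <- function(rel, sizes) {
  c_n <- length(sizes)
  if (c_n == 1L) return(1L)
  perms <- candidate_perms(rel, sizes, use_sizes = TRUE)
  keys <- vapply(seq_len(nrow(perms)), function(r) {
    p <- perms[r, ]
    paste(c(sign_chr(diag(rel)[p]), sprintf("%04d", 9999L - sizes[p]),
            sign_chr(rel[p, p])), collapse = "")
  }, character(1))
  # internal sign first (+ before -), then size descending, then the
  # lexicographically smallest relation matrix
  perms[order(keys, method = "radix")[1], ]
}

# Candidate class orderings for canonicalization.  Classes are first
# distinguished by iterated isomorphism-invariant colors (internal sign,
# optionally size, then the sorted multiset of signed relations to every
# color); only permutations within residual color ties need to be
# explored, which keeps the search exact yet small for the class graphs
# the dynamics produces.  If a tie group is pathologically large the
# search is truncated (beyond the ~6-class graphs the archetypes cover,
# exactness is not guaranteed).
candidate_perms <- function(rel, sizes, use_sizes = TRUE, cap = 5040L) {
  c_n <- length(sizes)
  color <- if (use_sizes) {
    sprintf("%s|%04d", sign_chr(diag(rel)), 9999L - sizes)
  } else {
    sign_chr(diag(rel))
  }
  repeat {
    new_color <- vapply(seq_len(c_n), function(a) {
      nb <- sort(vapply(setdiff(seq_len(c_n), a), function(b) {
        paste(sign_chr(rel[a, b]), sign_chr(rel[b, a]), color[b])
      }, character(1)), method = "radix")
      paste(color[a], paste(nb, collapse = "/"))
    }, character(1))
    if (length(unique(new_color)) == length(unique(color))) break
    color <- new_color
  }
  base <- order(color, method = "radix")
  groups <- split(base, color[base])
  groups <- groups[order(vapply(groups, function(g) color[g[1]],
                                character(1)), method = "radix")]
  n_perms <- prod(factorial(lengths(groups)))
  if (n_perms > cap) {
    return(matrix(unlist(groups), nrow = 1))
  }
  per_group <- lapply(groups, function(g) {
    if (length(g) == 1L) return(matrix(g, 1, 1))
    matrix(g[permutations(length(g))], nrow = factorial(length(g)))
  })
  out <- per_group[[1]]
  for (pg in per_group[-1]) {
    out <- cbind(out[rep(seq_len(nrow(out)), each = nrow(pg)), ,
                     drop = FALSE],
                 pg[rep(seq_len(nrow(pg)), times = nrow(out)), ,
                    drop = FALSE])
  }
  out
}

sign_chr <- function(v) {
  out <- ifelse(is.na(v), ".", ifelse(is.nan(v), "!",
                ifelse(v > 0, "+", "-")))
  out[is.nan(v)] <- "!"
  out
}

permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' @export
print.node_partition <- function(x, ...) {
  cat(sprintf("<node_partition> %d classes, sizes %s\n",
              length(x$blocks),
              paste(lengths(x$blocks), collapse = ", ")))
  invisible(x)
}

#' Per-node class membership as a tibble
#' @param x a `node_partition`.
#' @param ... unused.
#' @return a tibble with `actor` and `class`.
#' @export
tidy.node_partition <- function(x, ...) {
  tibble::tibble(actor = seq_along(x$membership), class = x$membership)
}

#' Quotient class graph of a sign matrix
#'
#' Encodes a frozen state as the matrix of relations between node
#' classes plus the class sizes.  Every block of `s` induced by `p` must
#' carry a single sign; the within-class sign of a singleton class is
#' undefined and stored as `NA`.
#'
#' @param s a [sign_matrix()].
#' @param p a `node_partition` of `s`; defaults to [refine_classes()].
#' @return a `class_graph`: list with `c` (number of classes), `sizes`,
#'   and `rel` (`c x c` matrix of +1/-1, `NA` on singleton diagonals).
#' @examples
#' class_graph(make_template(template_spec("HB", c(4, 3))))
#' @export
class_graph <- function(s, p = refine_classes(s)) {
  if (!is_sign_matrix(s)) s <- sign_matrix(s)
  stopifnot(inherits(p, "node_partition"))
  cls <- p$membership
  ids <- seq_along(p$blocks)
  rel <- block_rel(s, cls, ids)
  if (any(is.nan(rel))) {
    bad <- which(is.nan(rel), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "inconsistent partition: block (%d, %d) mixes relation signs",
      bad[1], bad[2]), call. = FALSE)
  }
  structure(list(c = length(ids), sizes = lengths(p$blocks), rel = rel),
            class = "class_graph")
}

#' @export
print.class_graph <- function(x, ...) {
  cat(sprintf("<class_graph> %d classes, sizes (%s)\n", x$c,
              paste(x$sizes, collapse = ", ")))
  rel <- matrix(sign_chr(x$rel), x$c, x$c)
  rownames(rel) <- colnames(rel) <- seq_len(x$c)
  print(rel, quote = FALSE)
  invisible(x)
}

#' Block relations of a class graph as a tibble
#' @param x a `class_graph`.
#' @param ... unused.
#' @return a tibble with `from`, `to`, `sign`.
#' @export
tidy.class_graph <- function(x, ...) {
  idx <- expand.grid(from = seq_len(x$c), to = seq_len(x$c))
  tibble::tibble(from = idx$from, to = idx$to,
                 sign = x$rel[cbind(idx$from, idx$to)])
}

#' Canonical isomorphism key of a class graph
#'
#' Two class graphs receive the same key iff they are isomorphic as
#' signed digraphs with (`with_sizes = TRUE`) or without size labels.
#' Exact search over all class permutations (intended for up to ~6
#' classes).
#'
#' @param g a `class_graph`.
#' @param with_sizes include class sizes in the key.
#' @return a character key.
#' @export
canonical_key <- function(g, with_sizes = TRUE) {
  stopifnot(inherits(g, "class_graph"))
  perms <- candidate_perms(g$rel, g$sizes, use_sizes = with_sizes)
  keys <- vapply(seq_len(nrow(perms)), function(r) {
    p <- perms[r, ]
    body <- paste(sign_chr(g$rel[p, p]), collapse = "")
    if (with_sizes) {
      paste0(paste(g$sizes[p], collapse = ","), "#", body)
    } else {
      body
    }
  }, character(1))
  sort(keys, method = "radix")[1]
}

#' Match a class graph against the known archetypes
#'
#' Tries to map the classes of `g` onto the role order of each archetype
#' (HB, CII, CIII, CIV) so that every defined block sign matches the
#' archetype's pattern; undefined singleton within-class signs match
#' anything.  For HB the two interchangeable roles are ordered by size
#' (larger class first).
#'
#' @param g a `class_graph`.
#' @return a [template_spec()] with role-ordered sizes, or `NULL` when no
#'   archetype matches ("other").
#' @examples
#' identify_template(class_graph(make_template(template_spec("CIV", c(4, 3, 2, 1)))))
#' @export
identify_template <- function(g) {
  stopifnot(inherits(g, "class_graph"))
  kinds <- switch(as.character(g$c),
                  "1" = "HB", "2" = c("HB", "CII"), "3" = "CIII",
                  "4" = "CIV", character(0))
  for (kind in kinds) {
    pat <- template_pattern(kind)
    k <- ncol(pat)
    if (g$c == 1L) {
      # degenerate single clique: all-friendly HB with an empty class 2
      if (isTRUE(g$rel[1, 1] == 1)) {
        return(template_spec("HB", c(g$sizes[1], 0L)))
      }
      next
    }
    perms <- permutations(g$c)
    hits <- list()
    for (r in seq_len(nrow(perms))) {
      p <- perms[r, ]  # p[role] = class index of g taking that role
      rel <- g$rel[p, p]
      ok <- all(rel == pat | (is.na(rel) & row(rel) == col(rel)))
      if (isTRUE(ok)) hits[[length(hits) + 1L]] <- g$sizes[p]
    }
    if (length(hits) > 0L) {
      if (kind == "HB") {
        sz <- hits[[which.max(vapply(hits, `[`, integer(1), 1L))]]
      } else {
        sz <- hits[[1L]]
      }
      return(template_spec(kind, sz))
    }
  }
  NULL
}

#' One-call classification of a frozen state
#'
#' Convenience wrapper: refine classes, build the class graph, identify
#' the archetype and compute the canonical key.
#'
#' @param s a [sign_matrix()].
#' @return a one-row tibble with `kind` (`"HB"`, `"CII"`, `"CIII"`,
#'   `"CIV"` or `"other"`), `N1`..`N4` (role-ordered sizes, 0-padded; `NA`
#'   for "other"), `c`, and `key`.
#' @export
classify_state <- function(s) {
  g <- class_graph(s)
  tmpl <- identify_template(g)
  sz <- rep(NA_integer_, 4)
  kind <- "other"
  if (!is.null(tmpl)) {
    kind <- tmpl$kind
    sz <- rep(0L, 4)
    sz[seq_along(tmpl$sizes)] <- tmpl$sizes
  }
  tibble::tibble(kind = kind, N1 = sz[1], N2 = sz[2], N3 = sz[3],
                 N4 = sz[4], c = g$c, key = canonical_key(g, TRUE))
}

#' DOT rendering of a class graph
#'
#' Solid arrows are friendly relations, dashed arrows hostile ones;
#' within-class relations of classes of two or more actors are drawn as
#' self-loops.
#'
#' @param g a `class_graph`.
#' @return a character scalar of DOT source.
#' @export
class_graph_dot <- function(g) {
  stopifnot(inherits(g, "class_graph"))
  lines <- c("digraph class_graph {")
  for (a in seq_len(g$c)) {
    lines <- c(lines, sprintf('  c%d [label="class %d\\n(%d)"];',
                              a, a, g$sizes[a]))
  }
  for (a in seq_len(g$c)) {
    for (b in seq_len(g$c)) {
      v <- g$rel[a, b]
      if (is.na(v)) next
      lines <- c(lines, sprintf("  c%d -> c%d [style=%s];",
                                a, b, if (v > 0) "solid" else "dashed"))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' JSON rendering of a class graph
#'
#' Sizes plus the relation matrix as "+"/"-" strings (singleton
#' within-class relations as ".").
#'
#' @param g a `class_graph`.
#' @return a character scalar of JSON.
#' @export
class_graph_json <- function(g) {
  stopifnot(inherits(g, "class_graph"))
  rel <- matrix(sign_chr(g$rel), g$c, g$c)
  as.character(jsonlite::toJSON(
    list(sizes = g$sizes, rel = rel), auto_unbox = FALSE))
}

#' Class-graph diagram
#'
#' Classes on a circle; solid arrows friendly, dashed hostile; loops for
#' within-class relations are annotated on the node label.
#'
#' @param object a `class_graph`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.class_graph <- function(object, ...) {
  k <- object$c
  ang <- pi / 2 - 2 * pi * (seq_len(k) - 1) / max(k, 2)
  nodes <- tibble::tibble(
    class = seq_len(k), x = cos(ang), y = sin(ang),
    label = sprintf("%d\nn=%d%s", seq_len(k), object$sizes,
                    ifelse(is.na(diag(object$rel)), "",
                           ifelse(diag(object$rel) > 0, " (+)", " (−)"))))
  idx <- which(row(object$rel) != col(object$rel), arr.ind = TRUE)
  edges <- tibble::tibble(
    x = nodes$x[idx[, 1]], y = nodes$y[idx[, 1]],
    xend = nodes$x[idx[, 2]], yend = nodes$y[idx[, 2]],
    sign = ifelse(object$rel[idx] > 0, "friendly", "hostile"))
  shrink <- 0.82
  edges <- dplyr::mutate(edges,
    xend = .data$x + shrink * (.data$xend - .data$x),
    yend = .data$y + shrink * (.data$yend - .data$y))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(.data$x, .data$y, xend = .data$xend, yend = .data$yend,
                   linetype = .data$sign),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches")),
      curvature = 0) +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(.data$x, .data$y, label = .data$label)) +
    ggplot2::scale_linetype_manual(
      values = c(friendly = "solid", hostile = "dashed")) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void()
}
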
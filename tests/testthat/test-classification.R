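test_that("an all-friendly network collapses to a single class", {
  p <- refine_classes(sign_matrix(matrix(1, 6, 6)))
  expect_identical(length(p$blocks), 1L)
  g <- class_graph(sign_matrix(matrix(1, 6, 6)), p)
  expect_identical(g$sizes, 6L)
  expect_identical(g$rel[1, 1], 1)
})

test_that("archetype constructions round-trip through classification", {
  specs <- list(
    template_spec("HB", c(4, 3)),
    template_spec("CII", c(5, 2)),
    template_spec("CIII", c(3, 3, 1)),
    template_spec("CIII", c(4, 4, 1)),
    template_spec("CIV", c(4, 3, 2, 1)),
    template_spec("CIV", c(3, 3, 2, 1)))
  for (spec in specs) {
    s <- make_template(spec)
    g <- class_graph(s, refine_classes(s))
    expect_identical(sort(g$sizes), sort(spec$sizes),
                     info = spec$kind)
    tm <- identify_template(g)
    expect_identical(tm$kind, spec$kind, info = spec$kind)
    expect_identical(tm$sizes, spec$sizes, info = spec$kind)
  }
})

test_that("the two-clique balanced split is recovered even at equal sizes", {
  # equal clique sizes defeat any purely count-based seeding
  s <- make_template(template_spec("HB", c(4, 4)))
  p <- refine_classes(s)
  expect_identical(lengths(p$blocks), c(4L, 4L))
})

test_that("refinement matches the exhaustive partition oracle on small n", {
  set.seed(51)
  cases <- c(lapply(1:12, function(i) random_sign_matrix(sample(3:5, 1))),
             list(make_template(template_spec("CIII", c(2, 2, 1))),
                  make_template(template_spec("HB", c(3, 2)))))
  for (s in cases) {
    p <- refine_classes(s)
    oracle <- oracle_coarsest_partitions(s)
    expect_identical(length(oracle), 1L)
    expect_true(same_partition(p$membership, oracle[[1]]))
  }
})

test_that("classification is invariant under node relabeling", {
  set.seed(61)
  for (rep in 1:6) {
    ev <- evolve(random_initial(7))
    if (!ev$converged) next
    s <- ev$sign
    key <- canonical_key(class_graph(s), with_sizes = TRUE)
    perm <- sample(7)
    s2 <- permute_sign_matrix(s, perm)
    expect_identical(canonical_key(class_graph(s2), with_sizes = TRUE), key)
  }
})

test_that("refinement is idempotent", {
  set.seed(71)
  for (rep in 1:5) {
    s <- random_sign_matrix(6)
    p1 <- refine_classes(s)
    p2 <- refine_classes(s)
    expect_identical(p1$membership, p2$membership)
    # refining a matrix already grouped by p1 finds the same blocks
    expect_true(same_partition(p1$membership, refine_classes(s)$membership))
  }
})

test_that("canonical keys distinguish what they should", {
  g_hb <- class_graph(make_template(template_spec("HB", c(4, 3))))
  g_cii <- class_graph(make_template(template_spec("CII", c(4, 3))))
  expect_false(canonical_key(g_hb) == canonical_key(g_cii))

  g1 <- class_graph(make_template(template_spec("CIV", c(4, 3, 2, 1))))
  g2 <- class_graph(make_template(template_spec("CIV", c(3, 4, 2, 1))))
  expect_false(canonical_key(g1, TRUE) == canonical_key(g2, TRUE))
  expect_identical(canonical_key(g1, FALSE), canonical_key(g2, FALSE))
})

test_that("class graphs with mismatched block signs classify as other", {
  # an all-friendly 3-class graph is not a recognized archetype
  g <- structure(list(c = 3L, sizes = c(3L, 2L, 2L),
                      rel = matrix(1, 3, 3)), class = "class_graph")
  expect_null(identify_template(g))
  # three mutually hostile cliques: symmetric, but not two-clique balance
  pat <- diag(2, 3) - 1
  cls <- rep(1:3, times = c(3, 2, 2))
  s <- pat[cls, cls]
  expect_identical(classify_state(sign_matrix(s))$kind, "other")
})

test_that("class_graph rejects partitions with mixed blocks", {
  s <- make_template(template_spec("HB", c(4, 3)))
  bad <- structure(list(membership = rep(1L, 7),
                        blocks = list(1:7)), class = "node_partition")
  expect_error(class_graph(s, bad), "mixes relation signs")
})

test_that("DOT export mirrors the arrow conventions", {
  g <- class_graph(make_template(template_spec("CII", c(5, 2))))
  dot <- class_graph_dot(g)
  expect_match(dot, "digraph")
  expect_match(dot, "style=dashed")
  expect_match(dot, "style=solid")
  js <- class_graph_json(g)
  expect_match(js, '"sizes":\\[5,2\\]')
  expect_match(js, '"\\+"')
})
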
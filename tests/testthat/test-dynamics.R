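test_that("the derivative matches hand evaluation", {
  # all zeros: every product term vanishes
  z <- relation_matrix(matrix(0, 4, 4))
  expect_true(all(heider_rhs(z) == 0))
  # corners are fixed points: the (1 - x^2) factor vanishes
  set.seed(11)
  s <- random_sign_matrix(5)
  expect_true(all(heider_rhs(relation_matrix(unclass(s))) == 0))
  # n = 3, all relations 0.5: single k term, (1 - 0.25) * 0.25 = 0.1875
  h <- relation_matrix(matrix(0.5, 3, 3))
  d <- heider_rhs(h)
  expect_equal(offdiag_vals(d), rep(0.1875, 6))
})

test_that("a corner initial state converges immediately", {
  s <- make_template(template_spec("HB", c(4, 3)))
  ev <- evolve(relation_matrix(unclass(s)))
  expect_true(ev$converged)
  expect_identical(ev$t_end, 0)
  expect_identical(unclass(ev$sign), unclass(s))
})

test_that("trajectories stay bounded and converged states are generically stationary", {
  set.seed(21)
  n_conv <- 0; n_stat <- 0
  for (rep in 1:8) {
    ev <- evolve(random_initial(7))
    expect_lte(max(abs(unclass(ev$final))), 1)
    if (ev$converged) {
      expect_lte(corner_gap_test(ev$final), ev$tol)
      n_conv <- n_conv + 1
      n_stat <- n_stat + oracle_stationary(ev$sign)
    }
  }
  # the stop rule can accept a saddle-grazing first corner visit of a
  # cycling trajectory, but generic frozen states are stationary
  expect_gte(n_conv, 7)
  expect_gte(n_stat, n_conv - 1)
})

test_that("symmetric initial conditions stay symmetric and end balanced", {
  set.seed(31)
  n_bal <- 0; n_runs <- 10
  for (rep in seq_len(n_runs)) {
    m <- matrix(stats::runif(49, -1, 1), 7, 7)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    ev <- evolve(relation_matrix(m))
    expect_true(ev$converged)
    s <- unclass(ev$sign)
    expect_identical(s, t(s))
    if (balanced_triads(s)) n_bal <- n_bal + 1
  }
  # balance is the generic symmetric outcome (jammed symmetric states
  # are possible but rare)
  expect_gte(n_bal, n_runs - 1)
})

test_that("asymmetric random states converge to sign-stationary corners", {
  set.seed(41)
  ev <- evolve(random_initial(7))
  expect_true(ev$converged)
  s <- unclass(ev$sign)
  t_sums <- s %*% s
  expect_true(all(sign(t_sums[row(s) != col(s)]) ==
                    s[row(s) != col(s)]))
})

test_that("discretize requires a corner state", {
  x <- matrix(1 - 1e-9, 5, 5)
  expect_true(all(offdiag_vals(unclass(discretize(relation_matrix(x)))) == 1))
  x[2, 3] <- -(1 - 1e-9)
  s <- discretize(relation_matrix(x))
  expect_identical(s[2, 3], -1)
  x[4, 5] <- 0.5
  expect_error(discretize(relation_matrix(x)), "not a corner")
})

test_that("an even number of actors triggers a warning", {
  expect_warning(evolve(random_initial(4, seed = 5)), "even number")
  expect_silent(suppressMessages(evolve(random_initial(5, seed = 5))))
})

test_that("the trace option records a plottable trajectory", {
  ev <- evolve(random_initial(5, seed = 9), trace = TRUE)
  expect_true(!is.null(ev$trace))
  expect_true(all(abs(ev$trace$x) <= 1 + 1e-8))
  p <- autoplot(ev)
  expect_s3_class(p, "ggplot")
})
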
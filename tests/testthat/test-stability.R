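test_that("sign-condition stationarity matches hand-derived CII cases", {
  # N1 = 5 > N2 + 2 = 4: stationary
  rep5 <- is_stationary(make_template(template_spec("CII", c(5, 2))))
  expect_true(rep5$stationary)
  expect_identical(nrow(rep5$violating_links), 0L)

  # N1 = 4 <= N2 + 2 = 5: internal class-1 links have sum N1 - 2 - N2 = -1
  rep4 <- is_stationary(make_template(template_spec("CII", c(4, 3))))
  expect_false(rep4$stationary)
  internal1 <- rep4$violating_links$i <= 4 & rep4$violating_links$j <= 4
  expect_true(any(internal1))
  expect_true(all(rep4$violating_links$t_sum[internal1] == -1))

  # all-friendly corner: every triad sum is n - 2 > 0
  all_pos <- sign_matrix(matrix(1, 6, 6))
  rep_pos <- is_stationary(all_pos)
  expect_true(rep_pos$stationary)
})

test_that("zero triad sums are reported, not resolved", {
  # 4 actors: one clique pair vs one hostile pair gives T = 0 links
  s <- matrix(1, 4, 4)
  s[3, 4] <- s[4, 3] <- -1
  s[1, 3] <- s[3, 1] <- -1
  rep <- is_stationary(sign_matrix(s))
  expect_false(rep$stationary)
  expect_gt(nrow(rep$zero_sum_links) + nrow(rep$violating_links), 0)
  td <- tidy(rep)
  expect_true(all(c("i", "j", "t_sum", "problem") %in% names(td)))
})

test_that("closed-form stability agrees with the sign condition exhaustively", {
  for (n in 5:11) {
    for (kind in c("HB", "CII", "CIII", "CIV")) {
      for (sz in all_size_splits(kind, n)) {
        spec <- template_spec(kind, sz)
        s <- make_template(spec)
        expect_identical(
          template_stable(spec), is_stationary(s)$stationary,
          info = sprintf("%s (%s)", kind, paste(sz, collapse = ",")))
      }
    }
  }
})

test_that("closed-form self-evaluations agree with direct summation", {
  for (n in c(7, 9)) {
    for (kind in c("HB", "CII", "CIII", "CIV")) {
      for (sz in all_size_splits(kind, n)) {
        spec <- template_spec(kind, sz)
        tse <- template_self_evaluations(spec)
        f_direct <- oracle_self_evaluation(make_template(spec))
        cls <- rep.int(seq_along(sz), sz)
        expect_identical(as.numeric(tse$f[cls]), f_direct,
                         info = sprintf("%s (%s)", kind,
                                        paste(sz, collapse = ",")))
      }
    }
  }
})

test_that("degenerate trailing-zero templates delegate to lower archetypes", {
  # CIV with empty fourth class is a three-class graph with roles 1/2 swapped
  expect_identical(template_stable(template_spec("CIV", c(2, 5, 2, 0))),
                   template_stable(template_spec("CIII", c(5, 2, 2))))
  # CIII with empty third class is plain two-clique balance: always stable
  expect_true(template_stable(template_spec("CIII", c(2, 5, 0))))
  expect_true(template_stable(template_spec("HB", c(4, 0))))
})

test_that("stable four-class graphs give negative F in the small classes", {
  for (n in c(9, 11)) {
    for (sz in all_size_splits("CIV", n)) {
      spec <- template_spec("CIV", sz)
      if (!template_stable(spec)) next
      if (!(sz[2] > sz[4] && sz[1] > sz[3])) next
      f <- template_self_evaluations(spec)$f
      expect_true(all(f[3:4] < 0),
                  info = paste(sz, collapse = ","))
    }
  }
})
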
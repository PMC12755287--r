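test_that("Fisher exact p matches frozen enumeration values", {
  expect_equal(fisher_exact(table2x2(5, 5, 5, 5))$p_value, 1.0)
  expect_equal(fisher_exact(table2x2(1, 9, 9, 1))$p_value, 0.001093334,
               tolerance = 1e-6)
  expect_equal(fisher_exact(table2x2(0, 10, 5, 5))$p_value, 0.03250774,
               tolerance = 1e-6)
})

test_that("Fisher p equals both enumeration and fisher.test on random tables", {
  for (tb in random_tables(200, n_max = 30, seed = 21)) {
    a <- tb[["a"]]; b <- tb[["b"]]; c <- tb[["c"]]; d <- tb[["d"]]
    p <- fisher_exact(table2x2(a, b, c, d))$p_value
    expect_equal(p, oracle_fisher_p(a, b, c, d), tolerance = 1e-12)
    if (a + c > 0 && b + d > 0) {
      expect_equal(p,
                   fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("Fisher p is invariant under arm swap and double column swap", {
  for (tb in random_tables(100, n_max = 40, seed = 31)) {
    a <- tb[["a"]]; b <- tb[["b"]]; c <- tb[["c"]]; d <- tb[["d"]]
    p <- fisher_exact(table2x2(a, b, c, d))$p_value
    expect_equal(fisher_exact(table2x2(c, d, a, b))$p_value, p)
    expect_equal(fisher_exact(table2x2(b, a, d, c))$p_value, p)
  }
})

test_that("Pearson chi-square matches the closed form and chisq.test", {
  r <- pearson_chisq(table2x2(50, 50, 50, 50))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1.0)

  r <- pearson_chisq(table2x2(60, 40, 40, 60))
  expect_equal(r$statistic, 8.0)  # all expected counts are 50
  expect_equal(r$p_value, 0.004677735, tolerance = 1e-6)
  ref <- suppressWarnings(
    chisq.test(matrix(c(60, 40, 40, 60), 2, byrow = TRUE), correct = FALSE))
  expect_equal(r$p_value, unname(ref$p.value))

  degen <- pearson_chisq(table2x2(0, 100, 0, 100))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
})

test_that("Pearson statistic is zero exactly when ad = bc", {
  for (tb in random_tables(200, seed = 41)) {
    a <- tb[["a"]]; b <- tb[["b"]]; c <- tb[["c"]]; d <- tb[["d"]]
    if (a + c == 0 || b + d == 0) next
    stat <- pearson_chisq(table2x2(a, b, c, d))$statistic
    if (a * d == b * c) expect_equal(stat, 0) else expect_gt(stat, 0)
  }
})

test_that("test selection follows the context rules", {
  # simulation: Fisher iff N <= 50 or any cell < 5
  expect_equal(select_test(table2x2(2, 28, 6, 24), "simulation")$test_used,
               "fisher_exact")                       # N = 60, min cell 2
  expect_equal(select_test(table2x2(40, 360, 30, 370), "simulation")$test_used,
               "pearson_chisq")                      # N = 800, min cell 30
  expect_equal(select_test(table2x2(10, 15, 10, 15), "simulation")$test_used,
               "fisher_exact")                       # N = 50 boundary
  expect_equal(select_test(table2x2(5, 21, 5, 20), "simulation")$test_used,
               "pearson_chisq")                      # N = 51, min cell 5
  # empirical: chi-square iff N > 5000 and all cells >= 50
  expect_equal(select_test(table2x2(60, 2940, 90, 2910), "empirical")$test_used,
               "pearson_chisq")
  expect_equal(select_test(table2x2(49, 2951, 90, 2910), "empirical")$test_used,
               "fisher_exact")                       # one cell below 50
  expect_equal(select_test(table2x2(60, 2440, 90, 2410), "empirical")$test_used,
               "fisher_exact")                       # N = 5000 not > 5000
})

test_that("significance flag is two-sided p <= 0.05 with an inclusive tie", {
  r <- select_test(table2x2(1, 9, 9, 1), "simulation")
  expect_true(r$significant)
  expect_false(select_test(table2x2(5, 5, 5, 5), "simulation")$significant)
  # exactly at alpha counts as significant
  expect_true(.subset2(pfrnb:::.new_test_result(0.05, "fisher_exact", 0.05),
                       "significant"))
})
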
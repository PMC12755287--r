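test_that("the three named patterns and residual classes are assigned", {
  expect_equal(as.character(classify_triplet(0.04, 0.35, 0.55)), "CP")
  expect_equal(as.character(classify_triplet(0.04, 0.02, 0.05)), "SFW")
  expect_equal(as.character(classify_triplet(0.20, 0.15, 0.03)),
               "concordant_null")
  # significant + fragile + moderate robustness fits no named pattern
  expect_equal(as.character(classify_triplet(0.05, 0.10, 0.075)),
               "other_significant")
  # nonsignificant but unstable
  expect_equal(as.character(classify_triplet(0.5, 0.05, 0.01)),
               "other_nonsignificant")
})

test_that("pattern boundaries follow the inclusive/exclusive conventions", {
  # p = 0.05 is significant; mfq = 0.10 is fragile; rq = 0.227 is strong
  expect_equal(as.character(classify_triplet(0.05, 0.11, 0.227)), "CP")
  expect_equal(as.character(classify_triplet(0.05, 0.10, 0.0749)), "SFW")
  expect_equal(as.character(classify_triplet(0.0501, 0.11, 0.074)),
               "concordant_null")
  expect_error(classify_triplet(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("every triplet gets exactly one pattern (partition property)", {
  set.seed(91)
  p <- runif(500); mfq <- runif(500); rq <- runif(500)
  pat <- classify_triplet(p, mfq, rq)
  expect_false(anyNA(pat))
  expect_equal(sum(table(pat)), 500)
  expect_setequal(levels(pat),
                  c("CP", "SFW", "concordant_null", "other_significant",
                    "other_nonsignificant"))
})

test_that("raising rq at fixed p and mfq never moves a trial into SFW", {
  set.seed(92)
  for (i in 1:100) {
    p <- runif(1, 0, 0.05); mfq <- runif(1)
    rqs <- sort(runif(5))
    pats <- as.character(classify_triplet(rep(p, 5), rep(mfq, 5), rqs))
    sfw_idx <- which(pats == "SFW")
    if (length(sfw_idx) > 0) {
      expect_equal(sfw_idx, seq_along(sfw_idx))  # SFW only at the low-rq end
    }
  }
})

test_that("stable significant trials at rq >= 0.227 are always CP", {
  set.seed(93)
  p <- runif(200, 0, 0.05)
  mfq <- runif(200, 0.1000001, 1)
  rq <- runif(200, 0.227, 1)
  expect_true(all(classify_triplet(p, mfq, rq) == "CP"))
})

test_that("analyze_trial composes the module results", {
  tr <- analyze_trial(table2x2(0, 10, 5, 5), context = "simulation")
  expect_true(tr$test$significant)
  expect_equal(tr$fragility$fi, 1L)
  expect_equal(tr$fragility$mfq, 0.10)
  expect_equal(tr$rq, 0.50)   # |0 - 50| / 100
  expect_equal(tr$stability, "fragile")
  expect_equal(tr$robustness, "strong")
  # significant + fragile + strong is a residual significant pattern
  expect_equal(as.character(tr$pattern), "other_significant")

  neutral <- analyze_trial(table2x2(5, 5, 5, 5), context = "simulation")
  expect_equal(neutral$test$p_value, 1)
  expect_equal(neutral$rq, 0)
  expect_false(neutral$test$significant)

  extreme <- analyze_trial(table2x2(50, 0, 0, 50), context = "simulation")
  expect_equal(extreme$rq, 1.0)
  expect_true(extreme$test$significant)
  expect_equal(extreme$fragility$fi,
               oracle_fi(50, 0, 0, 50, "simulation")$fi)
})

test_that("the vectorised engine agrees with per-table analysis", {
  tabs <- random_tables(40, seed = 94)
  a <- vapply(tabs, `[[`, 0, "a"); b <- vapply(tabs, `[[`, 0, "b")
  c_ <- vapply(tabs, `[[`, 0, "c"); d <- vapply(tabs, `[[`, 0, "d")
  rec <- pfrnb:::.analyze_cells(a, b, c_, d, context = "simulation")
  expect_equal(nrow(rec), 40)
  expect_equal(sum(table(rec$pattern)), 40)  # partition sums to n
  for (i in c(1, 7, 23, 40)) {
    tr <- analyze_trial(table2x2(a[i], b[i], c_[i], d[i]),
                        context = "simulation")
    expect_equal(rec$p[i], tr$test$p_value)
    expect_equal(rec$fi[i], tr$fragility$fi)
    expect_equal(rec$rq[i], tr$rq)
    expect_equal(as.character(rec$pattern[i]), as.character(tr$pattern))
  }
})
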
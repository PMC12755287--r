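test_that("modified arm is the fewer-events arm, with deterministic ties", {
  expect_equal(modified_arm(table2x2(2, 18, 6, 14)),
               list(arm = 1L, n_mod = 20L))   # fewer events
  expect_equal(modified_arm(table2x2(5, 25, 5, 10)),
               list(arm = 2L, n_mod = 15L))   # event tie -> smaller arm
  expect_equal(modified_arm(table2x2(5, 10, 5, 10)),
               list(arm = 1L, n_mod = 15L))   # full tie -> arm 1
})

test_that("a single toggle flips a just-significant table", {
  # (0,10,5,5) is significant under Fisher (p ~ 0.0325); (1,9,5,5) is not
  # (p ~ 0.141), so the fragility index is 1 and MFQ = 0.10.
  fr <- fragility_index(table2x2(0, 10, 5, 5), context = "simulation")
  expect_equal(fr$fi, 1L)
  expect_equal(fr$modified_arm, 1L)
  expect_equal(fr$n_mod, 10L)
  expect_equal(fr$mfq, 0.10)
  expect_equal(fr$fq, 1 / 20)
  expect_equal(fr$direction, "to_nonsignificant")
  expect_false(fr$capped)
})

test_that("fragility index equals the brute-force search on random tables", {
  for (tb in random_tables(150, n_max = 40, seed = 51)) {
    a <- tb[["a"]]; b <- tb[["b"]]; c <- tb[["c"]]; d <- tb[["d"]]
    fr <- fragility_index(table2x2(a, b, c, d), context = "simulation")
    ref <- oracle_fi(a, b, c, d, "simulation")
    expect_equal(fr$fi, ref$fi,
                 info = sprintf("table (%d,%d,%d,%d)", a, b, c, d))
    expect_equal(fr$capped, ref$capped)
    expect_equal(fr$n_mod, ref$n_mod)
    expect_equal(fr$mfq, ref$fi / ref$n_mod)
  }
})

test_that("toggling fi - 1 outcomes never flips; fi does (uncapped tables)", {
  for (tb in random_tables(80, n_max = 40, seed = 61)) {
    a <- tb[["a"]]; b <- tb[["b"]]; c <- tb[["c"]]; d <- tb[["d"]]
    fr <- fragility_index(table2x2(a, b, c, d), context = "simulation")
    if (fr$capped) next
    ma <- modified_arm(table2x2(a, b, c, d))
    e_obs <- if (ma$arm == 1L) a else c
    oe <- if (ma$arm == 1L) c else a
    on <- if (ma$arm == 1L) c + d else a + b
    sig0 <- oracle_significant(e_obs, ma$n_mod - e_obs, oe, on - oe,
                               "simulation")
    # every split strictly closer than fi keeps the classification
    for (k in seq_len(fr$fi - 1)) {
      for (e in c(e_obs - k, e_obs + k)) {
        if (e < 0 || e > ma$n_mod) next
        expect_equal(
          oracle_significant(e, ma$n_mod - e, oe, on - oe, "simulation"),
          sig0)
      }
    }
    # at distance fi at least one side flips
    flipped <- any(vapply(c(e_obs - fr$fi, e_obs + fr$fi), function(e) {
      if (e < 0 || e > ma$n_mod) return(FALSE)
      oracle_significant(e, ma$n_mod - e, oe, on - oe,
                         "simulation") != sig0
    }, logical(1)))
    expect_true(flipped)
  }
})

test_that("nonsignificant tables get a reverse fragility index", {
  fr <- fragility_index(table2x2(5, 5, 5, 5), context = "simulation")
  expect_equal(fr$direction, "to_significant")
  expect_gte(fr$fi, 1L)
  # significant tables toggle toward nonsignificance
  fr2 <- fragility_index(table2x2(1, 9, 9, 1), context = "simulation")
  expect_equal(fr2$direction, "to_nonsignificant")
})

test_that("capped tables report fi = n_mod and MFQ = 1", {
  # A 1-vs-1 trial can never reach significance: capped, maximally stable.
  fr <- fragility_index(table2x2(0, 1, 1, 0), context = "simulation")
  expect_true(fr$capped)
  expect_equal(fr$fi, fr$n_mod)
  expect_equal(fr$mfq, 1)
})

test_that("MFQ bounds and the FQ relationship hold on random tables", {
  for (tb in random_tables(150, seed = 71)) {
    fr <- fragility_index(table2x2(tb[["a"]], tb[["b"]], tb[["c"]],
                                   tb[["d"]]), context = "simulation")
    expect_gte(fr$mfq, 0)
    expect_lte(fr$mfq, 1)
    expect_lte(fr$fq, fr$mfq)   # n_mod <= N
    if (!fr$capped) expect_gte(fr$fi, 1L)
    # 1:1 allocation: MFQ = 2 * FQ, so MFQ 0.10 <=> FQ 0.05
    if (tb[["a"]] + tb[["b"]] == tb[["c"]] + tb[["d"]]) {
      expect_equal(fr$mfq, 2 * fr$fq)
    }
  }
})

test_that("stability classification is fragile at or below 0.10", {
  expect_equal(classify_stability(0.10), "fragile")   # boundary inclusive
  expect_equal(classify_stability(0.102), "stable")
  expect_equal(classify_stability(0.052), "fragile")
  expect_equal(classify_stability(c(0, 1)), c("fragile", "stable"))
  expect_error(classify_stability(1.2), "\\[0, 1\\]")
  expect_error(classify_stability(-0.1), "\\[0, 1\\]")
})
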
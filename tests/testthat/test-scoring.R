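test_that("time term scales minutes by 0.04, caps at the no-visualization score", {
  expect_equal(time_term(15), 0.6)
  expect_equal(time_term(c(30, 60, 120, 180)), c(1.2, 2.4, 4.8, 7.2))
  expect_equal(time_term(NA), 9)
  expect_equal(time_term(240), 9)  # 0.04 * 240 = 9.6 would exceed the cap
  expect_error(time_term(-15), "non-negative")
  expect_error(time_term(45), "imaging frames")
})

test_that("transport index sums the components and ignores the collateral flag", {
  expect_equal(transport_index(0, 0, 15, 0, 0), 0.6)
  expect_equal(transport_index(9, 9, NA, 9, 9), 45)
  # worked bilateral example: mildly delayed left leg vs DBF-dominant right leg
  expect_equal(transport_index(3, 0, 60, 3, 0), 8.4)
  expect_equal(transport_index(3, 5, 60, 0, 5), 15.4)
  r <- make_read(3L, 5L, 60L, 0L, 5L, coll = FALSE)
  r_coll <- make_read(3L, 5L, 60L, 0L, 5L, coll = TRUE)
  expect_identical(score_reads(r, 240)$ti, score_reads(r_coll, 240)$ti)
  # pure function: repeated evaluation is bit-identical
  expect_identical(transport_index(3, 5, 60, 0, 5), transport_index(3, 5, 60, 0, 5))
})

test_that("invalid reads are rejected with the offending field named", {
  expect_error(transport_index(4, 0, 15, 0, 0), "K score")
  expect_error(transport_index(0, 1, 15, 0, 0), "D score")
  expect_error(validate_reads(make_read(N = 9L, t = 60L)), "N = 9")
  expect_error(validate_reads(make_read(N = 3L, t = NA)), "requires N = 9")
  expect_error(validate_reads(make_read(t = 45L)), "imaging frame")
  expect_error(validate_reads(make_read()[, -1]), "missing required column")
})

test_that("exhaustive enumeration respects the 0.6-45 TI range", {
  er <- enumerate_reads()
  ti <- transport_index(er$K, er$D, er$node_time_min, er$N, er$V)
  expect_equal(min(ti), 0.6)
  expect_equal(max(ti), 45)
  expect_true(all(ti >= 0.6 & ti <= 45))
})

test_that("censoring to the 120-min window snaps or re-scores node appearance", {
  base <- make_read(3L, 5L, 30L, 3L, 5L)
  cens <- censor_reads(base)
  expect_equal(cens$node_time_min, 60L)   # 30-min frame omitted: next seen at 60
  expect_equal(score_reads(base, 120)$ti - score_reads(base, 240)$ti, 1.2)

  late <- make_read(0L, 0L, 180L, 5L, 0L)
  cens_late <- censor_reads(late)
  expect_true(is.na(cens_late$node_time_min))
  expect_equal(cens_late$N, 9L)
  expect_equal(score_reads(late, 120)$ti - score_reads(late, 240)$ti, 5.8)

  kept <- make_read(5L, 5L, 120L, 5L, 5L)
  expect_identical(censor_reads(kept), kept)
  expect_equal(score_reads(kept, 120)$ti, score_reads(kept, 240)$ti)

  expect_error(censor_reads(base, integer(0)), "non-empty")
  expect_error(censor_reads(base, c(15, 45)), "subset")
})

test_that("censoring never decreases the TI and its smallest increase is 1.2", {
  er <- enumerate_reads()
  d <- score_reads(er, 120)$ti - score_reads(er, 240)$ti
  expect_true(all(d >= -1e-12))
  expect_equal(min(d[d > 1e-9]), 1.2)
})

test_that("binary criteria apply the stated dichotomies", {
  f <- binarize_reads(make_read(3L, 0L, 60L, 3L, 0L, FALSE))
  expect_false(any(unlist(f)))  # 60 min is not late; mild grades are not flags

  f <- binarize_reads(make_read(5L, 5L, NA, 9L, 9L, TRUE))
  expect_true(all(unlist(f)))

  f <- binarize_reads(make_read(9L, 0L, 120L, 0L, 0L, FALSE))
  expect_true(f$kinetics_delayed)
  expect_true(f$node_time_late)
  expect_false(f$dbf_present || f$nodes_not_visualized ||
                 f$vessel_not_visualized || f$collateral_present)
})
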
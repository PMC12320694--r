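test_that("Spearman correlation handles monotone and tied data", {
  expect_equal(spearman_test(1:4, c(10, 20, 30, 40))$estimate, 1)
  expect_equal(spearman_test(1:3, 3:1)$estimate, -1)
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- sample(1:5, n, replace = TRUE)  # heavy ties
    y <- sample(1:5, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_test(x, y)$estimate, cor(x, y, method = "spearman"))
    expect_equal(spearman_test(x, y)$estimate, cor(rank(x), rank(y)))
  }
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
  expect_error(spearman_test(1:2, 2:1), "at least 3")
})

test_that("exact Spearman p-values match full permutation enumeration", {
  skip_if_not_installed("e1071")
  set.seed(12)
  for (i in 1:8) {
    n <- sample(4:7, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    res <- spearman_test(x, y)
    orc <- sp_oracle(x, y)
    expect_true(res$exact)
    expect_equal(res$estimate, orc$rho)
    expect_equal(res$p_value, orc$p)
  }
})

test_that("large-sample Spearman p matches the t approximation of cor.test", {
  set.seed(13)
  x <- rnorm(30); y <- x + rnorm(30)
  res <- spearman_test(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_false(res$exact)
  expect_equal(res$estimate, unname(ct$estimate))
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-10)
})

test_that("Mann-Whitney U counts wins and the exact p matches enumeration", {
  res <- mann_whitney_test(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  # fully symmetric configuration: p must be exactly 1
  expect_equal(mann_whitney_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(14)
  for (i in 1:15) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    if (na + nb > 8) next
    a <- sample(1:4, na, replace = TRUE)  # ties across and within groups
    b <- sample(1:4, nb, replace = TRUE)
    res <- mann_whitney_test(a, b)
    orc <- mw_oracle(a, b)
    expect_true(res$exact)
    expect_equal(res$statistic, orc$U)
    expect_equal(res$p_value, orc$p)
    expect_true(res$p_value > 0 && res$p_value <= 1)
  }
  expect_error(mann_whitney_test(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney normal approximation matches wilcox.test", {
  set.seed(15)
  a <- rnorm(12); b <- rnorm(14, 0.8)
  res <- mann_whitney_test(a, b, exact_limit = 0, correct = FALSE)
  wt <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(res$statistic, unname(wt$statistic))
  expect_equal(res$p_value, wt$p.value, tolerance = 1e-10)
  res_cc <- mann_whitney_test(a, b, exact_limit = 0, correct = TRUE)
  wt_cc <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(res_cc$p_value, wt_cc$p.value, tolerance = 1e-10)
})

test_that("Wilcoxon signed-rank is exact for small n and matches oracles", {
  expect_error(wilcoxon_signed_rank_test(1:4, 1:4), "zero")
  # a single nonzero pair: both sign assignments equally extreme
  expect_equal(wilcoxon_signed_rank_test(c(1, 5), c(1, 3))$p_value, 1)
  set.seed(16)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    if (all(x == y)) next
    res <- wilcoxon_signed_rank_test(x, y)
    orc <- wsr_oracle(x, y)
    expect_true(res$exact)
    expect_equal(res$statistic, orc$V)
    expect_equal(res$p_value, orc$p)
  }
  # untied case: base R's exact signed-rank distribution is a valid oracle
  x <- c(1.3, 2.1, 0.4, 5.5, 3.2, 2.8)
  y <- c(2.0, 1.1, 0.9, 4.1, 3.9, 1.5)
  expect_equal(wilcoxon_signed_rank_test(x, y)$p_value,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
})

test_that("Wilcoxon normal approximation matches wilcox.test with ties", {
  set.seed(17)
  x <- sample(1:8, 25, replace = TRUE)
  y <- sample(1:8, 25, replace = TRUE)
  res <- wilcoxon_signed_rank_test(x, y, exact_limit = 0, correct = FALSE)
  wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE))
  expect_equal(res$p_value, wt$p.value, tolerance = 1e-10)
})

test_that("Kruskal-Wallis is tie-corrected and degenerates gracefully", {
  res <- kruskal_wallis_test(list(rep(2, 4), rep(2, 5)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  set.seed(18)
  g <- list(rnorm(8), rnorm(9, 0.5), rnorm(7, 1))
  res <- kruskal_wallis_test(g)
  kt <- kruskal.test(g)
  expect_equal(res$statistic, unname(kt$statistic))
  expect_equal(res$p_value, kt$p.value, tolerance = 1e-10)
  expect_error(kruskal_wallis_test(list(1:3)), "at least 2")
})

test_that("two-group Kruskal-Wallis equals the squared Mann-Whitney z", {
  set.seed(19)
  a <- rnorm(10); b <- rnorm(12, 0.6)  # untied continuous data
  p_kw <- kruskal_wallis_test(list(a, b))$p_value
  p_mw <- mann_whitney_test(a, b, exact_limit = 0, correct = FALSE)$p_value
  expect_equal(p_kw, p_mw, tolerance = 1e-10)
})

test_that("intra-rater ICC(A,1) behaves at the extremes and matches aov", {
  expect_equal(icc_intrarater(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  set.seed(20)
  r1 <- rnorm(1e4)
  r2 <- r1 + rnorm(1e4, sd = 25)  # agreement drowned in independent noise
  expect_lt(abs(icc_intrarater(r1, r2)), 0.1)
  m1 <- c(9, 6, 8, 7, 10, 6)
  m2 <- c(2, 1, 4, 1, 5, 2)
  expect_equal(icc_intrarater(m1, m2), icc_oracle(m1, m2))
  r3 <- r1 + rnorm(1e4, sd = 0.5)
  expect_equal(icc_intrarater(r1[1:50], r3[1:50]), icc_oracle(r1[1:50], r3[1:50]))
  expect_error(icc_intrarater(rep(3, 5), rep(3, 5)), "constant")
})
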
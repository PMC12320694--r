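test_that("LELI is the BMI-normalized sum of squared circumferences", {
  expect_equal(leli(rep(10, 5), 25), 20)
  expect_equal(leli(rep(35.4, 5), 25), 5 * 35.4^2 / 25)
  m <- rbind(rep(10, 5), rep(20, 5))
  expect_equal(leli(m, c(25, 25)), c(20, 80))
  expect_error(leli(c(10, 10, 10, 10), 25), "5 sites")
  expect_error(leli(rep(-1, 5), 25), "positive")
  expect_error(leli(rep(10, 5), 0), "bmi")
})

test_that("LELI scales quadratically in circumference and inversely in BMI", {
  set.seed(41)
  for (i in 1:25) {
    circ <- runif(5, 20, 60)
    bmi <- runif(1, 18, 35)
    s <- runif(1, 0.5, 2)
    expect_equal(leli(s * circ, bmi), s^2 * leli(circ, bmi))
    expect_equal(leli(circ, s * bmi), leli(circ, bmi) / s)
  }
})

test_that("%dLELI uses the reduction-positive sign convention", {
  expect_equal(pct_delta_leli(200, 200), 0)
  expect_equal(pct_delta_leli(250, 225), 10)
  expect_equal(pct_delta_leli(200, 203.6), -1.8)  # an increase shows as negative
  expect_error(pct_delta_leli(0, 100), "positive")
  expect_error(pct_delta_leli(100, -1), "positive")
})

test_that("%dLELI round-trips and is scale invariant", {
  set.seed(42)
  for (i in 1:25) {
    pre <- runif(1, 150, 300)
    r <- runif(1, -25, 60)
    expect_equal(pct_delta_leli(pre, pre * (1 - r / 100)), r)
    s <- runif(1, 0.1, 10)
    post <- runif(1, 100, 300)
    expect_equal(pct_delta_leli(s * pre, s * post), pct_delta_leli(pre, post))
  }
})

test_that("limb excess is the affected-minus-contralateral difference", {
  expect_equal(leli_excess(251.3, 200.2), 51.1)
  expect_equal(leli_excess(180, 180), 0)
  expect_equal(leli_excess(180, 200), -20)
  expect_error(leli_excess(-1, 200), "positive")
})
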
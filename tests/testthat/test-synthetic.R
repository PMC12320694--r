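test_that("configuration defaults are valid and bad configurations are rejected", {
  cfg <- cohort_config()
  expect_s3_class(cfg, "lymph_config")
  expect_equal(sum(cfg$stage_probs), 1)
  expect_error(cohort_config(stage_probs = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(cohort_config(severity_link = 1), "severity_link")
  expect_error(cohort_config(ti_outcome_rho = c(m1 = 0, m3 = -1, m6 = 0)), "ti_outcome_rho")
  expect_error(cohort_config(outcome_sds = c(m1 = 0, m3 = 5, m6 = 6.8)), "SD")
})

test_that("the generator is deterministic given (config, seed)", {
  cfg <- test_config()
  a <- generate_cohort(cfg, seed = 101)
  b <- generate_cohort(cfg, seed = 101)
  expect_identical(a$patients, b$patients)
  expect_identical(a$reads, b$reads)
  expect_identical(a$volumetry, b$volumetry)
  c <- generate_cohort(cfg, seed = 102)
  expect_false(identical(a$reads, c$reads))
})

test_that("every generated read is valid and affected limbs carry more volume", {
  cfg <- test_config(n = 200L)
  co <- generate_cohort(cfg, seed = 5)
  expect_silent(validate_reads(co$reads))
  vol <- co$volumetry[co$volumetry$timepoint == "pre", ]
  l <- leli(vol[paste0("c", 1:5)], vol$bmi)
  expect_gt(mean(l[vol$side == "affected"]), mean(l[vol$side == "contralateral"]))
})

test_that("large-sample component frequencies reproduce the target marginals", {
  cfg <- cohort_config()
  n <- 1e5
  reads <- withr::with_seed(31, lymphoti:::draw_affected_reads(rnorm(n), cfg))
  for (comp in c("K", "D", "N", "V")) {
    emp <- as.numeric(table(factor(reads[[comp]], levels = ti_score_levels))) / n
    expect_lt(max(abs(emp - cfg$marginals[[comp]])), 0.01)
    gof <- chisq.test(table(factor(reads[[comp]], levels = ti_score_levels)),
                      p = cfg$marginals[[comp]])
    expect_gt(gof$p.value, 0.01)
  }
  vis <- !is.na(reads$node_time_min)
  emp_t <- as.numeric(table(reads$node_time_min[vis])) / sum(vis)
  expect_lt(max(abs(emp_t - cfg$node_time_probs)), 0.01)
  # node time / node score consistency by construction
  expect_true(all(is.na(reads$node_time_min) == (reads$N == 9)))
})

test_that("zero copula link gives independent components", {
  cfg <- cohort_config(severity_link = 0)
  reads <- withr::with_seed(32, lymphoti:::draw_affected_reads(rnorm(2e4), cfg))
  ind <- suppressWarnings(chisq.test(table(reads$K, reads$D)))
  expect_gt(ind$p.value, 0.001)
})

test_that("generator mean TI matches the closed-form expectation", {
  cfg <- cohort_config()
  reads <- withr::with_seed(33, lymphoti:::draw_affected_reads(rnorm(1e5), cfg))
  ti <- transport_index(reads$K, reads$D, reads$node_time_min, reads$N, reads$V)
  expect_equal(mean(ti), expected_ti(cfg), tolerance = 0.15 / expected_ti(cfg))
})

test_that("stage-conditional mean TI increases with stage under a positive link", {
  cfg <- test_config(n = 3000L)
  co <- generate_cohort(cfg, seed = 6)
  ti <- score_reads(co$reads[co$reads$side == "affected", ], 240)$ti
  by_stage <- tapply(ti, co$patients$stage, mean)
  expect_true(all(diff(by_stage) > 0))
})

test_that("slope calibration hits its target and is monotone", {
  cfg <- cohort_config()
  expect_equal(calibrate_link(cfg, target_rho = 0), 0)
  s1 <- calibrate_link(cfg, target_rho = -0.366, n_cal = 1e5, seed = 1)
  s2 <- calibrate_link(cfg, target_rho = -0.55, n_cal = 1e5, seed = 1)
  expect_gt(s2, s1)
  expect_gt(s1, 0)
  # self-consistency on a fresh large sample
  cfg$outcome_slopes <- c(m1 = 0, m3 = s1, m6 = 0)
  big <- cohort_config(n_patients = 1e5)
  big$outcome_slopes <- cfg$outcome_slopes
  co <- generate_cohort(big, seed = 99)
  expect_equal(cohort_rho_3m(co), -0.366, tolerance = 0.02 / 0.366)
})

test_that("a zero outcome slope leaves TI and outcome uncorrelated", {
  cfg <- test_config(n = 45L, slopes = c(m1 = 0, m3 = 0, m6 = 0))
  rhos <- vapply(1:60, function(s) cohort_rho_3m(generate_cohort(cfg, seed = s)),
                 numeric(1))
  expect_lt(abs(mean(rhos)), 0.06)  # ~3 MC standard errors of 0
})

test_that("contralateral limbs are mostly normal with a rare elevated regime", {
  cfg <- test_config(n = 2000L)
  co <- generate_cohort(cfg, seed = 8)
  ti <- score_reads(co$reads[co$reads$side == "contralateral", ], 240)$ti
  expect_true(all(ti[ti <= 2] %in% c(0.6, 1.2)))
  elevated <- ti[ti > 2]
  expect_true(all(elevated %in% c(4.2, 5.4, 7.2, 8.4)))
  expect_equal(length(elevated) / 2000, 4 / 45, tolerance = 0.3)
})
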
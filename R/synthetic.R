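# Synthetic cohort generator. Emulates a 45-patient unilateral lower-extremity
# lymphedema series: a single latent severity per patient drives the clinical
# stage, the ordinal lymphoscintigraphy components (via a Gaussian copula
# thresholded at the target marginal quantiles), the node-appearance time, and
# the pre-operative volume excess. Postoperative %LELI change follows a linear
# outcome model in standardized TI_120 with Gaussian noise, whose slope is
# calibrated by bisection to a target population rank correlation.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the published cohort structure: 45 patients with Campisi
#' stage split 5/35/5 (stages 2/3/4); component-score marginals and
#' node-appearance-time distribution from the tabulated qualitative reads;
#' BMI 25.3 +/- 3.5 kg/m^2; contralateral LELI 200.2 +/- 18.8 with a mean
#' affected-limb excess of 51.1; mean %LELI reductions of 6.5/7.9/5.6% (SD
#' 4.9/5.0/6.8) at 1/3/6 months; and TI-outcome rank-correlation targets of
#' 0, -0.366 and -0.370 at 1, 3 and 6 months.
#'
#' @param n_patients Cohort size.
#' @param stage_probs Probabilities of Campisi stages 2/3/4 (named, sum 1).
#' @param marginals Named list of score probabilities over \{0,3,5,9\} for
#'   components `K`, `D`, `N`, `V`.
#' @param node_time_probs Distribution of node-appearance time (minutes) given
#'   that nodes are visualized (`N < 9`).
#' @param collateral_prob Probability of visible collateral flow.
#' @param severity_link Copula correlation between the latent severity and
#'   each component's latent variable, in \[0, 1).
#' @param outcome_means,outcome_sds Mean and SD (percent) of %LELI change at
#'   1/3/6 months (named `m1`, `m3`, `m6`).
#' @param ti_outcome_rho Target population Spearman correlation between TI_120
#'   and %LELI change per timepoint.
#' @param outcome_slopes Outcome-model slopes per timepoint (percent change
#'   per SD of TI). `NULL` means "calibrate on first use" — see
#'   [calibrate_config()].
#' @param ti_ref Reference mean/SD used to standardize TI inside the outcome
#'   model (display constants; rank correlations are invariant to them).
#' @param bmi_dist,age_dist,contra_leli_dist Normal mean/SD for BMI, age and
#'   contralateral pre-op LELI.
#' @param duration_dist Mean/SD (years) of lymphedema duration (lognormal,
#'   moment-matched).
#' @param excess_model Affected-limb LELI excess: `mean + link * z +
#'   N(0, sd)`, `z` the latent severity.
#' @param site_weights Relative contribution of each measurement site to the
#'   squared-circumference sum (normalized internally).
#' @param site_jitter Lognormal jitter SD applied to site weights per limb.
#' @param contra_elevated_prob Fraction of contralateral limbs drawn from the
#'   mildly elevated TI regime.
#' @return A `lymph_config` list.
#' @export
cohort_config <- function(
    n_patients = 45L,
    stage_probs = c(`2` = 5, `3` = 35, `4` = 5) / 45,
    marginals = list(
      K = c(`0` = 1, `3` = 16, `5` = 16, `9` = 12) / 45,
      D = c(`0` = 2, `3` = 7, `5` = 34, `9` = 2) / 45,
      N = c(`0` = 8, `3` = 6, `5` = 8, `9` = 23) / 45,
      V = c(`0` = 3, `3` = 13, `5` = 22, `9` = 7) / 45
    ),
    node_time_probs = c(`15` = 6, `30` = 5, `60` = 6, `120` = 5, `180` = 2) / 24,
    collateral_prob = 26 / 45,
    severity_link = 0.6,
    outcome_means = c(m1 = 6.5, m3 = 7.9, m6 = 5.6),
    outcome_sds = c(m1 = 4.9, m3 = 5.0, m6 = 6.8),
    ti_outcome_rho = c(m1 = 0, m3 = -0.366, m6 = -0.370),
    outcome_slopes = NULL,
    ti_ref = c(mean = 25.5, sd = 11.0),
    bmi_dist = c(mean = 25.3, sd = 3.5),
    age_dist = c(mean = 56, sd = 10),
    duration_dist = c(mean = 6.4, sd = 5.8),
    contra_leli_dist = c(mean = 200.2, sd = 18.8),
    excess_model = c(mean = 51.1, link = 10, sd = 18.8),
    site_weights = c(patella = 1600, above_patella = 3025, below_patella = 1444,
                     malleolus = 625, foot = 529),
    site_jitter = 0.05,
    contra_elevated_prob = 4 / 45) {
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(what, " must be non-negative and sum to 1", call. = FALSE)
    }
  }
  check_probs(stage_probs, "stage_probs")
  for (comp in c("K", "D", "N", "V")) {
    p <- marginals[[comp]]
    if (is.null(p) || length(p) != 4) stop("marginals$", comp, " must have 4 entries", call. = FALSE)
    check_probs(p, paste0("marginals$", comp))
  }
  check_probs(node_time_probs, "node_time_probs")
  if (severity_link < 0 || severity_link >= 1) {
    stop("severity_link must be in [0, 1)", call. = FALSE)
  }
  if (any(abs(ti_outcome_rho) >= 1)) stop("|ti_outcome_rho| must be < 1", call. = FALSE)
  if (any(outcome_sds <= 0) || bmi_dist[["sd"]] <= 0 || contra_leli_dist[["sd"]] <= 0) {
    stop("all SDs must be positive", call. = FALSE)
  }
  if (collateral_prob < 0 || collateral_prob > 1 ||
      contra_elevated_prob < 0 || contra_elevated_prob > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients), stage_probs = stage_probs,
         marginals = marginals, node_time_probs = node_time_probs,
         collateral_prob = collateral_prob, severity_link = severity_link,
         outcome_means = outcome_means, outcome_sds = outcome_sds,
         ti_outcome_rho = ti_outcome_rho, outcome_slopes = outcome_slopes,
         ti_ref = ti_ref, bmi_dist = bmi_dist, age_dist = age_dist,
         duration_dist = duration_dist, contra_leli_dist = contra_leli_dist,
         excess_model = excess_model,
         site_weights = site_weights / sum(site_weights),
         site_jitter = site_jitter,
         contra_elevated_prob = contra_elevated_prob),
    class = "lymph_config"
  )
}

#' Read a generator configuration from YAML
#'
#' Fields present in the file override [cohort_config()] defaults; `marginals`
#' entries and other named vectors follow the same naming.
#'
#' @param path YAML file.
#' @return A `lymph_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("stage_probs", "node_time_probs", "outcome_means", "outcome_sds",
               "ti_outcome_rho", "outcome_slopes", "ti_ref", "bmi_dist",
               "age_dist", "duration_dist", "contra_leli_dist", "excess_model",
               "site_weights")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$marginals)) raw$marginals <- lapply(raw$marginals, unlist)
  do.call(cohort_config, raw)
}

# draw an ordinal variable correlated with latent severity z through a
# Gaussian copula: threshold rho*z + sqrt(1-rho^2)*noise at the marginal
# quantiles so the target marginal is exact
ord_from_latent <- function(z, rho, probs, levels) {
  u <- stats::pnorm(rho * z + sqrt(1 - rho^2) * stats::rnorm(length(z)))
  levels[findInterval(u, cumsum(probs)[-length(probs)]) + 1L]
}

# Thresholds for the node-time latent conditional on node visualization.
# The time latent w_t and the node-score latent w_N share the severity z, so
# selecting on N < 9 (w_N below its quantile b) skews w_t low; thresholds are
# therefore set on the conditional law of w_t given w_N < b — a bivariate
# normal with correlation rho^2 — so that the time distribution GIVEN
# visualization equals node_time_probs exactly.
cond_time_thresholds <- function(rho, b, cum_probs) {
  cum_probs <- cum_probs[-length(cum_probs)]  # last cut is +Inf
  r <- rho^2
  if (r == 0) return(stats::qnorm(cum_probs))
  pb <- stats::pnorm(b)
  cdf <- function(q) {
    stats::integrate(function(x) {
      stats::dnorm(x) * stats::pnorm((b - r * x) / sqrt(1 - r^2))
    }, -Inf, q, rel.tol = 1e-10)$value / pb
  }
  vapply(cum_probs, function(p) {
    stats::uniroot(function(q) cdf(q) - p, c(-10, 10), tol = 1e-9)$root
  }, numeric(1))
}

# affected-limb reads given latent severities z (consumes RNG; call under a seed)
draw_affected_reads <- function(z, config) {
  n <- length(z)
  rho <- config$severity_link
  m <- config$marginals
  K <- ord_from_latent(z, rho, m$K, ti_score_levels)
  D <- ord_from_latent(z, rho, m$D, ti_score_levels)
  N <- ord_from_latent(z, rho, m$N, ti_score_levels)
  V <- ord_from_latent(z, rho, m$V, ti_score_levels)
  times <- as.integer(names(config$node_time_probs))
  b <- stats::qnorm(1 - m$N[["9"]])
  cuts <- cond_time_thresholds(rho, b, cumsum(config$node_time_probs))
  w_t <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
  t_all <- times[findInterval(w_t, cuts) + 1L]
  node_time <- ifelse(N == 9, NA_integer_, t_all)
  coll <- stats::pnorm(rho * z + sqrt(1 - rho^2) * stats::rnorm(n)) < config$collateral_prob
  tibble::tibble(K = K, D = D, node_time_min = node_time, N = N, V = V,
                 collateral = coll)
}

# contralateral reads: normal limbs plus a small mildly-elevated regime whose
# attainable TIs are {4.2, 5.4, 7.2, 8.4}
draw_contralateral_reads <- function(n, config) {
  node_time <- sample(c(15L, 30L), n, replace = TRUE, prob = c(0.7, 0.3))
  out <- tibble::tibble(
    K = rep(0L, n), D = rep(0L, n), node_time_min = node_time,
    N = rep(0L, n), V = rep(0L, n), collateral = rep(FALSE, n)
  )
  elev <- stats::runif(n) < config$contra_elevated_prob
  ne <- sum(elev)
  if (ne > 0) {
    out$K[elev] <- 3L
    out$V[elev] <- sample(c(0L, 3L), ne, replace = TRUE)
    out$node_time_min[elev] <- sample(c(30L, 60L), ne, replace = TRUE)
    out$collateral[elev] <- stats::runif(ne) < 0.5
  }
  out
}

#' Closed-form expected transport index under the generator marginals
#'
#' Sum of the component expectations plus the expected time term, with the
#' node-time distribution conditioned on node visualization (`N < 9`); the
#' copula correlation leaves all marginals, hence this expectation, unchanged.
#'
#' @param config A `lymph_config`.
#' @return Expected TI of an affected limb at the full window.
#' @export
expected_ti <- function(config = cohort_config()) {
  m <- config$marginals
  comp_mean <- function(p) sum(ti_score_levels * p)
  p_nv <- m$N[["9"]]
  times <- as.integer(names(config$node_time_probs))
  e_time <- p_nv * 9 + (1 - p_nv) * sum(pmin(0.04 * times, 9) * config$node_time_probs)
  comp_mean(m$K) + comp_mean(m$D) + comp_mean(m$N) + comp_mean(m$V) + e_time
}

# standardized TI entering the outcome model
z_ti <- function(ti, config) (ti - config$ti_ref[["mean"]]) / config$ti_ref[["sd"]]

#' Calibrate the outcome-model slope to a target rank correlation
#'
#' Finds, by monotone bisection on a large calibration sample, the slope `b`
#' such that the population Spearman correlation between TI_120 and the
#' outcome `mean - b * zTI + noise` equals `target_rho` (within `tol`). The
#' calibration sample (latent severities, reads, noise) is drawn once under
#' `seed` and held fixed, so the correlation is a deterministic decreasing
#' function of the slope.
#'
#' @param config A `lymph_config`.
#' @param target_rho Target Spearman correlation, |rho| < 1.
#' @param n_cal Calibration sample size (>= 10^4; default 10^5).
#' @param seed Seed for the calibration sample.
#' @param noise_sd Outcome noise SD (percent); defaults to the 3-month SD.
#' @param tol Calibration tolerance on the achieved correlation.
#' @return The slope (percent %LELI change per reference SD of TI).
#' @export
calibrate_link <- function(config = cohort_config(), target_rho = config$ti_outcome_rho[["m3"]],
                           n_cal = 1e5, seed = 1L,
                           noise_sd = config$outcome_sds[["m3"]], tol = 0.01) {
  if (abs(target_rho) >= 1) stop("|target_rho| must be < 1", call. = FALSE)
  if (n_cal < 1e4) stop("n_cal must be at least 10^4 for a stable calibration", call. = FALSE)
  if (target_rho == 0) return(0)
  sim <- withr::with_seed(as.integer(seed), {
    z <- stats::rnorm(n_cal)
    reads <- draw_affected_reads(z, config)
    list(ti = score_reads(reads, window = 120)$ti,
         eps = stats::rnorm(n_cal, 0, noise_sd))
  })
  rti <- rank(sim$ti)
  zti <- z_ti(sim$ti, config)
  f <- function(slope) stats::cor(rti, rank(-slope * zti + sim$eps))
  # f is decreasing in slope; bracket so f(lo) >= target >= f(hi)
  if (target_rho < 0) {
    lo <- 0; hi <- 1
    while (f(hi) > target_rho) {
      hi <- hi * 2
      if (hi > 1e6) stop("target correlation unattainable given the noise SD", call. = FALSE)
    }
  } else {
    hi <- 0; lo <- -1
    while (f(lo) < target_rho) {
      lo <- lo * 2
      if (lo < -1e6) stop("target correlation unattainable given the noise SD", call. = FALSE)
    }
  }
  mid <- (lo + hi) / 2
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm - target_rho) <= tol / 2 || (hi - lo) < 1e-9) break
    if (fm > target_rho) lo <- mid else hi <- mid
  }
  mid
}

#' Fill in calibrated outcome slopes
#'
#' Calibrates one slope per follow-up timepoint to the configuration's
#' `ti_outcome_rho` targets (a zero target gives slope zero without
#' simulation) and returns the configuration with `outcome_slopes` set.
#'
#' @inheritParams calibrate_link
#' @return The `lymph_config` with `outcome_slopes` populated.
#' @export
calibrate_config <- function(config = cohort_config(), n_cal = 1e5, seed = 1L, tol = 0.01) {
  months <- c("m1", "m3", "m6")
  slopes <- vapply(months, function(m) {
    calibrate_link(config, target_rho = config$ti_outcome_rho[[m]],
                   n_cal = n_cal, seed = seed,
                   noise_sd = config$outcome_sds[[m]], tol = tol)
  }, numeric(1))
  config$outcome_slopes <- slopes
  config
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort — patient covariates, bilateral lymphoscintigraphy
#' reads, and serial five-site circumference measurements — deterministically
#' from `(config, seed)`. Circumferences are synthesized backwards from target
#' LELI values (site weights with lognormal jitter, renormalized), so
#' [leli()] recovers the generated index exactly. If `config$outcome_slopes`
#' is `NULL` the slopes are first calibrated with [calibrate_config()] under
#' its default calibration seed.
#'
#' @param config A `lymph_config`.
#' @param seed Integer seed; the same `(config, seed)` pair always yields an
#'   identical cohort.
#' @return A `lymph_cohort`: list with tibbles `patients`, `reads`,
#'   `volumetry`, plus the `config` and `seed` used (provenance).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  if (is.null(config$outcome_slopes)) {
    message("outcome_slopes not set; calibrating (see calibrate_config())")
    config <- calibrate_config(config)
  }
  n <- config$n_patients
  seed <- as.integer(seed)
  res <- withr::with_seed(seed, {
    z <- stats::rnorm(n)
    stage_cuts <- stats::qnorm(cumsum(config$stage_probs))
    stage <- c(2L, 3L, 4L)[findInterval(z, stage_cuts[-length(stage_cuts)]) + 1L]

    reads_aff <- draw_affected_reads(z, config)
    reads_con <- draw_contralateral_reads(n, config)

    age <- round(pmin(pmax(stats::rnorm(n, config$age_dist[["mean"]],
                                        config$age_dist[["sd"]]), 25), 85))
    bmi <- pmax(stats::rnorm(n, config$bmi_dist[["mean"]], config$bmi_dist[["sd"]]), 16)
    dm <- config$duration_dist[["mean"]]; ds <- config$duration_dist[["sd"]]
    sdlog <- sqrt(log(1 + (ds / dm)^2))
    duration <- round(stats::rlnorm(n, log(dm) - sdlog^2 / 2, sdlog), 1)
    affected_side <- sample(c("right", "left"), n, replace = TRUE, prob = c(0.4, 0.6))

    contra_pre <- pmax(stats::rnorm(n, config$contra_leli_dist[["mean"]],
                                    config$contra_leli_dist[["sd"]]), 120)
    ex <- config$excess_model
    excess <- pmax(ex[["mean"]] + ex[["link"]] * z + stats::rnorm(n, 0, ex[["sd"]]), 5)
    aff_pre <- contra_pre + excess

    ti120 <- score_reads(reads_aff, window = 120)$ti
    zti <- z_ti(ti120, config)
    months <- c("m1", "m3", "m6")
    pct <- sapply(months, function(m) {
      config$outcome_means[[m]] - config$outcome_slopes[[m]] * zti +
        stats::rnorm(n, 0, config$outcome_sds[[m]])
    })
    pct <- pmin(pct, 90)  # post-op LELI must stay positive
    aff_post <- aff_pre * (1 - pct / 100)
    contra_post <- contra_pre * (1 + matrix(stats::rnorm(n * 3, 0, 0.005), n, 3))

    patient_id <- sprintf("P%03d", seq_len(n))
    timepoints <- c("pre", "1m", "3m", "6m")
    leli_long <- tibble::tibble(
      patient_id = rep(patient_id, times = 8),
      side = rep(c("affected", "contralateral"), each = 4 * n),
      timepoint = rep(rep(timepoints, each = n), times = 2),
      leli = c(aff_pre, aff_post[, 1], aff_post[, 2], aff_post[, 3],
               contra_pre, contra_post[, 1], contra_post[, 2], contra_post[, 3]),
      bmi = rep(bmi, times = 8)
    )
    w0 <- config$site_weights
    jit <- matrix(stats::rnorm(nrow(leli_long) * 5, 0, config$site_jitter),
                  nrow(leli_long), 5)
    W <- matrix(w0, nrow(leli_long), 5, byrow = TRUE) * exp(jit)
    W <- W / rowSums(W)
    circ <- sqrt(leli_long$leli * leli_long$bmi * W)
    volumetry <- tibble::tibble(
      patient_id = leli_long$patient_id, side = leli_long$side,
      timepoint = leli_long$timepoint,
      c1 = circ[, 1], c2 = circ[, 2], c3 = circ[, 3], c4 = circ[, 4],
      c5 = circ[, 5], bmi = leli_long$bmi
    )

    reads <- dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(patient_id = patient_id, side = "affected"), reads_aff),
      dplyr::bind_cols(tibble::tibble(patient_id = patient_id, side = "contralateral"), reads_con)
    )
    patients <- tibble::tibble(
      patient_id = patient_id, age = age, stage = stage,
      duration_years = duration, bmi = bmi, affected_side = affected_side
    )
    list(patients = patients, reads = reads, volumetry = volumetry)
  })
  validate_reads(res$reads)
  structure(c(res, list(config = config, seed = seed)), class = "lymph_cohort")
}

#' @export
print.lymph_cohort <- function(x, ...) {
  cat("Synthetic/loaded lymphedema cohort:", nrow(x$patients), "patients,",
      nrow(x$reads), "limb reads,", nrow(x$volumetry), "volumetry rows",
      if (!is.na(x$seed)) paste0("(seed ", x$seed, ")") else "", "\n")
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes `reads.csv`, `volumetry.csv` and `patients.csv` in the schemas read
#' back by [load_cohort()]. Non-visualized node times are written as empty
#' fields; the collateral flag as 0/1.
#'
#' @param cohort A `lymph_cohort`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reads <- cohort$reads
  reads$collateral <- as.integer(reads$collateral)
  readr::write_csv(reads, file.path(dir, "reads.csv"), na = "")
  readr::write_csv(cohort$volumetry, file.path(dir, "volumetry.csv"), na = "")
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"), na = "")
  invisible(dir)
}
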
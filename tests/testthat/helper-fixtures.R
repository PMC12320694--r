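# Shared fixtures and independent brute-force oracles for the test suite.

make_read <- function(K = 0L, D = 0L, t = 15L, N = 0L, V = 0L, coll = FALSE) {
  tibble::tibble(K = K, D = D, node_time_min = t, N = N, V = V, collateral = coll)
}

# small cohort config with outcome slopes pre-set so pipeline tests skip the
# expensive calibration step (slope values are arbitrary for those tests)
test_config <- function(n = 12L, slopes = c(m1 = 0, m3 = 1, m6 = 1)) {
  cfg <- cohort_config(n_patients = n)
  cfg$outcome_slopes <- slopes
  cfg
}

# Mann-Whitney exact oracle: U from direct pairwise win-counting (not rank
# sums) and enumeration of every labeling of the pooled sample
mw_oracle <- function(a, b) {
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pooled), na)
  mu <- na * length(b) / 2
  u_obs <- u_stat(a, b)
  us <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  list(U = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

# Wilcoxon signed-rank exact oracle: per-pattern loop over all 2^n sign flips
wsr_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  vs <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  list(V = v_obs, p = mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9))
}

# Spearman exact oracle: mid-ranks + Pearson formula over every permutation
# (permutation matrix from e1071, independent of the implementation's own)
sp_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  P <- e1071::permutations(length(x))
  rho_obs <- stats::cor(rx, ry)
  rhos <- apply(P, 1, function(p) stats::cor(rx, ry[p]))
  list(rho = rho_obs, p = mean(abs(rhos) >= abs(rho_obs) - 1e-12))
}

# ICC(A,1) oracle: mean squares taken from an aov() fit rather than computed
# by hand
icc_oracle <- function(r1, r2) {
  n <- length(r1)
  d <- data.frame(y = c(r1, r2), subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- stats::anova(stats::aov(y ~ subj + rater, data = d))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

# Spearman(TI_120, 3-month %LELI change) of one cohort, computed through the
# exported scoring and volumetrics surface
cohort_rho_3m <- function(cohort) {
  aff <- cohort$reads[cohort$reads$side == "affected", ]
  ti <- score_reads(aff, window = 120)$ti
  names(ti) <- aff$patient_id
  vol <- cohort$volumetry[cohort$volumetry$side == "affected", ]
  l <- leli(vol[paste0("c", 1:5)], vol$bmi)
  pre <- l[vol$timepoint == "pre"]
  names(pre) <- vol$patient_id[vol$timepoint == "pre"]
  post <- l[vol$timepoint == "3m"]
  names(post) <- vol$patient_id[vol$timepoint == "3m"]
  ids <- names(pre)
  pct <- pct_delta_leli(pre[ids], post[ids])
  spearman_test(ti[ids], pct)$estimate
}
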
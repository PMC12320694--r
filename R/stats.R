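# Nonparametric test battery. All tests are two-sided. Small samples get
# exact p-values by enumeration (which remains valid under ties, unlike the
# exact paths of the base distribution functions); larger samples use the
# standard tie-corrected approximations. Thresholds for switching are fixed:
# permutation Spearman up to n = 9, exact Mann-Whitney up to combined n = 10,
# exact signed-rank up to 15 nonzero pairs.

new_lymph_test <- function(method, statistic, p_value, n, exact, estimate = NULL) {
  structure(
    list(method = method, statistic = statistic, p_value = p_value,
         n = n, exact = exact, estimate = estimate),
    class = "lymph_test"
  )
}

#' @export
print.lymph_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$estimate)) cat("  estimate =", format(x$estimate), "\n")
  cat("  statistic =", format(x$statistic),
      " p =", format.pval(x$p_value, digits = 4),
      " n =", paste(x$n, collapse = "/"),
      if (x$exact) " (exact)" else " (approximate)", "\n")
  invisible(x)
}

# all permutations of v as a matrix (length(v)! rows); recursion is vectorized
# per level so n = 9 (362,880 rows) stays fast enough for the exact path
perm_matrix <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L, 1L))
  parts <- vector("list", n)
  for (i in seq_len(n)) {
    parts[[i]] <- cbind(v[i], perm_matrix(v[-i]), deparse.level = 0)
  }
  do.call(rbind, parts)
}

#' Spearman rank correlation test
#'
#' Tie-corrected Spearman correlation: the Pearson correlation of mid-ranks.
#' For `n <= exact_limit` the two-sided p-value is exact, from full
#' enumeration of all permutations of one variable's ranks (valid under ties);
#' otherwise it uses the t approximation with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @param exact_limit Largest n for the exact permutation p-value.
#' @return A `lymph_test` with `estimate` = rho.
#' @export
spearman_test <- function(x, y, exact_limit = 9) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("correlation undefined: constant input", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_limit) {
    perms <- perm_matrix(seq_len(n))
    ry_perm <- matrix(ry[perms], nrow(perms), n)
    s <- as.numeric(ry_perm %*% rx)
    rho_all <- (s - n * mean(rx) * mean(ry)) / ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    exact <- TRUE
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE))
    p <- max(p, .Machine$double.xmin)
    exact <- FALSE
  }
  new_lymph_test("Spearman rank correlation", statistic = rho, p_value = p,
                 n = n, exact = exact, estimate = rho)
}

#' Mann-Whitney U test (two independent groups)
#'
#' U counts the wins of group `a` over group `b` (ties count one half). For
#' combined samples up to `exact_limit` the two-sided p-value comes from exact
#' enumeration of all group labelings of the pooled mid-ranks, so it remains
#' exact under ties; larger samples use the tie-corrected normal
#' approximation, with continuity correction unless `correct = FALSE`.
#'
#' @param a,b Numeric vectors (each non-empty, combined length >= 3).
#' @param exact_limit Largest combined n for the exact p-value.
#' @param correct Apply the continuity correction in the normal approximation.
#' @return A `lymph_test`; `statistic` is U for group `a`.
#' @export
mann_whitney_test <- function(a, b, exact_limit = 10, correct = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b); n <- na + nb
  if (na == 0 || nb == 0) stop("both groups must be non-empty", call. = FALSE)
  if (n < 3) stop("need at least 3 observations in total", call. = FALSE)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (n <= exact_limit) {
    idx <- utils::combn(n, na)
    Us <- colSums(matrix(r[idx], na, ncol(idx))) - na * (na + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    exact <- TRUE
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- (na * nb / 12) * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      num <- U - mu
      if (correct) num <- num - sign(num) * 0.5
      p <- min(1, 2 * stats::pnorm(abs(num) / sqrt(sigma2), lower.tail = FALSE))
    }
    exact <- FALSE
  }
  new_lymph_test("Mann-Whitney U test", statistic = U, p_value = p,
                 n = c(na, nb), exact = exact)
}

#' Wilcoxon signed-rank test (paired samples)
#'
#' Differences `x - y` are ranked by absolute value after dropping zeros; the
#' statistic is the positive rank sum. Up to `exact_limit` nonzero pairs the
#' two-sided p-value is exact via enumeration of all sign assignments (valid
#' under tied ranks); otherwise the tie-corrected normal approximation is
#' used.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_limit Largest number of nonzero differences for the exact
#'   p-value.
#' @param correct Apply the continuity correction in the normal approximation.
#' @return A `lymph_test`; `n` is the number of nonzero pairs.
#' @export
wilcoxon_signed_rank_test <- function(x, y, exact_limit = 15, correct = TRUE) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero", call. = FALSE)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= exact_limit) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- as.numeric(signs %*% r)
    p <- mean(abs(Vs - mu) >= abs(V - mu) - 1e-9)
    exact <- TRUE
  } else {
    sigma2 <- sum(r^2) / 4
    num <- V - mu
    if (correct) num <- num - sign(num) * 0.5
    p <- min(1, 2 * stats::pnorm(abs(num) / sqrt(sigma2), lower.tail = FALSE))
    exact <- FALSE
  }
  new_lymph_test("Wilcoxon signed-rank test", statistic = V, p_value = p,
                 n = n, exact = exact)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom. When every pooled value is identical the tie correction removes
#' all rank variance; by convention H = 0 and p = 1.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return A `lymph_test`; `n` gives per-group sizes.
#' @export
kruskal_wallis_test <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  grp <- rep(seq_along(groups), sizes)
  Rj <- tapply(r, grp, sum)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / sizes) - 3 * (N + 1)
  ties <- table(r)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) {
    H <- 0
    p <- 1
  } else {
    H <- H / C
    p <- stats::pchisq(H, df = length(groups) - 1, lower.tail = FALSE)
  }
  new_lymph_test("Kruskal-Wallis rank-sum test", statistic = H,
                 p_value = min(1, max(p, .Machine$double.xmin)),
                 n = as.integer(sizes), exact = FALSE)
}

#' Intra-rater intraclass correlation (two-way, absolute agreement, single)
#'
#' ICC(A,1): the single-measure, absolute-agreement coefficient from the
#' two-way mixed-effects ANOVA decomposition, quantifying agreement between
#' two reading passes of the same rater over the same subjects.
#'
#' @param r1,r2 Paired ratings of the same n >= 3 subjects.
#' @return The ICC, a number in \[-1, 1\].
#' @export
icc_intrarater <- function(r1, r2) {
  keep <- stats::complete.cases(r1, r2)
  r1 <- r1[keep]; r2 <- r2[keep]
  n <- length(r1)
  if (length(r2) != n) stop("ratings must be paired", call. = FALSE)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  x <- cbind(r1, r2)
  if (stats::sd(x) == 0) stop("constant ratings: ICC undefined", call. = FALSE)
  k <- 2
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  mse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom == 0) stop("constant ratings: ICC undefined", call. = FALSE)
  (msr - mse) / denom
}
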
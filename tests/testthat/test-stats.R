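# brute-force one-way RM-ANOVA via explicit projection matrices
bruteforce_rmF <- function(y) {            # y: n x k matrix
  n <- nrow(y); k <- ncol(y)
  v <- as.vector(y)                        # subject fastest
  X_full <- model.matrix(~ factor(rep(1:k, each = n)) +
                           factor(rep(1:n, k)))
  X_red <- model.matrix(~ factor(rep(1:n, k)))
  P <- function(X) X %*% solve(crossprod(X), t(X))
  rss_full <- sum((v - P(X_full) %*% v)^2)
  rss_red <- sum((v - P(X_red) %*% v)^2)
  ((rss_red - rss_full) / (k - 1)) / (rss_full / ((k - 1) * (n - 1)))
}

test_that("pointwise RM-ANOVA matches the projection-matrix oracle and the design df", {
  a <- rm_anova_pointwise(array(rnorm(16 * 3 * 2), c(16, 3, 2)))
  expect_equal(c(a$df1, a$df2), c(2, 30))
  set.seed(51)
  for (i in 1:5) {
    y <- matrix(rnorm(15), 5, 3)
    mine <- rm_anova_pointwise(y)
    expect_equal(mine$F, bruteforce_rmF(y), tolerance = 1e-10)
  }
  # identical condition means (with subject-level variation) -> F ~ 0
  e <- matrix(rnorm(18), 6, 3)
  y0 <- sweep(e, 2, colMeans(e)) + rnorm(6)
  expect_equal(rm_anova_pointwise(y0)$F, 0, tolerance = 1e-12)
  expect_error(rm_anova_pointwise(matrix(rnorm(3), 1, 3)), "subjects")
  yna <- matrix(rnorm(15), 5, 3); yna[2, 2] <- NA
  expect_error(rm_anova_pointwise(yna), "missing")
})

test_that("RM-ANOVA F is invariant to per-subject constants and GG adjustment is conservative", {
  set.seed(52)
  y <- array(rnorm(8 * 3 * 10), c(8, 3, 10))
  f1 <- rm_anova_pointwise(y)
  y2 <- y + array(rep(rnorm(8, 0, 50), 30), c(8, 3, 10))
  f2 <- rm_anova_pointwise(y2)
  expect_equal(f1$F, f2$F, tolerance = 1e-10)
  # GG adjustment is conservative wherever the test could matter
  # (for F below ~1 shrinking both dfs can lower p; nothing is
  # significant there, so the standard formula is kept unmonotonized)
  p_unadj <- pf(f1$F, f1$df1, f1$df2, lower.tail = FALSE)
  rel <- p_unadj <= 0.1
  if (!any(rel)) {            # force one decisive point
    y[, 3, 1] <- y[, 3, 1] + 3
    f1 <- rm_anova_pointwise(y)
    p_unadj <- pf(f1$F, f1$df1, f1$df2, lower.tail = FALSE)
    rel <- p_unadj <= 0.1
  }
  expect_true(all(f1$p[rel] >= p_unadj[rel] - 1e-12))
})

test_that("Greenhouse-Geisser epsilon handles both extremes and matches a contrast-based oracle", {
  expect_equal(gg_epsilon(diag(3) * 2 + 1), 1)       # compound symmetry
  # one dominant difference direction -> lower bound 1/(k-1) = 0.5
  S <- tcrossprod(c(1, 0, -1)) + diag(3) * 1e-9
  expect_equal(gg_epsilon(S), 0.5, tolerance = 1e-6)
  # independent oracle via orthonormal contrasts: eps from eigenvalues of
  # C' S C where C spans the difference space
  set.seed(53)
  for (i in 1:5) {
    S <- cov(matrix(rnorm(40 * 4), 40, 4))
    k <- 4
    Cc <- qr.Q(qr(cbind(rep(1, k), matrix(rnorm(k * (k - 1)), k))))[, -1]
    lam <- eigen(t(Cc) %*% S %*% Cc, symmetric = TRUE)$values
    eps_o <- sum(lam)^2 / ((k - 1) * sum(lam^2))
    expect_equal(gg_epsilon(S), eps_o, tolerance = 1e-12)
  }
})

test_that("max-statistic permutation controls the family-wise error and detects large effects", {
  # alpha ~ 0: empty mask
  set.seed(54)
  y <- array(rnorm(8 * 3 * 20), c(8, 3, 20))
  pt <- permutation_correct(y, n_perm = 200, alpha = 1e-6, seed = 1)
  expect_false(any(pt$mask))
  # tiny group triggers exhaustive enumeration: (3!)^2 = 36 <= 100
  y2 <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  pt2 <- permutation_correct(y2, n_perm = 100, alpha = 0.05, seed = 1)
  expect_true(pt2$exhaustive)
  expect_length(pt2$null_max, 36)
  # a 10-SD condition effect is always detected
  hits <- replicate(20, {
    y3 <- array(rnorm(8 * 3 * 10), c(8, 3, 10))
    y3[, 3, 4] <- y3[, 3, 4] + 10
    any(permutation_correct(y3, n_perm = 200, alpha = 0.05,
                            seed = sample.int(1e6, 1))$mask[4])
  })
  expect_true(all(hits))
  expect_error(permutation_correct(y, n_perm = 50), "n_perm")
})

test_that("permutation p values are uniform under the null", {
  set.seed(55)
  pvals <- replicate(300, {
    y <- array(rnorm(6 * 3 * 1), c(6, 3, 1))
    permutation_correct(y, n_perm = 120, alpha = 0.05,
                        seed = sample.int(1e6, 1))$p_fwe[1]
  })
  # permutation p values are discrete, so ties are expected
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("paired t matches its formula, t.test, and handles degenerate input", {
  set.seed(56)
  a <- rnorm(12); b <- rnorm(12)
  mine <- paired_t(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter))
  flip <- paired_t(b, a)
  expect_equal(flip$t, -mine$t)
  expect_equal(paired_t(a, a)$t, 0)
})

test_that("trend contrasts reproduce the worked means and vanish under symmetry", {
  # subject matrix whose column means are the pain means
  set.seed(57)
  y <- matrix(rnorm(16 * 3, sd = 0.3), 16, 3)
  y <- sweep(y, 2, colMeans(y))
  y <- sweep(y, 2, c(2.78, 2.83, 3.34), `+`)
  lin <- trend_contrast(y, "linear")
  expect_equal(lin$estimate, -1 * 2.78 + 0 * 2.83 + 1 * 3.34,
               tolerance = 1e-10)
  expect_equal(lin$df1, 1); expect_equal(lin$df2, 15)
  sym <- matrix(rep(c(1.2, 5, 1.2), each = 10), 10, 3)
  expect_equal(trend_contrast(sym, "linear")$estimate, 0)
  eq <- matrix(2, 8, 3)
  expect_equal(trend_contrast(eq, "linear")$estimate, 0)
  expect_equal(trend_contrast(eq, "quadratic")$estimate, 0)
  # quadratic picks up a pure-curvature pattern
  quad <- sweep(matrix(rnorm(30, sd = 0.1), 10, 3), 2, c(1, 3, 1), `+`)
  expect_gt(abs(trend_contrast(quad, "quadratic")$estimate), 3)
})

test_that("RM-ANCOVA recovers slopes, flags degeneracy, and reduces to RM-ANOVA without covariates", {
  set.seed(58)
  n <- 16; k <- 3
  cond_eff <- c(0, 0.5, 1)
  cov1 <- matrix(rnorm(n * k), n, k)
  y <- sweep(-0.5 * cov1, 2, cond_eff, `+`) +
    matrix(rnorm(n * k, 0, 0.1), n, k)
  fit <- rm_ancova(y, list(c1 = cov1))
  expect_equal(fit$covariates$slope, -0.5, tolerance = 0.1)
  expect_equal(fit$covariates$df2, n * (k - 1) - (k - 1) - 1)
  # paper-style df: 3 covariates with n = 16 -> (1, 27)
  fit3 <- rm_ancova(y, list(c1 = cov1,
                            c2 = matrix(rnorm(n * k), n, k),
                            c3 = matrix(rnorm(n * k), n, k)))
  expect_equal(fit3$covariates$df2, rep(27, 3))
  # covariate identical to the dependent: slope 1, degenerate
  fitd <- rm_ancova(y, list(self = y))
  expect_equal(fitd$covariates$slope, 1, tolerance = 1e-8)
  expect_true(fitd$degenerate)
  # orthogonal covariate: slope within 3 SE of zero
  cov_o <- matrix(rnorm(n * k), n, k)
  fito <- rm_ancova(y, list(c1 = cov1, o = cov_o))
  expect_lt(abs(fito$covariates$slope[2]) /
              fito$covariates$se[2], 3)
  # zero-variance covariate drops out: condition F equals plain RM-ANOVA
  fit0 <- rm_ancova(y, list(z = matrix(5, n, k)))
  plain <- rm_anova_pointwise(y)
  expect_equal(fit0$condition$F, plain$F, tolerance = 1e-10)
  # collinear covariates are refused by name
  expect_error(rm_ancova(y, list(a = cov1, b = cov1 * 2 + 1e-8)),
               "collinear.*a.*b")
})

test_that("significant intervals are exact run-length scans", {
  t_ax <- seq(0, 0.099, by = 0.001)
  expect_equal(nrow(significant_intervals(rep(FALSE, 100), t_ax)), 0)
  m <- rep(FALSE, 100); m[21:30] <- TRUE
  iv <- significant_intervals(m, t_ax)
  expect_equal(iv$start_ms, 20)
  expect_equal(iv$end_ms, 29)
  expect_equal(iv$n_points, 10)
  set.seed(59)
  for (i in 1:5) {
    m <- runif(50) < 0.3
    iv <- significant_intervals(m, t_ax[1:50])
    # brute-force scan
    runs <- list(); j <- 1
    while (j <= 50) {
      if (m[j]) {
        s <- j
        while (j < 50 && m[j + 1]) j <- j + 1
        runs[[length(runs) + 1]] <- c(s, j)
      }
      j <- j + 1
    }
    expect_equal(nrow(iv), length(runs))
    if (length(runs)) {
      expect_equal(iv$start_ms, sapply(runs, function(r) t_ax[r[1]]) * 1000)
      expect_equal(iv$end_ms, sapply(runs, function(r) t_ax[r[2]]) * 1000)
    }
  }
})

test_that("fluence follows the spot-area formula", {
  expect_equal(fluence(1.50, 4), 11.94, tolerance = 1e-3)
  expect_equal(fluence(0, 4), 0)
  expect_equal(fluence(2.0, 4), 2.0 / (pi * 0.2^2), tolerance = 1e-12)
  expect_equal(fluence(2.0, 4), 15.92, tolerance = 1e-3)
  expect_error(fluence(1, 0), "diameter")
})
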
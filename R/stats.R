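#' Greenhouse-Geisser epsilon
#'
#' Sphericity-correction factor computed from the k x k covariance
#' matrix of the repeated conditions:
#' `eps = (sum lambda)^2 / ((k-1) sum lambda^2)` over the eigenvalues of
#' the double-centered covariance, clipped to `[1/(k-1), 1]`.
#'
#' @param S Condition covariance matrix (k x k).
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
#' @examples
#' gg_epsilon(diag(3))  # compound symmetry -> 1
gg_epsilon <- function(S) {
  k <- nrow(S)
  Jc <- diag(k) - matrix(1 / k, k, k)
  Sc <- Jc %*% S %*% Jc
  lam <- Re(eigen(Sc, symmetric = TRUE, only.values = TRUE)$values)
  num <- sum(lam)^2
  den <- (k - 1) * sum(lam^2)
  if (den <= 0) return(1)
  min(1, max(1 / (k - 1), num / den))
}

# vectorized one-way repeated-measures F over time: y is n x k x T
rm_anova_F <- function(y) {
  d <- dim(y); n <- d[1]; k <- d[2]; Tn <- d[3]
  Y <- matrix(y, n * k, Tn)                       # subject fastest, then cond
  cond <- rep(seq_len(k), each = n)
  subj <- rep(seq_len(n), k)
  gm <- colMeans(Y)
  mc <- rowsum(Y, cond) / n                       # k x T condition means
  ms <- rowsum(Y, subj) / k                       # n x T subject means
  ss_cond <- n * colSums(sweep(mc, 2, gm)^2)
  resid <- Y - mc[cond, , drop = FALSE] - ms[subj, , drop = FALSE] +
    rep(gm, each = n * k)
  ss_err <- colSums(resid^2)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fv <- (ss_cond / df1) / (ss_err / df2)
  list(F = Fv, df1 = df1, df2 = df2)
}

#' Pointwise one-way repeated-measures ANOVA
#'
#' At each time point, the within-subject one-way F for the condition
#' factor, the Greenhouse-Geisser epsilon estimated from the condition
#' covariance at that time point, and the epsilon-adjusted p value.
#'
#' @param y Numeric array subjects x conditions x time (a single time
#'   point may be passed as an n x k matrix). Missing cells are an error.
#' @param conditions Optional condition labels (dimension 2).
#' @return An object of class `lep_anova` (also a tidy tibble via
#'   [generics::tidy()]): per-time `F`, `df1`, `df2`, `epsilon`,
#'   `p` (uncorrected, GG-adjusted).
#' @export
rm_anova_pointwise <- function(y, conditions = NULL) {
  if (is.matrix(y)) y <- array(y, dim = c(dim(y), 1L))
  if (anyNA(y)) stop("missing cells are not supported (no imputation)")
  d <- dim(y)
  if (d[1] < 2 || d[2] < 2) stop("need >= 2 subjects and >= 2 conditions")
  fv <- rm_anova_F(y)
  eps <- vapply(seq_len(d[3]), function(t_)
    gg_epsilon(stats::cov(y[, , t_])), numeric(1))
  p <- stats::pf(fv$F, fv$df1 * eps, fv$df2 * eps, lower.tail = FALSE)
  structure(list(F = fv$F, df1 = fv$df1, df2 = fv$df2, epsilon = eps,
                 p = p, n = d[1], k = d[2],
                 conditions = conditions %||% paste0("c", seq_len(d[2]))),
            class = "lep_anova")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lep_anova <- function(x, ...) {
  cat(sprintf("pointwise RM-ANOVA: %d time points, df = (%d, %d), n = %d\n",
              length(x$F), x$df1, x$df2, x$n))
  invisible(x)
}

#' @export
tidy.lep_anova <- function(x, ...) {
  tibble::tibble(time_index = seq_along(x$F), F = x$F,
                 df1 = x$df1, df2 = x$df2,
                 epsilon = x$epsilon, p = x$p)
}

# all k! permutations of 1..k
perms_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, ifelse(sub >= i, sub + 1L, sub))
  }))
}

#' Max-statistic permutation correction over components x time
#'
#' Family-wise control of the pointwise repeated-measures F across all
#' components and time points of one analysis family: condition labels
#' are randomly relabeled within subject (all `k!` relabelings equally
#' likely), the maximum F over the whole family is collected per
#' permutation, and a point is significant when its permutation p value
#' `(1 + #{max-null >= F}) / (n_perm + 1)` is at most `alpha`. When the
#' group is small enough that `(k!)^n <= n_perm`, all relabelings are
#' enumerated exhaustively instead.
#'
#' @param y Array subjects x conditions x points, where points indexes
#'   the flattened components x time family.
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Family-wise significance level.
#' @param seed Seed for the random relabelings.
#' @return An object of class `lep_permtest`: `mask` (logical per
#'   point), `p_fwe` (permutation-corrected p), `F`, `null_max`
#'   (max-statistic null distribution), `threshold` (the (1-alpha)
#'   null quantile), `exhaustive`.
#' @export
permutation_correct <- function(y, n_perm = 2000, alpha = 0.05, seed = 1) {
  if (n_perm < 100) stop("`n_perm` must be >= 100")
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]")
  d <- dim(y); n <- d[1]; k <- d[2]
  obs <- rm_anova_F(y)
  old <- .Random.seed_exists(); set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  pk <- perms_of(k)
  n_all <- factorial(k)^n
  exhaustive <- is.finite(n_all) && n_all <= n_perm
  relabelings <- if (exhaustive) {
    idx <- rep(1L, n)
    out <- vector("list", n_all)
    for (i in seq_len(n_all)) {
      out[[i]] <- do.call(rbind, lapply(idx, function(j) pk[j, ]))
      # odometer increment over subjects
      for (s in seq_len(n)) {
        idx[s] <- idx[s] + 1L
        if (idx[s] <= nrow(pk)) break
        idx[s] <- 1L
      }
    }
    out
  } else {
    lapply(seq_len(n_perm), function(i)
      pk[sample.int(nrow(pk), n, replace = TRUE), , drop = FALSE])
  }
  null_max <- vapply(relabelings, function(rl) {
    yp <- y
    for (s in seq_len(n)) yp[s, , ] <- y[s, rl[s, ], ]
    max(rm_anova_F(yp)$F)
  }, numeric(1))
  p_fwe <- vapply(obs$F, function(f)
    (1 + sum(null_max >= f)) / (length(null_max) + 1), numeric(1))
  mask <- p_fwe <= alpha
  thr <- stats::quantile(null_max, 1 - alpha, names = FALSE, type = 1)
  structure(list(mask = mask, p_fwe = p_fwe, F = obs$F,
                 df1 = obs$df1, df2 = obs$df2,
                 null_max = null_max, threshold = thr,
                 alpha = alpha, exhaustive = exhaustive),
            class = "lep_permtest")
}

#' @export
print.lep_permtest <- function(x, ...) {
  cat(sprintf("max-F permutation test: %d points, %d permutations%s, %d significant at alpha = %g\n",
              length(x$F), length(x$null_max),
              if (x$exhaustive) " (exhaustive)" else "",
              sum(x$mask), x$alpha))
  invisible(x)
}

#' @export
tidy.lep_permtest <- function(x, ...) {
  tibble::tibble(point = seq_along(x$F), F = x$F, p_fwe = x$p_fwe,
                 significant = x$mask)
}

#' Paired t test (closed form)
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the per-subject differences,
#' two-sided, df = n - 1.
#'
#' @param a,b Per-subject values under the two conditions.
#' @return Tibble with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  n <- length(d)
  s <- stats::sd(d)
  t <- if (s == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else mean(d) / (s / sqrt(n))
  tibble::tibble(t = t, df = n - 1,
                 p = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE),
                 mean_diff = mean(d))
}

#' Polynomial trend contrast across ordered conditions
#'
#' Orthogonal polynomial contrast over the positive -> neutral ->
#' negative ordering: linear `(-1, 0, 1)` or quadratic `(1, -2, 1)` for
#' k = 3. Per subject the contrast score is formed and tested against
#' zero, giving F with df (1, n - 1).
#'
#' @param y Subjects x conditions matrix, columns in the tested order.
#' @param order `"linear"` or `"quadratic"`.
#' @return Tibble with `estimate` (contrast of condition means), `F`,
#'   `df1`, `df2`, `p`.
#' @export
trend_contrast <- function(y, order = c("linear", "quadratic")) {
  order <- match.arg(order)
  k <- ncol(y)
  cf <- if (k == 3) {
    if (order == "linear") c(-1, 0, 1) else c(1, -2, 1)
  } else {
    cp <- stats::contr.poly(k)
    cc <- cp[, if (order == "linear") 1 else 2]
    cc / max(abs(cc))
  }
  L <- as.vector(y %*% cf)
  n <- length(L)
  Fv <- n * mean(L)^2 / stats::var(L)
  tibble::tibble(estimate = mean(L), F = Fv, df1 = 1, df2 = n - 1,
                 p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE))
}

#' Repeated-measures analysis of covariance
#'
#' Within-subject linear model for one repeated factor with continuous
#' covariates entered jointly: the dependent variable and all covariates
#' are centered within subject (removing between-subject differences),
#' then `y ~ condition + covariates` is fit with pooled slopes. Error
#' df is `n(k-1) - (k-1) - p` for p covariates. Reports per-covariate
#' slope and F, and the covariate-adjusted condition F.
#'
#' @param y Subjects x conditions matrix of the dependent measure.
#' @param covariates Named list of subjects x conditions matrices.
#' @param collinearity_tol Error when the within-subject correlation
#'   between two covariates exceeds this.
#' @return List of class `lep_ancova`: `covariates` (tibble name, slope,
#'   se, F, df1, df2, p), `condition` (tibble F, df1, df2, p),
#'   `degenerate` flag.
#' @export
rm_ancova <- function(y, covariates, collinearity_tol = 0.999) {
  n <- nrow(y); k <- ncol(y); p <- length(covariates)
  stopifnot(p >= 1, !is.null(names(covariates)))
  ctr <- function(m) m - rowMeans(m)
  yc <- as.vector(ctr(y))
  Xcov <- vapply(covariates, function(m) as.vector(ctr(m)),
                 numeric(n * k))
  # a covariate constant within subject carries no within-subject
  # information: drop it, so the model reduces to the plain RM-ANOVA
  keep <- apply(Xcov, 2, function(v) stats::sd(v) > 0)
  dropped <- names(covariates)[!keep]
  covariates <- covariates[keep]
  Xcov <- Xcov[, keep, drop = FALSE]
  p <- length(covariates)
  if (p == 0) {
    av <- rm_anova_pointwise(array(y, dim = c(n, k, 1)))
    return(structure(list(
      covariates = tibble::tibble(name = dropped, slope = 0, se = NA_real_,
                                  F = 0, df1 = 1, df2 = av$df2,
                                  p = NA_real_),
      condition = tibble::tibble(F = av$F, df1 = av$df1, df2 = av$df2,
                                 p = av$p),
      degenerate = FALSE, dropped = dropped), class = "lep_ancova"))
  }
  if (p > 1) {
    cc <- stats::cor(Xcov)
    bad <- which(abs(cc) > collinearity_tol & upper.tri(cc), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("collinear covariates: %s and %s",
                   names(covariates)[bad[1, 1]],
                   names(covariates)[bad[1, 2]]))
  }
  cond <- factor(rep(seq_len(k), each = n))
  Xc <- stats::model.matrix(~cond)[, -1, drop = FALSE]
  X <- cbind(Xc, Xcov)
  df2 <- n * (k - 1) - (k - 1) - p
  fit <- stats::lm.fit(cbind(1, X), yc)
  rss <- sum(fit$residuals^2)
  degenerate <- rss < 1e-12 * sum(yc^2)
  sigma2 <- rss / df2
  XtXi <- chol2inv(chol(crossprod(cbind(1, X))))
  coefs <- fit$coefficients
  se <- sqrt(pmax(diag(XtXi), 0) * sigma2)
  cov_idx <- (1 + (k - 1)) + seq_len(p)       # after intercept + condition
  cov_tab <- tibble::tibble(
    name = names(covariates),
    slope = unname(coefs[cov_idx]),
    se = unname(se[cov_idx]),
    F = unname((coefs[cov_idx] / se[cov_idx])^2),
    df1 = 1, df2 = df2)
  cov_tab$p <- stats::pf(cov_tab$F, 1, df2, lower.tail = FALSE)
  # adjusted condition F: SS drop when removing condition columns
  fit0 <- stats::lm.fit(cbind(1, Xcov), yc)
  ss_cond <- sum(fit0$residuals^2) - rss
  Fc <- (ss_cond / (k - 1)) / sigma2
  cond_tab <- tibble::tibble(F = Fc, df1 = k - 1, df2 = df2,
                             p = stats::pf(Fc, k - 1, df2,
                                           lower.tail = FALSE))
  structure(list(covariates = cov_tab, condition = cond_tab,
                 degenerate = degenerate, dropped = dropped),
            class = "lep_ancova")
}

#' @export
print.lep_ancova <- function(x, ...) {
  cat("repeated-measures ANCOVA (within-subject centering, pooled slopes)\n")
  print(x$covariates)
  cat("condition (adjusted):\n"); print(x$condition)
  invisible(x)
}

#' Contiguous significant intervals from a mask
#'
#' Run-length scan of a logical mask into `[start, end]` intervals on
#' the supplied time axis, reported in ms.
#'
#' @param mask Logical vector.
#' @param time Time axis in s (same length).
#' @return Tibble with `start_ms`, `end_ms`, `n_points`.
#' @export
significant_intervals <- function(mask, time) {
  stopifnot(length(mask) == length(time))
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble::tibble(start_ms = time[starts[keep]] * 1000,
                 end_ms = time[ends[keep]] * 1000,
                 n_points = r$lengths[keep])
}

#' Radiant exposure (fluence) of a laser pulse
#'
#' `fluence = energy / (pi (d/2)^2)` with the spot diameter converted
#' to cm, giving J/cm^2.
#'
#' @param energy_J Pulse energy in joules.
#' @param spot_diameter_mm Spot diameter in mm.
#' @return Fluence in J/cm^2.
#' @export
#' @examples
#' fluence(1.50, 4)  # ~11.94 J/cm^2
fluence <- function(energy_J, spot_diameter_mm) {
  if (any(spot_diameter_mm <= 0)) stop("spot diameter must be > 0")
  r_cm <- spot_diameter_mm / 10 / 2
  energy_J / (pi * r_cm^2)
}
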
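# build a synthetic "source series" list with known spatial maps and
# time courses: X_i = M_i S + noise, maps sparse and well-separated
make_mixture <- function(n_blocks = 6, K = 3, nv = 400, nt = 80,
                         noise = 0, seed = 1, gains = NULL) {
  set.seed(seed)
  S <- matrix(0, K, nv)
  centers <- round(seq(nv / (K + 1), nv * K / (K + 1), length.out = K))
  for (k in seq_len(K))
    S[k, ] <- exp(-(seq_len(nv) - centers[k])^2 / (2 * 15^2))
  M <- vector("list", n_blocks)
  X <- vector("list", n_blocks)
  t_ax <- seq(0, 1 - 1 / nt, by = 1 / nt)
  for (i in seq_len(n_blocks)) {
    M[[i]] <- sapply(seq_len(K), function(k)
      exp(-(t_ax - 0.2 - 0.15 * k)^2 / (2 * 0.05^2)) *
        (if (is.null(gains)) 1 else gains[[i]][k]))
    X[[i]] <- M[[i]] %*% S + matrix(rnorm(nt * nv, 0, noise), nt, nv)
  }
  list(X = X, S = S, M = M)
}

test_that("PCA reduction is lossless at the data rank and stores block structure", {
  mx <- make_mixture(n_blocks = 4, K = 3, noise = 0)
  red <- stack_and_reduce(mx$X, n_pc = 3)
  expect_equal(nrow(red$U), 4 * 80)
  expect_equal(red$blocks$first_row, c(1, 81, 161, 241))
  rec <- reduction_reconstruct(red, 3)
  Xc <- do.call(rbind, mx$X)
  Xc <- Xc - rowMeans(Xc)
  expect_lt(sum((rec - Xc)^2) / sum(Xc^2), 1e-8)
  expect_equal(apply(red$Y, 1, var), rep(1, 3), tolerance = 1e-8)
})

test_that("PCA beats random projections in explained variance", {
  mx <- make_mixture(n_blocks = 4, K = 5, noise = 0.3, seed = 3)
  X <- do.call(rbind, mx$X); Xc <- X - rowMeans(X)
  red <- stack_and_reduce(mx$X, n_pc = 5)
  pca_ev <- sum((reduction_reconstruct(red, 5))^2)
  set.seed(4)
  for (i in 1:5) {
    Q <- qr.Q(qr(matrix(rnorm(nrow(Xc) * 5), ncol = 5)))
    rnd_ev <- sum((Q %*% (t(Q) %*% Xc))^2)
    expect_lt(rnd_ev, pca_ev + 1e-8)
  }
})

test_that("Infomax separates Laplacian mixtures (Amari index) and is seed-deterministic", {
  set.seed(5)
  n <- 5000
  S <- matrix(sample(c(-1, 1), 2 * n, TRUE) * rexp(2 * n), 2, n)
  A <- matrix(c(1, 0.6, -0.4, 1), 2, 2)
  X <- A %*% S
  # whiten
  ed <- eigen(tcrossprod(X) / n)
  Kw <- diag(1 / sqrt(ed$values)) %*% t(ed$vectors)
  Y <- Kw %*% X
  fit <- run_infomax(Y, 2, seed = 9)
  W_total <- fit$W %*% Kw
  P <- abs(W_total %*% A)
  amari <- function(P) {
    k <- nrow(P)
    (sum(rowSums(P / apply(P, 1, max)) - 1) +
       sum(colSums(P / rep(apply(P, 2, max), each = k)) - 1)) /
      (2 * k * (k - 1))
  }
  expect_lt(amari(P), 0.05)
  fit2 <- run_infomax(Y, 2, seed = 9)
  expect_identical(fit$W, fit2$W)
  fit3 <- run_infomax(Y, 2, seed = 10)
  expect_false(identical(fit$W, fit3$W))
})

test_that("ICASSO recovers the source count to within one on a well-separated simulation", {
  mx <- make_mixture(n_blocks = 6, K = 5, nv = 500, noise = 0.05, seed = 6)
  red <- stack_and_reduce(mx$X, n_pc = 8)
  ica <- run_icasso(red, K_candidates = 3:8, n_runs = 15, seed = 11)
  expect_true(abs(ica$K - 5) <= 1)
  expect_true(all(ica$stability >= 0.8))
  # the five true sources are represented by highly stable clusters
  match_stab <- sapply(seq_len(5), function(k)
    max(ica$stability[apply(abs(cor(t(ica$maps), mx$S[k, ])), 1,
                            which.max)]))
  expect_true(all(match_stab > 0.9))
  # determinism: identical inputs give identical selection and maps
  ica2 <- run_icasso(red, K_candidates = 3:8, n_runs = 15, seed = 11)
  expect_identical(ica$maps, ica2$maps)
  expect_warning(run_icasso(red, K_candidates = 5, n_runs = 1, seed = 1),
                 "degenerate")
})

test_that("back-reconstruction recovers generating time courses and condition gains", {
  gains <- list(c(1, 1, 1), c(1, 1, 1), c(1.3, 1, 1),
                c(1, 1, 1), c(1, 1, 1), c(1.3, 1, 1))
  mx <- make_mixture(n_blocks = 6, K = 3, noise = 0, seed = 7,
                     gains = gains)
  red <- stack_and_reduce(mx$X, n_pc = 3)
  fit <- run_infomax(red$Y, 3, seed = 2)
  nm <- lepsica:::normalize_maps(fit$maps)
  # exact case: data built from the group maps themselves round-trips
  M0 <- matrix(rnorm(40 * 3), 40, 3)
  X0 <- M0 %*% nm$maps
  tc0 <- back_reconstruct(list(maps = nm$maps), list(X0))
  for (k in 1:3)
    expect_gt(abs(cor(tc0$value[tc0$component == k],
                      M0[, k] - mean(M0[, k]))), 0.999)
  tcs <- back_reconstruct(list(maps = nm$maps, reduction = red), mx$X)
  # match recovered to true components by map correlation
  match <- apply(abs(cor(t(nm$maps), t(mx$S))), 2, which.max)
  # correlation with the generating time course (Infomax-limited)
  for (k in 1:3) {
    rec <- tcs$value[tcs$component == match[k]][1:80]  # block 1
    expect_gt(abs(cor(rec, mx$M[[1]][, k])), 0.99)
  }
  # gain ratio: block 3 vs block 1 peak of component 1 = 1.3
  for (k in c(1)) {
    v1 <- tcs$value[tcs$component == match[k]][1:80]
    v3 <- tcs$value[tcs$component == match[k]][(2 * 80 + 1):(3 * 80)]
    expect_equal(max(abs(v3)) / max(abs(v1)), 1.3, tolerance = 0.05)
  }
  # unmodulated component unchanged across blocks
  v1 <- tcs$value[tcs$component == match[2]][1:80]
  v3 <- tcs$value[tcs$component == match[2]][(2 * 80 + 1):(3 * 80)]
  expect_equal(max(abs(v3)) / max(abs(v1)), 1, tolerance = 0.01)
})

test_that("Z-maps standardize, threshold, and calibrate on null input", {
  g <- fx_grid(14)
  zm0 <- component_zmap(rep(0, g$n), g, smooth_fwhm = 0)
  expect_length(zm0$surviving, 0)
  set.seed(12)
  # unsmoothed standard-normal maps: suprathreshold fraction ~ 1 - Phi(3.1)
  fr <- replicate(40, {
    zm <- component_zmap(rnorm(g$n), g, smooth_fwhm = 0, z_threshold = 3.1)
    length(zm$surviving) / g$n
  })
  p0 <- 1 - pnorm(3.1)
  se <- sqrt(p0 * (1 - p0) / (40 * g$n))
  expect_lt(abs(mean(fr) - p0), 4 * se)
  # smoothing + peak bookkeeping
  v <- numeric(g$n); v[100] <- 10
  zm <- component_zmap(v, g)
  expect_true(all(zm$z[zm$surviving] >= zm$threshold))
})

test_that("group T maps floor degenerate variance and recover a consistent cluster", {
  g <- fx_grid(14)
  # identical maps across subjects: zero variance flagged, T finite
  m <- matrix(rep(rnorm(g$n), 4), 4, g$n, byrow = TRUE)
  gm <- group_tmap(m, g, t_threshold = 50)
  expect_true(length(gm$degenerate) == g$n)
  expect_true(all(is.finite(gm$t)))
  # one-voxel textbook t
  set.seed(13)
  x <- rnorm(6)
  m2 <- matrix(0, 6, g$n); m2[, 7] <- x
  gm2 <- group_tmap(m2, g, t_threshold = 1e9)
  expect_equal(gm2$t[7], mean(x) / (sd(x) / sqrt(6)), tolerance = 1e-10)
  # consistent simulated cluster: neighborhood of voxel v across subjects
  v <- 200
  d <- sqrt(colSums((t(g$pos) - g$pos[v, ])^2))
  blob <- exp(-d^2 / (2 * 20^2))
  m3 <- do.call(rbind, lapply(1:8, function(i) blob +
                                rnorm(g$n, 0, 0.05)))
  gm3 <- group_tmap(m3, g, t_threshold = 8)
  expect_gt(nrow(gm3$peaks), 0)
  top <- gm3$peaks[1, ]
  expect_lt(sqrt(sum((c(top$x, top$y, top$z) - g$pos[v, ])^2)), 15)
})

test_that("downstream statistics are invariant to component sign and order", {
  mx <- make_mixture(n_blocks = 6, K = 3, noise = 0.02, seed = 14)
  red <- stack_and_reduce(mx$X, n_pc = 3)
  fit <- run_infomax(red$Y, 3, seed = 3)
  nm <- lepsica:::normalize_maps(fit$maps)
  flip <- nm$maps * c(-1, 1, -1)
  reord <- flip[c(2, 3, 1), ]
  tc1 <- back_reconstruct(list(maps = nm$maps), mx$X)
  tc2 <- back_reconstruct(list(maps = reord), mx$X)
  # peak |amplitude| per block x component is permutation of the original
  p1 <- sort(round(tapply(abs(tc1$value),
                          paste(tc1$component, rep(1:6, each = 240)), max), 8))
  p2 <- sort(round(tapply(abs(tc2$value),
                          paste(tc2$component, rep(1:6, each = 240)), max), 8))
  expect_equal(as.vector(p1), as.vector(p2))
})

test_that("explained variance of the reconstruction is non-decreasing in K", {
  mx <- make_mixture(n_blocks = 4, K = 4, noise = 0.2, seed = 15)
  evf <- sapply(2:4, function(k) {
    fit <- group_ica(mx$X, n_pc = 6, K = k, seed = 5)
    fit$explained
  })
  expect_true(all(diff(evf) >= -1e-6))
})
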
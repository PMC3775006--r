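test_that("epoching follows the half-open sample-count convention", {
  rec <- matrix(rnorm(4 * 5000), 4)
  ep <- epoch_data(rec, 1000, c(1.5, 2.5), -0.3, 0.8)
  expect_equal(dim(ep$data), c(2, 4, 1100))
  ep2 <- epoch_data(rec, 1000, 2.0, -0.8, 0.7)
  expect_equal(dim(ep2$data)[3], 1500)
  ep3 <- epoch_data(rec, 1000, 2.0, 0, 0.001)
  expect_equal(dim(ep3$data)[3], 1)
  # sample k corresponds to t_min + k/rate
  expect_equal(ep$data[1, 2, 1], rec[2, round(1.5 * 1000) - 300 + 1])
  expect_error(epoch_data(rec, 1000, 4.9, -0.3, 0.8), "trial 1")
})

test_that("common average reference zeroes the spatial mean and is idempotent", {
  x <- matrix(rnorm(12), 3, 4)
  y <- common_average_reference(x)
  expect_equal(max(abs(colMeans(y))), 0, tolerance = 1e-12)
  expect_equal(common_average_reference(y), y, tolerance = 1e-12)
  expect_equal(common_average_reference(x + 5), y, tolerance = 1e-12)
  expect_equal(as.vector(common_average_reference(matrix(c(3, 1), 2, 1))),
               c(1, -1))
  expect_error(common_average_reference(matrix(1, 1, 4)), "2 channels")
})

test_that("PCA artifact removal recovers and removes a known blink topography", {
  set.seed(21)
  mon <- fx_montage(32)
  topo <- blink_topography(mon)
  base <- matrix(rnorm(32 * 20000, 0, 1), 32, 20000)
  rec <- inject_blinks(base, 15, topo, 250, amplitude = 80)
  ons <- attr(rec, "blink_onsets")
  cleaned <- pca_artifact_removal(rec, ons, 250)
  U <- attr(cleaned, "removed_topography")
  expect_gt(abs(cor(U[, 1], topo)), 0.99)
  # blink-locked average amplitude drops below 5% of the original
  locked <- function(m) {
    acc <- 0
    for (on in ons[ons + 74 <= ncol(m)]) acc <- acc + m[, on:(on + 74)]
    acc / length(ons)
  }
  expect_lt(max(abs(locked(cleaned))) / max(abs(locked(rec))), 0.05)
  # no-blink recording passes through essentially unchanged
  expect_warning(quiet <- pca_artifact_removal(base, integer(0), 250),
                 "fewer than 3")
  expect_lt(max(abs(quiet - base)), 1e-6 * max(abs(base)))
})

test_that("signals orthogonal to the blink topography survive the projection", {
  set.seed(22)
  mon <- fx_montage(32)
  topo <- blink_topography(mon)
  # build a source pattern orthogonal to the blink topography
  v <- rnorm(32); v <- v - sum(v * topo) / sum(topo^2) * topo
  v <- v - mean(v)
  v <- v - sum(v * topo) / sum(topo^2) * topo
  pulse <- exp(-(seq(0, 1, length.out = 250) - 0.5)^2 / (2 * 0.05^2))
  sig <- outer(v, pulse) * 10
  rec <- cbind(sig, matrix(0, 32, 5000))
  rec <- inject_blinks(rec, 30, topo, 250, amplitude = 100)
  cleaned <- pca_artifact_removal(rec, attr(rec, "blink_onsets"), 250)
  peak_in <- max(abs(sig))
  peak_out <- max(abs(cleaned[, 1:250]))
  expect_gt(peak_out / peak_in, 0.98)
})

test_that("peak-to-peak rejection removes exactly the contaminated trials", {
  set.seed(23)
  dat <- array(rnorm(5 * 4 * 100, 0, 5), c(5, 4, 100))
  dat[3, 2, 50] <- 500
  ep <- lepsica:::new_lep_epochs(dat, 250, c(-0.1, 0.3), "S01", "neutral")
  kept <- reject_artifact_epochs(ep, 100)
  expect_equal(dim(kept$data)[1], 4)
  log <- attr(kept, "rejection_log")
  expect_equal(log$trial, 3)
  expect_match(log$channels, "2")
  none <- reject_artifact_epochs(ep, Inf)
  expect_equal(dim(none$data)[1], 5)
  bad <- ep; bad$data[, , 1] <- 1e6
  expect_error(reject_artifact_epochs(bad, 100), "all trials")
})

test_that("band-pass is zero-phase with the specified pass and stop behavior", {
  rate <- 1000
  t <- seq(0, 4 - 1 / rate, by = 1 / rate)
  s10 <- matrix(sin(2 * pi * 10 * t), 1)
  f10 <- bandpass_filter(s10, 2, 35, rate)
  mid <- 1000:3000
  expect_equal(max(abs(f10[mid])), 1, tolerance = 0.05)
  # phase: cross-correlation peak at zero lag (< 1 ms)
  cc <- sapply(-3:3, function(l) cor(f10[1, mid], s10[1, mid + l]))
  expect_equal(which.max(cc), 4)
  s60 <- matrix(sin(2 * pi * 60 * t), 1)
  f60 <- bandpass_filter(s60, 2, 35, rate)
  expect_lt(max(abs(f60[mid])), 0.1)
  dc <- matrix(5, 1, 4000)
  fdc <- bandpass_filter(dc, 2, 35, rate)
  expect_lt(abs(mean(fdc[mid])), 0.05)
  # a symmetric pulse keeps its peak latency
  pulse <- matrix(exp(-(t - 2)^2 / (2 * 0.05^2)), 1)
  fp <- bandpass_filter(pulse, 2, 35, rate)
  expect_lt(abs(which.max(fp) - which.max(pulse)), 1.5)
  expect_error(bandpass_filter(s10, 40, 35, rate), "invalid band")
})

test_that("baseline correction zeroes the baseline mean per channel", {
  dat <- array(rnorm(2 * 3 * 275), c(2, 3, 275))
  ep <- lepsica:::new_lep_epochs(dat, 250, c(-0.3, 0.8), "S01", "neutral")
  bc <- baseline_correct(ep, c(-0.3, 0))
  idx <- 1:75
  for (tr in 1:2)
    expect_equal(max(abs(rowMeans(bc$data[tr, , idx]))), 0,
                 tolerance = 1e-9)
  # constant channel -> all zero
  cst <- lepsica:::new_lep_epochs(array(3, c(1, 2, 275)), 250,
                                  c(-0.3, 0.8), "S01", "neutral")
  expect_equal(max(abs(baseline_correct(cst, c(-0.3, 0.8))$data)), 0)
  # ramp 0..1 over the baseline subtracts ~0.5
  ramp <- matrix(0, 1, 275); ramp[1, 1:75] <- seq(0, 1, length.out = 75)
  ev <- structure(list(data = ramp, rate = 250, window = c(-0.3, 0.8)),
                  class = "lep_evoked")
  bce <- baseline_correct(ev, c(-0.3, 0))
  expect_equal(bce$data[1, 150], ramp[1, 150] - 0.5, tolerance = 1e-6)
})

test_that("averaging is the arithmetic mean with variance reduction 1/n", {
  dat <- array(rnorm(6 * 2 * 50), c(6, 2, 50))
  ep <- lepsica:::new_lep_epochs(dat, 250, c(0, 0.2), "S01", "neutral")
  av <- average_epochs(ep)
  expect_equal(av$data, apply(dat, c(2, 3), mean))
  expect_equal(av$n_epochs, 6)
  same <- lepsica:::new_lep_epochs(array(rep(dat[1, , ], each = 3),
                                         c(3, 2, 50)), 250, c(0, 0.2),
                                   "S01", "neutral")
  expect_equal(average_epochs(same)$data, dat[1, , ])
  pm <- lepsica:::new_lep_epochs(array(c(dat[1, , ], -dat[1, , ]),
                                       c(2, 2, 50)) * 0, 250, c(0, 0.2),
                                 "S01", "neutral")
  pm$data[1, , ] <- dat[1, , ]; pm$data[2, , ] <- -dat[1, , ]
  expect_equal(max(abs(average_epochs(pm)$data)), 0)
  # Monte-Carlo: variance of the average of n white-noise trials ~ 1/n
  set.seed(31)
  vr <- replicate(200, {
    x <- array(rnorm(8 * 1 * 20), c(8, 1, 20))
    e <- lepsica:::new_lep_epochs(x, 250, c(0, 0.08), "S01", "neutral")
    var(as.vector(average_epochs(e)$data))
  })
  expect_equal(mean(vr), 1 / 8, tolerance = 0.05)
})

test_that("global field power equals the spatial SD of average-referenced data", {
  uni <- matrix(4, 5, 10)
  expect_equal(max(global_field_power(uni)), 0)
  two <- matrix(c(1, -1), 2, 3)
  expect_equal(global_field_power(two), rep(1, 3))
  set.seed(32)
  x <- matrix(rnorm(40), 8, 5)
  ref <- apply(sweep(x, 2, colMeans(x)), 2,
               function(v) sqrt(mean(v^2)))
  expect_equal(global_field_power(x), ref, tolerance = 1e-12)
})

test_that("filtering commutes with averaging for the linear zero-phase filter", {
  set.seed(33)
  dat <- array(rnorm(4 * 3 * 500), c(4, 3, 500))
  ep <- lepsica:::new_lep_epochs(dat, 500, c(0, 1), "S01", "neutral")
  a1 <- bandpass_filter(average_epochs(ep), 2, 35)
  a2 <- average_epochs(bandpass_filter(ep, 2, 35))
  # the 2 Hz edge puts poles near the unit circle; float error through the
  # recursion reaches ~1e-8 relative even though the operator is linear
  expect_equal(a1$data, a2$data, tolerance = 1e-7)
})
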
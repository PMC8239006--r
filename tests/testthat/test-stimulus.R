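test_that("wave movies are seed-deterministic and empty at zero rate", {
  m1 <- generate_wave_movie(duration = 60000, pixel_scale = 2, seed = 4)
  m2 <- generate_wave_movie(duration = 60000, pixel_scale = 2, seed = 4)
  expect_identical(m1$frames, m2$frames)
  expect_false(identical(m1$frames,
                         generate_wave_movie(duration = 60000, pixel_scale = 2,
                                             seed = 5)$frames))
  m0 <- generate_wave_movie(duration = 5000, wave_rate = 0, seed = 1)
  expect_true(all(m0$frames == 0))
  expect_error(generate_wave_movie(duration = -1), "positive")
})

test_that("white noise is temporally uncorrelated with ~2.8-deg autocorrelation", {
  m <- generate_white_noise_movie(extent = 60, duration = 20000,
                                  frame_interval = 50, seed = 8)
  ## per-pixel lag-1 temporal autocorrelation ~ 0
  nfr <- ncol(m$frames)
  px <- m$frames[seq(1, nrow(m$frames), by = 37), ]
  ac1 <- apply(px, 1, function(v) cor(v[-1], v[-nfr]))
  expect_lt(abs(mean(ac1)), 0.05)
  ## spatial autocorrelation of a Gaussian(sigma=2)-filtered field has
  ## sigma = 2*sqrt(2): measure the lag profile along rows
  n <- m$n
  f <- matrix(m$frames[, 1], n, n)
  lags <- 0:8
  prof <- vapply(lags, function(L) {
    a <- f[1:(n - L), ]; b <- f[(1 + L):n, ]
    mean(a * b)
  }, 1)
  prof <- prof / prof[1]
  fit <- coef(stats::nls(prof ~ exp(-lags^2 / (2 * s^2)),
                         start = list(s = 2)))
  expect_equal(unname(fit[["s"]]), 2 * sqrt(2), tolerance = 0.15)
})

test_that("receptive-field sampling respects truncation, spread and uniform angles", {
  rf <- sample_receptive_fields(10000, 5.3, 13.4, seed = 6)
  expect_true(all(rf$x^2 + rf$y^2 <= 50^2))
  expect_equal(sd(rf$x), 5.3, tolerance = 0.05 * 5.3)
  expect_equal(sd(rf$y), 5.3, tolerance = 0.05 * 5.3)
  cnt <- table(cut(rf$theta, seq(0, 360, by = 30)))
  expect_gt(chisq.test(cnt)$p.value, 0.001)
  expect_error(sample_receptive_fields(0, 5), "positive")
})

test_that("rasterized two-lobe filters balance to zero and rotate consistently", {
  rf <- list(x = 3, y = -2, theta = 37, diameter = 13.4, kind = "gabor")
  img <- rasterize_filter(rf, pixel_scale = 1, extent = 120)
  expect_lt(abs(sum(img)), 1e-10)
  ## rotating by 180 degrees swaps the lobes: the image negates
  rf2 <- rf; rf2$theta <- rf$theta + 180
  expect_equal(rasterize_filter(rf2, 1, 120), -img, tolerance = 1e-10)
  ## On/Off kinds are single-signed
  on <- rasterize_filter(list(x = 0, y = 0, theta = 0, diameter = 10,
                              kind = "on"), 1, 120)
  off <- rasterize_filter(list(x = 0, y = 0, theta = 0, diameter = 10,
                               kind = "off"), 1, 120)
  expect_true(all(on >= 0) && all(off <= 0))
  expect_equal(on, -off)
  expect_error(rasterize_filter(list(x = 58, y = 0, theta = 0,
                                     diameter = 13.4, kind = "gabor"),
                                1, 120), "extent")
})

test_that("receptive-field noise perturbs without destroying the filter", {
  img <- rasterize_filter(list(x = 0, y = 0, theta = 10, diameter = 13.4,
                               kind = "gabor"), 1, 120)
  ## forced zero scale leaves the image unchanged
  expect_equal(add_rf_noise(img, seed = 2, scale_range = c(0, 0)), img)
  ovl <- vapply(1:20, function(s) {
    rf_overlap(img, add_rf_noise(img, seed = s))
  }, 1)
  expect_gt(mean(ovl), 0.1)
  expect_lt(mean(ovl), 0.999)
})

test_that("LN encoding reduces to homogeneous Poisson without stimulus", {
  ## all-zero movie at the nominal baseline: empirical rate ~ a = 0.2 Hz
  ## (coarse pixels keep the fixture small; the stimulus is zero anyway)
  m <- generate_wave_movie(extent = 120, duration = 1200000, wave_rate = 0,
                           pixel_scale = 3, seed = 1)
  rf <- sample_receptive_fields(10, 5.3, 13.4, seed = 2)
  tr <- ln_encode(m, rf, a = 0.2, b = 9.4, seed = 3)
  rate <- mean(event_rate(tr))            # events per minute
  se <- sqrt(12 * 20 * 10) / (10 * 20)    # Poisson SE of the pooled rate/min
  expect_lt(abs(rate - 12), 3 * se)
  ## b = 0: rate independent of any stimulus
  m2 <- generate_wave_movie(extent = 120, duration = 600000, pixel_scale = 3,
                            seed = 4)
  tr2 <- ln_encode(m2, rf, a = 0.2, b = 0, seed = 5)
  expect_equal(mean(event_rate(tr2)), 12, tolerance = 0.3)
  expect_error(ln_encode(m2, rf, a = -1), "positive")
})

test_that("event trains are binary boxcars of the event duration", {
  tr <- train_of(list(c(0, 200, 230), c(1000)), x_dur = 50,
                 duration_ms = 2000)
  X <- event_indicator(tr, dt = 5)
  expect_true(all(X %in% c(0L, 1L)))
  ## first event: steps 1..10 on; overlapping events 200 & 230 merge into
  ## one run of 16 steps (200..280 ms)
  expect_equal(sum(X[1:10, 1]), 10)
  runs <- rle(X[, 1])
  expect_equal(runs$lengths[runs$values == 1], c(10, 16))
  expect_equal(event_rate(tr), c(3, 1) / (2 / 60))
})

test_that("correlated Poisson trains hit their rate and correlation targets", {
  ## c = 1: all trains share the mother exactly
  t1 <- correlated_poisson(4, 15, 1, 600000, seed = 9)
  for (k in 2:4) expect_equal(t1$onsets[[k]], t1$onsets[[1]])
  ## c = 0: independent; binned-count correlation ~ 0
  t0 <- correlated_poisson(2, 30, 0, 3600000, seed = 10)
  b0 <- vapply(t0$onsets, function(o) tabulate(floor(o / 1000) + 1, 3600), numeric(3600))
  expect_lt(abs(cor(b0[, 1], b0[, 2])), 0.05)
  ## c = 0.35 at 15/min over 4 h: empirical count correlation ~ 0.35
  tc <- correlated_poisson(6, 15, 0.35, 4 * 3600000, seed = 11)
  expect_equal(mean(event_rate(tc)), 15, tolerance = 1)
  nb <- 4 * 3600
  bc <- vapply(tc$onsets, function(o) tabulate(floor(o / 1000) + 1, nb), numeric(nb))
  cc <- cor(bc)[upper.tri(diag(6))]
  expect_equal(mean(cc), 0.35, tolerance = 0.05)
  expect_error(correlated_poisson(2, 15, 1.2, 1000), "\\[0, 1\\]")
})

test_that("event trains round-trip through the CSV exporter", {
  tr <- correlated_poisson(3, 20, 0.2, 120000, seed = 12)
  p <- tempfile(fileext = ".csv")
  write_event_trains(tr, p)
  rt <- read_event_trains(p, n = 3, x_dur = 50, duration_ms = 120000)
  expect_equal(rt$onsets, tr$onsets, ignore_attr = TRUE)
})
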
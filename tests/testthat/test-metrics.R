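test_that("boxcar correlations: identical trains 1, independent ~ 0", {
  tr <- correlated_poisson(2, 20, 1, 600000, seed = 31)
  C <- boxcar_correlation(tr)
  expect_equal(C[1, 2], 1)
  tr0 <- correlated_poisson(2, 60, 0, 3600000, seed = 32)
  C0 <- boxcar_correlation(tr0)
  expect_lt(abs(C0[1, 2]), 0.05)
  ## constant (empty) train: the pair is missing, not zero
  trc <- train_of(list(c(0, 1000), numeric(0)), duration_ms = 60000)
  expect_true(is.na(boxcar_correlation(trc)[1, 2]))
})

test_that("boxcar-filtered correlation tracks the MIP copy probability", {
  tr <- correlated_poisson(4, 15, 0.35, 2 * 3600000, seed = 33)
  C <- boxcar_correlation(tr)
  expect_equal(mean(C[upper.tri(C)]), 0.35, tolerance = 0.05)
})

test_that("coactivity counts overlapping events", {
  a <- train_of(list(c(0, 1000, 2000), c(0, 1000, 2000)), duration_ms = 4000)
  expect_equal(coactivity(a, 1, 2), 1)
  b <- train_of(list(c(0, 1000), c(500, 2000)), duration_ms = 4000)
  expect_equal(coactivity(b, 1, 2), 0)
  ## partial overlap (onsets 30 ms apart, 50-ms events)
  d <- train_of(list(c(0, 1000), c(30, 3000)), duration_ms = 4000)
  expect_equal(coactivity(d, 1, 2), 0.5)
  expect_true(is.na(coactivity(train_of(list(numeric(0), c(1))), 1, 2)))
  ## coactivity grows with the MIP copy probability
  co <- vapply(c(0.1, 0.5, 0.9), function(cc) {
    tr <- correlated_poisson(2, 30, cc, 1800000, seed = 34)
    coactivity(tr, 1, 2)
  }, 1)
  expect_true(all(diff(co) > 0))
})

test_that("orientation difference folds to [0, 90] with mod-180 symmetry", {
  expect_equal(orientation_difference(0, 180), 0)
  expect_equal(orientation_difference(10, 350), 20)
  expect_equal(orientation_difference(45, 90), 45)
  th <- runif(50, 0, 360)
  th2 <- runif(50, 0, 360)
  expect_equal(orientation_difference(th, th2),
               orientation_difference(th2, th))
  expect_equal(orientation_difference(th + 180, th2),
               orientation_difference(th, th2))
  expect_true(all(orientation_difference(th, th2) <= 90))
})

test_that("somatic preference is the circular average, with degenerate guard", {
  expect_equal(somatic_preference(c(20, 20)), 20)
  expect_equal(somatic_preference(c(10, 20, 30)), 20)
  expect_equal(circular_dispersion(c(20, 20, 80))[3],
               orientation_difference(80, somatic_preference(c(20, 20, 80))))
  expect_error(somatic_preference(c(0, 180)), "degenerate")
  ## all equal: dispersion zero
  expect_equal(circular_dispersion(rep(33, 5)), rep(0, 5))
  ## the axial mean handles mixed polarities where the plain mean degenerates
  expect_equal(somatic_preference(c(0, 180), axial = TRUE), 0)
  expect_equal(somatic_preference(c(10, 190, 20, 200), axial = TRUE), 15)
})

test_that("receptive-field offsets are distances to the mean center", {
  expect_equal(rf_offset(cbind(3, 4)), 0)
  expect_equal(rf_offset(cbind(c(-1, 1), c(0, 0))), c(1, 1))
  ctr <- cbind(rnorm(10), rnorm(10))
  expect_equal(rf_offset(ctr), rf_offset(ctr + 5))
})

test_that("filter overlap is the pixelwise Pearson correlation", {
  f <- rasterize_filter(list(x = 0, y = 0, theta = 30, diameter = 13.4,
                             kind = "gabor"), 1, 120)
  expect_equal(rf_overlap(f, f), 1)
  expect_equal(rf_overlap(f, -f), -1)
  g <- rasterize_filter(list(x = 30, y = 30, theta = 30, diameter = 13.4,
                             kind = "gabor"), 1, 120)
  expect_lt(abs(rf_overlap(f, g)), 0.02)
  expect_true(is.na(rf_overlap(f, f * 0)))
})

test_that("cluster-size fit recovers a known lambda and rejects flat input", {
  set.seed(35)
  d <- runif(3000, 0, 75)
  tab <- data.frame(distance = d,
                    correlation = 0.4 * exp(-d^2 / (2 * 6^2)) + 0.05 +
                      rnorm(3000, 0, 0.05))
  fit <- cluster_size_fit(tab)
  expect_equal(fit$lambda, 6, tolerance = 1)
  flat <- data.frame(distance = d, correlation = 0.1 + rnorm(3000, 0, 0.01))
  expect_error(cluster_size_fit(flat), "fit-failure")
})

test_that("survival and stable fractions behave like their definitions", {
  ## no turnover: survival stays 1
  empty <- data.frame(time_ms = numeric(0), old_id = integer(0))
  s <- survival_stats(empty, 30, t_grid_ms = c(0, 1e6, 2e6))
  expect_equal(s$curves$survival, rep(1, 3))
  expect_equal(s$survival_final, 1)
  ## one replacement among 30 at day 1
  log1 <- data.frame(time_ms = 86400000, old_id = 5L)
  s1 <- survival_stats(log1, 30, t_grid_ms = c(0, 86400000, 2 * 86400000))
  expect_equal(s1$curves$survival, c(1, 29 / 30, 29 / 30))
  ## survival non-increasing, stable non-decreasing on a busier log
  log2 <- data.frame(time_ms = sort(runif(40, 0, 5e6)),
                     old_id = sample.int(30, 40, replace = TRUE))
  s2 <- survival_stats(log2, 30, t_grid_ms = seq(0, 6e6, length.out = 20))
  expect_true(all(diff(s2$curves$survival) <= 1e-12))
  expect_true(all(diff(s2$curves$stable) >= -1e-12))
  expect_equal(s2$curves$stable[20], 1)
})

test_that("coaxial/orthogonal partition splits visual space at 45 degrees", {
  ctr <- rbind(c(10, 0), c(0, 10), c(5, 5), c(0, 0))
  lab <- coaxial_orthogonal_partition(ctr, theta_soma = 0,
                                      soma_center = c(0, 0))
  expect_equal(lab$label, c("coaxial", "orthogonal", "coaxial", "coaxial"))
  expect_equal(lab$ambiguous, c(FALSE, FALSE, FALSE, TRUE))
  ## partition covers every synapse exactly once
  expect_equal(nrow(lab), nrow(ctr))
  expect_true(all(lab$label %in% c("coaxial", "orthogonal")))
})
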
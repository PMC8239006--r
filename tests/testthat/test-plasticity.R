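test_that("parameter presets carry the nominal and control values", {
  p <- plasticity_params()
  expect_equal(p$rho, (2 * 0.45 - 1) / (2 * (1 - 0.45)))
  expect_equal(p$tau_w, p$tau_W / (2 * (1 - p$eta)))
  s <- plasticity_params("stdp")
  expect_equal(c(s$tau_M, s$tau_Y, s$eta, s$phi), c(60, 1, 0.3, 3 / 5))
  expect_equal(c(s$tau_v, s$tau_u), c(60, 1))
  expect_error(plasticity_params(bogus = 1), "unknown")
})

test_that("dendritic nonlinearity matches its closed form", {
  expect_equal(dendritic_nonlinearity(c(-1, 0.3, 2), gamma = 0),
               c(-1, 0.3, 2))
  expect_equal(dendritic_nonlinearity(0.125, gamma = 1), 0.25)
  expect_equal(dendritic_nonlinearity(100, gamma = 1), 0.5, tolerance = 1e-9)
  ## monotone nondecreasing for intermediate gamma
  x <- seq(-0.5, 1, by = 0.01)
  expect_true(all(diff(dendritic_nonlinearity(x, gamma = 0.6)) >= 0))
  expect_error(dendritic_nonlinearity(0, gamma = 2), "gamma")
})

test_that("cooperativity gate counts strictly more than min_count neighbors", {
  D <- matrix(0, 6, 6)
  pos <- c(0, 1, 2, 3, 4, 50)
  D <- abs(outer(pos, pos, "-"))
  ## 5 synapses 1 um apart all active: gate true for each of them
  la <- c(rep(0, 5), -Inf)
  g <- cooperativity_gate(la, 0, D, spacing_thr = 10, timing_thr = 100,
                          min_count = 3)
  expect_true(all(g[1:5]))
  expect_false(g[6])
  ## single active synapse: gate false everywhere
  g1 <- cooperativity_gate(c(0, rep(-Inf, 5)), 0, D, 10, 100, 3)
  expect_false(any(g1))
  ## exactly 4 active neighbors -> true; 3 -> false (count excludes self)
  la4 <- c(0, 0, 0, 0, 0, -Inf)
  expect_true(cooperativity_gate(la4, 0, D, 10, 100, 3)[1])
  la3 <- c(0, 0, 0, 0, -Inf, -Inf)
  expect_false(cooperativity_gate(la3, 0, D, 10, 100, 3)[1])
})

test_that("compiled generalized stepper equals the R reference exactly", {
  p <- plasticity_params()
  tr <- correlated_poisson(3, 40, 0.4, 20000, seed = 21)
  D <- abs(outer(c(0, 4, 9), c(0, 4, 9), "-"))
  S <- proximity_matrix(D, p$sigma_c)
  res <- simulate_generalized(tr, S, p, dt = 5)
  X <- event_indicator(tr, dt = 5)
  st <- list(v = numeric(3), u = numeric(3), w = rep(0.5, 3))
  for (t in seq_len(nrow(X))) st <- step_generalized(st, X[t, ], S, 5, p)
  expect_equal(res$w, st$w, tolerance = 1e-12)
  expect_equal(res$v, st$v, tolerance = 1e-12)
  expect_equal(res$u, st$u, tolerance = 1e-12)
})

test_that("compiled neurotrophin stepper equals the R reference exactly", {
  p <- plasticity_params()
  tr <- correlated_poisson(2, 40, 0.3, 10000, seed = 22)
  S <- proximity_matrix(matrix(c(0, 5, 5, 0), 2), p$sigma_c)
  res <- simulate_neurotrophin(tr, S, p, dt = 1)
  X <- event_indicator(tr, dt = 1)
  st <- list(M = numeric(2), Y = numeric(2), P = numeric(2), B = numeric(2),
             W = rep(0.5, 2))
  for (t in seq_len(nrow(X))) st <- step_neurotrophin(st, X[t, ], S, 1, p)
  expect_equal(res$W, st$W, tolerance = 1e-12)
  expect_equal(res$P, st$P, tolerance = 1e-12)
  expect_equal(res$B, st$B, tolerance = 1e-12)
  expect_equal(res$M, st$M, tolerance = 1e-12)
})

test_that("without input all accumulators decay and W freezes once B=P=0", {
  p <- plasticity_params()
  tr <- train_of(list(numeric(0)), duration_ms = 10000)
  st0 <- list(M = 2, Y = 1, P = 0.5, B = 0.5, W = 0.5)
  res <- simulate_neurotrophin(tr, matrix(1, 1, 1), p, dt = 1, state = c(
    st0, list(W_gaba = numeric(0))))
  expect_lt(res$M, 2e-7)
  expect_lt(res$Y, 1e-9)
  expect_lt(res$P + res$B, 1e-9)
  ## with conversion quiescent (M = 0) equal B and P decay together and the
  ## efficacy never moves
  st1 <- list(M = 0, Y = 0, P = 0.3, B = 0.3, W = 0.5)
  res1 <- simulate_neurotrophin(tr, matrix(1, 1, 1), p, dt = 1, state = c(
    st1, list(W_gaba = numeric(0))))
  expect_equal(res1$W, 0.5, tolerance = 1e-12)
})

test_that("sustained drive without conversion relaxes B/(B+P) to eta", {
  p <- plasticity_params(phi = 0)     # no MMP9: conversion off
  tr <- train_of(list(seq(0, 59950, by = 100)), duration_ms = 60000)
  res <- simulate_neurotrophin(tr, matrix(1, 1, 1), p, dt = 1)
  expect_equal(res$B / (res$B + res$P), 0.45, tolerance = 1e-3)
})

test_that("neurotrophin conversion moves mass from P to B without creating it", {
  ## one step with M large vs M = 0: P+B changes identically (the -MP and
  ## +MP terms cancel); only the split differs
  p <- plasticity_params()
  s1 <- list(M = 2, Y = 1, P = 0.3, B = 0.2, W = 0.5)
  s0 <- list(M = 0, Y = 1, P = 0.3, B = 0.2, W = 0.5)
  S <- matrix(1, 1, 1)
  r1 <- step_neurotrophin(s1, 0, S, 0.05, p)
  r0 <- step_neurotrophin(s0, 0, S, 0.05, p)
  expect_equal(r1$P + r1$B, r0$P + r0$B, tolerance = 1e-6)
  expect_gt(r1$B, r0$B)
  expect_lt(r1$P, r0$P)
})

test_that("generalized rule potentiates driven synapses, depresses idle neighbors", {
  p <- plasticity_params()
  ## isolated synapse, sustained events: v exceeds -rho and w grows
  tr <- train_of(list(seq(0, 119950, by = 100)), duration_ms = 120000)
  res <- simulate_generalized(tr, matrix(1, 1, 1), p, dt = 5)
  expect_gt(res$v, -p$rho)
  expect_gt(res$w, 0.5)
  ## unstimulated synapse next to an active one: u > 0, v = 0 -> depression
  tr2 <- train_of(list(seq(0, 119950, by = 100), numeric(0)),
                  duration_ms = 120000)
  S <- proximity_matrix(matrix(c(0, 3, 3, 0), 2), p$sigma_c)
  res2 <- simulate_generalized(tr2, S, p, dt = 5)
  expect_lt(res2$w[2], 0.5)
  expect_gt(res2$w[1], 0.5)
})

test_that("gamma = 0 reproduces the plain postsynaptic update bit for bit", {
  p0 <- plasticity_params(gamma = 0)
  pg <- plasticity_params(gamma = 0.5)
  tr <- correlated_poisson(3, 30, 0.3, 30000, seed = 23)
  S <- proximity_matrix(abs(outer(c(0, 2, 5), c(0, 2, 5), "-")), p0$sigma_c)
  r0 <- simulate_generalized(tr, S, p0, dt = 5)
  rg <- simulate_generalized(tr, S, pg, dt = 5)
  r00 <- simulate_generalized(tr, S, p0, dt = 5)
  expect_identical(r0$w, r00$w)
  expect_false(identical(r0$w, rg$w))
})

test_that("efficacies stay inside [0, 1] under extreme drive", {
  p <- plasticity_params()
  tr <- train_of(list(seq(0, 59950, by = 50)), duration_ms = 60000)  # solid ON
  res <- simulate_generalized(tr, matrix(1, 1, 1), p, dt = 5, w0 = 0.99)
  expect_lte(res$w, 1)
  expect_gte(res$w, 0)
  resn <- simulate_neurotrophin(tr, matrix(1, 1, 1), p, dt = 1, w0 = 0.99)
  expect_lte(resn$W, 1)
  expect_gte(resn$W, 0)
})

test_that("halving the Euler step changes 1-min trajectories by < 1%", {
  p <- plasticity_params()
  tr <- correlated_poisson(3, 30, 0.3, 60000, seed = 24)
  S <- proximity_matrix(abs(outer(c(0, 3, 8), c(0, 3, 8), "-")), p$sigma_c)
  ## onsets snapped to the coarse grid so both runs see identical input
  tr$onsets <- lapply(tr$onsets, function(o) round(o / 10) * 10)
  r10 <- simulate_generalized(tr, S, p, dt = 10, record_every_ms = 1000)
  r5 <- simulate_generalized(tr, S, p, dt = 5, record_every_ms = 1000)
  expect_lt(max(abs(r10$w_hist - r5$w_hist)), 0.01)
  n10 <- simulate_neurotrophin(tr, S, p, dt = 2, record_every_ms = 1000)
  n5 <- simulate_neurotrophin(tr, S, p, dt = 1, record_every_ms = 1000)
  expect_lt(max(abs(n10$W_hist - n5$W_hist)), 0.01)
})

test_that("GABA efficacies track the proximity-weighted B - P of neighbors", {
  p <- plasticity_params(gaba_mode = "inhibitory")
  S <- matrix(1, 1, 1); S_ei <- matrix(exp(-0.5), 1, 1)
  ## excitatory B = P: GABA weight stays put
  st <- list(M = 0, Y = 0, P = 0.2, B = 0.2, W = 0.5)
  r <- step_neurotrophin(st, 0, S, 1, p, W_gaba = 0.5, S_ei = S_ei,
                         x_gaba = 0, gaba_sign = -1)
  expect_equal(r$W_gaba, 0.5, tolerance = 1e-9)
  ## sign of the change follows the sign of B - P
  st$B <- 0.4
  expect_gt(step_neurotrophin(st, 0, S, 1, p, W_gaba = 0.5, S_ei = S_ei,
                              x_gaba = 0, gaba_sign = -1)$W_gaba, 0.5)
  st$B <- 0.05
  expect_lt(step_neurotrophin(st, 0, S, 1, p, W_gaba = 0.5, S_ei = S_ei,
                              x_gaba = 0, gaba_sign = -1)$W_gaba, 0.5)
})

test_that("scenario A floors calcium at zero under strong inhibition", {
  p <- plasticity_params(gaba_mode = "inhibitory")
  ## one silent excitatory synapse, one furiously active GABA synapse on top
  tr <- train_of(list(numeric(0)), duration_ms = 5000)
  gtr <- train_of(list(seq(0, 4950, by = 50)), duration_ms = 5000)
  res <- simulate_neurotrophin(tr, matrix(1, 1, 1), p, dt = 1,
                               gaba_trains = gtr,
                               S_ei = matrix(1, 1, 1), Wg0 = 1)
  expect_gte(res$Y, 0)
})
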
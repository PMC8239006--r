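test_that("synapse placement matches floor(L*nu) with 0.5 efficacies", {
  d <- linear_dendrite(150)
  syn <- place_synapses(d, 0.2, seed = 1)
  expect_equal(nrow(syn), 30)
  expect_true(all(syn$efficacy == 0.5))
  expect_true(all(syn$pos >= 0 & syn$pos <= 150))
  expect_equal(nrow(place_synapses(linear_dendrite(64), 0.5, seed = 1)), 32)
  expect_error(place_synapses(linear_dendrite(1), 0.2), "density")
})

test_that("linear pairwise distances honor periodic boundaries", {
  d <- linear_dendrite(150, periodic = TRUE)
  D <- pairwise_distance(d, c(10, 145))
  expect_equal(D[1, 2], 15)
  expect_equal(diag(D), c(0, 0))
  dn <- linear_dendrite(150, periodic = FALSE)
  expect_equal(pairwise_distance(dn, c(10, 145))[1, 2], 135)
  expect_error(pairwise_distance(d, c(-5, 10)), "off the dendrite")
})

test_that("tree path distances follow hand geometry on a Y-shaped tree", {
  tr <- y_tree()
  ## one synapse on each tip segment at the very tip, one near the soma
  syn <- data.frame(segment = c(10L, 15L, 1L), offset = c(10, 10, 0))
  D <- pairwise_distance(tr, syn)
  expect_equal(D[1, 2], 100)       # tip to tip through the branch point
  expect_equal(D[1, 3], 100)       # tip to soma
  expect_equal(soma_distance(tr, syn), c(100, 100, 0))
  ## two children of the branch point at offsets 5 and 7
  syn2 <- data.frame(segment = c(6L, 11L), offset = c(5, 7))
  expect_equal(pairwise_distance(tr, syn2)[1, 2], 12)
  ## metric properties on random placements
  syn3 <- place_synapses(tr, 0.15, seed = 3)
  D3 <- pairwise_distance(tr, syn3)
  expect_equal(D3, t(D3))
  n <- nrow(D3)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(D3[i, j], D3[i, k] + D3[k, j] + 1e-9)
})

test_that("proximity matrix is the Gaussian of distance with a hard cutoff", {
  D <- matrix(c(0, 6, 36, 6, 0, 6, 36, 6, 0), 3)
  S <- proximity_matrix(D, 6)
  expect_equal(diag(S), rep(1, 3))
  expect_equal(S[1, 2], exp(-0.5))
  expect_equal(S[1, 3], 0)           # 6 sigma: beyond the 5-sigma cutoff
  expect_equal(S, t(S))
})

test_that("SWC round-trips and resamples to 10-um segments", {
  path <- straight_swc()
  tr <- load_swc(path)
  expect_equal(nrow(tr$segments), 10)
  expect_equal(max(tr$segments$d1), 100)
  ## write -> read -> write is byte-stable
  p1 <- tempfile(fileext = ".swc"); p2 <- tempfile(fileext = ".swc")
  write_swc(tr, p1)
  write_swc(load_swc(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
  ## resampling is idempotent on segment count
  r1 <- resample_dendrite(tr, 10)
  expect_equal(nrow(resample_dendrite(r1, 10)$segments), nrow(r1$segments))
  ## multi-root files are rejected
  bad <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 1 -1", "2 3 0 10 0 1 -1"), bad)
  expect_error(load_swc(bad), "root")
})

test_that("synthetic trees are seed-deterministic and SWC round-trip", {
  t1 <- synthetic_tree(depth = 3, seed = 11)
  t2 <- synthetic_tree(depth = 3, seed = 11)
  expect_equal(t1$segments, t2$segments)
  expect_false(isTRUE(all.equal(t1$segments,
                                synthetic_tree(depth = 3, seed = 12)$segments)))
  p <- tempfile(fileext = ".swc")
  write_swc(t1, p)
  rt <- load_swc(p)
  expect_equal(total_length(rt), total_length(t1), tolerance = 1e-6)
  expect_equal(max(rt$segments$d1), max(t1$segments$d1), tolerance = 1e-6)
  ## distal regimes exist relative to the strongest attenuation factor
  expect_gt(max(t1$segments$d1), 2 * 125 * 0.8)
})

test_that("turnover replaces only sub-threshold synapses and preserves N", {
  d <- linear_dendrite(150)
  syn <- place_synapses(d, 0.2, seed = 2)
  syn$theta <- runif(30, 0, 360); syn$cx <- 0; syn$cy <- 0
  sampler <- function(n) sample_receptive_fields(n, 5.3, 13.4)
  ## nothing below threshold: no change, empty log
  set.seed(1)
  out <- apply_turnover(syn, d, 0.02, sampler, time_ms = 0)
  expect_equal(out$synapses, syn)
  expect_equal(nrow(out$log), 0)
  ## one dying synapse: exactly one replacement at efficacy 0.5
  syn$efficacy[7] <- 0.01
  out <- apply_turnover(syn, d, 0.02, sampler, time_ms = 1000)
  expect_equal(nrow(out$log), 1)
  expect_equal(out$log$old_id, 7)
  expect_equal(out$synapses$efficacy[7], 0.5)
  expect_equal(nrow(out$synapses), 30)
})

test_that("density ramp schedules insertions and conserves neighborhood calcium", {
  r <- density_ramp(L = 150, nu_start = 0.2, nu_end = 0.8,
                    duration_days = 4, add_interval_min = 64)
  expect_equal(nrow(r), 90)
  expect_true(all(r$time_ms %% (64 * 60000) == 0))
  ## sigma_c * increment * nu constant over the ramp
  total <- r$sigma_c * r$drive_scale * r$nu
  expect_equal(total, rep(total[1], nrow(r)), tolerance = 1e-12)
  expect_error(density_ramp(nu_start = 0.5, nu_end = 0.2), "exceed")
})
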
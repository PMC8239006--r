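## Protocol runners: the induction protocols (distance-rate sweep, burst
## pairing), the density/correlation phase diagram, and the multi-day
## developmental simulations on branches and trees.
##
## The developmental engine works in epochs: stimulus responses are
## pre-computed once for a pool of candidate receptive fields over one loop
## of the stimulus movie, events are drawn per epoch from the looped rate
## traces, the compiled stepper advances the state, and structural
## plasticity (turnover, density-ramp insertions) is applied at epoch
## boundaries.  Replacement synapses draw their receptive field from the
## pre-encoded pool, whose members follow exactly the sampling distribution
## of fresh receptive fields (uniform orientation, Gaussian center).

.substreams <- function(seed, n = 10) {
  set.seed(seed)
  sample.int(2^30, n)
}

#' Distance- and rate-dependent plasticity sweep
#'
#' Two synapses on a periodic linear branch; one is driven with regular
#' 50-ms bursts at the given rates while the other stays silent.  Efficacies
#' are frozen at 0.5 and the expected change is measured as the temporal
#' average of B - P over the run.
#'
#' @param rates burst rates (per minute).
#' @param distances synapse separations (um).
#' @param params a [plasticity_params()].
#' @param duration_min simulated minutes per cell.
#' @param L branch length (um).
#' @param dt Euler step (ms).
#' @return Data frame: rate, distance, dw_stim, dw_unstim (mean B - P).
#' @export
run_distance_rate_sweep <- function(rates = c(1, 5, 10, 15, 20),
                                    distances = c(0, 3, 6, 10, 15),
                                    params = plasticity_params(),
                                    duration_min = 40, L = 150, dt = 1) {
  dend <- linear_dendrite(L, periodic = TRUE)
  dur <- duration_min * 60000
  out <- expand.grid(rate = rates, distance = distances)
  out$dw_stim <- NA_real_; out$dw_unstim <- NA_real_
  for (i in seq_len(nrow(out))) {
    pos <- c(10, 10 + out$distance[i])
    S <- proximity_matrix(pairwise_distance(dend, pos), params$sigma_c,
                          params$proximity_cutoff)
    onsets <- if (out$rate[i] > 0) seq(0, dur - 1, by = 60000 / out$rate[i])
              else numeric(0)
    tr <- .new_event_train(list(onsets, numeric(0)), params$x_dur, dur)
    res <- simulate_neurotrophin(tr, S, params, dt = dt, freeze_W = TRUE)
    out$dw_stim[i] <- res$mean_BP[1]
    out$dw_unstim[i] <- res$mean_BP[2]
  }
  out
}

#' Burst-timing-dependent plasticity protocol
#'
#' A single synapse receives `n_pairings` pairings of a presynaptic and a
#' postsynaptic burst at temporal offset `dT = t_post - t_pre`.  Each burst
#' lasts 1 s and contains ten 50-ms events (100-ms onset spacing).  The
#' postsynaptic burst injects calcium of amplitude `B_amp` directly; the
#' synaptic calcium drive is disabled for this protocol so calcium reflects
#' postsynaptic stimulation only.
#'
#' @param offsets_s temporal offsets (s).
#' @param params a [plasticity_params()].
#' @param n_pairings pairings per offset.
#' @param pairing_interval_s time between pairings (s).
#' @param dt Euler step (ms).
#' @return Data frame: offset_s, pct_change (of the 0.5 baseline).
#' @export
run_btdp <- function(offsets_s = c(-3, -2, -1.5, -1, -0.5, -0.05,
                                   0.05, 0.5, 1, 1.5, 2, 3),
                     params = plasticity_params(), n_pairings = 10,
                     pairing_interval_s = 10, dt = 1) {
  burst <- seq(0, 900, by = 100)
  margin <- 5000
  dur <- margin * 2 + n_pairings * pairing_interval_s * 1000
  out <- data.frame(offset_s = offsets_s, pct_change = NA_real_)
  for (i in seq_along(offsets_s)) {
    base <- margin + (seq_len(n_pairings) - 1) * pairing_interval_s * 1000
    pre <- as.vector(outer(burst, base, "+"))
    post <- as.vector(outer(burst, base + offsets_s[i] * 1000, "+"))
    tr <- .new_event_train(list(sort(pre)), params$x_dur, dur)
    res <- simulate_neurotrophin(tr, matrix(1, 1, 1), params, dt = dt,
                                 forced_bap_ms = sort(post),
                                 drive_scale = 0)
    out$pct_change[i] <- (res$W[1] - 0.5) / 0.5 * 100
  }
  out
}

#' Density-correlation phase diagram
#'
#' Mean instantaneous efficacy change (weights frozen at 0.5) of synapses on
#' a linear branch as a function of synaptic density and input correlation,
#' driven by correlated Poisson trains, with the analytic drive and critical
#' correlation attached per cell.
#'
#' @param nu densities (per um).
#' @param corr correlations.
#' @param reps seeded repetitions per cell.
#' @param params a [plasticity_params()].
#' @param duration_min minutes of input per repetition.
#' @param L branch length (um).
#' @param rate event rate (per min).
#' @param dt Euler step (ms).
#' @param seed integer seed.
#' @return Data frame: nu, c, mean_dw, analytic (closed-form drive),
#'   c_star.
#' @export
run_phase_diagram <- function(nu = c(0.05, 0.19, 0.33, 0.47, 0.61, 0.75),
                              corr = seq(0, 0.5, by = 0.1),
                              reps = 10, params = plasticity_params(),
                              duration_min = 12, L = 30, rate = 15, dt = 5,
                              seed = 1) {
  ss <- .substreams(seed, 2)
  kap <- kappa_bound(params, rate)
  grid <- expand.grid(nu = nu, c = corr)
  grid$mean_dw <- NA_real_
  dur <- duration_min * 60000
  for (i in seq_len(nrow(grid))) {
    N <- max(1L, floor(L * grid$nu[i]))
    acc <- 0
    for (r in seq_len(reps)) {
      set.seed(ss[1] + i * 1000 + r)
      pos <- runif(N, 0, L)
      S <- proximity_matrix(pairwise_distance(linear_dendrite(L, TRUE), pos),
                            params$sigma_c, params$proximity_cutoff)
      tr <- correlated_poisson(N, rate, grid$c[i], dur, params$x_dur)
      res <- simulate_generalized(tr, S, params, dt = dt, freeze_w = TRUE,
                                  seed = ss[2] + i * 1000 + r)
      acc <- acc + mean(res$mean_dw)
    }
    grid$mean_dw[i] <- acc / reps
  }
  grid$analytic <- vapply(seq_len(nrow(grid)), function(i)
    homogeneous_drive(grid$nu[i], grid$c[i], params, rate), 1)
  grid$c_star <- critical_correlation(grid$nu, params$sigma_c, kap)
  grid
}

## ---- developmental engine ----------------------------------------------

## pool responses over one stimulus loop -> per-frame event probabilities
.encode_pool <- function(pool, stimulus, loop_ms, extent, pixel_scale,
                         frame_interval, a, b, wave_args, seed) {
  grid <- .movie_grid(extent, pixel_scale)
  times <- seq(0, loop_ms - frame_interval / 2, by = frame_interval)
  Fs <- NULL
  ## rasterize pool filters once
  dummy <- list(n = grid$n, ax = grid$ax)
  Fs <- .rf_filter_matrix(dummy, pool)
  nt <- length(times)
  resp <- matrix(0, nrow(pool), nt)
  chunk <- 600L
  set.seed(seed)
  wk <- if (is.null(wave_args$wave_kind)) "ring" else wave_args$wave_kind
  if (stimulus == "waves") {
    waves <- .sample_waves(loop_ms, wave_args$wave_rate, extent,
                           wave_args$wave_speed, wave_args$wave_width, wk)
  }
  for (st in seq(1, nt, by = chunk)) {
    en <- min(nt, st + chunk - 1)
    if (stimulus == "waves") {
      fr <- .render_waves(waves, times[st:en], grid, wave_args$wave_speed,
                          wave_args$wave_width)
    } else {
      mv <- generate_white_noise_movie(extent, (en - st + 1) * frame_interval,
                                       pixel_scale, frame_interval,
                                       seed = seed + st)
      fr <- mv$frames
    }
    resp[, st:en] <- as.matrix(Matrix::t(Fs) %*% fr)
  }
  rate <- a / 1000 * exp(b * resp)
  1 - exp(-rate * frame_interval)      # event-onset probability per frame
}

## draw an event_train_set for the given synapses over [t0, t0+dur) from the
## looped per-frame probabilities
.draw_pool_events <- function(p_on, pool_idx, t0_ms, dur_ms, frame_interval,
                              x_dur) {
  nf_loop <- ncol(p_on)
  f0 <- round(t0_ms / frame_interval)
  nf <- round(dur_ms / frame_interval)
  cols <- ((f0 + seq_len(nf) - 1) %% nf_loop) + 1
  P <- p_on[pool_idx, cols, drop = FALSE]
  hit <- which(matrix(runif(length(P)), nrow(P)) < P, arr.ind = TRUE)
  onsets <- split((hit[, 2] - 1) * frame_interval,
                  factor(hit[, 1], levels = seq_along(pool_idx)))
  .new_event_train(lapply(onsets, function(v) sort(unname(v))), x_dur, dur_ms)
}

## distance rows for replaced synapses (avoids full recomputation)
.refresh_distances <- function(dendrite, syn, D, idx) {
  if (!length(idx)) return(D)
  if (dendrite$mode == "linear") {
    for (k in idx) {
      dx <- abs(syn$pos - syn$pos[k])
      if (dendrite$periodic) dx <- pmin(dx, dendrite$L - dx)
      D[k, ] <- dx; D[, k] <- dx
    }
    return(D)
  }
  s <- dendrite$segments
  chains <- lapply(seq_len(nrow(s)), function(i) .anc_chain(s, i))
  dsoma <- s$d0[syn$segment] + syn$offset
  for (k in idx) {
    dk <- vapply(seq_len(nrow(syn)), function(j) {
      if (syn$segment[k] == syn$segment[j]) return(abs(syn$offset[k] - syn$offset[j]))
      common <- intersect(chains[[syn$segment[k]]], chains[[syn$segment[j]]])
      if (!length(common)) return(dsoma[k] + dsoma[j])
      if (common[1] == syn$segment[k]) return(dsoma[j] - dsoma[k])
      if (common[1] == syn$segment[j]) return(dsoma[k] - dsoma[j])
      dsoma[k] + dsoma[j] - 2 * s$d1[common[1]]
    }, 1)
    D[k, ] <- dk; D[, k] <- dk
  }
  D
}

#' Developmental branch-clustering simulation
#'
#' Full pipeline: sample receptive fields, encode a looped stimulus movie
#' through the LN cascade, advance the generalized plasticity model in
#' epochs with structural turnover, and return the state needed for
#' organization reports.
#'
#' @param species `"ferret"`, `"mouse"` or `"macaque"` (receptive-field
#'   preset).
#' @param stimulus `"waves"` or `"white_noise"`.
#' @param days simulated days.
#' @param dendrite the dendrite (default: 150-um periodic branch).
#' @param nu synaptic density (per um).
#' @param params a [plasticity_params()].
#' @param dt Euler step (ms).
#' @param epoch_s epoch length (s); turnover is applied at epoch
#'   boundaries.
#' @param loop_s stimulus loop length (s).
#' @param pool_size candidate receptive-field pool size.
#' @param extent,pixel_scale,frame_interval stimulus geometry.
#' @param a,b LN nonlinearity parameters (Hz, unitless).
#' @param wave_args wave surrogate parameters.
#' @param bap_on enable threshold bAPs (trees); A_th is calibrated once, on
#'   a frozen-efficacy probe, to `bap_target` burst initiations per minute
#'   when `calibrate_bap = TRUE`, then held fixed so the winner-take-all
#'   feedback between the dominant synapse population and the soma can
#'   develop.
#' @param calibrate_bap recalibrate A_th for the morphology at hand.
#' @param bap_target somatic burst-initiation rate for the calibration
#'   (per minute).
#' @param coop_on enable the cooperativity gate.
#' @param ramp optional [density_ramp()] schedule.
#' @param seed master seed (split into substreams for placement, pool,
#'   stimulus, events and bAPs).
#' @return A `clustering_run` object.
#' @export
run_branch_clustering <- function(species = "ferret", stimulus = "waves",
                                  days = 1,
                                  dendrite = linear_dendrite(150, TRUE),
                                  nu = 0.2,
                                  params = plasticity_params(),
                                  dt = 5, epoch_s = 300, loop_s = 360,
                                  pool_size = 800,
                                  extent = 120, pixel_scale = 1,
                                  frame_interval = 50,
                                  a = 0.2, b = 9.4,
                                  wave_args = list(wave_speed = 100,
                                                   wave_rate = 6,
                                                   wave_width = 10,
                                                   wave_kind = "ring"),
                                  bap_on = FALSE, calibrate_bap = TRUE,
                                  bap_target = 15,
                                  coop_on = FALSE,
                                  ramp = NULL, seed = 1) {
  sp <- species_preset(species)
  ss <- .substreams(seed, 8)
  syn <- place_synapses(dendrite, nu, seed = ss[1])
  N <- nrow(syn)
  pool <- sample_receptive_fields(pool_size, sp$sigma_p, sp$diameter,
                                  seed = ss[2])
  syn$pool_idx <- seq_len(N)           # first N pool members are the synapses
  syn$theta <- pool$theta[syn$pool_idx]
  syn$cx <- pool$x[syn$pool_idx]
  syn$cy <- pool$y[syn$pool_idx]
  p_on <- .encode_pool(pool, stimulus, loop_s * 1000, extent, pixel_scale,
                       frame_interval, a, b, wave_args, ss[3])
  D <- pairwise_distance(dendrite, syn)
  sigma_c <- params$sigma_c
  S <- proximity_matrix(D, sigma_c, params$proximity_cutoff)
  sdist <- soma_distance(dendrite, syn)

  epoch_ms <- epoch_s * 1000
  n_epochs <- as.integer(round(days * 86400 / epoch_s))
  state <- list(v = numeric(N), u = numeric(N), w = rep(0.5, N))
  turnover_log <- data.frame(time_ms = numeric(0), old_id = integer(0),
                             new_position_um = numeric(0),
                             new_theta_deg = numeric(0))
  w_hist <- matrix(NA_real_, N, n_epochs)
  bap_count <- 0
  A_th_used <- params$A_th
  drive_scale <- 1
  ramp_next <- 1L

  set.seed(ss[4])
  if (bap_on && calibrate_bap) {
    probe <- .draw_pool_events(p_on, syn$pool_idx, 0, 600000,
                               frame_interval, params$x_dur)
    A_th_used <- calibrate_bap_threshold(probe, S, params, sdist,
                                         target_per_min = bap_target,
                                         dt = dt)
  }
  pars <- params
  pars$A_th <- A_th_used

  for (ep in seq_len(n_epochs)) {
    t0 <- (ep - 1) * epoch_ms
    tr <- .draw_pool_events(p_on, syn$pool_idx, t0, epoch_ms, frame_interval,
                            params$x_dur)
    res <- simulate_generalized(tr, S, pars, dt = dt,
                                w0 = state$w, v0 = state$v, u0 = state$u,
                                coop_on = coop_on,
                                distances = if (coop_on) D else NULL,
                                bap_on = bap_on, soma_dist = sdist,
                                drive_scale = drive_scale,
                                seed = ss[5] + ep)
    state <- list(v = res$v, u = res$u, w = res$w)
    bap_count <- bap_count + res$n_bap
    w_hist[seq_len(nrow(syn)), ep] <- res$w

    ## structural plasticity: replacement of silenced synapses
    dead <- which(state$w < params$W_thr)
    if (length(dead)) {
      newidx <- sample.int(nrow(pool), length(dead), replace = TRUE)
      if (dendrite$mode == "linear") {
        syn$pos[dead] <- runif(length(dead), 0, dendrite$L)
        newpos <- syn$pos[dead]
      } else {
        sg <- dendrite$segments
        segi <- sample.int(nrow(sg), length(dead), replace = TRUE,
                           prob = sg$length)
        syn$segment[dead] <- segi
        syn$offset[dead] <- runif(length(dead)) * sg$length[segi]
        newpos <- sg$d0[segi] + syn$offset[dead]
      }
      syn$pool_idx[dead] <- newidx
      syn$theta[dead] <- pool$theta[newidx]
      syn$cx[dead] <- pool$x[newidx]
      syn$cy[dead] <- pool$y[newidx]
      syn$birth_ms[dead] <- t0 + epoch_ms
      state$w[dead] <- 0.5
      state$v[dead] <- 0; state$u[dead] <- 0
      D <- .refresh_distances(dendrite, syn, D, dead)
      S <- proximity_matrix(D, sigma_c, params$proximity_cutoff)
      sdist <- soma_distance(dendrite, syn)
      turnover_log <- rbind(turnover_log, data.frame(
        time_ms = t0 + epoch_ms, old_id = syn$id[dead],
        new_position_um = newpos, new_theta_deg = syn$theta[dead]))
    }

    ## density ramp: scheduled insertions + calcium conservation scaling
    if (!is.null(ramp)) {
      while (ramp_next <= nrow(ramp) && ramp$time_ms[ramp_next] <= t0 + epoch_ms) {
        newidx <- sample.int(nrow(pool), 1)
        newpos <- runif(1, 0, dendrite$L)
        syn <- rbind(syn, data.frame(
          id = max(syn$id) + 1L, pos = newpos, segment = NA_integer_,
          offset = NA_real_, efficacy = 0.5, type = "excitatory",
          birth_ms = t0 + epoch_ms, pool_idx = newidx,
          theta = pool$theta[newidx], cx = pool$x[newidx],
          cy = pool$y[newidx]))
        state$w <- c(state$w, 0.5)
        state$v <- c(state$v, 0); state$u <- c(state$u, 0)
        sigma_c <- ramp$sigma_c[ramp_next]
        drive_scale <- ramp$drive_scale[ramp_next]
        D <- pairwise_distance(dendrite, syn)
        S <- proximity_matrix(D, sigma_c, params$proximity_cutoff)
        sdist <- soma_distance(dendrite, syn)
        w_hist <- rbind(w_hist, rep(NA_real_, n_epochs))
        ramp_next <- ramp_next + 1L
      }
    }
  }
  syn$efficacy <- state$w
  structure(list(
    species = species, stimulus = stimulus, days = days,
    dendrite = dendrite, synapses = syn, pool = pool, p_on = p_on,
    distances = D, proximity = S, soma_dist = sdist,
    turnover_log = turnover_log, w_hist = w_hist,
    n_initial = N, bap_count = bap_count, A_th = A_th_used,
    params = params,
    stim_geom = list(extent = extent, pixel_scale = pixel_scale,
                     frame_interval = frame_interval),
    seed = seed, report_seed = ss[6]),
    class = "clustering_run")
}

#' @export
print.clustering_run <- function(x, ...) {
  cat(sprintf("<clustering_run> %s / %s, %g day(s), %d synapses, %d turnovers\n",
              x$species, x$stimulus, x$days, nrow(x$synapses),
              nrow(x$turnover_log)))
  invisible(x)
}

#' Tree simulation with backpropagating action potentials
#'
#' [run_branch_clustering()] on a dendritic tree with the somatic
#' accumulator and threshold bAPs enabled; `bap_sigma` sets the attenuation
#' factor.
#'
#' @inheritParams run_branch_clustering
#' @param bap_sigma bAP attenuation factor (um): 25, 75 or 125.
#' @param ... forwarded to [run_branch_clustering()].
#' @export
run_tree_global <- function(species = "ferret", bap_sigma = 75,
                            dendrite = synthetic_tree(seed = 42),
                            days = 1, params = plasticity_params(),
                            seed = 1, ...) {
  params$bap_sigma <- bap_sigma
  run_branch_clustering(species = species, stimulus = "waves", days = days,
                        dendrite = dendrite, params = params,
                        bap_on = TRUE, seed = seed, ...)
}

#' Organization report for a developmental run
#'
#' Regenerates a window of stationary input from the trained configuration,
#' computes boxcar-filtered pairwise correlations, and assembles the
#' pairwise (distance, correlation, orientation difference, receptive-field
#' overlap) and per-synapse (path distance to soma, circular dispersion,
#' receptive-field offset) tables plus scalar summaries.
#'
#' @param run a `clustering_run`.
#' @param window_min minutes of activity for the correlation estimate.
#' @param fit_cluster_size attempt the Gaussian cluster-size fit.
#' @return List of class `organization_report` with elements `pairs`,
#'   `synapses`, `scalars`.
#' @export
organization_report <- function(run, window_min = 30,
                                fit_cluster_size = FALSE) {
  syn <- run$synapses
  N <- nrow(syn)
  set.seed(run$report_seed)
  tr <- .draw_pool_events(run$p_on, syn$pool_idx, 0, window_min * 60000,
                          run$stim_geom$frame_interval, run$params$x_dur)
  C <- boxcar_correlation(tr)
  ## rasterized filters of the live synapses for overlap
  grid <- .movie_grid(run$stim_geom$extent, run$stim_geom$pixel_scale)
  Fs <- .rf_filter_matrix(list(n = grid$n, ax = grid$ax),
                          run$pool[syn$pool_idx, ])
  npx <- nrow(Fs)
  mns <- Matrix::colMeans(Fs)
  Gram <- as.matrix(Matrix::crossprod(Fs)) / npx
  covm <- Gram - outer(mns, mns)
  sds <- sqrt(pmax(diag(covm), 0))
  Ov <- covm / outer(sds, sds)
  ut <- which(upper.tri(run$distances), arr.ind = TRUE)
  pairs <- data.frame(
    i = ut[, 1], j = ut[, 2],
    distance = run$distances[ut],
    correlation = C[ut],
    dtheta = orientation_difference(syn$theta[ut[, 1]], syn$theta[ut[, 2]]),
    overlap = Ov[ut])
  th_soma <- somatic_preference(syn$theta, axial = TRUE)
  per_syn <- data.frame(
    id = syn$id,
    soma_dist = run$soma_dist,
    theta = syn$theta,
    dispersion = circular_dispersion(syn$theta, th_soma),
    rf_offset = rf_offset(cbind(syn$cx, syn$cy)))
  sv <- survival_stats(run$turnover_log, run$n_initial,
                       t_grid_ms = seq(0, run$days * 86400000,
                                       length.out = 50),
                       end_ms = run$days * 86400000)
  scalars <- list(theta_soma = th_soma,
                  survival_final = sv$survival_final,
                  turnovers = nrow(run$turnover_log),
                  mean_rate_per_min = mean(event_rate(tr)),
                  bap_count = run$bap_count)
  if (fit_cluster_size) {
    scalars$cluster_lambda <- tryCatch(
      cluster_size_fit(pairs)$lambda, error = function(e) NA_real_)
  }
  structure(list(pairs = pairs, synapses = per_syn, scalars = scalars,
                 survival = sv),
            class = "organization_report")
}

#' @export
print.organization_report <- function(x, ...) {
  cat(sprintf("<organization_report> %d pairs, %d synapses, survival %.2f\n",
              nrow(x$pairs), nrow(x$synapses), x$scalars$survival_final))
  invisible(x)
}

#' Inhibitory co-clustering simulation
#'
#' Neurotrophin-model branch run with plastic GABAergic synapses whose
#' efficacies follow the proximity-weighted sum of B - P over excitatory
#' synapses.  Scenario A (`"inhibitory"`): GABA subtracts calcium and Y is
#' floored at 0.  Scenario B (`"excitatory-then-switch"`): GABA adds calcium
#' until `switch_day`, then subtracts.
#'
#' @inheritParams run_branch_clustering
#' @param scenario `"A"` or `"B"`.
#' @param nu_gaba GABA synapse density (per um).
#' @return List with the synapse tables (incl. GABA), turnover log and the
#'   per-excitatory-synapse orientation difference to the nearest GABA
#'   synapse.
#' @export
run_inhibitory <- function(scenario = c("A", "B"), species = "ferret",
                           days = 0.5,
                           dendrite = linear_dendrite(150, TRUE),
                           nu = 0.2, nu_gaba = 0.04,
                           params = plasticity_params(),
                           dt = 5, epoch_s = 300, loop_s = 360,
                           pool_size = 800, extent = 120, pixel_scale = 1,
                           frame_interval = 50, a = 0.2, b = 9.4,
                           wave_args = list(wave_speed = 100, wave_rate = 6,
                                            wave_width = 10,
                                            wave_kind = "ring"),
                           seed = 1) {
  scenario <- match.arg(scenario)
  params$gaba_mode <- if (scenario == "A") "inhibitory"
                      else "excitatory-then-switch"
  sp <- species_preset(species)
  ss <- .substreams(seed, 8)
  syn <- place_synapses(dendrite, nu, seed = ss[1])
  gsyn <- place_synapses(dendrite, nu_gaba, seed = ss[7], type = "GABA")
  N <- nrow(syn); NI <- nrow(gsyn)
  pool <- sample_receptive_fields(pool_size, sp$sigma_p, sp$diameter,
                                  seed = ss[2])
  syn$pool_idx <- seq_len(N)
  gsyn$pool_idx <- N + seq_len(NI)
  for (tb in c("syn", "gsyn")) {
    t0 <- get(tb)
    t0$theta <- pool$theta[t0$pool_idx]
    t0$cx <- pool$x[t0$pool_idx]; t0$cy <- pool$y[t0$pool_idx]
    assign(tb, t0)
  }
  p_on <- .encode_pool(pool, "waves", loop_s * 1000, extent, pixel_scale,
                       frame_interval, a, b, wave_args, ss[3])
  all_pos <- function() {
    if (dendrite$mode == "linear")
      c(syn$pos, gsyn$pos)
    else stop("inhibitory runs use linear branches")
  }
  D_all <- pairwise_distance(dendrite, all_pos())
  S_all <- proximity_matrix(D_all, params$sigma_c, params$proximity_cutoff)
  S <- S_all[seq_len(N), seq_len(N)]
  S_ei <- S_all[seq_len(N), N + seq_len(NI), drop = FALSE]

  epoch_ms <- epoch_s * 1000
  n_epochs <- as.integer(round(days * 86400 / epoch_s))
  state <- list(M = numeric(N), Y = numeric(N), P = numeric(N),
                B = numeric(N), W = rep(0.5, N), W_gaba = rep(0.5, NI))
  log <- data.frame(time_ms = numeric(0), old_id = integer(0),
                    new_position_um = numeric(0), new_theta_deg = numeric(0),
                    type = character(0))
  switch_ms <- params$switch_day * 86400000
  set.seed(ss[4])
  for (ep in seq_len(n_epochs)) {
    t0 <- (ep - 1) * epoch_ms
    tr <- .draw_pool_events(p_on, syn$pool_idx, t0, epoch_ms, frame_interval,
                            params$x_dur)
    gtr <- .draw_pool_events(p_on, gsyn$pool_idx, t0, epoch_ms,
                             frame_interval, params$x_dur)
    res <- simulate_neurotrophin(tr, S, params, dt = dt,
                                 gaba_trains = gtr, S_ei = S_ei,
                                 state = state,
                                 gaba_switch_ms = switch_ms - t0)
    state <- list(M = res$M, Y = res$Y, P = res$P, B = res$B, W = res$W,
                  W_gaba = res$W_gaba)
    ## turnover for both populations
    for (popn in c("E", "I")) {
      wvec <- if (popn == "E") state$W else state$W_gaba
      tab <- if (popn == "E") syn else gsyn
      dead <- which(wvec < params$W_thr)
      if (!length(dead)) next
      newidx <- sample.int(nrow(pool), length(dead), replace = TRUE)
      tab$pos[dead] <- runif(length(dead), 0, dendrite$L)
      tab$pool_idx[dead] <- newidx
      tab$theta[dead] <- pool$theta[newidx]
      tab$cx[dead] <- pool$x[newidx]; tab$cy[dead] <- pool$y[newidx]
      tab$birth_ms[dead] <- t0 + epoch_ms
      wvec[dead] <- 0.5
      if (popn == "E") {
        state$W <- wvec; state$M[dead] <- 0; state$Y[dead] <- 0
        state$P[dead] <- 0; state$B[dead] <- 0; syn <- tab
      } else {
        state$W_gaba <- wvec; gsyn <- tab
      }
      log <- rbind(log, data.frame(time_ms = t0 + epoch_ms,
                                   old_id = tab$id[dead],
                                   new_position_um = tab$pos[dead],
                                   new_theta_deg = tab$theta[dead],
                                   type = popn))
      D_all <- pairwise_distance(dendrite, all_pos())
      S_all <- proximity_matrix(D_all, params$sigma_c,
                                params$proximity_cutoff)
      S <- S_all[seq_len(N), seq_len(N)]
      S_ei <- S_all[seq_len(N), N + seq_len(NI), drop = FALSE]
    }
  }
  syn$efficacy <- state$W
  gsyn$efficacy <- state$W_gaba
  ## orientation relation to the nearest GABA synapse
  d_ei <- abs(outer(syn$pos, gsyn$pos, "-"))
  if (dendrite$periodic) d_ei <- pmin(d_ei, dendrite$L - d_ei)
  nearest <- apply(d_ei, 1, which.min)
  ei <- data.frame(
    exc_id = syn$id,
    gaba_id = gsyn$id[nearest],
    distance = d_ei[cbind(seq_len(N), nearest)],
    dtheta = orientation_difference(syn$theta, gsyn$theta[nearest]))
  list(scenario = scenario, synapses = syn, gaba = gsyn,
       turnover_log = log, ei_relation = ei, params = params)
}
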
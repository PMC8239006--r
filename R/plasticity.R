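## Plasticity simulators.
##
## The compiled core advances the state; the R functions here prepare event
## feeds, proximity matrices and parameters, and expose single-step reference
## updates used by the tests to pin the compiled arithmetic.

## events (ms onsets per synapse) -> sorted (synapse, step) pairs
.events_to_steps <- function(trains, dt, n_steps = NULL) {
  ons <- trains$onsets
  syn <- rep(seq_along(ons), vapply(ons, length, 1L))
  stp <- floor(unlist(ons) / dt)
  if (!is.null(n_steps)) {
    keep <- stp < n_steps
    syn <- syn[keep]; stp <- stp[keep]
  }
  o <- order(stp)
  list(syn = as.integer(syn[o] - 1L), step = as.integer(stp[o]),
       dur = as.integer(max(1, round(trains$x_dur / dt))))
}

.coop_csr <- function(D, spacing) {
  n <- nrow(D)
  idx <- lapply(seq_len(n), function(k) which(D[k, ] <= spacing & seq_len(n) != k) - 1L)
  list(ptr = as.integer(c(0, cumsum(vapply(idx, length, 1L)))),
       idx = as.integer(unlist(idx)))
}

#' Sigmoidal dendritic nonlinearity
#'
#' `g(I) = gamma * c1 / (1 + exp(-c2*(I - c3))) + (1 - gamma) * I`.
#' `gamma = 0` is the identity (linear dendrite); `gamma = 1` is a pure
#' sigmoid saturating at `c1`.
#'
#' @param I postsynaptic drive (vectorized).
#' @param gamma nonlinearity strength in \[0, 1\].
#' @param c1,c2,c3 sigmoid amplitude, slope and midpoint.
#' @export
dendritic_nonlinearity <- function(I, gamma = 0, c1 = 0.5, c2 = 35,
                                   c3 = 0.125) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  gamma * c1 / (1 + exp(-c2 * (I - c3))) + (1 - gamma) * I
}

#' Cooperativity gate
#'
#' TRUE for synapse k iff strictly more than `min_count` other synapses
#' within `spacing_thr` (path distance) were active within the trailing
#' `timing_thr` window.  When FALSE the efficacy update of k is suppressed.
#'
#' @param last_active_ms per-synapse time of most recent activity (-Inf if
#'   never active).
#' @param now_ms current time.
#' @param distances pairwise distance matrix (um).
#' @param spacing_thr spacing threshold (um).
#' @param timing_thr timing threshold (ms).
#' @param min_count required neighbor count (gate opens when count >
#'   min_count).
#' @export
cooperativity_gate <- function(last_active_ms, now_ms, distances,
                               spacing_thr = 10, timing_thr = 100,
                               min_count = 3) {
  n <- length(last_active_ms)
  recent <- (now_ms - last_active_ms) <= timing_thr
  vapply(seq_len(n), function(k) {
    nb <- distances[k, ] <= spacing_thr & seq_len(n) != k
    sum(recent & nb) > min_count
  }, logical(1))
}

#' Simulate the generalized neurotrophin-inspired model
#'
#' Integrates `tau_v vdot = -v + phi_eff x`, `tau_u udot = -u + g(sum_l s_kl
#' w_l x_l) [+ s_k B_amp B(t)]`, `tau_w wdot = F(u (v + rho))` with w clipped
#' to \[0, 1\], by explicit Euler at step `dt`.  Optional pieces: dendritic
#' nonlinearity (`params$gamma > 0`), cooperativity gate, threshold-triggered
#' probabilistic backpropagating action potentials, forced bAP times.
#'
#' @param trains an `event_train_set` of presynaptic events.
#' @param S proximity matrix.
#' @param params a [plasticity_params()].
#' @param duration_ms simulated time (defaults to the train duration).
#' @param dt Euler step (ms).
#' @param w0,v0,u0 initial state (scalars recycled).
#' @param freeze_w keep efficacies fixed (measure instantaneous change).
#' @param coop_on enable the cooperativity gate (needs `distances`).
#' @param distances pairwise distances, required when `coop_on`.
#' @param bap_on enable threshold bAPs; `soma_dist` gives per-synapse path
#'   distances to the soma for the attenuation factor.
#' @param soma_dist path distances to soma (um).
#' @param forced_bap_ms times at which a bAP is forced (e.g. pairing
#'   protocols).
#' @param drive_scale scaling of the per-event calcium increment.
#' @param record_every_ms record trajectories every this many ms (0 = none).
#' @param seed integer seed for the bAP Bernoulli draws.
#' @return List with final `v`, `u`, `w`, per-synapse `mean_dw` (time-average
#'   of the unclipped update, per ms), trajectory `w_hist`, bAP counts/times.
#' @export
simulate_generalized <- function(trains, S, params = plasticity_params(),
                                 duration_ms = NULL, dt = 5,
                                 w0 = 0.5, v0 = 0, u0 = 0,
                                 freeze_w = FALSE,
                                 coop_on = FALSE, distances = NULL,
                                 bap_on = FALSE, soma_dist = NULL,
                                 forced_bap_ms = numeric(0),
                                 drive_scale = 1,
                                 record_every_ms = 0, seed = 1,
                                 record_A = FALSE) {
  n <- nrow(S)
  if (trains$n != n) stop("trains and proximity matrix disagree in size")
  if (is.null(duration_ms)) duration_ms <- trains$duration_ms
  n_steps <- as.integer(round(duration_ms / dt))
  ev <- .events_to_steps(trains, dt, n_steps)
  coop <- if (coop_on) {
    if (is.null(distances)) stop("coop_on requires distances")
    .coop_csr(distances, params$coop_spacing)
  } else list(ptr = integer(n + 1), idx = integer(0))
  sk <- if (!is.null(soma_dist)) {
    bap_attenuation(soma_dist, params$bap_sigma)
  } else rep(1, n)
  res <- cpp_sim_generalized(
    n_steps, dt, ev$syn, ev$step, ev$dur,
    S, sk,
    rep_len(v0, n), rep_len(u0, n), rep_len(w0, n),
    params$tau_v, params$tau_u, params$tau_w,
    params$phi * params$x_dur, params$rho,
    params$gamma, params$c1, params$c2, params$c3,
    coop_on, coop$ptr, coop$idx, params$coop_timing, params$coop_min,
    freeze_w,
    bap_on, params$A_th, params$bap_prob, params$B_amp,
    as.integer(round(params$x_dur / dt)), params$bap_refractory,
    as.integer(sort(round(forced_bap_ms / dt))),
    drive_scale,
    if (record_every_ms > 0) as.integer(round(record_every_ms / dt)) else 0L,
    as.integer(seed), record_A)
  res$time_hist <- if (record_every_ms > 0)
    seq(0, by = record_every_ms, length.out = ncol(res$w_hist)) else numeric(0)
  res
}

#' Simulate the full neurotrophin model
#'
#' Integrates the MMP9 (M), calcium (Y), proBDNF (P), BDNF (B) and efficacy
#' (W) equations, with the M*P conversion moving proBDNF to BDNF, optional
#' GABAergic synapses (efficacies following the proximity-weighted sum of
#' B - P; calcium contribution excitatory, inhibitory, or switching at
#' `params$switch_day`), and optional forced bAP events injecting
#' `B_amp * s_k` into the calcium equation.
#'
#' @inheritParams simulate_generalized
#' @param gaba_trains optional `event_train_set` for GABAergic synapses.
#' @param S_ei proximity of excitatory (rows) to GABAergic (cols) synapses.
#' @param Wg0 initial GABA efficacies.
#' @param freeze_W keep excitatory efficacies fixed.
#' @param record_every_ms trajectory recording interval (0 = none).
#' @return List with final `M`, `Y`, `P`, `B`, `W`, `W_gaba`, per-synapse
#'   `mean_BP` (time average of B - P), and trajectories.
#' @export
simulate_neurotrophin <- function(trains, S, params = plasticity_params(),
                                  duration_ms = NULL, dt = 1,
                                  w0 = 0.5,
                                  gaba_trains = NULL, S_ei = NULL, Wg0 = 0.5,
                                  freeze_W = FALSE,
                                  soma_dist = NULL,
                                  forced_bap_ms = numeric(0),
                                  drive_scale = 1,
                                  record_every_ms = 0,
                                  state = NULL, gaba_switch_ms = NULL) {
  n <- nrow(S)
  if (trains$n != n) stop("trains and proximity matrix disagree in size")
  if (dt > min(params$tau_P, params$tau_B) * 2)
    warning("dt is large relative to tau_P/tau_B; the exponential update ",
            "remains stable but temporal detail is lost")
  if (is.null(duration_ms)) duration_ms <- trains$duration_ms
  n_steps <- as.integer(round(duration_ms / dt))
  ev <- .events_to_steps(trains, dt, n_steps)
  ni <- 0L
  if (!is.null(gaba_trains)) {
    if (is.null(S_ei)) stop("GABA synapses need S_ei")
    ni <- gaba_trains$n
    gev <- .events_to_steps(gaba_trains, dt, n_steps)
  } else {
    S_ei <- matrix(0, n, 0)
    gev <- list(syn = integer(0), step = integer(0))
  }
  mode <- params$gaba_mode
  gaba_sign0 <- switch(mode, off = 0L, inhibitory = -1L,
                       `excitatory-then-switch` = 1L,
                       stop("unknown gaba_mode: ", mode))
  if (is.null(gaba_switch_ms) && identical(mode, "excitatory-then-switch"))
    gaba_switch_ms <- params$switch_day * 86400000
  switch_step <- if (identical(mode, "excitatory-then-switch"))
    as.integer(round(gaba_switch_ms / dt)) else n_steps + 1L
  y_floor <- identical(mode, "inhibitory")
  sk <- if (!is.null(soma_dist)) {
    bap_attenuation(soma_dist, params$bap_sigma)
  } else rep(1, n)
  if (is.null(state))
    state <- list(M = numeric(n), Y = numeric(n), P = numeric(n),
                  B = numeric(n), W = rep_len(w0, n),
                  W_gaba = rep_len(Wg0, ni))
  res <- cpp_sim_neurotrophin(
    n_steps, dt, ev$syn, ev$step, ev$dur,
    gev$syn, gev$step,
    S, S_ei, sk,
    state$M, state$Y, state$P, state$B, state$W,
    state$W_gaba,
    params$tau_M, params$tau_Y, params$tau_P, params$tau_B, params$tau_W,
    params$phi * params$x_dur, params$eta, params$alpha, params$beta,
    gaba_sign0, switch_step, y_floor, freeze_W,
    as.integer(sort(round(forced_bap_ms / dt))), params$B_amp,
    as.integer(round(params$x_dur / dt)),
    drive_scale,
    if (record_every_ms > 0) as.integer(round(record_every_ms / dt)) else 0L)
  res$time_hist <- if (record_every_ms > 0)
    seq(0, by = record_every_ms, length.out = ncol(res$W_hist)) else numeric(0)
  res
}

#' Single Euler step of the generalized model (reference implementation)
#'
#' Pure-R update mirroring one step of the compiled core, used to document
#' and test the arithmetic.  `state` is a list with `v`, `u`, `w`.
#'
#' @param state list(v, u, w).
#' @param x 0/1 event indicator vector.
#' @param S proximity matrix.
#' @param dt step (ms).
#' @param params a [plasticity_params()].
#' @param bap 0/1 somatic signal; `sk` attenuation factors.
#' @param sk per-synapse bAP attenuation.
#' @return Updated state list.
#' @export
step_generalized <- function(state, x, S, dt, params = plasticity_params(),
                             bap = 0, sk = rep(1, length(x))) {
  phi_eff <- params$phi * params$x_dur
  ## the bAP injection bypasses the dendritic nonlinearity
  drive_g <- dendritic_nonlinearity(as.vector(S %*% (state$w * x)),
                                    params$gamma, params$c1, params$c2,
                                    params$c3) + sk * params$B_amp * bap
  v <- state$v + dt / params$tau_v * (-state$v + phi_eff * x)
  u <- state$u + dt / params$tau_u * (-state$u + drive_g)
  w <- pmin(1, pmax(0, state$w + dt * u * (v + params$rho) / params$tau_w))
  list(v = v, u = u, w = w)
}

#' Single step of the neurotrophin model (reference implementation)
#'
#' Euler for M, Y, W; exact exponential update for the stiff P/B pair given
#' step-frozen M and Y (P first, then B with the mid-step P in the
#' conversion term), mirroring the compiled core.
#'
#' @param state list(M, Y, P, B, W).
#' @param x 0/1 event indicator.
#' @param S proximity matrix.
#' @param dt step (ms).
#' @param params a [plasticity_params()].
#' @param x_gaba,W_gaba,S_ei,gaba_sign optional GABA drive pieces.
#' @param bap,sk optional somatic calcium injection.
#' @return Updated state list.
#' @export
step_neurotrophin <- function(state, x, S, dt, params = plasticity_params(),
                              x_gaba = NULL, W_gaba = NULL, S_ei = NULL,
                              gaba_sign = 0, bap = 0,
                              sk = rep(1, length(x))) {
  phi_eff <- params$phi * params$x_dur
  drive <- as.vector(S %*% (state$W * x)) + sk * params$B_amp * bap
  if (!is.null(x_gaba) && gaba_sign != 0)
    drive <- drive + gaba_sign * as.vector(S_ei %*% (W_gaba * x_gaba))
  M <- state$M + dt / params$tau_M * (-state$M + phi_eff * x)
  Y <- state$Y + dt / params$tau_Y * (-state$Y + drive)
  if (identical(params$gaba_mode, "inhibitory")) Y <- pmax(Y, 0)
  Pss <- (1 - params$eta) * Y / (1 + M)
  eP <- exp(-(1 + M) * dt / params$tau_P)
  Pnew <- Pss + (state$P - Pss) * eP
  Pbar <- (state$P + Pnew) / 2
  Bss <- params$eta * Y + M * Pbar
  B <- Bss + (state$B - Bss) * exp(-dt / params$tau_B)
  W <- pmin(1, pmax(0, state$W + dt / params$tau_W *
                      (params$alpha * B - params$beta * Pnew)))
  out <- list(M = M, Y = Y, P = Pnew, B = B, W = W)
  if (!is.null(W_gaba)) {
    out$W_gaba <- pmin(1, pmax(0, W_gaba + dt / params$tau_W *
                                 as.vector(t(S_ei) %*% (B - Pnew))))
  }
  out
}
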
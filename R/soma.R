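## Somatic accumulator and backpropagating action potentials.

#' Somatic drive
#'
#' `A = sum_k w_k u_k`, the linear sum of postsynaptic accumulators weighted
#' by efficacy.  The bAP feedback contribution must be excluded from `u`
#' before summing (the simulator keeps a bAP-free copy of u for exactly this
#' purpose, avoiding a positive feedback loop).
#'
#' @param w efficacies; @param u postsynaptic accumulators.
#' @export
somatic_drive <- function(w, u) {
  if (length(w) != length(u)) stop("w and u must align")
  sum(w * u)
}

#' Probabilistic bAP generation at threshold crossing
#'
#' Returns 1 with probability `bap_prob` when `A` crosses `A_th` from below
#' (`prev_A < A_th <= A`), 0 otherwise.
#'
#' @param A current somatic drive; @param prev_A drive at the previous step.
#' @param A_th threshold; @param bap_prob firing probability per crossing.
#' @export
maybe_fire_bap <- function(A, prev_A, A_th = 25, bap_prob = 0.25) {
  if (prev_A < A_th && A >= A_th) as.integer(runif(1) < bap_prob) else 0L
}

#' bAP attenuation factor
#'
#' `s_k = exp(-d_k^2 / (2*sigma_bap^2))`: the calcium delivered to synapse k
#' by a somatic bAP is `s_k * B_amp`.
#'
#' @param d path distance to the soma (um, vectorized).
#' @param sigma_bap attenuation factor (um), typically 25, 75 or 125.
#' @export
bap_attenuation <- function(d, sigma_bap = 75) {
  if (any(d < 0)) stop("distances must be non-negative")
  if (sigma_bap <= 0) stop("sigma_bap must be positive")
  exp(-d^2 / (2 * sigma_bap^2))
}

#' Calibrate the bAP threshold to a target somatic burst rate
#'
#' The nominal threshold (25) presumes the full-size reconstruction it was
#' tuned on; for other morphologies the defining property is that the rate
#' of somatic burst initiations (upward threshold crossings) matches the
#' synaptic event rate (~15 per minute).  Placing the threshold this high in
#' the somatic-drive distribution also makes the soma selective: only the
#' strongest collective events — waves driving the dominant synapse
#' population — initiate bursts.  Runs a short probe simulation with frozen
#' efficacies, records the somatic drive, and returns the threshold whose
#' upward-crossing rate hits `target_per_min`.
#'
#' @param trains probe event trains.
#' @param S proximity matrix.
#' @param params a [plasticity_params()].
#' @param soma_dist path distances to the soma.
#' @param target_per_min target crossing (burst-initiation) rate.
#' @param dt Euler step (ms).
#' @return Calibrated threshold (same units as A).
#' @export
calibrate_bap_threshold <- function(trains, S, params = plasticity_params(),
                                    soma_dist = NULL, target_per_min = 15,
                                    dt = 5) {
  probe <- simulate_generalized(trains, S, params, dt = dt, freeze_w = TRUE,
                                bap_on = TRUE, soma_dist = soma_dist,
                                record_A = TRUE, seed = 1)
  threshold_for_crossings(probe$A_full, trains$duration_ms / 60000,
                          target_per_min, params$bap_refractory / dt)
}

## threshold whose upward-crossing count (with a refractory gap) best
## matches target_per_min over `minutes` of somatic drive trace
threshold_for_crossings <- function(A, minutes, target_per_min = 15,
                                    refractory_steps = 40) {
  cand <- stats::quantile(A, probs = c(seq(0.5, 0.99, by = 0.01),
                                       seq(0.991, 0.9999, by = 0.0005)),
                          names = FALSE)
  cand <- unique(cand[cand > 0])
  if (!length(cand)) return(Inf)
  target <- target_per_min * minutes
  n <- length(A)
  count_cross <- function(th) {
    up <- which(A[-1] >= th & A[-n] < th)
    if (length(up) < 2) return(length(up))
    ## enforce the refractory gap between counted crossings
    keep <- 1L; last <- up[1]
    for (i in up[-1]) if (i - last > refractory_steps) {
      keep <- keep + 1L; last <- i
    }
    keep
  }
  crossings <- vapply(cand, count_cross, 1L)
  cand[which.min(abs(crossings - target))]
}
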
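## Steady-state analytics of the generalized model.
##
## All closed-form results live in event-normalized units: one time unit is
## the event duration x_dur, so phi -> phi*x_dur, an event rate r (events/min)
## becomes the indicator mean mu = r*x_dur/60000, and tau -> tau/x_dur.

## convert to event units
.event_units <- function(params, rate_per_min) {
  list(phi = params$phi * params$x_dur,
       mu = rate_per_min * params$x_dur / 60000,
       tau_u = params$tau_u / params$x_dur,
       tau_v = params$tau_v / params$x_dur,
       rho = params$rho)
}

#' Correlation bound kappa
#'
#' The constant `kappa = (-rho/phi - mu) * (tau_u + tau_v)` separating the
#' regime where the heterosynaptic component stabilizes (input correlation
#' above kappa) from the regime where it can depress (below kappa), evaluated
#' in event-duration time units.  At nominal parameters and a 15 per-minute
#' event rate it is ~0.32.
#'
#' @param params a [plasticity_params()] object.
#' @param rate_per_min presynaptic event rate, events per minute.
#' @return kappa (dimensionless).
#' @examples
#' kappa_bound(plasticity_params(), 15)   # ~0.32
#' @export
kappa_bound <- function(params = plasticity_params(), rate_per_min = 15) {
  e <- .event_units(params, rate_per_min)
  (-e$rho / e$phi - e$mu) * (e$tau_u + e$tau_v)
}

#' Critical input correlation
#'
#' `c* = (kappa*S - 1)/(S - 1)` with the neighborhood sum
#' `S = sqrt(2*pi) * sigma_c * nu`.  For correlations above `c*` synapses on a
#' homogeneously driven branch potentiate on average, below it they depress
#' (when `S > 1`); as density grows, `c*` approaches `kappa` from below.
#'
#' @param nu synaptic density (per um).
#' @param sigma_c calcium spread standard deviation (um).
#' @param kappa correlation bound, e.g. from [kappa_bound()].
#' @return c* (may fall outside \[0, 1\], in which case no sign change occurs
#'   for admissible correlations).
#' @examples
#' critical_correlation(0.5, 6, 0.32)  # ~0.216
#' @export
critical_correlation <- function(nu, sigma_c = 6, kappa = 0.32) {
  S <- sqrt(2 * pi) * sigma_c * nu
  if (any(abs(S - 1) < 1e-12)) stop("singular neighborhood sum S = 1")
  (kappa * S - 1) / (S - 1)
}

#' FWHM to Gaussian standard deviation
#'
#' `sigma = fwhm / (2*sqrt(2*log(2)))`, used to translate measured calcium
#' propagation distances (full width at half maximum) into the spread
#' constant `sigma_c`.
#'
#' @param fwhm full width at half maximum (> 0).
#' @examples
#' fwhm_to_sigma(7.97)   # ~3.4 um
#' fwhm_to_sigma(17.6)   # ~7.5 um
#' @export
fwhm_to_sigma <- function(fwhm) {
  if (any(fwhm <= 0)) stop("fwhm must be positive")
  fwhm / (2 * sqrt(2 * log(2)))
}

## \int tri(t) * Gamma(t) dt for boxcar events: tri(t) = (1-|t|)+ in event
## units; Gamma(t) = exp(-|t|/tau_u) / (tau_u + tau_v).
.kernel_overlap <- function(tau_u, tau_v) {
  f <- function(t) (1 - abs(t)) * exp(-abs(t) / tau_u) / (tau_u + tau_v)
  2 * stats::integrate(f, 0, 1, rel.tol = 1e-8)$value
}

#' Expected change in synaptic efficacy
#'
#' Long-run expected `dw/dt` for every synapse on a branch, for stationary
#' boxcar event trains with pairwise count correlations `c_kl`:
#' `tau_w <dw_k/dt> = phi * sum_l s_kl w_l (int gammabar_kl Gamma + mu_k mu_l)
#'  + rho * sum_l s_kl w_l mu_l`,
#' where the cross-covariance of two correlated boxcar trains is
#' `gammabar_kl(t) = c_kl * min(mu_k, mu_l) * (1-|t|)+` (event units) and the
#' autocovariance uses `c_kk = 1`.  Evaluated by numerical quadrature of the
#' covariance-kernel overlap.
#'
#' @param rates per-synapse event rates (events/min); scalar is recycled.
#' @param corr pairwise correlation: scalar (homogeneous, applied to all
#'   off-diagonal pairs) or full matrix.
#' @param w synaptic efficacies.
#' @param s proximity matrix (unit diagonal).
#' @param params a [plasticity_params()] object.
#' @return Expected `dw/dt` per synapse, per ms.
#' @export
expected_weight_change <- function(rates, corr, w, s,
                                   params = plasticity_params()) {
  n <- nrow(s)
  rates <- rep_len(rates, n)
  if (any(rates < 0)) stop("rates must be non-negative")
  w <- rep_len(w, n)
  C <- if (is.matrix(corr)) corr else matrix(corr, n, n)
  if (any(C < -1 | C > 1)) stop("correlations must lie in [-1, 1]")
  diag(C) <- 1
  e <- .event_units(params, 1)   # just for taus/phi/rho
  mu <- rates * params$x_dur / 60000
  G <- .kernel_overlap(e$tau_u, e$tau_v)
  ## covariance amplitude for pair (k,l): c_kl * min(mu_k, mu_l)
  Mmin <- outer(mu, mu, pmin)
  cov_term <- C * Mmin * G
  drive <- e$phi * as.vector((s * (cov_term + outer(mu, mu))) %*% w) +
    e$rho * as.vector(s %*% (w * mu))
  ## drive = tau_w <wdot> in event units; convert to per ms
  drive / (params$tau_w / params$x_dur) / params$x_dur
}

#' Analytic sign of the mean efficacy change on a homogeneous branch
#'
#' Homogeneous-branch specialization of [expected_weight_change()] with the
#' continuum neighborhood sum `S = sqrt(2*pi)*sigma_c*nu`; its zero contour in
#' the (density, correlation) plane is the critical correlation `c*`.
#'
#' @inheritParams critical_correlation
#' @param c input correlation.
#' @param params a [plasticity_params()] object.
#' @param rate_per_min event rate.
#' @return Signed drive (same sign as the expected efficacy change).
#' @export
homogeneous_drive <- function(nu, c, params = plasticity_params(),
                              rate_per_min = 15) {
  e <- .event_units(params, rate_per_min)
  S <- sqrt(2 * pi) * params$sigma_c * nu
  G <- .kernel_overlap(e$tau_u, e$tau_v)
  mu <- e$mu
  e$phi * (mu * G * (1 + (S - 1) * c) + S * mu^2) + e$rho * S * mu
}

#' Linearized two-synapse protocol prediction
#'
#' Predicted efficacy change rates for the protocol where one of two synapses
#' is driven with events at `rate_per_min` while the other is silent:
#' the driven synapse follows `K1*mu + K2*mu^2` and the silent one
#' `K3 * mu * exp(-d^2/(2*sigma_c^2))`.  The constants are obtained
#' numerically from the expected-change quadrature specialized to this
#' configuration (they are not free parameters).
#'
#' @param rate_per_min event rates to evaluate (vector, events/min).
#' @param d distances between the two synapses (um, vector).
#' @param params a [plasticity_params()] object.
#' @param w frozen efficacy of both synapses.
#' @return List with `constants` (K1, K2, K3, per event-unit mu) and a data
#'   frame `grid` (rate, distance, dw_stimulated, dw_unstimulated, per ms).
#' @export
linearized_protocol_prediction <- function(rate_per_min = 1:20,
                                           d = seq(0, 15, by = 1),
                                           params = plasticity_params(),
                                           w = 0.5) {
  e <- .event_units(params, 1)
  G <- .kernel_overlap(e$tau_u, e$tau_v)
  ## from the quadrature specialized to (active, silent):
  ## driven:  phi*w*(mu*G + mu^2) + rho*w*mu  -> K1 = w*(phi*G + rho), K2 = phi*w
  ## silent:  rho*w*mu * s(d)                 -> K3 = rho*w
  K1 <- w * (e$phi * G + e$rho)
  K2 <- e$phi * w
  K3 <- e$rho * w
  conv <- 1 / (params$tau_w / params$x_dur) / params$x_dur   # drive -> per ms
  grid <- expand.grid(rate = rate_per_min, distance = d)
  mu <- grid$rate * params$x_dur / 60000
  att <- exp(-grid$distance^2 / (2 * params$sigma_c^2))
  grid$dw_stimulated <- (K1 * mu + K2 * mu^2) * conv
  grid$dw_unstimulated <- K3 * mu * att * conv
  list(constants = c(K1 = K1, K2 = K2, K3 = K3), grid = grid)
}

#' Sample parameter perturbations (sensitivity-analysis priors)
#'
#' Draws parameter sets from the sensitivity priors: `tau_M, tau_v ~
#' N(600, 300)` ms truncated at 5 ms; `tau_Y, tau_u ~ N(300, 150)` ms
#' truncated at 5 ms; `tau_B, tau_P ~ exp(N(4, 1))` ms truncated at 1 ms;
#' `sigma_c ~ N(8, 1)` um truncated at 4 um; `phi ~ N(3/50, 3/500)` per ms;
#' `eta ~ Uniform(0.40, 0.50)`.
#'
#' @param n number of draws.
#' @param seed integer seed.
#' @return Data frame with one row per draw.
#' @export
sample_parameter_perturbations <- function(n, seed = 1) {
  if (n <= 0) stop("n must be positive")
  set.seed(seed)
  rtrunc <- function(n, gen, lower) {
    x <- gen(n)
    while (any(bad <- x < lower)) x[bad] <- gen(sum(bad))
    x
  }
  data.frame(
    tau_M = rtrunc(n, function(m) rnorm(m, 600, 300), 5),
    tau_v = rtrunc(n, function(m) rnorm(m, 600, 300), 5),
    tau_Y = rtrunc(n, function(m) rnorm(m, 300, 150), 5),
    tau_u = rtrunc(n, function(m) rnorm(m, 300, 150), 5),
    tau_B = rtrunc(n, function(m) exp(rnorm(m, 4, 1)), 1),
    tau_P = rtrunc(n, function(m) exp(rnorm(m, 4, 1)), 1),
    sigma_c = rtrunc(n, function(m) rnorm(m, 8, 1), 4),
    phi = rnorm(n, 3 / 50, 3 / 500),
    eta = runif(n, 0.40, 0.50)
  )
}
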
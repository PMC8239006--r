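#' Plasticity model parameters
#'
#' Builds the parameter set shared by the neurotrophin model and its
#' generalized reduction.  Defaults are the nominal values of the model
#' (time constants in ms, distances in um); the `"stdp"` preset switches the
#' accumulator time constants to the fast spike-timing control
#' (tau_M = 60 ms, tau_Y = 1 ms, eta = 0.3, phi = 3/5 per ms).
#'
#' The MMP9 efficiency `phi` is stored per ms as printed; the drive that
#' enters the accumulator equations is the dimensionless `phi * x_dur`
#' (time measured in units of the event duration), the convention under
#' which the analytic correlation bound kappa evaluates to ~0.32.
#'
#' Derived entries: `rho = ((alpha+beta)*eta - beta) / ((alpha+beta)*(1-eta))`
#' and `tau_w = tau_W / ((alpha+beta)*(1-eta))`.
#'
#' @param preset `"nominal"` or `"stdp"`.
#' @param ... named overrides of any parameter (applied before deriving
#'   `rho` and `tau_w`).
#' @return A list of class `"plasticity_params"`.
#' @examples
#' p <- plasticity_params()
#' p$rho      # -1/11
#' p$tau_w    # 6000 / 1.1 ms
#' @export
plasticity_params <- function(preset = c("nominal", "stdp"), ...) {
  preset <- match.arg(preset)
  p <- list(
    preset = preset,
    ## time constants (ms)
    tau_W = 6000, tau_P = 5, tau_B = 5, tau_Y = 300, tau_M = 600,
    tau_u = 300, tau_v = 600,
    ## neurotrophin constants
    eta = 0.45, phi = 3 / 50, alpha = 1, beta = 1,
    ## space
    sigma_c = 6, proximity_cutoff = 5,   # cutoff in multiples of sigma_c
    ## events
    x_dur = 50,
    ## structural plasticity
    W_thr = 0.02,
    ## soma / bAP
    A_th = 25, B_amp = 5, bap_prob = 0.25, bap_sigma = 75,
    bap_refractory = 200,
    ## dendritic nonlinearity (gamma = 0 disables)
    gamma = 0, c1 = 0.5, c2 = 35, c3 = 0.125,
    ## cooperativity gate (off unless coop_on in the simulators)
    coop_spacing = 10, coop_timing = 100, coop_min = 3,
    ## inhibitory plasticity
    gaba_mode = "off", switch_day = 4
  )
  if (preset == "stdp") {
    p$tau_M <- 60;  p$tau_v <- 60
    p$tau_Y <- 1;   p$tau_u <- 1
    p$eta <- 0.3;   p$phi <- 3 / 5
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(p$eta > 0, p$eta < 1, p$alpha + p$beta > 0,
            p$tau_W > 0, p$tau_u > 0, p$tau_v > 0, p$x_dur > 0)
  d <- derive_generalized_params(p$eta, p$alpha, p$beta, p$tau_W)
  p$rho <- d[["rho"]]
  p$tau_w <- d[["tau_w"]]
  class(p) <- "plasticity_params"
  p
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat("<plasticity_params> preset:", x$preset, "\n")
  cat(sprintf("  eta=%.3g phi=%.3g/ms rho=%.4g tau_w=%.4g ms sigma_c=%g um\n",
              x$eta, x$phi, x$rho, x$tau_w, x$sigma_c))
  invisible(x)
}

#' Derived constants of the generalized model
#'
#' `rho` (heterosynaptic offset) and `tau_w` (efficacy time constant of the
#' reduced model) from the neurotrophin parameters:
#' `rho = ((alpha+beta)*eta - beta)/((alpha+beta)*(1-eta))`,
#' `tau_w = tau_W/((alpha+beta)*(1-eta))`.  With balanced binding affinities
#' (`alpha = beta = 1`) this is `rho = (2*eta-1)/(2*(1-eta))`.
#'
#' @param eta constitutive BDNF fraction, in (0, 1).
#' @param alpha,beta BDNF / proBDNF binding-affinity gains (default 1).
#' @param tau_W efficacy time constant of the full model (ms).
#' @return Named numeric vector with `rho` and `tau_w`.
#' @examples
#' derive_generalized_params(0.45)        # rho = -1/11
#' derive_generalized_params(0.5)[["rho"]]  # 0
#' @export
derive_generalized_params <- function(eta, alpha = 1, beta = 1, tau_W = 6000) {
  if (!is.finite(eta) || eta <= 0 || eta >= 1)
    stop("eta must lie strictly inside (0, 1)")
  if (alpha + beta <= 0) stop("alpha + beta must be positive")
  ab <- alpha + beta
  c(rho = (ab * eta - beta) / (ab * (1 - eta)),
    tau_w = tau_W / (ab * (1 - eta)))
}

#' Species receptive-field presets
#'
#' Receptive-field center spread `sigma_p` (deg) and Gabor diameter (deg)
#' for the three species used throughout: ferret (5.3, 13.4), mouse (26, 20)
#' and macaque (2, 2).
#'
#' @param species `"ferret"`, `"mouse"` or `"macaque"`.
#' @return List with `species`, `sigma_p`, `diameter`.
#' @export
species_preset <- function(species = c("ferret", "mouse", "macaque")) {
  species <- match.arg(species)
  switch(species,
    ferret  = list(species = "ferret",  sigma_p = 5.3, diameter = 13.4),
    mouse   = list(species = "mouse",   sigma_p = 26,  diameter = 20),
    macaque = list(species = "macaque", sigma_p = 2,   diameter = 2))
}
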
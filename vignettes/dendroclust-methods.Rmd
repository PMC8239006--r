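---
title: "Models and methods behind dendroclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dendroclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendroclust)
```

# The scientific problem

Synapses on the dendrites of developing cortical pyramidal neurons are not
arranged at random: nearby synapses tend to carry correlated activity, and in
the adult they share stimulus features — receptive-field *orientation* in the
ferret visual cortex, receptive-field *overlap* (retinotopic proximity) in the
mouse.  `dendroclust` simulates a developmental account of how this
organization can emerge from three ingredients: (i) a synapse-local plasticity
rule with timing-dependent cooperation and distance-dependent competition,
(ii) patterned spontaneous input (retinal-wave-like traveling activity)
filtered through species-specific synaptic receptive fields, and (iii)
structural plasticity that replaces silenced synapses.

# The neurotrophin plasticity model

Each excitatory synapse $k$ carries five unitless variables: the
synapse-specific protease accumulator $M_k$ (MMP9), the spatially spreading
postsynaptic calcium $Y_k$, the two neurotrophins $P_k$ (proBDNF) and $B_k$
(BDNF), and the efficacy $W_k \in [0,1]$.  Presynaptic events are 50-ms
boxcars $x_k(t) \in \{0,1\}$.  With proximity weights
$s_{kl} = e^{-d_{kl}^2/2\sigma_c^2}$ (path distance $d_{kl}$, calcium spread
$\sigma_c = 6\,\mu m$):

$$\tau_M \dot M_k = -M_k + \phi\, x_k, \qquad
  \tau_Y \dot Y_k = -Y_k + \textstyle\sum_l s_{kl} W_l x_l,$$
$$\tau_P \dot P_k = -P_k + (1-\eta) Y_k - M_k P_k, \qquad
  \tau_B \dot B_k = -B_k + \eta Y_k + M_k P_k,$$
$$\tau_W \dot W_k = \alpha B_k - \beta P_k .$$

Calcium-triggered release delivers neurotrophin in the constitutive ratio
$\eta = 0.45$ (proBDNF-dominated); MMP9 converts proBDNF to BDNF at the active
synapse.  A driven synapse therefore accumulates a BDNF surplus and
potentiates, while an idle neighbor receives calcium-triggered neurotrophin
without conversion and depresses — distance-dependent heterosynaptic
competition.

## Unit convention for the drive

All times are milliseconds.  The one genuinely open dimensional question is
the drive coefficient $\phi$ ("3/50 per ms"): taken literally against a 0/1
indicator it caps $M$ at 0.06, below the potentiation threshold
$M^\ast = 1-2\eta = 0.1$, so no synapse could ever potentiate.  The steady
state analysis (below) resolves this: the analytic bound
$\kappa \approx 0.32$ is reproduced exactly when time is measured in units of
the 50-ms event duration, i.e. the effective drive is
$\phi_{\mathrm{eff}} = \phi\, x_{\mathrm{dur}} = 3$ on the indicator.  The
package fixes this convention everywhere (simulators and analytics agree by
construction).

## Numerical scheme

Explicit Euler at $dt = 5$ ms for multi-day runs and $dt = 1$ ms for the
induction protocols — except $P$ and $B$, whose linear ODEs are advanced by
their exact exponential solution with $M$ and $Y$ frozen over the step.  Plain
Euler on $P$ is unstable whenever $(1+M)\,dt/\tau_P > 2$ (always true at
$dt = 5$ ms once $M > 1$); the exponential update is unconditionally stable
and exact in the stiff limit, and the hybrid passes a step-halving check
(1-minute trajectories change by $<1\%$ in sup-norm).  Efficacies are clipped
hard to $[0,1]$.  Proximity weights are zeroed beyond $5\sigma_c$ (error
$< 4\times 10^{-6}$ per pair).

# The generalized model

A quasi-steady-state reduction of $P, B$ followed by linearization around
$M = 0$ gives the analytically tractable rule used for the long simulations:

$$\tau_v \dot v_k = -v_k + \phi\, x_k,\qquad
  \tau_u \dot u_k = -u_k + g\!\Big(\sum_l s_{kl} w_l x_l\Big),\qquad
  \tau_w \dot w_k = u_k (v_k + \rho),$$

with $\rho = \frac{(\alpha+\beta)\eta - \beta}{(\alpha+\beta)(1-\eta)} =
-1/11$ at nominal values and $\tau_w = \tau_W / ((\alpha+\beta)(1-\eta))$.
The negative offset $\rho$ is the resting proBDNF surplus: calcium arriving
at a presynaptically silent synapse ($v = 0$) depresses it.  On a two-synapse
instance the two models' efficacy trajectories correlate above 0.999; the
reduction is slightly more potentiation-driven (the discarded higher-order
terms attenuate MMP9), which the package's equivalence test observes as
expected.

$g$ is the optional dendritic nonlinearity
$g(I) = \gamma c_1/(1+e^{-c_2(I-c_3)}) + (1-\gamma) I$
($c_1 = 0.5, c_2 = 35, c_3 = 0.125$; $\gamma = 0$ disables it, and the
$\gamma = 0$ code path is bit-identical to the plain update).  A cooperativity
gate can additionally require more than three neighbors within a spacing
threshold to have been active within a timing threshold before any efficacy
update is applied.

# Steady-state analytics

For stationary boxcar event trains the long-run expected efficacy change is

$$\tau_w \langle \dot w_k\rangle = \phi \sum_l s_{kl} w_l
  \Big( \int \bar\gamma_{kl}(s)\,\Gamma(s)\,ds + \mu_k \mu_l \Big)
  + \rho \sum_l s_{kl} w_l \mu_l,$$

with kernel $\Gamma(t) = e^{-|t|/\tau_u}/(\tau_u + \tau_v)$ and, for the
multiple-interaction-process construction used throughout, cross-covariance
$\bar\gamma_{kl}(t) = c\,\mu\,(1-|t|)_+$ in event units.  The package
evaluates the integral by adaptive quadrature (`stats::integrate`,
tolerance $10^{-8}$); the printed closed form replaces
$\int (1-|t|)_+ e^{-|t|/\tau_u} dt$ by its $e^0$ approximation, which is why
the quadrature contour and the printed $c^\ast$ differ by a few percent near
threshold (the sign tests tolerate this).

Homogeneous branches admit the two constants the package exposes directly:
$\kappa = (-\rho/\phi - \mu)(\tau_u + \tau_v) \approx 0.32$ (the input
correlation above which the heterosynaptic component stabilizes regardless of
density) and the critical correlation
$c^\ast = (\kappa S - 1)/(S - 1)$ with neighborhood sum
$S = \sqrt{2\pi}\,\sigma_c\,\nu$.  The two-synapse induction protocol has the
linearized forms $\langle\dot w_1\rangle = K_1\mu + K_2\mu^2$ (driven) and
$\langle\dot w_2\rangle = K_3\,\mu\,e^{-d^2/2\sigma_c^2}$ (silent);
`linearized_protocol_prediction()` derives the constants from the quadrature
specialized to that configuration
($K_1 = w(\phi G + \rho)$, $K_2 = \phi w$, $K_3 = \rho w$ with $G$ the
kernel-covariance overlap), rather than fitting anything.

# The input stage

## Surrogate waves

Simulating retinal circuitry is beyond this package's scope; it substitutes
parameterized traveling fronts, because the only property the plasticity
model consumes is orientation- and position-selective coactivation.  The
default front geometry is an expanding **ring**: each wave grows at 100°/s
from a random origin point, with a Gaussian cross-section of 10° FWHM, and
waves arrive as a Poisson process at 6 per minute (the arrival rate is the
one calibrated value, fixed once so the LN cascade at its nominal gain
yields the target ~15 events per minute).  Rings were chosen over infinite
straight ridges (still available as `wave_kind = "plane"`) for two reasons:
real retinal waves are compact growing domains, and an infinite coherent
ridge coactivates every aligned receptive field across the whole visual
field simultaneously, which lets orientation alignment alone synchronize
synapses whose receptive fields do not even overlap — erasing the
distinction between orientation-based and overlap-based organization that
the species comparison rests on.  A ring's local front orientation rotates
with viewing angle from its origin, so coherent coactivation additionally
requires receptive fields to be near each other in visual space.
White-noise control movies are i.i.d. Gaussian pixels smoothed with a
2° spatial Gaussian, normalized to unit variance and scaled to amplitude
0.09 — calibrated once so the control is rate-matched (~15 events/min)
through the same nonlinearity; an un-scaled control would drive hundreds of
events per minute through the exponential and confound the comparison.

## Receptive fields and the LN cascade

A synaptic receptive field is a two-lobe Gabor: two opposite-sign Gaussian
lobes of identical shape (long axis $\sigma = $ diameter/4 along the ridge,
short axis diameter/8) displaced by diameter/2 along the orientation axis, so
the composite footprint is about one diameter in every direction.  Each lobe
is normalized to unit absolute integral before differencing, giving the
nonlinearity gain $b$ a diameter-independent meaning, and making the filter
sum exactly zero.  Centers are drawn from a symmetric Gaussian with the
species' spread $\sigma_p$ (ferret 5.3°, mouse 26°, macaque 2°), rejected
and resampled outside the 50° circle; orientations are uniform on [0°, 360°).
The lobe separation is not stated anywhere; diameter/2 was chosen so the
footprint matches the stated diameter and is exposed through the rasterizer.

The filter response drives an exponential nonlinearity
$a\,e^{b\,\langle H, s\rangle}$ ($a = 0.2$ Hz, $b = 9.4$); events are drawn
per 50-ms frame with probability $1 - e^{-\text{rate}\cdot\Delta}$ and
extended to 50 ms, merging overlaps.

# Developmental simulations

Multi-day runs advance in 300-s epochs: events are drawn from the looped
(360 s) stimulus encoding, the compiled stepper integrates the epoch, and
structural plasticity applies at epoch boundaries — every synapse whose
efficacy fell below $W_{\mathrm{thr}} = 0.02$ is replaced at a uniform random
position with a fresh receptive field and efficacy 0.5 (count preserved,
every replacement logged).  Replacement receptive fields are drawn from a
pre-encoded pool of 800 candidates whose members follow exactly the fresh
sampling distribution; this avoids re-filtering the movie at every
replacement and is statistically equivalent to sampling anew.  The loop
length (360 s of stimulus reused cyclically, ~72 waves) trades memory for
stimulus diversity; multi-day runs revisit the same waves many times, which
mildly accelerates the selection of a consistent configuration but does not
change which configurations are stable.

Default study conditions: a 150-µm periodic linear branch at density
$\nu = 0.2\,\mu m^{-1}$ (30 synapses), 15 simulated days for branch runs.
Because the compiled core is fast, the full 15-day condition is run where
the organization statistics matter (survival, ferret orientation
clustering); the control and mouse arms of the species comparison use 2-day
runs with 5 seeds each — under ring waves mouse turnover has essentially
ceased by day 2, so longer runs add no information there.  Tree runs use a
synthetic binary tree (~620 µm cable, maximum path distance ~260 µm, 10-µm
segments) at a 10-ms Euler step for 1.5 simulated days per seed and 3 seeds
per condition, keeping the attenuation-factor sweep within desk scale; the
step-halving convergence check covers the coarser tree step.

## Soma and backpropagating action potentials

The somatic accumulator $A = \sum_k w_k u_k$ excludes the bAP contribution to
$u$ (the simulator integrates a bAP-free copy of $u$ for this purpose), so
there is no positive feedback loop.  On each upward crossing of the threshold
$A_{\mathrm{th}}$ a bAP fires with probability 0.25, delivering calcium
$s_k B_{\mathrm{amp}}$, $s_k = e^{-d_k^2/2\sigma_{\mathrm{bAP}}^2}$
($B_{\mathrm{amp}} = 5$; attenuation factors 25, 75, 125 µm).  A 200-ms
refractory period prevents step-size-dependent multiple draws while the
accumulator hovers at threshold.  The nominal threshold 25 presumes the
full-size reconstruction it was tuned on; its defining property is a somatic
burst-initiation rate comparable to the synaptic event rate (~15 per
minute), so for other morphologies `calibrate_bap_threshold()` derives a
threshold from a frozen-efficacy probe epoch.  The threshold is calibrated
once and then held fixed for the whole run: a fixed threshold lets somatic
firing grow with the potentiation of whichever synapse population first
dominates the accumulator, which is the feedback that can lock the soma to
an orientation (re-calibrating each epoch would keep re-leveling that
competition).  The two spatial constants that share a symbol in the source
material — calcium spread (6 µm) and bAP attenuation (25–125 µm) — are
independent parameters here.

# Organization metrics

Pairwise activity correlations are Pearson correlations of 3-s boxcar-filtered
event indicators (mimicking slow calcium imaging).  Orientation difference is
$\min(|\theta_i'-\theta_j'|, 180° - |\theta_i'-\theta_j'|)$ with
$\theta' = \theta \bmod 180°$.  The somatic preference is the circular
average $\arg \frac1N \sum e^{i\theta_j}$ over 360° — deliberately *not* the
axial (doubled-angle) convention, matching the printed formula; the mod-180
reduction happens only inside the difference.  Circular dispersion is the
orientation difference to the somatic preference; receptive-field offset is
the Euclidean distance to the mean center.  One caveat the package resolves
explicitly: the plain 360° circular mean is ill-defined for axial data — as
soon as a population clusters at $\theta$ and $\theta + 180°$ (functionally
identical filters up to sign) the resultant vanishes and "dispersion"
relative to it becomes uniform noise.  `somatic_preference()` therefore
implements the plain mean (with a degenerate-input error) as the default and
an `axial = TRUE` variant using the standard angle-doubling convention;
organization reports use the axial preference.  Cluster size is the $\lambda$ of
a Gaussian $A_0 e^{-\Delta d^2/2\lambda^2}$ fitted (Levenberg–Marquardt) to
the 2-µm-binned correlation-vs-distance profile after subtracting the
>50 µm baseline.  Undefined statistics (zero-variance trains, empty
references) propagate as missing values, never as zeros.

# What the synthetic stimulus does and does not show

The surrogate reproduces: traveling fronts with random directions, LN-encoded
correlations that decay with orientation difference under waves and are flat
under white noise, and ~15 events/min at nominal gain.  It does not model:
wave domain boundaries and refractoriness, speed/size heterogeneity across
developmental stages, or retinotopic biases in wave propagation.  Passing
tests therefore demonstrate that the plasticity rule organizes synapses given
correlated traveling input with these statistics — not that the specific
retinal circuitry produces exactly these statistics.

# Known limitations and deliberate scope choices

* The burst-pairing (BTDP) curve is asymmetric: potentiation extends to
  about +1.8 s on the post-after-pre side (depression appears beyond),
  while the pre-after-post side crosses near −1 s.  This follows from
  $\tau_v = 600\,$ms vs $\tau_u = 300\,$ms — the pairing kernel is a
  two-sided exponential with unequal tails — and is unavoidable at Table-level
  parameters under the unit convention fixed by $\kappa$.  The package
  documents the measured curve rather than forcing symmetry.
* Mouse overlap clustering is weak on desk-scale branches: at
  $\nu = 0.2\,\mu m^{-1}$ the critical correlation is approximately zero, so
  after the initial elimination phase every surviving synapse is marginally
  stable and competition largely ceases before receptive-field co-location
  is strongly selected.  The functional signature (activity correlations
  decaying with dendritic distance) is robust; the receptive-field-overlap
  gradient is not.
* Global (soma-referenced) organization on the scaled synthetic tree does
  not reliably emerge: with a ~620-µm tree, the ~10 independent distal
  clusters all potentiate beyond bAP reach, so the somatic accumulator rises
  for waves of every orientation and threshold crossings never lock to a
  dominant orientation — the proximal zone churns instead of homogenizing.
  The corresponding tests state the expected trends and measure them
  honestly; larger morphologies (hundreds of synapses) and richer wave
  statistics are the plausible missing ingredients.
* Inhibitory scenarios implement the stated homeostatic GABA rule with a
  GABA density of 0.04 µm⁻¹ (one GABA synapse per five excitatory — the
  source leaves the count open).
* No cable-equation electrophysiology, no receptor kinetics, no apical/basal
  asymmetries; trees are never periodic.
* The spike-timing control preset (`plasticity_params("stdp")`) shortens the
  accumulator time constants so the plasticity window no longer matches the
  slow input correlations; it is provided for control experiments and is
  exercised by the test suite only as a preset.

# Reproducing the headline numbers

`scripts/acceptance.R` recomputes, from a fresh seed: the analytic constants
($\kappa$, the FWHM conversions), and the stable-synapse fraction of the
15-day ferret branch condition across 5 seeds.  The test suite
(`tests/testthat/test-acceptance.R`) additionally verifies the phase-diagram
sign structure against the analytic contour, the induction protocols, the
species dissociation, the bAP-driven global organization, and the oracle
equivalences (reduction vs full model, analytic expected change vs
frozen-efficacy simulation, cluster-size recovery).
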
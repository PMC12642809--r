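---
title: "Partition-diffusion dosimetry in PDMS microdevices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partition-diffusion dosimetry in PDMS microdevices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdmsdose)
```

## The problem

Polydimethylsiloxane (PDMS), the elastomer most microfluidic cell-culture
devices are cast from, absorbs hydrophobic solutes. Steroid hormones added
to culture media — estradiol, progesterone — partition into the channel
walls and diffuse onward into the bulk polymer, so the dose cells actually
experience can be far below, and dynamically distorted from, the dose
delivered at the inlet. `pdmsdose` implements a partition-diffusion
transport model of this loss, the inverse problem that measures its
parameters from simple two-chamber membrane experiments, and forward
simulations of static and perfused channel devices under pulse and
circadian dosing.

## The transport model

Concentrations in solution ($c_S$) and in PDMS ($c_P$) obey

$$\partial_t c_S = D_S \nabla^2 c_S - \nabla\cdot(c_S \mathbf v),
\qquad
\partial_t c_P = D_P \nabla^2 c_P,$$

with $\mathbf v$ the fluid velocity, coupled at every solution-PDMS
interface by a kinetic partition flux

$$J = H\,(K_{PS}\, c_S - c_P),$$

positive into the polymer. $K_{PS}$ is the PDMS-solution partition
coefficient (equilibrium is $c_P = K_{PS} c_S$), and $H$ (mm/h) an
interfacial mass-transfer coefficient. Because measurable working solutions
of these hormones need DMSO as a cosolvent, $K_{PS}$ depends on the DMSO
volume fraction $f$ through the log-linear mixing law

$$\log_{10} K_{PS}(f) = f \log_{10} K_{PD} + (1-f)\log_{10} K_{PW},$$

which also provides the extrapolation route from mixed-solvent experiments
back to the aqueous coefficient $K_{PW}$ (`kps_from_fraction()`,
`extrapolate_partition()`).

The model is linear in concentration, so units are arbitrary but must be
consistent; every solver output scales exactly with the schedule amplitude
(this is a tested invariant). Canonical internal units are mm, hours,
mm²/h, mm/h and mm³/h; `convert_flow_rate()` maps the lab-customary uL/min
to mm³/h (1 uL = 1 mm³).

Three bundled parameter sets (`chemical()`) cover the measured steroid
panel: progesterone (strong partitioning, $K_{PW}\sim 2000$), estradiol
(moderate, $K_{PW}\sim 15$) and aldosterone, which shows no detectable
PDMS interaction and is represented explicitly as *non-interacting* — an
impermeable interface — rather than as a $K\to 0$ limit, which keeps the
PDMS solve well-conditioned and makes "no loss" exact. The bundled $\log H
\ge 1.56$ values are non-rate-limiting lower bounds; the solvers default to
$H = 10^{1.56}$ mm/h and provide an equilibrium-interface option
($c_P = K_{PS} c_S$ enforced at the wall). A tested property requires the
two to agree within 1% for the bundled chemicals, which is exactly what
"non-rate-limiting" means.

## Membrane experiments and the inverse problem

The measurement geometry is two stirred 300-uL chambers separated by an
80-um PDMS membrane; the source chamber starts loaded, the sink blank, and
both are sampled over 24 h. `simulate_membrane()` solves the 1-D composite
problem (chamber | membrane | chamber) with a conservative finite-volume
scheme: cell capacities and exchange conductances, implicit Euler steps via
a precomputed propagator, interface fluxes combining the half-cell
resistances with $1/H$ in series. Mass conservation therefore holds to
round-off (drift $<10^{-4}$ is asserted, machine precision is achieved).
Because a blot mixer stirs the chambers only imperfectly, the chambers are
modelled by default as 1-D diffusive layers with an *effective* diffusivity
$D_{S,\mathrm{eff}}$; a well-mixed mode exists for oracle tests against the
closed-form partition equilibrium
$c_{eq}(V_{src}+V_{snk}+K_{PS}AL) = c_0 V_{src}$
(`equilibrium_concentrations()`).

The exposed membrane area is not derivable from the chamber volumes, so it
is an explicit field of `membrane_assembly()`; the documented fixture
default is 38.5 mm² (a 7-mm circular opening).

`fit_membrane_experiment()` estimates $(\log K_{PS}, \log D_P, \log H,
\log D_{S,\mathrm{eff}})$ by bounded Levenberg-Marquardt least squares in
log-parameter space (the parameters span orders of magnitude), with three
deterministic multi-starts around a data-driven initial guess to mitigate
local minima. Standard errors come from the local quadratic approximation
at the optimum. Replicates are fitted jointly with shared parameters rather
than averaged first, preserving the noise structure. The upper bound on
$\log_{10} D_P$ is 0.5: diffusion in crosslinked PDMS cannot outpace free
solution diffusion ($D_S \approx 2$ mm²/h for these solutes), and without
this physical bound the optimizer can trade a fast membrane against an
artificially slow chamber.

When transport is not interface-limited the objective is flat in $\log H$;
the fit scans $\log H \in [0,3]$ with the other parameters held at their
optimum and reports the smallest grid value whose residual sum of squares
lies within 1% of the minimum as a lower bound, setting `h_is_lower_bound`
when the profile stays flat to the top of the scan. Holding the other
parameters fixed (rather than re-profiling) is adequate precisely because
the flag only fires when $H$ barely influences the fit.

`extrapolate_partition()` is a weighted linear regression of fitted
$\log K_{PS}$ on $f$: intercept $=\log K_{PW}$, intercept + slope
$=\log K_{PD}$. When per-point standard errors are supplied they are known
noise levels, not relative weights, so the covariance is never rescaled
*below* the propagated measurement-noise level by the low-df residual
variance estimate.

## Synthetic data

`generate_membrane_dataset()` emulates the membrane study with known ground
truth: DMSO fractions $\{0.05, 0.10, 0.20, 0.30\}$ (the measurable
cosolvent range), sampling at $\{0,1,2,4,8,12,24\}$ h (spanning the
transients, which approach equilibrium over hours to days), three
replicates, and multiplicative log-normal noise with a 5% coefficient of
variation — absorbance-derived concentration error scales roughly with
signal, and the mean-one parameterization keeps the noiseless limit exact.
The stirred-chamber truth is $\log_{10} D_{S,\mathrm{eff}} = 0.7$
(≈ 5 mm²/h), i.e. mixing-enhanced transport a few-fold above molecular
diffusion; the generator is a pure function of its inputs and seed and
restores the caller's RNG state. What the generator does *not* emulate:
spectral processing, instrument drift, outliers, or chamber hydrodynamics
beyond the effective-diffusivity abstraction — recovery tests therefore
validate the estimator, not the full measurement chain.

`circadian_schedule()` is a parameterized stand-in for smoothed in-vivo
hormone rhythms: a truncated cosine series with a mean, harmonic
amplitudes and an acrophase, constrained (or clipped, flagged by a warning)
to stay nonnegative.

## The channel model and its dimensional reduction

`simulate_channel()` models a rectangular channel embedded in a PDMS slab.
The default reduction is 2-D (axial $x$ × height $z$), justified by the
15:1 width:height aspect ratio of the reference perfusion geometry
(10.55 × 1.5 × 0.1 mm channel in a 4-mm slab, `device_preset("bioreactor")`):

* the channel half-height is resolved (mid-plane symmetry) with
  plane-Poiseuille flow, discretely renormalized so the cross-section flux
  equals $Q$ exactly;
* the top/bottom slab is a 1-D PDMS domain per axial station (width $2W$,
  depth $(\text{slab}-h)/2$, geometrically stretched grid finest at the
  wall) fed by the wall-adjacent solution cell;
* the side walls are a second 1-D PDMS domain (width $2h$, depth = lateral
  margin) fed by the cross-section-mean concentration through a lumped
  lateral resistance $(W/4)/D_S$ — cross-channel mixing is fast relative
  to wall uptake, and the side walls contribute only ~6% of the perimeter
  in the reference geometry (more in squatter static geometries, where
  this term matters).

Outer slab boundaries are no-flux; the default 2-mm lateral margin exceeds
the 48-h PDMS penetration depth $\sqrt{D_P t}\lesssim 0.8$ mm for
progesterone, so it does not bind. End-wall (inlet/outlet face) absorption
is neglected (~4% of wetted area in the static geometry). Channels start
pre-filled at the schedule's $t=0$ value by default (`init = "inlet"`): a
pulse beginning at $t=0$ then has no spurious transit-holdover "depletion",
and a non-interacting chemical shows exactly zero loss; `init = "blank"`
is available.

Two time-integration drivers share this spatial model:

* **Transient** operator splitting — implicit upwind advection + axial
  diffusion along each row, then an implicit transverse step (vertical
  diffusion, wall exchange, slab diffusion) with precomputed dense
  propagators. The finite-volume construction makes the global mass ledger
  close to round-off, which the `$ledger` field reports. This driver is
  accurate when the advective Courant number is moderate: static devices
  ($Q=0$) and low flow rates with CFL-scale steps.
* **Quasi-steady** (`quasi_steady = TRUE`) — at perfusion rates of
  1-100 uL/min the channel residence time (seconds) is far below the
  dosing timescales (hours), so the in-channel field is taken as the
  steady solution of advection + transverse diffusion + wall exchange
  against the current slab state (one precomputed dense solve), and the
  slab advances implicitly between channel solves with a Robin wall
  coupling. This is the default choice for pulse and multi-day circadian
  runs; the transient driver at CFL-scale steps is the brute-force
  cross-check, and a tested property requires the two to agree within 2%
  on dose metrics.

Default resolutions (desk scale, seconds-to-minutes per run): 45 axial
cells, 7 half-height cells, 26 + 18 stretched PDMS cells, 0.005-h
quasi-steady steps for 4-h pulse runs and 0.01-h steps for 48-h circadian
runs; a tested property requires 2× refinement to move depletion metrics by
less than 2 percentage points. Pulse scenarios simulate 4 h in total — the
1-h pulse plus a 3-h chase window over which post-pulse release is
integrated; release percentages necessarily depend on that observation
window, since desorption tails decay like $\sqrt{t}$.

## Dose metrics and the delivered-mass definition

`dose_metrics()` quantifies dosing fidelity from the delivered mass
$M(t) = \int_0^t Q\,c(\tau)\,d\tau$: pulse depletion
($1 - M_{out}/M_{in}$ over the dosing window), post-pulse release
($M_{out}$ after the window / $M_{in}$ during it), delivered fraction of
targeted exposure, instantaneous outlet bioavailability (averaged over the
second half of the window, past the initial transit), and the phase lag
maximizing inlet-outlet correlation for periodic schedules.

Two concentrations can stand in for $c$ in $M(t)$, and for strongly
absorbed chemicals they differ substantially:

* `basis = "channel_average"` (default) — the volume-averaged in-channel
  concentration, i.e. the hormone actually present in transit through the
  device, which is the quantity usually plotted when judging whether cells
  inside the channel see the intended dose;
* `basis = "outlet"` — the flow-weighted (mixing-cup) exit concentration,
  the dose reaching strictly downstream targets. For a strong absorber at
  low flow this is exponentially attenuated along the channel length and
  can be orders of magnitude below the channel average.

Both cumulative masses are recorded in every result so either convention
can be audited after the fact.

`simulate_static_device()` covers the no-flow protocol: load, wait, empty,
refill while the PDMS retains its load — per-interval loss percentages
quantify the (non-)saturability of the walls.

## Numerical and design choices, in brief

* Implicit Euler everywhere: the PDMS/solution diffusivity contrast makes
  the composite systems stiff; capacities-and-conductances finite volumes
  guarantee conservation and positivity (the operators are Metzler
  matrices, so the implicit propagators are nonnegative).
* Interface fluxes combine half-cell resistances and $1/H$ in series,
  $J = (K_{PS}c_S - c_P)/(1/H + K_{PS}\delta_S/2D_S + \delta_P/2D_P)$,
  which degrades gracefully to the equilibrium interface as $H\to\infty$
  and to an impermeable wall at $H=0$.
* Degenerate inputs fail loudly: negative times/concentrations, multiple
  DMSO fractions in one fit, quasi-steady with $Q=0$, static protocol with
  $Q\neq 0$, over-amplified periodic schedules (rejected, or clipped with
  a warning when explicitly permitted).
* Tie-break in the $H$ scan: the *smallest* flat grid value is reported,
  making the bound conservative.

## Known limitations

* The 2-D reduction with lumped side walls reproduces wall-flux physics at
  desk scale but not corner effects or the 3-D entrance flow; tolerances on
  comparisons with full 3-D FEM solutions of the same equations should
  allow several percentage points on integrated dose metrics.
* Quasi-steady mode has no in-channel storage dynamics, so sub-residence
  transients (seconds) are invisible; its ledger accounts inlet/outlet/slab
  masses but not the instantaneous channel content between macro steps.
* Asymptotic standard errors from the local quadratic approximation
  under-cover slightly for weakly identified parameters (the
  $D_P$-$D_{S,\mathrm{eff}}$ trade-off); empirical 2-SE coverage in the
  50-seed recovery suites runs in the high-80s to mid-90s percent range
  depending on the fraction.
* Post-pulse release and delivered-fraction values depend on the
  observation window and on the delivered-mass basis; both are explicit,
  recorded choices rather than hidden conventions.
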
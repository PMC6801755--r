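---
title: "Modelling the chemomechanical coupling of kinesin dimers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the chemomechanical coupling of kinesin dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinesim)
```

## The model

Kinesin-1 and kinesin-2 dimers walk hand-over-hand along microtubules in
8.2 nm steps, hydrolysing ATP as they go. The central modelling question
is how the chemistry couples to the mechanics: why does a backward load
slow the motor, why do neck-linker (NL) extension mutants hydrolyse
several ATP per step while the wild type uses about one, and why is the
total ATPase rate nevertheless insensitive to load and NL length?

`kinesim` implements a kinetic scheme in which the ATPase rate constants
of the two heads are *independent of force and of NL length*. The
trailing head (forward-pointing NL) hydrolyses ATP at `k(+)`, the
leading head (backward-pointing NL) at `k(-) << k(+)`. Load and NL
mechanics enter only through two branching probabilities:

* `P0`, the probability that immediately after phosphate release the
  ADP-head escapes its transiently weakened binding site and reaches the
  one-head-bound intermediate (INT). For wild-type dimers the ~30 pN of
  internal NL tension makes escape certain (`P0 = 1`); for
  extended-NL mutants `P0(0) < 1` and load assists escape on the side it
  acts on: `P0(F) = 1 - (1 - P0(0)) exp(-|F| delta / kBT)` with
  `delta = 1` nm (about a Debye length).
* `PE`, the probability that the tethered head in INT rebinds to the
  *forward* rather than the rearward site. NL docking of the bound head
  supplies an energy barrier `ED` against rearward rebinding, giving
  `PE = rho / (rho + k(+)/k(-))` with the reduced ratio
  `rho = r0^(1 - F/FS)`; `r0` is the zero-force stepping ratio and
  `FS = ln(r0) kBT / d(+)` the wild-type stall force.

Everything observable then follows from two stepping rates,

```
forward  = P0(0) PE(F) k(+)        backward = P0(F) (1 - PE(F)) k(-)
```

(for a backward load `F > 0`; an assisting load mirrors the roles of
`P0(0)` and `P0(F)`, and the two branches join continuously at `F = 0`).
Velocity is `(forward - backward) d`, the dwell time is the reciprocal
total stepping rate, the diffusion constant is
`(forward + backward) d^2/2`, the randomness parameter is `2D/(vd)`, the
ATP cost per (forward) step is the constant total ATPase rate
`k(+) + k(-)` divided by the (forward) stepping rate, power is `v F`,
and efficiency divides power by `(k(+) + k(-)) deltaG` with
`deltaG = 20 kBT` per ATP. A deliberately important consequence of the
scheme: the total hydrolysis rate is `k(+) + k(-)` at every load —
coupling efficiency, not chemistry, absorbs the force dependence.

The seven parameter presets (`motor_presets()`) are the published fits
for Drosophila kinesin-1 (DmK), bovine brain kinesin-1, human kinesin-1
(HsK) and its cysteine-light variant (HsK-CL), the corresponding
six-residue NL-extension mutants (HsK-6AA, HsK-CL-6AA), and the
kinesin-2 KIF17. Derived quantities close the loop on the published
analysis: `kin_docking_energy()` inverts
`r0 = (k(+)/k(-)) exp(ED/kBT)` (3.34 kBT for DmK, 1.56 kBT for Bovine,
consistent with the 1-2 kBT measured for NL docking), and
`kin_characteristic_distance()` returns `d(+) = kBT ln(r0)/FS` (4 nm for
kinesin-1 — about half a step).

## Parameters and units

| parameter | meaning | units | default |
|---|---|---|---|
| `r0` | stepping ratio at zero force | — | preset |
| `FS` | stall-force scale (`= ` stall force for wild type) | pN | preset |
| `k_plus`, `k_minus` | trailing / leading head ATPase rates | s^-1 | preset |
| `P0_zero` | escape probability at zero force | — | 1 |
| `kb` | second-order ATP binding rate | uM^-1 s^-1 | 3.3 |
| `k_off_leading` | ATP dissociation, leading head | s^-1 | 30 |
| `k_off_other` | ATP dissociation elsewhere | s^-1 | 0 |
| `delta` | force scale of escape probability | nm | 1 |
| `d` | step size (microtubule period) | nm | 8.2 |
| `temperature` | absolute temperature | K | 298 |

Forces are in pN and positive when resisting (backward); energies are
expressed in kBT with `kBT = 0.0138065 * 298 = 4.114` pN nm at the
default temperature. The step size is treated as exactly 8.2 nm; the
±2 nm step-size scatter seen in bead recordings is attributed to bead
fluctuations and is not modelled. `kb` and `k_off_leading` were only
characterised for the extended-NL mutants and KIF17; the presets carry
those values over to the other species so every preset can be simulated
at low ATP, which is an extrapolation to keep in mind when interpreting
low-ATP runs for wild-type presets.

## Stochastic engines

`simulate_trace()` implements the fixed-timestep scheme (`dt = 1e-4` s):
per step each head draws one uniform variate per candidate transition
(binding, dissociation, hydrolysis), at most one chemical transition
fires per head per step, and the "immediate" cascades — detachment to
INT, NL docking once the bound head holds ATP, rebinding
(forward with `PE`), ADP release — resolve within the same step. The
scheme is first-order in `rate * dt`, so the wrapper refuses any active
rate with `rate * dt >= 0.01` and points to `exact_trace()`, the
continuous-time event-driven engine for the identical Markov state
machine. The exact engine is unbiased at any rate and is the default for
ensembles; the two engines are cross-checked against each other in the
test suite at conditions where both are valid.

Conventions adopted where the scheme is silent:

* a futile escape that rebinds to its original site leaves the head
  nucleotide-free, and ATP binding then proceeds at `kb [ATP]` rather
  than instantaneously — at saturating ATP the two readings coincide,
  at low ATP only this one keeps the futile cycle consuming binding
  events;
* ATP cannot dissociate from the MT-bound head while in INT (the
  backward NL orientation that enables dissociation only exists for a
  bound leading head);
* the initial state is two-head-bound with both heads ATP-loaded at
  saturating ATP and nucleotide-free at finite ATP; the first 1% of each
  trace is excluded from event counters as burn-in;
* reproducibility: each trace consumes one seeded RNG stream
  (`base_seed + trace index` in ensembles), making every ensemble
  bit-reproducible.

**Saturating ATP.** `conditions(atp = Inf)` routes the engines to the
branch without nucleotide-binding kinetics. This branch is the regime of
all the closed-form expressions, and it is how the package represents
the 2 mM "saturating" condition of the optical-trap experiments: at
finite concentration the ~0.15 ms binding wait per ATPase cycle
introduces a small occupancy lag absent from the closed forms, so
simulations meant to be compared against the analytic expressions should
use the saturating branch, and finite concentrations should be reserved
for genuinely non-saturating questions (Michaelis-Menten behaviour,
low-ATP stepping).

## Trace analysis

`bead_position_series()` renders a trace the way a trapped bead reports
it under backward load: the bead follows the head farther from it, so
rear-head excursions to INT are invisible, a rebind from INT to the
front site reads +d and front-head detachment reads -d. Without a
backward load the centre-of-mass convention is used (this is also the
convention behind all closed-form observables). `detect_steps()` applies
the dwell-threshold convention of 2 kHz recordings: a level must persist
longer than 0.5 ms to count, shorter excursions are merged away. At
saturating ATP the INT state is instantaneous and the detected stepping
ratio coincides with the centre-of-mass one; at low ATP the two differ
by construction, which is the point of the convention.

`summarize_traces()` estimates: velocity as the per-trace end-to-end
slope (mean ± SEM over traces); the stepping ratio from pooled
forward/backward counts (per-trace ratios are undefined whenever a trace
has no backward step) with the count-propagation error
`r sqrt(1/nF + 1/nB)`; the diffusion constant from the slope of the
ensemble position variance over the second half of the run, where the
initial-condition transient has decayed, with a 10-block jackknife SEM;
the randomness parameter as `2D/(vd)` (the ensemble estimator — the
finite-time ratio converges much more slowly); and the ATP
stoichiometries `N`, `NF` from pooled hydrolysis and step totals
(per-trace ratios carry an O(1/steps) bias that pooling avoids).

## Fitting

`fit_force_velocity()` reproduces how the preset table was obtained:
bounded Levenberg-Marquardt on `(v_model - v_obs)/sigma` (unit weights
when no uncertainties are given — the published analysis states no
weighting scheme), with standard errors from the Jacobian covariance at
the optimum, which is one defensible convention among several and is
labelled as such. Because `r0` and `FS` enter the velocity only through
`exp((1 - F/FS) ln r0)`, the likelihood surface has a pronounced ridge;
the optimiser therefore restarts from five deterministic jittered
initial points within bounds (`r0` in (1, 1e5), `FS` in (0.5, 20) pN,
rates in (0.1, 1e4) s^-1, `P0_zero` in (0.01, 1]). The joint
wild-type/mutant protocol shares `r0, FS, k(+), k(-)` across both
datasets with a mutant-only `P0_zero`, exactly the construction used for
the HsK / HsK-6AA pair. `fit_stepping_ratio()` fits on the log ratio,
where the wild-type model is linear in force with slope `-ln(r0)/FS`.

`generate_synthetic_fv()` is the package's synthetic-data generator:
multiplicative Gaussian noise of fixed coefficient of variation on the
model curve, emulating the roughly relative errors of optical-trap
velocity estimates. It does not emulate trap compliance, drift,
force-calibration error, or correlated noise, so parameter-recovery
results bound what the estimator can do on idealised data, not on raw
recordings. Recovery studies in the tests use 15 forces spanning
assisting loads to near stall, 2-3% noise, and 50 replicates with fixed
seeds. On such data `FS` and `k(+)` are recovered to a fraction of a
percent and `k(-)` to better than a percent in the median, while `r0` is
the weakly identified direction of the ridge: its log-scale spread at 2%
velocity noise is an order of magnitude larger than the others', and its
sampling distribution is noticeably skewed. Stepping-ratio data
constrain `r0` far more directly and are the preferred input when the
zero-force ratio itself is the quantity of interest.

## Problem sizes and numerical choices

* Ensemble cross-checks against the closed forms run all seven presets
  at 0, 2 and 4 pN with 1000 traces of 10 s each (the exact engine),
  comparing velocity, stepping ratio, ATP per step and total hydrolysis
  rate at 3 SEM.
* The Michaelis-Menten check titrates 5-2000 uM (about Km/6 to 60 Km,
  the span of typical single-molecule titrations) and requires relative
  residuals from a fitted hyperbola below 5%; the state machine is only
  approximately hyperbolic in [ATP], and the approximation degrades at
  extreme sub-Km concentrations outside that span.
* The dwell-time series over the number of hydrolyses per step is summed
  to 5000 terms in the tests; near stall the per-hydrolysis stepping
  probability drops to a few percent and a few hundred terms are not yet
  at 1e-9 relative accuracy.
* `kin_stall_force()` returns `FS` exactly for wild-type parameters and
  otherwise bisects the net stepping rate on [0, FS] to 1e-6 pN;
  `kin_max_power()` maximises on (0, stall) with `stats::optimize()` at
  tolerance 1e-9. `kin_randomness()` raises an error at stall rather
  than returning an arbitrarily large float; the tabular `kin_scan()`
  surface reports `Inf` there instead so grids including stall remain
  usable.

## Known limitations

The model contains no irreversible dissociation pathway, so run lengths
and processivity cannot be studied; trap stiffness (position-dependent
force) is not simulated; rate constants are temperature-independent in
this implementation (fixed `kBT` scale per run); stalk-length and
limping effects are out of scope. Near stall (within ~0.5 pN) stochastic
summaries are statistically fragile — the net displacement vanishes
while its variance does not — and quantitative comparisons there should
use the closed forms.
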
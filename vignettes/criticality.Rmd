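---
title: "Growth towards criticality: the model and the avalanche analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth towards criticality: the model and the avalanche analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(critdev)
```

This vignette is the package's own account of its science: the growth model
and its assumptions, the avalanche analysis and its numerical choices, the
calibrated parameter regimes and why they look the way they do, and the
known limitations. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The growth network

The simulator is a two-dimensional recurrent network of `n` stochastic
threshold neurons (default 100, on a 10x10 grid with spacing 10) with
uni-directional synapses. Four per-neuron variables evolve in discrete time
(forward Euler, interval = one simulated step):

* **Membrane potential** `v`, confined to `[v_floor, 1]`. Each step a
  non-refractory neuron spikes with probability `v` (a fresh uniform
  threshold per neuron per step); `v` relaxes towards `v_rest` with time
  constant `tau_v` and jumps by `eps_j * Omega[i, j]` for every presynaptic
  neuron `j` that spiked this step. `eps_j` is `+w_exc` for excitatory and
  `-w_inh` for inhibitory neurons. The hard upper bound of 1 makes `v` a
  probability; the lower clip (default 0) means inhibition cannot drive a
  neuron below complete silence.
* **Calcium** `ca`, a slow activity trace: decay constant `tau_ca`, influx
  `beta_ca` per own spike.
* **Dendritic acceptance** `d` and **axonal supply** `a`, radii of two
  circular fields. Per step, `d` changes by `-rho_d * (ca - ca_target)` and
  `a` by `+rho_a * (ca - ca_target)`, both clipped at zero: a neuron firing
  above its homeostatic set-point retracts dendrite and extends axon, one
  firing below it does the opposite. The fields are frozen exactly at
  `ca = ca_target`.

The connectivity `Omega[i, j]` — synaptic density from the axon of `j` to
the dendrite of `i` — is the intersection area of the two disks (an
abstract stand-in for the probability of synapse formation; a smooth
Gaussian-overlap kernel is available as `kernel = "gaussian"`). The
diagonal is zero: autapses would contaminate the avalanche statistics with
self-excitation. Growth and connectivity are updated every step, on the
same Euler clock as the dynamics.

Two developmental events are modelled explicitly. First, the **inhibitory
conversion** (the developmental switch of GABA action): when the mean
calcium first reaches the target, a fixed random 20% of the neurons flip
the sign of their coupling prefactor. The subset is sampled at network
initialisation — distributionally identical to sampling at the switch, and
it keeps the compiled and pure-R engines on the same RNG stream. Second,
**acute inhibition changes** (`apply_inhibition_jump()`) rescale the
inhibitory weight of an equilibrated network instantly.

### Homeostasis fixes the firing rate

In equilibrium the calcium balance per step, `ca/tau_ca = beta_ca * R`,
pins the firing rate at `R* = ca_target / (beta_ca * tau_ca)` regardless of
connectivity, inhibition, or initial conditions (`steady_state_rate()`).
Inhibition is compensated structurally: stronger inhibitory weights force
larger total connectivity at the same rate, which is exactly what the
simulations show. The equilibrium constrains only the mean synaptic
density; in the (axonal, dendritic) field plane a whole level curve of
field combinations realises it, so the attained balance between `a` and `d`
— unlike the rate — depends on the initial conditions
(`fixed_point()$on_hyperbola`).

## 2. The two calibrated regimes

The literal parameter values behind the published phenomenology are not
recoverable, so the package calibrates its own defaults and documents them.
During calibration one structural trade-off emerged clearly, and it is worth
stating because it is a genuine property of this model class:

* The **homeostatic regime** (`model_params()`, the default) uses slow
  growth relative to calcium (`rho_d = 2e-4`, `tau_ca = 1000`,
  `beta_ca = 0.5`, `ca_target = 2`, `v_rest = 2e-4`, `w_exc = 0.02`). The
  development is quasi-static: the network stalls just below the ignition
  point of sustained reverberation, which is precisely what parks it near
  criticality, and it settles cleanly into firing-rate homeostasis (mean
  calcium within ~2% of target by ~7e4 steps). The pooled steady-state rate
  `n * R* = 0.4` spikes/step keeps the adaptive avalanche time bin at ~2.5
  steps, comfortably above the raster resolution. This regime drives
  `run_phase_experiment()` and all homeostasis/criticality properties.
* The **explosive regime** (`model_params(regime = "explosive")`) slows the
  calcium kinetics relative to growth (`tau_ca = 1e4`, `beta_ca = 0.05`,
  `rho_d = 4e-3`, `v_rest = 1e-4`, `ca_target = 5`; same `R* = 0.01` up to
  scale). Because the sub-ignition ("bursty") firing rate can no longer
  deliver the calcium target, growth is forced through the ignition point
  and connectivity overshoots the sustained-activity threshold several-fold
  before calcium catches up: the mean membrane potential saturates near its
  hard bound during the transition (`overshoot_plateau()`, ~0.93-0.96 per
  seed). The price of the violent overshoot is a persistent post-transition
  relaxation cycle — verified out to 8e5 steps — so this regime is used for
  the Phase II saturation analysis only, not for equilibrium statistics.

No single parameter set reproduced both the saturating overshoot and
budget-feasible clean homeostasis; the two regimes are both honest corners
of the same model, and the choice between them is a statement about which
phase of development is under study. The measured plateau of ~0.93 (rather
than 1.00) is itself structural: during the overshoot pruning a few percent
of neurons transiently lose their dendritic field entirely (clipped at
zero) and sit at rest, capping the population mean.

Remaining defaults: initial fields `a = 5` (homeostatic) or `a = 8`
(explosive), `d = 1` — no connections exist at spacing 10, and the axonal
reserve must survive the dendritic-outgrowth phase: too small an initial
axon dies back before ignition and the network never forms, a real failure
mode of the model. The explosive regime carries the larger reserve because
an occasional premature half-ignition otherwise depletes the axons and
leaves the network dead instead of completing the transition. Refractory
period 4 steps, so the rate ceiling is 0.2 spikes/neuron/step;
`v_floor = 0`.

## 3. The avalanche analysis

`avalanche_analysis()` chains five operations, each exported:

1. **Time bin** (`compute_time_bin()`): the mean pooled inter-spike
   interval, excluding intervals beyond the lag below which 99% of the area
   of the mean cross-correlogram lies (`mean_cross_correlation()`,
   `cc_cutoff()`; all ordered unit pairs, binarised trains, default maximum
   lag 1000 time units at the native resolution). The exclusion keeps slow
   inter-burst structure out of the bin. Zero intervals from simultaneous
   spikes are retained: the plain mean is the stated definition, and an
   interval-between-distinct-times variant was tried and rejected because
   it systematically merges distinct bursts. Consequence, documented as a
   limitation: rasters whose pooled rate approaches one spike per time unit
   push the bin to the resolution floor, below which avalanche detection on
   integer-time data degenerates. The default homeostatic rate was chosen
   to stay well clear of that floor.
2. **Detection** (`detect_avalanches()`): maximal runs of pooled spikes
   with consecutive gaps strictly below the bin; a silence of at least one
   bin ends an avalanche. Every spike lands in exactly one avalanche
   (asserted against a brute-force scan on random rasters).
3. **Size distribution** (`size_distribution()`): empirical `P(s)` over
   observed sizes.
4. **Power-law regression** (`fit_power_law()`): unweighted least squares
   through `(log10 s, log10 P)`. The published prescription fixes the fit
   to the left linear region but its end point is not recoverable; the
   default policy starts at the smallest observed size and extends the
   window while the regression keeps `R^2 >= 0.98`, stopping at the first
   violation. Both ends are overridable.
5. **Deviation and label** (`delta_measure()`, `classify_state()`): the
   mean log10 residual of *all* observed sizes from the left-anchored line.
   Excess large-avalanche mass gives a positive deviation, a truncated tail
   a negative one. Thresholds +-0.1 (log10 units) are heuristic, matching
   eyeball classification of the fixtures, and configurable. Note one
   consequence of averaging over size *points* rather than probability
   mass: excess mass concentrated at a single size (e.g. a hard cutoff)
   barely moves the measure; it takes a spread-out bump. The
   branching-process generator therefore truncates cascades at a variable
   size (uniform on `[max_size/5, max_size]`), which is also the physically
   sensible picture of a finite system.

The battery (`spatial_subsample_test()`, `bin_robustness_test()`,
`scaling_function_collapse()`, `fano_factor()`) quantifies scale-freeness.
Collapse quality is the maximum pairwise sup-distance between rescaled
empirical distribution functions of onset-to-onset inter-avalanche
intervals (the published test is visual; onset-to-onset is our convention).
Fano windows are disjoint, starting at the recording onset; window lengths
below 10 resolutions or above a twentieth of the recording are excluded
from the exponent fit by default.

## 4. The staged-inhibition experiment

`run_phase_experiment()` mirrors the developmental protocol: growth under a
strong inhibitory onset (`w_inh = 10 * w_exc` at the switch), a homeostatic
epoch, a gradual reduction of the inhibitory weight to the excitatory level
(10 steps of 2000 time steps), and re-equilibration. Four windows are
analysed: early development (`[0, 0.85 * switch)`), the activity overshoot
(`[switch - 2000, switch + 4000)` — the overshoot brackets the crossing,
which fires mid-burst), the strongly inhibited epoch (last 30000 steps of
the first segment), and the balanced epoch (last 40000 steps). With the
default seed the four windows classify as subcritical (deviation -0.46,
the near-Poisson initial state), supercritical (+0.12), subcritical
(-0.40) and critical (-0.04) — the full developmental sequence.

Two caveats belong here rather than in fine print. First, window deviations
carry seed-to-seed noise of roughly +-0.15 at these window lengths, so
individual legs of the sequence can cross the +-0.1 thresholds on other
seeds. Second, the *causal* dependence of the equilibrium deviation on the
inhibitory weight is weaker in this reconstruction than in the published
account: with the potential floored at zero, an inhibitory volley can
subtract at most the current potential (~0.004 in equilibrium), so acute
inhibition saturates and the subcritical epoch owes as much to the
developmental stage as to the weight itself. Removing the floor
(hyperpolarisation) strengthens inhibition but destabilises the
strong-inhibition equilibria; the floor was kept.

The measured inhibitory share of total synaptic density at balanced
weights is ~33-39%, not the neuron share of 20%. The mechanism is
geometric: connectivity is local at equilibrium, neurons neighbouring an
inhibitory cell compensate the suppression by dendritic growth, and that
growth disproportionately inflates the overlap with the very axon that
suppresses them (the axonal and dendritic radii themselves are
statistically identical across the two populations — the asymmetry lives
entirely in the neighbours' dendrites). The acceptance script reports the
honestly computed value.

## 5. Mean-field companion

Averaging over neurons replaces the recurrent input by
`W * f(Omega_bar) * V_bar` with `W = w_exc` and `f` linear
(`f = n * Omega_bar`, the mean row sum; the published density function is
not recoverable and linearity is the minimal monotone choice). The
dimensionless gain `g = tau_v * W * f` splits three regimes: zero coupling
(potential relaxes to rest, calcium to `beta_ca * tau_ca * v_rest`),
bounded (`g < 1`; limits grow with density), and the transition (`g >= 1`;
potential clipped at 1, calcium flagged divergent — never a floating-point
overflow). `mean_field_solution()` solves the *discrete-time* averaged map
exactly (geometric bases), so it agrees with direct Euler integration to
machine precision rather than to `O(1/tau)`.

`nullcline()` replaces the firing nonlinearity with a sigmoid of steepness
`k` (default 30, midpoint 0.5; the published steepness is unknown) and
scans a dense potential grid for stationary points, refining each bracket
by bisection to 1e-10; where the drive still exceeds the leak at the hard
bound, the saturated state `V = 1` is reported as the upper branch. For
steep `k` the solution set is S-shaped — one or three branches — which is
the hysteresis underlying the explosive transition. `fixed_point()`
intersects the stationary relation with the homeostatic rate, inverting
the refractory-corrected firing relation `r = V/(1 + 4V)`.

## 6. Synthetic fixtures: what they do and do not show

`poisson_raster()` (independent homogeneous trains) and
`branching_raster()` (Poisson-driven Galton-Watson cascades, offspring
`Poisson(sigma)` on uniformly random units at the next step, cascades laid
out serially with a guard gap) are statistical reference models with known
ground truth: Fano factor 1 and strongly negative deviation for the
Poisson case; size exponent -3/2, mean cascade size `1/(1 - sigma)` below
criticality, and a deviation measure ordered in `sigma` for the cascades.
They validate the *analysis stack*, and the critical cascade fixture is the
oracle for the -1.5 exponent. They do not emulate real recordings'
spatial correlations, electrode subsampling artefacts, slow
non-stationarities, or burst substructure; passing on fixtures therefore
certifies the statistics pipeline, not the biology. Culture-like data
additionally pass through `electrode_selection()` (exclusion of units more
than two standard deviations above the mean count, single pass; at least
50 active electrodes required), with "active" defined as at least one
spike in the analysed window.

## 7. Problem sizes

Defaults were chosen so that the full test suite and the acceptance script
run comfortably on a single CPU: developments of 0.8-1.2e5 steps for
equilibrium statistics, 2.5e4 steps for the overshoot scenario, 1.2e4
cascades (~1e6 spikes) for the branching oracle, and 10 seeds for the two
stochastic headline quantities. The compiled core simulates roughly 3e3-3e4
steps per second depending on field sizes (the connectivity update
dominates; it is quadratic in `n` with a trigonometric kernel per
overlapping pair).
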
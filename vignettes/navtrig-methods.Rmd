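---
title: "Modelling mutant NaV1.1 channels in trigeminal nociceptive fibers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mutant NaV1.1 channels in trigeminal nociceptive fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(navtrig)
```

`navtrig` models how gain- and loss-of-function mutations of the NaV1.1
sodium channel reshape nociceptive firing in the thin myelinated Aδ-fibers of
the meninges. This vignette is the package's own account of the model: the
equations and their assumptions, the parameters that matter, how the
undetermined constants were calibrated and frozen, and what the shipped
baseline does and does not reproduce.

## Channel gating

Every conductance is a Hodgkin–Huxley product of independent gates. A gate
`x` relaxes exponentially toward a Boltzmann steady state with a bell-shaped
(Gaussian) voltage-dependent time constant:

$$x_\infty(V) = \frac{1}{1 + e^{\mp (V - V_{1/2})/k}}, \qquad
\tau_x(V) = \tau_{floor} + (\tau_{peak} - \tau_{floor})\,
e^{-\left((V - V_0)/b\right)^2}.$$

Two deliberate choices here:

* **Bell-shaped τ.** The three-parameter Gaussian form is sometimes written
  with a positive exponent, which diverges away from its center; voltage-clamp
  τ measurements are bell-shaped, so the package implements the peaked
  (negative-exponent) form, with an additive floor so relaxation stays finite
  at extreme voltages.
* **Conductance-form activation.** Experimental activation parameters
  describe the *conductance–voltage* curve. With `m³` kinetics, the gate
  therefore relaxes to the cube root of the Boltzmann
  (`conductance_boltzmann = TRUE`), so that `m³` at steady state reproduces
  the measured curve exactly. Without this convention the simulated
  activation midpoint would sit ≈ `1.35 k` (≈ 10 mV) right of the catalogued
  value and parameter recovery would be impossible.

The NaV1.1 current is `I = m³ h s r · ḡ (V − E_Na)`: fast activation `m`,
fast inactivation `h`, slow inactivation `s`, and a recovery variable `r`
that is neutral (held at 1) by default. Variants reported with accelerated
recovery (L1670W, Q1478K on fast inactivation; L1649Q on slow inactivation)
scale the hyperpolarized branch of the corresponding τ surface by 0.5 instead
of introducing extra kinetic states, because no rate constants are available
for a genuine `r` scheme.

### The variant catalogue and τ calibration

`inst/extdata/nav11_catalogue.csv` holds, per variant and per study-matched
wild type: activation, fast-inactivation and slow-inactivation `(V½, k)`,
and the slow-inactivation time constant at its reference voltage (−10 mV for
most pairs, −5 mV for the Q1478K pair, 0 mV for the L1649Q pair; the M145T
pair has no slow-inactivation data and its `s` gate is disabled).

The `(a, b, V₀)` parameters of every τ surface are not published, so they
are calibrated:

* `τ_s`: the Gaussian is centered on the slow-inactivation midpoint with a
  40 mV width and 50 ms floor; the peak is solved *in closed form* so the
  simulated development protocol returns the catalogued τ_slow at the
  reference voltage. Because development of `s` at a fixed voltage is a
  single exponential with time constant `τ_s(V)`, this calibration is exact,
  and `simulate_slow_inactivation_tau()` recovers the catalogued values to
  < 0.001 %.
* `τ_m` (peak 0.15 ms, width 40 mV, floor 0.02 ms, centered on the
  activation midpoint) and `τ_h` (peak 6 ms, width 70 mV, floor 3 ms,
  centered on the fast-inactivation midpoint) were chosen so that simulated
  clamp protocols recover every catalogued `(V½, k)` within 2 mV and 15 %.
  The recovery error is dominated by fast-inactivation decay during the peak
  measurement, which varies across test voltages; wide, shallow τ surfaces
  make that suppression nearly uniform so normalization cancels it.

### Clamp protocols

Clamp simulations never integrate step-by-step: within each fixed-voltage
phase the gate trajectory is evaluated in closed form, making the protocols
fast and exact. The activation protocol steps from −100 mV to each test
voltage (−100…+20 mV, 10-mV increments) and records the peak of `m³h` (slow
gates frozen at the holding state); availability conditions each voltage to
fast-gate equilibrium with slow gates held; the slow-inactivation protocol
uses 25 log-spaced conditioning durations (50 ms – 12 s), a 20-ms recovery
gap at −80 mV (long enough for `h`, short enough that `s` barely moves), a
test pulse, and a single-exponential fit. The holding potential (−80 mV) is
a package choice; the source protocols do not state it.

## Receptors and transmitter time course

Mast-cell-derived ATP and serotonin act on P2X3/P2X2 and 5-HT3 receptors at
the fiber terminals. Full Markov receptor schemes are out of scope; the
package uses a two-gate reduction: an activation gate relaxing toward the
Hill occupancy of the agonist, and a desensitization gate relaxing toward
`1 − depth · Hill(C)` with separate onset/recovery time constants. Defaults
(EC50 1 µM / Hill 1.5 / τ_act 5 ms / τ_des 100 ms / depth 0.97 for P2X3;
EC50 2 µM / Hill 2 / τ_des 2 s for 5-HT3; EC50 30 µM / τ_des 10 s / depth
0.5 for P2X2) encode the field's qualitative picture — P2X3 fast and deeply
desensitizing, P2X2 persistent — and are configurable.

Free transmitter follows either an instantaneous-rise pulse with exponential
diffusional decay, or the point-source 3-D diffusion solution
`∝ t^{-3/2} e^{-r²/4Dt}` rescaled to the event's peak concentration. All
reference scenarios use diffusion mode with a source–terminal distance of
8 µm (D = 300 µm²/s for ATP, 400 µm²/s for 5-HT): the resulting slow rise
and fall sweeps the terminal through its firing corridor and is what
produces spike *trains* rather than single onset spikes. First-order
clearance (ATP hydrolysis, half-life 200 ms; 5-HT uptake, half-life 2 s)
multiplies either profile and can be switched off to reproduce the
clearance-removal comparisons.

## The fiber model

The Aδ-fiber is a tree: a 1.1 cm stem whose proximal end (toward the
trigeminal ganglion) is the recording point, and two 1.1 cm branches, each
built from 2 × 2 µm nodes of Ranvier alternating with 5-µm-diameter
myelinated internodes, ending in a thin unmyelinated terminal
(1 µm × 200 µm, four compartments) that carries the receptor pools. Nodes
carry NaV1.1 (0.5 S/cm², or 0.35 in knock-down variants), NaV1.6 (0.35),
NaV1.7, a low level of NaV1.8, and KV1/KV3/KV4; the terminal carries the
same complement at half density plus a dense TTX-resistant NaV1.8 population
(1.6 S/cm²) and the adaptation conductance. Three cable choices deserve
comment:

* **Internode length 300 µm** (not the more conservative 200 µm): chosen for
  conduction speed. The two-release experiment depends on branch transit
  times being short relative to the release interval, otherwise the spike
  trains from the two branches annihilate at the junction.
* **Terminal NaV1.8.** At a terminal depolarized by sustained generator
  current, NaV1.1/1.6/1.7 fast inactivation is engaged and repetitive firing
  dies. The depolarized inactivation range of NaV1.8 keeps the terminal
  oscillator alive — precisely the role this channel is credited with in
  nociceptive endings.
* **Adaptation (KCa).** The calcium-activated potassium channel is reduced to
  a voltage-only gate that charges rapidly during a spike (τ ≈ 2 ms at spike
  voltages) and decays slowly near the inter-spike potential (τ ≈ 35 ms at
  −55 mV), acting as a spike-triggered medium-AHP that spaces and ultimately
  terminates bursts. It is placed only at terminals, so antidromically
  propagating spikes do not silence the opposite branch.

Leak reversal is balanced per compartment so the configured resting potential
(−65 mV) is an exact fixed point; an unstimulated fiber drifts by < 10⁻³ mV.
Slow-inactivation gates initialize at their −80 mV steady state: `τ_s` is
tens of seconds, so resting `s` reflects the fiber's rested hyperpolarized
history rather than instantaneous equilibrium at −65 mV. Without this, the
resting slow-inactivation occupancy would differ several-fold across the
catalogue (s∞(−65) ranges from 0.13 to 0.95) and wild-type responses from
different source studies would diverge far more than their published
responses do.

### Numerics

The membrane equation is integrated semi-implicitly: gates advance by the
exact exponential update at the current voltage (unconditionally stable,
bounds-preserving for any step), then the voltage system — linear once the
conductances are fixed — is solved directly on the tree in Hines order, with
leak, channel, synaptic and axial terms all implicit. Gate rates use
precomputed lookup tables (0.05 mV resolution). The default step is
0.0125 ms; the convergence contract is that spike counts are invariant under
halving of the step, which the acceptance suite checks on the two-release
mutant scenario. Voltages beyond ±200 mV raise a numerical-failure error
naming the compartment.

Spike detection is an upward crossing of 0 mV at the recording point with a
1-ms refractory separation and linear-interpolated crossing times.

## Calibration of the baseline

Parameters not fixed by the catalogue or by the geometry were frozen by a
deterministic procedure (`calibrate_baseline()`):

1. fix the printed constants (geometry, NaV1.1 0.5 / NaV1.6 0.35 S/cm²,
   agonist concentrations, nerve composition);
2. solve the `s`-gate τ surfaces in closed form (above);
3. choose the remaining free scalars so that the **wild type** anchors the
   model: the WT branched fiber under two 1 µM ATP releases 15 ms apart must
   fire exactly 5 spikes, with a nodal action-potential overshoot inside
   +20…+45 mV. The shipped baseline meets the anchor at receptor-conductance
   scale 1.0 (overshoot 44 mV).

Mutant behavior is never part of the objective: every mutant count is a
prediction of the frozen baseline. This is the package's central validity
argument — and it cuts both ways, so the outcomes are reported plainly:

* Reproduced exactly: the anchor (WT 5 spikes at 15 ms); WT_M145T 4 spikes;
  the combined ATP+5-HT wild-type counts of the L263V, M145T and R1648H
  study pairs (6 spikes each); every slow-inactivation time constant; and
  all qualitative orderings — gain-of-function mutants fire at least as much
  as their wild types, the loss-of-function mutant at most as much, in all
  six pairs, with the L263V response more than double its wild type's.
* Not reproduced (the acceptance suite leaves these red): the wild type
  fires 5 rather than 4 spikes at the 10-ms interval; L263V fires 12 rather
  than 8; the combined-agonist counts of the WT_L263V, WT_Q1478K and
  WT_L1649Q fibers are 8/6/11 rather than 6/7/7; and the 0.6 µM 5-HT
  threshold dose evokes 2 rather than exactly 1 mutant spike (the wild type
  correctly stays silent). A gating-kinetics setting exists that lands the
  L263V counts exactly (τ_m peak 0.2 ms, τ_h peak 6 ms with narrower
  surfaces), but it violates the clamp parameter-recovery bounds that
  validate the channel model in the first place; the two constraint sets
  could not be met simultaneously anywhere in the explored parameter family,
  and the clamp-consistent baseline was kept.

The virtual-treatment experiments show the same pattern: for Q1478K the
printed behavior is reproduced exactly (correcting fast inactivation is the
strongest intervention and restores the wild-type count); for L263V all
three corrections reduce firing but fast inactivation, not activation, is
strongest; for L1649Q correcting fast inactivation paradoxically *increases*
firing in this model — the corrected channel's lower availability prevents
the depolarization block that otherwise terminates the mutant's burst.

## The whole nerve

The nerve bundles 5 Aδ-fibers (variant-carrying, with a 75/25 P2X3/P2X2 ATP
pool), 5 unmyelinated C-fiber stand-ins (NaV1.7/NaV1.8/KV1, no NaV1.1,
calibrated to fire about one spike per 1 µM ATP event), and 10
agonist-insensitive fibers. Sustained agonists are constant concentrations
with per-fiber onset jitter (uniform 0–500 ms) and ±10 % heterogeneity in
conductances, both seeded: the published model does not state how its 20
fibers were desynchronized, so this scheme is a declared substitute. Under
100 µM ATP + 2 µM 5-HT the L263V nerve produces roughly 70 % more merged
spikes than wild type, with the bulk of merged inter-spike intervals below
0.1 s. The test suite runs nerves at 0.5–0.7 s duration (a size chosen to
exercise the machinery; rate statistics stabilize with longer runs).

## What the synthetic data do and do not show

Surrogate "experimental" spike trains are renewal processes (exponential or
gamma inter-spike intervals). They exist so the Kolmogorov–Smirnov
validation machinery — the two-sample test used to compare ISI
distributions, with exact small-sample p-values — can be exercised end to
end without the original recordings, which are not available. Tests built on
them assert statistical behavior (identical trains give p = 1; a
shape-4 gamma train is distinguished from Poisson with > 80 % power at ~500
intervals); they deliberately assert nothing about biological agreement.

## Known limitations

* Single nominal temperature; no Markov channel schemes, stochastic gating,
  extracellular potentials, or calcium dynamics (the KCa reduction is
  voltage-only).
* The non-NaV1.1 channel parameters are literature-style defaults frozen by
  the calibration, not fits to a published parameter set.
* Absolute spike counts are sensitive to the gating-τ surfaces at the
  integer level (see the calibration outcomes above); orderings and relative
  effects are robust across the explored family, and conclusions should rest
  on those.
* The C-fiber is explicitly a stand-in with simplified geometry.
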
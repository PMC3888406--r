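---
title: "From single-cell early afterdepolarizations to fibrillatory wave patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From single-cell early afterdepolarizations to fibrillatory wave patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Early afterdepolarizations (EADs) are depolarizing reversals of the membrane
voltage during the repolarizing phase of a cardiac action potential (AP).
They appear whenever the *repolarization reserve* — the net outward-current
margin that completes repolarization — is eroded, e.g. by enhanced L-type
Ca current or blocked delayed-rectifier K currents (long-QT mutations, drug
toxicity, adrenergic stress).  `eadwave` provides a self-contained pipeline
for studying how cellular EADs scale up to tissue-level arrhythmia:

1. a modified human ventricular ionic model whose repolarization reserve is
   tunable (`make_params()`),
2. single-cell AP simulation, EAD detection and two-parameter phase
   diagrams (`simulate_ap()`, `classify_ap()`, `sweep_phase_diagram()`),
3. a 2D isotropic monodomain tissue solver with plane-wave (P1), S1–S2
   cross-field (P2) and periodic-pacing protocols plus non-conducting
   barrier grids (`tissue_config()`, `run_tissue()`),
4. pattern analysis: Na/Ca wavefront attribution, pseudo-ECG, averaged
   power spectra, interbeat intervals, phase-singularity counting, pattern
   classification and the phase-wave barrier test (`classify_pattern()` and
   friends).

## The ionic model and its modifications

The cell kinetics are the ten Tusscher–Panfilov 2006 (TP06) endocardial
human ventricular model: 12 Hodgkin–Huxley gates, intracellular Na/K/Ca
dynamics with SR release–uptake and rapid buffering, and the full current
set \(I_{Na}, I_{K1}, I_{to}, I_{Kr}, I_{Ks}, I_{CaL}, I_{NaCa}, I_{NaK},
I_{pCa}, I_{pK}, I_{bNa}, I_{bCa}\).  Units are mV, ms, pA/pF and mM
throughout.  Two EAD-promoting modifications are built into the baseline:

* the voltage-inactivation time constant \(\tau_f(V)\) of the L-type Ca
  channel is multiplied by `tau_f_scale` (default **0.5**, i.e. halved),
  which lets \(I_{CaL}\) reactivate during the plateau;
* because the faster \(f\) gate alone shortens the AP, the baseline
  \(G_{CaL}\) is set to **twice** the published TP06 value
  (\(2 \times 3.980\times10^{-5}\) mm\(^3\mu\)F\(^{-1}\)ms\(^{-1}\)),
  restoring the AP duration and its rate dependence.

`tau_f_scale` multiplies the whole \(\tau_f(V)\) curve uniformly; no
voltage-range restriction is applied.  The four conductances that control
the repolarization reserve are exposed as dimensionless multipliers
(`mult_CaL`, `mult_Ks`, `mult_Kr`, `mult_NaCa`) on the baselines
\(G_{Ks} = 0.3923027\), \(G_{Kr} = 0.1532432\) nS/pF and
\(k_{NaCa} = 1000\) pA/pF.  All other constants are the published TP06
endocardial values; the full set is serializable with `write_params()`
under the published names.

## Numerics

* **Integration.**  Gates use the Rush–Larsen exact-exponential update
  \(g' = g_\infty + (g - g_\infty)e^{-\Delta t/\tau_g}\), which cannot leave
  \([0,1]\); voltage and concentrations use forward Euler.  A pure
  forward-Euler gate mode (`euler_gates = TRUE`) exists for fidelity
  checks; both modes agree to first order in \(\Delta t\).
* **Lookup tables.**  All voltage-dependent rate expressions are tabulated
  on a 0.02 mV grid over \([-150, 150]\) mV with linear interpolation
  (relative error \(\sim 10^{-8}\)), rebuilt per run because they fold in
  \(\Delta t\) and the multipliers.  A hard guard rejects states outside
  \([-150, 150]\) mV.
* **Degenerate inputs.**  The GHK-type \(I_{CaL}\) driving force has a
  removable singularity at \(V = 15\) mV, replaced by its analytic limit.
* **Tissue.**  The monodomain equation
  \(\partial_t V = D\nabla^2 V - (I_{ion} + I_{stim})\) is discretized with
  a 5-point Laplacian on a node-centred grid.  Coupling is defined per
  *edge*: a cut edge contributes the centre value (zero flux), so Neumann
  boundaries and internal barriers share one mechanism.  The explicit
  scheme requires \(\Delta t \le \Delta x^2/(4D)\), enforced at config
  time.
* **Defaults.**  \(\Delta t = 0.02\) ms, \(\Delta x = 0.25\) mm,
  \(D = 1.54\times10^{-3}\) cm\(^2\)/ms — the standard settings for this
  model, giving a plane-wave conduction velocity near 0.7 mm/ms that
  scales as \(\sqrt D\).  Stimuli default to 20 pA/pF for 2 ms.

## Single-cell classification

`classify_ap()` labels a trace `NORMAL`, `EAD` or `OSCILLATORY`:

* an **EAD** is a local minimum of V above `plateau_floor` (−40 mV)
  followed by a rise of at least `rise_min` (1 mV), after the upstroke and
  before the first return below `rest_threshold` (−75 mV);
* reversals within `blank_after_upstroke` (100 ms) of the upstroke are
  ignored: the spike-notch-dome of a healthy human ventricular AP is an
  early reversal that is *not* an EAD, and without this blanking the
  baseline cell would be mislabelled;
* a trace that never returns below `rest_threshold` within `window_rest`
  (3 s) of the last stimulus is **OSCILLATORY**; non-repolarization
  dominates any EAD count (tie-break).

All thresholds live in `classifier_config()` — the underlying transitions
are gradual and no single cut is privileged.  On the analytic template
family (`make_ap_trace()`) the classifier is exact by construction.
`detect_ead_drivers()` reports the current balance at each EAD onset; in
the EAD regime the dominant inward term is the reactivating \(I_{CaL}\).

Phase diagrams (`sweep_phase_diagram()`) sweep `mult_CaL` (default 1–8)
against one of `mult_Ks`/`mult_Kr`/`mult_NaCa` (default 0–1).  Reducing the
repolarization reserve always walks NORMAL → EAD → OSCILLATORY with no
reverse transitions; `check_regime_ordering()` reports violations rather
than silently accepting them.

## Canonical regime points

`regime_params()` freezes four (mult_CaL, mult_Ks) pairs chosen once from
the package's own 8×6 phase diagram:

| regime   | point    | single-cell behaviour      | tissue behaviour            |
|----------|----------|----------------------------|-----------------------------|
| baseline | (1, 1)   | normal AP                  | plane wave / single spiral  |
| sf_a     | (4, 0.6) | multiple EADs              | breakup into small Ca-led spirals |
| sf_b     | (6, 1)   | normal single-stimulus AP  | S1–S2 spiral breaks into Na-led chaos |
| osc      | (8, 0.4) | non-repolarizing, ~6 Hz    | synchronized phase-wave oscillation |

`sf_a` sits mid-EAD-region; `sf_b` sits in the no-EAD region adjacent to
the EAD boundary, where breakup needs the S1–S2 substrate; `osc` lies well
inside the oscillatory region, where the single-cell limit cycle runs at
about 167 ms (≈6 Hz), the middle of the 4–8 Hz band the region spans.  The
oscillation frequency in the 2D oscillatory pattern equals the single-cell
frequency and is independent of the initiation protocol, because the
pattern is a field of phase-shifted local oscillators, not a propagating
excitation.

## Initiation protocols and barriers

* **P1** stimulates a 6-node-wide strip at the left edge (full edge height
  by default, configurable) once — the low-rate limit of tissue pacing.
* **P2** is the standard S1–S2 cross-field protocol: S1 = P1; the S2
  stimulus fires over the bottom-left quarter at the moment the S1
  *waveback* sweeps past the middle of that quarter (the column at nx/4
  repolarizes below −40 mV after having been excited, checked every ms).
  Firing on the waveback rather than the front places S2 exactly on the
  refractory gradient, which is what lets it curl into one
  counter-rotating spiral; event-driven timing is used instead of a fixed
  delay because the correct S2 moment shifts with the multipliers.
* **paced** re-applies P1 periodically (300–1000 ms) for a configured
  epoch; the emergent pattern class is insensitive to the pacing rate.
* **Barriers** (`apply_barrier_grid()`) cut the coupling along a square
  lattice of pitch `block` (default 40 nodes = 1 cm), leaving states
  untouched.  Non-conducting edges are the primary implementation; a
  refractory-line variant can be emulated by scheduling a persistent
  stimulus on the lattice nodes, but the mask route is exact and is what
  the tests use.

## Pattern classification

`classify_pattern()` gathers evidence — sustainment, Na/Ca upstroke
attribution, the averaged power spectrum, Hilbert-phase singularity counts,
per-node amplitudes — and applies explicit rules (all thresholds in
`pattern_config()`):

* **not sustained** (no node above −70 mV beyond 3 s after the last
  stimulus plus one domain-crossing time): `SELF_TERMINATED_SFa` if
  wavebreaks (≥2 singularities) occurred first, else `NO_SUSTAINED_EAD` if
  EAD reversals occurred anywhere, else `PLAIN_PROPAGATION`;
* **sustained**: `OSC` when no upstroke is Na-mediated, per-node amplitude
  stays under `osc_amp_max` (40 mV) and, when run, the barrier test says
  phase waves; `SINGLE_SPIRAL` when exactly one singularity persists and
  no breakup occurred; otherwise the Na-mediated fraction splits `SF_a`
  (< `sf_split` = 0.2) from `SF_b`.

An upstroke (upward crossing of −30 mV) counts as Na-mediated when its
pre-upstroke floor is below `na_floor` (−60 mV, above which \(I_{Na}\) is
inactivated) *and* the Na availability \(m^3hj\) at the crossing exceeds
`na_avail_min` (0.01).  The continuous `na_fraction` is always reported
alongside the discrete label because the SF_a/SF_b transition is gradual.
Spiral counting uses the topological charge of the Hilbert phase of V on
grid plaquettes — an implementation choice; any method that finds rotor
cores would do.

`phase_wave_test()` operationalizes the phase-wave/trigger-wave
distinction: continue a developed pattern under a barrier grid; diffusive
(trigger) waves are absorbed — activity dies or stays confined to isolated
compartments — while phase waves, which require no coupling, keep
"propagating" across the lattice.  The verdict is decided by the fraction
of compartments still active in the last quarter of the test window
(≥ 0.5 ⇒ `PHASE_WAVES`).  One caveat the tests surfaced: deep in the EAD
regime the fibrillation-driven Ca loading can leave every cell in
sustained depolarized oscillation, so after the barriers absorb the waves
the isolated compartments keep oscillating on their own — the verdict then
correctly reads phase waves for what has locally *become* an oscillatory
medium.  The spiral/oscillatory distinction is gradual, not sharp, and
the barrier verdict should be read together with the per-node amplitudes
and the Na fraction.  The pseudo-ECG is the far-field dipole integral
\(\sum \nabla V \cdot \nabla(1/r)\, dA\) for an electrode 2.5 mm above the
domain centre; the averaged spectrum sums mean-removed periodograms over
an even sublattice of (by default) 10000 nodes, no taper.

## The synthetic generator

`make_ap_trace()` and `make_movie()` produce analytic traces and movies
with known ground truth: template APs with k raised-cosine EAD humps,
single-passage plane and target waves, rotating spiral fields with one or
two cores, pure phase-gradient oscillation fields, and seeded white noise;
`make_oscillator_state()` builds a decoupled-oscillator tissue state (run
it with `D = 0`) for the barrier test.  Gate-product channels are
synthesized consistently with the declared Na/Ca truth.  These fixtures
exercise every analysis operator without the PDE solver, and each one
round-trips: its generated label equals the analysis label.  They make no
attempt at physiological realism beyond what the decision rules read —
passing them shows the *rules* are implemented correctly, not that the
rules are optimal for noisy optical-mapping data.

## Problem sizes and what the tests show

The package's test suite runs desk-scale versions of every mechanism:
100×100 nodes at 1 mm spacing (10×10 cm) for 3.8 s for the spiral and
breakup checks, 60×60 at 0.25 mm for the oscillatory-regime runs, 24×24
for the barrier-fixture matrix, alongside the full single-cell phase
diagram.  The 1 mm spacing is a deliberate coarsening: the discrete
dynamics at coarse dx are those of a proportionally larger fine-grid
domain, and 10 cm is the smallest domain in which an S1–S2 spiral
persists (the spiral wavelength is ~7 cm); the conduction velocity drops
from 0.71 to 0.42 mm/ms in the process, which the pattern-class checks
tolerate.  The oscillatory regime is size-insensitive (it is a local
limit cycle).  One mechanism does not fit on a desk: wavebreak initiation
from the waveback of a *single* P1 plane wave.  At every size and spacing
we tried (2.5 cm patches to 30 cm corridors) the EAD band is plainly
visible in the line profiles — every node shows the secondary plateau
depolarization — but the humps remain electrotonically synchronized and
never detach into a retrograde wave; building that dispersion in a
homogeneous medium needs the full 600×600-node, ≥10 s production setting.
The same breakup physics is exercised desk-scale through the S1–S2
route, where the spiral supplies the dispersion and the EAD dynamics
shatter it into sustained Ca-mediated fibrillation.

## Known limitations

* Homogeneous, isotropic, 2D monodomain tissue; endocardial kinetics only.
  No fiber anisotropy, heterogeneity, bidomain electrics or 3D geometry.
* Forward-Euler diffusion at fixed \(\Delta t\); no adaptive stepping.
* The pattern classifier's thresholds are calibrated for this model's
  dynamic range; optical-mapping data would need renormalized voltages.
* Temperature is fixed at 310 K; no Markov channel models.
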
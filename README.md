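# eadwave

Multiscale simulation and analysis of **early afterdepolarization (EAD)
driven arrhythmias** in human ventricular tissue.

An EAD is a depolarizing reversal of the membrane voltage during the
repolarizing phase of an action potential (AP).  EADs appear when the
*repolarization reserve* — the net outward current that completes
repolarization — is eroded, as in long-QT syndromes or drug cardiotoxicity,
and they are a recognized trigger of ventricular fibrillation.  `eadwave`
is for computational electrophysiologists who want to walk the whole chain
from ionic conductances to fibrillatory wave patterns in one package:

* **Ionic model** — the ten Tusscher–Panfilov 2006 (TP06) endocardial human
  ventricular cell model with two EAD-promoting modifications: the L-type
  Ca inactivation time constant τ_f(V) halved, and the baseline G_CaL
  doubled (2 × 3.980·10⁻⁵ mm³ µF⁻¹ ms⁻¹) to restore the AP duration.  The
  conductances G_CaL, G_Ks, G_Kr and k_NaCa are exposed as multipliers on
  their baselines.  Gates integrate by Rush–Larsen, V and concentrations by
  forward Euler (Rcpp core, voltage lookup tables).
* **Single cell** — `simulate_ap()`, EAD classification
  (`classify_ap()`: NORMAL / EAD / OSCILLATORY), EAD current decomposition
  (`detect_ead_drivers()`), and two-parameter phase diagrams
  (`sweep_phase_diagram()`).  Reducing the repolarization reserve always
  walks NORMAL → EAD → OSCILLATORY.
* **2D tissue** — isotropic monodomain solver
  ∂V/∂t = D∇²V − (I_ion + I_stim), 5-point Laplacian, no-flux boundaries,
  plane-wave (P1), S1–S2 cross-field (P2) and periodic-pacing protocols,
  and non-conducting barrier grids (`tissue_config()`, `run_tissue()`,
  `apply_barrier_grid()`).
* **Pattern analysis** — Na- vs Ca-mediated wavefront attribution
  (`attribute_waves()`), pseudo-ECG (Σ ∇V·∇(1/r) dA, `pseudo_ecg()`),
  averaged temporal power spectra (`mean_power_spectrum()`), interbeat
  intervals, Hilbert-phase singularity counting, pattern classification
  into spiral fibrillation types a/b, oscillatory (phase-wave) activity
  and non-sustained classes (`classify_pattern()`), and the barrier-grid
  phase-wave test (`phase_wave_test()`).
* **Synthetic fixtures** — analytic AP templates and voltage/gate movies
  with known ground truth (`make_ap_trace()`, `make_movie()`,
  `make_oscillator_state()`) so every analysis operator is testable
  without the PDE solver.

See the methods vignette (`vignettes/eadwave-methods.Rmd`) for the model,
the classifier rules, all tunable thresholds and the package's design
choices.

## Worked example

Classify one EAD-regime action potential and sweep a small phase diagram:

```r
library(eadwave)

p <- make_params(mult_CaL = 4, mult_Ks = 0.6)   # reduced repolarization reserve
tr <- simulate_ap(p, record_currents = TRUE)
classify_ap(tr)
#> AP class: EAD (3 EADs, repolarized)

head(detect_ead_drivers(tr)[, c("ead", "t_onset", "I_CaL", "I_Ks",
                                "ical_dominant_inward")], 1)
#> # A tibble: 1 × 5
#>     ead t_onset I_CaL  I_Ks ical_dominant_inward
#>   <int>   <dbl> <dbl> <dbl> <lgl>
#> 1     1     327 -2.38  1.77 TRUE

pd <- sweep_phase_diagram(c(1, 3, 5, 8), "Ks", c(0.4, 1))
dplyr::count(pd, label)
#> # A tibble: 3 × 2
#>   label           n
#>   <chr>       <int>
#> 1 EAD             2
#> 2 NORMAL          4
#> 3 OSCILLATORY     2
```

The classification says the trace repolarized but carried three plateau
reversals (EADs), each driven by reactivation of the L-type Ca current —
`I_CaL` is the largest inward term at every onset.  The sweep shows the
regime ordering: at full G_Ks the cell is normal up to high G_CaL, while
at 40 % G_Ks it passes through the EAD band into oscillatory dynamics.

In the oscillatory regime the cell never returns to rest and oscillates
near 6 Hz; tissue made of such cells produces synchronized "waves" that
are *phase waves* — they cross non-conducting barriers untouched, unlike
the trigger waves of spiral fibrillation:

```r
tr <- simulate_ap(regime_params("osc"), tail_ms = 10000)
dominant_frequency(trace_power_spectrum(tr, t_min = 1000))
#> [1] 5.991346
```

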
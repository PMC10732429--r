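---
title: "A whole-cell biophysical model of Merkel-cell mechanotransduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A whole-cell biophysical model of Merkel-cell mechanotransduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Merkel cells are epidermal touch receptors. They do not fire Na⁺ action
potentials; instead, mechanical load on the cell opens Piezo2 channels, the
resulting Ca²⁺ entry and depolarisation recruit voltage-gated Ca²⁺ channels
and intracellular Ca²⁺ handling, and the slow cytosolic Ca²⁺ signal drives
vesicular neurotransmitter release onto the Aβ afferent for tens of seconds —
far outlasting the rapidly inactivating Piezo2 current itself. `merkelcell`
implements this chain as one deterministic stiff ODE system with 28 state
variables and exposes the four classic experimental drives (current pulses,
high-K⁺ bath swap, hypotonic shock, indentation ramp-and-hold) as runnable
protocols.

# The model

## Membrane electrophysiology

Six voltage-gated channel populations are modelled with Hodgkin–Huxley
gating: the A-type K⁺ channels Kv1.4 (activation `m⁴`, biexponential
inactivation `0.7 h_fast + 0.3 h_slow`) and Kv4.2 (`m h`), the
Ca²⁺-activated BKCa channel (`n`, with a Ca²⁺-dependent half-activation
voltage `V_half = −43.3 log10(C_Ca / 1 mM) − 110` mV and a Gaussian slope
factor in `pCa`), a delayed rectifier KDR (`n`), the L-type Cav1.2
(`m h h_Ca`, with algebraic Ca²⁺-dependent inactivation
`h_Ca = 1/(1 + (C_Ca/1 µM)⁴)`) and the P/Q-type Cav2.1 (`n`). Each gating
variable relaxes as `dx/dt = (x∞(V) − x)/τ_x(V)` with the fitted steady
curves and time constants evaluated in mV/ms and converted at the boundary.

Every membrane pathway is expressed as a molar flux density, **positive into
the cytosol** (mol m⁻² s⁻¹). Channel fluxes are `J = −g · p_open · (V_m −
E)/F` for cations and `+g (V_m − E)/F` for Cl⁻; the published molar
convention for Ca²⁺-carrying channels (division by `F`, not `2F`) is kept,
and the charge balance books those fluxes with weight 2, so charge and mass
bookkeeping match the source equations exactly. The source equations mix
signs pathway-by-pathway; this single convention, checked by physiological
direction tests (Ca²⁺ leak inward at rest, K⁺ channels outward above
`E_K`, Na⁺/K⁺ pump hyperpolarising) and by an independent charge
re-summation oracle in the test suite, resolves them.

Transport: a saturating Na⁺/K⁺ pump (3 Na⁺ out / 2 K⁺ in, net +1 charge
out), an electroneutral NKCC1 cotransporter driven by
`C_Na,o C_K,o C_Cl,o² − C_Na C_K C_Cl²`, an electroneutral KCC2
cotransporter implemented as the product-difference driving force
`P (C_K C_Cl − C_K,o C_Cl,o)` (the printed expression is not well-formed;
the printed rate constant, whose unit cannot be coherent with any product
form, is read as the flux per mM² of product difference), a Hill-type
plasma-membrane Ca²⁺ pump, and an electrogenic 3:1 Na⁺/Ca²⁺ exchanger of
the standard voltage-dependent form. The exchanger's driving bracket,
`e^{ηVF/RT} C_Na³ C_Ca,o − e^{(η−1)VF/RT} C_Na,o³ C_Ca`, is **positive in
reverse mode** (1 Ca²⁺ in, 3 Na⁺ out, net +1 charge out per cycle); that
orientation is the only one under which the source's ion, Ca²⁺ and charge
balances are mutually consistent, and it reproduces the stated physiology —
Ca²⁺ extrusion at rest, reversal under depolarisation.

## Piezo2

Piezo2 is a four-state machine gated by cortex stress σ: closed `C`, open
`O`, short-time inactivated `In` (with `C + O + In = 1`), and a slow
availability factor `h_slow`; the conducted flux is
`−g O h_slow (V_m − E)/F`, booked entirely as Ca²⁺ (the channel's Na⁺/K⁺
permeation is ignored, a stated model simplification). Two equation sets
apply: under *loading* the closed pool drains through `O` into `In`; under
*unloading* `In` recovers directly to `C` with `O` frozen. The phase flag is
protocol-driven — `loading` while a mechanical stimulus (indentation ramp or
hold, hypotonic swelling) is applied, `unloading` otherwise — because the
source switches equation sets without a σ-based criterion. Two numerical
guards keep the state on the probability simplex for arbitrary
phase/stress sequences: state targets are clamped to the available pool
(`In → min(In∞, 1−O)`, and in the loading phase with falling stress `C →
min(C∞, 1−O)` with `O` decaying); under monotone loading the published
equations are reproduced exactly. `piezo2_advance()` provides the exact
exponential-relaxation kernel at fixed σ for unit testing; in whole-cell
runs the same equations ride in the global state vector (no operator
splitting).

## Internal stores

SERCA pumps Ca²⁺ into the ER with a Hill law; the ryanodine receptor
releases it above a cytosolic threshold (0.3 µM) with a steep sigmoid times
the ER–cytosol gradient; the IP₃ receptor combines an always-on leak with an
IP₃-gated term (`Hill³` in IP₃) and slow Ca²⁺ activation/inhibition gates
`m, h` (τ = 10 s and 20 s). IP₃ is produced from a precursor pool at a
Ca²⁺-dependent rate and degrades first-order; the precursor replenishes
through a saturating sigmoid. Mitochondria take Ca²⁺ up through the MCU
(Hill exponent 2.3) and return it through the mitochondrial exchanger; both
mitochondrial balances carry the buffer factor `1/(1+β_MT)` on **both** the
store and the cytosol side, so the conserved closed-cell quantity is the
plain sum `n_Ca + n_Ca,ER + n_Ca,MT` (verified to 10⁻⁶ relative over 10 s
in the tests).

Two printed-form idiosyncrasies are resolved the standard way, each behind a
config switch that restores the literal text: the inhibition gate relaxes as
`(h∞ − h)/τ_h` (the printed `(h∞ − m)/τ_h` would let `h` leave [0, 1]), and
the Ca²⁺ dissociation constant in the IP₃ production term is squared in both
places it appears (`literal_ip3ca = TRUE` restores the unsquared variant).

### A numerical hazard: the ryanodine threshold

As written, the release law jumps from 0 to `P/2 · (C_Ca,ER − C_Ca)` at the
threshold, and the permeability is enormous (8.5 cm/ms): a stiff adaptive
solver chatters indefinitely on the induced sliding surface. The whole-cell
integrator therefore multiplies the above-threshold branch by a C¹
smoothstep ramp of width 0.002 µM (< 1 % of the threshold, configurable via
`ryr_ramp_width`); the exported `ryr_flux()` kernel keeps the literal
piecewise law, and the spec-level behaviour (zero at and below threshold,
saturated release above) is unchanged.

## Volume mechanics and indentation

Water crosses the membrane as `J_w = −α (ΔP − ΔΠ)` with
`ΔΠ = RT (ΣC_in − ΣC_out)`; the intracellular sum includes an impermeant
species A⁻ whose amount and mean valence are solved **once** at
initialisation so that the seeded state is simultaneously electro-neutral
and osmotically balanced (the source states near-electro-neutrality but
never gives the amount). The cortex is elastic in the area strain,
`σ = K/2 (S/S_ref − 1) − σ_a`, and Laplace's law `ΔP = 2 h_c σ / r` closes
the loop. Exocytosis adds one vesicle area `4π r_ve²` to `S_ref` per fusion
event and tension-suppressed endocytosis removes it; turnover modifies
`S_ref` only, as written.

Indentation uses a volume-conserving sphere-to-cylinder map: at depth `d`
the cell is a cylinder of height `H = 2 r_ini − d` and radius
`√(V/(πH))`. One honest property of this reconstruction: the surface jumps
above the sphere's at first contact, dips slightly until the equal-area
height `(4V/π)^{1/3}`, and grows strictly only beyond it — so "any contact
loads the cortex" holds everywhere, but strict monotonicity in `d` only
past the shallow-contact region. The geometry sits behind
`compressed_geometry()` so a spherical-cap alternative can be swapped in.

## Vesicle cycle

The pool refills at `k_ve/(1 + e^{(n_ve − 500)/50})` — decreasing in the
pool size, following the text's statement that synthesis is inversely
related to the pool (the printed sigmoid has the opposite orientation;
`literal_vesicle_sign = TRUE` restores it) — and drains by exocytosis,
`k_exo/(1 + e^{−(C_Ca − 0.2 µM)/0.01 µM}) n_ve`. The instantaneous
exocytosis rate is the model's transmitter-release proxy; "exocytosis
duration" is operationalised as the time this rate exceeds 2× its
pre-stimulus baseline (factor configurable in `summarize_trace()`).

# Units, parameters, presets

Internally everything is coherent SI (s, V, m, mol, Pa; concentrations in
mol/m³, numerically mM). The parameter registry stores each constant with
the unit its published value is quoted in (mS/cm², mol cm⁻² ms⁻¹, µM, …)
and converts once at the boundary; a round-trip test guards every
conversion. Two presets, `"fig2"` and `"fig3"`, carry the two published
columns of channel conductances and pump rates; all validation scenarios
use `"fig2"`. The high-K⁺/hypotonic parameter column and the external and
initial-value tables of the source's supplement are not available, so those
scenarios also use the `"fig2"` column, the default bath is Na 145 / K 5 /
Cl 110 / Ca 2 mM (mannitol only in the hypotonic baseline), and initial
states are always produced by rest relaxation, never hard-coded.

## The cell radius

The radius is not published. It is set to 7 µm on three grounds: (i) the
Piezo2 characterisation protocol indents to 7.9 µm, which requires a cell
taller than that with room to spare; (ii) at the validation current
(114.1 pA, the largest pulse of the current-step experiment) the membrane
should depolarise to the ~0 to +25 mV scale seen in the reference
recordings — with a 5 µm radius the current density is so high that no
combination of the published K⁺ conductances can hold the peak below
~+77 mV, while 7 µm lands at ~+22 mV; (iii) dissociated Merkel cells are
10–15 µm across. The radius is configurable (`r_ini`).

# Initialisation and integration

`initialize_rest()` finds the stimulus-free fixed point: staged stiff
relaxation with algebraic re-anchoring of the two slow membrane-turnover
coordinates between stages (the vesicle pool at its synthesis/consumption
balance and `S_ref` at the cortex stress where endocytosis matches
exocytosis — their intrinsic relaxation time is ~10³ s, far slower than
everything else), followed by a damped Newton polish on the scaled
derivative to a max-norm residual below 10⁻⁸ s⁻¹. A consequence worth
knowing: the resting cortex stress is high (~1.1 kPa), because at low
tension endocytosis would strip membrane area until tension rises to meet
the resting exocytosis rate — this is forced by the published turnover
constants, and it leaves Piezo2 within a few hundred Pa of its activation
midpoint, which is precisely what makes 3–7 µm indentations effective.

Whole-cell runs use `deSolve::lsoda` (rtol 10⁻⁶; absolute tolerances set
per variable from resting magnitudes) with protocol onsets/offsets as
solver restart points, so discontinuous drives never cross a step. The
suite cross-checks the adaptive solution against a fixed-step fourth-order
Runge–Kutta oracle at 1 µs steps over a 200 ms window (0.1 % scaled
agreement). The model is deterministic; a seed argument exists only for
interface hygiene.

Problem sizes used by the tests and the endpoint script — 28 state
variables; 0.2–0.4 s horizons for pulse shapes; 10–40 s for the high-K⁺,
conservation and compression studies; 60 s for the Ca²⁺-load endpoint —
were chosen to match the corresponding experimental windows.

# What the simulations do and do not show

The protocols emulate the classic experimental drives, not their
recordings: there is no fluorescence-indicator kinetics, no spatial Ca²⁺
diffusion or waves (the cell is a single well-mixed pool, as in the
source), no afferent spiking, no vesicle "kiss-and-run", and no
hypotonic inhibition of cytoplasmic mobility — so a passing qualitative
regression says the *equations* reproduce the claimed shape, not that a
real cell would.

Three published behaviours do **not** emerge from the printed constants,
and the corresponding checks are deliberately left failing rather than
tuned:

* With the Cav2.1 conductance doubled, cytosolic Ca²⁺ under the 60 s pulse
  self-limits near ~27 µM (not >50 µM): as Ca²⁺ accumulates, `E_Ca` falls
  toward the depolarised plateau and the driving force vanishes.
* The peak potential is not monotone across the full Cav1.2 sweep
  {0, 2, 20, 200 mS/cm²}: with `K_BKCa = 1 mM` as printed, a low-Ca²⁺ cell
  has BKCa right-shifted by ~+60 mV, so the zero-Cav1.2 run plateaus
  *higher* than the small-conductance peak (the sweep is monotone over the
  nonzero values). A µM-scale BKCa Ca²⁺ sensitivity would restore the
  published ordering, but the printed constant is kept.
* Blocking ER Ca²⁺ handling *raises* the high-K⁺ peak by ~2 % instead of
  dropping it: the printed ER permeabilities lock `C_Ca,ER` to the cytosol
  on sub-ms timescales while the ER pump is ~40× weaker than the
  plasma-membrane pump, so the ER can never hold a concentrated store and
  acts only as a ~10 % buffer volume.

# Known limitations

Single well-mixed compartment; Piezo2 carries only Ca²⁺; store geometry is
static (no ER/mitochondrial swelling); IP₃ and its precursor are tracked as
concentrations and are not diluted by volume change (as written); the
loading/unloading phase flag is protocol-driven, so oscillating mechanical
stimuli within one "loading" window rely on the documented recovery
branch; and the `"fig3"` preset describes an oscillating cell whose rest
state may be a limit cycle rather than a fixed point, in which case
`initialize_rest()` reports the residual and fails rather than returning a
moving target.
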
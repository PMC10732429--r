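# merkelcell

Whole-cell biophysical simulation of a Merkel cell — the epidermal touch
receptor that converts skin indentation into sustained neurotransmitter
release onto slowly adapting type 1 (SA1) Aβ afferents.

Merkel cells do not fire Na⁺ action potentials. The model couples, in one
stiff ODE system (28 state variables):

* **Membrane electrophysiology** — Hodgkin–Huxley gating for Kv1.4, Kv4.2,
  BKCa, KDR, Cav1.2 and Cav2.1 (`dx/dt = (x∞(V) − x)/τ_x(V)`), ohmic leaks,
  a Na⁺/K⁺ pump, NKCC1/KCC2 cotransporters, a plasma-membrane Ca²⁺ pump and
  a 3:1 Na⁺/Ca²⁺ exchanger; the membrane potential obeys
  `C_m dV_m/dt = F Σᵢ zᵢ Jᵢ + I_app/S_ref` with all fluxes positive into
  the cytosol.
* **Piezo2 mechanotransduction** — a four-state stress-gated machine
  (closed/open/inactivated on the simplex `C + O + In = 1`, plus a slow
  availability factor), conducting Ca²⁺ as `−g O h_slow (V_m − E)/F`.
* **Internal Ca²⁺ stores** — SERCA, ryanodine receptor (Ca²⁺-induced Ca²⁺
  release above 0.3 µM), IP₃ receptor with slow activation/inhibition
  gates, IP₃/precursor turnover, mitochondrial uniporter and exchanger.
* **Volume mechanics** — osmotic water flux `J_w = −α(ΔP − ΔΠ)`, elastic
  cortex stress `σ = K/2 (S/S_ref − 1) − σ_a`, Laplace pressure, and a
  volume-conserving sphere-to-cylinder indentation geometry.
* **Vesicle cycle** — Ca²⁺-dependent exocytosis (the transmitter-release
  proxy), pool replenishment, and tension-dependent endocytosis feeding
  membrane area back into `S_ref`.

The four classic experimental drives are built in as protocols: rectangular
current pulses, high-K⁺ bath swap (+130 mM K⁺ / −130 mM Na⁺), hypotonic
shock (mannitol removal), and indentation ramp-and-hold (1 µm/ms), plus a
scenario registry mirroring the corresponding figure protocols.

## Worked example

Relax the cell to rest and indent it by 5 µm:

```r
library(merkelcell)

m <- merkel_model()          # "fig2" preset, relaxes to the resting state
summary(m)
#> Merkel-cell whole-cell model (preset 'fig2')
#>   bath: Na 145, K 5, Cl 110, Ca 2 mM (mannitol 0 mM)
#>   impermeant species: n_A = 1.353e-13 mol, mean valence -1.373
#>   resting state: Vm = -55.72 mV (residual 5.51e-10)
#>   resting composition:
#>     C_Na 13.4 mM, C_K 138 mM, C_Cl 4 mM, C_Ca 0.1259 uM
#>     C_Ca_ER 0.1259 uM, C_Ca_MT 0.1549 uM, IP3 1.05 uM
#>     volume 1373.8 um^3, S/S_ref 1.346, cortex stress 1138 Pa, vesicles 844

tr <- run_protocol(m, protocol_compression(5, 1, onset = 0.005, hold = Inf),
                   horizon = 20)
s <- summarize_trace(tr)
#> peak Vm        -16.5 mV     depolarisation from -55.7 mV rest
#> peak C_Ca       5.70 uM     Piezo2 + Cav-driven Ca2+ transient
#> Ca duration      1.3 s      time above half the Ca2+ rise
#> exo duration    17.6 s      exocytosis above 2x its resting rate
```

Reading: the ramp loads the cortex (rest stress ~1.1 kPa rises past the
Piezo2 midpoint at 1.45 kPa), Piezo2 opens and rapidly inactivates, the
brief Ca²⁺ influx and depolarisation recruit the voltage-gated Ca²⁺
channels, and although the membrane repolarises within a second, vesicle
release stays elevated for ~18 s — the model's account of how a rapidly
adapting channel produces a slowly adapting output. Deeper indentations
lengthen the release window (`run_scenario("fig13_compression")`).

Other entry points: `protocol_high_k()`, `protocol_hypotonic()`,
`protocol_current_pulse()`; `plot(tr)` for a four-panel trace view;
`list_scenarios()` / `run_scenario()` for the figure-mirroring scenario
registry with CSV output; `load_config()` / `write_config()` for a YAML
parameter file with explicit units; `inst/cli/merkelcell.R` for a thin
command-line front end (`run`, `rest`, `list-scenarios`).

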
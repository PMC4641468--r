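# knaephys

Analysis of sodium-activated potassium (K_Na) current in small-diameter
dorsal root ganglion (DRG) neurons, and of its role in setting
action-potential threshold and rheobase.

Small DRG neurons — the cell bodies of itch- and pain-sensing afferents —
express a Na⁺-activated K⁺ conductance carried by Slo2.2 (Slack) subunits.
Removing it (Slo2 double knockout, "dKO") lowers rheobase, shifts the
phase-plane spike threshold to more negative voltages and raises firing rates
at every injected current, while leaving the spike waveform and
afterhyperpolarization unchanged: K_Na acts as a brake on action-potential
initiation. `knaephys` implements the full analysis chain behind this kind of
study, together with a conductance-based DRG neuron simulator so that every
stage can be exercised offline against known ground truth.

## What is in the package

* **Simulator** — single-compartment neuron, `C dV/dt = −ΣI_ion + I_inj`,
  with a fast transient Nav conductance (Boltzmann activation, V_h = −10 mV,
  z = 4.1 e), a delayed rectifier, a passive leak, and a K_Na conductance
  gated instantaneously by submembrane [Na⁺] through a Hill function
  (EC50 = 40 mM, n = 3.5, whole-cell maximum 69 nS, unitary 127 pS).
  Submembrane Na⁺ lives in a 2 fl shell fed by Nav influx and cleared with a
  25 ms extrusion time constant. Whole-cell voltage clamp scales K_Na by the
  pipette-dialysis factor `(1 − e^(−t/60 s)) · e^(−t/900 s)`. Current clamp,
  voltage clamp, inside-out single-channel records, and log-normally
  perturbed cohorts (`simulate_current_clamp`, `simulate_voltage_clamp`,
  `simulate_single_channel`, `make_cohort`).
* **Leak quantification** — difference current of the −80 → −120 mV step,
  dialysis/rundown time-course fits, and the voltage-dependent Cs⁺ block
  `f(V) = 1 − A / (1 + exp(−zF(V − V_h)/RT))` with multi-start
  Levenberg–Marquardt fitting (`leak_difference_current`, `leak_time_course`,
  `fractional_inhibition`, `fit_cs_block`, `eval_cs_block`).
* **Excitability features** — spike detection, dV/dt (10 %-of-peak)
  threshold, rheobase by family scan or simulator bisection, f–I curves, AP
  shape, ramp zero-crossing, input resistance, train AHPs (`detect_aps`,
  `ap_threshold`, `rheobase`, `fi_curve`, `ramp_zero_crossing`,
  `input_resistance`, `train_ahp`, `ap_shape_features`).
* **Closed-form biophysics** — chord-conductance resting potential
  `V_m = Σ gᵢEᵢ / Σ gᵢ`, K_Na conductance sweeps, Nernst potentials,
  Boltzmann chord-conductance fits, linear resting conductance, and
  single-channel conductance from all-points amplitude histograms
  (`chord_model`, `chord_vm`, `gkna_sweep`, `nernst`, `boltzmann_chord_fit`,
  `linear_conductance_fit`, `single_channel_conductance`,
  `unitary_amplitude`).
* **Group statistics** — two-sample Kolmogorov–Smirnov comparisons with the
  small-sample switch to Student's t (both n < 10), and a summary table in
  the conventional layout (`ks_two_sample`, `compare_cohorts`,
  `summarize_table`).
* **Pipeline & IO** — CSV-per-sweep + JSON-sidecar containers
  (`write_sweeps`/`read_sweeps`) and a deterministic end-to-end run
  (`run_config`, `run_pipeline`).

## Worked example

```r
library(knaephys)

# Chord-conductance resting potential with the background conductances
# g_K = 0.7 nS (E_K −80), g_Na = 0.165 nS (E_Na +60), g_Cl = 0.3 nS (E_Cl −50):
chord_vm(chord_model())
#> [1] -52.44635
# ... and after adding 0.16 nS of K_Na (reversal E_K):
chord_vm(chord_model(g_kna = 0.16))
#> [1] -55.77358     # ~3.3 mV of hyperpolarization from Po ≈ 0.002

# Simulate one wild-type cell through the standard protocol set and extract
# its excitability features:
cell <- simulate_standard_cell(make_cohort(1, "WT", seed = 1)[[1]])
extract_features(cell)
#>       id genotype       cm        mp      rin rheobase threshold  ap_peak
#> 1 WT-001       WT 19.30137 -64.77621 843.9362       26 -30.52971 37.63691
#>   half_width      ahp count60 count100 count200 ramp_crossing
#> 1   2.473464 -79.5206      14       17       22     -42.04495
```

`rheobase` is in pA (smallest 20 ms current step that elicits a spike),
`threshold` is the membrane voltage at which dV/dt reaches 10 % of its peak
during the first spike (mV), `count60/100/200` are spikes per 1 s step, and
`ramp_crossing` is the command voltage at which the net current turns inward
during a 40 ms depolarizing ramp. A dKO cohort run through the same code
shows lower rheobase, more negative threshold, higher counts and a more
negative ramp crossing — the hyperexcitability signature of K_Na loss:

```r
res <- run_pipeline(run_config(seed = 1, n_per_group = 6))
res$summary   # mean ± sem per genotype and the KS/t p-value per measure
```

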
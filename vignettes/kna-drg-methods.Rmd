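---
title: "Quantifying sodium-activated potassium current in DRG neurons: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sodium-activated potassium current in DRG neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knaephys)
```

## The scientific problem

Small-diameter dorsal root ganglion (DRG) neurons — the somata of itch- and
pain-sensing afferents — carry a Na⁺-activated K⁺ conductance (K_Na, encoded
by the Slo2.2/Slack subunit). Deleting it makes the neurons more excitable in
a specific way: the rheobase falls, the action-potential threshold moves to
more negative voltages, and firing rates rise at every level of injected
current, while the spike waveform and the afterhyperpolarization (AHP) are
essentially untouched. K_Na in these cells therefore acts as a brake on AP
*initiation*, not on repolarization.

`knaephys` implements the complete analysis chain behind such a study:

1. a conductance-based single-compartment DRG neuron with submembrane Na⁺
   handling and Hill-activated K_Na (`neuron_params`,
   `simulate_current_clamp`, `simulate_voltage_clamp`,
   `simulate_single_channel`, `make_cohort`);
2. quantification of the Na⁺-dependent background ("leak") current from
   hyperpolarizing steps, its dialysis/rundown time course, and the
   voltage-dependent block by extracellular Cs⁺ (`leak_difference_current`,
   `leak_time_course`, `fractional_inhibition`, `fit_cs_block`);
3. excitability feature extraction: phase-plane (dV/dt) threshold, rheobase,
   f–I curves, AP shape, ramp zero-crossing, input resistance, train AHPs
   (`detect_aps`, `ap_threshold`, `rheobase`, `fi_curve`,
   `ramp_zero_crossing`, `input_resistance`, `train_ahp`);
4. closed-form biophysics: chord-conductance resting potential, Nernst
   potentials, Boltzmann activation fits, single-channel conductance
   (`chord_model`, `chord_vm`, `gkna_sweep`, `nernst`,
   `boltzmann_chord_fit`, `single_channel_conductance`);
5. cohort statistics in the reporting convention of the field
   (`ks_two_sample`, `compare_cohorts`, `summarize_table`) and an
   end-to-end pipeline (`run_pipeline`).

Because the raw recordings behind such studies are generally not public, the
simulator is a first-class component: every analysis stage is exercised
against synthetic data whose ground truth is known.

## The neuron model

The membrane equation is

$$C \frac{dV}{dt} = -\big(I_{Nav} + I_{Kdr} + I_{KNa} + I_{leak}\big) + I_{inj}$$

with four conductances:

* **Fast transient Nav** — Boltzmann activation gate $m$ with
  $V_h = -10$ mV and effective charge $z = 4.1\,e$ (the values obtained by
  chord-conductance fits to peak inward current in these neurons), first-order
  inactivation gate $h$, $I_{Nav} = \bar g_{Na}\, m\, h\, (V - 60)$.
* **Delayed-rectifier K** — single gate $n$,
  $I_{Kdr} = \bar g_{K}\, n\, (V + 80)$.
* **Passive leak** — ohmic, $0.8$ nS at $-60$ mV, setting the ~1.25 GΩ input
  resistance of these small cells.
* **K_Na** — instantaneously gated by submembrane Na⁺ through a Hill
  function, $I_{KNa} = \bar g_{KNa}\, \mathrm{Po}([\mathrm{Na}]_s)\,(V + 80)$
  with $\mathrm{Po} = [\mathrm{Na}]_s^{3.5} / ([\mathrm{Na}]_s^{3.5} +
  40^{3.5})$. The whole-cell maximum is 69 nS; the channel itself is treated
  as voltage-independent between −80 and −20 mV, consistent with the weak
  voltage dependence of the 127 pS unitary events.

All Boltzmann slopes use $RT/F$ at 19 °C (room-temperature recordings),
$RT/F \approx 25.17$ mV.

### Submembrane Na⁺ handling

K_Na channels sense Na⁺ in a thin submembrane shell (default volume 2 fl)
fed by Nav influx and cleared with a first-order extrusion time constant
(25 ms):

$$\frac{d[\mathrm{Na}]_s}{dt} = -\frac{I_{Nav}}{F\,v_{shell}} -
\frac{[\mathrm{Na}]_s - [\mathrm{Na}]_{rest}}{\tau_{x}}$$

Two deliberate choices live here, and they are the package's answer to the
genuinely open question of how K_Na is activated at the foot of the AP:

* **A basal submembrane [Na⁺] of 10 mM** is maintained at rest. Through the
  Hill curve this yields ≈0.5 nS of standing K_Na in the wild type — a static
  load that raises rheobase, moves the dV/dt threshold to more positive
  voltages, and hyperpolarizes the resting potential, all without touching
  the AP upstroke. This is what makes the wild-type/knockout orderings of
  threshold and rheobase come out as observed: a brake that acted only
  *during* the upstroke would blunt peak dV/dt and push the measured
  10 %-of-peak threshold the wrong way.
* **In current clamp the basal value is independent of pipette Na⁺ over
  0–10 mM** (extrusion keeps the shell at its set point), mirroring the
  experimental finding that firing, rheobase and threshold do not differ
  between 0 and 10 mM pipette Na⁺. In voltage clamp the shell rests at
  `max(basal, pipette)`: 70 mM pipette dialysis dominates and drives the
  large background current of the leak protocol.

The dynamic (influx-driven) component then adds activity-dependent braking:
Na⁺ accumulated during firing slows wild-type trains, and Nav influx during
a depolarizing voltage ramp builds the outward K_Na hump that delays the
voltage at which net current turns inward.

### Dialysis and rundown

In whole-cell voltage clamp the K_Na conductance scales with

$$s(t) = \left(1 - e^{-t/\tau_{eq}}\right)\, e^{-t/\tau_{run}}$$

($\tau_{eq} = 60$ s, $\tau_{run} = 900$ s): zero at break-in, near-plateau by
3 minutes, slow decline by 30 minutes. Nav and leak are unaffected by
dialysis. `leak_time_course` fits this product jointly even for series
confined to the first minutes, because the rundown term already biases a
rise-only fit by ~30 % at 5 minutes.

### Free parameters and how they were set

Capacitance (16.1 pF), the Nav activation pair ($-10$ mV, $4.1\,e$), the K_Na
maximum (69 nS), unitary conductance (127 pS), Hill parameters (EC50 40 mM,
coefficient 3.5), dialysis time constants, recording noise (0.3 mV / 5 pA)
and temperature are the study's stated or derived values. The remaining
kinetic parameters (Nav $\bar g$ 60 nS, $\tau_m$ 0.3 ms, $\tau_h$ 14 ms,
inactivation $V_h$ −42 mV / 4.5 e; Kdr $\bar g$ 80 nS, $V_h$ −5 mV, $z$ 4 e,
$\tau_n$ 14 ms; leak 0.8 nS at −60 mV; shell 2 fl, $\tau_x$ 25 ms, basal
10 mM) were chosen once so that the default wild-type and knockout templates
jointly reproduce the qualitative physiology: ~GΩ input resistance, broad
overshooting spikes with an AHP near −80 mV, sustained repetitive firing
without depolarization block up to 200 pA, a ramp current that turns net
inward within the ramp for both genotypes, and every reported
wild-type/knockout ordering (rheobase, threshold, f–I counts, ramp
zero-crossing, resting potential). They are defaults of `neuron_params()`,
not constants, and all are documented there.

Two honest limitations of this operating point: absolute rheobase
(~28 pA WT / 20 pA dKO) sits below the experimental ~87/58 pA because real
DRG neurons carry additional subthreshold K⁺ conductances (A-type) that are
outside this model's scope; and the resting-potential separation between
genotypes (~10 mV) is larger than the ~3 mV reported, because the standing
K_Na needed for the threshold ordering also weighs on the resting potential.
All group-level *orderings* are preserved, which is what the analyses here
assert; the corresponding experimental means are not reproducible without
the raw recordings in any case.

## The analysis operations

**Leak quantification.** The Na⁺-dependent background current is the
difference current of a −80 → −120 mV step: mean current over the step
plateau minus mean over the pre-step baseline, each window being the last
25 % of its segment with the first 2 ms discarded (uncompensated capacitive
settling). Sign convention: inward negative, so the K⁺ background appears as
a negative difference current that grows to the nA scale over ~3 minutes of
70 mM Na⁺ dialysis.

**Cs⁺ block.** 20 mM extracellular Cs⁺ blocks the K_Na current with a
voltage-dependent fraction

$$f(V) = 1 - \frac{A}{1 + \exp(-zF(V - V_h)/RT)}$$

complete at hyperpolarized voltages and saturating at $1 - A$ (≈ 61 %
residual inhibition for $A = 0.39$) when depolarized. `fractional_inhibition`
computes $f$ from matched control/Cs⁺ I–V records (total current by default,
or with a Na⁺-free or KNa-null reference subtracted), excludes voltages whose
control current sits below a noise floor (default 25 pA — in particular the
step at E_K, where the K_Na driving force vanishes), and clips stray values
into [0, 1] with a warning. `fit_cs_block` is a multi-start
Levenberg–Marquardt fit; a fit whose curve is essentially flat over the data
is flagged degenerate (voltage-independent limit, $V_h$ unidentifiable).
Because $z \approx 0.68\,e$ makes the curve shallow (slope factor
$RT/zF \approx 37$ mV), $V_h$ is intrinsically hard to pin down under noise:
the Monte-Carlo calibration in the test suite puts the median $|V_h|$ error
near 10 mV at 5 % current noise, and the tests assert the calibrated bound
rather than an optimistic one.

**Phase-plane threshold.** dV/dt is the centered difference of a 5-point
moving-average-smoothed trace; the threshold of the first AP is the voltage
at the *last* upward crossing of 10 % of peak dV/dt before the dV/dt peak
(the last-crossing rule discards stimulus-onset artifacts), linearly
interpolated between samples. Both the fraction and the smoothing width are
arguments.

**Rheobase** is the smallest current eliciting ≥ 1 AP in a 20 ms step from
−60 mV, scanned on a 2 pA grid from 20 to 300 pA; when given model
parameters instead of recorded sweeps, `rheobase` bisects the grid (the
underlying spike dynamics are noise-free, so bisection and exhaustive
scanning agree exactly).

**Ramp zero-crossing.** On a 40 ms depolarizing ramp the net current is
smoothed lightly, the inward surge is located as the current minimum within
the ramp, and the crossing is the last downward zero crossing before that
minimum, interpolated on the *command* voltage axis. The default ramp runs
−60 → −5 mV: over the −60 → −20 mV range alone the wild-type template's
K_Na hump can keep the net current outward throughout, which is exactly the
braking phenomenon under study, so the wider ramp is used to guarantee a
crossing for both genotypes.

**Train AHPs.** `train_ahp` measures the post-train voltage minimum relative
to the pre-train baseline over 1 s after the last pulse (5 ms blanking). The
measure includes the fast post-spike AHP; the scientific claim is the
*invariance* across 1, 5 and 10 pulses at 7.1 Hz — no slow AHP accumulates —
and that is what the tests assert (differences < 1.5 mV).

**Group statistics.** The two-sample Kolmogorov–Smirnov test is used when
both groups have n ≥ 10, otherwise a two-tailed unpaired Student's t-test
(pooled variance), and the choice is recorded. The KS p-value is exact for
small tie-free samples and asymptotic otherwise, so the KS branch is slightly
conservative (empirical size ≈ 0.03 at n = 12 for α = 0.05); the t branch is
exact under normality. `summarize_table` emits the canonical summary layout
(capacitance, resting potential, input resistance, rheobase, dV/dt threshold,
AP peak, half-width, AHP, 60/100/200 pA AP counts) with mean ± sem, n and the
p-value per row; absent features are reported absent, never imputed.

**Chord-conductance model.** The resting potential is the
conductance-weighted mean of reversal potentials,
$V_m = \sum g_i E_i / \sum g_i$ — equivalently the unique zero of total chord
current. With the default background branches (g_K 0.7 nS at −80 mV, g_Na
0.165 nS at +60 mV, g_Cl 0.3 nS at −50 mV; 1.165 nS total) the baseline is
−52.4 mV, and adding 0.16 nS of K_Na (reversal E_K) hyperpolarizes by
≈3.3 mV. Expressed as a fraction of the 69 nS whole-cell maximum, 0.16 nS is
an effective open probability of ≈0.002. `gkna_sweep` tabulates this in
0.02 nS increments and reports the expected K_Na current both at a fixed
evaluation voltage (−50 mV: 0.16 nS × 30 mV ≈ 4.8 pA under the chord form)
and at each row's own $V_m$; a published back-calculation quotes ~8 pA for
the same conductance, a figure the chord form does not reproduce and which
likely reflects an open-channel rectification assumption that cannot be
reconstructed — both columns are reported, neither is asserted as truth.

**Single-channel analysis.** Records are two-state Markov chains with
exponential dwell times, stationary open probability given by the Hill curve
of bath Na⁺, and open-level amplitude $\gamma (V - E_K)$ with $E_K =
+18.35$ mV for the inside-out solution pair (152.5 mM K⁺ out / 73.6 mM in).
`unitary_amplitude` builds the all-points histogram and fits a two-Gaussian
mixture to the bin counts; the unitary amplitude is the peak separation, and
regressing it on voltage returns the slope conductance (127 pS) and reversal.

## Worked example

```{r example, eval = FALSE}
library(knaephys)

# chord-conductance resting potential and the effect of 0.16 nS K_Na
chord_vm(chord_model())                      # -52.4 mV
chord_vm(chord_model(g_kna = 0.16))          # -55.8 mV (~3.3 mV more negative)

# simulate a WT cell and extract its excitability features
cell <- simulate_standard_cell(make_cohort(1, "WT", seed = 1)[[1]])
extract_features(cell)

# full pipeline: cohorts, leak time course, Cs+ block fit, summary table
res <- run_pipeline(run_config(seed = 1, n_per_group = 6))
res$summary
```

## What the synthetic data do and do not show

The generator reproduces the statistical and biophysical *structure* the
analyses assume: dialysis-limited rise and slow rundown of the background
current, voltage-dependent Cs⁺ block, weakly voltage-dependent 127 pS unitary
events with Hill-type Na⁺ gating, genotype differences confined to AP
initiation, log-normal cell-to-cell variability (fractional sd 0.25, matching
the rheobase coefficient of variation typical of such cohorts). It does not
emulate space-clamp error, electrode drift, seal leak, Nav channel diversity
(no TTX-resistant subtypes), A-type or Ca²⁺-activated K⁺ currents, or
temperature sensitivity (a single-compartment, Q10-free model). Passing
tests therefore certify the *analysis chain* — that each operation recovers
known ground truth and preserves the reported orderings — not that the model
is a complete account of DRG electrophysiology.

## Numerical choices

Fixed-step RK4 at the protocol sample interval (default 0.02 ms; halving the
step changes no AP count by more than 1), with command-input interpolation at
RK4 substeps. Voltage clamp forces $V$ along the command and integrates
gating and shell Na⁺ only. Submembrane [Na⁺] is clamped non-negative. The
multi-start Levenberg–Marquardt fits bound parameters physically
(0 ≤ A ≤ 1, z > 0, g ≥ 0) and keep the lowest-RSS convergent start; fit
failure after all starts is an error naming the data range. Cohort sub-seeds
are derived from the cohort seed by a fixed prime stride, so cohorts are
reproducible cell by cell and two runs with the same seed write byte-identical
files. Simulation sizes throughout the tests (1 s f–I sweeps, 30 s
single-channel records, cohorts of 8–30, 100–200 Monte-Carlo replicates) were
chosen as the smallest that give stable estimates of the quantities asserted.
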
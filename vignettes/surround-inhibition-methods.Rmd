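---
title: "Modeling surround inhibition under low-amplitude spinal cord stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling surround inhibition under low-amplitude spinal cord stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scsdh)
```

`scsdh` is an integrated in-silico workflow for studying how low-amplitude,
low-frequency epidural spinal cord stimulation (SCS) suppresses nociceptive
transmission in the spinal dorsal horn (DH) through surround inhibition, plus
the spike-train analysis pipeline used to test the same hypothesis on
extracellular recordings. This vignette explains the models, the parameters
that matter, the design decisions taken where the design was genuinely open,
and what the synthetic data do and do not establish about real recordings.

## The scientific picture

Dorsal column (DC) axons are collaterals of large myelinated (A-beta) tactile
afferents, arranged somatotopically: fibers from a given peripheral field
enter, rise to the most dorsomedial position about two segments rostral of
entry, and are displaced ventrolaterally by later-entering fibers. An epidural
electrode therefore activates a *complement* of DC axons determined by
amplitude and rostrocaudal position. The package's circuit hypothesis: axons
from the *surround* receptive field drive inhibitory interneurons whose
projections converge on the wide-dynamic-range (WDR) projection neuron of the
*center* field, so a stimulation amplitude that recruits mostly surround
fibers suppresses the center WDR neuron, while stronger stimulation recruits
center fibers whose direct monosynaptic excitation cancels the inhibition.
Suppression versus amplitude is therefore nonmonotonic, with an interior
optimum below the motor threshold (MT, fixed at 100 uA; the perception
threshold is taken as 50% of MT).

## Extracellular field

The finite-element field of the original experimental setting is replaced by
an analytic volume conductor: two point sources (cathode -I, anode +I) in an
infinite homogeneous anisotropic medium with white-matter conductivities
(0.6 S/m longitudinal, 0.083 S/m transverse). An insulating boundary in the
electrode plane represents the silicone-backed paddle and overlying bone;
because the sources lie in that plane, its image sources exactly double the
potential in the tissue. Users with a genuine finite-element export can load
it with `load_field_table()` (rectilinear CSV grid, trilinear interpolation)
and every downstream step accepts either field.

Two geometric parameters were genuinely open and were fixed against printed
operating points of the modeled preparation, not against any downstream
result:

* **Epidural offset (0.15 mm).** The rat dorsal epidural gap plus dura is of
  order 0.1-0.2 mm. The offset was chosen so that recruitment over the true
  fiber-diameter distribution reproduces three anchors: the most excitable
  fibers reach threshold around 16-30 uA (activation begins near 20-30% of
  MT); near-surround (tier 2) fibers begin recruiting just above the 50%-MT
  perception threshold, so center and surround recruitment are best separated
  at 40-50% MT; and fibers deep in the dorsal columns stay inexcitable below
  150 uA.
* **Fiber lattice extents (0.70 mm mediolateral, 0.45 mm dorsoventral).**
  Rat dorsal column cross-section at low-thoracic levels.

## Dorsal column axons

Axons are double-cable myelinated fibers: nodes of Ranvier carrying fast Na+,
persistent Na+, slow K+ and linear leak channels; passive myelin attachment
(MYSA), paranode (FLUT) and internode (STIN) sections; and an explicit
periaxonal layer under the myelin. Geometry follows the published
diameter-parameter table for this model class, interpolated within the
published range and, below its 5.7-um minimum, linearly extrapolated with the
least-squares slope over the table anchored at the 5.7-um row, floored at
physical minima (internodal axon diameter at least 1 um). Membrane dynamics
integrate with the second-order implicit (Crank-Nicolson) scheme at
0.0125 ms; gating states advance by staggered exponential updates. A spike is
an upward crossing of -20 mV with a 1-ms lockout, recorded at the most
rostral node (the analog of a cervical confirmation recording).

The activation threshold (AT) is defined on a *single* symmetric biphasic
pulse of the train's pulse width, bisected to 1% between 1 and 1000 uA; this
gives a train-independent normalization axis. Numerical guard: only
non-finite or absurd (>1e6 mV) membrane potentials abort a simulation —
near-electrode potentials at the upper bisection bracket legitimately exceed
hundreds of millivolts.

Near threshold the periodically driven axon fires irregularly — bursts and
skipped pulses — and entrains 1:1 only from roughly 120% of AT upward. This
amplitude-dependence of spike-train regularity, not just of recruitment
count, is what the downstream network converts into the nonmonotonic
suppression profile.

**Response libraries.** `build_response_library()` simulates each (position,
diameter, frequency, pulse width, amplitude) tuple once and stores spike
trains plus thresholds. Three documented regime rules keep libraries
desk-scale: amplitudes below AT are silent by construction (single-pulse
silence implies train silence for the interpulse intervals used here);
amplitudes above 1.6 x AT are represented as fully entrained 1:1 firing at
the single-pulse latency (the cable model itself entrains 1:1 from about
1.2-1.4 x AT, so the bound is conservative); between those bounds the full
train is simulated for a window (acceptance scale: 1.0 s) and extended periodically, pulse-aligned, to the
requested duration — the deterministic periodically driven axon settles to a
stationary pattern, so the extension preserves rates and entrainment
structure while halving simulation cost.

## Somatotopic map sampling

Candidate positions on a 10 x 6 lattice are ranked by Z = X^0.15 + Y^0.45
with X, Y normalized ranks in [0, 1] (0 = most medial / most dorsal; ties
broken by X then Y). The 20 smallest-Z positions form tier 1, the next 20
tier 2, the next 20 tier 3. A map draws 15 of 20 positions per tier without
replacement and wires tiers to the three circuit zones by targeting
condition: center (1 to 1, 2 to 2, 3 to 3), surround (1 to 2, 2 to 1,
3 to 3), or mix (tier 1 split 8/7 between zones 1 and 2, tier 2 the
complement). The lattice coordinate ranked by Y is implemented as
dorsoventral depth: the ranking explicitly selects "most medial and dorsal"
positions, which is only consistent with a dorsoventral reading of the
second coordinate.

Fiber diameters are drawn from a truncated normal on [2.2, 8] um whose
*post-truncation* mean and SD equal 4.4 and 1.0 um (the published values
describe the drawn diameters; naive truncation of Normal(4.4, 1) would bias
the mean by +0.035 um and shrink the SD to 0.96). The pre-truncation
parameters are moment-matched numerically.

## Dorsal horn network

Three nodes (zones), each holding one excitatory interneuron (EX), one
inhibitory interneuron (IN) and one WDR projection neuron, with four
compartments per neuron (dendrite, soma, hillock, axon) at the published
dimensions, 15 A-beta + 15 A-delta + 3 C afferent slots per node, and the
published synaptic conductances, kinetics and reversal potentials. Inter-node
connections run from each node's interneurons (and EX) to the other nodes'
neurons, reciprocally. Synaptic conductances are peak-normalized double
exponentials; NMDA carries a sigmoidal voltage-dependent block (half-block
-20 mV, slope 8 mV), required for wind-up. Excitatory synapses sit on the
dendrite, inhibitory ones on the soma. Integration is Crank-Nicolson at
0.0125 ms with spikes detected at the soma (-20 mV, 2-ms lockout).

The ionic inventory of each cell class is not recoverable from the circuit's
published description, so it is a design choice exposed in
`dh_membrane_defaults()` and fixed against behavioral contracts rather than
channel-level data: Hodgkin-Huxley-type Na / delayed-rectifier K on soma,
hillock and axon everywhere; an A-type K current plus a Ca-gated K
(adaptation) current on the IN; a slow Ca current plus Ca-dependent
nonspecific cation current on the WDR (wind-up under repetitive C drive).
Two passive choices matter most:

* **IN input resistance is deliberately low** (leak 1e-3 S/cm2 vs 4e-4 on
  EX/WDR). A high-impedance IN fires once per afferent EPSP and saturates at
  baseline, leaving no headroom for stimulation-driven inhibition; the
  low-impedance IN integrates summating high-rate drive, so sparse irregular
  DC input recruits it weakly and dense input strongly — the gain structure
  surround inhibition needs.
* **The contracts used for tuning** (before any acceptance run): quiescence
  without input; sustained WDR firing under neuropathic afferent drive;
  strictly higher WDR rates with GABA_A and glycine removed; graded (not
  all-or-none) suppression of the center WDR by surround-targeted
  stimulation.

Pain states scale GABA_A conductance (down to 0.5), shift GABA_A/glycine
reversal potentials in 4-mV steps up to +16 mV, activate up to 50% more
A-delta/C inputs in surround nodes (implemented as additional activity merged
into existing slots), and scale A-beta drive to the IN (down to 0.5); 30
states are drawn by Latin hypercube sampling with the reversal shift snapped
to its 4-mV grid.

### A known limitation: the extreme disinhibition corner

With the GABA_A conductance halved *and* the inhibitory reversal shifted the
full +16 mV (to -54 mV), the shifted reversal lies above this circuit's
resting and interspike potentials, so the remaining inhibitory conductance is
net depolarizing: surround stimulation then produces no suppression at any
amplitude, rather than suppression with an optimum displaced to higher
amplitudes. We verified this holds for both somatic and dendritic (shunting)
placement of the inhibitory synapses. Intermediate pain states behave
conventionally (weaker, right-shifted suppression); only the joint extreme
corner inverts. Interpreting recordings through this package should treat
that corner as outside the model's validated regime.

## Synthetic data generators

* **Afferent pain input**: per-fiber rates from a gamma distribution
  (shape 2) with population means 2.2 Hz (A) and 1.5 Hz (C). One third of A
  fibers burst; bursts have 2 + Poisson(4) spikes (mean 6), exponential
  intra-burst intervals (mean 30 ms), and exponential inter-burst intervals
  (mean 551 ms) *within bursting episodes*; episodes are separated by
  quiescent gaps sized so each train realizes its drawn mean rate. The
  episodic structure is the only arrangement under which the three published
  burst means and the published population rate can hold simultaneously —
  continuous bursting at those statistics alone fires at ~8.6 Hz, four times
  the stated population mean. Burst membership is annotated in the output so
  burst statistics are measured directly rather than re-detected.
* **Pain states**: 4-D Latin hypercube (one sample per stratum per axis).
* **Unit waveforms**: the two-Gaussian mean-waveform model sampled at 40 kHz
  over 1.2 ms plus white noise; monophasic (putatively excitatory, pEX)
  units have a dominant lobe (|a2/a1| < 0.25), biphasic (putatively
  inhibitory, pIN) units have opposite-sign lobes of comparable size.
* **Recorded sessions**: Poisson baseline (default 600 s, mirroring the
  ten-minute spontaneous recordings such protocols use) and per-amplitude
  stimulation windows at baseline rate times a known modulation factor, with
  pulse times kept for artifact bookkeeping. Ground truth rides along for
  closed-loop tests.

What passing closed-loop tests show — and what they do not: the generators
emulate rate structure, burst statistics, waveform shape dichotomy and
stationary rate modulation. They do not emulate spike-sorting errors,
overlapping spikes, electrode drift, true non-stationarity, or correlated
population activity; closed-loop recovery therefore bounds pipeline error
under ideal sorting, not recording-chain error.

## Spike-train analysis pipeline

* **Bin width** per neuron and frequency by the shift-averaged spike-count
  cost C(D) = (2 mean(k) - var(k)) / D^2 over a log grid from 10 to 2000 ms
  (the cited selection method's cost functional, which the source text does
  not reprint).
* **Responder rule**: stimulation bins z-scored against the mean and SD of
  *all* complete baseline bins at the same width; a unit is a responder when
  three or more consecutive bins reach |z| >= 1.96; direction is the sign of
  the summed significant z. Bins whose stimulation-artifact blanking (1 ms
  per pulse) covers more than 25% of the bin are dropped together with the
  phase-matched baseline bins; zero baseline variance falls back to the
  Poisson approximation, flagged.
* **Normalization** divides each unit's per-amplitude rate changes by the
  largest absolute change (+1 excitatory / -1 inhibitory); all-zero vectors
  pass through.
* **Inclusion**: baseline rate at least 1.5 Hz and a responder at one or
  more amplitudes.
* **Clustering**: covariance PCA (responses already share the [-1, 1]
  scale), first two components, fuzzy c-means (fuzzifier 2.0, at most 500
  iterations, objective tolerance 1e-5, 10 seeded restarts) for 2-6
  clusters; cluster counts scored by mean silhouette and the Davies-Bouldin
  index.
* **Waveform classification**: nonlinear least-squares fit of the
  two-Gaussian model (5 heuristic starts), shape features (signed lobe
  ratio, lobe widths, inter-lobe interval; a fitted lobe narrower than 1.5
  samples is treated as a fit artifact), and a quadratic Gaussian
  discriminant trained on the generator's feature distributions. A unit is
  assigned pEX or pIN only when the class posterior exceeds 0.60. The
  discriminant is a plain serializable object and can be retrained on any
  labeled set.

## Experiments and problem sizes

`run_amplitude_sweep()`, `run_parameter_grid()`, `run_pain_state_sweep()` and
`run_onset_timecourse()` orchestrate the study designs. The default scale is
the package's acceptance scale — 6-s simulations with stimulation over the
final 3 s, 25 map seeds (the study's map count),
library train windows of 1.0 s — chosen as the
smallest design in which the targeting and amplitude effects are stable
across seeds; `paper_scale = TRUE` in `experiment_config()` restores the full
18 s / 10 s protocol. The unstimulated epoch is identical across amplitudes
for a given seed, so the integrator checkpoints at stimulation onset and
resumes bit-exactly per amplitude; an identity test guards the equivalence.
All randomness flows from explicit integer seeds; rerunning any configuration
reproduces outputs exactly.

## Numerical choices collected

* Integration step 0.0125 ms everywhere; Crank-Nicolson with staggered
  exponential gating updates.
* Axon threshold bisection: bracket [1, 1000] uA, relative tolerance 1%.
* Spike detection: -20 mV upward crossing; lockout 1 ms (axon), 2 ms
  (network somata).
* Charge balance of stimulus pulses is exact by construction (equal-sample
  cathodic and anodic phases, no interphase gap).
* Tier ties broken by (X, then Y) ascending; library lookups snap diameters
  to the nearest simulated grid value (0.2-um steps below 6 um).
* Degenerate inputs: empty spike trains fall back to a 500-ms analysis bin
  with a warning; rank-deficient response matrices cluster on the available
  component, flagged; unclassifiable waveform fits propagate to
  "unclassified".
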
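---
title: "Decoding whisker deflection intensity from barrel-cortex evoked responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding whisker deflection intensity from barrel-cortex evoked responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A linear silicon probe in the rat somatosensory barrel cortex records, across
all six cortical layers, the response evoked by deflecting a single whisker
with one of three stimulus amplitudes (large / medium / small, driven by
2.8 / 2.0 / 1.6 V piezo pulses). The recording contains two complementary
signals: the local field potential (LFP, 0.1--300 Hz), a population-level
analog trace with a characteristic negative deflection peaking roughly 25 ms
after the stimulus, and multi-unit activity (MUA, 300--3000 Hz), threshold
events from small groups of nearby neurons. Under urethane-like anesthesia
the cortex alternates at roughly 1 Hz between active UP and quiescent DOWN
states, which modulate the evoked response.

`whiskdecode` implements the full decoding pipeline on this kind of data:
feature-level statistics of the evoked responses, and single-trial
classification of the stimulus amplitude with spiking neural networks —
primarily a liquid state machine (LSM) — against conventional machine-learning
baselines, including evaluations conditioned on the cortical state and on the
cortical layer supplying the LFP.

Because the underlying in-vivo recordings are not publicly distributable, the
package ships a synthetic-recording generator whose outputs have the
statistical structure the analysis assumes. All tests and the acceptance
script run on synthetic sessions; headline accuracies from the original
in-vivo dataset are not reproducible here, and the package makes no attempt
to imitate them numerically.

# The synthetic session generator

`synth_config()` / `generate_recording()` produce a multi-electrode session:

* **Geometry.** 27 in-cortex channels in contiguous blocks per layer
  (II:4, III:5, IV:5, Va:4, Vb:4, VI:5), mirroring a 65 µm-pitch probe
  spanning 0 to −1800 µm. Any partition summing to 27 is accepted.
* **States.** UP/DOWN intervals alternate with gamma-distributed durations
  (shape 2, mean $1/(2 f)$ per state at alternation rate $f \approx 1$ Hz).
  The shape-2 choice avoids the degenerate near-zero intervals an
  exponential draw would produce.
* **Background spiking.** Per channel, Poisson spikes at 10 Hz during UP and
  0.5 Hz during DOWN (both configurable), rendered as biphasic
  derivative-of-Gaussian waveforms (~0.2 ms lobes, ≈85 µV negative peak).
* **Evoked LFP.** Each stimulus injects a difference-of-alpha-functions
  template: a fast negative lobe peaking 25 ms post onset and a slower
  positive lobe giving the rebound within the following 100 ms. The peak
  magnitude is `evoked_gain(class) × layer_gain(layer)`, times `state_gain`
  (1.4) when the stimulus falls in a DOWN state; the small class is delayed
  by `rol_shift_small` (4 ms). Layer gains peak in the thalamorecipient
  layers III/IV.
* **Evoked MUA.** A spike burst within 100 ms whose first-spike latency is
  longer for the small class and for DOWN states, and whose spike count
  scales with the class most strongly in layers III/IV.
* **Noise.** Three components: slow biological noise band-limited below
  250 Hz (15 µV), a bounded 450 Hz mains harmonic (5 µV) inside the spike
  band, and a small white thermal component (0.4 µV). This decomposition is
  deliberate: with wideband *Gaussian* noise, a fixed 3σ detection threshold
  crosses pure noise at a Rice-formula rate of tens of events per second
  regardless of the noise amplitude — no scaling can fix it, and the
  UP/DOWN contrast the state detector relies on drowns. Real spike-band
  noise floors that make 3σ detection usable are dominated by bounded or
  narrow-band components; the generator models exactly that regime. The
  amplitude-threshold detector then operates with essentially no false
  positives, which is the premise of every MUA-based step downstream.

Ground-truth state and planted peak magnitude are returned in a sidecar
table (`truth`) that tests may read but the pipeline never does.

The generator's default inter-stimulus interval is 1.5 s rather than the
10 s of the in-vivo protocol: the trial counts (61/63/61), not the idle time
between trials, carry all the statistical structure, and a 10 s ISI would
only inflate sessions ~7-fold. The protocol value remains one config field
away.

What the generator does **not** emulate: electrode drift and gliosis,
spike-waveform diversity across units, distance-dependent LFP attenuation
and phase shifts, anesthesia-depth drift, and any nonstationarity across the
session. Consequently, green tests here demonstrate that the pipeline's
logic recovers planted structure under realistic noise — not that the
classifiers would reach any particular accuracy on in-vivo data.

# Preprocessing

`bandpass()` splits each channel with zero-phase (forward–backward) elliptic
filters: the LFP band as an order-2 highpass at 0.1 Hz cascaded with an
order-4 lowpass at 300 Hz (a single bandpass with a normalized low edge of
2·10⁻⁵ is numerically ill-conditioned), the spike band as an order-4
bandpass 300--3000 Hz. Passband ripple is 0.01 dB and stopband attenuation
40 dB; zero-phase filtering squares the ripple, and 0.01 dB keeps repeated
filtering of in-band signals within 1% RMS. Zero-phase filtering is chosen
so the filters add no latency bias to onset-latency estimates. The LFP
branch is decimated by plain subsampling (valid because the signal is
already band-limited to 300 Hz) to 2500 Hz for the feature path or 1000 Hz
for the classifier path.

`detect_spikes()` thresholds each spike-band channel at $Thr = 3\sigma_n$
with the robust noise estimate $\sigma_n = \mathrm{median}(|x|)/0.6745$ —
the plain standard deviation over a trace containing spikes would inflate
the threshold. Detection is bipolar (on $|x|$) with a 1 ms dead time; a
single-polarity flag exists for preparations where the negative lobe alone
is wanted. `group_mua()` merges spikes separated by strictly less than
20 ms into MUA events; a gap of exactly 20 ms splits events.

# UP/DOWN state detection

`compute_ifr()` counts spikes in 10 ms windows stepped by 1 ms, per
electrode, divides by the window length (Hz — the scale cancels in the
threshold comparison) and sums over electrodes. The global mean of this
cumulative profile is the threshold; UP intervals are maximal runs strictly
above it (ties fall to DOWN; a silent trace is all-DOWN). The mean is taken
over the full session, evoked epochs included — at the default ISI the
evoked contribution raises the threshold slightly, which only makes the
labeler more conservative about UP. `label_stimuli()` marks a stimulus UP
when any UP interval intersects the half-open window 50 ms before onset
(half-open so the onset sample itself never contributes).

# Evoked-response features

Per trial and layer (channel-mean LFP at 2500 Hz):

* **ROL** — first instant within 20 ms of onset where the absolute trace
  derivative exceeds mean + 3 SD of the pre-stimulus baseline derivative
  (nominal 10 s baseline, truncated to the available pre-stimulus span).
  The derivative is taken on a 2 ms boxcar-smoothed copy so broadband noise
  does not set the threshold; smoothing can be disabled.
* **RPA** — response peak (most negative value within 50 ms after the onset
  instant) combined with the onset-instant voltage as the drop
  $|x(\mathrm{ROL}) - RP|$. Of the readings of "combining the onset and
  peak voltages", the drop is the only one that is positive and monotone in
  response size; a literal signed sum can cancel.
* **PR** — maximum positive voltage within 100 ms after the main peak,
  absent when the trace stays non-positive.
* **tLFP** — AUC/RD, where RD runs from the onset instant to the first
  return to the onset-instant voltage after the peak (capped at 300 ms and
  flagged when capped) and AUC integrates $|x - x(\mathrm{ROL})|$ over RD.
* **MUA latency / duration / rate** — the first layer-pooled spike after
  onset (within 100 ms) starts the evoked MUA; spikes with gaps < 20 ms
  extend it. Latency is that first-spike time, duration $T = t_2 - t_1$,
  rate $n/T$ (missing, not infinite, for single-spike events). During UP
  states ongoing background can contribute the first spike; this shortens
  UP latencies, in the same direction as the planted state effect.

# Nonparametric statistics

`wilcoxon_rank_sum()` and `kruskal_dunn()` are implemented from the rank
formulas with explicit midrank tie handling — exact enumeration of the
conditional null for small samples, tie-corrected normal / chi-squared
approximations otherwise — and are cross-checked in the tests against both
base R (`wilcox.test`, `kruskal.test`) and permutation oracles.
`build_sig_table()` arranges, per layer and feature, UP-vs-DOWN rank-sum
tests at each intensity (diagonal cells) and intensity-pair Dunn tests
within each state (off-diagonal), the latter gated on a Kruskal–Wallis
omnibus test at α = 0.05. Dunn p-values are unadjusted by default (Holm by
flag); no grid-wide multiplicity correction is applied. The strongest
printed significance grade is rendered at the numeric cutoff p ≤ 10⁻⁴.
Under label shuffling the gated off-diagonal cells are conservative
(their marginal rate is the omnibus rate times the conditional Dunn rate),
while the ungated diagonal cells hold the nominal level — the acceptance
suite checks exactly that.

# Threshold-crossing encoding

`encode()` converts an analog trace into events on $2N$ channels
($N = 50$ thresholds): rising channel $i$ fires at sample $t+1$ iff
$x_t \le \vartheta_i < x_{t+1}$, falling channel $i$ iff
$x_t \ge \vartheta_i > x_{t+1}$ — strict inequality on the new sample, so a
trace sitting exactly on a threshold emits nothing. Thresholds are the $N$
interior points of a uniform partition of the signal range, so one monotone
sweep of the range crosses each exactly once. The range is pooled from the
training split and frozen at test time to avoid leakage (per-trial ranges
are supported but discard amplitude information, which here *is* the
class signal).

# The liquid state machine

LIF neurons with exponential postsynaptic currents: resting potential 0 mV,
C = 30 pF, τ_m = 30 ms (so R = 1 GΩ), τ_syn 3 ms (excitatory) / 2 ms
(inhibitory), threshold 15 mV, reset 13.8 mV, refractory 2 ms, constant
bias 7 pA. Two liquids: 330E/80I fed by the 100 encoder channels (input
weights U(250, 750) pA) and 100E/25I fed by the 27 electrode channels
directly (U(15, 45) pA). Every neuron receives exactly 2 excitatory and 1
inhibitory recurrent synapses; weights N(100, 70) / N(500, 350) /
N(−400, 280) pA by class, sign-clipped; delays N(10, 20) ms clipped to
[3, 200] ms; each input channel projects to 4 random excitatory neurons.
Recurrent synapses carry Tsodyks–Markram short-term plasticity. The
class-wise (U, τ_rec, τ_fac) means follow the Maass-2002 convention —
EE (0.5, 1.1 s, 50 ms), EI (0.05, 125 ms, 1.2 s), IE (0.25, 0.7 s, 20 ms),
II (0.32, 144 ms, 60 ms) — jittered ±50% per synapse, since the source
parameter set is not published with the model.

Numerics: fixed-step Euler integration at 0.1 ms with delays rounded to the
grid; synaptic arrivals via per-delay ring buffers; membrane potentials
initialized uniformly over [0, θ) to desynchronize the liquid (the
alternative fixed −70 mV start is a config switch; with a 15 mV threshold
it merely delays the first spikes). Per-neuron background noise is a
100 Hz Poisson generator with a fixed weight drawn N(2, 1) pA — the noise
source statistics are otherwise unspecified, so rate and weight are both
exposed in the config. The readout is the excitatory spike trains filtered
with a 5 ms exponential kernel, sampled 45 ms after onset, fed to a linear
SVM (one-vs-one, cost C grid-searched). Each trial is simulated from 1 s
before onset so spontaneous activity shapes the liquid state. The
MUA-liquid readout instant and filter mirror the LFP case; they are
configurable.

## Hardware-constraint emulation

`apply_hardware_constraints()` maps the liquid onto the constraint set of a
mixed-signal neuromorphic processor: four synapse types (sign × synaptic
time constant) sharing one weight magnitude each (the median absolute
weight of the type), per-synapse quantization to `round(|w|/base)` parallel
unit connections (zero-rounded synapses drop out), fan-in truncation to 64
incoming units per neuron in input order, zero delays (events land on the
next integration step), static synapses, and multiplicative Gaussian
mismatch (CV 20%, clipped at ±2 SD) on τ_m, θ, V_reset and C per neuron.

# The BPTT-trained spiking network

A discrete-time LIF network (1 ms steps, τ_m = 20 ms, R = 1 GΩ, threshold
b = 0.01 — interpreted in volts, consistent with R = 1 GΩ and pA-scale
currents; a unitless mode is a config switch) trained end-to-end. The
membrane map is $V \leftarrow \alpha V + (1-\alpha) R I$ with
$\alpha = e^{-\delta t/\tau}$, reset by threshold subtraction, and a 2 ms
refractory hold (duration unstated in the source model; 2 ms matches the
liquid's neurons). The spike derivative is replaced by the dampened
triangular pseudo-derivative $\gamma \max(0, 1-|v|)$, $\gamma = 0.3$, at
the normalized potential $v = (V-b)/b$. Readout: three leaky integrators
(τ = 20 ms) with a softmax at the window end — the readout architecture is
not pinned down by the source beyond "activation of readout units", and
leaky integrators are the minimal spiking-compatible choice. Training:
minibatch SGD on cross-entropy + L1, learning rate halved after more than
10 stalled epochs, and a sign-constrained Deep-Rewiring variant whose
target connectivity is the liquid scheme's live-connection count (input
fan-out 4 onto excitatory neurons; recurrent in-degree 2E+1I): a magnitude
crossing zero goes dormant, and dormant slots are resampled uniformly among
scheme-respecting positions until the count is restored. Plain SGD (no
momentum) is assumed where the optimizer details are unstated.

**Gradient validation.** The finite-difference check of the backward pass
runs the *same* code path with the hard threshold replaced by a continuous
nonlinearity whose derivative is exactly the pseudo-derivative (a clipped
quadratic ramp). The hard forward is not differentiable, so differentiating
it numerically would compare the surrogate against a function it is not the
gradient of; the soft mode isolates the correctness of the BPTT machinery
itself. With γ = 0, gradients through spikes vanish identically — a sanity
test guards that too.

# Baselines

* **FF** — 80 rectified-linear hidden units on the 50-sample (1 kHz) LFP
  window, per-feature standardization learned on the training split,
  L-BFGS for 50 iterations, L2 10⁻³, init U(−k, k) with
  $k = 1/\sqrt{\text{fan-in}}$ (the conventional reading of the printed
  init bound; $1/\text{fan-in}$ is available by flag), early stopping at
  the best validation accuracy. Written in-package over `optim()`.
* **LSTM** — 64 units, the same window fed sequentially through one input
  neuron, SGD with learning rate 0.1, momentum 0.9, batch 32, 250 epochs,
  early stopping; standardization uses training-split statistics (the
  per-trial alternative is noted as ambiguous in the source description).
  Forward and backward are implemented in-package and finite-difference
  checked in the tests.
* **HC+RF** — random forest (100 trees) on {RPA, PR, ROL, tLFP, window
  mean, window SD}; features-per-split and node size grid-searched. The
  split criterion is Gini: the installed forest implementation does not
  expose information gain, so the criterion dimension of the grid is fixed.
* **RF (MUA)** — per-channel exponential filter (τ = 16 ms) of the spike
  trains read at 30 ms post onset, into the same forest setup.

# Evaluation protocol

`run_protocol()` performs 20 independent evaluations (5 in the acceptance
suite; the protocol is O(runs)): per run an independent stratified
80/20 train/test split with 20% of training held out for validation, grid
search on validation only, a single test evaluation, and mean ± SD over
runs. Stratification departs from a purely random split deliberately: with
185 trials a random 20% test draw can lose a class entirely; a flag
restores pure random splits. Liquid wiring is resampled each run along
with the split, mirroring the "initial parameters and splits randomly
chosen per evaluation" reading. Default grids: weight scales
{0.5, 1, 2} per dimension and C ∈ {0.1, 1, 10} — the searched
hyperparameters are named in the source protocol, the grid values are not.
`state_conditioned_eval()` scores UP-only and DOWN-only test subsets of
models trained on the combined data; `layer_conditioned_eval()` reruns the
LFP-liquid pipeline with each layer's mean LFP as encoder input. `psth()`
provides 4 ms-binned trial-averaged response histograms.

# Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run on: the full 61/63/61-trial
synthetic session for feature-recovery, type-I-error, population-rate and
end-to-end classification checks (5 evaluation runs for the latter); a
24-trial session for unit tests; a 90-trial session with all state effects
disabled for the state-conditioned null check; and a 60-trial high-SNR
session for the state-labeler agreement check. These sizes are the
package's choices for routine verification; every one of them scales up
through the config objects.

# Known limitations

* The synthetic generator plants class/state/layer structure through a small
  number of parametric mechanisms; classifiers may exploit planted structure
  more easily than in-vivo structure, so synthetic accuracies say nothing
  quantitative about real recordings.
* The LSM readout trains an SVM per grid point per run; at desk scale this
  is minutes, but the cost is linear in grid size × runs × trials.
* Event-driven (exact) simulation is not implemented; 0.1 ms Euler stepping
  bounds spike-time accuracy at the step size.
* Class-probability renderings for the SVM readout use softmax over
  decision values rather than pairwise-coupling probability estimation.
* Deployment to physical neuromorphic hardware is out of scope; the
  constraint emulation covers fan-in, weight sharing/quantization, missing
  delays and parameter mismatch only.
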
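---
title: "Surrogate neural-network models of membrane potential: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate neural-network models of membrane potential: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

voltcast builds fast surrogate models of neuronal voltage dynamics: a
biophysical ground-truth simulator generates membrane-potential responses to
synaptic event trains, windowed datasets turn those traces into a supervised
one-step forecasting problem, a family of neural-network architectures is
trained on them, and the trained surrogates are run closed-loop — alone, with
a spiking Izhikevich head, or embedded in a recurrent microcircuit with
short-term synaptic plasticity. This vignette records the scientific choices
behind each stage: the models, their parameters and units, the numerical
conventions, and the places where the design was genuinely open.

## The ground-truth point neuron

The reference cell is a single 25 x 25 µm cylinder (membrane area
`pi * d * L` ≈ 1963 µm²) with specific capacitance 1 µF/cm², specific
membrane resistance 1 kΩ·cm², axial resistivity 35.4 Ω·cm (used only by the
cable variant) and a resting potential of −70 mV. The active variant adds
the classic squid-axon sodium / delayed-rectifier / leak triplet at
densities gNa = 0.12, gK = 0.036, g_leak = 0.0003 S/cm² with reversal
potentials +50, −77 and −54.3 mV. Synapses are alpha-conductance point
processes, `g(t) = w · ((t−t0)/τ) · exp(1 − (t−t0)/τ)`, peaking at exactly
the quantal amplitude `w` at `t0 + τ`; the reference excitatory synapse has
τ = 2 ms, w = 2.5 nS, E_rev = 0 mV and the inhibitory one τ = 1 ms,
w = 8 nS, E_rev = −90 mV.

Three conventions deserve comment:

* **Unit reading of the densities.** Conductance-density values for this
  model circulate with mutually inconsistent unit strings; voltcast
  uses the canonical simulator values above (S/cm²), which reproduce the
  textbook behavior of the squid conductances, and reads the membrane
  resistance as a specific resistance in kΩ·cm².
* **Resting balance.** The passive leak reversal is not a free parameter:
  `steady_state_init()` sets it so that the complete model (gates at their
  voltage-clamped steady state) rests at exactly `v_rest`. This mirrors the
  customary steady-state initialization of compartmental simulators — the
  model is then integrated event-free for 2 s and required to drift less
  than 0.01 mV over a further second.
* **Integration.** Gates use exponential Euler, the voltage an implicit
  (backward-Euler) update, at an internal step of 25 µs; output is
  decimated to 1 kHz by taking the sample at each integer millisecond.
  Tests verify that halving the internal step moves subthreshold peaks by
  less than 1%, and that the 25-µs EPSP peak agrees with a 1-µs reference
  integration within 0.5%.

### Spike threshold conventions

Two operational definitions of the AP threshold coexist in the package.
`ap_threshold(method = "dvdt")` reports the voltage at the first sample
where dV/dt exceeds a criterion (default 20 mV/ms) before the spike peak —
the convention used for current-clamp recordings with fast rise times. For
quantal conductance sweeps, however, near-rheobase spikes take off directly
from the top of the EPSP: the dV/dt criterion then lands well up the
upstroke (around −48 to −50 mV in this model, regardless of the criterion
value between 6 and 20 mV/ms), which is not what a sweep measures. The
default for sweep summaries is therefore `method = "boundary"`: the peak
depolarization of the largest subthreshold trial, i.e. the voltage
separating sub- from suprathreshold responses. On the reference model this
boundary lies near −57.7 mV.

A related observation, reproduced by the acceptance suite: with the
reference parameters the entire standard 0.1–3.5 nS sweep remains
subthreshold (all 35
trials, amplitude linear in conductance with r ≈ 0.999); the first
suprathreshold quantum appears only when the sweep is continued at the same
increment (at 4.3 nS). The sweep summary therefore extends the grid past
the standard endpoint when the threshold has to be measured. The
amplitude-per-conductance gain of this membrane is ≈ 2.4 mV/nS (confirmed
independently by a closed-form RC convolution oracle in the test suite);
the reference slope value this package targets for the same fit sits one
decade higher, so the acceptance report states the slope per 10 nS.

### NMDA compound synapse

The `nmda` synapse kind multiplies its alpha conductance by a Boltzmann
gate of the instantaneous membrane potential,
`A2 + (A1 − A2)/(1 + exp((x0 − v)/dx))` with A1 = 1, A2 = −1,
x0 = −63.32 mV, dx = 0.013 mV — a near-step gate. The sign in the exponent
is fixed so that the gate *increases* with depolarization (relief of
block); with the signs of the reference formulation taken literally the gate would close on
depolarization and coincidence detection would be impossible. Note the
A2 = −1 floor means the hyperpolarized branch inverts the nominal synaptic
current rather than silencing it; this is kept as specified. The compound
synapse is an AMPA event plus an NMDA event at the same onset.
`simulate_coincidence_protocol()` uses 2 nS per component by default,
calibrated so that the coincident AMPA-only compound stays subthreshold
while NMDA boosting can reach threshold; spiking is confined to a
contiguous inter-stimulus window around coincidence.

### Cable stand-in

`simulate_cable_neuron()` is an unbranched chain of equal cylinders
(optional geometric diameter taper), passive everywhere except the somatic
compartment, which carries the HH channels. It exists to exercise the
per-site (1 + n sites)-channel data format and cable attenuation ordering —
it is explicitly *not* a reconstructed morphology, and no fidelity claims
about detailed dendritic models rest on it. Passive compartments rest at
`v_rest` by construction (their leak reversal is `v_rest`), the soma through
its balanced leak.

## Stimulus generators

All generators are pure functions of their parameters and a seed, with
onsets on the 1-ms grid (matching the 1-kHz channel encoding):

* `random_train()` — uniform onsets, counts split 8:3 between excitatory
  and inhibitory synapses (rounding excess to excitatory), fixed quantal
  sizes 2.5/8 nS.
* `quantal_sweep()` — 0.1–3.5 nS in 0.1-nS increments, one single-event
  train per conductance.
* `paired_pulse_protocols()` — equal-weight pulse trains, ISI 2–10 ms in
  1-ms steps.
* `variable_weight_train()` — normally distributed excitatory weights,
  mean 2.5 nS and variance 0.001 nS² (the reference value "variance 0.001 nS" is
  read as a variance in nS², matching the intended narrow distribution), negative
  draws clipped at zero.
* `ei_grid()` — rate × E/I-ratio × replicate grids (reference ratios 2:1
  and 1:2) feeding the firing-response curve fits.

What these emulate — stationary, uniform-random synaptic bombardment with
fixed or narrowly distributed quantal sizes — is deliberately simpler than
in-vivo-like input: no rate modulation, no spatial structure, no
correlations between synapses. Surrogates trained and validated on these
corpora are validated *for these statistics*; nothing here demonstrates
generalization to structured natural input.

## Windowed datasets and normalization

Each supervised row is a 64-sample (64-ms) history window over an ordered
channel set — `v, exc, inh` and optionally the two ionic currents (3 or 5
channels), or `v` plus one channel per synapse site (e.g. 201) — with the
next sample of the target series as the label. Synaptic channels hold the
quantal conductance (nS) at the onset sample and zero elsewhere. Windows
never cross trace boundaries.

Voltage is mapped affinely to [0, 1] from the fixed physiological bounds
(−90, +40) mV rather than per-trace extrema, so the inverse transform is
model-independent; out-of-bounds samples are clipped and counted. Because
1-kHz sampling truncates AP peaks at random phases, detected spike-peak
samples are replaced by a standardized +40 mV before scaling — two traces
with differently truncated APs then normalize identically. Conductance
channels are scaled by 10 nS, current channels affinely from (−30, 30) nA.

Splits are 80/10/10 by contiguous blocks: overlapping windows make shuffled
splits leak training data into the test set, so block splitting is the
conservative reading of a bare "80-10-10" statement.

The curriculum is the fixed stage order resting → subthreshold →
suprathreshold; at each later stage a replay fraction (default 0.3 — the
mixing is part of the original protocol but its amount is not stated,
so the default is a package choice) of every batch is drawn from earlier
stages to counter catastrophic forgetting. A test bounds the post-curriculum
degradation of stage-1 validation loss.

## The architecture family

`build_surrogate()` reproduces five forecasting stacks: linear (flatten →
64-unit affine → affine head), nonlinear (sigmoid on the 64-unit layer),
deep (nine tanh layers 128…1024…64 with dropout 0.15), a WaveNet-style
stack of 12 causal convolutions (128 filters, kernel 2, dilations 2^0…2^11,
tanh) and the CNN-LSTM (convolutions 128/100/50 with kernels 1/5/1 and
relu/relu/tanh activations under He/He/Glorot-uniform initializers,
flatten, sequence repeat, a 128-unit LSTM returning sequences, four
100-unit SELU layers with dropout 0.15, affine head).

Free-parameter counts are part of the architectural contract. Under the
flatten-first convention with 5 input channels and a 3-unit head the
builders count 20,739 / 20,739 / 2,465,859 / 363,651 / 1,817,869 — the
first four match their reference magnitudes to three significant digits,
which pins down the counting convention; the CNN-LSTM's reference count is
6.8% above the arithmetic of its stated stack, and no natural variant
(kernel order, head width, repeat length) closes that gap, so the
discrepancy is documented rather than fudged. The sequence-repeat length
defaults to 1 (one-step prediction). A `time_distributed = TRUE` variant
replaces the leading flatten by a per-timestep 64-unit map, the smaller
formulation used for point-neuron training.

`build_multi()` is the per-site variant: 201-channel input, convolutions
512/256/128 with an L1 penalty (default 1e-5) on the first layer — the
penalty drives per-synapse filter specialization, which
`extract_first_layer_filters()` quantifies as a 512 × 200 selectivity
matrix — three stacked 128-unit LSTMs, a relu dense layer plus four SELU
layers, and an affine head whose bias can be refit post hoc on the
validation split (`fit_output_bias()`, the simpler of the two bias-correction
options considered).

`attach_nmda_head()` prepends a frozen layer that rescales the NMDA input
channel by the Boltzmann gate of the instantaneous normalized voltage. The
reference layer-space constants (x0 = 1.44, dx = 0.12) belong to the
original study's normalization; `nmda_head_params_from_norm()` derives the
constants consistent with this package's own affine map (x0 ≈ 0.205,
dx = 1e-4), and the tests verify the two gates agree point-wise through the
transform.

All layers, initializers (He/Glorot/LeCun uniform), optimizers and
backpropagation are implemented in the package on plain R matrix
arithmetic; a finite-difference gradient check in the development history
and the oracle-identity tests guard the implementation.

## Training

`training_config()` exposes the reference training protocol: Adam with Nesterov
momentum (default), plain Adam, or Adamax (default for the
multicompartment surrogate); global gradient-norm clipping at 1; MAE is
sufficient for passive traces while MSE is required once APs are present
(to weight the rare spike samples); early stopping on validation loss with
patience 10 (20 for long runs), restoring the best-validation weights.
Hyperparameters without a reference value default to: learning rate 1e-3 (2e-3 for
Adamax), batch size 256. For the linear-surrogate acceptance runs the
package uses lr 3e-3, which converges the (convex) linear fit within ~10⁴
steps; the default stays at the conservative 1e-3.

`partial_retrain()` freezes everything except the fully connected head
(bit-identical weights before/after, enforced by test) — the adaptation
route for biophysical variants such as the ±10 mV delayed-rectifier shift,
where the synaptic feature layers are kept and only the readout adapts.

## Closed-loop prediction

`teacher_forced()` scores one-step accuracy. `autoregressive()` implements
continuous self-reliant prediction: after a 64-ms ground-truth
initialization, the model's own predictions are fed back into the voltage
(and, for multi-output models, current) channels in normalized space, while
the synaptic channels always come from the scheduled event train. Predicted
spike peaks are fed back unmodified (no re-standardization during
feedback). Batched evaluation (`evaluate_closed_loop()`) runs all repeats
as one rolling batch; the standard protocol is 50 repeats × 500 ms.
Contract tests include an injected exact-AR(1) oracle that must be
reproduced to machine precision, a contraction probe whose fixed point is
known in closed form, and a channel-isolation test proving predictions
never leak into event channels.

## The Izhikevich head

The five-parameter layer integrates `v' = 0.04v² + 5v + 140 − u + I`,
`u' = a(bv − u)` with one explicit update per 1-kHz sample scaled by the
free `dt`, cutoff +30, reset `v ← c`, `u ← u + d`. `fit_izhikevich()`
minimizes a composite objective — normalized squared firing-rate error over
current steps plus normalized subthreshold MSE over traces, default weights
1:1 — by Nelder-Mead restarts (default 20) from canonical firing-phenotype
anchors, with `a`, `dt` and an input gain searched in log space. The gain
maps physical drive (nA at 1 kHz) onto the model's current axis and is
fitted because the layer has no canonical unit convention for its
drive.

The fast-spiking teacher (`make_fs_teacher()`) is a design choice — the
original study's teacher parameters are not available. voltcast uses the
active reference cell with a tenfold higher membrane resistance (input
resistance ≈ 92 MΩ, the higher-R_in end of fast-spiking phenotypes) and
measures the f-I curve over 0.05–0.45 nA steps *on top of a weak random
synaptic background*: the deterministic squid-conductance model is a
class-II oscillator whose rate jumps discontinuously at rheobase and
plateaus near 70 Hz, and background noise linearizes the onset into the
graded f-I curve such cells show in vivo (it also gives the simplex a
smooth landscape). Subthreshold fidelity is measured on synaptic-barrage
segments (250 events/s at 0.25/0.75 nS — small-signal regime), with the
1-kHz synaptic current reconstructed from the event train and the recorded
voltage as the layer's drive. As in the original study, the f-I and
subthreshold numbers come from two separate fits of the same layer family
(rate-only and trace-only objectives).

## The recurrent network engine

Cells are interchangeable backends (`izh_backend()` is the desk-scale
reference; a trained CNN-LSTM drops in through the same contract, which a
scripted-backend identity test pins down). Connectivity among 150 cells:
per unordered pair, reciprocal with probability 0.5·p_uni (both edges 1.5×
stronger), otherwise unidirectional with probability p_uni; rows are
presynaptic. Transmission uses the Tsodyks-Markram model with U = 0.38,
D = 365.6 ms, F = 25.71 ms: between spikes u decays (τ = F) and R recovers
(τ = D); on a spike u ← u + U(1−u), release = u·R, R ← R − u·R. The five
contact sites of a connection share the presynaptic train and constants, so
their states are identical by construction and are stored once per edge
with a ×5 delivery multiplier. Delivered conductance
(g_conn × multiplier × contacts × release) enters the postsynaptic
excitatory channel exactly 1 ms after the presynaptic AP peak; a
bookkeeping audit equates total delivered and expected conductance every
run.

The sweep protocol runs 100 ms of pre-stimulus activity, a 50-nS stimulus
at 100 ms (calibrated to recruit the whole population within 10 ms), and
observation to 250 ms. Instability is the pre-stimulus population AP count
(discarding the first 10 ms of settling); immediate response is the number
of cells firing within 10 ms of the stimulus; a run is "stable" when the
instability count is below 5 (reported stability percentages in this literature come
without a criterion, so the threshold is a named config constant).
Excitation scaling multiplies the recurrent quantal size, inhibition
scaling the background inhibitory quantal size. Background rates have no
reference values; defaults (150/56 events/s at 1.5/6 nS) were chosen once so the
reference network sits in the marginal regime where both stable and
oscillatory outcomes occur. Acceptance asserts sign-level trends only:
instability non-decreasing in excitatory drive and decreasing with lowered
recurrent connectivity.

## Problem sizes

The test and acceptance runs use deliberately reduced problem sizes chosen
as the package's own evaluation scale: 3 × 10-s passive training traces
(~30k windows) for the linear surrogate with 50 × 500-ms closed-loop
repeats; 9 × 3 noisy f-I steps of 1 s and 3 × 2-s barrage segments for the
Izhikevich fits; 150-cell, 250-ms networks with a 3 × 2 × 3-run sweep grid.
The full-scale CNN-LSTM trainings (days of GPU time at full scale)
are out of scope for the test suite; the CNN-LSTM path is validated by
parameter counts, gradient-exactness oracles, toy trainings (including the
L1-sparsity comparison) and the closed-loop contracts instead.

## Known limitations

* The cable stand-in is not a morphology; no claim about detailed dendritic
  integration follows from it.
* The NMDA gate's A2 = −1 hyperpolarized branch inverts (rather than
  blocks) the current, as specified.
* The deterministic HH teacher is class II; f-I comparisons are only
  meaningful under the noisy-background protocol described above.
* Network background statistics are package defaults, not reference values;
  only sign-level network trends are asserted.
* Exact bitwise training reproducibility is promised only in
  single-threaded execution (BLAS threading can reorder reductions).
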
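# voltcast

Surrogate neural-network models of neuronal membrane potential.

Detailed biophysical neuron models are accurate but slow: every synaptic
event must be integrated at microsecond resolution through stiff channel
kinetics. voltcast implements the alternative explored by a line of recent
work in computational neuroscience — train a multivariate time-series
forecasting network to *become* the neuron. The package is aimed at
computational neuroscientists who want to (a) generate controlled
ground-truth voltage data from Hodgkin-Huxley point neurons and passive
cable chains, (b) train and dissect forecasting architectures that predict
the next membrane-potential sample from a 64-ms history of voltage and
synaptic input channels, (c) run those surrogates closed-loop as
self-reliant simulators, and (d) assemble them into recurrent cortical
microcircuits with short-term synaptic plasticity for network-level
experiments such as connectivity/excitation parameter sweeps.

## The model in brief

The ground truth is a single compartment (25 x 25 µm, Cm = 1 µF/cm²,
Rm = 1 kΩ·cm², rest −70 mV) with squid-type channels
(gNa = 0.12, gK = 0.036, g_leak = 0.0003 S/cm²; E_Na = +50, E_K = −77,
E_leak = −54.3 mV) driven by alpha-conductance synapses
(g(t) = w·(t/τ)·e^{1−t/τ}; excitatory τ = 2 ms, 2.5 nS, 0 mV; inhibitory
τ = 1 ms, 8 nS, −90 mV), integrated at 25 µs and sampled at 1 kHz.

A surrogate f maps a window of the last 64 samples across C channels
(voltage, excitatory and inhibitory conductance, optionally the two ionic
currents, or one channel per synapse site) to the next sample:

    v[t] = f(v[t−64…t−1], s[t−64…t−1])

Five architectures are provided (linear, nonlinear, deep, dilated-causal
convolutional, CNN-LSTM) plus a 201-channel CNN-LSTM for per-site input, an
NMDA Boltzmann gating layer, and a five-parameter Izhikevich spiking head
(v' = 0.04v² + 5v + 140 − u + I, u' = a(bv − u), reset c/d, trainable step
scale) fitted by multi-start Nelder-Mead. Closed-loop prediction feeds the
model's own output back into its voltage channel while synaptic channels
follow the stimulus schedule. Networks of 150 surrogate cells are wired
with reciprocity-weighted random connectivity and Tsodyks-Markram synapses
(U = 0.38, D = 365.6 ms, F = 25.71 ms; release = u·R per spike, delivered
over 5 contacts with a 1-ms delay).

See `vignettes/surrogate-neurons.Rmd` for the full methods account.

## Worked example

Simulate a passive neuron under random synaptic bombardment, train the
linear surrogate, and score a closed-loop prediction:

```r
library(voltcast)

neuron <- compartment_model(active = FALSE)
events <- lapply(1:3, function(i) random_train(10000, 400, seed = 100 + i))
traces <- lapply(events, function(ev) {
  simulate_point_neuron(neuron, ev, 10000, record_currents = TRUE)
})

ds <- make_windows(traces, events, targets = c("v", "i_na", "i_k")) |>
  split_dataset() |>
  normalize_dataset()

fit <- build_surrogate("linear", input_channels = 5, output_width = 3,
                       seed = 11) |>
  train_surrogate(ds, training_config(loss = "mse", lr = 3e-3,
                                      max_epochs = 150, patience = 20,
                                      seed = 12))

held_ev <- random_train(10000, 400, seed = 999)
held_tr <- simulate_point_neuron(neuron, held_ev, 10000,
                                 record_currents = TRUE)
scores <- evaluate_closed_loop(fit$model, list(held_tr), list(held_ev),
                               n_rep = 50, horizon_ms = 500, seed = 5)
mean(scores$explained_variance)
#> [1] 0.9961862
```

The last number is the mean explained variance (1 − MSE/var) of fifty
500-ms self-reliant predictions on a held-out input stream: the linear
surrogate tracks the passive membrane almost perfectly. The quantal sweep
of the active model is equally compact:

```r
active <- compartment_model()
sweep <- quantal_sweep(0.1, 3.5, 0.1)
traces <- lapply(sweep, function(ev) simulate_point_neuron(active, ev, 100))
iv_summary(traces, as.numeric(names(sweep)), v_rest = -70)
#> <vc_iv_summary> slope 2.431 mV/nS (r = 0.9995, n_sub = 35); AP threshold absent (all subthreshold)
```

i.e. the subthreshold response grows linearly at ~2.4 mV per nS across all
35 quanta; continuing the sweep past 3.5 nS locates the first spike and the
sub/suprathreshold boundary voltage (≈ −57.7 mV), the sweep's operational
AP threshold.

A thin command-line wrapper is included for shell pipelines:

```sh
Rscript inst/cli/voltcast.R --subcommand stimgen --seed 1 --out out/
```

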
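---
title: "Mirrored STDP as an autoencoder: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mirrored STDP as an autoencoder: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mstdpnet)
```

# The problem

Autoencoders learn representations by requiring that feedback through tied
weights reconstructs the input, with weight changes
`ΔW = (x − x̂) yᵀ` (the Oja subspace rule). Two obstacles make a naive
biological reading implausible: the rule needs the *difference* of two
activity patterns, and it needs feedforward and feedback synapses — which
are physically distinct — to change identically. This package implements a
spiking-network resolution of both: the difference arises from the *timing*
of spikes under additive STDP, and the identical changes arise from using
temporally opposed STDP variants at the two pathways.

# Network

Two excitatory populations — `n_vis` visible and `n_hid` hidden
conductance-based LIF neurons — are reciprocally all-to-all connected
(feedforward `W`, feedback `Q`) with no lateral connections. Each layer has
a pool of inhibitory LIF neurons, all-to-all coupled with the layer's
excitatory cells at fixed uniform weights; these weights never learn. A
trial lasts 65 ms: external Poisson input drives the visible layer for the
first 10 ms, and activity then unfolds in three rough bouts — initial
visible (`x`), hidden (`y`), feedback-driven late visible (`x̂`). With the
default parameters hidden units fire near the *end* of the visible bout:
feedforward weights settle at values weak enough that many input spikes
must be integrated before threshold. This is a stable property of the
learning rule itself — a unit that fired early would have many visible
spikes arriving after its spike, and those pairings depress its weights.

## Neuron model

Membrane dynamics follow the Vogels–Abbott family: dimensionless synaptic
conductances (relative to leak) with exponential decay, reversal potentials
0 mV (excitatory) and −80 mV (inhibitory), and a spike-frequency adaptation
conductance incremented at each spike that reverses at the inhibitory
potential. Defaults (`neuron_params()`): τ_m = 20 ms, V_rest = −70 mV,
V_thresh = −54 mV, V_reset = −60 mV, 2 ms refractory, τ_e = 5 ms,
τ_i = 10 ms, adaptation increment 0.02 (0.05 in the bars study
configuration, which sharpens the end of the visible bout), adaptation
τ = 100 ms. Inhibitory neurons use τ_m = 10 ms and no adaptation. Published variants of
this model family differ in their per-population values; the defaults here
are drawn from that family and every one is overridable (`neuron_params()`,
`network_config()`, and the `np_hid` / `np_inh` overrides in
`simulate_trial()`).

External input is delivered as excitatory conductance events
(`w_ext` per input spike); the alternative reading of the input as a
current pulse is not implemented.

# Plasticity

Feedforward synapses follow additive, all-to-all pair-based STDP with
exponential kernels; feedback synapses follow the temporally reversed rule
(aSTDP). Expressed over visible spike times `t_k` and hidden spike times
`t_l`, both reduce to one kernel — potentiation `exp(-|Δt|/τ+)` when the
hidden spike is later, depression `−exp(-|Δt|/τ−)` otherwise — so

- `Δw_ij = η K(S_i, S_j)` and `Δq_ji = ζ K(S_i, S_j)` exactly, per trial;
- starting from `Q = (ζ/η) Wᵀ` the tied relation is preserved forever
  (bit-exactly when ζ/η is a power of two, to ~1e−12 otherwise);
- had feedback used plain STDP instead, each isolated spike pair would
  change `q_ji` with the *opposite* sign of `w_ij` — the wrong symmetry.

Two conventions required a decision. Simultaneous spikes (`t_l = t_k`)
count as depression under STDP and hence potentiation under aSTDP,
following the weak inequality in the rule's definition. And τ+ is paired
with the potentiation branch in *both* rules, which keeps the two plots of
the kernel mirror images of each other; the printed form of the reversed
rule can be read either way, and this reading is the only one consistent
with the mirrored construction.

Updates are accumulated over the trial and applied once at trial end,
then clipped — to `[0, w_max]` in non-negative mode, `[−w_max, w_max]` in
signed mode. The trial is the natural unit because the bout-factor
analysis treats it as one; applying pair updates online would make the
result depend on within-trial ordering.

## The effective rule and its limit

Approximating every pair separation by the mean bout separations Δt1
(visible→hidden) and Δt2 (hidden→late visible) moves the exponentials out
of the sums:

`Δw_ij ≈ η (β x_i − γ x̂_i) y_j`, `β = exp(−Δt1/τ+)`, `γ = exp(−Δt2/τ−)`.

When all spikes of each bout are concentrated at single instants the
approximation is an identity, which the tests exploit: simulated pair sums
match the bout formula to machine precision, and under Gaussian jitter of
the spike times the relative error decreases with the jitter width
(≈ 3.5% at σ = 0.5 ms, ≈ 14% at σ = 2 ms with the default kernel). When
parameters satisfy `γ/β = 1/α` the effective rule is exactly `η β` times
the scaled autoencoder rule `(x − x̂/α) yᵀ`, whose fixed point is the
scaled reconstruction `x̂ = α x`. The package keeps the scaled rule as an
analysis oracle (`scaled_autoencoder_rule()`); training always uses the
spike-pair rule.

`count_bouts()` splits visible spikes at a boundary (by default the end of
the input window) for diagnostics only; plasticity itself is all-pairs and
never consults the boundary.

# Homeostasis

Each hidden unit tracks `A_j`, an exponential moving average
(`ema_decay = 0.01`, an effective window of ~100 trials — a free choice,
long enough to average over the stimulus ensemble) of whether it fired at least once per trial, and after each
trial moves its synaptic offset `φ_j` (additive mode) or scaling factor
`Φ_j` (multiplicative mode, floored at 0) by `κ (ρ − A_j)`. Scaling acts
only on the *feedforward excitation of hidden units*: effective weights
`w̃_ij = w_ij + φ_j` or `w_ij Φ_j` are used in simulation, while plasticity
operates on raw weights. Feedback onto visible units is not scaled; the
reconstruction pathway could plausibly share the scaling, but restricting
it to the visible→hidden efficacy is the conservative choice. The
homeostatic update runs after the plasticity update each trial; at these
rates the order makes no measurable difference. During evaluation both plasticity and
homeostasis are frozen; freezing homeostasis too is again the conservative
reading of "plasticity disabled". An evaluation-only multiplier on `Φ_j`
(`scale_boost`, e.g. 1.5) reproduces the manipulation of raising hidden
excitability at test: on the trained bars network it never decreases any
stimulus's hidden spike count and improves the reconstruction correlation
by a few points.

Defaults: κ = 0.01 (additive, weights live on a ~0.01–0.5 conductance
scale) and κ = 0.5 (multiplicative, factors live near 1); the bars study
uses κ = 0.05 with multiplicative scaling.

# Stimulus pipeline

`preprocess_stimulus()` subtracts a per-pixel dataset mean (row-major
flattening, 0-based semantics internal); `split_on_off()` maps the signed
result to non-negative ON/OFF channels, doubling the dimension — losslessly,
since ON − OFF recovers the signed vector. `contrast_filter()` keeps
patches whose mean ON/OFF rate (equivalently mean |signed value|) reaches
0.06; "at least" is inclusive. The mean of the ON/OFF vector is the only
reading under which that threshold is not vacuous, because the signed
values are nearly zero-mean after preprocessing. `poisson_encode()` draws
one homogeneous Poisson train per visible neuron over the input window,
rate = ON/OFF value × `rate_scale`.

`rate_scale` defaults to 1000 spikes/s per unit value with a 10 ms window,
so a unit-intensity pixel contributes ~10 input spikes — the magnitude of
the initial activity bout. The trial runs 65 ms with a 2 ms synaptic
delay; all activity in practice ends well before 30 ms, matching the
regime the model describes.

# Synthetic data and what the tests show

`make_bars_dataset()` enumerates the `2 × grid` single-bar images (plus
optional two-bar superpositions); `generate_synthetic_stimuli()` adds blob
and stroke ensembles. Bars were chosen because each stimulus is
reconstructable from a sparse hidden code, so the toy set exercises the
same loop — encode, three bouts, mirrored STDP, synaptic scaling — as image
experiments, at desk scale and with known latent structure.

What the bars ensemble does *not* emulate: the statistics of handwritten
digits or whitened natural patches (graded intensities, correlated
structure, a large i.i.d. training stream), or the ~31–62× overcomplete
hidden layers of the full-scale experiments. One consequence is worth
stating plainly. With 16 hidden units for 16 bars, lifetime-sparsity
homeostasis at ρ = 1/16 is satisfied equally well by *duplicated* units —
two units tuned to the same bar each still fire on 1/16 of trials. Nothing
in the rule set penalises duplication (synaptic scaling controls lifetime,
not population, sparseness), so coverage freezes near the
multinomial-capture level (~10 of 16 bars claimed; the specialists that do
form reconstruct their bar at correlation ≈ 0.95). The seeded reference
run therefore reaches a mean test correlation of ≈ 0.49 and bar recovery
of ≈ 0.6–0.75 depending on the stopping point, while the weight-symmetry
correlation rises from ≈ 0 to ≈ 0.87. Passing tests show the mechanism —
loss decreases, weights symmetrize, specialists form — not parity with
overcomplete large-scale runs.

# Numerical choices

- **Integration**: exponential Euler at dt = 0.1 ms, conductances held
  constant within a step — exact for constant drive, standard and stable
  for these time constants. The closed-form LIF f-I curve is matched
  within 1.4% at dt = 0.1; halving dt changes ensemble spike counts by
  under 2%.
- **Delays**: every recurrent spike is delivered exactly one synaptic
  delay (2 ms = 20 steps) after emission via per-step increment buffers;
  external input spikes are delivered in the step containing their
  timestamp. A zero delay is promoted to one step.
- **Refractoriness**: spike times are grid times; a neuron may fire again
  once `t ≥ t_spike + t_ref`, so inter-spike intervals never fall below
  the refractory period.
- **Signed weights**: a negative entry contributes an inhibitory
  conductance of equal magnitude, keeping one connection object per pair.
- **Degenerate correlations**: a Pearson correlation with a constant
  vector (e.g. a test stimulus that evokes no hidden spikes) is undefined;
  such pairs contribute 0 — neutral — to the reconstruction loss and are
  counted in the `n_degenerate` diagnostic.
- **Seeds**: one master seed derives independent substreams for weight
  initialization, presentation order, per-trial encoding, and per-test-image
  encoding, so test inputs are frozen across evaluations and a
  checkpointed run resumes bit-identically (weights are persisted as text
  at 17 significant digits, which round-trips doubles exactly).
- **Runaway guard**: training aborts if a trial's total spike count
  exceeds 20× the median of the first 100 trials — guarding against the
  runaway excitation that non-negative weights invite at low sparsity.

# Problem sizes

The shipped tests and the acceptance script run the 128-visible/16-hidden
bars network for 5,000 presentations (about 90 s), homeostasis-only runs of
5,000 trials at ρ ∈ {0.02, 0.1}, 50-record plasticity-oracle comparisons,
and a 100-trial LIF ensemble — sizes at which every check completes in a
few minutes on one core while still exercising the full mechanism. The
trainer itself has no size limits beyond memory; the full-scale experiment
sizes are supported but are not part of the test suite.

# Known limitations

- Lifetime-sparsity homeostasis cannot enforce population sparseness or
  prevent duplicate receptive fields (see above); a 1×-complete hidden
  layer on bars leaves some stimuli without a dedicated unit.
- Dendritic compartments, conduction-delay heterogeneity, short-term
  synaptic dynamics, and triplet/voltage/multiplicative STDP variants are
  out of scope.
- Image whitening is not performed; patch experiments expect pre-whitened
  inputs.
- The inhibitory pools are a control mechanism, not a model of selective
  inhibition; their weights are uniform and fixed.
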
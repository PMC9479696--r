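---
title: "Surrogate-gradient training of adaptive spiking networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-gradient training of adaptive spiking networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snnet)
```

This vignette is the package's account of the science it implements: the
neuron models and their discretization, the surrogate-gradient training
procedure, the conventions adopted where the literature leaves choices
open, what the synthetic data generator does and does not emulate, and the
package's known limitations.

## From physical neurons to the discrete forward pass

The adaptive leaky integrate-and-fire (adLIF) neuron couples a membrane
potential $u(t)$, relaxing toward rest with time constant $\tau_u$
(order 10 ms) while integrating input current, to a slower adaptation
current $w(t)$ with time constant $\tau_w$ (order 100 ms). Adaptation has
two components: a *subthreshold* coupling $a$ that feeds the potential
back into the recovery current continuously, and a *spike-triggered* jump
$b$ added at each emitted spike. When $u$ reaches the threshold the neuron
spikes and is reset.

`continuous_neuron_model()` holds this physical parameterization;
`continuous_to_discrete()` applies the exponential-integrator step (1 ms
by default) and the change of variables that sends the threshold to 1 and
the reset to 0, yielding the dimensionless per-step form implemented in
`adlif_step()`:

$$u[t] = \alpha\,u[t-1] + (1-\alpha)\,I[t] - w[t-1] - \vartheta\,s[t-1]$$
$$w[t] = \beta\,w[t-1] + (1-\beta)\,a\,u[t-1] + b\,s[t-1]$$
$$s[t] = \mathbb{1}\{u[t] \ge \vartheta\},\qquad \vartheta = 1$$

with $\alpha = e^{-\Delta t/\tau_u}$ and $\beta = e^{-\Delta t/\tau_w}$.
Three conventions matter and are fixed throughout:

* **Previous-step reads.** Both updates read only $t-1$ quantities, in the
  order written above; `run_layer_dynamics()` and the batched network
  forward implement exactly this order, and the test suite pins it to a
  scalar per-step oracle.
* **Soft reset.** Crossing threshold subtracts $\vartheta$ at the next
  step instead of clamping $u$; residual drive above threshold is
  retained. Gradients are allowed to flow through the reset term — the
  backward pass differentiates the full recursion, with no detached
  branches.
* **Resting start.** Every sequence starts from $u = w = s = 0$.

The plain LIF neuron is the special case $a = b = 0$ (`lif_step()`), with
$w \equiv 0$ and $\alpha$ the only neuron parameter. As a comparison
variant, `moving_threshold_step()` implements the alternative adaptation
mechanism in which the threshold itself is dynamic: a trace
$\eta[t] = \rho\,\eta[t-1] + s[t-1]$ raises the effective threshold to
$\vartheta_0 + \gamma\,\eta[t]$ before decaying back. The source
literature describes this mechanism without printing its recursion, so the
exponential-trace form above was adopted — the simplest recursion with the
described behavior — with $\rho$ and $\gamma$ trainable in the same ranges
as $\beta$ and $b$ respectively.

### Heterogeneous, trainable, range-limited neuron parameters

Every neuron owns its own $\alpha, \beta, a, b$ ("trainable and
heterogeneous"), initialized uniformly within ranges chosen from
physiologically plausible time constants at the 1 ms step:

| parameter | range | corresponds to |
|---|---|---|
| $\alpha$ | $[0.60, 0.96]$ | $\tau_u \approx 2$–$25$ ms |
| $\beta$  | $[0.96, 0.99]$ | $\tau_w \approx 25$–$100$ ms |
| $a$      | $[-1, 1]$      | subthreshold coupling strength |
| $b$      | $[0, 2]$       | spike-triggered jump size |

Range enforcement during training is a hard projection
(`clamp_neuron_params()`) after every Adam step rather than a smooth
reparameterization — the simplest mechanism that keeps every parameter
inside its closed interval at all times, and one the tests can verify
exactly. Whether the readout's integrator constant should be trainable is
not settled in the literature; here it is trainable like the hidden
$\alpha$s, clamped to the same range.

## Surrogate gradients

The forward pass keeps the exact Heaviside comparison; only the backward
pass substitutes a finite pseudo-derivative (`surrogate_grad()`,
`spike_function()`). The default is the boxcar,

$$\frac{\partial s}{\partial u} =
\begin{cases}0.5 & |u - \vartheta| \le 0.5\\ 0 & \text{otherwise,}\end{cases}$$

boundary inclusive. Its appeal is cost (a comparison) and a hard
cutoff that silences gradients from neurons far from threshold. Three
alternatives ship with standard parameterizations — sigmoid derivative
(slope 10), Gaussian (sd 0.5), piecewise linear (half-width 1) — their
exact shapes being conventions rather than published constants. Because R
has no automatic differentiation, the whole backward pass
(backpropagation through time across layers, recurrence, batch norm,
dropout and the four readouts) is written analytically in the package; it
is validated against central finite differences on the smooth baseline
models and against an independent scalar-loop BPTT reference on the
spiking models.

## Network, regularization and readout

A network maps an $(N, T, F)$ batch to $(N, C)$ class scores through
hidden layers and a readout (`network_config()`, `build_network()`,
`snn_forward()`). The stimulus of layer $l$ is
$I^l[t] = W^{l\top} x^l[t] + V^{l\top} s^l[t-1] + b^l$: feedforward from
the current step, recurrence from the previous step, with $\mathrm{diag}(V) = 0$
enforced at build time and after every update (`zero_diagonal()`) so that
a spike cannot re-excite its own neuron against refractoriness.
Conventions adopted where the literature states only *that* a technique is
used:

* **Batch normalization** is applied to the feedforward drive $W^\top x$
  with statistics pooled over batch and time, before the recurrent term
  and bias are added — normalizing the recurrent pathway would let batch
  statistics interfere with the spiking feedback loop. It carries no
  trainable gain/shift: the bias and the neuron parameters already provide
  those degrees of freedom, and this keeps the parameter accounting
  identical to the published per-layer contributions. Running means and
  variances (momentum 0.1) serve evaluation.
* **Dropout** ($p = 0.1$) is applied to each hidden layer's output
  activity; the recurrent feedback reads the post-dropout spikes, so one
  mask per (step, neuron) serves both consumers. Inverted scaling keeps
  the expected drive constant; evaluation is deterministic.
* **Readout**: non-spiking leaky integrators with no recurrence. Four
  schemes are implemented (`readout_scores()`): spike count (the readout
  then runs as a spiking layer), last potential, maximal potential, and
  the default cumulative softmax $o_i = \sum_t
  \mathrm{softmax}(u_i[t])$, whose per-example scores sum exactly to $T$.
* **Baselines**: MLP, RNN, one-gate light-gated unit and GRU share the
  stimulus formula with real-valued activities (sigmoid by default).
  Recurrent baselines apply the cumulative softmax at the penultimate
  layer followed by a linear map; non-recurrent ones accumulate the final
  linear outputs over time. Per gate they carry their own feedforward,
  recurrent and bias blocks, hence exactly 2x (light unit) and 3x (GRU)
  the per-layer cost of an RNN.

## Training recipe

`train()` runs minibatch Adam (default $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$) on the cross-entropy of the
readout scores, with full-sequence BPTT (no truncation, no gradient
clipping — none proved necessary at the scales studied). Initial learning
rates: 0.01 for binary spike-raster inputs, 0.001 conventional for
real-valued features. A plateau scheduler multiplies the rate by 0.7 after
10 consecutive epochs without validation-accuracy improvement. After every
step: neuron parameters are clamped, recurrent diagonals re-zeroed, and
sparsity masks re-applied so pruned weights stay exactly zero. Datasets
without an official validation split get a seeded, label-stratified 5%
hold-out (`split_train_valid()`). Epoch count (100) and batch size (128)
are package defaults, not published constants. Inference picks the
highest-activity readout neuron, ties broken deterministically toward the
lowest class index. Degenerate cases are defined, not accidental: zero
epochs return the model untouched; a non-finite potential or loss aborts
with the layer and step named.

## Sparsification and energy accounting

`count_parameters()` reproduces the per-layer accounting: feedforward
$N^{l-1} N^l$, recurrent $N^l N^l$ (the structurally zero diagonal is
included, following the published counting rule), biases $N^l$, neuron
parameters $N^l$ (LIF), $4N^l$ (adLIF) or $3N^l$ (moving threshold), and
readout feedforward + bias + one $\alpha$ per class. It is tested to equal
exhaustive enumeration of every built model's trainable scalars.

Random pruning (`sparsity_config()`, `make_sparsity_masks()`) removes a
proportion $p$ of connections either from the first layer's feedforward
matrix or from all hidden layers' feedforward and recurrent matrices. The
retained count is exact — $\mathrm{round}((1-p)E)$ ones drawn uniformly
over the $E$ maskable entries of the whole scope, not per-tensor — the
one simple rule consistent with every published sparse total
(per-tensor rounding provably disagrees on the 95% all-hidden sweep).
Whether those totals came from exact-cardinality or Bernoulli masks was
not stated; exact cardinality is adopted because it reproduces them
deterministically. Readout weights, biases and neuron parameters are
never masked.

`energy_report()` implements the synaptic-operation model: a dense
recurrent layer costs $N^l(N^{l-1} + N^l + 1)$ MACs per step; binary
spikes reduce this to $\bar\nu\,N^l(N^{l-1} + N^l + 1)$ ACs at firing
rate $\bar\nu$, and each AC costs 0.1 pJ against 3.2 pJ per MAC (45 nm
CMOS figures). At $\bar\nu = 0.1$ the two factors give the 10x sparsity
and 32x per-operation gains whose product is the 320x headline ratio —
an algebraic identity independent of layer sizes, which the tests check
over random architectures. Neuron-state updates, which scale only with
$N^l$, are reported separately and excluded from the ratio. Firing rates
are reported per time step ($\bar\nu \in [0,1]$,
`firing_stats()`); mapping them to Hz requires fixing the physical step
duration, which binned event data does not itself determine, so no Hz
conversion is built in.

## Data interfaces

Event datasets (spike times in seconds, channel indices, integer labels —
the 700-channel convention of cochlear-encoded speech corpora) are read
and written as a plain-text JSON container with the same logical grouping
as the published HDF5 layout (`read_event_file()`,
`write_event_file()`); readers validate shapes and name any missing key.
`bin_events()` maps an event at time $t$ to bin
$\lfloor t/\mathrm{dur}\cdot T\rfloor$, clipping endpoint events into the
last bin, and binarizes by default ("sparse binary tensor" convention)
while conserving counts when binarization is off. `wav_to_filterbank()`
provides the standard log-mel front-end (40 filters, 25 ms Hamming
window, 10 ms hop, pre-emphasis 0.97, floor $10^{-10}$ — conventional
values, stated here because they are conventions), and
`poisson_encode()` turns non-negative rate features into Bernoulli spike
rasters with probability $\min(1, \mathrm{gain}\cdot\mathrm{rate})$ per
cell.

## The synthetic task: what it emulates, and what it does not

`synth_spike_task()` generates the event-like benchmark the tests train
on. Each class is a fixed random template of anchor events on a
700-channel x 100-step grid; an example is its class template with
per-event Gaussian temporal jitter (sd 2 steps, rounded, clipped to the
grid) plus background spikes at rate 0.005 per cell. Two design choices
deserve emphasis:

* **Shared channel pools.** By default all classes place their events on
  one common set of channels and differ only in *when* those channels
  fire. This puts class identity into spatiotemporal structure — the
  property that separates event-based recognition from static pattern
  matching — and makes the baseline comparison meaningful: a per-step
  model whose scores are accumulated over time is permutation-invariant
  across steps and therefore nearly blind to these classes, while the
  neuron dynamics of an SNN can exploit them. With
  `shared_channels = FALSE` the task degrades gracefully into one that
  channel-marginal statistics can solve.
* **Split sizes.** Defaults are 100/20/20 examples per class
  (train/valid/test), a roughly four-fold scaled-down echo of the
  per-class abundance of the real event-based speech corpora; at these
  sizes a 2x64 adLIF network trains in a few minutes on one CPU.

The generator is fully seeded and bit-reproducible, and its noiseless
limit is exact (every example equals its template). What it does *not*
emulate: the strong channel correlations and tonotopic ordering of a
cochlear model, speaker variability, utterance-length variation (all
sequences share one duration), and class-imbalanced corpora. Passing the
learning tests therefore demonstrates that the training machinery works
on timing-coded data at realistic sparsity — not that any particular
accuracy will transfer to a specific real corpus.
`synth_feature_task()` is the real-valued analog (smooth spectro-temporal
bumps plus white noise) for the filterbank pathway.

## Numerical choices and degenerate inputs

Collected here so none is implicit: boxcar boundary inclusive; weights
initialized uniform $\pm 1/\sqrt{\mathrm{fan\text{-}in}}$, biases zero;
batch-norm epsilon $10^{-5}$, variance floored at zero before the square
root; softmax and log-sum-exp max-shifted for stability; argmax ties to
the lowest index; empty sequences, inverted ranges, out-of-range labels,
negative rates and non-square recurrent matrices rejected with
contract errors; events exactly at the utterance end clipped into the
last bin; jittered template events clipped to the grid; an all-zero
input through a zero-bias network yields exactly uniform cumulative-
softmax scores $T/C$.

## Scales used by the test suite

The suite exercises full-size parameter accounting (up to the 3x1024
recurrent architecture) but trains only desk-scale models: the
learning-capability test uses the generator defaults above with a 2x64
adLIF network and a same-shape MLP for 30 epochs each (a few minutes on
one CPU); unit tests train 2-16 unit models for a handful of epochs.
These sizes are the package's chosen trade-off between statistical
meaningfulness and a test suite that runs everywhere.

## Known limitations

* CPU-only, dense linear algebra through R's BLAS; no GPU path and no
  sparse-matrix exploitation of spike sparsity at compute time (sparsity
  is accounted, not exploited).
* The hand-written backward covers the shipped building blocks;
  arbitrary user-defined layers would need their own adjoints.
* Event files use the package's JSON container; binary HDF5 corpora must
  be converted externally before loading.
* The quadratic (Izhikevich) and exponential (AdEx) adaptive neurons,
  tandem ANN-SNN learning, probabilistic units and firing-rate
  regularizers are out of scope.
* Checkpoints are R serializations (`saveRDS()`), not portable across
  frameworks.
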
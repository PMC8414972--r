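---
title: "Latency-coded spiking autoencoders: model, training scheme, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latency-coded spiking autoencoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikelat)
```

## The neuron model

Every neuron in `spikelat` fires at most once, and all information is
carried by *when* it fires. An input spike at time $t_i$ with weight $w_i$
contributes an α-function post-synaptic kernel, so the membrane potential
before the neuron's own spike is

$$V(t) = \sum_{i:\, t_i \le t} w_i\,(t - t_i)\, e^{\tau (t_i - t)},$$

with a decay rate $\tau$ and threshold $\theta$ shared across the network
(`model_params()`). The kernel rises from zero at the input's onset, peaks
$1/\tau$ later, and decays — a shape chosen for its resemblance to measured
post-synaptic potentials. With the causal sums
$A = \sum_i w_i e^{\tau t_i}$ and $B = \sum_i w_i e^{\tau t_i} t_i$, the
earliest crossing of $\theta$ solves in closed form through the principal
branch of the Lambert W function:

$$t_{out} = \frac{B}{A} - \frac{1}{\tau}
  W_0\!\left(-\frac{\tau\theta}{A} e^{\tau B/A}\right).$$

The principal branch gives the *ascending* crossing (the secondary branch
is the descending one, which is not a spike). No solution exists when the
drive never reaches the threshold: either $A \le 0$ (no net positive drive)
or the Lambert argument falls below $-1/e$.

`simulate_neuron()` implements the event-based semantics around this
formula: inputs are processed in ascending time order, the candidate
crossing is recomputed after each input, and a candidate is only *valid* if
it falls between the current input and the next one — a later input can
delay or abolish a predicted spike, but never precedes one that has already
happened. Simultaneous inputs are folded into one event so their order is
irrelevant, and a candidate landing exactly on the next input's time is
accepted (the new input cannot act before the crossing). An input arriving
exactly at $t_{out}$ is excluded from the causal set — consistent with the
gradient rule below, which gives such inputs no derivative.

## Exact gradients

Differentiating the closed form gives, for each causal input $j$,

$$\frac{\partial t_{out}}{\partial t_j}
  = \frac{w_j e^{\tau t_j}\big(\tau(t_j - B/A) + W + 1\big)}{A\,(1+W)},
  \qquad
\frac{\partial t_{out}}{\partial w_j}
  = \frac{e^{\tau t_j}\big(t_j - B/A + W/\tau\big)}{A\,(1+W)},$$

where $W$ is the Lambert value cached at the solution. Three properties
anchor the test suite: the input-time partials of any spiking neuron sum to
exactly 1 (shift every input by $\Delta$ and the spike shifts by $\Delta$);
non-causal inputs get exactly zero; and both partials diverge as
$1 + W \to 0$, which happens when the potential grazes the threshold
tangentially. The divergence is why training clips every partial to
$[-c, +c]$ at evaluation time (per-partial, not on the accumulated
gradient, because that is where the blow-up lives). When
$|1+W| < 10^{-6}$ we substitute the clipped sign of the numerator.

## Numerical choices

* **Time-frame shifting.** $e^{\tau t}$ overflows for large latencies, so
  all causal sums are computed with times shifted to the latest input of
  the train ($t_i \leftarrow t_i - t_{ref}$, exponents all $\le 0$); exact
  translation equivariance of the model makes the shift lossless. The
  solution and its cached $A, B, t_{ref}$ stay in that frame so the
  gradient formulas reuse them consistently.
* **Lambert W.** Evaluated by a vectorised Halley iteration (branch-point
  series seed near $-1/e$, log seed elsewhere, relative tolerance
  $10^{-14}$); arguments within $10^{-12}$ below $-1/e$ are clamped to the
  branch point and treated as tangency. Vectorisation matters: one training
  epoch evaluates $W_0$ tens of thousands of times, and the layer-level
  solver batches all (event, neuron) candidates of a layer into a single
  call.
* **Candidate validity** uses a $10^{-9}$ absolute tolerance on the lower
  edge of the window, absorbing rounding when a crossing lands on an event
  time.

## Architecture and training

The autoencoder is an input–hidden–output stack (`autoencoder_spec()`),
hidden layer smaller than the pixel count, output the same size. Each
non-input layer additionally receives $p$ *synchronisation pulses*: shared
auxiliary inputs whose spike times are learnable, with ordinary learnable
weights per neuron. Pulses start evenly spread over the encoding interval
(endpoints included for $p \ge 2$, midpoint for $p = 1$) and their times
are clamped non-negative after every update, since spike times are
non-negative by definition. The learnable-parameter count of an
$i\!-\!h\!-\!o$ network is $(i{+}p)h + (h{+}p)o + 2p$.

Weights initialise from a *shifted Glorot* scheme:
$\sigma = \sqrt{2/(\mathrm{fan}_{in} + \mathrm{fan}_{out})}$ and mean
$\mu = m\sigma$ with separate multipliers $m$ for regular and pulse
connections. Pulses count toward $\mathrm{fan}_{in}$ — they enter the same
weighted sum. Strongly negative regular multipliers seed the inhibitory
regime that trained networks end up in anyway (see below).

Training minimises the latency-targeted squared error
$\sum_i (\tilde t_i - t_i - l)^2$: the output neuron of a pixel spiking at
$t_i$ should fire at $t_i + l$. The printed operand order of the loss in
the source literature transposes the two spike times; we implement the
orientation that makes the stated target $\tilde t = t + l$ the minimiser.
Input pixels that emit no spike carry no information, so their output terms
are excluded from the loss — forcing their outputs toward an arbitrary time
would contradict the encoding. An output neuron that fails to spike enters
the loss through a surrogate spike time, by default $l + 2$ (twice the
encoding interval past the latest target): a "large value" on the scale of
the problem, large enough to hurt, bounded enough not to destabilise the
squared loss. Its adjoint does not flow through spike-time derivatives
(there is no spike to differentiate); instead *any* silent non-input neuron
receives a constant $-\text{penalty}$ on each incoming weight derivative,
pushing its weights up until it fires again.

Optimisation is Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$ — conventional values, unstated in the source
material) with separate learning rates for weights and pulse times, and
per-batch gradients averaged (not summed) over examples so that the
learning rate keeps its meaning across batch sizes. The two bundled
operating points (`train_config()`, `train_config_l16()`) are tuned
short-latency ($l = 1$) and long-latency ($l = 16$) hyperparameter sets:
decay/threshold, pulse count, initialisation multipliers, batch size,
derivative clip, no-spike penalty and the two learning rates.

## Encoding, decoding, noise

Pixels map to spike times in $[0,1]$; encoded value 1 means "no
information" and becomes the `NO_SPIKE` sentinel (`Inf`, so it orders after
every real spike). Bright-stroke data (raw MNIST-style IDX files, readable
via `read_idx()`) is inverted first ($v \mapsto 1 - v$) so salient pixels
spike early; the package's own synthetic images are generated ink-on-white
and are already in that convention. Decoding inverts the target map:
$\hat v = \mathrm{clamp}(\tilde t - l, 0, 1)$, silence decoding to the
no-information value.

Denoising corrupts each encoded value as
$t \mapsto \max(0, \min(t + \eta r, 1))$ with $r \sim N(1, 1)$ drawn
independently per pixel. Centring the noise at 1 pushes corruption toward
the uninformative end: white pixels stay white almost surely, while
occasional negative excursions create spurious early spikes. White pixels
are represented as the value 1 before noising so that the same rule acts on
every pixel; whether the original work noised non-spiking pixels at all is
not stated, so this is a declared choice, not inferred intent. Training
pairs noisy inputs with clean targets.

## The synthetic fixture generator

`generate_fixtures()` emulates the statistics that matter at desk scale:
mostly-empty images with a centred salient stroke covering roughly 19% of
the pixels (mirroring the ~150 informative pixels of a 784-pixel
handwritten digit), graded brightness, and per-image ±1-pixel jitter over a
handful of distinct stroke classes (bars, cross, ring, diagonal). Stroke
thickness scales with the image side so the salient fraction is stable
across sizes. What it does **not** emulate: digit-like shape variety,
correlated stroke deformation, and within-class diversity beyond jitter and
brightness noise. Passing fixture-scale tests therefore demonstrates the
*mechanics* (encoding, event-based forward pass, exact-gradient training,
denoising, inhibition analysis) — not reconstruction quality on real
handwritten-digit data.

Default experiments use 8×8 images, 64 examples, hidden sizes 2–4
(mirroring full-scale embedding ratios of ~5–20% of informative pixels),
50 training epochs, and the $l = 1$ hyperparameter column with batch 3.
These sizes keep every training-based test in the seconds-to-minutes range
on one CPU.

## Long-latency training and the role of inhibition

Reconstructing at a large target latency forces the network to hold
information in membrane potentials long after the inputs arrive. Trained
networks solve this with *negative evidence accumulation*: regular
connections become inhibitory on average in both layers, while pulses
become strongly excitatory and drift toward late times, acting as triggers
that release the stored (inhibition-shaped) state at the right moment. The
package reproduces this signature at fixture scale
(`weight_distribution()`, `spike_distribution()`), with hidden-layer spikes
staying early relative to the delayed outputs.

One scaling subtlety: the long-latency operating point pairs a small weight
learning rate with very long training in its original setting, and its
strongly inhibitory initialisation relies on the no-spike penalty to revive
silent neurons — a process whose duration is measured in optimiser steps,
not epochs. Fixture-scale long-latency runs therefore use the
fixture-scale batch size (3) and 300 epochs, preserving the step count
(~6×10³) that the recovery dynamic needs; with the original batch size at
64 images the hidden layer never recovers and the network degenerates to a
pulse-driven constant decoder.

## Known limitations

* Single spike per neuron, feedforward only; no membrane reset dynamics,
  recurrence, or convolutional weight sharing.
* The capacity trend (reconstruction error falling with embedding size) is
  a full-scale phenomenon; the fixture task's learnable structure fits in a
  2-dimensional embedding, so at desk scale embedding sizes 2 and 4 perform
  equivalently and the trend is not expected to reproduce.
* Near-tangency instances (potential grazing the threshold) have formally
  unbounded derivatives; clipping makes training robust to them but the
  individual partials are not meaningful there.
* The t-SNE / SVM analyses of embedding quality are external: the package
  exports embeddings (`embed_dataset()`, CLI `embed`) but does not bundle
  those analyses.
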
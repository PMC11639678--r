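---
title: "Contrastive signal-dependent plasticity: model, calibration, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive signal-dependent plasticity: model, calibration, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The circuit

`csdp` simulates a stack of $L$ leaky integrate-and-fire (LIF) layers
that is *recurrent in time rather than in wiring*: at every integration
step, layer $\ell$ reads only the **previous step's** spike vectors of
layer $\ell-1$ (bottom-up, through $W^\ell$), layer $\ell+1$ (top-down,
through $V^\ell$), itself (lateral inhibition through a hollow
$M^\ell$), and optionally a clamped one-hot class spike vector (through
$B^\ell$). Because no layer waits on any other layer's *current* output,
all layers step in parallel and the trajectory is invariant to the order
in which layers are evaluated — a contract the test suite checks
bit-exactly. Within a layer the update order is fixed: current →
voltage → spike/reset → threshold → trace.

Assumptions inherited from this design: spikes are binary and
synchronous on a grid of width $\Delta t$; the resting potential is 0
and reset is instantaneous (no refractory period); the spiking
nonlinearity is a strict threshold comparison, so exact threshold
equality does not spike; synaptic efficacies are bounded
($W,V,B,G,A \in [-1,1]$, lateral $M \in [0,1]$) and clipped back after
every optimizer step.

Sensory input arrives as Bernoulli spike trains: each pixel intensity in
$[0,1]$ is the per-step spike probability of one input channel. Labels,
when used, are clamped deterministically: the class channel emits 1 at
every step.

## The plasticity rule

Each neuron keeps an activation trace
$z \leftarrow z + (\Delta t/\tau_{tr})(-z + \gamma s)$, a calcium-like
low-pass filter of its spikes. A layer's *goodness probability* is
$p = \sigma\!\big(\sum_k z_k^2 - \theta_z\big)$, its probability that
the current input is in-distribution. Training minimizes the logistic
contrastive loss $C(z, y_{type})$, pushing $p$ up for real samples
($y_{type}=1$) and down for synthesized negatives ($y_{type}=0$). The
per-neuron modulator is the exact derivative
$\delta_i = \partial C/\partial z_i = 2 z_i (p - y_{type})$ — pinned in
the tests against central finite differences — and every afferent
bundle's update is a modulated Hebbian product of $\delta$ (or the
current postsynaptic spike, for the decay term) with the *previous*
step's presynaptic spikes. At the first step of a window there is no
presynaptic history; zero vectors are used, so only the decay term can
be non-zero there.

**Sign convention.** Update tensors are *gradients*: they are handed to
a minimizing Adam step ($\eta = 0.002$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$), applied at **every
integration step** within the stimulus window (online adaptation).
Flipping the sign of the update tensors silently inverts learning.

**Batch reductions.** Synaptic updates are averaged over the combined
positive+negative minibatch, which keeps the decay factor
$\lambda_d$'s effective scale independent of batch size. The scalar
homeostatic thresholds use the batch-*mean* spike count in their
increment for the same reason.

## Negative samples

Exactly one negative is synthesized per positive and appended to the
minibatch (doubling it), tagged $y_{type}=0$:

* **supervised** — the image is copied unchanged and paired with a class
  drawn uniformly from the incorrect ones;
* **unsupervised** — a distinct batch partner is rotated by an angle
  drawn uniformly from $(\pi/4,\, 7\pi/4)$ and mixed in,
  $x^- = \eta x + (1-\eta) r$, with $\eta = 0.55$, clipped to $[0,1]$.

Rotation semantics are a genuinely open choice; this package uses
inverse-mapped bilinear resampling about the image center with zero
fill, isolated in `rotate_bilinear()` so alternatives can be swapped in.
Rotated images stay graded and are re-encoded by the ordinary Bernoulli
sampler, not re-binarized.

## Task heads

The **generative head** gives each layer a bundle $G^\ell$ that predicts
the spikes of the layer below with the same LIF dynamics (leaky voltage,
strict threshold, gated reset), trained by the error-driven Hebbian rule
$\Delta G^\ell = R_E\, e^{\ell-1} (s^\ell)^\top$ with
$e = s_\mu - s \in \{-1,0,1\}$. Reconstructions average a *clipped*
trace of the bottom predictor's spikes over the window; the clip to
$[0,1]$ is essential, since the printed recurrence otherwise grows
without bound for a persistently spiking unit. Predictor **thresholds
are fixed** at `v_thr_init` rather than homeostatic: the
spikes-minus-one homeostat is a sparsity prior for representational
layers, but a predictor must match its target layer's activity level —
the bottom predictor's target is the image itself, with tens of active
pixels, and because the homeostat rises $\sim\!50\times$ faster than it
decays at that activity level it acts as a ratchet that suppresses
reconstruction entirely at desk scale.

The **classifier head** is a $C$-unit LIF group driven by all hidden
layers through bundles $A^\ell$, with its own printed homeostatic
threshold update, trained by $\Delta A^\ell = R_E(\mu_y - s_y)(s^\ell)^\top$.
Its softmax over accumulated spike counts is the fast class posterior;
the slow alternative (`goodness_scan_classify()`) clamps each candidate
class in turn and picks the one maximizing time-averaged total goodness.
Both heads train on **positive samples only**: negatives carry
deliberately wrong labels (teaching $A$ the inverse mapping) and
confabulated images (teaching $G$ to reproduce them). Even in
unsupervised mode the classifier synapses see the true labels — the
class error signal affects only them, never the circuit.

At evaluation time plasticity is off, the class input is not clamped,
and **all adaptive thresholds are frozen** at their trained values.
Freezing matters beyond hygiene: the homeostat's batch-mean increment
would otherwise couple test samples, making predictions depend on
evaluation batch composition, and evaluating would mutate the model.

## Parameters, units, defaults

| parameter | meaning | default | notes |
| --- | --- | --- | --- |
| `dt` | integration step (ms) | 3 | reference operating point |
| `tau_m` | membrane time constant (ms) | 30 | a free constant of the model; 10 steps of leak |
| `tau_tr` | trace time constant (ms) | 3 | equal to `dt`, so the trace degenerates to `gamma * s`; configurable for slower traces |
| `gamma` | trace increment | 0.05 | see calibration below |
| `theta_z` | goodness threshold | 10 | scalar or per-layer; see calibration below |
| `lambda_v` | homeostasis rate | 0.001 | threshold drift per (spike − 1) |
| `lambda_d` | synaptic decay factor | 5e-5 | second term of the update rules |
| `R_E`, `R_I` | resistances | 1, 1 | not pinned; desk-scale recipe lowers `R_I` |
| `T_ms` | stimulus window (ms) | 90 | reference range 90–150; lower bound chosen for speed |
| `v_thr_init` | initial thresholds | 1 | not pinned; thresholds persist across patterns |
| `eta` (Adam) | step size | 0.002 | reference value |

## Calibrating goodness at desk scale

The trace's fixed point under sustained spiking is $\gamma$, so a
layer's goodness sum is bounded by $J\gamma^2$ and each spike moves the
sigmoid argument by at most $\gamma^2$. The reference constants
($\gamma = 0.05$, $\theta_z = 10$) put the crossing point at
$\theta_z/\gamma^2 = 4000$ persistently active neurons — sensible for
layers of thousands of units, but for desk-scale layers of tens of
units the probability would sit pinned at $\sigma(-\theta_z)$ with a
vanishing gradient. Meanwhile the homeostat drives every layer toward
roughly one spike per step regardless of width. `calibrate_goodness()`
therefore places the threshold at the *operating point*,
$\theta_z = k\,\gamma^2$ with a target of $k = 1$ spike, and the
desk-scale recipe uses $\gamma = 1$ so a single spike moves the sigmoid
argument by 1.

The second desk-scale adjustment is $R_I = 0.25$. With full-strength
random lateral weights ($M \sim U(0,1)$ summed over tens of neighbours)
the winner-take-all competition is so sharp that layer activity cannot
express the graded positive/negative differences the contrastive loss
needs; quartering the inhibitory resistance softens the competition.
Both adjustments were selected by pilot runs on the synthetic task (the
usual development-set procedure for these hyperparameters) and then
frozen; the reference defaults remain the package defaults.

```{r}
cfg <- calibrate_goodness(
  csdp_config(c(144, 64, 32), n_classes = 2, gamma = 1, R_I = 0.25,
              T_ms = 90))
```

## The synthetic data generator

`make_synthetic_dataset()` emulates the statistical shape of the
MNIST-family inputs the model targets: per-class binary templates
(procedural glyphs — bars, diagonals, crosses, box, disc, X, T, L,
checker — defined for any side ≥ 4 and any class count) with
independent per-pixel flip noise, normalized intensities in $[0,1]$,
integer labels, and write-through to the IDX byte format so the real
reader is exercised end to end. It reproduces: Bernoulli-encodable
graded/binary pixels, class-conditional structure, label noise through
pixel flips, and exact determinism under a seed. It does **not**
reproduce: stroke-level within-class variability (every sample shares
one template), class overlap/ambiguity, spatial correlation of noise,
or dataset scale. Tests passing on this generator therefore demonstrate
that the learning dynamics behave as designed — contrastive separation,
readout accuracy, reconstruction improvement — not that the model
reaches any particular accuracy on handwritten-character data.

Study conditions are fixed once and reused by the tests and the
acceptance script: 2 classes, 12×12 pixels, flip noise 0.05, 100
patterns per class, network 144–64–32, $T = 90$ ms ($\Delta t = 3$ ms,
30 steps), minibatch 20, ≤ 10 epochs, Adam $\eta = 0.002$. These sizes
keep a full supervised-plus-unsupervised acceptance run under a minute
on one CPU while leaving every phenomenon of interest measurable.

## Numerical choices

* Strict spike inequality: `v_hat > v_thr`; exact equality does not
  spike. Thresholds are clipped at 0.
* The goodness probability is computed with a numerically safe sigmoid
  and clamped to the open interval (0, 1) at double precision; the
  contrastive loss is evaluated in softplus form, so neither branch can
  overflow or take `log(0)`.
* Argmax ties (classification, accuracy) resolve to the lowest class
  index.
* `tau_tr = dt` makes the trace exactly `gamma * s`; the closed form is
  tested, and slower traces are available by raising `tau_tr`.
* Reconstruction traces are hard-clipped to $[0,1]$ every step, with
  the spike increment applied outside the decay factor, exactly as the
  recurrence is printed (the two readings coincide at
  `tau_tr = dt`).
* Checkpoints use R's native serialization (version 3, uncompressed) —
  an array-container round trip that is byte-stable, so determinism can
  be checked by file hash. No HDF5 dependency is required.
* RNG streams derive from `(seed, epoch, batch)` through a small
  integer hash kept below $2^{31}$, so batch-level work could be
  reordered or parallelized without changing results.

## Limitations

* Synapses are signed and may change sign during learning, violating
  Dale's law; a nonnegative reformulation with explicit inhibitory
  units is out of scope here, as are refractory periods, per-neuron
  adaptive thresholds, self-excitation, and Izhikevich-style dynamics.
* The per-layer goodness threshold must be calibrated to layer width
  and activity (see above); no single `theta_z` works across scales.
* Negative synthesis assumes image-like inputs (rotation mixing); other
  modalities need their own negative generators.
* The trainer is a single-threaded reference implementation: the
  layer-parallel contract is verified logically (order invariance), not
  exploited for speed. MNIST-scale runs work but are slow in plain R;
  the package's purpose is correctness and auditability at study scale.
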
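---
title: "Dropout in an engram-like network: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dropout in an engram-like network: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Deep brain stimulation (DBS) can both disrupt and enhance memory, sometimes
from the same stimulation target. One candidate explanation treats a memory
as an engram — a subset of neurons and synapses recruited at encoding — and
stimulation as the transient silencing ("dropout") of engram nodes. This
package operationalizes that hypothesis in a small convolutional classifier
of handwritten glyphs: the 100-unit fully connected layer stands in for the
engram, and dropout applied to that layer models stimulation. When the
silencing happens during learning, it should act like stimulation applied
around encoding (enhancement via a more robust, redundant engram); when it
happens only at recall, it should act like stimulation during
consolidation/retrieval (disruption). A transfer-learning protocol — reusing
a trained network on a new glyph inventory after replacing its output head —
models a novel memory task following chronic stimulation.

The package's claims are deliberately *qualitative orderings* of learning
curves, not numeric endpoints: the original observations are curve families
whose exact values depend on unstated optimizer details, so the reproducible
content is which conditions end up above or below which.

## The model

The classifier is fixed throughout:

* input `28 x 28 x 1` glyph image, pixels in `[0, 1]`;
* convolution, 32 filters of `3 x 3`, valid (no padding) → `26 x 26 x 32`;
* `2 x 2` max pooling, stride 2 → `13 x 13 x 32`;
* convolution, 64 filters of `3 x 3` → `11 x 11 x 64`;
* `2 x 2` max pooling → `5 x 5 x 64` (the odd trailing row/column is
  dropped by floor division; this is what takes 11 to 5);
* global max pooling → 64 latent features;
* fully connected layer of 100 units — the engram layer, the only dropout
  target;
* linear output head with one unit per class.

ReLU is the activation of the hidden layers. The output layer cannot be a
ReLU if its scores are to be probabilities, so the output activation belongs
to the loss: the default scores each class with an independent sigmoid
against a one-hot target and takes the *mean binary cross-entropy over
classes* (the literal reading of "binary cross-entropy" for a multi-class
one-hot target); a softmax/categorical cross-entropy variant is available
via `loss_spec("softmax")` for sensitivity analysis. Predicted class is
always the argmax. Probabilities are clipped to
`[clip_epsilon, 1 - clip_epsilon]` (default `1e-7`) so the loss is finite at
saturated outputs; the gradient of a clipped coordinate is zero, which keeps
analytic gradients consistent with finite differences of the actually
computed loss.

Training is plain stochastic gradient descent: batches of 10, 500 epochs at
the original scale, learning rate 0.01, seeded reshuffling each epoch.
Optimizer, learning rate, and initialization are not stated in the source
material; plain SGD with fan-in-scaled uniform weights
(`U(-sqrt(6/fan_in), sqrt(6/fan_in))`, zero biases) is the simplest
defensible choice, and the orderings the package tests are robust to it by
design. All of this is configurable in `engram_net()`.

### The dropout operator

`dropout_policy(phase, rate)` controls the manipulation. Masks are Bernoulli
keep/drop vectors over the 100 fully connected units, one fresh mask per
optimization or evaluation step (per-sample masks are available via
`per_sample = TRUE`). Kept units are rescaled by `1/(1 - rate)` (inverted
dropout), so the operator preserves the expected activation; rescaling can
be disabled for sensitivity analysis, and the disruption effect does not
depend on it. Three phases:

* `none` — the operator is the identity and the engine is mask-free;
* `train` — masks during training only; evaluation is standard inference
  (the usual use of dropout as a regularizer, and the model of stimulation
  around learning);
* `test` — training is dropout-free; masks are applied just prior to each
  evaluation batch (the model of stimulation during recall).

Dropout is applied to the fully connected layer only — not to the output
layer, where masking class scores would conflate classification with the
manipulation, and not to the convolutional layers, which play the role of
sensory cortex rather than the engram region.

Dropout RNG, data-shuffling RNG, and initialization RNG are independent
seeded streams derived from one master seed, so conditions sharing a seed
see identical data order and initial weights and differ *only* in the
masks.

## Synthetic data

Experiments run on synthetic EMNIST-like glyphs so that nothing needs to be
downloaded: 36 classes (digits 0–9, uppercase A–Z), each a fixed stroke
skeleton (polylines and elliptical arcs) rasterized onto the 28×28 grid.
Intra-class variability emulates handwriting variation with a random affine
jitter (rotation ±12°, translation ±1.8 px, isotropic scale ±12%), a
sampled stroke width (1.8–3.2 px), Gaussian blur (σ = 0.6 px), and additive
clipped pixel noise (σ = 0.05). These defaults were chosen once as a
plausible stand-in for natural variability: enough that nearest-centroid
classification is imperfect and the network has something to learn, little
enough that the task is learnable to high accuracy within tens of epochs.
`generate_dataset()` is a pure function of `(classes, n, params, seed)`;
train/test disjointness is by seed separation, not sample tracking —
distinct seeds give independently sampled jitters, which for a continuous
jitter distribution almost surely never collide.

What the generator does *not* emulate: real stroke topology variation
(cursive forms, alternate glyph shapes), correlated writer styles, label
noise, and the merged upper/lower-case classes of the real 47-class
inventory. Passing tests therefore show that the dropout phenomenology holds
on a learnable 28×28 glyph task of matched geometry — not that effect sizes
match the real dataset. For work on the real data, `load_idx()` reads the
standard IDX containers (optionally gzipped) and applies the dataset
family's transposed storage orientation by default.

## The experiments

Three seeded, multi-replicate harnesses emit per-epoch records (mean
training loss, test accuracy, test loss) per condition:

1. **Placement** (`run_experiment1`): `control`, `dropout-train-50`,
   `dropout-test-50` on digits. Expected orderings: test-phase dropout
   collapses accuracy (operationalized as less than half the control mean);
   train-phase dropout does not harm it (within 0.02 of control).
2. **Rate sweep** (`run_experiment2`): baseline 0% plus 20/40/60/80%
   train-phase dropout. Expected: 80% underperforms baseline and shows the
   highest mean training loss at every epoch after the fifth; at least one
   moderate rate matches or beats baseline.
3. **Transfer** (`run_experiment3`): networks pretrained on digits with and
   without 50% train dropout are transferred to 26 uppercase letters by
   stripping and re-initializing the output head (`transfer_network()`; all
   layers stay trainable), against a scratch baseline. Expected: both
   transfers beat scratch; the dropout-pretrained transfer beats the
   control transfer on accuracy and on training/test loss.

Design choices where the design was genuinely open:

* The source material reports single curves per condition; the package
  defaults to replicate seeds (3) and reports means with percentile
  bootstrap intervals, because single-run orderings are noise-sensitive. A
  single-replicate, original-size mode is `experiment_config(...,
  study_scale = TRUE, n_replicates = 1)`.
* Whether transferred networks keep dropout during letter retraining is
  genuinely open. The package retrains both transfers identically without
  dropout (`retrain_dropout = FALSE`), so the comparison isolates what the
  chronically stimulated network carries over — the quality of its
  transferred "skeleton" features. The alternative reading, in which each
  transfer continues its source policy, is available via
  `retrain_dropout = TRUE`; note that continued 50% dropout slows 26-class
  convergence so strongly that at scaled horizons it dominates any feature
  effect.
* The scratch baseline trains without dropout: its purpose is isolating the
  effect of transfer, not of dropout.
* The rate sweep gets an explicit 0% condition so "higher/lower than
  baseline" is anchored in-run rather than across experiments.
* Evaluation under test-phase dropout draws one mask per evaluation batch,
  reading "dropped at each step" as optimization/evaluation steps.

### Problem sizes

The original study trains for 500 epochs on 1,000/1,000 digits and
5,000/1,000 letters. The package's default scaled sizes are chosen on one
criterion: every condition must train to (near-)convergence, because the
orderings above are statements about converged networks — train-phase
dropout slows early learning, so at a mid-convergence horizon it looks
harmful rather than helpful. On the synthetic task, digit networks plateau
(test accuracy ≈ 0.99) after roughly 3,500 SGD updates. The defaults are:
experiment 1, 75 epochs on 500/300 digits; experiment 2, 75 epochs on
450/250 digits (five conditions); experiment 3, a 75-epoch pretraining on
500 digits followed by 75 epochs on 520/260 letters; 3 replicate seeds,
which keeps the full suite in the tens of minutes on one CPU. The original
sizes remain available via `study_scale = TRUE`.

## Numerical choices

* **Gradient verification.** `gradient_check()` compares every analytic
  gradient with central finite differences (step `1e-5`) on reduced
  networks; the worst relative error `|a - f| / max(|a| + |f|, 1e-8)` is
  required to be below `1e-4` and lands around `1e-8` in practice.
* **Pooling ties and odd edges.** Max pooling breaks ties toward the first
  element in column-major order and drops trailing rows/columns of odd
  dimensions; both are fixed conventions so the backward routing is
  deterministic.
* **Degenerate inputs.** A rate of 1 is rejected (it would zero the engram
  layer and make the inverted scaling undefined); `n_classes < 2`, kernels
  larger than their input, and non-finite training losses raise errors
  rather than propagate.
* **Reproducibility.** Every stochastic component (init, shuffle, train
  masks, test masks, data generation, bootstrap) is seeded through
  independent streams; identical configurations produce byte-identical
  result CSVs.

## Known limitations

The engram metaphor is structural, not biophysical: no stimulation
parameters (frequency, current, anatomy) are modeled, and nothing here
speaks to synaptogenesis or plasticity mechanisms. The synthetic glyphs are
a geometric stand-in for handwriting, and they are *easier* than real
handwriting in one consequential way: the control network reaches test
accuracy ≈ 1.0 with test loss equal to training loss, i.e. the task has
essentially no generalization gap at these sizes. Dropout's benefits are
regularization benefits — they appear where an unregularized network
overfits. Consequently the disruption effect (test-phase dropout) and the
high-rate cost (80% dropout) reproduce robustly here, and train-phase
dropout matches control at convergence, but the *advantage* of
dropout-pretraining for transfer is not expected to reproduce on this
generator and should be studied on the real dataset via `load_idx()`.
Orderings near ties can additionally be seed-sensitive — which is why the
package reports replicate means with bootstrap intervals rather than
single curves.
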
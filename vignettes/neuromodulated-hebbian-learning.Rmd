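---
title: "Neuromodulated Hebbian learning: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuromodulated Hebbian learning: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific model implemented by `neurohebb`,
the reasoning behind its tunable parameters and numerical choices, what the
synthetic data generator does and does not emulate, and the package's known
limitations.

## The model

The network has three layers. An image `ỹ` (length `D`, pixel values
0–255) is normalized to input activations

$$y_d = (A - D)\,\frac{\tilde y_d}{\sum_{d'} \tilde y_{d'}} + 1,$$

so that every activation is at least 1, the total is exactly `A`, and the
code is invariant to multiplicative contrast changes — a stand-in for fast
feed-forward inhibition in sensory cortex. `A > D` is required; the package
parameterizes `A = D + 116`, holding the contrast budget `A − D` constant
across image sizes.

Representation neurons integrate through a linearised logarithm,
$S(w) = w$ for $w < 1$ and $\log w + 1$ otherwise, $I_c = \sum_d S(W_{cd})
y_d$, and compete through a temperature-controlled softmax
$s_c = \exp(I_c/\tau)/\sum_{c'} \exp(I_{c'}/\tau)$ modeling global lateral
inhibition. The log transfer keeps integration close to the log-likelihood
of a mixture model while remaining non-negative; the linear branch keeps
small weights well defined.

Learning is online and local:

$$\Delta W_{cd} = \epsilon \cdot M \cdot s_c\,(y_d - W_{cd}),$$

one update per stimulus, no minibatching. The scalar modulator `M` is the
single point where the neuromodulators act: `M = 1` is plain Hebbian
density estimation; an acetylcholine-like signal scales `M` by attentional
demand; a dopamine-like signal sets `M` from the reward-prediction-error
scenario and may be negative, pushing active weights away from the current
input. A row equal to `y` is a fixed point, so converged rows are
activation-weighted means of the inputs they win.

The classifier head stores `B`, the per-class running mean of `s` over all
labeled examples seen, refreshed every 100 images, and decodes
$t_k \propto \sum_c B_{kc} s_c / \sum_{k'} B_{k'c}$. Classification is the
argmax of `t`; classification confidence is $\kappa = \max_k t_k$.

**ACh.** Release follows
$\mathrm{ACh} = \alpha / (1 + \exp(\beta(\bar\kappa_{\hat m}/\bar\kappa - 1)))$,
where $\bar\kappa_{\hat m}$ is the mean confidence of the *inferred* class
of the current stimulus and $\bar\kappa$ the global mean. Low relative
confidence (a demanding stimulus) yields high release. Because the inferred
class is used, release needs no environmental feedback. A stimulus-wise
variant substitutes the stimulus' own $\kappa$; it weights individual
outliers more heavily and is provided as `mode = "stimulus_wise"`.

**DA.** Gaussian noise of variance $\upsilon$ added to `I` occasionally
flips the decision; such trials are explorative (reward not predicted).
Reward is delivered when the emitted decision matches the label. The four
scenarios release the four constants $\delta_{\pm/\pm}$. The Hebbian term
uses the *noisy* activations — the ones that produced the emitted, rewarded
decision — because credit should go to the units that made the choice; the
noiseless activations are available behind a flag for ablation. Unlabeled
stimuli provide no reward, hence no representation update (a plain-Hebbian
fallback is available behind `unlabeled_hebbian`); `full_reinforcement`
models the cheap-reward regime where rewards exist for all stimuli while
the classifier sees only the labeled subset.

**Critical period.** All protocols first pre-train by plain Hebbian
learning until the moving average of test accuracy over 5 classifier
refreshes improves by less than 0.2 percentage points relative to the
preceding window (or a maximum epoch budget is reached). This models the
developmental critical period after which representations are stable and
neuromodulators drive the remaining plasticity.

## Parameters, defaults, and why

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `A` | `D + 116` | total input activation; the contrast budget above the per-pixel baseline of 1. |
| `C` | 49 (`network_config`), 16 (`hebbnet`) | representation size. 49 suits full-scale digit data; the fitting wrapper and the bundled benchmarks use small scale. |
| `ε` | 0.01 (`network_config`), 0.05 (`hebbnet`) | Hebbian learning rate. The small value suits long full-scale runs; the small-scale value converges within the benchmark budgets (contraction factor `(1 − ε s_c)` per presentation). |
| `τ` | 1 | softmax temperature; 1 is strong competition, larger values flatten the code (see the sparseness sweep). |
| `υ` | 2 | exploration-noise variance, chosen so that a pre-trained benchmark network explores on roughly 5% of trials — enough explorative trials to learn from without degrading the emitted decisions. |
| `α, β` | 10, 10 | ACh scale and steepness. With confidence ratios spanning roughly 0.8–1.2 on the benchmarks, this gives demanding classes several-fold larger updates than easy ones. |
| `δ−/+, δ+/−, δ+/+, δ−/−` | +0.5, −0.25, +0.02, 0 | DA release profile, set by a coarse grid search maximizing benchmark accuracy — the same procedure that defines these constants in the first place. The qualitative shape (positive surprise ≫ 0 > disappointed prediction; correctly predicted outcomes near zero) is the scientific content; the small positive `δ+/+` keeps a trickle of density estimation running on correct trials, which stabilizes learning when competition is not sharply winner-take-all. |
| `weight_floor` | 1e-8 | clamp after each update. Negative DA can push weights below zero where the log transfer is undefined; clamping preserves the transfer's domain with minimal distortion. |
| refresh schedule | 100 images | classifier weights and confidence statistics refresh cadence. |
| EMA decay | 0.99 per refresh | confidence statistics track the evolving network; the long memory reflects that per-class confidence estimates need many refreshes to stabilize. |

`B` is a cumulative running mean over all labeled examples, the literal
reading of its defining average; no windowing or forgetting is applied.

## The synthetic data generator

`synthetic_spec()` / `generate_synthetic_digits()` produce image datasets
emulating the statistical structure of centred hand-written-digit data:

* each class is a compact intensity blob with a fixed per-pixel texture,
  confined to its own cell of the image grid (disjoint support across
  classes at `prototype_overlap = 0`);
* `prototype_overlap` blends every prototype with one shared prototype
  (identical classes at 1);
* i.i.d. Gaussian pixel noise and optional integer translation jitter give
  within-class variability; draws are clipped to [0, 255] and all-zero
  images are redrawn;
* an optional `hard_pair` rebuilds one class as a blob adjacent to another
  class's blob at a centre offset proportional to `1 − mix` — two
  neighboring density modes, the image analogue of two adjacent tone
  frequencies, and the source of graded class difficulty;
* prototypes are deterministic functions of `(seed, class)`, so fixtures
  are bit-reproducible across machines.

The bundled study conditions (`synthetic_benchmark()`) are frozen at:
10×10 images, 5 classes, overlap 0.2, pixel noise SD 35, no jitter
(digit datasets are centred and size-normalized; jitter remains available
and tested), hard pair (3,4) at mix 0.82, 1000 training / 400 test images.
The imbalanced benchmark subsamples to a 60:1 ratio favoring classes 0–1
and keeps the test set balanced. The release-schedule experiments use
`C = 10` (about two units per class, so representation capacity is a real
constraint, as it is at full scale) and 8-epoch post-plateau phases; the
δ-grid experiment runs its DA phase at ε = 0.01 because release values of
magnitude 1 at the small-scale rate are destructive for every cell, which
would mask the profile's shape.

What the generator does **not** emulate: stroke-like correlated structure,
within-class style variation (slant, thickness), heavy-tailed pixel noise,
and graded similarity among *all* classes — only the designated hard pair
is confusable. Passing benchmarks therefore demonstrate the mechanisms —
redistribution of units by demand (ACh), tuning sharpening by reward
prediction errors (DA), representation expansion under pairing — not
full-scale accuracy figures. Full-scale runs require the IDX readers and a
user-supplied digit dataset.

## Numerical and design choices

* Softmax and posteriors are computed with max-subtraction; argmax ties
  break toward the lowest index, making every decision deterministic.
* Presentation order is a seeded shuffle per epoch; all stochastic steps
  flow from one seed, so runs are bit-reproducible.
* Updates clamp at `weight_floor` rather than renormalizing, preserving
  the update rule's form.
* A weight row initialization on the converged scale (uniform band scaled
  so rows sum to ≈ `A`) puts the dynamics in their basin without biasing
  any unit.
* `preferred_class()` offers a frequency-weighted variant
  (`argmax_k N_k B_{kc}`): on strongly imbalanced data the unweighted
  argmax of the per-class *average* response misassigns units that win a
  tiny class's few examples while mostly serving a common class. The
  imbalanced-data experiments use the weighted count; uniform-data
  experiments use the plain definition.
* `selectivity()` excludes units whose preferred-class mean response does
  not exceed `1/C` (the uniform-code level): a unit that never wins
  retains its initialization and its pseudo-tuning is noise. The floor is
  an argument; 0 recovers the literal definition.
* Confidence–accuracy curves bin κ in units of posterior probability
  (default bin width 0.02) on `[1/K, 1]`.
* Statistical comparisons across seeds use Welch's t-test at α = 0.01
  (`grid_search` reports cells not significantly different from the best).

## Known limitations

* Desk-scale dynamics are not a quantitative stand-in for full-scale
  results; accuracies, correlations and selectivities reproduce the
  *qualitative* phenomena under the frozen benchmark conditions.
* At flat competition (τ ≳ 1.25 under the benchmark conditions) the
  modulators' leverage shrinks: confidence ratios compress toward 1
  (weakening ACh's differential) and negative DA updates spread across
  many units. The sparseness sweep covers τ ∈ [0.5, 1.25], within which
  the improvements persist; beyond it the Hebbian control and the
  modulated networks converge to similar flat-code performance.
* Exploration's benefit over greedy DA is modest at small scale; it grows
  with task difficulty and representation size.
* The modulators are per-stimulus scalars: no receptor-level, phasic/tonic
  or spatially heterogeneous release dynamics, no spiking dynamics, and no
  back-propagation baselines.
* The classifier head uses explicit label averaging; a fully Hebbian
  classifier layer is out of scope.
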
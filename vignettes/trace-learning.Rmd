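---
title: "Trace learning and invariant object recognition in a hierarchical competitive network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trace learning and invariant object recognition in a hierarchical competitive network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visnet)
```

## The model

`visnet` implements a desk-scale model of the primate ventral visual
stream: a feedforward hierarchy of four competitive Layers (capital-L
"Layer" denotes a network stage corresponding to a cortical area, V2
through anterior inferior temporal cortex). The model addresses one
computational question: how can neurons learn to respond to an *object*
rather than to a particular image, when every transform of the object —
shifted, deformed, or seen from a catastrophically different view —
produces a different pattern on the retina?

The answer explored here is *slow learning*: exploiting the statistics
under which objects are experienced. Transforms of one object occur close
together in **time** (you rotate a cup, you do not teleport between
different cups frame by frame), and successive transforms usually overlap
in **space** on the retina. Two unsupervised mechanisms use these
statistics:

* the **short-term-memory trace rule**, which associates the current
  input with a decaying memory of recent postsynaptic activity, so that
  images seen close together in time converge onto the same neurons; and
* **continuous spatial transformation (CT) learning**, in which a purely
  associative rule suffices because successive transforms share active
  input elements and therefore re-activate (and re-train) the same
  winners; temporal order is then irrelevant, and objects can even be
  interleaved.

### Architecture

Each Layer is a grid of neurons (32 x 32 by default). A neuron receives a
fixed number of afferents from the preceding stage, sampled from a 2D
Gaussian centred on its topologically mapped position; the Gaussian scale
is `radius / 1.4895`, which places ~67% of the connection probability mass
within the stated fan-in radius. The default stack is:

| Layer | neurons | afferents | radius |
|------:|--------:|----------:|-------:|
| 4     | 32 x 32 | 200       | 12     |
| 3     | 32 x 32 | 200       | 12     |
| 2     | 32 x 32 | 200       | 12     |
| 1     | 32 x 32 | 272       | 15     |
| input | 64 x 64 x 32 |      |        |

Receptive fields grow stage by stage so that any single Layer-4 neuron can
be traced back to the entire retina (`receptive_field_positions()`
verifies this). The input is a V1-like code: a rectified Gabor bank with 4
spatial frequencies (octave steps from 0.25 cycles/pixel), 4 orientations
and 2 signs — 32 channels. Layer-1 afferents are allocated across
frequency bands in proportion to frequency, the remainder going to the
highest band, since high-frequency channels carry more independent samples
per unit area.

The retina defaults to 64 x 64 (a 256 x 256 variant is available via
`experiment_config(retina = 256)`); Layer sizes, fan-in counts and radii
are kept at their standard values so the convergence geometry is
preserved.

### Activation and competition

A neuron's activation is the inner product of its weights with the
presynaptic rates on its afferents. Competition within a Layer is
implemented by threshold setting: rates are `max(h - t, 0)` (optionally
squashed by a sigmoid), with `t` found by bisection so that the population
sparseness

\[ a = \frac{(\sum_i y_i / n)^2}{\sum_i y_i^2 / n} \]

equals the configured target within 1e-3 (default `a = 0.01`; for binary
rates `a` is simply the active fraction). Only the most strongly activated
neurons remain above threshold. Rates are rescaled to a maximum of 1,
which leaves `a` unchanged (the measure is scale-invariant) and keeps
drive comparable across Layers.

### Learning rules

All plasticity is local. With presynaptic rates \(x_j\), postsynaptic rate
\(y\), and the exponential trace
\(\bar y^\tau = (1-\eta)\,y^\tau + \eta\,\bar y^{\tau-1}\):

* **hebbian** — \(\delta w_j = \alpha\, y\, x_j\). Used in Layer 1, where
  feature combinations must be bound in their correct relative spatial
  positions (a T, an L and a + are made of the same strokes) *before* any
  invariance learning starts above.
* **trace** — \(\delta w_j = \alpha\, \bar y\, x_j\). Used in Layers 2-4.
* **trace_error** — \(\delta w_j = \alpha\,(\bar y - y)\, x_j\), a local
  error-correcting variant (increments may be negative; weights are
  clipped at zero).

After every presentation each neuron's weight vector is renormalised to
unit L2 length, the standard stabilisation for competitive learning.

**Trace timing.** A discrete implementation must choose whether the trace
driving the update at step \(\tau\) includes the current rate
(\(\bar y^\tau\), option `trace_timing = "post"`) or only past activity
(\(\bar y^{\tau-1}\), option `"pre"`, the default). The difference
matters. Writing the per-epoch drive of a neuron as a mixture over the
transforms of an object, the "post" trace gives each view's own winners a
self-reinforcement term of weight \(1-\eta\) on top of the cross-view
terms \((1-\eta)\eta^{\mathrm{lag}}\); at \(\eta = 0.8\) the own:cross
ratio is roughly 2:1, so each view keeps its own winners and invariance
remains graded and partial. With the "pre" trace the self term vanishes
(the update associates the current input *only* with past activity), the
drive is symmetric across the views that share a training sequence, and
the views of an object genuinely merge onto common neurons. Only the
"pre" variant reproduces all-or-none view-invariant cells in the
catastrophic-view experiment below; the same ranking of these two rule
variants is well established in the trace-learning literature. With
\(\eta = 0\) both timings reduce to pure associative learning on the
current rate, preserving the identity between `trace` with `eta = 0` and
`hebbian`.

The trace is reset between objects by default (`trace_reset =
"per-object"`), so nothing links the last view of one object to the first
view of the next.

## Training protocols

`train_network()` trains the stack in ascending order (staged); while
Layer *k* learns, Layers below are frozen. Because they are frozen, their
responses to each stimulus are computed once and cached; this is exactly
equivalent to recomputing the forward pass at every presentation (the
`mode = "recompute"` option exists and the test suite asserts the
equivalence) but dominates the runtime saving.

Presentation order carries the statistics that the learning rules exploit:

* `object-grouped-permuted` — all transforms of one object in random
  order, then the next object, trace reset at the boundary. This is the
  temporal-continuity regime.
* `spatially-ordered-fine-step` — transforms visited in
  transform-parameter order, objects interleaved at each step. This is the
  CT regime (`ct_train()` forces the associative rule and adds a
  `step_size` for coarse-step controls).
* `fully-interleaved` — a global random permutation; a control that
  destroys both statistics.

Default epochs are 50 for Layer 1 and 100 for Layers 2-4 with constant
per-Layer learning rates (0.1 by default); weight renormalisation bounds
growth, so no annealing is used. The experiment presets use fewer epochs
(5 for Layer 1, 50-60 above): with a handful of training images Layer-1
competitive learning converges almost immediately, and longer Layer-1
training at these tiny stimulus counts makes its feature neurons drift
toward mixtures of whole training images, which degrades the separation
the upper Layers depend on. (At realistic image counts this is not a
concern, and the package default keeps the conventional 50.)

## Synthetic stimulus generators

The experiments of interest are defined by their presentation
*statistics*, not by particular photographs, so the package generates
parameter-controlled stand-ins:

* `render_translated()` — a shape stamped at a list of pixel offsets
  (`translation_grid(25, 16)` is the named preset grid).
* `render_square_edge_combinations()` — the 13 stimuli made of the four
  edges of a square (4 singles, 4 adjacent pairs, 4 adjacent triples, the
  square), or all 15 nonempty subsets; the feature-binding probe.
* `render_feature_conjunctions()` — T, L and + from identical strokes.
* `render_catastrophic_views()` — objects whose "views" are mutually
  uncorrelated block glyphs. Every view is decorrelated against **every**
  other view in the set (|pixel correlation| <= 0.1, enforced on the full
  rendered images), because identity is supposed to be defined *solely*
  by the view-to-object assignment: any residual image similarity — also
  across objects — is a confound for what is being tested. Glyphs carry a
  fixed number of ON blocks (equal contrast energy per view, as renders
  of real objects would have) and cover most of the canvas, since a large
  shared blank border would inflate all pairwise correlations toward the
  ceiling.
* `render_deforming_object()` — identity x deformation grids: oriented
  stripe textures warped by a horizontal sinusoidal displacement field
  whose amplitude is the "wind force"; stripe periods exceed twice the
  maximum amplitude so pixel distance grows monotonically with level.
* `render_curvature_objects()` — elongated shafts with concave, straight
  or convex edge profiles at several metric levels and tilts, cropped top
  and bottom; the non-accidental-property set.
* `composite_on_background()` and `occlude()` — clutter and partial
  occlusion operators that leave labels untouched.

What these generators do **not** emulate: photometric variation
(lighting, shading), 3D perspective, scale changes, or natural image
statistics. A passing experiment therefore shows that the *mechanism*
extracts the intended statistic; it does not certify performance on
natural images.

## Evaluation

`decode_percent_correct()` reports object decoding from a Layer's rates
with a nearest-class-mean decoder on cosine similarity — about the
simplest biologically plausible readout, and deterministic given a seed
(ties are broken uniformly at random). The invariance measure is
`leave-transforms-out`: class means are fit with one transform held out,
cycled so every transform is tested exactly once. Resubstitution
(`all-transforms`) is kept as a diagnostic of raw discriminability.
Chance is 100/n_objects.

Two single-neuron measures accompany it: `invariant_cell_count()` (neurons
above threshold for every transform of exactly one object and none of any
other; threshold defaults to half the maximum rate) and
`single_cell_information()`, a plug-in mutual information between object
identity and the binned rate (equipopulated bins, default 4, no bias
correction — adequate at these stimulus counts, biased upward at much
larger ones).

## The experiments

Each preset of `run_experiment()` reproduces one training-statistics
regime at desk scale (runtimes are for the default 64-px retina, one CPU):

* **cups** (catastrophic views): 2 objects x 4 mutually uncorrelated
  views, object-grouped trace training. Layer-4 leave-one-view-out
  decoding reaches 100% and view-invariant cells emerge ("responds to
  every view of one object and to no view of the other"), while an
  identically trained pure-Hebbian control stays at chance — image
  similarity cannot solve this task, temporal grouping can. Unit-level
  (invariant-cell) convergence is the deepest attractor of the merging
  dynamics and does not form on every random instantiation under global
  competition (see Limitations); population-level invariance (the 100%
  decoding) is the robust signature. ~15 s per training run.
* **translation**: several glyph objects on a coarse position grid,
  trace training; leave-positions-out decoding well above chance and
  above the Hebbian control.
* **ct**: a fine-step position continuum trained with the *associative*
  rule, objects interleaved — above-chance held-out decoding driven
  purely by spatial overlap; a coarse-step control whose consecutive
  transforms share no active inputs stays at chance.
* **binding**: the 13 edge combinations (plus T/L/+) are mutually
  discriminable at Layer 4 — relative spatial position survives the
  hierarchy even for subset/superset stimuli.
* **deformation**: on an identity x level grid, grouping presentations by
  identity builds deformation-invariant identity coding; grouping the
  *same images* by level reverses the inequality. Only the temporal
  statistics differ.

## Numerical choices

* Gabor kernels are even (cosine) phase, zero-mean to machine precision,
  truncated at ±2.4 sigma (odd extent). The envelope follows a 1.5-octave
  bandwidth, `sigma = 0.3924 / f`; at the default retina the lowest
  frequency then yields a 63-px kernel, the largest that fits a 64-px
  image. Each kernel is normalised to unit energy so the four frequency
  bands drive Layer 1 comparably.
* Convolution is FFT-based with replicate (edge) padding, so a uniform
  image produces exactly zero output everywhere including the borders.
* The response volume per image is contrast-normalised to unit L2 norm
  (configurable off), keeping input drive comparable across stimuli so
  the threshold search is stable.
* The sparseness threshold is found by bisection on `t` (60 iterations or
  |a - target| <= 5e-4); the objective is evaluated on the final rates,
  so the invariant holds for the sigmoid option too. Unreachable targets
  (e.g. all activations equal) raise a competition-failure error naming
  the Layer and stimulus.
* Connectivity sampling is without replacement (fan-in counts are exact);
  out-of-grid draws are redrawn, which renormalises the truncated
  Gaussian at Layer borders. Truncation at borders slightly raises the
  within-radius fraction (~71% on a 32 x 32 grid vs 67% unbounded) —
  measured, not corrected, since the radius contract is about the
  unbounded distribution.
* All randomness flows from one experiment seed through fixed integer
  derivations (per-Layer, per-epoch), so runs are bit-reproducible.

## Limitations

* Competition is global within a Layer (one threshold per stimulus). The
  biological circuit — and richer implementations — use *local* lateral
  inhibition, which lets a merging neuron displace only its neighbours.
  With global competition the final step of view merging (one neuron
  winning for every view) is seed-dependent in the catastrophic-view
  setting; the package reports it honestly via `invariant_cell_count()`.
* The decoder is a stand-in: reported percent-correct figures depend on
  the readout choice, and no claim of equivalence with any particular
  published decoding pipeline is made.
* Desk scale: 8-64 training images, 64-px retina. Capacity questions
  (many objects, many transforms) are out of scope.
* The information estimator is plug-in, without bias correction.
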
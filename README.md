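# visnet

Hierarchical competitive networks with trace learning for invariant
visual object recognition, at desk scale, in R.

## The problem

A neuron in the anterior inferior temporal cortex can respond to an
object across retinal positions, deformations, and even views that share
no low-level image features. No supervised signal tells the visual system
which images belong to which object, so the invariance must be learned
from the statistics of natural viewing: transforms of one object occur
close together in time and usually overlap on the retina.

`visnet` implements the standard model of this process for researchers
and students of the ventral visual stream: a four-Layer feedforward
hierarchy of competitive networks over a V1-like Gabor input, trained by
local rules only. Layer 1 uses pure Hebbian learning to bind features in
their correct relative positions; Layers 2–4 use the short-term-memory
**trace rule**

    dw_j = alpha * ybar * x_j,      ybar_t = (1 - eta) y_t + eta ybar_{t-1}

so that images presented close together in time are associated onto the
same postsynaptic neurons (an error-correcting variant
`dw_j = alpha (ybar - y) x_j` is included). Competition within each Layer
sets the activation threshold so the population sparseness
`a = (sum y / n)^2 / (sum y^2 / n)` hits a configured target (default
0.01). The package also implements **continuous spatial transformation
(CT) learning** — invariance from spatial overlap alone, with a purely
associative rule and interleaved objects — plus synthetic stimulus
generators, training protocols, and decoding-based evaluation for the
classic experiments: translation invariance, feature binding (the 13
edge-combinations of a square; T/L/+), catastrophic view changes,
deformation-vs-identity grouping, curvature classes, clutter and
occlusion, and an optic-flow input variant for object-based global
motion.

## A worked example: catastrophic view changes

Two objects, four views each; the views are mutually uncorrelated block
glyphs, so nothing but the temporal grouping during training can link the
views of an object:

```r
library(visnet)

stim <- render_catastrophic_views(n_objects = 2, n_views = 4, seed = 1)
net  <- visnet_network(c(64, 64), gabor_bank(), default_layer_specs(), seed = 1)

protocol <- training_protocol(order_policy = "object-grouped-permuted",
                              epochs_per_layer = c(5, 50, 50, 50),
                              trace_reset = "per-object", seed = 1)
trained <- train_network(net, stim, protocol)

report <- evaluate_network(trained$net, stim, scheme = "leave-transforms-out",
                           seed = 1)
report
#> Decoding (leave-transforms-out): 100.0% correct (chance 50.0%), 2 objects
#> Invariant cells: 12; median per-neuron information: 0.000 bits
```

Every one of the 8 images is assigned to the correct object by a
nearest-class-mean decoder fit on the *other* views (100% vs a chance
level of 50%), and 12 Layer-4 neurons respond to every view of exactly
one object and to no view of the other. Retraining the identical
sequence with the trace turned off (`rule = "hebbian"`) leaves decoding
at 50%: image similarity alone cannot solve this task.

The same pipeline is scriptable end-to-end:

```r
cfg <- experiment_config(preset = "cups", seed = 1)
run_experiment(cfg, "out/")   # stimuli, network, logs, report.json
```

or from a shell via the bundled CLI
(`Rscript $(Rscript -e 'cat(system.file("cli/visnet.R", package="visnet"))') run --preset cups --seed 1 --out out/`).
Presets: `translation`, `cups`, `binding`, `ct`, `deformation`,
`curvature`, `clutter`, `flow`.

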
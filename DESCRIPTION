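Package: visnet
Title: Hierarchical Competitive Networks with Trace Learning for Invariant
    Object Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale model of the primate ventral visual stream as a
    four-Layer feedforward hierarchy of competitive networks. Retinal images
    are encoded by a rectified Gabor filter bank (or an optic-flow channel
    for the dorsal-stream variant), each Layer samples afferents from a
    topologically mapped Gaussian neighbourhood of the preceding Layer, and
    competition is implemented by setting the activation threshold so that
    population sparseness reaches a configured target. Synaptic plasticity
    is local: pure Hebbian learning in Layer 1 (feature binding), and a
    short-term-memory trace rule (or its error-correcting variant) in the
    upper Layers, so that transforms of an object seen close together in
    time converge onto the same output neurons. Includes synthetic stimulus
    generators (translation grids, edge combinations, catastrophically
    changing views, deforming objects, curvature classes, clutter and
    occlusion operators), training protocols imposing temporal or spatial
    presentation statistics (including continuous spatial transformation
    learning), and decoding-based invariance evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
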
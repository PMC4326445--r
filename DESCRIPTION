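Package: emgmlp
Title: Predicting Arm Muscle EMG Envelopes from Hand Kinematics and Grip
    Force with Time-Delay Multilayer Perceptrons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting the electromyogram (EMG) envelopes of
    twelve arm muscles from six degree-of-freedom hand kinematics and
    thumb grip force, the signal pathway proposed for deriving muscle
    stimulation templates in upper-limb functional electrical
    stimulation.  Implements the full pipeline: a synthetic session
    generator with known ground-truth muscle activations, zero-phase
    Butterworth conditioning of EMG and kinematic channels (second-order
    sections), MVC normalization, time-delay embedding, a from-scratch
    full-batch momentum-backpropagation multilayer perceptron with tanh
    hidden units and linear outputs, per-muscle squared-correlation
    scoring, and experiment drivers for the loaded/unloaded
    cross-training condition matrix and the network-capacity comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
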
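Package: vibdecode
Title: Speed and Direction Decoding from Trigeminal Brainstem Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for extracellular recordings of trigeminal
    brainstem responses to whisker-array sweeps at multiple speeds and
    directions. Provides a ground-truth synthetic data generator, local field
    potential (LFP) based trial alignment, semi-supervised spike sorting with
    mixture-of-Gaussians clustering and template matching, PSTH contact-window
    estimation, three-factor ANOVA tuning analysis over an LFP filterbank, and
    two shift-invariant maximum-likelihood decoders (Gaussian LFP template
    classifier and binned Bernoulli spike-train classifier) evaluated with
    leave-one-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    mclust,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
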
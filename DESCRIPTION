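Package: octamb
Title: Ambiguity Quantification and Mapping for Retinal Layer Boundaries in OCT
Version: 0.1.0
Authors@R:
    person("octamb", "developers", email = "octamb@users.noreply.github.com",
           role = c("aut", "cre"))
Description: Quantifies how ambiguous the detection of retinal layer
    boundaries is in optical coherence tomography (OCT) B-scans. A compact
    encoder-decoder network with vertical 7x1 convolutions and a
    multiple-dilated-convolution block emits, for every A-scan, a probability
    distribution over the depth of each of six boundaries; the Shannon
    entropy of that distribution is averaged into a per-layer ambiguity
    index, arranged into smoothed, normalized, jet-colorized en-face
    ambiguity maps over a volume, and evaluated against abnormality labels
    with Mann-Whitney U tests and ROC/AUC. Includes a synthetic layered
    retina phantom with ground-truth boundaries and injectable lesions for
    end-to-end validation, plus a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
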
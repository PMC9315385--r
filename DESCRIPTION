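Package: synergylab
Title: Muscle Synergy Analysis of Isometric Knee Extension from Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to analyse surface electromyography (EMG) of isometric
    knee-extension trials and to study the redundancy of muscle synergies.
    The package generates synthetic multichannel EMG sessions with full
    ground truth, localizes contraction trials from summed spectrograms,
    derives per-muscle activation features with a data-driven frequency
    cut-off, drives a simplified planar musculoskeletal knee model with
    Hill-type muscles to measure balancing knee torques, and searches for
    alternative activation patterns that reproduce the same torque with a
    real-valued genetic algorithm.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
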
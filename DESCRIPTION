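Package: cxcompass
Title: Bayesian Motion-Sensitivity Scoring and Compass-Network Modeling
    for Insect Central-Complex Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing visual self-motion responses of insect
    central-complex neurons and for modeling the head-direction compass
    circuit of the protocerebral bridge. Implements a three-hypothesis
    Bayesian comparison of per-bin Bernoulli firing probabilities between
    motion and stationary stimulation phases (with Bayes factors and
    posterior-weighted motion-sensitivity and direction-selectivity
    scores), spike detection and trial binning for intracellular voltage
    recordings, Monte-Carlo power analysis, and an anatomically masked
    linear recurrent network of CL1a and CL2 columnar neurons whose
    connectivity is optimized to maintain a head-direction activity bump
    and to shift it during simulated turns via connectivity modulation.
    Includes generators for synthetic recordings with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
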
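Package: spikelex
Title: Spiking Multi-Area Network Model of Word Learning and Oscillatory
    Brain Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates word learning in a multi-area spiking neural network
    of the left-hemispheric language and sensorimotor cortices. Excitatory
    cells are leaky integrate-and-fire neurons with spike-rate adaptation;
    learning uses a spike-gated, discretised Artola-Broecher-Singer Hebbian
    rule on excitatory-to-excitatory synapses. Cell assemblies for "word"
    stimuli emerge through repeated grounding trials that pair auditory,
    articulatory and semantic (visual or motor) activation patterns. The
    package also provides the accompanying analysis chain: simulated
    event-related potentials, Morlet wavelet time-frequency decomposition
    (total, evoked, induced power), inter-area wavelet coherence, cluster-based
    permutation statistics and peak-amplitude tests, so that word-versus-
    pseudoword gamma-band effects can be reproduced at reduced scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
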
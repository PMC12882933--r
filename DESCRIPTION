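Package: braillesim
Title: Perceptual Similarity Analysis and Simulation for the Braille Alphabet
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the perceptual structure of the 26-letter
    braille alphabet. Encodes the letters as six-dot binary patterns and
    computes dot-level information statistics (binary-entropy
    informativeness, presence/absence cue validity), tests strict linear
    separability of each letter with an exact linear-feasibility oracle and
    a delta-rule perceptron, builds accuracy- and reaction-time-based
    dissimilarity matrices from same-different trial logs (filtering,
    within-participant RT rescaling, symmetry testing with a default-prior
    Bayes factor, symmetrization), performs Ward hierarchical clustering
    with cophenetic and multiscale-bootstrap AU diagnostics, and simulates
    trial-level same-different data with a planted latent similarity
    structure for end-to-end pipeline validation. Ships the published
    26 x 26 accuracy and RT dissimilarity matrices as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, ape
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
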